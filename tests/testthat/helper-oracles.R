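# Independent oracles used against the implementation.

# Per-base brute-force sweep: walks every query position and applies the
# same HSP-assignment rule (higher pident, then higher bitscore, then lower
# qstart) one base at a time.
oracle_merge_hsps <- function(hsps, ref_len) {
  ident_sum <- 0
  covered <- 0L
  for (p in 0:(ref_len - 1L)) {
    covering <- which(hsps$qstart <= p & p < hsps$qend)
    if (length(covering) == 0L) next
    ord <- order(-hsps$pident[covering], -hsps$bitscore[covering],
                 hsps$qstart[covering])
    best <- covering[ord[1L]]
    ident_sum <- ident_sum + hsps$pident[best]
    covered <- covered + 1L
  }
  list(merged_identity = ident_sum / covered,
       merged_coverage = 100 * covered / ref_len,
       covered_bp = covered)
}

random_hsps <- function(n, ref_len) {
  qs <- sample.int(ref_len, n, replace = TRUE) - 1L
  qe <- pmin(ref_len, qs + sample.int(max(2L, ref_len %/% 2L), n,
                                      replace = TRUE))
  qe <- pmax(qe, qs + 1L)
  data.frame(qid = "q", sid = "s",
             pident = round(runif(n, 50, 100), 1),
             alen = qe - qs, mismatch = 0L, gapopen = 0L,
             qstart = qs, qend = qe,
             sstart = qs, send = qe,
             evalue = 0, bitscore = round(runif(n, 10, 500), 1),
             strand = "+", stringsAsFactors = FALSE)
}

# --- set-partition enumeration (restricted growth strings) -----------------

enumerate_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, 0L)
  out
}

# fast unweighted modularity for a membership vector
fast_modularity <- function(memb, ea, eb, deg) {
  m <- length(ea)
  k <- max(memb)
  e_c <- tabulate(memb[ea][memb[ea] == memb[eb]], nbins = k)
  d_c <- vapply(seq_len(k), function(c) sum(deg[memb == c]), numeric(1L))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# exhaustive modularity optimum over all set partitions of the nodes
oracle_best_partition <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  ea <- match(graph$edges$a, nodes)
  eb <- match(graph$edges$b, nodes)
  deg <- tabulate(c(ea, eb), nbins = n)
  best_q <- -Inf
  best <- NULL
  for (memb in enumerate_partitions(n)) {
    q <- fast_modularity(memb, ea, eb, deg)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  list(Q = best_q,
       communities = lapply(split(nodes, best), sort))
}

# --- graph construction helpers --------------------------------------------

pairs_from_edges <- function(a, b, identity = 90, coverage = 90) {
  data.frame(a = pmin(a, b), b = pmax(a, b),
             merged_identity = rep_len(identity, length(a)),
             merged_coverage = rep_len(coverage, length(a)),
             n_hsps = rep_len(1L, length(a)),
             covered_bp = rep_len(100L, length(a)),
             stringsAsFactors = FALSE)
}

ssn_from_edges <- function(nodes, a, b, identity = 90, coverage = 90) {
  build_network(pairs_from_edges(a, b, identity, coverage), nodes)
}

clique_edges <- function(ids) {
  cmb <- t(combn(ids, 2L))
  list(a = cmb[, 1L], b = cmb[, 2L])
}

# union of cliques given as a list of id vectors
clique_union_graph <- function(cliques) {
  ed <- lapply(cliques, clique_edges)
  ssn_from_edges(unlist(cliques),
                 unlist(lapply(ed, `[[`, "a")),
                 unlist(lapply(ed, `[[`, "b")))
}

# Erdos-Renyi graph, resampled until connected
random_connected_graph <- function(n, p = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    cmb <- t(combn(nodes, 2L))
    keep <- runif(nrow(cmb)) < p
    if (!any(keep)) next
    g <- ssn_from_edges(nodes, cmb[keep, 1L], cmb[keep, 2L])
    # connectivity by BFS
    adj <- ripnet:::ssn_adjacency(g)
    seen <- nodes[1L]
    frontier <- nodes[1L]
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == n) return(g)
  }
}

# small wrapper so tests read naturally
ari <- function(x, y) mclust::adjustedRandIndex(x, y)
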