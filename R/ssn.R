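# Sequence similarity network: nodes are TE copies, edges connect pairs
# whose merged identity and coverage clear the thresholds.  Community
# detection is unweighted greedy modularity maximization; edge attributes
# are kept only for centroid tie-breaking.

#' Build a thresholded sequence similarity network
#'
#' An edge is drawn between two copies iff their merged identity and merged
#' coverage both exceed the thresholds. The default thresholds (identity
#' > 80, coverage > 80) are the terminal-repeat settings; internal-region
#' networks use coverage > 70. Thresholds are strict (`>`) by default;
#' `strict = FALSE` switches to `>=`. Isolated nodes are retained.
#'
#' @param pairs Data.frame of pair scores from [score_pairs()].
#' @param nodes Character vector of all node ids (must include every id in
#'   `pairs`).
#' @param min_identity,min_coverage Percent thresholds (defaults 80 and 80).
#' @param strict Logical; `TRUE` uses strict inequality.
#' @param node_attrs Optional data.frame of node attributes with an `id`
#'   column (e.g. length, gc, species, copy_class).
#' @return An object of class `ssn`: a list with elements `nodes` (character
#'   vector), `edges` (data.frame `a, b, merged_identity, merged_coverage,
#'   ...`), `node_attrs`, and the thresholds used.
#' @export
build_network <- function(pairs, nodes, min_identity = 80, min_coverage = 80,
                          strict = TRUE, node_attrs = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (nrow(pairs) > 0L) {
    unknown <- setdiff(unique(c(pairs$a, pairs$b)), nodes)
    if (length(unknown) > 0L) {
      stop("pair references unknown node(s): ", paste(unknown, collapse = ", "))
    }
  }
  keep <- if (strict) {
    pairs$merged_identity > min_identity & pairs$merged_coverage > min_coverage
  } else {
    pairs$merged_identity >= min_identity & pairs$merged_coverage >= min_coverage
  }
  edges <- pairs[which(keep), , drop = FALSE]
  edges <- edges[edges$a != edges$b, , drop = FALSE]  # no self loops
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, node_attrs = node_attrs,
                 min_identity = min_identity, min_coverage = min_coverage,
                 strict = strict),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat("Sequence similarity network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (identity ",
      if (x$strict) "> " else ">= ", x$min_identity,
      ", coverage ", if (x$strict) "> " else ">= ", x$min_coverage, ")\n",
      sep = "")
  invisible(x)
}

# adjacency list of an ssn (named list id -> character vector of neighbours)
ssn_adjacency <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[i]; b <- graph$edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Node degrees of a similarity network
#'
#' @param graph An `ssn` object.
#' @return Named integer vector of degrees, one per node.
#' @export
ssn_degree <- function(graph) {
  deg <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0L) {
    tab <- table(c(graph$edges$a, graph$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Newman modularity of a partition of an unweighted network
#'
#' Q = sum over communities c of (e_c / m - (d_c / 2m)^2), with m the edge
#' count, e_c the number of intra-community edges and d_c the total degree of
#' community c. Undefined for an edgeless graph (`NA` with a warning).
#'
#' @param graph An `ssn` object.
#' @param partition A list of character vectors of node ids, disjoint and
#'   jointly covering the nodes, or a `ssn_partition` object.
#' @return The modularity Q, in `[-0.5, 1]`.
#' @export
modularity_score <- function(graph, partition) {
  if (inherits(partition, "ssn_partition")) partition <- partition$communities
  check_partition(graph$nodes, partition)
  m <- nrow(graph$edges)
  if (m == 0L) {
    warning("modularity is undefined for an edgeless graph")
    return(NA_real_)
  }
  member <- community_membership(partition)
  deg <- ssn_degree(graph)
  ca <- member[graph$edges$a]
  cb <- member[graph$edges$b]
  e_c <- table(factor(ca[ca == cb], levels = seq_along(partition)))
  d_c <- vapply(partition, function(comm) sum(deg[comm]), numeric(1L))
  sum(as.numeric(e_c) / m - (d_c / (2 * m))^2)
}

community_membership <- function(partition) {
  member <- integer(0)
  for (i in seq_along(partition)) {
    member[partition[[i]]] <- i
  }
  member
}

check_partition <- function(nodes, partition) {
  if (any(lengths(partition) == 0L)) stop("empty community in partition")
  all_ids <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("partition communities are not disjoint")
  }
  if (!setequal(all_ids, nodes)) {
    stop("partition does not cover the node set")
  }
  invisible(TRUE)
}

#' Greedy modularity community detection (Clauset-Newman-Moore)
#'
#' Starts from singleton communities and repeatedly merges the connected pair
#' of communities with the largest modularity gain, stopping when no merge
#' increases Q. Only communities joined by at least one edge are merged, so
#' connected components are never split across a merge. Gain ties are broken
#' by the lexicographically smallest community-pair label (a community is
#' labelled by its smallest member id), which makes the partition
#' reproducible across runs. The detection is unweighted.
#'
#' @param graph An `ssn` object (non-empty).
#' @return An object of class `ssn_partition`: list with `communities` (list
#'   of character vectors, ordered by decreasing size then label),
#'   `modularity` (Q of the final partition, `NA` for an edgeless graph) and
#'   `labels` (community labels `"1"`, `"2"`, ... in that order).
#' @export
greedy_modularity_communities <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0L) stop("empty graph")
  m <- nrow(graph$edges)
  if (m == 0L) {
    comms <- as.list(graph$nodes)
    return(new_partition(comms, NA_real_))
  }
  # communities indexed 1..k; track membership, degree sums and
  # inter-community edge counts
  comm_of <- setNames(seq_len(n), graph$nodes)
  members <- as.list(graph$nodes)
  deg <- ssn_degree(graph)
  a_frac <- as.numeric(deg[graph$nodes]) / (2 * m)  # d_c / 2m per community
  # e[i, j]: number of edges between communities i and j (i < j), stored in a
  # named environment-free list keyed "i:j"
  ekey <- function(i, j) paste0(min(i, j), ":", max(i, j))
  e_between <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(m)) {
    i <- comm_of[[graph$edges$a[r]]]
    j <- comm_of[[graph$edges$b[r]]]
    k <- ekey(i, j)
    cur <- if (is.null(e_between[[k]])) 0L else e_between[[k]]
    assign(k, cur + 1L, envir = e_between)
  }
  alive <- rep(TRUE, n)
  label_of <- graph$nodes  # smallest member id per community
  repeat {
    keys <- ls(e_between)
    if (length(keys) == 0L) break
    best_gain <- 0
    best_pair <- NULL
    best_label <- NULL
    for (k in keys) {
      ij <- as.integer(strsplit(k, ":", fixed = TRUE)[[1L]])
      i <- ij[1L]; j <- ij[2L]
      if (!alive[i] || !alive[j]) next
      gain <- e_between[[k]] / m - 2 * a_frac[i] * a_frac[j]
      if (gain <= 0) next
      lab <- sort(c(label_of[i], label_of[j]))
      if (is.null(best_pair) || gain > best_gain + 1e-12 ||
          (abs(gain - best_gain) <= 1e-12 &&
           (lab[1L] < best_label[1L] ||
            (lab[1L] == best_label[1L] && lab[2L] < best_label[2L])))) {
        best_gain <- gain
        best_pair <- c(i, j)
        best_label <- lab
      }
    }
    if (is.null(best_pair)) break
    i <- best_pair[1L]; j <- best_pair[2L]
    # merge j into i
    members[[i]] <- c(members[[i]], members[[j]])
    members[j] <- list(NULL)
    comm_of[members[[i]]] <- i
    a_frac[i] <- a_frac[i] + a_frac[j]
    label_of[i] <- min(label_of[i], label_of[j])
    alive[j] <- FALSE
    # reroute j's inter-community edge counts to i
    for (k in ls(e_between)) {
      ij <- as.integer(strsplit(k, ":", fixed = TRUE)[[1L]])
      if (ij[1L] == j || ij[2L] == j) {
        other <- if (ij[1L] == j) ij[2L] else ij[1L]
        cnt <- e_between[[k]]
        rm(list = k, envir = e_between)
        if (other == i) next  # becomes intra-community
        nk <- ekey(i, other)
        cur <- if (is.null(e_between[[nk]])) 0L else e_between[[nk]]
        assign(nk, cur + cnt, envir = e_between)
      }
    }
  }
  comms <- members[alive]
  comms <- lapply(comms, sort)
  part <- new_partition(comms, NA_real_)
  part$modularity <- modularity_score(graph, part)
  part
}

new_partition <- function(communities, Q) {
  labels_by_min <- vapply(communities, min, character(1L))
  ord <- order(-lengths(communities), labels_by_min)
  communities <- communities[ord]
  structure(list(communities = communities,
                 modularity = Q,
                 labels = as.character(seq_along(communities))),
            class = "ssn_partition")
}

#' @export
print.ssn_partition <- function(x, ...) {
  cat("Partition: ", length(x$communities), " communities (sizes ",
      paste(lengths(x$communities), collapse = ", "), "), Q = ",
      format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Filter out small communities
#'
#' Communities below the minimum size are removed and their members returned
#' as unclassified. With the default rule (`keep_rule = "ge"`) communities
#' with fewer than `min_size` members are dropped, i.e. kept iff size >=
#' `min_size`; `keep_rule = "gt"` keeps only communities strictly larger than
#' `min_size`.
#'
#' @param partition An `ssn_partition` or list of communities.
#' @param min_size Integer size threshold (default 5).
#' @param keep_rule `"ge"` (keep size >= min_size, the default) or `"gt"`
#'   (keep size > min_size).
#' @return A list with `kept` (an `ssn_partition` over the surviving nodes)
#'   and `unclassified` (character vector of dropped members).
#' @export
filter_small_communities <- function(partition, min_size = 5,
                                     keep_rule = c("ge", "gt")) {
  keep_rule <- match.arg(keep_rule)
  comms <- if (inherits(partition, "ssn_partition")) partition$communities
           else partition
  if (length(comms) == 0L) {
    return(list(kept = structure(list(communities = list(),
                                      modularity = NA_real_,
                                      labels = character(0)),
                                 class = "ssn_partition"),
                unclassified = character(0)))
  }
  sizes <- lengths(comms)
  keep <- if (keep_rule == "ge") sizes >= min_size else sizes > min_size
  unclassified <- sort(unlist(comms[!keep], use.names = FALSE))
  kept <- if (any(keep)) new_partition(comms[keep], NA_real_) else
    structure(list(communities = list(), modularity = NA_real_,
                   labels = character(0)), class = "ssn_partition")
  list(kept = kept, unclassified = as.character(unclassified))
}

#' Community centroid (exemplar) of a similarity network community
#'
#' The centroid is the member with the highest degree within the community's
#' induced subgraph, so edges to other communities do not distort the choice.
#' Ties are broken by the largest summed merged identity over incident
#' induced edges, then by lexicographically smallest id.
#'
#' @param graph An `ssn` object.
#' @param community Character vector of member ids (non-empty).
#' @return A single node id.
#' @export
centroid <- function(graph, community) {
  if (length(community) == 0L) stop("empty community")
  community <- as.character(community)
  e <- graph$edges
  induced <- e$a %in% community & e$b %in% community
  e <- e[induced, , drop = FALSE]
  deg <- setNames(integer(length(community)), community)
  idsum <- setNames(numeric(length(community)), community)
  if (nrow(e) > 0L) {
    tab <- table(c(e$a, e$b))
    deg[names(tab)] <- as.integer(tab)
    for (i in seq_len(nrow(e))) {
      idsum[e$a[i]] <- idsum[e$a[i]] + e$merged_identity[i]
      idsum[e$b[i]] <- idsum[e$b[i]] + e$merged_identity[i]
    }
  }
  ord <- order(-deg, -idsum, community)
  community[ord[1L]]
}

#' Export a network as an edge-list TSV and a node table
#'
#' @param graph An `ssn` object.
#' @param edge_path Path for the edge list TSV.
#' @param node_path Optional path for a node table TSV (id plus attributes).
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(graph, edge_path, node_path = NULL) {
  write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(node_path)) {
    nodes <- data.frame(id = graph$nodes, degree = ssn_degree(graph),
                        stringsAsFactors = FALSE)
    if (!is.null(graph$node_attrs)) {
      nodes <- merge(nodes, graph$node_attrs, by = "id", all.x = TRUE,
                     sort = TRUE)
    }
    write.table(nodes, node_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(edge_path)
}
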