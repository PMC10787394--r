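# Forward simulator of an LTR-retrotransposon family under repeat-induced
# point mutation (RIP).  Subfamilies differ in the U3 half of the terminal
# repeat; the rest of the LTR (R + U5, with a fixed TATA-box) and the
# internal region are shared.  Copies transpose with identical paired LTRs
# and a target-site duplication, then per cycle undergo neutral mutation,
# solo-LTR formation, fragmentation, optional nested insertion, and RIP.
#
# Every copy carries a homology map: blocks of its own sequence mapped onto
# a common ancestral coordinate axis (U3 = [0, u3_len), conserved LTR half =
# [u3_len, ltr_len), internal = [ltr_len, ltr_len + internal_len); the 3'
# LTR maps onto the LTR ranges again).  Exact pairwise hits are derived from
# block overlaps, which substitutes for an external all-vs-all search.

BASES <- c("A", "C", "G", "T")

#' Simulator configuration
#'
#' @param n_subfamilies Number of subfamilies (U3 variants).
#' @param copies_per_subfamily Full copies inserted per subfamily.
#' @param ltr_len Terminal repeat length in bp (default 400, the typical
#'   size of the terminal repeats of the element family emulated).
#' @param u3_len Length of the variable U3 half of the LTR in bp
#'   (default 200; must be smaller than `ltr_len`).
#' @param internal_len Internal (coding) region length in bp (default 6600,
#'   so a full element is about 7.4 kb).
#' @param u3_divergence Per-site substitution probability between a
#'   subfamily's U3 block and the ancestral U3 (default 0.5).
#' @param neutral_mut_rate Per-site per-cycle neutral substitution
#'   probability (default 1e-4).
#' @param n_cycles Number of simulation cycles (default 3).
#' @param p_solo Per-cycle probability that a full copy undergoes LTR-LTR
#'   recombination into a solo-LTR (default 0.1).
#' @param p_frag Per-cycle probability that a copy is truncated from one end
#'   (default 0.05).
#' @param p_nested Per-cycle probability that a full copy receives a nested
#'   insertion, splitting it into two fragments around a new copy
#'   (default 0).
#' @param rip_p_cpa Per-site C-to-T probability at CpA sites (and G-to-A at
#'   TpG) per RIP exposure (default 0.05).
#' @param rip_p_other The same probability at other C/G sites (default 0.01;
#'   must not exceed `rip_p_cpa`, as RIP prefers CpA/TpG).
#' @param rip_min_len Minimum copy length for RIP exposure in bp
#'   (default 400, the typical repeat-length requirement).
#' @param rip_min_id Minimum merged percent identity with another copy for
#'   RIP exposure (default 80, the similarity requirement reported for
#'   *N. crassa*).
#' @param tsd_len Target-site-duplication length in bp (default 5).
#' @param genome_len Genome (single contig) length in bp, or `NULL` to size
#'   it automatically from the requested copies.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subfamilies = 3, copies_per_subfamily = 20,
                       ltr_len = 400, u3_len = 200, internal_len = 6600,
                       u3_divergence = 0.5, neutral_mut_rate = 1e-4,
                       n_cycles = 3, p_solo = 0.1, p_frag = 0.05,
                       p_nested = 0, rip_p_cpa = 0.05, rip_p_other = 0.01,
                       rip_min_len = 400, rip_min_id = 80, tsd_len = 5,
                       genome_len = NULL, seed = 1L) {
  cfg <- list(n_subfamilies = as.integer(n_subfamilies),
              copies_per_subfamily = as.integer(copies_per_subfamily),
              ltr_len = as.integer(ltr_len), u3_len = as.integer(u3_len),
              internal_len = as.integer(internal_len),
              u3_divergence = u3_divergence,
              neutral_mut_rate = neutral_mut_rate,
              n_cycles = as.integer(n_cycles),
              p_solo = p_solo, p_frag = p_frag, p_nested = p_nested,
              rip_p_cpa = rip_p_cpa, rip_p_other = rip_p_other,
              rip_min_len = as.integer(rip_min_len), rip_min_id = rip_min_id,
              tsd_len = as.integer(tsd_len),
              genome_len = if (is.null(genome_len)) NULL else
                as.integer(genome_len),
              seed = as.integer(seed))
  probs <- c(cfg$u3_divergence, cfg$neutral_mut_rate, cfg$p_solo, cfg$p_frag,
             cfg$p_nested, cfg$rip_p_cpa, cfg$rip_p_other)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$u3_len >= cfg$ltr_len) stop("u3_len must be smaller than ltr_len")
  if (cfg$rip_p_other > cfg$rip_p_cpa) {
    stop("rip_p_other must not exceed rip_p_cpa")
  }
  if (cfg$n_subfamilies < 1L || cfg$copies_per_subfamily < 1L) {
    stop("need at least one subfamily and one copy")
  }
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) sample(BASES, n, replace = TRUE)

# substitute positions idx to a uniformly chosen different base
substitute_sites <- function(seq, idx) {
  if (length(idx) == 0L) return(seq)
  cur <- seq[idx]
  pick <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), "")
  seq[idx] <- pick
  seq
}

new_copy <- function(seq, blocks, subfamily, class, tsd) {
  list(seq = seq, blocks = blocks, subfamily = subfamily, class = class,
       rip_exposures = 0L, tsd_left = tsd, tsd_right = tsd,
       spacer_before = TRUE)
}

full_copy_blocks <- function(cfg) {
  u3 <- cfg$u3_len; ltr <- cfg$ltr_len; int <- cfg$internal_len
  data.frame(
    copy_start = c(0L, u3, ltr, ltr + int, ltr + int + u3),
    anc_start = c(0L, u3, ltr, 0L, u3),
    len = c(u3, ltr - u3, int, u3, ltr - u3)
  )
}

#' Simulate an LTR-retrotransposon family under RIP
#'
#' Draws one ancestral LTR (variable U3 half followed by a conserved half
#' starting with a fixed TATA-box motif) and one internal region, derives
#' subfamily LTR variants by substituting U3 sites at rate `u3_divergence`,
#' inserts copies with identical paired LTRs and a target-site duplication,
#' then runs `n_cycles` cycles of neutral mutation, solo-LTR formation,
#' fragmentation, optional nested insertion and RIP ([apply_rip()]).
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_result`: list with `genome` (named
#'   character vector of length one), `copies` (truth table: `id, subfamily,
#'   copy_class, contig, start, end, strand, rip_exposures, length, gc`;
#'   coordinates 0-based half-open, ids `contig_start-end` 1-based),
#'   `copy_objs` (internal copy objects with homology blocks, named by id),
#'   and `config`.
#' @export
simulate_family <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  u3 <- cfg$u3_len; ltr <- cfg$ltr_len; int <- cfg$internal_len
  anc_u3 <- rand_seq(u3)
  conserved <- rand_seq(ltr - u3)
  conserved[1:6] <- c("T", "A", "T", "A", "A", "A")  # TATA-box at U3/R border
  internal <- rand_seq(int)
  sub_u3 <- lapply(seq_len(cfg$n_subfamilies), function(k) {
    hit <- which(stats::runif(u3) < cfg$u3_divergence)
    substitute_sites(anc_u3, hit)
  })
  copies <- list()
  for (k in seq_len(cfg$n_subfamilies)) {
    ltr_seq <- c(sub_u3[[k]], conserved)
    for (cc in seq_len(cfg$copies_per_subfamily)) {
      copies[[length(copies) + 1L]] <- new_copy(
        seq = c(ltr_seq, internal, ltr_seq),
        blocks = full_copy_blocks(cfg),
        subfamily = k, class = "full",
        tsd = rand_seq(cfg$tsd_len))
    }
  }
  for (cycle in seq_len(cfg$n_cycles)) {
    # neutral mutation
    copies <- lapply(copies, function(cp) {
      hit <- which(stats::runif(length(cp$seq)) < cfg$neutral_mut_rate)
      cp$seq <- substitute_sites(cp$seq, hit)
      cp
    })
    # solo-LTR formation (full copies only)
    for (i in seq_along(copies)) {
      if (copies[[i]]$class == "full" && stats::runif(1L) < cfg$p_solo) {
        copies[[i]] <- make_solo_ltr(copies[[i]], cfg)
      }
    }
    # fragmentation
    for (i in seq_along(copies)) {
      if (stats::runif(1L) < cfg$p_frag) {
        copies[[i]] <- fragment_copy(copies[[i]])
      }
    }
    # nested insertion: a new copy splits a full host copy
    if (cfg$p_nested > 0) {
      full_idx <- which(vapply(copies, function(cp) cp$class == "full",
                               logical(1L)))
      for (i in full_idx) {
        if (stats::runif(1L) < cfg$p_nested && length(full_idx) > 1L) {
          tmpl <- copies[[sample(setdiff(full_idx, i), 1L)]]
          copies <- insert_nested(copies, host = i, template = tmpl, cfg)
        }
      }
    }
    copies <- apply_rip(copies, cfg)
  }
  assemble_genome(copies, cfg)
}

#' Collapse a full copy into a solo-LTR by LTR-LTR recombination
#'
#' The element is replaced by a single LTR: positions up to a uniform
#' breakpoint come from the 5' LTR and the rest from the 3' LTR, as in
#' ectopic recombination between the two terminal repeats. The target-site
#' duplication is retained. Operates on the simulator's internal copy
#' objects.
#'
#' @param copy A full-copy object from the simulator.
#' @param config The [sim_config()] in effect.
#' @return The solo-LTR copy object (class `"solo"`).
#' @export
make_solo_ltr <- function(copy, config) {
  stopifnot(copy$class == "full")
  ltr <- config$ltr_len; int <- config$internal_len; u3 <- config$u3_len
  b <- sample(0:ltr, 1L)
  from5 <- if (b > 0L) copy$seq[seq_len(b)] else character(0)
  from3 <- if (b < ltr) copy$seq[(ltr + int + b + 1L):(2L * ltr + int)]
           else character(0)
  copy$seq <- c(from5, from3)
  copy$blocks <- data.frame(copy_start = c(0L, u3), anc_start = c(0L, u3),
                            len = c(u3, ltr - u3))
  copy$class <- "solo"
  copy
}

# truncate a copy uniformly from one end; blocks are trimmed accordingly
fragment_copy <- function(copy) {
  len <- length(copy$seq)
  if (len < 2L) return(copy)
  k <- sample(seq_len(len - 1L), 1L)
  if (stats::runif(1L) < 0.5) {
    kept <- c(0L, k)          # keep the left part
    copy$tsd_right <- character(0)
  } else {
    kept <- c(k, len)         # keep the right part
    copy$tsd_left <- character(0)
  }
  copy$seq <- copy$seq[(kept[1L] + 1L):kept[2L]]
  copy$blocks <- trim_blocks(copy$blocks, kept[1L], kept[2L])
  copy$class <- "fragment"
  copy
}

# restrict blocks to copy range [from, to) and rebase copy coordinates
trim_blocks <- function(blocks, from, to) {
  s <- pmax(blocks$copy_start, from)
  e <- pmin(blocks$copy_start + blocks$len, to)
  keep <- s < e
  data.frame(
    copy_start = (s - from)[keep],
    anc_start = (blocks$anc_start + (s - blocks$copy_start))[keep],
    len = (e - s)[keep]
  )
}

# split a full host copy around a newly transposed nested copy
insert_nested <- function(copies, host, template, cfg) {
  h <- copies[[host]]
  len <- length(h$seq)
  pos <- sample(seq_len(len - 1L), 1L)
  left <- h; right <- h
  left$seq <- h$seq[seq_len(pos)]
  left$blocks <- trim_blocks(h$blocks, 0L, pos)
  left$class <- "fragment"; left$tsd_right <- character(0)
  right$seq <- h$seq[(pos + 1L):len]
  right$blocks <- trim_blocks(h$blocks, pos, len)
  right$class <- "fragment"; right$tsd_left <- character(0)
  right$spacer_before <- FALSE
  nested <- new_copy(template$seq, template$blocks, template$subfamily,
                     "nested", rand_seq(cfg$tsd_len))
  nested$spacer_before <- FALSE
  copies[[host]] <- left
  append(copies, list(nested, right), after = host)
}

#' Apply one cycle of RIP to a set of simulated copies
#'
#' A copy is RIP-exposed in a cycle iff it is at least `rip_min_len` long
#' and shares at least `rip_min_id` merged percent identity with at least
#' one other copy; both members of a qualifying pair are mutable. Exposure
#' uses the same merged-identity computation as the classifier
#' ([merge_hsps()]) over the copies' exact homology blocks. Exposed copies
#' mutate C to T with probability `rip_p_cpa` when the next base is A (CpA)
#' and G to A with `rip_p_cpa` when the previous base is T (TpG, the
#' reverse-strand CpA); other C/G sites mutate at `rip_p_other`. RIP only
#' removes C/G, so GC content never increases.
#'
#' @param copies List of simulator copy objects.
#' @param config The [sim_config()] in effect.
#' @return The list of copies after mutation, with `rip_exposures`
#'   incremented on exposed copies.
#' @export
apply_rip <- function(copies, config) {
  n <- length(copies)
  if (n < 2L) return(copies)
  lens <- vapply(copies, function(cp) length(cp$seq), integer(1L))
  candidate <- which(lens >= config$rip_min_len)
  exposed <- rep(FALSE, n)
  id_cache <- new.env(hash = TRUE, parent = emptyenv())
  pair_id <- function(i, j) {
    key <- paste0(min(i, j), ":", max(i, j))
    hit <- id_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- copy_pair_identity(copies[[i]], copies[[j]])
    assign(key, val, envir = id_cache)
    val
  }
  subfam <- vapply(copies, function(cp) cp$subfamily, integer(1L))
  for (i in candidate) {
    partners <- setdiff(seq_len(n), i)
    partners <- partners[order(subfam[partners] != subfam[i])]
    for (j in partners) {
      if (pair_id(i, j) >= config$rip_min_id) {
        exposed[i] <- TRUE
        break
      }
    }
  }
  for (i in which(exposed)) {
    copies[[i]] <- rip_mutate(copies[[i]], config)
  }
  copies
}

# merged identity (percent) between two copies over their homology blocks
copy_pair_identity <- function(x, y) {
  hsps <- block_hsps(x, y, "x", "y")
  if (nrow(hsps) == 0L) return(0)
  merge_hsps(hsps, ref_len = length(x$seq))$merged_identity
}

# exact HSPs between two copies from overlapping ancestral blocks
block_hsps <- function(x, y, xid, yid) {
  rows <- list()
  for (i in seq_len(nrow(x$blocks))) {
    bx <- x$blocks[i, ]
    for (j in seq_len(nrow(y$blocks))) {
      by <- y$blocks[j, ]
      a1 <- max(bx$anc_start, by$anc_start)
      a2 <- min(bx$anc_start + bx$len, by$anc_start + by$len)
      if (a1 >= a2) next
      qs <- bx$copy_start + (a1 - bx$anc_start)
      ss <- by$copy_start + (a1 - by$anc_start)
      L <- a2 - a1
      matches <- sum(x$seq[(qs + 1L):(qs + L)] == y$seq[(ss + 1L):(ss + L)])
      pident <- 100 * matches / L
      rows[[length(rows) + 1L]] <- data.frame(
        qid = xid, sid = yid, pident = pident, alen = L,
        mismatch = L - matches, gapopen = 0L,
        qstart = qs, qend = qs + L, sstart = ss, send = ss + L,
        evalue = 0, bitscore = 2 * L * pident / 100, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(qid = character(0), sid = character(0),
                      pident = numeric(0), alen = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# context-dependent C->T / G->A mutation of one exposed copy
rip_mutate <- function(copy, config) {
  s <- copy$seq
  n <- length(s)
  nxt <- c(s[-1L], "X")
  prv <- c("X", s[-n])
  p <- numeric(n)
  isC <- s == "C"; isG <- s == "G"
  p[isC] <- ifelse(nxt[isC] == "A", config$rip_p_cpa, config$rip_p_other)
  p[isG] <- ifelse(prv[isG] == "T", config$rip_p_cpa, config$rip_p_other)
  hit <- stats::runif(n) < p
  s[hit & isC] <- "T"
  s[hit & isG] <- "A"
  copy$seq <- s
  copy$rip_exposures <- copy$rip_exposures + 1L
  copy
}

# lay the copies out on a single contig with random spacers and TSDs
assemble_genome <- function(copies, cfg) {
  n <- length(copies)
  copy_lens <- vapply(copies, function(cp) length(cp$seq), integer(1L))
  tsd_lens <- vapply(copies, function(cp)
    length(cp$tsd_left) + length(cp$tsd_right), integer(1L))
  n_spacers <- sum(vapply(copies, function(cp) cp$spacer_before,
                          logical(1L))) + 1L
  min_spacer <- 50L
  needed <- sum(copy_lens) + sum(tsd_lens) + n_spacers * min_spacer
  if (is.null(cfg$genome_len)) {
    genome_len <- needed + n_spacers * 250L
  } else {
    genome_len <- cfg$genome_len
    if (genome_len < needed) {
      stop("genome too small for requested copies: need at least ", needed,
           " bp, got ", genome_len)
    }
  }
  extra <- genome_len - needed
  # split the slack over the spacers at random
  cuts <- sort(sample.int(extra + 1L, n_spacers - 1L, replace = TRUE) - 1L)
  extra_per <- diff(c(0L, cuts, extra))
  spacer_lens <- min_spacer + extra_per
  parts <- list()
  pos <- 0L
  spacer_i <- 1L
  truth <- vector("list", n)
  objs <- list()
  contig <- "contig_1"
  for (i in seq_len(n)) {
    cp <- copies[[i]]
    if (cp$spacer_before) {
      sp <- rand_seq(spacer_lens[spacer_i]); spacer_i <- spacer_i + 1L
      parts[[length(parts) + 1L]] <- sp
      pos <- pos + length(sp)
    }
    if (length(cp$tsd_left) > 0L) {
      parts[[length(parts) + 1L]] <- cp$tsd_left
      pos <- pos + length(cp$tsd_left)
    }
    start <- pos
    parts[[length(parts) + 1L]] <- cp$seq
    pos <- pos + length(cp$seq)
    end <- pos
    if (length(cp$tsd_right) > 0L) {
      parts[[length(parts) + 1L]] <- cp$tsd_right
      pos <- pos + length(cp$tsd_right)
    }
    ext <- interval_to_external(start, end)
    id <- format_copy_id(contig, ext$start, ext$end, "+")
    seq_str <- paste(cp$seq, collapse = "")
    truth[[i]] <- data.frame(
      id = id, subfamily = paste0("S", cp$subfamily),
      copy_class = cp$class, contig = contig,
      start = start, end = end, strand = "+",
      rip_exposures = cp$rip_exposures,
      length = length(cp$seq), gc = gc_content(seq_str),
      stringsAsFactors = FALSE)
    objs[[id]] <- cp
  }
  parts[[length(parts) + 1L]] <- rand_seq(spacer_lens[spacer_i])
  genome <- paste(unlist(parts), collapse = "")
  structure(list(
    genome = setNames(genome, contig),
    copies = do.call(rbind, truth),
    copy_objs = objs,
    config = cfg
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated LTR-retrotransposon family: ", nrow(x$copies), " copies (",
      paste(names(table(x$copies$copy_class)),
            table(x$copies$copy_class), sep = "=", collapse = ", "),
      ") in ", x$config$n_subfamilies, " subfamilies; genome ",
      nchar(x$genome), " bp\n", sep = "")
  invisible(x)
}

#' Exact all-vs-all hit table from simulated homology blocks
#'
#' For every pair of copies, emits one HSP per overlapping homologous block
#' pair with the exact per-site identity of the two blocks, in both
#' query/subject directions, in the same canonical form as
#' [read_tabular_hits()] output. Blocks below the emission floor (identity <
#' `min_pident` or length < `min_alen`) are suppressed, emulating the
#' sensitivity of a real local-alignment search.
#'
#' @param sim A `sim_result` or the output of [extract_terminal_repeats()].
#' @param min_pident Emission floor on percent identity (default 50).
#' @param min_alen Emission floor on HSP length in bp (default 30).
#' @return A hits data.frame (internal coordinate convention).
#' @export
truth_hits <- function(sim, min_pident = 50, min_alen = 30) {
  objs <- sim$copy_objs
  ids <- names(objs)
  rows <- list()
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        h <- block_hsps(objs[[i]], objs[[j]], ids[i], ids[j])
        h <- h[h$pident >= min_pident & h$alen >= min_alen, , drop = FALSE]
        if (nrow(h) == 0L) next
        rev <- data.frame(
          qid = h$sid, sid = h$qid, pident = h$pident, alen = h$alen,
          mismatch = h$mismatch, gapopen = h$gapopen,
          qstart = h$sstart, qend = h$send, sstart = h$qstart,
          send = h$qend, evalue = h$evalue, bitscore = h$bitscore,
          strand = h$strand, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- h
        rows[[length(rows) + 1L]] <- rev
      }
    }
  }
  if (length(rows) == 0L) {
    return(block_hsps(list(blocks = data.frame()[0, ], seq = character(0)),
                      list(blocks = data.frame()[0, ], seq = character(0)),
                      "", "")[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the terminal-repeat dataset from a simulation
#'
#' Emulates the curated terminal-repeat copy set used for classification:
#' for each full (or nested) copy the 5' LTR is taken; solo-LTRs are kept
#' whole; fragments contribute their most complete run of LTR-derived
#' blocks (the one retaining the most U3). Mirroring the curation of real
#' datasets, a copy is kept only if the extracted terminal repeat retains an
#' alignable stretch of the variable U3 region (at least `min_u3_overlap`
#' bp): a conserved-half-only remnant matches every subfamily equally and
#' carries no subfamily signal. Ids are `contig_start-end` names of the
#' extracted interval.
#'
#' @param sim A `sim_result`.
#' @param min_u3_overlap Minimum U3 overlap in bp for a copy to enter the
#'   curated set (default 30, the minimum alignable block size).
#' @return A list shaped like a `sim_result` restricted to the terminal
#'   repeats: `copies` (truth table rows with `source_id` linking back),
#'   `copy_objs`, `config`; class `sim_copies`.
#' @export
extract_terminal_repeats <- function(sim, min_u3_overlap = 30) {
  cfg <- sim$config
  ltr <- cfg$ltr_len
  objs <- list()
  truth <- list()
  for (i in seq_len(nrow(sim$copies))) {
    row <- sim$copies[i, ]
    cp <- sim$copy_objs[[row$id]]
    is_ltr_block <- cp$blocks$anc_start < ltr
    if (!any(is_ltr_block)) next
    # maximal contiguous runs of LTR-derived blocks
    runs <- list()
    i <- 1L
    while (i <= nrow(cp$blocks)) {
      if (!is_ltr_block[i]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= nrow(cp$blocks) && is_ltr_block[j + 1L] &&
             cp$blocks$copy_start[j + 1L] ==
               cp$blocks$copy_start[j] + cp$blocks$len[j]) {
        j <- j + 1L
      }
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    u3_of_run <- vapply(runs, function(r) {
      b <- cp$blocks[r[1L]:r[2L], , drop = FALSE]
      sum(pmax(0L, pmin(b$anc_start + b$len, cfg$u3_len) - b$anc_start))
    }, numeric(1L))
    best <- which.max(u3_of_run)
    if (u3_of_run[best] < min_u3_overlap) next
    first <- runs[[best]][1L]
    last <- runs[[best]][2L]
    from <- cp$blocks$copy_start[first]
    to <- cp$blocks$copy_start[last] + cp$blocks$len[last]
    seq <- cp$seq[(from + 1L):to]
    blocks <- trim_blocks(cp$blocks[first:last, , drop = FALSE], from, to)
    start <- row$start + from
    end <- row$start + to
    ext <- interval_to_external(start, end)
    id <- format_copy_id(row$contig, ext$start, ext$end, "+")
    objs[[id]] <- list(seq = seq, blocks = blocks,
                       subfamily = cp$subfamily, class = cp$class,
                       rip_exposures = cp$rip_exposures)
    truth[[length(truth) + 1L]] <- data.frame(
      id = id, source_id = row$id, subfamily = row$subfamily,
      copy_class = row$copy_class, contig = row$contig,
      start = start, end = end, strand = "+",
      rip_exposures = row$rip_exposures,
      length = length(seq), gc = gc_content(paste(seq, collapse = "")),
      stringsAsFactors = FALSE)
  }
  structure(list(copies = do.call(rbind, truth), copy_objs = objs,
                 config = cfg),
            class = "sim_copies")
}

#' Copy sequences of a simulation as a named character vector
#'
#' @param sim A `sim_result` or `sim_copies` object.
#' @return Named character vector of copy sequences.
#' @export
sim_sequences <- function(sim) {
  vapply(sim$copy_objs, function(cp) paste(cp$seq, collapse = ""), "")
}

#' Write simulation outputs to a directory
#'
#' Writes `genome.fa`, `copies.fa` (terminal-repeat or copy FASTA),
#' `truth.tsv`, `hits.tsv` (outfmt-6) and `full_copies.bed`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_fasta(sim_sequences(sim), file.path(dir, "copies.fa"))
  write.table(sim$copies, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_tabular_hits(truth_hits(sim), file.path(dir, "hits.tsv"))
  full <- sim$copies[sim$copies$copy_class %in% c("full", "nested"), ,
                     drop = FALSE]
  write_bed(data.frame(contig = full$contig, start = full$start,
                       end = full$end, name = full$subfamily, score = 0,
                       strand = full$strand, stringsAsFactors = FALSE),
            file.path(dir, "full_copies.bed"))
  invisible(dir)
}
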