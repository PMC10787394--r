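# Per-pair merged identity and coverage over the non-overlapping union of
# HSPs.  RIP-degraded TE copies typically align as several fragmented,
# partially overlapping local hits; taking only the top hit understates both
# identity and coverage, so every HSP contributes, with each covered base
# counted exactly once.

#' Remove self hits and keep one direction per sequence pair
#'
#' All-vs-all searches report each pair in both query/subject directions.
#' Self hits (`qid == sid`) are discarded; for every unordered pair the
#' direction with the larger total bitscore is retained with all of its HSPs
#' and the other direction is dropped entirely. Total-bitscore ties keep the
#' direction whose query id sorts first, so the result is deterministic.
#'
#' @param hits Data.frame of hits as returned by [read_tabular_hits()].
#' @return The cleaned hits data.frame.
#' @export
remove_self_and_reciprocal <- function(hits) {
  hits <- hits[hits$qid != hits$sid, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  dir_key <- paste(hits$qid, hits$sid, sep = "\r")
  total <- tapply(hits$bitscore, dir_key, sum)
  dirs <- do.call(rbind, strsplit(names(total), "\r", fixed = TRUE))
  a <- pmin(dirs[, 1L], dirs[, 2L])
  b <- pmax(dirs[, 1L], dirs[, 2L])
  pair_key <- paste(a, b, sep = "\r")
  keep_dir <- vapply(split(seq_along(total), pair_key), function(idx) {
    ord <- order(-total[idx], dirs[idx, 1L], dirs[idx, 2L])
    names(total)[idx[ord[1L]]]
  }, character(1L))
  hits[dir_key %in% keep_dir, , drop = FALSE]
}

#' Merge the HSPs of one directed pair into a single identity and coverage
#'
#' Projects all HSPs of one (query, subject) pair onto query coordinates and
#' resolves overlaps by assigning every overlapped base to the HSP with the
#' higher percent identity (ties: higher bitscore, then lower query start),
#' so each covered base is counted exactly once. The merged identity is the
#' coverage-weighted mean of HSP identities over their assigned bases; the
#' merged coverage is the interval-union length over `ref_len`.
#'
#' @param hsps Data.frame of hits sharing one `(qid, sid)` pair
#'   (internal 0-based half-open query coordinates).
#' @param ref_len Reference length in bp (by default the query length).
#' @return A one-row data.frame with columns `a, b` (the pair, sorted),
#'   `merged_identity`, `merged_coverage`, `n_hsps`, `covered_bp`.
#' @export
merge_hsps <- function(hsps, ref_len) {
  if (nrow(hsps) == 0L) stop("merge_hsps: empty HSP list")
  if (length(unique(hsps$qid)) != 1L || length(unique(hsps$sid)) != 1L) {
    stop("merge_hsps: HSPs from more than one (query, subject) pair")
  }
  stopifnot(is.numeric(ref_len), ref_len > 0)
  # priority order: the assignment rule as a stable sort
  ord <- order(-hsps$pident, -hsps$bitscore, hsps$qstart)
  hsps <- hsps[ord, , drop = FALSE]
  assigned <- numeric(nrow(hsps))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(hsps))) {
    assigned[i] <- interval_difference_length(
      hsps$qstart[i], hsps$qend[i], taken_start, taken_end)
    taken_start <- c(taken_start, hsps$qstart[i])
    taken_end <- c(taken_end, hsps$qend[i])
  }
  covered <- sum(assigned)
  data.frame(
    a = min(hsps$qid[1L], hsps$sid[1L]),
    b = max(hsps$qid[1L], hsps$sid[1L]),
    merged_identity = sum(hsps$pident * assigned) / covered,
    merged_coverage = 100 * covered / ref_len,
    n_hsps = nrow(hsps),
    covered_bp = as.integer(covered),
    stringsAsFactors = FALSE
  )
}

# Length of [start, end) minus the union of [starts_i, ends_i).
interval_difference_length <- function(start, end, starts, ends) {
  if (length(starts) == 0L) return(end - start)
  s <- pmax(starts, start)
  e <- pmin(ends, end)
  keep <- s < e
  if (!any(keep)) return(end - start)
  s <- s[keep]; e <- e[keep]
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  # merge the clipped intervals, subtract their total length
  merged_len <- 0L
  cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      merged_len <- merged_len + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  merged_len <- merged_len + (cur_e - cur_s)
  (end - start) - merged_len
}

#' Compute merged pair scores for a cleaned hit table
#'
#' Groups hits by directed pair (after [remove_self_and_reciprocal()]) and
#' merges each group with [merge_hsps()]. The coverage denominator is, by
#' default, the query length of the retained direction; `coverage_ref` can
#' instead select the shorter or longer sequence of the pair.
#'
#' @param hits Cleaned hits data.frame (one direction per pair).
#' @param lengths Named integer vector mapping sequence id to length in bp.
#' @param coverage_ref One of `"query"`, `"shorter"`, `"longer"`.
#' @return A data.frame of pair scores sorted by `(a, b)`.
#' @export
score_pairs <- function(hits, lengths,
                        coverage_ref = c("query", "shorter", "longer")) {
  coverage_ref <- match.arg(coverage_ref)
  if (nrow(hits) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      merged_identity = numeric(0),
                      merged_coverage = numeric(0),
                      n_hsps = integer(0), covered_bp = integer(0),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(c(hits$qid, hits$sid))
  missing <- setdiff(ids, names(lengths))
  if (length(missing) > 0L) {
    stop("sequence id missing from lengths: ",
         paste(missing, collapse = ", "))
  }
  key <- paste(hits$qid, hits$sid, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  rows <- lapply(groups, function(idx) {
    g <- hits[idx, , drop = FALSE]
    ref_len <- switch(coverage_ref,
      query = lengths[[g$qid[1L]]],
      shorter = min(lengths[[g$qid[1L]]], lengths[[g$sid[1L]]]),
      longer = max(lengths[[g$qid[1L]]], lengths[[g$sid[1L]]]))
    merge_hsps(g, ref_len)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pair-score table as TSV
#'
#' @param pairs Data.frame from [score_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
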