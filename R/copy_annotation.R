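# Copy-retrieval and RepeatMasker post-processing: merge genome hits into
# haplotypes, decide whether a terminal-repeat occurrence is part of a full
# element (5' or 3' end), a nested insertion, or a solo/fragment copy, and
# aggregate per-species per-subfamily counts.

#' Merge genome hits into haplotype intervals with flank extension
#'
#' Hits on the same contig and strand whose gaps are at most `merge_gap` are
#' merged into one haplotype. Haplotypes shorter than `min_size` are
#' dropped; survivors are extended by `flank` bp on each side and clipped at
#' the contig ends. The defaults (`min_size` 4000, `flank` 2000) are the
#' internal-region retrieval settings for an element whose internal region is
#' several kb.
#'
#' @param hits Data.frame of query-vs-genome hits (as from
#'   [read_tabular_hits()]; the subject is the genome, so `sid` is the
#'   contig and `sstart`/`send` the genomic coordinates, 0-based half-open).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param min_size Minimum merged haplotype length in bp (default 4000).
#' @param flank Extension in bp on each side (default 2000).
#' @param merge_gap Maximum gap between hits to merge, in bp (default 1000).
#' @return A data.frame of intervals `contig, start, end, strand` (0-based
#'   half-open), sorted by contig and start.
#' @export
merge_hits_to_haplotypes <- function(hits, contig_lengths,
                                     min_size = 4000, flank = 2000,
                                     merge_gap = 1000) {
  if (min_size < 0 || flank < 0 || merge_gap < 0) {
    stop("min_size, flank and merge_gap must be non-negative")
  }
  if (nrow(hits) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(unique(hits$sid), names(contig_lengths))
  if (length(missing) > 0L) {
    stop("contig missing from contig_lengths: ",
         paste(missing, collapse = ", "))
  }
  groups <- split(seq_len(nrow(hits)), paste(hits$sid, hits$strand, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    g <- hits[idx, , drop = FALSE]
    ord <- order(g$sstart, g$send)
    s <- g$sstart[ord]; e <- g$send[ord]
    ms <- s[1L]; me <- e[1L]
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_along(s)[-1L]) {
      if (s[i] - me <= merge_gap) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    data.frame(contig = g$sid[1L], start = out_s, end = out_e,
               strand = g$strand[1L], stringsAsFactors = FALSE)
  })
  hap <- do.call(rbind, rows)
  hap <- hap[hap$end - hap$start >= min_size, , drop = FALSE]
  if (nrow(hap) > 0L) {
    L <- contig_lengths[hap$contig]
    hap$start <- pmax(0L, hap$start - as.integer(flank))
    hap$end <- pmin(as.integer(L), hap$end + as.integer(flank))
  }
  hap <- hap[order(hap$contig, hap$start), , drop = FALSE]
  rownames(hap) <- NULL
  hap
}

#' Build a full-copy annotation table
#'
#' A full copy is an element with two terminal repeats flanking an internal
#' region. Given the element interval and the two LTR lengths, this derives
#' the 5' LTR, 3' LTR and internal intervals. All coordinates are 0-based
#' half-open; `ltr5` is the left-hand LTR regardless of strand ("5'" and
#' "3'" columns follow element orientation, see [select_5prime_ltr()]).
#'
#' @param contig,start,end,strand Element coordinates.
#' @param ltr_left_len,ltr_right_len Lengths of the left and right terminal
#'   repeats in bp.
#' @param ltr_left_label,ltr_right_label Optional subfamily labels of the
#'   two terminal repeats.
#' @param element_id Optional element identifiers; defaults to
#'   `contig_start-end` names (1-based inclusive).
#' @return A data.frame with one row per element: `element_id, contig, start,
#'   end, strand, ltr_left_start, ltr_left_end, ltr_right_start,
#'   ltr_right_end, internal_start, internal_end, ltr_left_label,
#'   ltr_right_label`.
#' @export
full_copy_table <- function(contig, start, end, strand = "+",
                            ltr_left_len, ltr_right_len = ltr_left_len,
                            ltr_left_label = NA_character_,
                            ltr_right_label = NA_character_,
                            element_id = NULL) {
  n <- length(contig)
  stopifnot(all(start < end),
            all(start + ltr_left_len + ltr_right_len < end))
  if (is.null(element_id)) {
    ext <- interval_to_external(start, end)
    element_id <- format_copy_id(contig, ext$start, ext$end, strand)
  }
  data.frame(
    element_id = element_id, contig = contig,
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n),
    ltr_left_start = as.integer(start),
    ltr_left_end = as.integer(start + ltr_left_len),
    ltr_right_start = as.integer(end - ltr_right_len),
    ltr_right_end = as.integer(end),
    internal_start = as.integer(start + ltr_left_len),
    internal_end = as.integer(end - ltr_right_len),
    ltr_left_label = rep_len(ltr_left_label, n),
    ltr_right_label = rep_len(ltr_right_label, n),
    stringsAsFactors = FALSE
  )
}

overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

#' Classify the genomic context of a terminal-repeat occurrence
#'
#' A hit overlapping an element end (within `end_tolerance` bp) is a
#' full-copy LTR (`FULL_5P` for the left end, `FULL_3P` for the right); a
#' hit overlapping only the internal region is a nested copy (`NESTED`); a
#' hit overlapping no full copy is `SOLO_FRAGMENT`. A hit overlapping both
#' ends of one element spans the whole element and is flagged for curation
#' (an error).
#'
#' @param ltr A one-row data.frame or list with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param full_copies Full-copy table from [full_copy_table()].
#' @param end_tolerance Slack in bp around the element ends (default 10).
#' @return One of `"FULL_5P"`, `"FULL_3P"`, `"NESTED"`, `"SOLO_FRAGMENT"`.
#' @export
classify_copy_context <- function(ltr, full_copies, end_tolerance = 10) {
  if (nrow(full_copies) == 0L) return("SOLO_FRAGMENT")
  fc <- full_copies[full_copies$contig == ltr$contig, , drop = FALSE]
  if (nrow(fc) == 0L) return("SOLO_FRAGMENT")
  tol <- end_tolerance
  # an "end" is the element boundary position widened by the tolerance
  hit5 <- overlaps(ltr$start, ltr$end, fc$start - tol, fc$start + tol + 1L)
  hit3 <- overlaps(ltr$start, ltr$end, fc$end - tol - 1L, fc$end + tol)
  if (any(hit5 & hit3)) {
    stop("terminal-repeat hit spans both ends of element ",
         fc$element_id[which(hit5 & hit3)[1L]], "; flagged for curation")
  }
  if (any(hit5)) return("FULL_5P")
  if (any(hit3)) return("FULL_3P")
  nested <- overlaps(ltr$start, ltr$end, fc$internal_start, fc$internal_end)
  if (any(nested)) return("NESTED")
  "SOLO_FRAGMENT"
}

#' Post-process RepeatMasker hits into per-species subfamily counts
#'
#' Applies the four post-processing rules to a RepeatMasker annotation made
#' with a library of subfamily exemplars:
#' (1) drop hits whose genomic span is not longer than `min_len` (by default
#' 250 bp, so only hits extending into the variable U3 region are counted);
#' (2) assign each survivor a copy context against the full-copy
#' annotation ([classify_copy_context()]);
#' (3) drop putative solo-LTRs that overlap a curated full-copy-boundary
#' terminal repeat (any overlap of 1 bp or more);
#' (4) count the remainder per species and subfamily, split into full-copy
#' LTRs, solo/fragment copies and nested copies.
#'
#' @param rm_hits Data.frame from [read_repeatmasker_out()].
#' @param full_copies Full-copy table from [full_copy_table()].
#' @param curated_ltrs Optional data.frame of curated terminal-repeat
#'   intervals at full-copy boundaries (`contig, start, end`, 0-based
#'   half-open), used by rule (3).
#' @param species Species tag for this annotation file.
#' @param min_len Span threshold in bp, strict (default 250).
#' @param end_tolerance Passed to [classify_copy_context()].
#' @return A list with `counts` (data.frame `species, subfamily, full,
#'   solo_fragment, nested`), `hits` (the per-hit table with a `context` or
#'   drop-reason column `fate`), and `dropped` (named integer vector with
#'   counts for `short` and `boundary_overlap`).
#' @export
postprocess_repeatmasker <- function(rm_hits, full_copies,
                                     curated_ltrs = NULL, species = "unknown",
                                     min_len = 250, end_tolerance = 10) {
  n <- nrow(rm_hits)
  fate <- character(n)
  span <- rm_hits$end - rm_hits$begin
  fate[span <= min_len] <- "dropped_short"
  for (i in which(fate == "")) {
    ctx <- classify_copy_context(
      list(contig = rm_hits$contig[i], start = rm_hits$begin[i],
           end = rm_hits$end[i]),
      full_copies, end_tolerance = end_tolerance)
    fate[i] <- ctx
  }
  if (!is.null(curated_ltrs) && nrow(curated_ltrs) > 0L) {
    for (i in which(fate == "SOLO_FRAGMENT")) {
      cl <- curated_ltrs[curated_ltrs$contig == rm_hits$contig[i], ,
                         drop = FALSE]
      if (nrow(cl) > 0L &&
          any(overlaps(rm_hits$begin[i], rm_hits$end[i], cl$start, cl$end))) {
        fate[i] <- "dropped_boundary_overlap"
      }
    }
  }
  hits <- cbind(rm_hits, fate = fate, stringsAsFactors = FALSE)
  counted <- fate %in% c("FULL_5P", "FULL_3P", "NESTED", "SOLO_FRAGMENT")
  subfam <- sort(unique(rm_hits$repeat_name))
  counts <- data.frame(species = rep_len(species, length(subfam)),
                       subfamily = subfam,
                       full = integer(length(subfam)),
                       solo_fragment = integer(length(subfam)),
                       nested = integer(length(subfam)),
                       stringsAsFactors = FALSE)
  for (i in which(counted)) {
    r <- match(rm_hits$repeat_name[i], subfam)
    col <- switch(fate[i],
                  FULL_5P = "full", FULL_3P = "full",
                  NESTED = "nested", SOLO_FRAGMENT = "solo_fragment")
    counts[r, col] <- counts[r, col] + 1L
  }
  dropped <- c(short = sum(fate == "dropped_short"),
               boundary_overlap = sum(fate == "dropped_boundary_overlap"))
  list(counts = counts, hits = hits, dropped = dropped)
}

#' Flag full copies whose two terminal repeats belong to different
#' subfamilies
#'
#' After transposition the two LTRs of a copy are identical, so disparate
#' 5'/3' subfamily labels indicate gene conversion or ectopic recombination.
#' Elements missing either label are skipped with a warning.
#'
#' @param full_copies Full-copy table with `ltr_left_label` and
#'   `ltr_right_label` filled in.
#' @return Character vector of flagged `element_id`s.
#' @export
flag_disparate_ltrs <- function(full_copies) {
  has_both <- !is.na(full_copies$ltr_left_label) &
    !is.na(full_copies$ltr_right_label)
  if (any(!has_both)) {
    warning(sum(!has_both), " element(s) skipped: missing LTR label")
  }
  fc <- full_copies[has_both, , drop = FALSE]
  fc$element_id[fc$ltr_left_label != fc$ltr_right_label]
}

#' Select the 5' terminal repeat of each full copy
#'
#' The 5' LTR of a newly inserted copy is synthesized from the 3' LTR
#' template, so the two start identical and only one per element is kept for
#' classification. On plus-strand elements the 5' LTR is the left-hand
#' interval; on minus-strand elements it is the right-hand one.
#'
#' @param full_copies Full-copy table from [full_copy_table()].
#' @return A data.frame `element_id, id, contig, start, end, strand` with one
#'   row per element; `id` is the `contig_start-end` name of the selected
#'   LTR interval.
#' @export
select_5prime_ltr <- function(full_copies) {
  left <- full_copies$strand != "-"
  start <- ifelse(left, full_copies$ltr_left_start,
                  full_copies$ltr_right_start)
  end <- ifelse(left, full_copies$ltr_left_end, full_copies$ltr_right_end)
  ext <- interval_to_external(start, end)
  data.frame(
    element_id = full_copies$element_id,
    id = format_copy_id(full_copies$contig, ext$start, ext$end,
                        full_copies$strand),
    contig = full_copies$contig,
    start = as.integer(start), end = as.integer(end),
    strand = full_copies$strand,
    stringsAsFactors = FALSE
  )
}
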