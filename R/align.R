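# Optional end-to-end path without an external search: iterated
# Smith-Waterman local alignment with affine gaps.  Each round reports the
# optimal local alignment as one HSP, then masks its query interval with N
# (which scores negatively against every base) and realigns, so secondary
# HSPs in other regions are recovered.

#' Local alignment of two sequences into HSPs
#'
#' Smith-Waterman local alignment with affine gap penalties (defaults:
#' match +1, mismatch -2, gap open 5, gap extend 2), iterated by masking the
#' query interval of each reported HSP. Both strands of `b` are searched.
#' Percent identity is computed over aligned columns. Alignments scoring
#' below `min_score` are not reported.
#'
#' @param a,b Sequences (single strings) or single-element named character
#'   vectors; names become the query/subject ids (defaults `"a"`, `"b"`).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param min_score Score floor below which HSPs are discarded (default 25).
#' @param max_hsps Maximum HSPs reported per strand (default 10).
#' @return A hits data.frame in the same canonical form as
#'   [read_tabular_hits()] output (0-based half-open, strand column).
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2, min_score = 25, max_hsps = 10) {
  qid <- if (!is.null(names(a))) names(a)[1L] else "a"
  sid <- if (!is.null(names(b))) names(b)[1L] else "b"
  a <- toupper(unname(a[1L])); b <- toupper(unname(b[1L]))
  stopifnot(nchar(a) <= 20000, nchar(b) <= 20000)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  align_one_strand <- function(subject, strand) {
    query <- a
    out <- list()
    slen <- nchar(subject)
    for (k in seq_len(max_hsps)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(query), Biostrings::DNAString(subject),
        type = "local", substitutionMatrix = submat,
        gapOpening = gap_open, gapExtension = gap_extend)
      if (Biostrings::score(aln) < min_score) break
      qs <- Biostrings::start(Biostrings::pattern(aln))
      qe <- Biostrings::end(Biostrings::pattern(aln))
      ss <- Biostrings::start(Biostrings::subject(aln))
      se <- Biostrings::end(Biostrings::subject(aln))
      ncol_aln <- Biostrings::nchar(aln)
      nmat <- Biostrings::nmatch(aln)
      if (strand == "-") {
        tmp <- c(slen - se + 1L, slen - ss + 1L)
        ss <- tmp[1L]; se <- tmp[2L]
      }
      out[[k]] <- data.frame(
        qid = qid, sid = sid,
        pident = 100 * nmat / ncol_aln,
        alen = ncol_aln, mismatch = ncol_aln - nmat,
        gapopen = lengths(regmatches(
          as.character(aln), gregexpr("-+", as.character(aln)))),
        qstart = qs - 1L, qend = qe,
        sstart = ss - 1L, send = se,
        evalue = 0, bitscore = Biostrings::score(aln), strand = strand,
        stringsAsFactors = FALSE)
      # mask the reported query interval and realign
      substr(query, qs, qe) <- strrep("N", qe - qs + 1L)
    }
    out
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rows <- c(align_one_strand(b, "+"), align_one_strand(rc, "-"))
  if (length(rows) == 0L) {
    return(data.frame(qid = character(0), sid = character(0),
                      pident = numeric(0), alen = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
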