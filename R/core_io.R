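#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based, half-open [start, end), explicit
# strand.  BLAST tabular and RepeatMasker .out (1-based, inclusive) are
# converted at the file boundary and back on output.

#' Convert 1-based inclusive coordinates to the internal convention
#'
#' Internally all intervals are 0-based and half-open. File formats that use
#' 1-based inclusive coordinates (BLAST tabular, RepeatMasker) are converted
#' on input with this helper and back with [interval_to_external()].
#'
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @return A list with elements `start` and `end` (0-based half-open).
#' @seealso [interval_to_external()]
#' @export
interval_to_internal <- function(start, end) {
  stopifnot(all(start >= 1L), all(start <= end))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#'
#' @param start,end Integer vectors, 0-based half-open, `start < end`.
#' @return A list with elements `start` and `end` (1-based inclusive).
#' @export
interval_to_external <- function(start, end) {
  stopifnot(all(start >= 0L), all(start < end))
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Read a FASTA file of TE copy sequences
#'
#' Sequences are uppercased and line wraps removed. Identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the identifiers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(ids == "")) {
    stop("malformed FASTA header (empty id) in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in columns (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse a "contig_start-end" copy identifier
#'
#' Copy names encode genomic provenance as `contig_start-end` with 1-based
#' inclusive positions. The contig is everything left of the rightmost
#' underscore (contig names themselves may contain underscores). Identifiers
#' with `start > end` denote minus-orientation copies and are normalized so
#' `start < end` with strand `-`. `start == end` is rejected: after conversion
#' to the internal half-open convention it would be a zero-length interval.
#'
#' @param id Character vector of copy identifiers.
#' @return A data.frame with columns `id`, `contig`, `start`, `end`
#'   (1-based inclusive as in the name, normalized so start < end) and
#'   `strand`.
#' @examples
#' parse_copy_id("chr1_100-500")
#' parse_copy_id("scaf_2_300-250")  # minus orientation
#' @export
parse_copy_id <- function(id) {
  m <- regexpr("_([0-9]+)-([0-9]+)$", id)
  if (any(m < 0)) {
    stop("copy id without parsable '_start-end' suffix: ",
         paste(id[m < 0], collapse = ", "))
  }
  suffix <- substring(id, m + 1L)
  contig <- substring(id, 1L, m - 1L)
  parts <- strsplit(suffix, "-", fixed = TRUE)
  start <- as.integer(vapply(parts, `[`, "", 1L))
  end <- as.integer(vapply(parts, `[`, "", 2L))
  if (any(start == end)) {
    stop("degenerate interval (start == end) in copy id: ",
         paste(id[start == end], collapse = ", "))
  }
  strand <- ifelse(start > end, "-", "+")
  s <- pmin(start, end)
  e <- pmax(start, end)
  data.frame(id = id, contig = contig, start = s, end = e, strand = strand,
             stringsAsFactors = FALSE)
}

#' Format copy identifiers from coordinates
#'
#' Inverse of [parse_copy_id()]: builds `contig_start-end` names from 1-based
#' inclusive coordinates; minus-strand copies are written with start and end
#' swapped.
#'
#' @param contig,start,end,strand Vectors describing the copies.
#' @return Character vector of identifiers.
#' @export
format_copy_id <- function(contig, start, end, strand = "+") {
  ifelse(strand == "-",
         paste0(contig, "_", end, "-", start),
         paste0(contig, "_", start, "-", end))
}

#' Read all-vs-all hits in BLAST tabular (outfmt 6) format
#'
#' Expects the 12-column dialect `qid sid pident alen mismatch gapopen qstart
#' qend sstart send evalue bitscore`. Strand is inferred from the subject
#' coordinate order (`sstart > send` means minus strand) and subject
#' coordinates are canonicalized so `sstart <= send`. Query and subject
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a tab-separated hits file (no header).
#' @return A data.frame of hits with columns `qid, sid, pident, alen,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore, strand`;
#'   coordinates 0-based half-open.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  cols <- c("qid", "sid", "pident", "alen", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), 12L), cols))
    out$qid <- character(0); out$sid <- character(0)
    out$strand <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("expected 12 tab-separated columns, got ", nf[bad],
         " at line ", bad, " of ", path)
  }
  mat <- do.call(rbind, fields)
  hits <- data.frame(
    qid = mat[, 1L], sid = mat[, 2L],
    pident = as.numeric(mat[, 3L]), alen = as.integer(mat[, 4L]),
    mismatch = as.integer(mat[, 5L]), gapopen = as.integer(mat[, 6L]),
    qstart = as.integer(mat[, 7L]), qend = as.integer(mat[, 8L]),
    sstart = as.integer(mat[, 9L]), send = as.integer(mat[, 10L]),
    evalue = as.numeric(mat[, 11L]), bitscore = as.numeric(mat[, 12L]),
    stringsAsFactors = FALSE
  )
  canonicalize_hits(hits)
}

# Infer strand from subject coordinate order and convert both coordinate
# pairs to 0-based half-open.  Accepts a data.frame in external (1-based
# inclusive) convention.
canonicalize_hits <- function(hits) {
  stopifnot(all(hits$qstart <= hits$qend))
  minus <- hits$sstart > hits$send
  hits$strand <- ifelse(minus, "-", "+")
  s1 <- pmin(hits$sstart, hits$send)
  s2 <- pmax(hits$sstart, hits$send)
  q <- interval_to_internal(hits$qstart, hits$qend)
  s <- interval_to_internal(s1, s2)
  hits$qstart <- q$start; hits$qend <- q$end
  hits$sstart <- s$start; hits$send <- s$end
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("percent identity outside [0, 100]")
  }
  hits
}

#' Write hits in BLAST tabular (outfmt 6) format
#'
#' Converts internal coordinates back to 1-based inclusive and encodes minus
#' strand by swapping the subject coordinates, so the output round-trips
#' through [read_tabular_hits()].
#'
#' @param hits Data.frame as returned by [read_tabular_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  q <- interval_to_external(hits$qstart, hits$qend)
  s <- interval_to_external(hits$sstart, hits$send)
  minus <- hits$strand == "-"
  out <- data.frame(
    hits$qid, hits$sid, hits$pident, hits$alen, hits$mismatch, hits$gapopen,
    q$start, q$end,
    ifelse(minus, s$end, s$start), ifelse(minus, s$start, s$end),
    hits$evalue, hits$bitscore
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard whitespace-delimited .out layout (score, divergence,
#' deletion, insertion percentages, query contig and coordinates, strand,
#' repeat name and class, repeat coordinates, hit id). The usual 3-line
#' header is skipped if present and its absence tolerated with a warning.
#' Strand `C` (complement) is mapped to `-`; a trailing `*` overlap flag is
#' tolerated. Genomic coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a RepeatMasker .out file.
#' @return A data.frame with columns `score, divergence, deletion, insertion,
#'   contig, begin, end, left, strand, repeat_name, repeat_class, rep_begin,
#'   rep_end, rep_left, hit_id` (begin/end 0-based half-open).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- grepl("^\\s*(SW|score|perc)", lines)
  if (!any(is_header[seq_len(min(3L, length(lines)))])) {
    warning("no RepeatMasker header detected in ", path,
            "; parsing all lines as hits")
  }
  body <- lines[!is_header]
  if (length(body) == 0L) {
    return(data.frame(score = integer(0), divergence = numeric(0),
                      deletion = numeric(0), insertion = numeric(0),
                      contig = character(0), begin = integer(0),
                      end = integer(0), left = character(0),
                      strand = character(0), repeat_name = character(0),
                      repeat_class = character(0), rep_begin = integer(0),
                      rep_end = integer(0), rep_left = integer(0),
                      hit_id = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    bad <- which(nf < 15L)[1L]
    stop("truncated RepeatMasker row (", nf[bad], " fields) at line ",
         which(lines == body[bad])[1L], " of ", path)
  }
  mat <- t(vapply(fields, function(f) f[1:15], character(15L)))
  score <- suppressWarnings(as.integer(mat[, 1L]))
  if (anyNA(score)) {
    stop("non-numeric score in RepeatMasker row at data line ",
         which(is.na(score))[1L], " of ", path)
  }
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  strand <- mat[, 9L]
  if (!all(strand %in% c("+", "C", "-"))) {
    stop("unexpected strand symbol in ", path, ": ",
         paste(setdiff(unique(strand), c("+", "C", "-")), collapse = ", "))
  }
  strand[strand == "C"] <- "-"
  # On the C strand RepeatMasker prints repeat coordinates as (left) end begin
  rb <- ifelse(strand == "-", strip_paren(mat[, 14L]), strip_paren(mat[, 12L]))
  re <- ifelse(strand == "-", strip_paren(mat[, 13L]), strip_paren(mat[, 13L]))
  rl <- ifelse(strand == "-", strip_paren(mat[, 12L]), strip_paren(mat[, 14L]))
  g <- interval_to_internal(as.integer(mat[, 6L]), as.integer(mat[, 7L]))
  data.frame(
    score = score,
    divergence = as.numeric(mat[, 2L]),
    deletion = as.numeric(mat[, 3L]),
    insertion = as.numeric(mat[, 4L]),
    contig = mat[, 5L],
    begin = g$start, end = g$end,
    left = mat[, 8L],
    strand = strand,
    repeat_name = mat[, 10L],
    repeat_class = mat[, 11L],
    rep_begin = rb, rep_end = re, rep_left = rl,
    hit_id = as.integer(mat[, 15L]),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are taken as-is. Three to six columns are accepted.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `contig, start, end` and, when present,
#'   `name, score, strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3L) stop("BED rows need at least 3 columns in ", path)
  nf <- min(6L, nf)
  mat <- t(vapply(fields, function(f) f[seq_len(nf)], character(nf)))
  out <- data.frame(contig = mat[, 1L],
                    start = as.integer(mat[, 2L]),
                    end = as.integer(mat[, 3L]),
                    stringsAsFactors = FALSE)
  if (nf >= 4L) out$name <- mat[, 4L]
  if (nf >= 5L) out$score <- suppressWarnings(as.numeric(mat[, 5L]))
  if (nf >= 6L) out$strand <- mat[, 6L]
  if (any(out$start < 0L | out$start >= out$end)) {
    stop("invalid BED interval (need 0 <= start < end) in ", path)
  }
  out
}

#' Write intervals to BED
#'
#' @param intervals Data.frame with columns `contig, start, end` and
#'   optionally `name, score, strand` (coordinates 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("contig", "start", "end")
  opt <- c("name", "score", "strand")
  present <- opt[opt %in% names(intervals)]
  # BED columns are positional: fill gaps with placeholders
  out <- intervals[, cols, drop = FALSE]
  if (length(present) > 0L) {
    need <- opt[seq_len(max(match(present, opt)))]
    for (cn in need) {
      out[[cn]] <- if (cn %in% names(intervals)) intervals[[cn]] else
        switch(cn, name = ".", score = 0, strand = ".")
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny in newick format
#'
#' Thin wrapper around [ape::read.tree()] that checks leaf labels are unique.
#'
#' @param path Path to a newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' GC content of nucleotide sequences
#'
#' Returns 100 * (G + C) / (A + C + G + T) per sequence. Ambiguity codes and
#' N are excluded from the denominator so that RIP statistics are not diluted
#' by assembly gaps. A sequence with no A/C/G/T characters has undefined GC
#' content and yields `NA` with a warning.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of GC percentages in `[0, 100]` (or `NA`).
#' @examples
#' gc_content(c("GCGC", "ATAT", "ATGCN"))
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq))
  if (any(!nzchar(seq))) stop("empty sequence")
  up <- toupper(seq)
  counts <- function(pattern) {
    vapply(gregexpr(pattern, up), function(m) sum(m > 0L), integer(1L))
  }
  gc <- counts("[GC]")
  acgt <- counts("[ACGT]")
  out <- ifelse(acgt > 0L, 100 * gc / acgt, NA_real_)
  if (anyNA(out)) {
    warning("sequence with no A/C/G/T characters: GC content undefined")
  }
  out
}
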