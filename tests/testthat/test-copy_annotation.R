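# genome-hit rows for haplotype merging (subject = genome contig)
genome_hit <- function(contig, sstart1, send1, strand = "+") {
  data.frame(qid = "query", sid = contig, pident = 90,
             alen = send1 - sstart1 + 1L, mismatch = 0L, gapopen = 0L,
             qstart = 0L, qend = send1 - sstart1 + 1L,
             sstart = sstart1 - 1L, send = send1,
             evalue = 0, bitscore = 100, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("hits merge into haplotypes with min-size and flank extension", {
  lens <- c(tig1 = 20000L)
  h <- rbind(genome_hit("tig1", 100, 2000), genome_hit("tig1", 2500, 6000))
  hap <- merge_hits_to_haplotypes(h, lens, min_size = 4000, flank = 2000,
                                  merge_gap = 1000)
  expect_equal(nrow(hap), 1L)
  # merged 99-6000 (0-based), extended 2 kb each side, clipped at 0
  expect_equal(hap$start, 0L)
  expect_equal(hap$end, 8000L)

  # a 3.5 kb merged haplotype is dropped at min_size 4 kb
  h2 <- genome_hit("tig1", 1000, 4500)
  expect_equal(nrow(merge_hits_to_haplotypes(h2, lens, min_size = 4000,
                                             flank = 2000)), 0L)

  # gaps above merge_gap stay separate
  h3 <- rbind(genome_hit("tig1", 100, 4500), genome_hit("tig1", 9000, 13500))
  hap3 <- merge_hits_to_haplotypes(h3, lens, min_size = 4000, flank = 0,
                                   merge_gap = 1000)
  expect_equal(nrow(hap3), 2L)

  # extension clipped at contig end, never negative
  h4 <- genome_hit("tig1", 15000, 19500)
  hap4 <- merge_hits_to_haplotypes(h4, lens, min_size = 4000, flank = 2000)
  expect_equal(hap4$end, 20000L)

  # strands are merged independently
  h5 <- rbind(genome_hit("tig1", 100, 4500),
              genome_hit("tig1", 4600, 9100, strand = "-"))
  expect_equal(nrow(merge_hits_to_haplotypes(h5, lens, min_size = 4000,
                                             flank = 0)), 2L)

  expect_error(merge_hits_to_haplotypes(h, lens, min_size = -1), "negative")
  expect_error(merge_hits_to_haplotypes(h, c(other = 10L)), "contig")
})

test_that("haplotype merging is idempotent", {
  lens <- c(tig1 = 50000L)
  set.seed(9)
  s <- sort(sample.int(40000, 12))
  h <- do.call(rbind, lapply(s, function(x) genome_hit("tig1", x, x + 800)))
  hap <- merge_hits_to_haplotypes(h, lens, min_size = 0, flank = 0,
                                  merge_gap = 500)
  again <- merge_hits_to_haplotypes(
    data.frame(qid = "q", sid = hap$contig, pident = 90,
               alen = hap$end - hap$start, mismatch = 0L, gapopen = 0L,
               qstart = 0L, qend = hap$end - hap$start,
               sstart = hap$start, send = hap$end, evalue = 0,
               bitscore = 100, strand = hap$strand,
               stringsAsFactors = FALSE),
    lens, min_size = 0, flank = 0, merge_gap = 500)
  expect_equal(again[, c("contig", "start", "end", "strand")],
               hap[, c("contig", "start", "end", "strand")])
})

test_that("copy context distinguishes ends, nested and solo hits", {
  fc <- full_copy_table(contig = "tig1", start = 999L, end = 8300L,
                        strand = "+", ltr_left_len = 400L)
  # overlapping the element start is a 5' full-copy LTR
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 999L, end = 1400L), fc), "FULL_5P")
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 7900L, end = 8300L), fc), "FULL_3P")
  # inside the internal region only: nested
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 3999L, end = 4400L), fc), "NESTED")
  # elsewhere on the contig, or other contigs: solo/fragment
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 10000L, end = 10400L), fc), "SOLO_FRAGMENT")
  expect_equal(classify_copy_context(
    list(contig = "tig9", start = 1000L, end = 1400L), fc), "SOLO_FRAGMENT")
  # spanning the whole element touches both ends: curation error
  expect_error(classify_copy_context(
    list(contig = "tig1", start = 900L, end = 8400L), fc), "both ends")
  # end tolerance admits near-miss boundaries
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 1005L, end = 1400L), fc,
    end_tolerance = 10), "FULL_5P")
  expect_equal(classify_copy_context(
    list(contig = "tig1", start = 1050L, end = 1400L), fc,
    end_tolerance = 10), "NESTED")
})

test_that("copy context is translation invariant", {
  shift <- 5000L
  fc <- full_copy_table("tig1", 999L, 8300L, "+", 400L)
  fc2 <- full_copy_table("tig1", 999L + shift, 8300L + shift, "+", 400L)
  cases <- list(c(999L, 1400L), c(4000L, 4400L), c(12000L, 12400L))
  for (cs in cases) {
    expect_equal(
      classify_copy_context(list(contig = "tig1", start = cs[1],
                                 end = cs[2]), fc),
      classify_copy_context(list(contig = "tig1", start = cs[1] + shift,
                                 end = cs[2] + shift), fc2))
  }
})

test_that("RepeatMasker post-processing applies all four rules", {
  fc <- full_copy_table("tig1", 1000L, 8400L, "+", 400L)
  curated <- data.frame(contig = "tig1", start = 20000L, end = 20400L,
                        stringsAsFactors = FALSE)
  rm_hits <- data.frame(
    score = rep(200L, 5),
    divergence = 10, deletion = 0, insertion = 0,
    contig = "tig1",
    begin = c(0L, 30000L, 1000L, 4000L, 20050L),
    end = c(200L, 30260L, 1400L, 4400L, 20500L),
    left = "(0)", strand = "+",
    repeat_name = c("LTR1", "LTR1", "LTR1", "LTR2", "LTR2"),
    repeat_class = "LTR/Gypsy",
    rep_begin = 1L, rep_end = 400L, rep_left = 0L,
    hit_id = 1:5, stringsAsFactors = FALSE)
  out <- postprocess_repeatmasker(rm_hits, fc, curated, species = "sp1")
  # 200 bp hit dropped by the length rule (span must exceed 250)
  expect_equal(unname(out$dropped["short"]), 1L)
  # boundary-overlapping putative solo removed by rule 3
  expect_equal(unname(out$dropped["boundary_overlap"]), 1L)
  cnt <- out$counts
  expect_equal(cnt$full[cnt$subfamily == "LTR1"], 1L)          # 5' end hit
  expect_equal(cnt$solo_fragment[cnt$subfamily == "LTR1"], 1L) # 260 bp solo
  expect_equal(cnt$nested[cnt$subfamily == "LTR2"], 1L)
  # every hit is counted once or dropped by exactly one rule
  expect_equal(sum(cnt$full, cnt$solo_fragment, cnt$nested,
                   out$dropped), nrow(rm_hits))

  empty <- postprocess_repeatmasker(rm_hits[0, ], fc, curated)
  expect_equal(nrow(empty$counts), 0L)

  allshort <- rm_hits
  allshort$end <- allshort$begin + 250L   # spans of exactly 250 fail > 250
  shortout <- postprocess_repeatmasker(allshort, fc, curated)
  expect_equal(unname(shortout$dropped["short"]), 5L)
  expect_equal(sum(shortout$counts[, c("full", "solo_fragment", "nested")]),
               0L)
})

test_that("disparate LTR pairs are flagged and missing labels skipped", {
  fc <- full_copy_table(rep("tig1", 10),
                        start = seq(1000L, by = 20000L, length.out = 10),
                        end = seq(9000L, by = 20000L, length.out = 10),
                        strand = "+", ltr_left_len = 400L,
                        ltr_left_label = rep("LTR1", 10),
                        ltr_right_label = c("LTR1", "LTR4", "LTR1", "LTR1",
                                            "LTR2", rep("LTR1", 5)))
  flagged <- flag_disparate_ltrs(fc)
  expect_equal(length(flagged), 2L)
  expect_setequal(flagged, fc$element_id[c(2, 5)])

  fc$ltr_right_label[1] <- NA
  expect_warning(f2 <- flag_disparate_ltrs(fc), "missing")
  expect_equal(length(f2), 2L)
})

test_that("the 5' LTR follows element orientation", {
  fc <- full_copy_table(c("tig1", "tig1"), c(1000L, 20000L),
                        c(9000L, 28000L), strand = c("+", "-"),
                        ltr_left_len = 400L)
  sel <- select_5prime_ltr(fc)
  expect_equal(nrow(sel), 2L)
  # plus strand: left-hand LTR
  expect_equal(sel$start[1], 1000L)
  expect_equal(sel$end[1], 1400L)
  # minus strand: right-hand LTR, id written in reverse orientation
  expect_equal(sel$start[2], 27600L)
  expect_equal(sel$end[2], 28000L)
  expect_equal(sel$id[2], "tig1_28000-27601")

  # mixed set of elements yields one LTR per element
  set.seed(2)
  n <- 6L
  fcm <- full_copy_table(rep("tig2", n),
                         start = seq(1000L, by = 15000L, length.out = n),
                         end = seq(9000L, by = 15000L, length.out = n),
                         strand = sample(c("+", "-"), n, TRUE),
                         ltr_left_len = 400L)
  expect_equal(nrow(select_5prime_ltr(fcm)), n)
  expect_equal(anyDuplicated(select_5prime_ltr(fcm)$id), 0L)
})
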