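small_cfg <- function(...) {
  args <- modifyList(
    list(n_subfamilies = 2, copies_per_subfamily = 4,
         ltr_len = 100, u3_len = 50, internal_len = 300,
         rip_min_len = 100, n_cycles = 0, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("a single insertion has the full element anatomy with TSDs", {
  cfg <- sim_config(n_subfamilies = 1, copies_per_subfamily = 1,
                    ltr_len = 100, u3_len = 50, internal_len = 300,
                    n_cycles = 0, tsd_len = 5, seed = 3)
  sim <- simulate_family(cfg)
  expect_equal(nrow(sim$copies), 1L)
  row <- sim$copies[1, ]
  expect_equal(row$length, 2L * 100L + 300L)
  genome <- sim$genome[[1]]
  elem <- substr(genome, row$start + 1L, row$end)
  # the element is LTR + internal + LTR with identical paired LTRs
  expect_equal(substr(elem, 1, 100), substr(elem, 401, 500))
  # identical target-site duplications flank the element
  tsd_left <- substr(genome, row$start - 4L, row$start)
  tsd_right <- substr(genome, row$end + 1L, row$end + 5L)
  expect_equal(tsd_left, tsd_right)
  # the copy id encodes the genomic interval
  p <- parse_copy_id(row$id)
  expect_equal(p$start - 1L, row$start)
  expect_equal(p$end, row$end)
  # the extracted element matches the recorded copy sequence
  expect_equal(elem, unname(sim_sequences(sim)[row$id]))
})

test_that("without cycles all within-subfamily LTR pairs are identical", {
  sim <- simulate_family(small_cfg())
  ltrs <- extract_terminal_repeats(sim)
  seqs <- sim_sequences(ltrs)
  for (k in unique(ltrs$copies$subfamily)) {
    s <- seqs[ltrs$copies$id[ltrs$copies$subfamily == k]]
    expect_equal(length(unique(unname(s))), 1L)
  }
})

test_that("between-subfamily LTR identity matches the per-site expectation", {
  # each U3 site mutates independently in both subfamilies with prob d;
  # P(equal) = (1-d)^2 + d^2/3, conserved half stays identical
  d <- 0.5
  set.seed(55)
  ids <- replicate(60, {
    cfg <- sim_config(n_subfamilies = 2, copies_per_subfamily = 1,
                      ltr_len = 400, u3_len = 200, internal_len = 100,
                      u3_divergence = d, n_cycles = 0,
                      seed = sample.int(1e6, 1))
    sim <- simulate_family(cfg)
    ltrs <- extract_terminal_repeats(sim)
    h <- truth_hits(ltrs, min_pident = 0, min_alen = 1)
    ps <- score_pairs(remove_self_and_reciprocal(h),
                      setNames(ltrs$copies$length, ltrs$copies$id))
    ps$merged_identity
  })
  p_equal <- (1 - d)^2 + d^2 / 3
  expected <- 100 * (200 * p_equal + 200) / 400
  expect_equal(mean(ids), expected, tolerance = 0.02)
})

test_that("RIP mutates C/G in the right contexts and spares short copies", {
  cfg <- small_cfg()
  mk <- function(seq_chars, class = "solo") {
    list(seq = seq_chars,
         blocks = data.frame(copy_start = 0L, anc_start = 0L,
                             len = length(seq_chars)),
         subfamily = 1L, class = class, rip_exposures = 0L)
  }
  # deterministic context scan: CpA sites mutate, others do not
  cfg_hot <- sim_config(n_subfamilies = 2, copies_per_subfamily = 1,
                        ltr_len = 100, u3_len = 50, internal_len = 300,
                        rip_p_cpa = 1, rip_p_other = 0, rip_min_len = 5,
                        rip_min_id = 80, n_cycles = 0, seed = 1)
  copies <- list(mk(strsplit("ACACA", "")[[1]]),
                 mk(strsplit("ACACA", "")[[1]]))
  out <- apply_rip(copies, cfg_hot)
  expect_equal(paste(out[[1]]$seq, collapse = ""), "ATATA")
  # TpG context on the same strand: G after T mutates to A
  copies <- list(mk(strsplit("TGTGT", "")[[1]]),
                 mk(strsplit("TGTGT", "")[[1]]))
  out <- apply_rip(copies, cfg_hot)
  expect_equal(paste(out[[1]]$seq, collapse = ""), "TATAT")
  # non-CpA cytosines survive when rip_p_other = 0
  copies <- list(mk(strsplit("CCGCC", "")[[1]]),
                 mk(strsplit("CCGCC", "")[[1]]))
  out <- apply_rip(copies, cfg_hot)
  expect_equal(paste(out[[1]]$seq, collapse = ""), "CCGCC")

  # below rip_min_len a copy is never exposed
  cfg_len <- sim_config(n_subfamilies = 2, copies_per_subfamily = 1,
                        ltr_len = 100, u3_len = 50, internal_len = 300,
                        rip_p_cpa = 1, rip_p_other = 1, rip_min_len = 400,
                        n_cycles = 0, seed = 1)
  short <- replicate(2, mk(rep(c("C", "A"), 150)), simplify = FALSE)
  out <- apply_rip(short, cfg_len)
  expect_equal(out[[1]]$seq, short[[1]]$seq)
  expect_equal(out[[1]]$rip_exposures, 0L)

  # dissimilar copies are not exposed either
  set.seed(8)
  a <- mk(sample(c("A", "C", "G", "T"), 500, TRUE))
  b <- mk(sample(c("A", "C", "G", "T"), 500, TRUE))
  cfg_id <- sim_config(n_subfamilies = 2, copies_per_subfamily = 1,
                       ltr_len = 100, u3_len = 50, internal_len = 300,
                       rip_p_cpa = 1, rip_min_len = 100, rip_min_id = 80,
                       n_cycles = 0, seed = 1)
  out <- apply_rip(list(a, b), cfg_id)
  expect_equal(out[[1]]$rip_exposures, 0L)
})

test_that("RIP never creates C or G and GC is monotone non-increasing", {
  cfg <- sim_config(n_subfamilies = 2, copies_per_subfamily = 5,
                    ltr_len = 200, u3_len = 100, internal_len = 400,
                    rip_p_cpa = 0.3, rip_p_other = 0.1, rip_min_len = 200,
                    n_cycles = 0, seed = 21)
  sim <- simulate_family(cfg)
  copies <- sim$copy_objs
  gc_of <- function(cp) gc_content(paste(cp$seq, collapse = ""))
  gc_prev <- vapply(copies, gc_of, numeric(1L))
  for (cycle in 1:4) {
    before <- lapply(copies, `[[`, "seq")
    copies <- apply_rip(unname(copies), cfg)
    for (i in seq_along(copies)) {
      changed <- which(before[[i]] != copies[[i]]$seq)
      expect_true(all(copies[[i]]$seq[changed] %in% c("T", "A")))
      expect_true(all(before[[i]][changed] %in% c("C", "G")))
    }
    gc_now <- vapply(copies, gc_of, numeric(1L))
    expect_true(all(gc_now <= gc_prev + 1e-12))
    gc_prev <- gc_now
  }
})

test_that("solo-LTR formation recombines the two terminal repeats", {
  cfg <- small_cfg()
  sim <- simulate_family(cfg)
  full_id <- sim$copies$id[sim$copies$copy_class == "full"][1]
  cp <- sim$copy_objs[[full_id]]
  # identical LTRs: the solo equals either LTR exactly
  set.seed(4)
  solo <- make_solo_ltr(cp, cfg)
  expect_equal(solo$class, "solo")
  expect_equal(length(solo$seq), cfg$ltr_len)
  expect_equal(solo$seq, cp$seq[1:cfg$ltr_len])

  # one differing site: the breakpoint decides which allele survives
  cp2 <- cp
  p <- 60L  # inside the LTR
  old <- cp2$seq[cfg$ltr_len + cfg$internal_len + p]
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  cp2$seq[cfg$ltr_len + cfg$internal_len + p] <- alt  # 3' LTR allele differs
  seen <- character(0)
  for (i in 1:20) {
    solo2 <- make_solo_ltr(cp2, cfg)
    # breakpoint upstream of the site -> 3' allele; downstream -> 5' allele
    seen <- union(seen, solo2$seq[p])
    # every other position is unambiguous (the LTRs agree there)
    expect_equal(solo2$seq[-p], cp2$seq[seq_len(cfg$ltr_len)][-p])
  }
  expect_setequal(seen, c(old, alt))
  # genome length shrinks by internal_len + ltr_len exactly: the solo copy
  # retains one LTR out of LTR + internal + LTR
  expect_equal(length(cp$seq) - length(solo$seq),
               cfg$internal_len + cfg$ltr_len)
})

test_that("truth hits carry exact identities and respect the emission floor", {
  sim <- simulate_family(small_cfg())
  ltrs <- extract_terminal_repeats(sim)
  h <- truth_hits(ltrs, min_pident = 0, min_alen = 1)
  seqs <- sim_sequences(ltrs)
  # identical copies: one HSP at 100% covering the full length
  same <- ltrs$copies$id[ltrs$copies$subfamily == "S1"][1:2]
  hh <- h[h$qid == same[1] & h$sid == same[2], ]
  expect_equal(nrow(hh), 2L)   # U3 block + conserved block, contiguous
  expect_equal(unique(hh$pident), 100)
  expect_equal(sum(hh$alen), unname(nchar(seqs[same[1]])))

  # cross-subfamily pairs: diverged U3 block and near-identical conserved
  cross_q <- ltrs$copies$id[ltrs$copies$subfamily == "S1"][1]
  cross_s <- ltrs$copies$id[ltrs$copies$subfamily == "S2"][1]
  hc <- h[h$qid == cross_q & h$sid == cross_s, ]
  expect_equal(nrow(hc), 2L)
  expect_true(min(hc$pident) < 70)    # U3 at low identity
  expect_equal(max(hc$pident), 100)   # conserved half
  # per-site count oracle on the U3 block
  u3 <- which.min(hc$pident)
  q3 <- substr(seqs[cross_q], hc$qstart[u3] + 1L, hc$qend[u3])
  s3 <- substr(seqs[cross_s], hc$sstart[u3] + 1L, hc$send[u3])
  matches <- sum(strsplit(q3, "")[[1]] == strsplit(s3, "")[[1]])
  expect_equal(hc$pident[u3], unname(100 * matches / nchar(q3)))

  # the default floor suppresses the diverged U3 block
  hf <- truth_hits(ltrs)
  hcf <- hf[hf$qid == cross_q & hf$sid == cross_s, ]
  expect_equal(nrow(hcf), 1L)
  expect_equal(hcf$pident, 100)

  # solo vs full copy: hits are confined to LTR coordinates
  cfg <- small_cfg()
  full_id <- sim$copies$id[sim$copies$copy_class == "full"][1]
  cp <- sim$copy_objs[[full_id]]
  set.seed(5)
  solo <- make_solo_ltr(cp, cfg)
  pairset <- list(copy_objs = list(full = cp, solo = solo), config = cfg)
  hs <- truth_hits(pairset, min_pident = 0, min_alen = 1)
  hfull <- hs[hs$qid == "full", ]
  expect_true(all(hfull$qend <= cfg$ltr_len |
                  hfull$qstart >= cfg$ltr_len + cfg$internal_len))
  expect_true(all(hfull$send <= cfg$ltr_len))
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- small_cfg(n_cycles = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim(simulate_family(cfg), d1)
  write_sim(simulate_family(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the output
  cfg2 <- small_cfg(n_cycles = 2, seed = 12)
  d3 <- withr::local_tempdir()
  write_sim(simulate_family(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("a genome too small for the requested copies is rejected", {
  cfg <- small_cfg(genome_len = 1000L)
  expect_error(simulate_family(cfg), "genome too small")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(u3_divergence = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(u3_len = 400, ltr_len = 400), "u3_len")
  expect_error(sim_config(rip_p_cpa = 0.01, rip_p_other = 0.05),
               "rip_p_other")
})

test_that("local alignment finds HSPs with expected identity and bounds", {
  set.seed(33)
  a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # identical sequences: one full-length HSP at 100%
  h <- local_align(c(x = a), c(y = a))
  expect_equal(h$pident[1], 100)
  expect_equal(h$qstart[1], 0L)
  expect_equal(h$qend[1], 400L)
  expect_equal(h$strand[1], "+")

  # a shared 200 bp block embedded in unrelated sequence
  block <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  b <- paste0(left, block, right)
  h2 <- local_align(c(x = block), c(y = b))
  expect_equal(h2$sstart[1], 100L)
  expect_equal(h2$send[1], 300L)
  expect_equal(h2$pident[1], 100)

  # unrelated random sequences fall below the score floor
  u <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  v <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(nrow(local_align(c(x = u), c(y = v), min_score = 40)), 0L)

  # reverse-complement homology is reported on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  h3 <- local_align(c(x = a), c(y = rc))
  expect_equal(h3$strand[1], "-")
  expect_equal(h3$pident[1], 100)
})

test_that("truth hits and local alignment agree on ungapped homology", {
  cfg <- sim_config(n_subfamilies = 2, copies_per_subfamily = 2,
                    ltr_len = 150, u3_len = 75, internal_len = 200,
                    rip_p_cpa = 0.2, rip_p_other = 0.05, rip_min_len = 100,
                    n_cycles = 2, p_solo = 0, p_frag = 0, seed = 17)
  sim <- simulate_family(cfg)
  ltrs <- extract_terminal_repeats(sim)
  seqs <- sim_sequences(ltrs)
  ids <- ltrs$copies$id[ltrs$copies$subfamily == "S1"][1:2]
  th <- truth_hits(ltrs, min_pident = 0, min_alen = 1)
  th <- th[th$qid == ids[1] & th$sid == ids[2], ]
  la <- local_align(seqs[ids[1]], seqs[ids[2]], min_score = 20)
  # compare overall identity weighted over covered bases
  lens <- setNames(ltrs$copies$length, ltrs$copies$id)
  mi_truth <- merge_hsps(th, lens[ids[1]])$merged_identity
  mi_align <- merge_hsps(la, lens[ids[1]])$merged_identity
  expect_lt(abs(mi_truth - mi_align), 2)
})
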