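test_that("N50 matches its definition and the brute-force oracle", {
  expect_equal(compute_n50(7), 7)
  expect_equal(compute_n50(c(5, 4, 3, 2, 1)), 4)
  expect_error(compute_n50(numeric(0)), "empty")
  set.seed(1)
  for (trial in 1:200) {
    lens <- sample.int(1000, sample(1:30, 1), replace = TRUE)
    expect_equal(compute_n50(lens), oracle_n50(lens))
  }
})

test_that("contigs place exactly, reverse-complemented and with mismatches", {
  set.seed(2)
  scaf <- c(s1 = random_dna_str(3000))
  sub <- substr(scaf[[1]], 501, 1500)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(scaf[[1]], 1601, 2200))))
  ch <- strsplit(substr(scaf[[1]], 2301, 2800), "")[[1]]
  ch[250] <- setdiff(c("A", "C", "G", "T"), ch[250])[1]
  mut <- paste(ch, collapse = "")
  contigs <- c(exact = sub, revc = rc, onemm = mut, tiny = "ACGT")
  pl <- place_contigs(contigs, scaf, k = 31, max_mismatch_frac = 0.01)
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$identity[pl$contig_id == "exact"], 1.0)
  expect_equal(pl$start[pl$contig_id == "exact"], 500L)
  expect_equal(pl$orientation[pl$contig_id == "revc"], "revcomp")
  expect_equal(pl$identity[pl$contig_id == "revc"], 1.0)
  expect_equal(pl$identity[pl$contig_id == "onemm"], 1 - 1 / 500)
  unp <- attr(pl, "unplaced")
  expect_equal(unp$contig_id, "tiny")
  expect_match(unp$reason, "shorter")
})

test_that("reconciliation metrics follow coverage and distance arithmetic", {
  set.seed(3)
  scaf <- c(s1 = random_dna_str(1000))
  # exact tiling: coverage 1, missing 0, mean distance 0, identity 1
  tiling <- c(c1 = substr(scaf[[1]], 1, 400), c2 = substr(scaf[[1]], 401, 700),
              c3 = substr(scaf[[1]], 701, 1000))
  pl <- place_contigs(tiling, scaf, k = 31)
  rep1 <- reconcile(pl, scaf)
  expect_equal(rep1$coverage_fraction, 1.0)
  expect_equal(rep1$missing_bp, 0)
  expect_equal(rep1$mean_distance_bp, 0)
  expect_equal(rep1$mean_identity, 1.0)

  # overlap of 2 bp: mean distance -2, full coverage
  over <- c(c1 = substr(scaf[[1]], 1, 500), c2 = substr(scaf[[1]], 499, 1000))
  rep2 <- reconcile(place_contigs(over, scaf, k = 31), scaf)
  expect_equal(rep2$mean_distance_bp, -2)
  expect_equal(rep2$coverage_fraction, 1.0)

  # one 10 bp hole: missing 10, coverage 0.99
  hole <- c(c1 = substr(scaf[[1]], 1, 495), c2 = substr(scaf[[1]], 506, 1000))
  rep3 <- reconcile(place_contigs(hole, scaf, k = 31), scaf)
  expect_equal(rep3$missing_bp, 10)
  expect_equal(rep3$coverage_fraction, 0.99)
  expect_equal(rep3$mean_distance_bp, 10)
})

test_that("coverage windows, flags and copy-number ratios are consistent", {
  # constant depth: no flags
  tr <- coverage_flags(coverage_track(rep(100, 20000), width = 5000))
  expect_true(all(tr$flag == "normal"))
  expect_equal(nrow(tr), 4L)   # ceil(20000/5000)

  # thresholds mean +/- 2 sd
  depth <- rep(c(270, 250, 290, 270), each = 5000)
  tr2 <- coverage_track(depth, width = 5000)
  mu <- attr(tr2, "mean"); sd <- attr(tr2, "sd")
  fl <- coverage_flags(tr2, n_sd = 2)
  expect_true(all(fl$depth <= mu + 2 * sd & fl$depth >= mu - 2 * sd))
  expect_true(all(fl$flag == "normal"))

  # planted 5x region is flagged high
  depth5 <- c(rep(100, 40000), rep(500, 5000), rep(100, 40000))
  fl5 <- coverage_flags(coverage_track(depth5, width = 5000), n_sd = 2)
  expect_equal(fl5$flag[9], "high")
  expect_equal(sum(fl5$flag == "high"), 1L)

  # copy number: region at baseline ~ 1; 1350 over mean 270 ~ 5
  tr_base <- coverage_track(rep(100, 50000), width = 5000)
  expect_equal(estimate_copy_number(tr_base, "chr", 0, 5000)$ratio, 1.0)
  win <- data.frame(replicon = "chr", start = seq(0, 45000, 5000),
                    end = seq(5000, 50000, 5000),
                    depth = c(rep(270 * 10 / 9 - 1350 / 9, 9), 1350))
  tr_lit <- coverage_track(win)
  expect_equal(attr(tr_lit, "mean"), 270)
  cn <- estimate_copy_number(tr_lit, "chr", 45000, 50000)
  expect_equal(cn$ratio, 5.0)
  expect_equal(cn$copies, 5L)
  expect_error(estimate_copy_number(coverage_track(rep(0, 10000)), "chr", 0, 1000),
               "zero genome-wide mean")
})

test_that("bedGraph round trip preserves the track", {
  tr <- coverage_track(rpois(20000, 50), width = 5000)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  tr2 <- read_bedgraph(path)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("scaffold-end repeat statistics see planted shared blocks", {
  set.seed(6)
  block <- random_dna_str(30)
  s1 <- paste0(block, random_dna_str(170))            # block on 5' end of s1
  s2 <- paste0(random_dna_str(170), block)            # block on 3' end of s2
  scaf <- c(s1 = s1, s2 = s2)
  st <- scaffold_end_repeat_stats(scaf, end_len = 100, min_match = 20)
  expect_equal(st$fraction_with_repeat, 0.5)          # 2 of 4 ends
  expect_equal(st$mean_repeat_len, 30)
  expect_equal(st$mean_ends_matched, 1)

  # identical scaffolds: every end repetitive
  twin <- c(a = s1, b = s1)
  st2 <- scaffold_end_repeat_stats(twin, end_len = 100, min_match = 20)
  expect_equal(st2$fraction_with_repeat, 1.0)

  # random ends: no matches at min_match 20
  rnd <- c(x = random_dna_str(300), y = random_dna_str(300),
           z = random_dna_str(300))
  st3 <- scaffold_end_repeat_stats(rnd, end_len = 100, min_match = 20)
  expect_equal(st3$fraction_with_repeat, 0)

  # reverse-complement matches count too
  s3 <- paste0(random_dna_str(170),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(block))))
  st4 <- scaffold_end_repeat_stats(c(s1 = s1, s3 = s3),
                                   end_len = 100, min_match = 20)
  expect_equal(st4$fraction_with_repeat, 0.5)
})

test_that("repeat finders match brute-force enumeration on short sequences", {
  set.seed(7)
  for (trial in 1:8) {
    # low-complexity alphabet makes repeats frequent at small n
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                      prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    got_g <- find_repeats(s, l_g = 6)$global
    want_g <- oracle_global_repeats(s, 6)
    expect_equal(got_g, want_g, info = paste("global trial", trial))

    got_i <- find_repeats(s, l_i = 4, loop_max = 20)$inverted
    want_i <- oracle_inverted_repeats(s, 4, 20)
    expect_equal(got_i, want_i, info = paste("inverted trial", trial))

    got_t <- find_repeats(s, period_range = 1:6, c_min = 3)$tandem
    want_t <- oracle_tandem_repeats(s, 1:6, 3)
    expect_equal(got_t, want_t, info = paste("tandem trial", trial))
  }
})

test_that("planted repeats are recovered at catalogue defaults", {
  set.seed(8)
  base <- random_dna_str(10000)
  unit <- random_dna_str(40)
  s <- paste0(substr(base, 1, 3000), unit, substr(base, 3001, 7000),
              unit, substr(base, 7001, 10000))
  cat40 <- find_repeats(s, l_g = 25)
  expect_equal(nrow(cat40$global), 1L)
  expect_equal(cat40$global$length, 40L)
  expect_equal(cat40$global$start2 - cat40$global$start1, 4040L)

  # "ACACACAC": one tandem repeat, period 2, 4 copies
  td <- find_repeats("ACACACAC", c_min = 3)$tandem
  expect_equal(td$period, 2L)
  expect_equal(td$copies, 4L)

  # planted stem-loop: arm 5, loop 4
  iv <- find_repeats("CACGTAAAAACGTG", l_i = 4, loop_max = 10)$inverted
  expect_equal(iv$arm, 5L)
  expect_equal(iv$loop, 4L)

  expect_error(find_repeats("ACGU"), "outside A/C/G/T/N")
})
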