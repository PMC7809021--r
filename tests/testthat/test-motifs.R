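test_that("log-odds construction follows the pseudocount formula", {
  uni <- build_logodds(matrix(25, 4, 6))
  expect_true(all(abs(uni$logodds) < 1e-12))

  m <- matrix(0, 4, 1); m[1, 1] <- 100
  pwm <- build_logodds(m, pseudocount = 0.25)
  expect_equal(unname(pwm$logodds[1, 1]), log2((100.25 / 101) / 0.25))
  expect_equal(unname(pwm$logodds[2, 1]), log2((0.25 / 101) / 0.25))
  expect_error(build_logodds(matrix(-1, 4, 2)), "negative")
})

test_that("reverse complement is an involution and complements rows", {
  set.seed(73)
  pwm <- build_logodds(matrix(rpois(4 * 8, 20), 4, 8))
  rc <- reverse_complement_pwm(pwm)
  expect_equal(reverse_complement_pwm(rc)$counts, pwm$counts)
  expect_equal(unname(rc$counts["A", 1]), unname(pwm$counts["T", 8]))
  expect_equal(unname(rc$counts["G", 2]), unname(pwm$counts["C", 7]))
})

test_that("JASPAR matrices round trip through read and write", {
  set.seed(79)
  pwms <- list(M1 = build_logodds(matrix(rpois(4 * 7, 30), 4, 7), motif_id = "M1"),
               M2 = build_logodds(matrix(rpois(4 * 5, 10), 4, 5), motif_id = "M2"))
  f <- withr::local_tempfile()
  write_jaspar(pwms, f)
  back <- read_jaspar(f)
  expect_equal(names(back), c("M1", "M2"))
  expect_equal(back$M1$counts, pwms$M1$counts)
  expect_equal(back$M2$logodds, pwms$M2$logodds)
})

test_that("threshold calibration matches exhaustive k-mer enumeration", {
  set.seed(83)
  pwm <- build_logodds(matrix(rpois(4 * 4, 15), 4, 4))
  # exact distribution of the discretised (0.01-bit) score over all 256 4-mers
  kmers <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  scores <- apply(kmers, 1, function(k)
    0.01 * sum(round(pwm$logodds[cbind(k, 1:4)] / 0.01)))
  for (rate in c(1, 0.5, 0.1, 0.01, 1 / 256)) {
    thr <- calibrate_threshold(pwm, rate)
    achieved <- mean(scores >= thr)
    expect_lte(achieved, rate)
    # smallest such threshold: backing off one discretisation step breaks
    # the bound, unless the threshold already admits every k-mer
    if (achieved < 1)
      expect_gt(mean(scores >= thr - 0.01), rate)
  }
  t_all <- calibrate_threshold(pwm, 1)
  expect_equal(mean(scores >= t_all), 1)
})

test_that("Monte-Carlo hit rate agrees with the calibrated target", {
  set.seed(89)
  consensus <- matrix(0, 4, 8)
  consensus[cbind(sample(1:4, 8, TRUE), 1:8)] <- 50
  pwm <- build_logodds(consensus)
  thr <- calibrate_threshold(pwm, 1e-3)
  seq <- random_dna(2e5)
  hits <- scan_pwm(seq, pwm, thr)
  # the discrete score distribution means the achieved rate can sit well
  # below the requested one; compare against the rate the DP reports
  achieved <- attr(thr, "tail_prob")
  expect_lte(achieved, 1e-3)
  expected <- 2 * achieved * (2e5 - 7)  # both strands
  expect_gt(nrow(hits), expected / 2)
  expect_lt(nrow(hits), expected * 2)
})

test_that("scanning finds planted sites on both strands", {
  set.seed(97)
  consensus <- "ACGTTGCAAGGT"
  counts <- matrix(0, 4, nchar(consensus))
  counts[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")),
               seq_len(nchar(consensus)))] <- 100
  pwm <- build_logodds(counts)
  thr <- calibrate_threshold(pwm, 1e-4)
  seq <- paste0(random_dna(60), consensus, random_dna(60))
  hits <- scan_pwm(seq, pwm, thr)
  expect_true(any(hits$offset == 60 & hits$strand == "+"))

  rc_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rc_hits <- scan_pwm(rc_seq, pwm, thr)
  expect_true(any(rc_hits$strand == "-" &
                    rc_hits$offset == nchar(seq) - 60 - nchar(consensus)))
  # k-mers containing N are skipped even at a permissive threshold
  expect_equal(nrow(scan_pwm(strrep("N", 40), pwm, -1000)), 0)
})

test_that("scan results equal naive per-offset rescoring on random sequences", {
  set.seed(101)
  pwm <- build_logodds(matrix(rpois(4 * 6, 12), 4, 6))
  for (i in 1:100) {
    s <- random_dna(sample(10:60, 1))
    thr <- runif(1, -2, 4)
    got <- scan_pwm(s, pwm, thr)
    want <- scan_oracle(s, pwm, thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("motif fraction counts windows once and respects bounds", {
  consensus <- "TGGCCACCAGGG"
  counts <- matrix(0, 4, 12)
  counts[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")), 1:12)] <- 100
  pwm <- build_logodds(counts)
  thr <- calibrate_threshold(pwm)
  set.seed(103)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    random_dna(100), consensus, consensus, random_dna(100 - 12))))
  win_hit <- genomic_intervals("chr1", 95, 180)   # contains two sites: counted once
  win_miss <- genomic_intervals("chr1", 0, 80)
  expect_equal(motif_fraction(rbind(win_hit, win_miss), genome, pwm, thr), 0.5)
  expect_equal(motif_fraction(win_miss, genome, pwm, thr), 0)
  expect_error(motif_fraction(genomic_intervals("chr1", 0, 10000), genome, pwm, thr),
               "outside")
})

test_that("planted window fractions concentrate around the planting rate", {
  set.seed(107)
  consensus <- "GGGCATGTCC"
  counts <- matrix(0, 4, 10)
  counts[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")), 1:10)] <- 100
  pwm <- build_logodds(counts)
  thr <- calibrate_threshold(pwm)
  n_win <- 500
  seqs <- vapply(seq_len(n_win), function(i) {
    s <- random_dna(150)
    if (runif(1) < 0.4) substr(s, 70, 79) <- consensus
    s
  }, character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, sprintf("w%03d", 1:n_win)))
  wins <- genomic_intervals(sprintf("w%03d", 1:n_win), 0, 150)
  expect_lt(abs(motif_fraction(wins, genome, pwm, thr) - 0.4), 0.07)
})

test_that("motif enrichment reduces to the hypergeometric tail and detects planting", {
  set.seed(109)
  consensus <- "GGGCATGTCC"
  counts <- matrix(0, 4, 10)
  counts[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")), 1:10)] <- 100
  pwm <- build_logodds(counts)
  thr <- calibrate_threshold(pwm)
  make_windows <- function(n, rho, prefix) {
    seqs <- vapply(seq_len(n), function(i) {
      s <- random_dna(150)
      if (runif(1) < rho) substr(s, 70, 79) <- consensus
      s
    }, character(1))
    list(genome = setNames(seqs, paste0(prefix, seq_len(n))),
         wins = genomic_intervals(paste0(prefix, seq_len(n)), 0, 150))
  }
  fg <- make_windows(200, 0.4, "f"); bg <- make_windows(200, 0.05, "b")
  genome <- Biostrings::DNAStringSet(c(fg$genome, bg$genome))
  res <- motif_enrichment(fg$wins, bg$wins, genome, pwm, thr)
  expect_lte(res$p_one_sided, 1e-6)
  want <- hyper_tail_oracle(res$k_fg, res$k_fg + res$k_bg, 400, 200)
  expect_equal(res$p_one_sided, want, tolerance = 1e-10)

  # opposite contrast cannot also be enriched
  res_rev <- motif_enrichment(bg$wins, fg$wins, genome, pwm, thr)
  expect_gt(res_rev$p_one_sided, 1e-3)
  expect_error(motif_enrichment(fg$wins[0, ], bg$wins, genome, pwm, thr), "empty")
})
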