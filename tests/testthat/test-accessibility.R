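test_that("read adjustment follows the transposase dyad rule", {
  reads <- genomic_intervals(c("chr1", "chr1"), c(100, 200), c(151, 251),
                             strand = c("+", "-"))
  tr <- adjust_reads(reads)
  expect_equal(tr$positions$chr1, c(104, 246))  # start+4 and end-5

  # a (0, 0) shift keeps plus starts and puts minus points at the read end
  tr0 <- adjust_reads(reads, shift_plus = 0, shift_minus = 0)
  expect_equal(tr0$positions$chr1, c(100, 251))
})

test_that("adjusted positions are sorted per chromosome (re-sort oracle)", {
  set.seed(13)
  n <- 10000
  start <- sample.int(1e6, n)
  reads <- genomic_intervals(sample(c("chr1", "chr2"), n, TRUE), start,
                             start + 51, strand = sample(c("+", "-"), n, TRUE))
  tr <- adjust_reads(reads)
  for (chr in names(tr$positions)) {
    raw <- ifelse(reads$strand == "+", reads$start + 4, reads$end - 5)
    expect_equal(tr$positions[[chr]], sort(raw[reads$chrom == chr]))
  }
  expect_equal(tr$total, n)
})

test_that("negative adjusted positions are clamped to zero", {
  reads <- genomic_intervals("chr1", 0, 51, strand = "+")
  expect_message(tr <- adjust_reads(reads, shift_plus = -10), "clamped")
  expect_equal(tr$positions$chr1, 0)
})

test_that("Poisson upper tail is exact and stable", {
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(0, 0.001), 1)
  expect_equal(poisson_tail(1, 2), 1 - exp(-2))
  # testthat edition-3 tolerance is relative
  expect_equal(poisson_tail(20, 2), poisson_tail_oracle(20, 2), tolerance = 1e-9)
  set.seed(17)
  for (i in 1:100) {
    k <- sample(0:200, 1)
    lam <- runif(1, 0.01, 50)
    want <- poisson_tail_oracle(k, lam)
    expect_equal(poisson_tail(k, lam), want, tolerance = 1e-9)
  }
  expect_error(poisson_tail(1, 0), "lam")
})

test_that("Poisson tail is monotone in both arguments", {
  ks <- 0:50
  expect_true(all(diff(poisson_tail(ks, 5)) <= 0))
  lams <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(poisson_tail(10, lams)) >= 0))
})

test_that("peak calling finds exactly the planted region", {
  set.seed(19)
  len <- 1e6
  n_bg <- rpois(1, 0.02 * len)
  pos <- floor(runif(n_bg, 0, len))
  plant <- floor(runif(rpois(1, 0.16 * 2000), 500000, 502000))
  tr <- coverage_track(data.frame(chrom = "chr1", pos = c(pos, plant)))
  peaks <- call_peaks(tr, c(chr1 = len))
  hit <- peaks$start < 502000 & peaks$end > 500000
  expect_equal(sum(hit), 1)
  expect_true(all(peaks$summit_start >= peaks$start))
  expect_true(all(peaks$summit_end <= peaks$end))
  expect_equal(unique(peaks$summit_end - peaks$summit_start), 150)
})

test_that("zero reads produce zero peaks, not an error", {
  tr <- coverage_track(data.frame(chrom = character(), pos = numeric()))
  expect_equal(nrow(suppressWarnings(call_peaks(tr, c(chr1 = 1e5)))), 0)
})

test_that("every summit equals the exhaustive leftmost argmax", {
  set.seed(23)
  len <- 4e5
  pos <- c(floor(runif(rpois(1, 0.02 * len), 0, len)),
           floor(rnorm(300, 100000, 120)), floor(rnorm(250, 250000, 400)))
  tr <- coverage_track(data.frame(chrom = "chr1", pos = pos))
  peaks <- call_peaks(tr, c(chr1 = len))
  expect_gt(nrow(peaks), 0)
  spos <- sort(pos)
  for (i in seq_len(nrow(peaks))) {
    inside <- spos[spos >= peaks$start[i] & spos < peaks$end[i]]
    want <- summit_oracle(inside, peaks$start[i], peaks$end[i], 150)
    expect_equal(c(peaks$summit_start[i], peaks$summit_end[i]), want)
  }
})

test_that("peak calling is translation-equivariant", {
  set.seed(29)
  pos <- c(floor(runif(2000, 0, 2e5)), floor(rnorm(400, 80000, 150)))
  shift <- 3001
  p1 <- call_peaks(coverage_track(data.frame(chrom = "chr1", pos = pos)),
                   c(chr1 = 2e5))
  p2 <- call_peaks(coverage_track(data.frame(chrom = "chr1", pos = pos + shift)),
                   c(chr1 = 2e5 + shift))
  # window grid is absolute, so shift by a multiple of the 75-bp step
  shift75 <- 75 * 40
  p3 <- call_peaks(coverage_track(data.frame(chrom = "chr1", pos = pos + shift75)),
                   c(chr1 = 2e5 + shift75))
  expect_equal(p3$start, p1$start + shift75)
  expect_equal(p3$summit_start, p1$summit_start + shift75)
})

test_that("identical tracks yield no DARs and planted contrast is directional", {
  set.seed(31)
  len <- 5e5
  base <- floor(runif(rpois(1, 0.02 * len), 0, len))
  shared <- floor(rnorm(500, 2e5, 100))
  tr_a <- coverage_track(data.frame(chrom = "chr1",
                                    pos = c(base, shared)), condition = "parental")
  tr_b <- tr_a
  pk_a <- call_peaks(tr_a, c(chr1 = len))
  dars_same <- call_dars(pk_a, pk_a, tr_a, tr_b, c(chr1 = len))
  expect_equal(nrow(dars_same$gained), 0)
  expect_equal(nrow(dars_same$lost), 0)
  expect_gt(nrow(dars_same$shared), 0)

  # a region enriched 10x only in condition B must be gained, never lost
  b_only <- floor(rnorm(800, 4e5, 120))
  tr_b2 <- coverage_track(data.frame(chrom = "chr1", pos = c(base, shared, b_only)),
                          condition = "transformed")
  pk_b2 <- call_peaks(tr_b2, c(chr1 = len))
  dars <- call_dars(pk_a, pk_b2, tr_a, tr_b2, c(chr1 = len))
  g_hit <- dars$gained$start < 4e5 + 500 & dars$gained$end > 4e5 - 500
  expect_equal(sum(g_hit), 1)
  l_hit <- nrow(dars$lost) && any(dars$lost$start < 4e5 + 500 & dars$lost$end > 4e5 - 500)
  expect_false(as.logical(l_hit))

  # swapping the condition labels swaps gained and lost exactly
  swapped <- call_dars(pk_b2, pk_a, tr_b2, tr_a, c(chr1 = len))
  expect_equal(swapped$lost[c("chrom", "start", "end")],
               dars$gained[c("chrom", "start", "end")])
  expect_equal(swapped$gained[c("chrom", "start", "end")],
               dars$lost[c("chrom", "start", "end")])
})

test_that("peak-to-feature annotation uses strand-aware windows and priority", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 50000,
                      end = 80000, strand = "+")
  ann <- annotate_location(genomic_intervals("chr1", 48900, 49100), genes)
  expect_equal(ann$labels, "promoter")
  ann2 <- annotate_location(genomic_intervals("chr1", 120000, 120200), genes)
  expect_equal(ann2$labels, "midrange")
  ann3 <- annotate_location(genomic_intervals("chr1", 400000, 400200), genes)
  expect_equal(ann3$labels, "far")
  # minus-strand gene: promoter sits to the right of the TSS
  genes_m <- data.frame(gene_id = "g2", chrom = "chr1", start = 50000,
                        end = 80000, strand = "-")
  annm <- annotate_location(genomic_intervals("chr1", 80400, 80600), genes_m)
  expect_equal(annm$labels, "promoter")
  # proportions sum to one over the three classes
  set.seed(37)
  pk <- random_intervals(200, chroms = "chr1", max_pos = 5e5)
  annp <- annotate_location(pk, genes)
  expect_equal(sum(annp$proportions), 1)
  expect_error(annotate_location(pk, transform(genes, strand = "*")), "strand")
})

test_that("promoter direction table detects perfect association and ties", {
  genes <- data.frame(gene_id = c("up1", "dn1"), chrom = "chr1",
                      start = c(10000, 60000), end = c(20000, 70000),
                      strand = "+")
  de <- c(up1 = "up", dn1 = "down")
  mkpeaks <- function(starts) {
    df <- genomic_intervals("chr1", starts, starts + 200)
    n <- nrow(df)
    df$summit_start <- starts; df$summit_end <- starts + 150
    df$read_count <- rep(10, n); df$p_value <- rep(1e-6, n)
    df$condition <- rep("x", n)
    class(df) <- c("peaks", "data.frame")
    df
  }
  dars <- structure(list(gained = mkpeaks(c(9500, 9800)),
                         lost = mkpeaks(c(59500, 59800)),
                         shared = mkpeaks(numeric(0))), class = "dar_set")
  res <- promoter_direction_table(dars, genes, de)
  expect_equal(unname(res$proportions), c(1, 0))
  expect_false(res$flagged)

  same <- structure(list(gained = mkpeaks(c(9500, 59500)),
                         lost = mkpeaks(c(9600, 59600)),
                         shared = mkpeaks(numeric(0))), class = "dar_set")
  res2 <- promoter_direction_table(same, genes, de)
  expect_equal(res2$test$statistic, 0)
  expect_equal(res2$test$p, 1)

  empty <- structure(list(gained = mkpeaks(numeric(0)), lost = mkpeaks(9500),
                          shared = mkpeaks(numeric(0))), class = "dar_set")
  expect_true(promoter_direction_table(empty, genes, de)$flagged)
})

test_that("replicate correlation is 1 for identical tracks and matches cor()", {
  set.seed(41)
  len <- 1e6
  ctrs <- seq(1e5, 9e5, by = 1e5)
  strength <- seq(100, 900, by = 100)
  plant <- function() unlist(lapply(seq_along(ctrs), function(i)
    floor(rnorm(rpois(1, strength[i]), ctrs[i], 100))))
  pos1 <- c(floor(runif(5000, 0, len)), plant())
  t1 <- coverage_track(data.frame(chrom = "chr1", pos = pos1))
  res <- replicate_correlation(t1, t1, c(chr1 = len))
  expect_equal(res$r, 1)

  pos2 <- c(floor(runif(5000, 0, len)), plant())
  t2 <- coverage_track(data.frame(chrom = "chr1", pos = pos2))
  res2 <- replicate_correlation(t1, t2, c(chr1 = len))
  expect_false(res2$flagged)
  expect_equal(res2$r, stats::cor(res2$counts1, res2$counts2))
  expect_gt(res2$r, 0.8)
})
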