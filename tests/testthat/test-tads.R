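test_that("TAD merging keeps sources and drops exact duplicates", {
  a <- genomic_intervals("chr1", c(0, 100), c(100, 300))
  b <- genomic_intervals("chr1", c(0, 150), c(100, 250))
  merged <- merge_tad_sets(list(hela = a, gm = b))
  expect_equal(nrow(merged), 3)  # the identical 0-100 TAD appears once
  expect_equal(merged$source[merged$start == 0], "hela")
  one <- merge_tad_sets(list(only = a))
  expect_equal(one[c("chrom", "start", "end")], a)

  set.seed(43)
  sets <- lapply(1:7, function(i) random_intervals(60, max_pos = 5000, max_len = 500))
  m <- merge_tad_sets(setNames(sets, paste0("cl", 1:7)))
  keys <- unlist(lapply(sets, function(s) paste(s$chrom, s$start, s$end)))
  expect_equal(nrow(m), length(unique(keys)))
})

test_that("smallest overlapping TAD wins, with deterministic ties", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1.2e6, end = 1.3e6)
  tads <- merge_tad_sets(list(
    A = genomic_intervals("chr1", 1.0e6, 2.0e6),
    B = genomic_intervals("chr1", 1.1e6, 1.5e6)))
  asg <- assign_smallest_tad(genes, tads)
  expect_equal(tads$source[asg$tad[["g1"]]], "B")

  lonely <- data.frame(gene_id = "g2", chrom = "chr2", start = 10, end = 20)
  asg2 <- assign_smallest_tad(lonely, tads)
  expect_true(is.na(asg2$tad[["g2"]]))
})

test_that("assignment agrees with the scan-all-TADs oracle on random instances", {
  set.seed(47)
  genes <- random_intervals(500, max_pos = 50000, max_len = 2000)
  genes$gene_id <- sprintf("g%03d", seq_len(500))
  tads <- merge_tad_sets(list(x = random_intervals(80, max_pos = 50000, max_len = 9000),
                              y = random_intervals(80, max_pos = 50000, max_len = 9000)))
  asg <- assign_smallest_tad(genes, tads)
  for (i in seq_len(nrow(genes))) {
    best <- NA_integer_
    for (j in seq_len(nrow(tads))) {
      if (tads$chrom[j] != genes$chrom[i]) next
      ov <- min(genes$end[i], tads$end[j]) - max(genes$start[i], tads$start[j])
      if (ov < 1) next
      if (is.na(best)) { best <- j; next }
      len_j <- tads$end[j] - tads$start[j]
      len_b <- tads$end[best] - tads$start[best]
      if (len_j < len_b ||
          (len_j == len_b && (tads$start[j] < tads$start[best] ||
            (tads$start[j] == tads$start[best] && tads$source[j] < tads$source[best]))))
        best <- j
    }
    expect_identical(unname(asg$tad[i]), best)
  }
})

test_that("TAD direction declaration follows the up/down/mixed/none contract", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d", "e"), chrom = "chr1",
                      start = c(10, 110, 210, 220, 310),
                      end = c(20, 120, 220, 230, 320))
  tads <- merge_tad_sets(list(z = genomic_intervals(
    "chr1", c(0, 100, 200, 300), c(100, 200, 300, 400))))
  asg <- assign_smallest_tad(genes, tads)
  de <- c(a = "up", b = "stable", c = "up", d = "down", e = "stable")
  dir <- declare_direction(asg, de)
  expect_equal(dir, c("up", "none", "mixed", "none"))
})

test_that("direction counts match a per-TAD recount on random data", {
  set.seed(53)
  n <- 200
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                      start = s <- sort(sample.int(40000, n)), end = s + 50)
  tads <- merge_tad_sets(list(t = genomic_intervals(
    "chr1", seq(0, 39000, by = 1000), seq(1000, 40000, by = 1000))))
  asg <- assign_smallest_tad(genes, tads)
  de <- setNames(sample(c("up", "down", "stable"), n, TRUE), genes$gene_id)
  dir <- declare_direction(asg, de)
  for (j in seq_len(nrow(tads))) {
    members <- names(asg$tad)[!is.na(asg$tad) & asg$tad == j]
    has_up <- any(de[members] == "up"); has_down <- any(de[members] == "down")
    want <- if (has_up && has_down) "mixed" else if (has_up) "up"
            else if (has_down) "down" else "none"
    expect_equal(dir[j], want)
  }
})

test_that("footprint overlap in Mb matches a per-bp bitmap oracle", {
  expect_equal(tad_overlap_mb(genomic_intervals("chr1", 0, 1e6),
                              genomic_intervals("chr1", 2e6, 3e6)), 0)
  expect_equal(tad_overlap_mb(genomic_intervals("chr1", 0, 1e6),
                              genomic_intervals("chr1", 0, 1e6)), 1)
  set.seed(59)
  toy <- 1e4  # 10-kb toy genome, bp-resolution bitmap
  a <- random_intervals(30, chroms = "chrT", max_pos = toy, max_len = 2000)
  b <- random_intervals(30, chroms = "chrT", max_pos = toy, max_len = 2000)
  bit_a <- logical(toy + 3000); bit_b <- logical(toy + 3000)
  for (i in seq_len(nrow(a))) bit_a[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) bit_b[(b$start[i] + 1):b$end[i]] <- TRUE
  expect_equal(tad_overlap_mb(a, b), sum(bit_a & bit_b) / 1e6)
})

test_that("segregation permutation is degenerate-safe and matches enumeration", {
  tads <- merge_tad_sets(list(t = genomic_intervals(
    "chr1", c(0, 1e6, 2e6), c(1e6, 2e6, 3e6))))
  genes <- data.frame(gene_id = c("a", "b", "c", "d"), chrom = "chr1",
                      start = c(1e5, 2e5, 1.1e6, 2.1e6),
                      end = c(1.5e5, 2.5e5, 1.15e6, 2.15e6))
  asg <- assign_smallest_tad(genes, tads)

  # all DE genes in one direction: flagged, p = 1, never an error
  de1 <- c(a = "up", b = "up", c = "up", d = "stable")
  res1 <- segregation_permutation(asg, de1, n_perm = 50, seed = 1)
  expect_true(res1$flagged)
  expect_equal(res1$p_lower, 1)

  # 4 DE genes, 2 up / 2 down: exact null from the C(4,2) = 6 labelings
  de <- c(a = "up", b = "up", c = "down", d = "down")
  labelings <- utils::combn(4, 2)
  overlaps <- apply(labelings, 2, function(up_idx) {
    lab <- rep("down", 4); lab[up_idx] <- "up"
    names(lab) <- names(de)
    dir <- sapply(1:3, function(j) {
      members <- names(asg$tad)[asg$tad == j]
      hu <- any(lab[members] == "up"); hd <- any(lab[members] == "down")
      if (hu && hd) "mixed" else if (hu) "up" else if (hd) "down" else "none"
    })
    tad_overlap_mb(tads[dir %in% c("up", "mixed"), ],
                   tads[dir %in% c("down", "mixed"), ])
  })
  obs <- overlaps[1]  # the real labeling is a,b up
  exact_tail <- mean(overlaps <= obs)
  res <- segregation_permutation(asg, de, n_perm = 3000, seed = 7)
  expect_equal(res$observed_mb, obs)
  # empirical p concentrates on the enumerated tail probability
  expect_lt(abs(res$p_lower - exact_tail), 3 * sqrt(exact_tail / 3000) + 2 / 3000)
})

test_that("segregation p is invariant to swapping all up/down labels", {
  set.seed(61)
  tads <- merge_tad_sets(list(t = genomic_intervals(
    "chr1", seq(0, 9e6, 1e6), seq(1e6, 1e7, 1e6))))
  n <- 40
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                      start = s <- sort(sample.int(9.9e6, n)), end = s + 1000)
  asg <- assign_smallest_tad(genes, tads)
  de <- setNames(sample(c("up", "down", "stable"), n, TRUE), genes$gene_id)
  swapped <- c(up = "down", down = "up", stable = "stable")[de]
  names(swapped) <- names(de)
  r1 <- segregation_permutation(asg, de, 200, seed = 3)
  r2 <- segregation_permutation(asg, swapped, 200, seed = 3)
  expect_equal(r1$observed_mb, r2$observed_mb)
})

test_that("peak density is peaks per Mb and ties give p = 1", {
  tads <- merge_tad_sets(list(t = genomic_intervals("chr1", c(0, 2e6), c(2e6, 4e6))))
  peaks <- genomic_intervals("chr1", seq(1e5, 1e6, le = 10), seq(1e5, 1e6, le = 10) + 200)
  dirs <- c("up", "down")
  res <- peak_density_by_tad(peaks, tads, dirs)
  expect_equal(res$density$density[1], 5.0)
  expect_equal(res$density$density[2], 0.0)

  res_same <- peak_density_by_tad(peaks, tads, c("up", "up"))
  expect_true(res_same$flagged)

  # n = 4 vs 4: density test p equals the exact rank enumeration
  tads8 <- merge_tad_sets(list(t = genomic_intervals(
    "chr1", seq(0, 7e6, 1e6), seq(1e6, 8e6, 1e6))))
  set.seed(67)
  pk <- random_intervals(60, chroms = "chr1", max_pos = 8e6 - 300)
  dir8 <- rep(c("up", "down"), each = 4)
  res8 <- peak_density_by_tad(pk, tads8, dir8)
  x <- res8$density$density[dir8 == "up"]; y <- res8$density$density[dir8 == "down"]
  if (!anyDuplicated(c(x, y))) expect_equal(res8$test$p, mw_exact_oracle(x, y))
})

test_that("DAR-TAD strata match a brute-force re-scan", {
  set.seed(71)
  tads <- merge_tad_sets(list(
    big = genomic_intervals("chr1", seq(0, 4e6, 1e6), seq(1e6, 5e6, 1e6)),
    small = genomic_intervals("chr1", seq(5e5, 3.5e6, 1e6), seq(1e6, 4e6, 1e6))))
  dir <- sample(c("up", "down", "mixed", "none"), nrow(tads), TRUE)
  mk <- function(n) random_intervals(n, chroms = "chr1", max_pos = 5e6 - 400, max_len = 400)
  dars <- structure(list(gained = mk(40), lost = mk(40), shared = mk(5)),
                    class = "dar_set")
  strata <- link_dars_to_tads(dars, tads, dir)
  for (cl in c("gained", "lost")) {
    pk <- dars[[cl]]
    for (i in seq_len(nrow(pk))) {
      cand <- which(dir %in% c("up", "down") & tads$chrom == pk$chrom[i] &
                      tads$start < pk$end[i] & tads$end > pk$start[i])
      want <- if (!length(cand)) "outside" else {
        lens <- tads$end[cand] - tads$start[cand]
        dir[cand[order(lens, tads$start[cand])][1]]
      }
      expect_equal(strata[[cl]][i], want)
    }
  }
  # a DAR inside a single up TAD is gained-in-up; none overlapping -> outside
  one <- structure(list(
    gained = genomic_intervals("chr1", tads$start[which(dir == "up")[1]] + 10,
                               tads$start[which(dir == "up")[1]] + 100),
    lost = genomic_intervals("chr2", 0, 100), shared = mk(0)), class = "dar_set")
  if (any(dir == "up")) {
    s1 <- link_dars_to_tads(one, tads, dir)
    expect_equal(s1$lost, "outside")
  }
})
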