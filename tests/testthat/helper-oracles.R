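# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own interval/statistics code paths.

oracle_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j]) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= 1)
        out[[length(out) + 1]] <- data.frame(a_idx = i, b_idx = j, overlap_bp = ov)
    }
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer(), overlap_bp = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$a_idx, res$b_idx), ]
  rownames(res) <- NULL
  res
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# direct term-by-term summation of the Poisson upper tail
poisson_tail_oracle <- function(k, lam) {
  term <- exp(k * log(lam) - lam - lgamma(k + 1))
  tot <- 0
  i <- k
  repeat {
    tot <- tot + term
    i <- i + 1
    term <- term * lam / i
    if (i > k + 2000 || (term < tot * 1e-17 && i > lam)) break
  }
  tot
}

# term-by-term hypergeometric upper tail: P(X >= k) drawing n from N with K marked
hyper_tail_oracle <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), numeric(1)))
}

# exhaustive leftmost max-count window of width w within [lo, hi)
summit_oracle <- function(pos, lo, hi, w) {
  best_s <- lo; best_c <- -1
  for (s in lo:max(lo, hi - w)) {
    cnt <- sum(pos >= s & pos < s + w)
    if (cnt > best_c) { best_c <- cnt; best_s <- s }
  }
  c(best_s, best_s + w)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# per-offset naive PWM rescoring on both strands
scan_oracle <- function(seq, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  L <- pwm$length
  hits <- list()
  for (o in 0:(nchar(seq) - L)) {
    kmer <- chars[(o + 1):(o + L)]
    if (any(!kmer %in% c("A", "C", "G", "T"))) next
    fw <- sum(vapply(seq_len(L), function(j)
      pwm$logodds[kmer[j], j], numeric(1)))
    rc_kmer <- rev(unname(comp[kmer]))
    rv <- sum(vapply(seq_len(L), function(j)
      pwm$logodds[rc_kmer[j], j], numeric(1)))
    if (fw >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "+", score = fw)
    if (rv >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "-", score = rv)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(), score = numeric()))
  res <- do.call(rbind, hits)
  res <- res[order(res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# small simulation parameters for fast pipeline-level tests
small_sim_params <- function(seed, ...) {
  sim_params(n_chrom = 1, chrom_len = 4e6, n_dars_per_direction = 40,
             n_shared_peaks = 50, n_chip_background = 30, seed = seed, ...)
}
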