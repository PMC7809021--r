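#' Build a position weight matrix with log-odds scores
#'
#' From a 4 x L count matrix (rows A, C, G, T) the per-column probabilities
#' are `(count + pseudocount) / (column total + 4 * pseudocount)` and the
#' log-odds score of base b at column j is `log2(p[b,j] / background[b])`,
#' in bits.
#'
#' @param counts 4 x L non-negative matrix; rows in A, C, G, T order.
#' @param motif_id identifier string.
#' @param pseudocount added to every cell (default 0.25).
#' @param background base frequencies, default uniform.
#' @return list of class `pwm` with `counts`, `logodds`, `length`,
#'   `max_score`, `min_score`.
#' @export
build_logodds <- function(counts, motif_id = "motif", pseudocount = 0.25,
                          background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("build_logodds: counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("build_logodds: negative counts")
  stopifnot(length(background) == 4, all(background > 0))
  rownames(counts) <- c("A", "C", "G", "T")
  tot <- colSums(counts) + 4 * pseudocount
  prob <- sweep(counts + pseudocount, 2, tot, "/")
  lo <- log2(sweep(prob, 1, background, "/"))
  structure(list(motif_id = motif_id, counts = counts, pseudocount = pseudocount,
                 background = background, logodds = lo, length = ncol(counts),
                 max_score = sum(apply(lo, 2, max)),
                 min_score = sum(apply(lo, 2, min))),
            class = "pwm")
}

#' Reverse complement of a PWM
#'
#' Rows are complemented (A<->T, C<->G) and columns reversed; applying it
#' twice returns the original matrix.
#'
#' @param pwm a [build_logodds()] object.
#' @return the reverse-complement `pwm`.
#' @export
reverse_complement_pwm <- function(pwm) {
  rc <- pwm$counts[4:1, rev(seq_len(pwm$length)), drop = FALSE]
  build_logodds(rc, motif_id = pwm$motif_id, pseudocount = pwm$pseudocount,
                background = rev(pwm$background))
}

#' Read / write JASPAR-style position frequency matrices
#'
#' Format: a `>motif_id [name]` header followed by four lines
#' `A [ n1 n2 ... ]` (brackets optional), rows in A, C, G, T order.  Several
#' motifs per file are allowed.
#'
#' @param path file path.
#' @param pseudocount,background passed to [build_logodds()].
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("read_jaspar: no '>' header in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h]
    id <- strsplit(sub("^>", "", lines[from]), "\\s+")[[1]][1]
    rows <- lines[(from + 1):(from + 4)]
    vals <- lapply(rows, function(l) {
      nums <- gsub("[][ACGTacgt]", " ", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop("read_jaspar: ragged matrix for ", id, " in ", path)
    mat <- do.call(rbind, vals)
    out[[id]] <- build_logodds(mat, motif_id = id, pseudocount = pseudocount,
                               background = background)
  }
  out
}

#' @rdname read_jaspar
#' @param pwms named list of `pwm` objects (or a single one).
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- stats::setNames(list(pwms), pwms$motif_id)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id),
      vapply(1:4, function(i)
        paste0(c("A", "C", "G", "T")[i], " [ ",
               paste(format_coord(p$counts[i, ]), collapse = " "), " ]"),
        character(1)))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Calibrate a PWM score threshold for a target hit rate
#'
#' Computes the exact distribution of the PWM score of a random background
#' k-mer by dynamic programming over the score values discretised at `step`
#' bits, and returns the smallest threshold t such that
#' `P(score >= t) <= target_rate` (per strand per position).  If even the
#' best k-mer is more frequent than the target, the returned threshold lies
#' just above the maximal score and carries `attr(, "flagged") = TRUE`.
#'
#' @param pwm a [build_logodds()] object.
#' @param target_rate desired per-position hit probability, in (0, 1].
#' @param step score discretisation, bits (default 0.01).
#' @return threshold in bits, with attributes `tail_prob` (achieved rate)
#'   and `flagged`.
#' @export
calibrate_threshold <- function(pwm, target_rate = 1e-4, step = 0.01) {
  stopifnot(target_rate > 0, target_rate <= 1, step > 0)
  si <- round(pwm$logodds / step)
  lo_min <- sum(apply(si, 2, min)); lo_max <- sum(apply(si, 2, max))
  # v[s - lo_min + 1] = P(partial score sum = s); column minima are <= 0 and
  # maxima >= 0, so every partial sum stays within [lo_min, lo_max]
  v <- numeric(lo_max - lo_min + 1)
  v[0 - lo_min + 1] <- 1
  for (j in seq_len(pwm$length)) {
    nv <- numeric(length(v))
    for (b in 1:4) {
      s <- si[b, j]
      idx <- which(v > 0)
      nv[idx + s] <- nv[idx + s] + v[idx] * pwm$background[b]
    }
    v <- nv
  }
  tail <- rev(cumsum(rev(v)))
  ints <- seq(lo_min, lo_max)
  ok <- which(tail <= target_rate)
  if (length(ok)) {
    t_int <- ints[ok[1]]
    structure((t_int - 0.5) * step, tail_prob = tail[ok[1]], flagged = FALSE)
  } else {
    structure((lo_max + 0.5) * step, tail_prob = 0, flagged = TRUE)
  }
}

# integer base codes for a sequence string; N and friends become NA
.seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# raw score vector at every offset (0-based), NA where the k-mer has non-ACGT
.scores_at_offsets <- function(codes, lo) {
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + lo[codes[j:(j + nw - 1)] + 4 * (j - 1)]
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset on both strands and reports positions with score at or
#' above the threshold, ordered by offset with `+` before `-`.  Windows
#' containing non-ACGT characters are skipped.  A minus-strand hit at offset
#' o is the reverse-complement PWM scored on the forward sequence at o, so
#' scanning the reverse-complemented sequence yields the mirrored hit set.
#'
#' @param seq a character string (or `DNAString`).
#' @param pwm a [build_logodds()] object.
#' @param threshold score cutoff in bits (e.g. from [calibrate_threshold()]).
#' @return data.frame with `offset` (0-based), `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, threshold) {
  seq <- as.character(seq)
  codes <- .seq_codes(seq)
  sc_f <- .scores_at_offsets(codes, pwm$logodds)
  sc_r <- .scores_at_offsets(codes, reverse_complement_pwm(pwm)$logodds)
  hit_f <- which(!is.na(sc_f) & sc_f >= threshold)
  hit_r <- which(!is.na(sc_r) & sc_r >= threshold)
  out <- data.frame(offset = c(hit_f, hit_r) - 1L,
                    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
                    score = c(sc_f[hit_f], sc_r[hit_r]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# extract window sequences from a genome (DNAStringSet or named character)
.window_seqs <- function(windows, genome) {
  validate_intervals(windows, "windows")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  vapply(seq_len(nrow(windows)), function(i) {
    chr <- windows$chrom[i]
    if (!chr %in% names(genome))
      stop("window outside sequence: no chromosome ", chr)
    len <- Biostrings::width(genome[names(genome) == chr])[1]
    if (windows$end[i] > len)
      stop(sprintf("window outside sequence: %s:%d-%d (length %d)",
                   chr, windows$start[i], windows$end[i], len))
    as.character(Biostrings::subseq(genome[[chr]], windows$start[i] + 1,
                                    windows$end[i]))
  }, character(1))
}

# logical: does each window contain >= 1 hit
.window_has_hit <- function(windows, genome, pwm, threshold) {
  seqs <- .window_seqs(windows, genome)
  vapply(seqs, function(s) nrow(scan_pwm(s, pwm, threshold)) > 0, logical(1),
         USE.NAMES = FALSE)
}

#' Fraction of windows containing a motif
#'
#' The numerator counts windows with at least one hit, not hits, so a window
#' with several sites contributes once.
#'
#' @param windows interval data.frame (typically 150-bp summit windows).
#' @param genome DNAStringSet or named character vector.
#' @param pwm a `pwm` object.
#' @param threshold score cutoff in bits; defaults to
#'   [calibrate_threshold()] at 1e-4 per position.
#' @return fraction in [0, 1] (NA for zero windows).
#' @export
motif_fraction <- function(windows, genome, pwm,
                           threshold = calibrate_threshold(pwm)) {
  if (!nrow(windows)) return(NA_real_)
  mean(.window_has_hit(windows, genome, pwm, threshold))
}

#' Motif enrichment of one window set against another
#'
#' Counts windows with at least one hit in the foreground and in the
#' background (window-level presence/absence, each window counted once) and
#' computes the one-sided hypergeometric over-representation p-value via
#' [hypergeom_enrichment()].  In the mirrored design of the package's DAR
#' analyses the background of the gained set is the lost set and vice versa.
#'
#' @param fg_windows,bg_windows disjoint interval sets.
#' @param genome DNAStringSet or named character vector.
#' @param pwm a `pwm` object.
#' @param threshold score cutoff in bits.
#' @return an `enrichment_result` with extra fields `motif_id`, `threshold`.
#' @export
motif_enrichment <- function(fg_windows, bg_windows, genome, pwm,
                             threshold = calibrate_threshold(pwm)) {
  if (!nrow(fg_windows)) stop("motif_enrichment: empty foreground")
  k_fg <- sum(.window_has_hit(fg_windows, genome, pwm, threshold))
  k_bg <- if (nrow(bg_windows))
    sum(.window_has_hit(bg_windows, genome, pwm, threshold)) else 0
  res <- hypergeom_enrichment(k_fg, nrow(fg_windows), k_bg, nrow(bg_windows))
  res$motif_id <- pwm$motif_id
  res$threshold <- as.numeric(threshold)
  res
}
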