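#' Construct a set of genomic intervals
#'
#' The universal substrate of the package: a data.frame of intervals in
#' 0-based half-open coordinates (BED convention).  `start` is inclusive,
#' `end` exclusive, so `length = end - start` and two intervals that merely
#' abut (`end == start`) do not overlap.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-valued vectors, `0 <= start < end`.
#' @param strand optional vector over `"+"`, `"-"`, `"*"` (unstranded).
#' @param name optional feature names.
#' @param ... further per-interval columns carried along unchanged.
#' @return a data.frame with columns `chrom`, `start`, `end` and any extras,
#'   validated against the interval invariants.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL, ...) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0 || length(end) == 0) n <- 0
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), n)
  if (!is.null(strand)) df$strand <- rep_len(as.character(strand), n)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_intervals(df)
  df
}

#' Validate an interval data.frame
#'
#' Checks the coordinate invariants (`0 <= start < end`, non-empty `chrom`,
#' valid strand symbols) and fails with the offending coordinates in the
#' message.
#'
#' @param df a data.frame with at least `chrom`, `start`, `end`.
#' @param where label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, where = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(where, ": missing columns ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom) | is.na(df$start) | is.na(df$end) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("%s: invalid interval at row %d: %s:%s-%s",
                 where, i, df$chrom[i], format(df$start[i]), format(df$end[i])))
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*")))
    stop(where, ": strand must be one of +, -, *")
  invisible(df)
}

# IRanges view of one interval set, split by chromosome.
# Returns list(ir = IRanges per chrom, idx = original row indices per chrom).
.ir_by_chrom <- function(df) {
  sp <- split(seq_len(nrow(df)), df$chrom)
  ir <- lapply(sp, function(i) IRanges::IRanges(start = df$start[i] + 1L, end = df$end[i]))
  list(ir = ir, idx = sp)
}

#' Intersect two interval collections
#'
#' Reports every pair with at least 1 bp of overlap exactly once, with the
#' overlap size in bp (`min(ends) - max(starts)`).  Half-open abutment is not
#' overlap.  Input order is irrelevant; chromosome names are matched by exact
#' string equality.
#'
#' @param a,b interval data.frames (see [genomic_intervals()]).
#' @return data.frame with columns `a_idx`, `b_idx` (row indices into `a` and
#'   `b`) and `overlap_bp`, ordered by `a_idx` then `b_idx`.
#' @export
intersect_sets <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  empty <- data.frame(a_idx = integer(), b_idx = integer(), overlap_bp = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  A <- .ir_by_chrom(a); B <- .ir_by_chrom(b)
  out <- list()
  for (chr in intersect(names(A$ir), names(B$ir))) {
    hits <- IRanges::findOverlaps(A$ir[[chr]], B$ir[[chr]], minoverlap = 1L)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(A$ir[[chr]])[qi], IRanges::end(B$ir[[chr]])[si]) -
      pmax(IRanges::start(A$ir[[chr]])[qi], IRanges::start(B$ir[[chr]])[si]) + 1L
    out[[chr]] <- data.frame(a_idx = A$idx[[chr]][qi], b_idx = B$idx[[chr]][si],
                             overlap_bp = as.numeric(ov))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$a_idx, res$b_idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Which intervals of one set overlap any interval of another
#'
#' @param a,b interval data.frames.
#' @return logical vector: TRUE for each row of `a` with >= 1 bp overlap to
#'   any row of `b`.
#' @export
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(hit)
  p <- intersect_sets(a, b)
  hit[unique(p$a_idx)] <- TRUE
  hit
}

# Total bp of the union footprint of an interval set.
footprint_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  A <- .ir_by_chrom(df)
  sum(vapply(A$ir, function(ir) sum(IRanges::width(IRanges::reduce(ir))), numeric(1)))
}

# bp of the intersection of two sets' union footprints.
footprint_intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  A <- .ir_by_chrom(a); B <- .ir_by_chrom(b)
  tot <- 0
  for (chr in intersect(names(A$ir), names(B$ir))) {
    x <- IRanges::intersect(IRanges::reduce(A$ir[[chr]]), IRanges::reduce(B$ir[[chr]]))
    tot <- tot + sum(IRanges::width(x))
  }
  tot
}
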