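#' Read a BED file (BED3/BED4/BED6)
#'
#' Coordinates are kept in BED's native 0-based half-open convention, which is
#' also the package-internal convention, so no shifting occurs.  Columns
#' beyond the third are mapped to `name`, `score`, `strand` when present.
#'
#' @param path file path; tab-separated, no header.
#' @return interval data.frame; malformed lines raise an error naming the
#'   line number.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop("read_bed: ragged BED file ", path, " (line ", which(nf != nf[1])[1], ")")
  nc <- nf[1]
  if (nc < 3) stop("read_bed: need at least 3 columns in ", path)
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop("read_bed: malformed coordinates at line ", bad[1], " of ", path)
  df <- data.frame(chrom = m[, 1], start = start, end = end, stringsAsFactors = FALSE)
  if (nc >= 4) df$name <- m[, 4]
  if (nc >= 5) df$score <- suppressWarnings(as.numeric(m[, 5]))
  if (nc >= 6) df$strand <- m[, 6]
  validate_intervals(df, path)
  df
}

#' Write intervals as BED
#'
#' Emits BED3/4/5/6 depending on which of `name`, `score`, `strand` are
#' present (a later column forces earlier ones, filled with `"."`/`0`).
#' Writing then reading then writing again is byte-identical.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  have <- c(name = "name" %in% names(df), score = "score" %in% names(df),
            strand = "strand" %in% names(df))
  upto <- if (have["strand"]) 6 else if (have["score"]) 5 else if (have["name"]) 4 else 3
  if (upto >= 4) cols <- c(cols, list(if (have["name"]) df$name else rep(".", nrow(df))))
  if (upto >= 5) cols <- c(cols, list(if (have["score"]) format_coord(df$score) else rep("0", nrow(df))))
  if (upto >= 6) cols <- c(cols, list(df$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# integer-like numbers without scientific notation
format_coord <- function(x) {
  ifelse(x == floor(x), sprintf("%.0f", x), sub("0+$", "", sprintf("%.6f", x)))
}

#' Read / write a read-point track file
#'
#' A point track is a headerless two-column TSV (`chrom`, `position`) with one
#' row per read, positions 0-based.  Used for adjusted read-start coverage.
#'
#' @param path file path.
#' @return data.frame with `chrom` and `pos` columns, in file order.
#' @export
read_points <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(), pos = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L))
    stop("read_points: line ", which(lengths(fields) != 2L)[1], " of ", path,
         " does not have 2 columns")
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos) || any(pos < 0))
    stop("read_points: bad position at line ", which(is.na(pos) | pos < 0)[1], " of ", path)
  data.frame(chrom = m[, 1], pos = pos, stringsAsFactors = FALSE)
}

#' @rdname read_points
#' @param df data.frame with `chrom`, `pos`.
#' @export
write_points <- function(df, path) {
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  writeLines(paste(df$chrom, format_coord(df$pos), sep = "\t"), path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings keeping a fixed 80-column line width so
#' that write-read-write round trips are byte-identical.
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs a named DNAStringSet (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read / write an expression table
#'
#' Tab-separated with header; required columns `gene_id`, `log2fc`, `fdr`,
#' optional `mean_expr`.  `fdr` must lie in [0, 1]; duplicate gene ids are
#' rejected.
#'
#' @param path file path.
#' @return data.frame in file order.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_expression: missing columns ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("read_expression: duplicate gene_id ", df$gene_id[anyDuplicated(df$gene_id)])
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) stop("read_expression: fdr outside [0,1]")
  df
}

#' @rdname read_expression
#' @param df expression data.frame.
#' @export
write_expression <- function(df, path) {
  write_tsv(df, path)
}

# header-ful TSV writer with stable number formatting (used for all report
# tables; avoids write.table's quote/rowname surprises)
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x),
                formatC(x, digits = 15, format = "g")))
}
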