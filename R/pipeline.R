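# per-stage seeds derived from the single user-facing seed
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(stage)) * 10007) %% 2147483647)
}

#' Pipeline configuration
#'
#' Either a `simulate` block ([sim_params()]) or an `inputs` list of file
#' paths (`genome`, `genes`, `tads` = named vector of BED paths,
#' `expression`, `reads` = list per condition of read BED paths, `chip` =
#' named vector, `motifs` JASPAR path, `nutlin`).  Stage parameters default
#' to the package defaults.
#'
#' @param simulate a [sim_params()] object, or NULL when `inputs` is given.
#' @param inputs named list of input paths, or NULL.
#' @param thresholds a [de_thresholds()].
#' @param peak_params a [peak_call_params()].
#' @param annotation a [annotation_params()].
#' @param n_perm permutations for the segregation test.
#' @param motif_target_rate per-position hit rate for threshold calibration.
#' @param seed master seed (mandatory; every stage derives its own from it).
#' @param out_dir directory for report tables, or NULL for in-memory only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            thresholds = de_thresholds(),
                            peak_params = peak_call_params(),
                            annotation = annotation_params(),
                            n_perm = 1000, motif_target_rate = 1e-4,
                            seed, out_dir = NULL) {
  if (missing(seed)) stop("pipeline_config: seed is required")
  if (is.null(simulate) && is.null(inputs))
    stop("pipeline_config: either a simulate block or inputs must be given")
  structure(list(simulate = simulate, inputs = inputs, thresholds = thresholds,
                 peak_params = peak_params, annotation = annotation,
                 n_perm = n_perm, motif_target_rate = motif_target_rate,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `simulate`
#' block holds [sim_params()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("read_config: seed is required")
  simulate <- if (!is.null(y$simulate))
    do.call(sim_params, c(y$simulate, if (is.null(y$simulate$seed))
      list(seed = y$seed)))
  pipeline_config(
    simulate = simulate,
    inputs = y$inputs,
    thresholds = do.call(de_thresholds, as.list(y$thresholds)),
    peak_params = do.call(peak_call_params, as.list(y$peak_params)),
    annotation = do.call(annotation_params, as.list(y$annotation)),
    n_perm = if (!is.null(y$n_perm)) y$n_perm else 1000,
    motif_target_rate = if (!is.null(y$motif_target_rate)) y$motif_target_rate else 1e-4,
    seed = y$seed, out_dir = y$out_dir)
}

# load input files into the same shape simulate_dataset() returns
.load_inputs <- function(inputs) {
  need <- c("genome", "genes", "tads", "expression", "reads")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing input: ", paste(miss, collapse = ", "))
  for (f in unlist(inputs[c("genome", "genes", "expression")]))
    if (!file.exists(f)) stop("missing input file: ", f)
  genome <- read_fasta(inputs$genome)
  g <- read_bed(inputs$genes)
  genes <- data.frame(gene_id = g$name, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand, stringsAsFactors = FALSE)
  tads <- lapply(inputs$tads, read_bed)
  reads <- lapply(inputs$reads, function(paths) lapply(paths, read_bed))
  chip <- if (!is.null(inputs$chip)) lapply(inputs$chip, read_bed)
  pwms <- if (!is.null(inputs$motifs)) read_jaspar(inputs$motifs)
  nutlin <- if (!is.null(inputs$nutlin))
    utils::read.delim(inputs$nutlin, stringsAsFactors = FALSE)
  list(genome = genome,
       chrom_sizes = stats::setNames(Biostrings::width(genome), names(genome)),
       genes = genes, tads = tads, expression = read_expression(inputs$expression),
       reads = reads, chip = chip, pwms = pwms, nutlin = nutlin, truth = NULL)
}

# 150-bp summit windows of a peak table (falls back to midpoints)
summit_windows <- function(peaks, width = 150) {
  if (all(c("summit_start", "summit_end") %in% names(peaks)))
    return(genomic_intervals(peaks$chrom, peaks$summit_start, peaks$summit_end))
  mid <- floor((peaks$start + peaks$end) / 2)
  genomic_intervals(peaks$chrom, pmax(0, mid - width / 2),
                    pmax(0, mid - width / 2) + width)
}

#' Run the full integrative pipeline
#'
#' Executes, in dependency order: data simulation (or loading), DE
#' classification, read adjustment and per-condition peak calling,
#' comparative DAR calling, peak-location annotation, the promoter
#' direction table, TAD merging / gene assignment / direction declaration,
#' the segregation permutation test, peak density by TAD direction, DAR
#' stratification, motif enrichment (each DAR direction against the other,
#' for every supplied PWM, BH-adjusted across the panel), ChIP partitioning
#' and DAR-ChIP overlap, treatment-response group comparisons, replicate
#' correlation QC, and (for simulated data) planted-truth recovery metrics.
#' All randomness derives from the single config seed; rerunning an
#' identical config reproduces the report byte for byte.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return list of class `tadlink_report`; when `config$out_dir` is set the
#'   tables are also written as TSV plus a consolidated `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  log_stage("stage: data")
  data <- if (!is.null(config$simulate)) simulate_dataset(config$simulate)
  else .load_inputs(config$inputs)

  log_stage("stage: differential expression")
  de <- classify_de(data$expression, config$thresholds)
  de_counts <- table(factor(de, levels = c("up", "down", "stable")))

  log_stage("stage: peak calling")
  tracks <- lapply(stats::setNames(nm = names(data$reads)), function(cond) {
    reps <- lapply(seq_along(data$reads[[cond]]), function(k)
      adjust_reads(data$reads[[cond]][[k]], condition = cond,
                   replicate = as.character(k)))
    list(reps = reps, merged = do.call(track_merge, c(reps, list(condition = cond))))
  })
  cond_names <- names(tracks)
  if (length(cond_names) != 2)
    stop("run_pipeline: exactly two conditions (parental, transformed) required")
  parental <- if ("parental" %in% cond_names) "parental" else cond_names[1]
  transformed <- setdiff(cond_names, parental)[1]
  peaks <- lapply(tracks, function(t)
    call_peaks(t$merged, data$chrom_sizes, config$peak_params))

  log_stage("stage: DAR calling")
  dars <- call_dars(peaks[[parental]], peaks[[transformed]],
                    tracks[[parental]]$merged, tracks[[transformed]]$merged,
                    data$chrom_sizes, config$peak_params)

  log_stage("stage: annotation")
  annotation <- lapply(list(gained = dars$gained, lost = dars$lost,
                            shared = dars$shared), function(pk)
                              annotate_location(pk, data$genes, config$annotation))
  location_table <- do.call(rbind, lapply(names(annotation), function(cl)
    data.frame(class = cl, t(annotation[[cl]]$proportions))))
  promoter_direction <- promoter_direction_table(dars, data$genes, de,
                                                 config$annotation)

  log_stage("stage: TAD linking")
  tads <- merge_tad_sets(data$tads)
  assignment <- assign_smallest_tad(data$genes, tads)
  direction <- declare_direction(assignment, de)
  segregation <- segregation_permutation(assignment, de, config$n_perm,
                                         derive_seed(config$seed, "segregation"))
  density <- lapply(peaks, function(pk) peak_density_by_tad(pk, tads, direction))
  strata <- link_dars_to_tads(dars, tads, direction)

  log_stage("stage: motif enrichment")
  motif_table <- NULL
  if (!is.null(data$pwms) && nrow(dars$gained) && nrow(dars$lost)) {
    sw_g <- summit_windows(dars$gained); sw_l <- summit_windows(dars$lost)
    rows <- list()
    for (id in names(data$pwms)) {
      pwm <- data$pwms[[id]]
      thr <- calibrate_threshold(pwm, config$motif_target_rate)
      # scan each summit set once per motif, then form both contrasts
      hit_g <- .window_has_hit(sw_g, data$genome, pwm, thr)
      hit_l <- .window_has_hit(sw_l, data$genome, pwm, thr)
      for (dir in c("gained", "lost")) {
        k_fg <- sum(if (dir == "gained") hit_g else hit_l)
        k_bg <- sum(if (dir == "gained") hit_l else hit_g)
        n_fg <- if (dir == "gained") length(hit_g) else length(hit_l)
        n_bg <- if (dir == "gained") length(hit_l) else length(hit_g)
        e <- hypergeom_enrichment(k_fg, n_fg, k_bg, n_bg)
        rows[[paste(id, dir)]] <- data.frame(
          motif_id = pwm$motif_id, foreground = dir,
          k_fg = e$k_fg, n_fg = e$n_fg, k_bg = e$k_bg, n_bg = e$n_bg,
          fg_pct = 100 * e$fg_fraction, bg_pct = 100 * e$bg_fraction,
          p = e$p_one_sided, stringsAsFactors = FALSE)
      }
    }
    motif_table <- do.call(rbind, rows)
    motif_table$p_adj <- stats::p.adjust(motif_table$p, method = "BH")
    rownames(motif_table) <- NULL
  }

  log_stage("stage: ChIP overlap")
  chip_results <- NULL
  if (!is.null(data$chip) && length(data$chip) >= 1) {
    chip_results <- list()
    if (length(data$chip) >= 2) {
      chip_results$partition <- partition_peaks(data$chip[[1]], data$chip[[2]])
      chip_results$partition_counts <- c(
        shared = nrow(chip_results$partition$shared),
        a_specific = nrow(chip_results$partition$a_specific),
        b_specific = nrow(chip_results$partition$b_specific))
    }
    chip_tf <- if (!is.null(data$chip$transformed)) data$chip$transformed
    else data$chip[[length(data$chip)]]
    chip_results$dar_overlap <- dar_chip_overlap(dars, chip_tf, strata)
    chip_par <- if (!is.null(data$chip$parental)) data$chip$parental else data$chip[[1]]
    chip_results$lost_fraction <- chip_dar_fraction(chip_par, dars,
                                                    reference = chip_tf)
  }

  log_stage("stage: treatment response")
  nutlin_results <- NULL
  if (!is.null(data$nutlin) && !is.null(data$pwms) && nrow(dars$lost)) {
    p53_id <- grep("p53", names(data$pwms), ignore.case = TRUE, value = TRUE)
    p53_pwm <- data$pwms[[if (length(p53_id)) p53_id[1] else names(data$pwms)[1]]]
    thr <- calibrate_threshold(p53_pwm, config$motif_target_rate)
    lost_has_motif <- .window_has_hit(summit_windows(dars$lost), data$genome,
                                      p53_pwm, thr)
    groups <- build_groups(de, assignment, dars, lost_has_motif)
    nutlin_results <- c(list(groups = groups),
                        compare_response(groups, data$nutlin))
  }

  log_stage("stage: replicate QC")
  replicate_qc <- lapply(tracks, function(t) {
    n_sub <- min(t$reps[[1]]$total, t$reps[[2]]$total)
    replicate_correlation(t$reps[[1]], t$reps[[2]], data$chrom_sizes,
                          n_subsample = n_sub,
                          seed = derive_seed(config$seed, "replicate_qc"),
                          params = config$peak_params)$r
  })

  recovery <- NULL
  if (!is.null(data$truth)) {
    log_stage("stage: planted-truth recovery")
    recovery <- list(dar_jaccard = dar_recovery_jaccard(dars, data$truth$dars))
  }

  report <- structure(list(
    de_counts = de_counts,
    peak_counts = vapply(peaks, nrow, integer(1)),
    dar_counts = c(gained = nrow(dars$gained), lost = nrow(dars$lost),
                   shared = nrow(dars$shared)),
    location = location_table,
    promoter_direction = promoter_direction,
    tad_direction_counts = table(factor(direction,
                                        levels = c("up", "down", "mixed", "none"))),
    segregation = segregation,
    density = density,
    strata = strata,
    motif_enrichment = motif_table,
    chip = chip_results,
    nutlin = nutlin_results,
    replicate_qc = replicate_qc,
    recovery = recovery,
    peaks = peaks, dars = dars, de = de, assignment = assignment,
    direction = direction, data = data,
    provenance = list(seed = config$seed, n_perm = config$n_perm,
                      version = as.character(utils::packageVersion("tadlink")))),
    class = "tadlink_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  log_stage("done")
  report
}

#' @export
print.tadlink_report <- function(x, ...) {
  cat("tadlink report\n")
  cat("  DE genes: ", x$de_counts[["up"]], " up, ", x$de_counts[["down"]],
      " down, ", x$de_counts[["stable"]], " stable\n", sep = "")
  cat("  peaks: ", paste(names(x$peak_counts), x$peak_counts, collapse = ", "),
      "\n", sep = "")
  cat("  DARs: ", x$dar_counts[["gained"]], " gained, ", x$dar_counts[["lost"]],
      " lost, ", x$dar_counts[["shared"]], " shared\n", sep = "")
  cat(sprintf("  segregation: observed %.3f Mb, p = %.4g\n",
              x$segregation$observed_mb, x$segregation$p_lower))
  if (!is.null(x$motif_enrichment)) {
    cat("  motif enrichment (top):\n")
    top <- x$motif_enrichment[order(x$motif_enrichment$p), ][1, ]
    cat(sprintf("    %s in %s DARs: %.1f%% vs %.1f%%, p = %.3g\n",
                top$motif_id, top$foreground, top$fg_pct, top$bg_pct, top$p))
  }
  if (!is.null(x$recovery))
    cat(sprintf("  planted-DAR Jaccard: %.3f\n", x$recovery$dar_jaccard))
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits one TSV per table plus a consolidated `report.json` with the
#' headline numbers.  Identical reports produce byte-identical files.
#'
#' @param report a `tadlink_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_tsv(data.frame(status = names(report$de_counts),
                       n = as.integer(report$de_counts)), fp("de_counts.tsv"))
  write_tsv(report$location, fp("location_proportions.tsv"))
  if (!is.null(report$motif_enrichment))
    write_tsv(report$motif_enrichment, fp("motif_enrichment.tsv"))
  if (!is.null(report$chip))
    write_tsv(report$chip$dar_overlap$table, fp("chip_dar_overlap.tsv"))
  if (!is.null(report$nutlin) && !is.null(report$nutlin$tests))
    write_tsv(report$nutlin$tests, fp("nutlin_tests.tsv"))
  for (cl in c("gained", "lost", "shared")) {
    pk <- report$dars[[cl]]
    if (!nrow(pk)) next
    bed <- genomic_intervals(pk$chrom, pk$start, pk$end, name = cl,
                             score = round(-log10(pmax(pk$p_value, 1e-300)), 2),
                             strand = "*")
    write_bed(bed[c("chrom", "start", "end", "name", "score", "strand")],
              fp(paste0("dars_", cl, ".bed")))
  }
  summary <- list(
    de_counts = as.list(report$de_counts),
    peak_counts = as.list(report$peak_counts),
    dar_counts = as.list(report$dar_counts),
    tad_direction_counts = as.list(report$tad_direction_counts),
    segregation = list(observed_mb = report$segregation$observed_mb,
                       p_lower = report$segregation$p_lower,
                       n_perm = report$segregation$n_perm),
    density_p = lapply(report$density, function(d)
      if (!is.null(d$test)) d$test$p else NA),
    replicate_qc = report$replicate_qc,
    recovery = report$recovery,
    provenance = report$provenance)
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
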