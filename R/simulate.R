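#' Parameters of the synthetic regulatory-genome generator
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: a 2 x 10 Mb genome partitioned into 0.3-1.5 Mb TADs with three
#' cell-line TAD variants, 1-4 genes per TAD of which 20% are differentially
#' expressed with TAD-wise direction homogeneity 0.95, 150 planted DARs per
#' direction at 8-fold read enrichment over a 0.02 reads/bp background,
#' motif planting probabilities 0.4 (matched direction) versus 0.05
#' (opposite), ChIP co-location probabilities 0.7 (gained) versus 0.1
#' (lost), and a +0.5 shift in |log2FC| for the p53-responsive gene group.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length, bp.
#' @param tad_len_range TAD length range, bp.
#' @param n_celllines number of cell-line TAD variants (variants split a
#'   subset of reference TADs, exercising smallest-TAD assignment).
#' @param genes_per_tad integer range of genes per TAD.
#' @param gene_len_range gene body length range, bp.
#' @param frac_de fraction of genes differentially expressed.
#' @param segregation_pi probability that a DE-containing TAD is
#'   direction-homogeneous, in [0.5, 1].
#' @param bg_rate background read rate, reads per bp per condition (both
#'   replicates together).
#' @param n_dars_per_direction planted DARs per direction.
#' @param dar_width planted DAR width, bp.
#' @param dar_fold read-rate fold enrichment inside a DAR for its owning
#'   condition.
#' @param n_shared_peaks accessible regions shared by both conditions.
#' @param dar_tad_bias probability that a DAR is placed inside a TAD of its
#'   matching expression direction.
#' @param motif_rho_fg,motif_rho_bg probability of planting a motif in a
#'   matched-direction versus opposite-direction DAR summit.
#' @param chip_gained_p,chip_lost_p probability of a ChIP peak co-located
#'   with a gained / lost DAR.
#' @param n_chip_background unco-located background ChIP peaks.
#' @param chip_width ChIP peak width, bp.
#' @param nutlin_effect planted shift in |log2FC| for the down-regulated
#'   motif-bearing group after treatment.
#' @param nutlin_sd baseline treatment log2FC standard deviation.
#' @param read_len raw read length, bp.
#' @param seed RNG seed (mandatory).
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_chrom = 2, chrom_len = 10e6,
                       tad_len_range = c(0.3e6, 1.5e6), n_celllines = 3,
                       genes_per_tad = c(1, 4), gene_len_range = c(5000, 50000),
                       frac_de = 0.2, segregation_pi = 0.95, bg_rate = 0.02,
                       n_dars_per_direction = 150, dar_width = 300,
                       dar_fold = 8, n_shared_peaks = 200, dar_tad_bias = 0.9,
                       motif_rho_fg = 0.4, motif_rho_bg = 0.05,
                       chip_gained_p = 0.7, chip_lost_p = 0.1,
                       n_chip_background = 100, chip_width = 250,
                       nutlin_effect = 0.5, nutlin_sd = 0.2, read_len = 51,
                       seed) {
  if (missing(seed)) stop("sim_params: seed is required")
  p <- as.list(environment())
  stopifnot(p$n_chrom >= 1, p$chrom_len > 2 * p$tad_len_range[2],
            p$tad_len_range[1] > 0, p$tad_len_range[1] < p$tad_len_range[2],
            p$n_celllines >= 1, p$frac_de >= 0, p$frac_de <= 1,
            p$segregation_pi >= 0.5, p$segregation_pi <= 1,
            p$bg_rate > 0, p$dar_fold >= 1,
            p$motif_rho_fg >= 0, p$motif_rho_fg <= 1,
            p$motif_rho_bg >= 0, p$motif_rho_bg <= 1,
            p$chip_gained_p >= 0, p$chip_gained_p <= 1,
            p$chip_lost_p >= 0, p$chip_lost_p <= 1)
  structure(p, class = "sim_params")
}

#' Null-association variant of a parameter set
#'
#' Removes every planted association: direction homogeneity drops to 0.5,
#' motif planting is equal in both DAR directions, DAR placement ignores TAD
#' direction, ChIP co-location is equal for gained and lost, and the
#' treatment effect is 0.  Used for calibration and type-I-error studies.
#'
#' @param params a [sim_params()] object.
#' @return a modified `sim_params`.
#' @export
null_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  params$segregation_pi <- 0.5
  params$motif_rho_fg <- params$motif_rho_bg
  params$dar_tad_bias <- 0
  params$chip_gained_p <- 0.3
  params$chip_lost_p <- 0.3
  params$nutlin_effect <- 0
  params
}

#' @rdname null_params
#' @param tracks passed to [simulate_dataset()].
#' @export
null_variant <- function(params, tracks = TRUE) {
  simulate_dataset(null_params(params), tracks = tracks)
}

# synthetic motifs planted by the generator: near-deterministic consensus PFMs
.sim_pwms <- function() {
  consensus_pwm <- function(id, consensus) {
    codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    counts <- matrix(0, 4, length(codes))
    counts[cbind(codes, seq_along(codes))] <- 100
    build_logodds(counts, motif_id = id)
  }
  list(gained_tf = consensus_pwm("GAINED_TF_synthetic", "TGGCCACCAGGG"),
       p53_like = consensus_pwm("P53LIKE_synthetic", "GGGCATGTCC"))
}

# place n non-overlapping intervals of width w; each row of `regions` is a
# candidate container sampled with its given probability, NA rows mean
# genome-wide placement.  `occupied` is a per-chrom list of (start,end).
.place_intervals <- function(n, w, containers, use_container_p, chrom_sizes,
                             occupied, margin = 200) {
  chroms <- names(chrom_sizes)
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:100) {
      inside <- !is.null(containers) && nrow(containers) > 0 &&
        stats::runif(1) < use_container_p
      if (inside) {
        j <- sample.int(nrow(containers), 1)
        chr <- containers$chrom[j]
        lo <- containers$start[j]; hi <- containers$end[j] - w
      } else {
        chr <- sample(chroms, 1)
        lo <- 0; hi <- chrom_sizes[[chr]] - w
      }
      if (hi <= lo) next
      s <- floor(stats::runif(1, lo, hi))
      occ <- occupied[[chr]]
      clash <- !is.null(occ) && any(occ$start < s + w + margin & occ$end > s - margin)
      if (!clash) {
        out$chrom[i] <- chr; out$start[i] <- s; out$end[i] <- s + w
        occupied[[chr]] <- rbind(occ, data.frame(start = s, end = s + w))
        placed <- TRUE
        break
      }
    }
    if (!placed) {  # dense genome: accept a clash rather than fail
      chr <- sample(chroms, 1)
      s <- floor(stats::runif(1, 0, chrom_sizes[[chr]] - w))
      out$chrom[i] <- chr; out$start[i] <- s; out$end[i] <- s + w
      occupied[[chr]] <- rbind(occupied[[chr]], data.frame(start = s, end = s + w))
    }
  }
  list(intervals = out, occupied = occupied)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds a small genome whose chromosomes are partitioned into TADs (with
#' per-cell-line variants obtained by splitting a subset of domains),
#' populates TADs with genes, assigns TAD-wise segregated differential
#' expression, plants gained and lost DARs preferentially in up and down
#' TADs, plants motif consensus sequences in DAR centers, draws per-condition
#' per-replicate read tracks with Poisson noise and fold enrichment inside
#' the owning condition's DARs, places co-located ChIP peaks, and produces a
#' treatment-response table with a planted group effect.  Everything is
#' reproducible bit-exactly from the seed.
#'
#' @param params a [sim_params()] object.
#' @param tracks generate the genome-wide read tracks (the expensive part);
#'   with `FALSE` the `reads` element is NULL, for studies that only need
#'   the planted structure.
#' @param sequence generate the genome sequence (and plant motifs in it);
#'   with `FALSE` the `genome` element is NULL, for studies that only need
#'   the interval-level structure (e.g. permutation-test calibration).
#' @return list of class `sim_dataset` with elements `params`, `chrom_sizes`,
#'   `genome`, `genes`, `tads` (per-cell-line list), `expression`, `reads`
#'   (per condition, list of 2 replicate read data.frames), `chip`
#'   (`parental`, `transformed`), `pwms`, `nutlin`, `truth`.
#' @export
simulate_dataset <- function(params, tracks = TRUE, sequence = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  chrom_sizes <- stats::setNames(rep(p$chrom_len, p$n_chrom),
                                 paste0("chr", seq_len(p$n_chrom)))

  ## --- TADs: reference partition + split variants -------------------------
  ref_tads <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    bounds <- 0
    while (bounds[length(bounds)] < p$chrom_len) {
      len <- stats::runif(1, p$tad_len_range[1], p$tad_len_range[2])
      bounds <- c(bounds, min(bounds[length(bounds)] + len, p$chrom_len))
    }
    # merge a short terminal remainder into the previous domain
    if (length(bounds) > 2 &&
        diff(utils::tail(bounds, 2)) < p$tad_len_range[1])
      bounds <- bounds[-(length(bounds) - 1)]
    data.frame(chrom = chr, start = floor(utils::head(bounds, -1)),
               end = floor(bounds[-1]), stringsAsFactors = FALSE)
  }))
  rownames(ref_tads) <- NULL
  tad_sets <- list(cellline1 = ref_tads)
  if (p$n_celllines > 1) for (v in 2:p$n_celllines) {
    splittable <- which(ref_tads$end - ref_tads$start >= 2 * p$tad_len_range[1])
    to_split <- sample(splittable, size = max(1, round(0.3 * length(splittable))))
    parts <- lapply(seq_len(nrow(ref_tads)), function(i) {
      row <- ref_tads[i, ]
      if (i %in% to_split) {
        mid <- floor(stats::runif(1, row$start + p$tad_len_range[1] / 2,
                                  row$end - p$tad_len_range[1] / 2))
        data.frame(chrom = row$chrom, start = c(row$start, mid),
                   end = c(mid, row$end))
      } else row[c("chrom", "start", "end")]
    })
    tad_sets[[paste0("cellline", v)]] <- `rownames<-`(do.call(rbind, parts), NULL)
  }

  ## --- genes --------------------------------------------------------------
  gene_rows <- list()
  gid <- 0
  for (i in seq_len(nrow(ref_tads))) {
    n_g <- sample(p$genes_per_tad[1]:p$genes_per_tad[2], 1)
    for (g in seq_len(n_g)) {
      gid <- gid + 1
      len <- floor(stats::runif(1, p$gene_len_range[1], p$gene_len_range[2]))
      s <- floor(stats::runif(1, ref_tads$start[i], ref_tads$end[i] - len))
      gene_rows[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid), chrom = ref_tads$chrom[i],
        start = s, end = s + len, strand = sample(c("+", "-"), 1),
        tad = i, stringsAsFactors = FALSE)
    }
  }
  genes_full <- do.call(rbind, gene_rows)
  n_genes <- nrow(genes_full)

  ## --- TAD-wise segregated differential expression ------------------------
  n_de <- round(p$frac_de * n_genes)
  status <- rep("stable", n_genes)
  # DE expression is TAD-wise: gene-rich TADs are preferred hosts (coherent
  # regulatory domains), TAD directions alternate so both directions exist,
  # and each DE gene adopts its TAD's direction with probability pi.  At
  # pi = 0.5 the directions are i.i.d. coin flips, i.e. no TAD-direction
  # association at all, which is what the null variant requires.
  tad_sizes <- tabulate(genes_full$tad, nbins = nrow(ref_tads))
  tad_order <- order(-tad_sizes, stats::runif(nrow(ref_tads)))
  budget <- n_de
  de_tad_count <- 0
  for (ti in tad_order) {
    if (budget <= 0) break
    # single-gene remainders are only spent while fewer than two DE TADs
    # exist (both directions must occur); afterwards DE stays domain-wise
    if (budget == 1 && de_tad_count >= 2) break
    members <- which(genes_full$tad == ti)
    cap <- if (de_tad_count == 0) max(1, ceiling(n_de / 2)) else budget
    take <- utils::head(sample(members), min(length(members), cap, budget))
    if (!length(take)) next
    de_tad_count <- de_tad_count + 1
    dir <- if (de_tad_count %% 2 == 1) "up" else "down"
    adopt <- stats::runif(length(take)) < p$segregation_pi
    lab <- ifelse(adopt, dir, setdiff(c("up", "down"), dir))
    status[take] <- lab
    budget <- budget - length(take)
  }
  lfc <- stats::rnorm(n_genes, 0, 0.15)
  fdr <- stats::runif(n_genes, 0.05, 1)
  de_i <- status != "stable"
  lfc[de_i] <- ifelse(status[de_i] == "up", 1, -1) *
    (0.8 + stats::rexp(sum(de_i), rate = 2))
  fdr[de_i] <- stats::runif(sum(de_i), 0, 0.049)
  expression <- data.frame(gene_id = genes_full$gene_id, log2fc = lfc,
                           fdr = fdr,
                           mean_expr = stats::rlnorm(n_genes, 3, 1),
                           stringsAsFactors = FALSE)
  tad_dir_true <- .direction_from_labels(genes_full$tad, status, nrow(ref_tads))

  ## --- planted DARs and shared accessible regions -------------------------
  occupied <- stats::setNames(vector("list", length(chrom_sizes)), names(chrom_sizes))
  up_tads <- ref_tads[tad_dir_true == "up", , drop = FALSE]
  down_tads <- ref_tads[tad_dir_true == "down", , drop = FALSE]
  pg <- .place_intervals(p$n_dars_per_direction, p$dar_width, up_tads,
                         p$dar_tad_bias, chrom_sizes, occupied)
  occupied <- pg$occupied
  pl <- .place_intervals(p$n_dars_per_direction, p$dar_width, down_tads,
                         p$dar_tad_bias, chrom_sizes, occupied)
  occupied <- pl$occupied
  ps <- .place_intervals(p$n_shared_peaks, p$dar_width, NULL, 0, chrom_sizes,
                         occupied)
  occupied <- ps$occupied
  dars_true <- rbind(
    cbind(pg$intervals, direction = "gained", stringsAsFactors = FALSE),
    cbind(pl$intervals, direction = "lost", stringsAsFactors = FALSE))
  shared_true <- ps$intervals

  ## --- motif planting and genome sequence ---------------------------------
  pwms <- .sim_pwms()
  gain_consensus <- "TGGCCACCAGGG"
  lost_consensus <- "GGGCATGTCC"
  is_gain <- dars_true$direction == "gained"
  has_gain_motif <- ifelse(is_gain,
                           stats::runif(nrow(dars_true)) < p$motif_rho_fg,
                           stats::runif(nrow(dars_true)) < p$motif_rho_bg)
  has_lost_motif <- ifelse(is_gain,
                           stats::runif(nrow(dars_true)) < p$motif_rho_bg,
                           stats::runif(nrow(dars_true)) < p$motif_rho_fg)
  centers <- floor((dars_true$start + dars_true$end) / 2)
  genome <- NULL
  if (sequence) {
    letters4 <- c("A", "C", "G", "T")
    codes_of <- function(s) match(strsplit(s, "")[[1]], letters4)
    genome_codes <- lapply(chrom_sizes, function(len)
      sample.int(4, len, replace = TRUE))
    plant <- function(chr, at, consensus) {
      cd <- codes_of(consensus)
      genome_codes[[chr]][(at + 1):(at + length(cd))] <<- cd
    }
    for (i in seq_len(nrow(dars_true))) {
      if (has_gain_motif[i])
        plant(dars_true$chrom[i], centers[i] - 25, gain_consensus)
      if (has_lost_motif[i])
        plant(dars_true$chrom[i], centers[i] + 10, lost_consensus)
    }
    genome <- Biostrings::DNAStringSet(vapply(genome_codes, function(cd)
      rawToChar(as.raw(c(65L, 67L, 71L, 84L)[cd])), character(1)))
    names(genome) <- names(chrom_sizes)
  }

  ## --- read tracks ---------------------------------------------------------
  reads <- NULL
  if (tracks) {
    rate_rep <- p$bg_rate / 2
    elevated <- list(
      parental = rbind(shared_true, dars_true[!is_gain, c("chrom", "start", "end")]),
      transformed = rbind(shared_true, dars_true[is_gain, c("chrom", "start", "end")]))
    sim_rep <- function(cond) {
      pts <- list()
      for (chr in names(chrom_sizes)) {
        n_bg <- stats::rpois(1, rate_rep * chrom_sizes[[chr]])
        pos <- floor(stats::runif(n_bg, 0, chrom_sizes[[chr]]))
        ev <- elevated[[cond]]
        ev <- ev[ev$chrom == chr, , drop = FALSE]
        if (nrow(ev)) {
          # enriched reads pile up around the region center (Gaussian
          # profile) so every planted region has a well-defined summit;
          # the total excess still integrates to (dar_fold - 1) x background
          n_ex <- stats::rpois(nrow(ev), rate_rep * (p$dar_fold - 1) *
                                 (ev$end - ev$start))
          extra <- unlist(lapply(seq_len(nrow(ev)), function(i) {
            ctr <- (ev$start[i] + ev$end[i]) / 2
            wd <- ev$end[i] - ev$start[i]
            floor(pmin(pmax(stats::rnorm(n_ex[i], ctr, wd / 6),
                            ev$start[i]), ev$end[i] - 1))
          }))
          pos <- c(pos, extra)
        }
        pts[[chr]] <- pos
      }
      centers <- unlist(pts, use.names = FALSE)
      chrom <- rep(names(pts), lengths(pts))
      strand <- sample(c("+", "-"), length(centers), replace = TRUE)
      start <- ifelse(strand == "+", centers - 4, centers + 5 - p$read_len)
      lim <- chrom_sizes[chrom] - p$read_len
      start <- pmin(pmax(start, 0), lim)
      data.frame(chrom = chrom, start = start, end = start + p$read_len,
                 strand = strand, stringsAsFactors = FALSE)
    }
    reads <- list(parental = list(sim_rep("parental"), sim_rep("parental")),
                  transformed = list(sim_rep("transformed"), sim_rep("transformed")))
  }

  ## --- ChIP peaks ----------------------------------------------------------
  chip_at <- function(idx) {
    jit <- floor(stats::runif(length(idx), -50, 50))
    ctr <- centers[idx] + jit
    data.frame(chrom = dars_true$chrom[idx],
               start = pmax(0, ctr - floor(p$chip_width / 2)),
               end = pmax(0, ctr - floor(p$chip_width / 2)) + p$chip_width,
               stringsAsFactors = FALSE)
  }
  colocated_t <- ifelse(is_gain, stats::runif(nrow(dars_true)) < p$chip_gained_p,
                        stats::runif(nrow(dars_true)) < p$chip_lost_p)
  colocated_p <- ifelse(is_gain, stats::runif(nrow(dars_true)) < p$chip_lost_p,
                        stats::runif(nrow(dars_true)) < p$chip_gained_p)
  bg_chip <- .place_intervals(p$n_chip_background, p$chip_width, NULL, 0,
                              chrom_sizes, occupied)$intervals
  order_gi <- function(df) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  chip <- list(
    parental = order_gi(rbind(chip_at(which(colocated_p)), bg_chip)),
    transformed = order_gi(rbind(chip_at(which(colocated_t)), bg_chip)))

  ## --- treatment response --------------------------------------------------
  down_genes <- genes_full$gene_id[status == "down"]
  motif_lost_dars <- dars_true[has_lost_motif & !is_gain, , drop = FALSE]
  tad_has_motif_dar <- overlaps_any(ref_tads, motif_lost_dars)
  group_p53 <- genes_full$gene_id[status == "down" &
                                    tad_has_motif_dar[genes_full$tad]]
  base <- stats::rnorm(n_genes, 0, p$nutlin_sd)
  shift <- ifelse(genes_full$gene_id %in% group_p53, p$nutlin_effect, 0)
  nutlin <- data.frame(gene_id = genes_full$gene_id,
                       log2fc = sign(base) * (abs(base) + shift),
                       stringsAsFactors = FALSE)

  truth <- list(
    dars = dars_true,
    shared_peaks = shared_true,
    tad_direction = tad_dir_true,
    gene_status = stats::setNames(status, genes_full$gene_id),
    gene_tad = stats::setNames(genes_full$tad, genes_full$gene_id),
    has_gain_motif = has_gain_motif,
    has_lost_motif = has_lost_motif,
    chip_colocated_transformed = colocated_t,
    chip_colocated_parental = colocated_p,
    hras_down_p53 = group_p53,
    params = unclass(p))

  structure(list(params = p, chrom_sizes = chrom_sizes, genome = genome,
                 genes = genes_full[c("gene_id", "chrom", "start", "end", "strand")],
                 tads = tad_sets, expression = expression, reads = reads,
                 chip = chip, pwms = pwms, nutlin = nutlin, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", length(x$chrom_sizes), " chromosome(s) x ",
      format(x$chrom_sizes[[1]], big.mark = ","), " bp, ",
      nrow(x$genes), " genes, ", nrow(x$truth$dars), " planted DARs",
      if (is.null(x$reads)) " (no read tracks)", "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genome.fa`, `genes.bed` (BED6), one `tads_<cellline>.bed` per
#' variant, `expression.tsv`, `nutlin.tsv`, `reads_<condition>_rep<k>.bed`
#' (when tracks were generated), `chip_<condition>.bed`,
#' `motifs_synthetic.jaspar` and `truth.json`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  if (!is.null(dataset$genome)) write_fasta(dataset$genome, fp("genome.fa"))
  g <- dataset$genes
  write_bed(genomic_intervals(g$chrom, g$start, g$end, strand = g$strand,
                              name = g$gene_id, score = 0), fp("genes.bed"))
  for (src in names(dataset$tads))
    write_bed(dataset$tads[[src]], fp(paste0("tads_", src, ".bed")))
  write_expression(dataset$expression, fp("expression.tsv"))
  write_tsv(dataset$nutlin, fp("nutlin.tsv"))
  if (!is.null(dataset$reads))
    for (cond in names(dataset$reads))
      for (k in seq_along(dataset$reads[[cond]])) {
        r <- dataset$reads[[cond]][[k]]
        write_bed(genomic_intervals(r$chrom, r$start, r$end, strand = r$strand,
                                    name = ".", score = 0),
                  fp(sprintf("reads_%s_rep%d.bed", cond, k)))
      }
  for (cond in names(dataset$chip))
    write_bed(dataset$chip[[cond]], fp(paste0("chip_", cond, ".bed")))
  write_jaspar(dataset$pwms, fp("motifs_synthetic.jaspar"))
  jsonlite::write_json(dataset$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Jaccard index between called DARs and planted truth
#'
#' Region-level (default): a called DAR and a planted DAR match when they
#' overlap by >= 1 bp; the index is `matched / (called + planted - matched)`.
#' This is the natural resolution for a caller whose windows move in 75-bp
#' steps, so boundaries are only localised to within a window.  The
#' base-pair mode computes footprint intersection over footprint union
#' instead.
#'
#' @param dars a `dar_set` from [call_dars()].
#' @param truth_dars planted DAR interval data.frame.
#' @param mode `"region"` or `"bp"`.
#' @return Jaccard index in [0, 1].
#' @export
dar_recovery_jaccard <- function(dars, truth_dars, mode = c("region", "bp")) {
  mode <- match.arg(mode)
  called <- rbind(dars$gained[c("chrom", "start", "end")],
                  dars$lost[c("chrom", "start", "end")])
  if (!nrow(called) && !nrow(truth_dars)) return(1)
  if (!nrow(called) || !nrow(truth_dars)) return(0)
  if (mode == "bp") {
    inter <- footprint_intersect_bp(called, truth_dars)
    uni <- footprint_bp(called) + footprint_bp(truth_dars) - inter
    return(inter / uni)
  }
  n_match_called <- sum(overlaps_any(called, truth_dars))
  n_match_truth <- sum(overlaps_any(truth_dars, called))
  # matched pairs counted once: use the smaller side to avoid double counts
  m <- min(n_match_called, n_match_truth)
  m / (nrow(called) + nrow(truth_dars) - m)
}
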