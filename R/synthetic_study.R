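#' @keywords internal
"_PACKAGE"

## Canonical mark order; each mark owns an RNG stream split from the master
## seed so adding or dropping a mark never perturbs the draws of the others.
CHROMAGE_MARKS <- c("H3K27ac", "H3K27me3", "H3K4me3", "H2AK119ub")

CHROMAGE_CLASSES <- c("background", "identity", "bivalent_c1", "bivalent_c2",
                      "stress")

## Per-class per-mark baseline offsets (log2 units). They encode the planted
## chromatin signatures: identity genes are strongly active (high H3K27ac),
## both bivalent classes carry H3K4me3 + H3K27me3, and the two bivalent
## subclasses differ only in H2AK119ub (high vs low), mirroring the
## PRC1-mark-based subclustering of bivalent promoters.
CLASS_OFFSETS <- matrix(
  c(# H3K27ac H3K27me3 H3K4me3 H2AK119ub
    0,    0,    0,    0,    # background
    2,   -1,    1,   -1,    # identity
   -1,    2,    2,    2,    # bivalent_c1 (H2AK119ub-high)
   -1,    2,    2,   -2,    # bivalent_c2 (H2AK119ub-low)
    1,    0,  1.5,    0),   # stress
  nrow = 5, byrow = TRUE,
  dimnames = list(CHROMAGE_CLASSES, CHROMAGE_MARKS)
)

#' Configuration of a synthetic multi-mark chromatin study
#'
#' Describes a simulated two-genotype (WT vs HD), three-age histone-mark
#' profiling study with planted gene classes. Counts are drawn from a
#' negative binomial with mean `mu = 2^(baseline + class effect) * size
#' factor` and variance `mu + alpha * mu^2`. The HD genotype ages on an
#' accelerated clock: its effective age is `kappa * age` (multiplicative
#' mode) or `age + kappa` months (additive mode), so `kappa = 1.5` makes a
#' 6-month HD animal epigenetically 9 months old — a 3-month distortion.
#'
#' Class effects (log2 units, as a function of effective age `e`):
#' * `bivalent_c1`: H3K27ac slope `+beta_ac * e`, H3K27me3 `-beta_me3 * e`,
#'   H2AK119ub `-beta_ub * e`, H3K4me3 flat-high — progressive
#'   euchromatinization of bivalent developmental genes with loss of the
#'   PRC1 mark.
#' * `bivalent_c2`: same H3K27ac/H3K27me3 dynamics but H2AK119ub low and
#'   flat.
#' * `identity`: HD-only H3K27ac decline and H3K27me3 gain
#'   (`-/+ beta_identity * e`), flat in WT — loss of neuronal identity marks
#'   restricted to the disease genotype.
#' * `stress`: inverted-U in effective age for H3K27ac (mirrored for
#'   H3K27me3), `-/+ stress_curvature * (e - stress_peak_age)^2`; on the WT
#'   clock this peaks at `stress_peak_age`, while HD reads the same curve at
#'   accelerated ages and therefore declines.
#' * `background`: flat.
#'
#' @param seed master RNG seed (integer).
#' @param n_background,n_identity,n_bivalent_c1,n_bivalent_c2,n_stress gene
#'   counts per planted class. The defaults keep the dynamic classes a clear
#'   minority (~22% of genes): median-of-ratios normalization assumes that
#'   most regions are unchanged, as they are genome-wide.
#' @param ages strictly increasing chronological ages in months.
#' @param genotypes character vector, subset of `c("WT", "HD")`.
#' @param n_replicates biological replicates per (genotype, age) cell.
#' @param marks subset of `r paste(CHROMAGE_MARKS, collapse = ", ")`.
#' @param dispersion negative-binomial dispersion `alpha` (>= 0; 0 = Poisson).
#' @param baseline_log2_mean either a length-2 range applied to every mark or
#'   a named list of per-mark ranges for the gene baseline log2 mean.
#' @param baseline_jitter_sd SD (log2) of the per-gene-per-mark jitter added
#'   to a shared per-gene baseline, modelling correlated accessibility of a
#'   locus across marks.
#' @param size_factor_range range of the uniform library-size factors.
#' @param acceleration_kappa HD aging-acceleration parameter (> 0).
#' @param acceleration_mode `"multiplicative"` (effective age `kappa * age`)
#'   or `"additive"` (`age + kappa`).
#' @param beta_ac,beta_me3,beta_ub per-month log2 slopes of the bivalent-class
#'   mark trajectories.
#' @param beta_identity per-month log2 slope of the HD-only identity-gene
#'   changes.
#' @param stress_peak_age effective age (months) at which the stress-class
#'   euchromatin signal peaks on the WT clock.
#' @param stress_curvature curvature (log2 / month^2) of the stress-class
#'   quadratic.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_background = 1240L, n_identity = 60L,
                         n_bivalent_c1 = 120L, n_bivalent_c2 = 80L,
                         n_stress = 100L,
                         ages = c(2, 6, 10),
                         genotypes = c("WT", "HD"),
                         n_replicates = 3L,
                         marks = CHROMAGE_MARKS,
                         dispersion = 0.05,
                         baseline_log2_mean = c(4, 7),
                         baseline_jitter_sd = 0.25,
                         size_factor_range = c(0.6, 1.6),
                         acceleration_kappa = 1.5,
                         acceleration_mode = c("multiplicative", "additive"),
                         beta_ac = 0.06, beta_me3 = 0.06, beta_ub = 0.05,
                         beta_identity = 0.08,
                         stress_peak_age = 6, stress_curvature = 0.02) {
  acceleration_mode <- match.arg(acceleration_mode)
  if (length(ages) < 1L || any(diff(ages) <= 0))
    stop("ages must be strictly increasing")
  if (any(ages <= 0)) stop("ages must be positive")
  if (!all(genotypes %in% c("WT", "HD"))) stop("genotypes must be WT and/or HD")
  bad <- setdiff(marks, CHROMAGE_MARKS)
  if (length(bad)) stop("unknown mark(s): ", paste(bad, collapse = ", "))
  if (acceleration_kappa <= 0) stop("acceleration_kappa must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.list(baseline_log2_mean))
    baseline_log2_mean <- stats::setNames(
      rep(list(baseline_log2_mean), length(marks)), marks)
  if (!all(marks %in% names(baseline_log2_mean)))
    stop("baseline_log2_mean must cover every mark")
  if (size_factor_range[1] <= 0 || diff(size_factor_range) < 0)
    stop("invalid size_factor_range")
  cfg <- list(seed = as.integer(seed),
              n_background = n_background, n_identity = n_identity,
              n_bivalent_c1 = n_bivalent_c1, n_bivalent_c2 = n_bivalent_c2,
              n_stress = n_stress,
              ages = ages, genotypes = genotypes,
              n_replicates = as.integer(n_replicates), marks = marks,
              dispersion = dispersion,
              baseline_log2_mean = baseline_log2_mean,
              baseline_jitter_sd = baseline_jitter_sd,
              size_factor_range = size_factor_range,
              acceleration_kappa = acceleration_kappa,
              acceleration_mode = acceleration_mode,
              beta_ac = beta_ac, beta_me3 = beta_me3, beta_ub = beta_ub,
              beta_identity = beta_identity,
              stress_peak_age = stress_peak_age,
              stress_curvature = stress_curvature)
  class(cfg) <- "study_config"
  cfg
}

effective_age <- function(age, genotype, kappa, mode) {
  ifelse(genotype == "HD",
         if (mode == "multiplicative") kappa * age else age + kappa,
         age)
}

## Class-specific log2 effect for one mark at effective age e.
class_effect <- function(class, mark, genotype, effage, cfg) {
  e <- effage
  off <- CLASS_OFFSETS[class, mark]
  slope <- switch(
    class,
    background = 0,
    identity = if (genotype == "HD")
      switch(mark, H3K27ac = -cfg$beta_identity, H3K27me3 = cfg$beta_identity,
             0) else 0,
    bivalent_c1 = switch(mark, H3K27ac = cfg$beta_ac,
                         H3K27me3 = -cfg$beta_me3, H2AK119ub = -cfg$beta_ub,
                         0),
    bivalent_c2 = switch(mark, H3K27ac = cfg$beta_ac,
                         H3K27me3 = -cfg$beta_me3, 0),
    stress = 0
  )
  quad <- if (class == "stress" && mark %in% c("H3K27ac", "H3K27me3")) {
    s <- if (mark == "H3K27ac") -1 else 1
    s * cfg$stress_curvature * (e - cfg$stress_peak_age)^2
  } else 0
  off + slope * e + quad
}

study_classes <- function(cfg) {
  rep(CHROMAGE_CLASSES,
      times = c(cfg$n_background, cfg$n_identity, cfg$n_bivalent_c1,
                cfg$n_bivalent_c2, cfg$n_stress))
}

study_samples_one_mark <- function(cfg, mark) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      age_months = cfg$ages,
                      genotype = cfg$genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "age_months", "replicate")]
  data.frame(
    sample_id = sprintf("%s_%gm_r%d_%s", grid$genotype, grid$age_months,
                        grid$replicate, mark),
    mark = mark, genotype = grid$genotype, age_months = grid$age_months,
    replicate = grid$replicate, fraction = "NeuN+",
    stringsAsFactors = FALSE
  )
}

mark_stream_seed <- function(seed, mark) {
  as.integer((as.numeric(seed) * 1009 +
                99991 * match(mark, CHROMAGE_MARKS)) %% 2147483587L)
}

#' Expected negative-binomial means of a synthetic study
#'
#' Closed-form expected counts (`mu`, including size factors when requested)
#' for each gene, mark and sample of the design in `config`. Used to verify
#' the generator's moments against Monte-Carlo draws.
#'
#' @param config a [study_config()].
#' @param baseline_log2 optional genes-by-marks matrix of baseline log2 means;
#'   when `NULL` the class effects are applied to a baseline of 0, giving
#'   relative means.
#' @param size_factors optional per-mark named list of sample size factors.
#' @return Named list (per mark) of genes-by-samples matrices of means.
#' @export
study_expected_means <- function(config, baseline_log2 = NULL,
                                 size_factors = NULL) {
  classes <- study_classes(config)
  out <- list()
  for (mark in config$marks) {
    sheet <- study_samples_one_mark(config, mark)
    eff <- effective_age(sheet$age_months, sheet$genotype,
                         config$acceleration_kappa, config$acceleration_mode)
    fx <- matrix(0, length(classes), nrow(sheet))
    for (s in seq_len(nrow(sheet)))
      for (cl in CHROMAGE_CLASSES)
        fx[classes == cl, s] <- class_effect(cl, mark, sheet$genotype[s],
                                             eff[s], config)
    b <- if (is.null(baseline_log2)) 0 else baseline_log2[, mark]
    mu <- 2^(fx + b)
    if (!is.null(size_factors))
      mu <- sweep(mu, 2, size_factors[[mark]], "*")
    dimnames(mu) <- list(sprintf("gene%04d", seq_along(classes)),
                         sheet$sample_id)
    out[[mark]] <- mu
  }
  out
}

#' Generate a synthetic multi-mark chromatin study
#'
#' Draws region-by-sample count matrices (one per mark), the matching sample
#' sheet, a synthetic gene annotation and the ground truth (planted class per
#' gene, true size factors, baselines, acceleration parameter). The same
#' configuration, including the seed, always yields byte-identical output.
#'
#' @param config a [study_config()].
#' @return A list of class `synthetic_study` with elements `counts` (named
#'   list of [count_matrix()], one per mark), `samples` (sample sheet
#'   data.frame covering all marks), `regions` (BED-style data.frame),
#'   `truth` and `config`.
#' @export
#' @examples
#' study <- generate_study(study_config(seed = 7, n_background = 50,
#'                                      n_identity = 10, n_bivalent_c1 = 15,
#'                                      n_bivalent_c2 = 10, n_stress = 10))
#' study$counts$H3K27ac
generate_study <- function(config) {
  if (!inherits(config, "study_config")) config <- do.call(study_config, config)
  classes <- study_classes(config)
  n_genes <- length(classes)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  names(classes) <- gene_ids

  ## shared per-gene baseline propensity from the master stream
  set.seed(config$seed)
  b_unit <- stats::runif(n_genes)

  baseline <- matrix(NA_real_, n_genes, length(config$marks),
                     dimnames = list(gene_ids, config$marks))
  counts <- list()
  size_factors <- list()
  sheets <- list()
  for (mark in config$marks) {
    sheet <- study_samples_one_mark(config, mark)
    set.seed(mark_stream_seed(config$seed, mark))
    rng <- config$baseline_log2_mean[[mark]]
    b <- rng[1] + b_unit * diff(rng) +
      stats::rnorm(n_genes, 0, config$baseline_jitter_sd)
    baseline[, mark] <- b
    sf <- stats::runif(nrow(sheet), config$size_factor_range[1],
                       config$size_factor_range[2])
    names(sf) <- sheet$sample_id
    mu <- study_expected_means(
      structure(modifyList(unclass(config), list(marks = mark)),
                class = "study_config"),
      baseline_log2 = baseline, size_factors = stats::setNames(list(sf), mark)
    )[[mark]]
    n <- length(mu)
    draws <- if (config$dispersion == 0) stats::rpois(n, mu)
             else stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    m <- matrix(draws, n_genes, nrow(sheet),
                dimnames = list(gene_ids, sheet$sample_id))
    counts[[mark]] <- count_matrix(m, mark = mark)
    size_factors[[mark]] <- sf
    sheets[[mark]] <- sheet
  }

  regions <- data.frame(
    chrom = "chrS",
    start = (seq_len(n_genes) - 1L) * 10000L,
    end = (seq_len(n_genes) - 1L) * 10000L + 2000L,
    name = gene_ids,
    score = 0,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE
  )

  structure(
    list(counts = counts,
         samples = do.call(rbind, c(sheets, list(make.row.names = FALSE))),
         regions = regions,
         truth = list(classes = classes,
                      acceleration_kappa = config$acceleration_kappa,
                      acceleration_mode = config$acceleration_mode,
                      size_factors = size_factors,
                      baseline_log2_mean = baseline),
         config = config),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d genes, marks: %s; %s x ages (%s) x %d replicates\n",
    length(x$truth$classes), paste(x$config$marks, collapse = ","),
    paste(x$config$genotypes, collapse = "/"),
    paste(x$config$ages, collapse = ","), x$config$n_replicates))
  invisible(x)
}

#' Write a synthetic study to plain-text fixture files
#'
#' Emits `counts_<mark>.tsv` (one per mark), `samples.tsv`, `regions.bed`
#' (BED6), `truth.tsv` (gene_id, class) and `genesets.gmt` (one gene set per
#' planted class). All files round-trip losslessly through the package
#' readers.
#'
#' @param study a [generate_study()] result.
#' @param directory output directory (created if missing).
#' @return Named character vector of written file paths (the manifest).
#' @export
write_study_fixtures <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  manifest <- c()
  for (mark in names(study$counts)) {
    p <- file.path(directory, sprintf("counts_%s.tsv", mark))
    write_count_matrix(study$counts[[mark]], p)
    manifest[sprintf("counts_%s", mark)] <- p
  }
  p <- file.path(directory, "samples.tsv")
  utils::write.table(study$samples, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest["samples"] <- p
  p <- file.path(directory, "regions.bed")
  write_regions_bed(study$regions, p)
  manifest["regions"] <- p
  p <- file.path(directory, "truth.tsv")
  utils::write.table(
    data.frame(gene_id = names(study$truth$classes),
               class = unname(study$truth$classes)),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest["truth"] <- p
  p <- file.path(directory, "genesets.gmt")
  sets <- split(names(study$truth$classes), study$truth$classes)
  write_gmt(sets, p,
            descriptions = stats::setNames(
              sprintf("planted %s genes", names(sets)), names(sets)))
  manifest["genesets"] <- p
  manifest
}
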