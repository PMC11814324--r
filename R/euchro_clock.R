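## Euchromatin score and epigenetic clock: H3K27ac/H3K27me3 sample pairing,
## per-gene score, cluster-mean summaries, WT age regression, epigenetic-age
## prediction, and score-module detection.

#' Pair samples of two marks by biological replicate
#'
#' Joins the samples of two marks on (genotype, age, replicate) — the two
#' marks are profiled from splits of the same extract, so the triple
#' identifies the animal. Unmatched samples are reported with a warning; a
#' duplicated key within a mark is an error.
#'
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param mark_a,mark_b the two marks; `mark_a` is the positive (active) mark
#'   of the score.
#' @return data.frame with one row per pair: `pair_id`, `sample_a`,
#'   `sample_b`, `genotype`, `age_months`, `replicate`.
#' @export
pair_samples <- function(sheet, mark_a = "H3K27ac", mark_b = "H3K27me3") {
  a <- sheet[sheet$mark == mark_a, , drop = FALSE]
  b <- sheet[sheet$mark == mark_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both marks must be present in the sample sheet")
  key <- function(x) paste(x$genotype, x$age_months, x$replicate, sep = "|")
  ka <- key(a)
  kb <- key(b)
  for (mk in list(c(mark_a, "a"), c(mark_b, "b"))) {
    kk <- if (mk[2] == "a") ka else kb
    if (anyDuplicated(kk))
      stop("duplicate (genotype, age, replicate) within mark ", mk[1], ": ",
           paste(unique(kk[duplicated(kk)]), collapse = "; "))
  }
  common <- intersect(ka, kb)
  if (length(common) == 0L) stop("no matching sample pairs between the marks")
  lost <- c(a$sample_id[!ka %in% common], b$sample_id[!kb %in% common])
  if (length(lost))
    warning("unmatched sample(s) dropped: ", paste(lost, collapse = ", "))
  ia <- match(common, ka)
  ib <- match(common, kb)
  out <- data.frame(
    pair_id = sprintf("%s_%gm_r%d", a$genotype[ia], a$age_months[ia],
                      a$replicate[ia]),
    sample_a = a$sample_id[ia], sample_b = b$sample_id[ib],
    genotype = a$genotype[ia], age_months = a$age_months[ia],
    replicate = a$replicate[ia],
    stringsAsFactors = FALSE
  )
  ord <- order(match(out$genotype, c("WT", "HD")), out$age_months,
               out$replicate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene euchromatin score
#'
#' The euchromatin score of a gene in a paired sample is `z(H3K27ac) -
#' z(H3K27me3)`, the difference of the gene's z-scored normalized counts of
#' the active and repressive mark; higher means more open, active chromatin.
#' Both z-matrices must be computed over the same genes, each across all
#' samples of its mark (all genotypes and ages jointly), so WT and HD share
#' one scale.
#'
#' @param z_ac,z_me3 z-score matrices (see [gene_zscores()]) of the active
#'   and repressive mark.
#' @param pairing sample pairing from [pair_samples()] (`sample_a` = active
#'   mark, `sample_b` = repressive mark).
#' @return Genes-by-pairs matrix of scores, with `pairing` attached as
#'   attribute `"pairing"`.
#' @export
euchromatin_score <- function(z_ac, z_me3, pairing) {
  if (!identical(rownames(z_ac), rownames(z_me3)))
    stop("z-score matrices must cover identical gene ids in the same order")
  missing <- c(setdiff(pairing$sample_a, colnames(z_ac)),
               setdiff(pairing$sample_b, colnames(z_me3)))
  if (length(missing))
    stop("pairing references missing sample(s): ",
         paste(missing, collapse = ", "))
  score <- z_ac[, pairing$sample_a, drop = FALSE] -
    z_me3[, pairing$sample_b, drop = FALSE]
  colnames(score) <- pairing$pair_id
  attr(score, "pairing") <- pairing
  score
}

#' Mean euchromatin score over a gene set
#'
#' Unweighted per-pair mean of the score over the genes of a set (e.g. the
#' bivalent developmental-TF cluster feeding the clock). Genes absent from
#' the score matrix are reported and excluded, or raise an error.
#'
#' @param scores genes-by-pairs score matrix from [euchromatin_score()].
#' @param gene_set character vector of gene ids.
#' @param missing_genes `"exclude"` (warn) or `"error"`.
#' @return Named numeric vector, one mean score per pair.
#' @export
gene_set_mean_score <- function(scores, gene_set,
                                missing_genes = c("exclude", "error")) {
  missing_genes <- match.arg(missing_genes)
  if (length(gene_set) == 0L) stop("empty gene set")
  absent <- setdiff(gene_set, rownames(scores))
  if (length(absent)) {
    msg <- paste0("gene(s) not in score matrix: ",
                  paste(absent, collapse = ", "))
    if (missing_genes == "error") stop(msg)
    warning(msg)
  }
  present <- intersect(gene_set, rownames(scores))
  if (length(present) == 0L) stop("no gene of the set is in the score matrix")
  colMeans(scores[present, , drop = FALSE])
}

#' Fit the euchromatin-score clock
#'
#' Ordinary least squares of the per-pair mean score on chronological age,
#' fitted on one genotype (WT by default): the calibration line that turns a
#' chromatin score into an epigenetic age.
#'
#' @param pair_means named per-pair mean scores (see
#'   [gene_set_mean_score()]).
#' @param ages chronological ages (months), aligned with `pair_means`.
#' @param genotypes optional genotype vector aligned with `pair_means`; with
#'   `fit_genotype`, restricts the points used.
#' @param fit_genotype genotype fitted on (default `"WT"`).
#' @return A list of class `clock_model`: `slope` (score units/month),
#'   `intercept`, `r_squared`, `residual_sd`, `n`, `genotype`.
#' @export
fit_clock <- function(pair_means, ages, genotypes = NULL,
                      fit_genotype = "WT") {
  stopifnot(length(pair_means) == length(ages))
  keep <- if (is.null(genotypes)) rep(TRUE, length(ages))
          else genotypes == fit_genotype
  y <- pair_means[keep]
  x <- ages[keep]
  if (length(y) < 3L) stop("clock fit needs at least 3 points")
  if (length(unique(x)) < 2L) stop("clock fit needs at least 2 distinct ages")
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = if (sst > 0) 1 - ssr / sst else 1,
         residual_sd = sqrt(ssr / (length(y) - 2L)),
         n = length(y),
         genotype = if (is.null(genotypes)) NA_character_ else fit_genotype),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model (%s, n = %d): score = %.4f %+.4f * age; r2 = %.3f, residual SD = %.4f\n",
    x$genotype, x$n, x$intercept, x$slope, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict epigenetic age and acceleration
#'
#' Inverts the clock: `predicted age = (score - intercept) / slope`;
#' `acceleration = predicted - chronological` (months). A slope below
#' `slope_min` means the score carries no age information and prediction is
#' refused.
#'
#' @param model a [fit_clock()] result.
#' @param pair_means named per-pair mean scores.
#' @param ages chronological ages aligned with `pair_means`.
#' @param genotypes optional genotype labels carried through to the output.
#' @param slope_min minimal usable |slope| (score units/month).
#' @return data.frame with one row per pair: `pair_id`, `genotype`,
#'   `age_months`, `score`, `predicted_age`, `acceleration`.
#' @export
predict_epigenetic_age <- function(model, pair_means, ages, genotypes = NULL,
                                   slope_min = 1e-6) {
  stopifnot(inherits(model, "clock_model"),
            length(pair_means) == length(ages))
  if (abs(model$slope) <= slope_min)
    stop("clock slope |", signif(model$slope, 3), "| <= ", slope_min,
         ": the score does not change with age, epigenetic age is undefined")
  predicted <- (pair_means - model$intercept) / model$slope
  data.frame(
    pair_id = if (is.null(names(pair_means))) seq_along(pair_means)
              else names(pair_means),
    genotype = if (is.null(genotypes)) NA_character_ else genotypes,
    age_months = ages,
    score = unname(pair_means),
    predicted_age = unname(predicted),
    acceleration = unname(predicted - ages),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Detect co-regulated euchromatin-score modules
#'
#' Simplified module detection over score trajectories: keep the top
#' `variance_keep_fraction` of genes by across-pair score variance; for each
#' kept gene build the trajectory of group-mean scores ordered by (genotype,
#' age); standardize each trajectory; cluster with seeded kmeans over
#' `k_range`, selecting `k` by maximum mean silhouette width; report the
#' per-module mean trajectory per genotype.
#'
#' @param scores genes-by-pairs score matrix from [euchromatin_score()].
#' @param genotypes,ages per-pair design vectors aligned with the score
#'   columns (default: taken from the pairing attached to `scores`).
#' @param variance_keep_fraction fraction of genes kept by the variance
#'   filter.
#' @param k_range candidate numbers of modules.
#' @param seed integer RNG seed.
#' @return List with `modules` (named labels), `k`, `silhouette` (mean
#'   silhouette per candidate k), `trajectories` (standardized gene
#'   trajectories), `module_trajectories` (per module, per genotype mean
#'   trajectory over ages), `group_order`.
#' @export
detect_score_modules <- function(scores, genotypes = NULL, ages = NULL,
                                 variance_keep_fraction = 0.2,
                                 k_range = 2:8, seed = 1L) {
  pairing <- attr(scores, "pairing")
  if (is.null(genotypes)) genotypes <- pairing$genotype
  if (is.null(ages)) ages <- pairing$age_months
  stopifnot(length(genotypes) == ncol(scores), length(ages) == ncol(scores))
  v <- apply(scores, 1L, stats::var)
  if (all(v == 0)) stop("all scores are constant: no modules to detect")
  n_keep <- max(1L, ceiling(variance_keep_fraction * nrow(scores)))
  keep <- names(sort(v, decreasing = TRUE))[seq_len(n_keep)]
  ## trajectory of group means, genotypes in WT-first order, ages ascending
  geno_levels <- intersect(c("WT", "HD"), unique(genotypes))
  if (length(geno_levels) == 0L) geno_levels <- sort(unique(genotypes))
  age_levels <- sort(unique(ages))
  cols <- expand.grid(age = age_levels, genotype = geno_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  traj <- sapply(seq_len(nrow(cols)), function(j) {
    sel <- genotypes == cols$genotype[j] & ages == cols$age[j]
    if (!any(sel)) stop("empty (genotype, age) cell: ", cols$genotype[j],
                        " ", cols$age[j])
    rowMeans(scores[keep, sel, drop = FALSE])
  })
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1L,
                                         dimnames = list(keep, NULL))
  colnames(traj) <- sprintf("%s_%gm", cols$genotype, cols$age)
  mu <- rowMeans(traj)
  sd_pop <- sqrt(rowMeans((traj - mu)^2))
  traj_std <- (traj - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  traj_std[sd_pop == 0, ] <- 0
  if (max(k_range) > nrow(traj_std))
    stop("fewer retained genes than the largest candidate k")
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmeans_cluster(traj_std, k = k, seed = seed)
    fits[[i]] <- fit
    sil[i] <- if (k == 1L) -Inf else
      mean(cluster::silhouette(fit$cluster, stats::dist(traj_std))[, 3L])
  }
  best <- if (length(k_range) == 1L) 1L else which.max(sil)
  fit <- fits[[best]]
  k <- k_range[best]
  module_traj <- lapply(seq_len(k), function(cl) {
    genes <- names(fit$cluster)[fit$cluster == cl]
    prof <- colMeans(traj[genes, , drop = FALSE])
    split(unname(prof), cols$genotype)[geno_levels]
  })
  names(module_traj) <- paste0("M", seq_len(k))
  list(modules = fit$cluster, k = as.integer(k), silhouette = sil,
       trajectories = traj_std, module_trajectories = module_traj,
       group_order = cols)
}
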