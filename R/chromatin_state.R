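## Chromatin-state clustering: kmeans over mark profiles, bivalent-cluster
## selection, H2AK119ub high/low splitting, metaprofiles.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1L]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Seeded kmeans clustering of region profiles
#'
#' kmeans++ initialization followed by Lloyd iterations, repeated
#' `n_restarts` times; the restart with the lowest total within-cluster sum
#' of squares (inertia) is returned. Fully deterministic given `seed`. If a
#' restart produces an empty cluster it is re-initialized with a fresh
#' kmeans++ draw.
#'
#' @param features numeric matrix, regions by features, no missing values.
#' @param k number of clusters (`<=` number of regions).
#' @param seed integer RNG seed.
#' @param n_restarts number of kmeans++ restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param standardize_rows standardize each region's profile to mean 0 / SD 1
#'   before clustering (population SD; constant rows become all-zero), so
#'   marks with different dynamic ranges contribute equally.
#' @return A list of class `cluster_assignment`: `cluster` (named labels in
#'   `1..k`), `centers`, `inertia`, `k`, `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(features, k, seed, n_restarts = 10L,
                           max_iter = 300L, standardize_rows = FALSE) {
  x <- as.matrix(features)
  if (anyNA(x)) stop("features contain missing values")
  if (k > nrow(x)) stop("k exceeds the number of regions")
  if (k < 1L) stop("k must be >= 1")
  if (standardize_rows) {
    mu <- rowMeans(x)
    sd_pop <- sqrt(rowMeans((x - mu)^2))
    x <- (x - mu) / ifelse(sd_pop == 0, 1, sd_pop)
    x[sd_pop == 0, ] <- 0
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- NULL
    for (attempt in 1:5) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        stats::kmeans(x, centers = init, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      fit <- suppressWarnings(stats::kmeans(x, centers = kmeanspp_init(x, k),
                                            iter.max = max_iter,
                                            algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(
    list(cluster = stats::setNames(best$cluster, rownames(x)),
         centers = best$centers,
         inertia = best$tot.withinss,
         k = as.integer(k), seed = as.integer(seed),
         n_restarts = as.integer(n_restarts)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d regions in %d clusters (inertia %.4g)\n",
              length(x$cluster), x$k, x$inertia))
  print(table(x$cluster))
  invisible(x)
}

#' Per-gene mark-profile features for chromatin-state clustering
#'
#' Builds a genes-by-marks feature matrix of `log2(mean normalized count +
#' 1)` across the selected samples of each mark, the input to
#' [kmeans_cluster()]. Each mark is normalized with its own median-of-ratios
#' size factors. With `center_rows = TRUE` (default) each gene's profile is
#' centered (its mean over marks subtracted): this removes the per-gene
#' baseline level so clustering sees mark contrasts, while — unlike full
#' per-gene scaling — genes with no contrast stay near zero instead of
#' being inflated to unit-variance noise.
#'
#' When a sample `sheet` and `group_by` columns are given, one feature per
#' (mark, group) mean is produced instead of one per mark, resolving
#' temporal/genotype structure the way condition-wise profile heatmaps do —
#' necessary to separate classes whose signatures are dynamic rather than
#' constitutive.
#'
#' @param counts named list of raw [count_matrix()] objects (one per mark).
#' @param samples optional named list restricting, per mark, the sample ids
#'   averaged over.
#' @param sheet optional sample sheet (see [read_sample_sheet()]) covering
#'   the samples.
#' @param group_by character vector of sheet columns (e.g.
#'   `c("genotype", "age_months")`) defining the per-mark sample groups.
#' @param center_rows subtract each gene's mean over all features.
#' @return Numeric matrix, genes by features.
#' @export
mark_profile_features <- function(counts, samples = NULL, sheet = NULL,
                                  group_by = NULL, center_rows = TRUE) {
  stopifnot(is.list(counts), length(counts) >= 1L)
  cols <- lapply(names(counts), function(mark) {
    cm <- counts[[mark]]
    norm <- cm_counts(normalize_counts(cm, size_factors_median_of_ratios(cm)))
    if (!is.null(samples) && mark %in% names(samples))
      norm <- norm[, samples[[mark]], drop = FALSE]
    if (is.null(group_by)) {
      out <- matrix(log2(rowMeans(norm) + 1), ncol = 1,
                    dimnames = list(rownames(norm), mark))
    } else {
      if (is.null(sheet)) stop("group_by requires a sample sheet")
      sub <- sheet[match(colnames(norm), sheet$sample_id), , drop = FALSE]
      if (anyNA(sub$sample_id))
        stop("sample sheet does not cover all matrix columns")
      key <- interaction(sub[group_by], drop = TRUE, lex.order = TRUE)
      out <- sapply(levels(key), function(lv)
        log2(rowMeans(norm[, key == lv, drop = FALSE]) + 1))
      colnames(out) <- paste(mark, levels(key), sep = ".")
    }
    out
  })
  out <- do.call(cbind, cols)
  if (center_rows) out <- out - rowMeans(out)
  out
}

#' Select the bivalent cluster
#'
#' A bivalent cluster is high in both the active promoter mark H3K4me3 and
#' the repressive mark H3K27me3. Per-cluster mean signals of the two marks
#' are standardized across clusters and the cluster maximizing
#' `min(z_H3K4me3, z_H3K27me3)` is returned; ties are broken by the larger
#' sum of the two standardized means, then by the smaller cluster label.
#'
#' @param assignment a [kmeans_cluster()] result (or anything with a
#'   `cluster` vector).
#' @param k4_means,k27me3_means per-cluster mean signals, ordered by cluster
#'   label `1..k`.
#' @return Integer cluster label.
#' @export
select_bivalent_cluster <- function(assignment, k4_means, k27me3_means) {
  k <- length(k4_means)
  if (k < 2L) stop("need at least 2 clusters")
  if (length(k27me3_means) != k)
    stop("mark mean vectors must have one value per cluster")
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  z4 <- zs(k4_means)
  zme3 <- zs(k27me3_means)
  score <- pmin(z4, zme3)
  cand <- which(score == max(score))
  if (length(cand) > 1L) {
    sums <- (z4 + zme3)[cand]
    cand <- cand[sums == max(sums)]
  }
  as.integer(min(cand))
}

#' Per-cluster mean signal of a mark
#'
#' Convenience summary: mean of a per-region signal vector within each
#' cluster, ordered by label, as needed by [select_bivalent_cluster()].
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param signal named per-region numeric vector.
#' @return Numeric vector of length `k`.
#' @export
cluster_mark_means <- function(assignment, signal) {
  signal <- signal[names(assignment$cluster)]
  as.numeric(tapply(signal, assignment$cluster, mean)[as.character(
    seq_len(assignment$k))])
}

#' Split regions into signal-high and signal-low subclusters
#'
#' kmeans with `k = 2` on a single signal (optionally log-transformed); the
#' cluster with the larger mean signal is labelled `"high"` (cluster 1), the
#' other `"low"` (cluster 2), following the high/low naming convention for
#' H2AK119ub subclusters of bivalent promoters.
#'
#' @param signal named per-region numeric vector.
#' @param seed integer RNG seed.
#' @param log_transform cluster on `log2(signal + 1)`.
#' @return List with `high` and `low` (character vectors of region names)
#'   and the numeric `assignment` (1 = high, 2 = low).
#' @export
split_high_low <- function(signal, seed, log_transform = TRUE) {
  if (length(signal) < 2L) stop("need at least 2 regions")
  if (is.null(names(signal))) names(signal) <- seq_along(signal)
  x <- if (log_transform) log2(signal + 1) else signal
  if (stats::sd(x) == 0 || length(unique(x)) < 2L)
    stop("constant signal: no high/low split possible")
  fit <- kmeans_cluster(matrix(x, ncol = 1, dimnames = list(names(signal))),
                        k = 2L, seed = seed)
  m <- tapply(signal, fit$cluster, mean)
  high_lab <- as.integer(names(m)[which.max(m)])
  assignment <- ifelse(fit$cluster == high_lab, 1L, 2L)
  list(high = names(signal)[assignment == 1L],
       low = names(signal)[assignment == 2L],
       assignment = stats::setNames(assignment, names(signal)))
}

#' Metaprofile of binned signal across sample groups
#'
#' Averages binned region signal (see [bin_region_signal()]) over the
#' regions and samples of each group, per bin. With exactly two groups the
#' difference profile (second minus first) and the percent-change profile
#' (via [percent_signal_change()]) are also returned.
#'
#' @param binned named list of regions-by-bins matrices, one per sample,
#'   sharing one bin scheme.
#' @param groups named list of sample-id character vectors.
#' @param pseudocount passed to [percent_signal_change()] for the
#'   percent-change profile.
#' @return List with `profiles` (groups-by-bins matrix) and, for two groups,
#'   `difference` and `percent_change` per-bin vectors.
#' @export
metaprofile <- function(binned, groups, pseudocount = 1) {
  stopifnot(is.list(binned), is.list(groups))
  nb <- unique(vapply(binned, ncol, integer(1)))
  if (length(nb) != 1L) stop("inconsistent bin schemes across samples")
  prof <- t(vapply(groups, function(ids) {
    if (length(ids) == 0L) stop("empty group")
    missing <- setdiff(ids, names(binned))
    if (length(missing))
      stop("no binned signal for sample(s): ", paste(missing, collapse = ", "))
    colMeans(do.call(rbind, binned[ids]))
  }, numeric(nb)))
  rownames(prof) <- names(groups)
  out <- list(profiles = prof)
  if (length(groups) == 2L) {
    out$difference <- prof[2L, ] - prof[1L, ]
    out$percent_change <- percent_signal_change(prof[1L, ], prof[2L, ],
                                                pseudocount = pseudocount)
  }
  out
}
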