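#' Median-of-ratios size factors
#'
#' Library-size normalization of Anders & Huber: the reference for each
#' region is the geometric mean of its counts across samples (regions with a
#' zero in any sample are excluded), and a sample's size factor is the median
#' of its count-to-reference ratios over the reference regions.
#'
#' @param counts a [count_matrix()] or region-by-sample matrix of raw counts.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- cm_counts(counts)
  if (ncol(m) < 1L) stop("no samples")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop("no region has strictly positive counts in every sample; ",
         "consider a pseudo-reference (e.g. add a pseudocount) upstream")
  mk <- m[keep, , drop = FALSE]
  ref <- exp(rowMeans(log(mk)))
  sf <- apply(mk / ref, 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor and flags the matrix
#' normalized.
#'
#' @param counts a [count_matrix()] or matrix of raw counts.
#' @param sf named size-factor vector covering every sample
#'   (see [size_factors_median_of_ratios()]).
#' @return A normalized [count_matrix()].
#' @export
normalize_counts <- function(counts, sf) {
  m <- cm_counts(counts)
  missing <- setdiff(colnames(m), names(sf))
  if (length(missing))
    stop("missing size factor for sample(s): ", paste(missing, collapse = ", "))
  if (any(sf[colnames(m)] <= 0)) stop("size factors must be > 0")
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  count_matrix(norm, mark = cm_mark(counts), normalized = TRUE)
}

#' Per-region z-scores across samples
#'
#' Each region is centered and scaled across the chosen samples using the
#' population standard deviation (denominator `n`). Regions with zero SD are
#' set to all zeros, which keeps constant regions neutral in downstream
#' scores.
#'
#' @param norm a normalized [count_matrix()] or matrix.
#' @param samples optional character vector restricting the columns used
#'   (default: all).
#' @return Matrix of z-scores (regions by selected samples) with the
#'   per-region means and SDs attached as attributes `"center"` and
#'   `"scale"`.
#' @export
gene_zscores <- function(norm, samples = NULL) {
  m <- cm_counts(norm)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("z-scores need at least 2 samples")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  attr(z, "center") <- mu
  attr(z, "scale") <- sd_pop
  z
}

#' Method-of-moments dispersion estimates
#'
#' Per-region negative-binomial dispersion from within-group residuals of
#' normalized counts: `alpha = max(alpha_min, (s2 - mu) / mu^2)` with `s2`
#' the pooled within-group variance and `mu` the overall mean, optionally
#' shrunk toward the median dispersion across regions.
#'
#' @param counts raw [count_matrix()] or matrix.
#' @param sf size factors (see [size_factors_median_of_ratios()]).
#' @param groups factor/character of group membership, one per sample
#'   (aligned with the matrix columns).
#' @param alpha_min floor for the estimate.
#' @param shrink_weight weight `w` of the across-region median in
#'   `(1 - w) * alpha + w * median(alpha)`; 0 disables shrinkage.
#' @return Named numeric vector of dispersions, one per region.
#' @export
estimate_dispersion_mom <- function(counts, sf, groups, alpha_min = 1e-8,
                                    shrink_weight = 0.3) {
  norm <- cm_counts(normalize_counts(counts, sf))
  groups <- as.character(groups)
  if (length(groups) != ncol(norm))
    stop("groups must align with the matrix columns")
  tab <- table(groups)
  if (all(tab < 2L)) stop("need >= 2 replicates in at least one group")
  use <- groups %in% names(tab[tab >= 2L])
  norm <- norm[, use, drop = FALSE]
  groups <- groups[use]
  ss <- 0
  df <- 0
  for (g in unique(groups)) {
    x <- norm[, groups == g, drop = FALSE]
    ss <- ss + rowSums((x - rowMeans(x))^2)
    df <- df + ncol(x) - 1L
  }
  s2 <- ss / df
  mu <- rowMeans(norm)
  alpha <- pmax(alpha_min, (s2 - mu) / mu^2)
  alpha[!is.finite(alpha)] <- alpha_min
  if (shrink_weight > 0)
    alpha <- (1 - shrink_weight) * alpha +
      shrink_weight * stats::median(alpha)
  stats::setNames(alpha, rownames(norm))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the BH step-up procedure: with `p_(1) <= ... <=
#' p_(m)`, `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in
#' the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(scaled))))
  adj[order(o)]
}

#' Negative-binomial Wald test for differential enrichment
#'
#' Moment-based Wald test on normalized counts. For each region, the group
#' means \eqn{\hat\mu_A, \hat\mu_B} give `log2FC = log2((muB + pc) / (muA +
#' pc))` with standard error `SE = (1/ln 2) * sqrt(sum_g (1/n_g) *
#' (1/(mu_g + pc) + alpha))` (delta method under the NB variance `mu + alpha
#' mu^2`), Wald statistic `z = log2FC / SE` and two-sided normal p-value.
#' P-values are BH-adjusted and regions are called `up` / `down` when `padj <
#' padj_threshold`, with the sign of the fold change.
#'
#' @param counts raw [count_matrix()] or matrix.
#' @param sf size factors; computed with
#'   [size_factors_median_of_ratios()] when `NULL`.
#' @param groupA,groupB character vectors of sample ids (A is the reference;
#'   fold changes are B vs A).
#' @param alpha per-region dispersion vector (recycled if scalar); estimated
#'   with [estimate_dispersion_mom()] when `NULL`.
#' @param padj_threshold significance threshold on the adjusted p-value
#'   (default 0.1).
#' @param pseudocount added to the group means on the normalized-count scale
#'   to bound fold changes at zeros.
#' @return data.frame with one row per region: `region`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `padj`, `status`.
#' @export
nb_wald_differential <- function(counts, sf = NULL, groupA, groupB,
                                 alpha = NULL, padj_threshold = 0.1,
                                 pseudocount = 1) {
  m <- cm_counts(counts)
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  missing <- setdiff(c(groupA, groupB), colnames(m))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (is.null(sf)) sf <- size_factors_median_of_ratios(counts)
  norm <- cm_counts(normalize_counts(counts, sf))
  if (is.null(alpha)) {
    grp <- ifelse(colnames(m) %in% groupA, "A",
                  ifelse(colnames(m) %in% groupB, "B", NA))
    keep <- !is.na(grp)
    alpha <- estimate_dispersion_mom(m[, keep, drop = FALSE],
                                     sf[colnames(m)[keep]], grp[keep])
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(norm))
  if (length(alpha) != nrow(norm))
    stop("dispersion vector not aligned with regions")
  muA <- rowMeans(norm[, groupA, drop = FALSE])
  muB <- rowMeans(norm[, groupB, drop = FALSE])
  nA <- length(groupA)
  nB <- length(groupB)
  lfc <- log2((muB + pseudocount) / (muA + pseudocount))
  se <- (1 / log(2)) * sqrt((1 / nA) * (1 / (muA + pseudocount) + alpha) +
                            (1 / nB) * (1 / (muB + pseudocount) + alpha))
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- bh_adjust(p)
  status <- ifelse(padj < padj_threshold,
                   ifelse(lfc > 0, "up", "down"), "ns")
  status[padj < padj_threshold & lfc == 0] <- "ns"
  data.frame(region = rownames(norm),
             base_mean = (muA + muB) / 2,
             log2fc = lfc, se = se, stat = z, pvalue = p, padj = padj,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank tests over groups
#'
#' `mannwhitney_two_sided` runs a two-sided Mann-Whitney U test (exact
#' enumeration when both groups have at most 8 observations and no ties;
#' tie-corrected normal approximation otherwise); `kruskal_wallis` runs the
#' tie-corrected Kruskal-Wallis test with Bonferroni-corrected pairwise
#' Mann-Whitney post-hoc comparisons.
#'
#' @param values numeric vector of observations.
#' @param grouping factor/character of the same length.
#' @param test `"mannwhitney_two_sided"` or `"kruskal_wallis"`.
#' @return A list with `test`, `statistic`, `p_value` and (Kruskal-Wallis
#'   only) a `pairwise` data.frame of Bonferroni-corrected post-hoc
#'   p-values.
#' @export
rank_tests <- function(values, grouping,
                       test = c("mannwhitney_two_sided", "kruskal_wallis")) {
  test <- match.arg(test)
  grouping <- as.character(grouping)
  stopifnot(length(values) == length(grouping))
  groups <- split(values, grouping)
  if (any(lengths(groups) == 0L)) stop("empty group")
  if (test == "mannwhitney_two_sided") {
    if (length(groups) != 2L)
      stop("Mann-Whitney requires exactly 2 groups, got ", length(groups))
    res <- mwu_two_sided(groups[[1L]], groups[[2L]])
    list(test = test, statistic = res$statistic, p_value = res$p)
  } else {
    if (length(groups) < 2L) stop("Kruskal-Wallis requires >= 2 groups")
    kw <- stats::kruskal.test(values, factor(grouping))
    pairs <- utils::combn(names(groups), 2L)
    n_comp <- ncol(pairs)
    pw <- data.frame(
      group1 = pairs[1L, ], group2 = pairs[2L, ],
      p_raw = apply(pairs, 2L, function(pr)
        mwu_two_sided(groups[[pr[1L]]], groups[[pr[2L]]])$p),
      stringsAsFactors = FALSE
    )
    pw$p_bonferroni <- pmin(1, pw$p_raw * n_comp)
    list(test = test, statistic = unname(kw$statistic),
         p_value = kw$p.value, pairwise = pw)
  }
}

mwu_two_sided <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # degenerate: all observations identical
  list(statistic = unname(wt$statistic), p = min(1, p))
}

#' Percent signal change between two conditions
#'
#' `100 * (B - A) / (A + pseudocount)` per region.
#'
#' @param groupA_means,groupB_means aligned per-region mean signal vectors
#'   (A is the reference).
#' @param pseudocount added to the denominator; must be > 0 when A contains
#'   zeros.
#' @return Numeric vector of percentages.
#' @export
percent_signal_change <- function(groupA_means, groupB_means,
                                  pseudocount = 0) {
  stopifnot(length(groupA_means) == length(groupB_means))
  denom <- groupA_means + pseudocount
  if (any(denom == 0))
    stop("zero denominator; use a positive pseudocount")
  100 * (groupB_means - groupA_means) / denom
}
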