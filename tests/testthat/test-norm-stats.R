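# brute-force median-of-ratios, straight from the definition
sf_bruteforce <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  ref <- apply(m[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j)
    stats::median(m[keep, j] / ref), numeric(1))
}

rand_counts <- function(nr = 50, nc = 6) {
  m <- matrix(rnbinom(nr * nc, mu = 50, size = 5), nr, nc)
  dimnames(m) <- list(sprintf("r%03d", 1:nr), sprintf("s%d", 1:nc))
  m
}

test_that("size factors match the definition, DESeq2, and are
           scale-equivariant", {
  # worked examples
  m1 <- matrix(c(2, 2, 8, 8), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unname(size_factors_median_of_ratios(m1)), c(0.5, 2))
  m2 <- matrix(c(0, 4, 5, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unname(size_factors_median_of_ratios(m2)), c(1, 1))
  m3 <- matrix(5, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_equal(unname(size_factors_median_of_ratios(m3)), rep(1, 4))
  expect_error(
    size_factors_median_of_ratios(
      matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))),
    "pseudo-reference")

  set.seed(11)
  for (i in 1:10) {
    # odd sample count: the median is attained at a data point, so the
    # ratio-scale and log-scale (DESeq2) medians coincide exactly
    m <- rand_counts(50, 5)
    sf <- size_factors_median_of_ratios(m)
    expect_equal(unname(sf), sf_bruteforce(m))
    # independent oracle: DESeq2's estimator of the same quantity (DESeq2
    # interpolates the median in log space, so agreement is near-exact)
    expect_equal(unname(sf),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 0.005)
    # scale equivariance: factors are defined up to a common scale, so
    # scaling a column by c scales its factor relative to the others by c
    m4 <- m
    m4[, 3] <- m4[, 3] * 4
    sf4 <- size_factors_median_of_ratios(m4)
    expect_equal(unname(sf4[3] / sf4[1]), unname(4 * sf[3] / sf[1]))
  }
})

test_that("normalization divides by factors and inverts column scaling", {
  m <- rand_counts(20, 4) + 1
  cm <- count_matrix(m)
  sf <- stats::setNames(c(1, 2, 0.5, 1), colnames(m))
  norm <- normalize_counts(cm, sf)
  expect_true(norm$normalized)
  expect_equal(norm$counts[, 2], m[, 2] / 2)
  expect_equal(norm$counts[, 1], m[, 1])
  # scaling columns by sf then normalizing recovers the original
  scaled <- sweep(m, 2, sf, "*")
  back <- normalize_counts(count_matrix(scaled, normalized = TRUE), sf)
  expect_equal(back$counts, m)
  expect_error(normalize_counts(cm, sf[1:2]), "missing size factor")
})

test_that("z-scores use the population SD with the zero-SD policy", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 4))
  colnames(m) <- c("s1", "s2", "s3")
  z <- gene_zscores(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  mu <- mean(m["c", ]); s <- sqrt(mean((m["c", ] - mu)^2))
  expect_equal(unname(z["c", ]), unname((m["c", ] - mu) / s))
  # affine equivariance: negating inputs negates outputs
  zneg <- gene_zscores(-m)
  expect_equal(zneg, -z, ignore_attr = TRUE)
  expect_error(gene_zscores(m, "s1"), "at least 2")
})

test_that("method-of-moments dispersion recovers the truth and floors at
           alpha_min", {
  set.seed(21)
  sf1 <- stats::setNames(rep(1, 100), sprintf("s%03d", 1:100))
  groups <- rep(c("A", "B"), each = 50)
  # Poisson data: estimates should collapse toward the floor
  mp <- matrix(rpois(300 * 100, 100), 300, 100,
               dimnames = list(sprintf("r%03d", 1:300), names(sf1)))
  ap <- estimate_dispersion_mom(count_matrix(mp), sf1, groups,
                                shrink_weight = 0)
  expect_lt(stats::median(ap), 0.005)
  # NB data, alpha = 0.1, 200 samples per group
  sf2 <- stats::setNames(rep(1, 400), sprintf("s%03d", 1:400))
  mn <- matrix(rnbinom(200 * 400, mu = 100, size = 10), 200, 400,
               dimnames = list(sprintf("r%03d", 1:200), names(sf2)))
  an <- estimate_dispersion_mom(count_matrix(mn), sf2,
                                rep(c("A", "B"), each = 200),
                                shrink_weight = 0)
  expect_lt(abs(mean(an) / 0.1 - 1), 0.2)
  # underdispersed region hits the floor
  mu_row <- matrix(rep(c(10L, 11L), 3)[1:6], 1, 6,
                   dimnames = list("r", sprintf("s%d", 1:6)))
  af <- estimate_dispersion_mom(count_matrix(mu_row),
                                stats::setNames(rep(1, 6), colnames(mu_row)),
                                rep("A", 6), alpha_min = 1e-8,
                                shrink_weight = 0)
  expect_equal(unname(af), 1e-8)
})

test_that("the NB Wald test reproduces the closed-form oracle and the null
           identity", {
  # identical groups: LFC 0, p 1, ns
  m <- matrix(rep(c(10, 20, 30), 4), 3, 4,
              dimnames = list(c("a", "b", "c"), c("a1", "a2", "b1", "b2")))
  res <- nb_wald_differential(count_matrix(m),
                              sf = stats::setNames(rep(1, 4), colnames(m)),
                              groupA = c("a1", "a2"), groupB = c("b1", "b2"),
                              alpha = 0.05)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  expect_identical(res$status, rep("ns", 3))

  # hand-computed oracle: muA = 10, muB = 40, n = 3, alpha = 0.05, pc = 1
  m2 <- rbind(r1 = c(10, 10, 10, 40, 40, 40))
  colnames(m2) <- c(paste0("A", 1:3), paste0("B", 1:3))
  res2 <- nb_wald_differential(count_matrix(m2),
                               sf = stats::setNames(rep(1, 6), colnames(m2)),
                               groupA = paste0("A", 1:3),
                               groupB = paste0("B", 1:3), alpha = 0.05)
  lfc <- log2(41 / 11)
  se <- (1 / log(2)) * sqrt((1 / 3) * (1 / 11 + 0.05) +
                            (1 / 3) * (1 / 41 + 0.05))
  expect_equal(res2$log2fc, lfc)
  expect_equal(res2$se, se)
  expect_equal(res2$pvalue, 2 * pnorm(-lfc / se))
  expect_identical(res2$status, "up")
  expect_error(nb_wald_differential(count_matrix(m2), groupA = character(0),
                                    groupB = "B1"), "empty group")
})

test_that("BH adjustment equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m))
      adj[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
    adj
  }
  set.seed(5)
  for (i in 1:20) {
    p <- round(runif(30), 2)  # rounding forces ties
    expect_equal(bh_adjust(p), bh_bruteforce(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank tests give the exact MWU enumeration and tie-corrected
           approximations", {
  res <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                    test = "mannwhitney_two_sided")
  expect_equal(res$p_value, 0.1)  # 2/20 orderings as extreme
  same <- rank_tests(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                     test = "mannwhitney_two_sided")
  expect_equal(same$p_value, 1)
  kw <- rank_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                   test = "kruskal_wallis")
  expect_equal(unname(kw$statistic), 0)
  expect_identical(nrow(kw$pairwise), 3L)
  expect_true(all(kw$pairwise$p_bonferroni <= 1))
  expect_error(rank_tests(1:6, rep(c("a", "b", "c"), 2),
                          test = "mannwhitney_two_sided"), "exactly 2")
  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(2)
  x <- round(rnorm(30), 1); y <- round(rnorm(30, 0.5), 1)
  got <- rank_tests(c(x, y), rep(c("a", "b"), each = 30),
                    "mannwhitney_two_sided")
  want <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = FALSE)$p.value)
  expect_equal(got$p_value, want)
})

test_that("percent signal change applies the pseudocount rule", {
  expect_equal(percent_signal_change(c(2, 4), c(2, 4)), c(0, 0))
  expect_equal(percent_signal_change(2, 3), 50)
  expect_equal(percent_signal_change(0, 5, pseudocount = 1), 500)
  expect_error(percent_signal_change(0, 5), "pseudocount")
})
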