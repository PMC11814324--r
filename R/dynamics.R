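## Temporal and gene-family analyses: per-gene log2 fold changes, the
## PRC1-CBX paralog-switch statistic, trajectory-shape classification, and
## gene-set overlap / enrichment tests.

#' Per-gene log2 fold change between two sample groups
#'
#' `log2((mean_B + pc) / (mean_A + pc))` on normalized counts.
#'
#' @param norm normalized [count_matrix()] or matrix.
#' @param groupA,groupB disjoint, nonempty character vectors of sample ids
#'   (A is the reference).
#' @param pseudocount added to both group means.
#' @return Named numeric vector of fold changes, one per gene.
#' @export
log2fc_by_gene <- function(norm, groupA, groupB, pseudocount = 1) {
  m <- cm_counts(norm)
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  missing <- setdiff(c(groupA, groupB), colnames(m))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  muA <- rowMeans(m[, groupA, drop = FALSE])
  muB <- rowMeans(m[, groupB, drop = FALSE])
  log2((muB + pseudocount) / (muA + pseudocount))
}

#' Paralog-switch score with permutation null
#'
#' Formalizes a paralog switch within a gene family (e.g. PRC1 chromobox
#' genes: Cbx2/4/8 up, Cbx6/7 down) as `score = mean(LFC[up_set]) -
#' mean(LFC[down_set])`. The null draws `|up| + |down|` genes without
#' replacement from the background `B` times, randomly splits them into sets
#' of the observed sizes, and recomputes the score; the one-sided p-value is
#' `(1 + #(null >= observed)) / (B + 1)`.
#'
#' @param lfc named per-gene log2 fold-change vector (see
#'   [log2fc_by_gene()]).
#' @param up_set,down_set disjoint, nonempty gene sets within `background`.
#' @param background character vector of background genes (all must have an
#'   LFC value).
#' @param B number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param family optional family name carried in the result.
#' @return A list of class `switch_result`: `family`, `up_set`, `down_set`,
#'   `lfc` (per-gene values of both sets), `score`, `p_value`, `B`, `seed`.
#' @export
paralog_switch_score <- function(lfc, up_set, down_set, background,
                                 B = 1000L, seed = 1L, family = NA_character_) {
  if (B < 100L) stop("B must be >= 100")
  if (length(up_set) == 0L || length(down_set) == 0L) stop("empty gene set")
  if (length(intersect(up_set, down_set)))
    stop("up_set and down_set overlap")
  if (!all(c(up_set, down_set) %in% background))
    stop("up_set and down_set must be subsets of the background")
  missing <- setdiff(background, names(lfc))
  if (length(missing))
    stop("no LFC value for gene(s): ", paste(missing, collapse = ", "))
  n_up <- length(up_set)
  n_dn <- length(down_set)
  observed <- mean(lfc[up_set]) - mean(lfc[down_set])
  set.seed(as.integer(seed))
  null <- replicate(B, {
    draw <- sample(background, n_up + n_dn)
    mean(lfc[draw[seq_len(n_up)]]) - mean(lfc[draw[-seq_len(n_up)]])
  })
  p <- (1 + sum(null >= observed)) / (B + 1)
  structure(
    list(family = family, up_set = up_set, down_set = down_set,
         lfc = lfc[c(up_set, down_set)], score = observed, p_value = p,
         B = as.integer(B), seed = as.integer(seed)),
    class = "switch_result"
  )
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf(
    "switch_result%s: score = %.4f (up: %s | down: %s), permutation p = %.4g (B = %d)\n",
    if (is.na(x$family)) "" else paste0(" [", x$family, "]"),
    x$score, paste(x$up_set, collapse = ","),
    paste(x$down_set, collapse = ","), x$p_value, x$B))
  invisible(x)
}

#' Classify a three-age trajectory shape
#'
#' Given group means at three ordered ages `(m1, m2, m3)` and a tolerance
#' `epsilon`, the shape is, testing the rules in this order:
#' `peaked` if `m2 > max(m1, m3) + eps`; `dipped` if `m2 < min(m1, m3) -
#' eps`; `up` if `m3 - m1 > eps` and `m2 >= m1 - eps`; `down` if `m1 - m3 >
#' eps` and `m2 <= m1 + eps`; otherwise `flat`. Every triple maps to exactly
#' one shape.
#'
#' @param means numeric vector of exactly 3 group means, ordered by age.
#' @param epsilon positive tolerance, in score units. A data-driven default
#'   is provided by [trajectory_epsilon()].
#' @return One of `"peaked"`, `"dipped"`, `"up"`, `"down"`, `"flat"`.
#' @export
classify_trajectory <- function(means, epsilon) {
  if (length(means) != 3L)
    stop("classify_trajectory expects exactly 3 timepoints")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar")
  m1 <- means[1L]; m2 <- means[2L]; m3 <- means[3L]
  if (m2 > max(m1, m3) + epsilon) return("peaked")
  if (m2 < min(m1, m3) - epsilon) return("dipped")
  if (m3 - m1 > epsilon && m2 >= m1 - epsilon) return("up")
  if (m1 - m3 > epsilon && m2 <= m1 + epsilon) return("down")
  "flat"
}

#' @rdname classify_trajectory
#' @param mean_matrix genes-by-ages matrix (3 columns, ages ascending).
#' @return `classify_trajectories()`: named character vector of shapes.
#' @export
classify_trajectories <- function(mean_matrix, epsilon) {
  if (ncol(mean_matrix) != 3L) stop("expected 3 age columns")
  stats::setNames(
    apply(mean_matrix, 1L, classify_trajectory, epsilon = epsilon),
    rownames(mean_matrix))
}

#' Data-driven trajectory tolerance
#'
#' Pooled between-replicate standard deviation of the group means: for each
#' (genotype, age) cell the standard error of the cell mean is estimated
#' from the replicate scores, and the root-mean-square over cells is
#' returned. Used as the default `epsilon` of [classify_trajectory()].
#'
#' @param scores genes-by-pairs score matrix.
#' @param genotypes,ages per-pair design vectors.
#' @return Positive scalar.
#' @export
trajectory_epsilon <- function(scores, genotypes, ages) {
  cells <- split(seq_len(ncol(scores)), paste(genotypes, ages))
  se2 <- vapply(cells, function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    mean(apply(scores[, idx, drop = FALSE], 1L, stats::var)) / length(idx)
  }, numeric(1))
  se2 <- se2[!is.na(se2)]
  if (length(se2) == 0L)
    stop("need >= 2 replicates in at least one (genotype, age) cell")
  sqrt(mean(se2))
}

#' Overlap significance of two gene sets
#'
#' Tests whether the observed overlap `k = |A intersect B|` exceeds chance
#' given a universe U. The binomial test uses `X ~ Binomial(|A|, |B|/|U|)`,
#' the hypergeometric test `X ~ Hypergeometric(|U|, |B|, |A|)`; both report
#' the upper tail `P(X >= k)`. Fold enrichment is `k / (|A| |B| / |U|)`.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param test `"binomial"` (default) or `"hypergeometric"` (exact).
#' @return List with `overlap`, `expected`, `fold_enrichment`, `p_value`,
#'   `test`.
#' @export
gene_set_overlap_test <- function(setA, setB, universe,
                                  test = c("binomial", "hypergeometric")) {
  test <- match.arg(test)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  setA <- unique(setA)
  setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("gene sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB); nU <- length(universe)
  expected <- nA * nB / nU
  p <- if (test == "binomial")
    stats::pbinom(k - 1, nA, nB / nU, lower.tail = FALSE)
  else
    stats::phyper(k - 1, nB, nU - nB, nA, lower.tail = FALSE)
  list(overlap = k, expected = expected,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       p_value = p, test = test)
}

#' Hypergeometric enrichment of a query against a GMT collection
#'
#' For each gene set (intersected with the universe) the upper-tail
#' hypergeometric p-value of its overlap with the query is computed and the
#' p-values are BH-adjusted across sets.
#'
#' @param query character vector of genes of interest, subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @return data.frame sorted by p-value: `set`, `set_size`, `overlap`,
#'   `expected`, `fold_enrichment`, `p_value`, `padj`.
#' @export
gmt_enrichment <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    res <- gene_set_overlap_test(query, s, universe, test = "hypergeometric")
    data.frame(set = nm, set_size = length(s), overlap = res$overlap,
               expected = res$expected,
               fold_enrichment = res$fold_enrichment,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
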