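# Shared helpers: a reduced study for fast unit tests and the clock pipeline
# used across files.

small_config <- function(seed = 1L, ...) {
  study_config(seed = seed, n_background = 300, n_identity = 30,
               n_bivalent_c1 = 60, n_bivalent_c2 = 40, n_stress = 50, ...)
}

mark_zscores <- function(study, mark) {
  cm <- study$counts[[mark]]
  gene_zscores(normalize_counts(cm, size_factors_median_of_ratios(cm)))
}

score_from_study <- function(study) {
  pairing <- pair_samples(study$samples)
  euchromatin_score(mark_zscores(study, "H3K27ac"),
                    mark_zscores(study, "H3K27me3"), pairing)
}

clock_pipeline <- function(study) {
  sc <- score_from_study(study)
  pairing <- attr(sc, "pairing")
  c1 <- names(study$truth$classes)[study$truth$classes == "bivalent_c1"]
  pm <- gene_set_mean_score(sc, c1)
  model <- fit_clock(pm, pairing$age_months, pairing$genotype, "WT")
  list(model = model,
       estimates = predict_epigenetic_age(model, pm, pairing$age_months,
                                          pairing$genotype),
       pairing = pairing, scores = sc)
}
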