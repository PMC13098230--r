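test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "fmtrewire_input_error")
  expect_error(bh_adjust(c(0.1, NA)), class = "fmtrewire_input_error")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    # q is monotone non-decreasing when ordered by p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("differential abundance flags constants and validates groups", {
  m <- cbind(flat = rep(1, 8), shifted = c(1:4, 11:14))
  tab <- wide_table(m)
  res <- differential_abundance(tab, tab$sample_id[1:4], tab$sample_id[5:8])
  expect_true(res$constant[res$feature == "flat"])
  expect_equal(res$p_value[res$feature == "flat"], 1)
  expect_lt(res$p_value[res$feature == "shifted"], 0.05)
  expect_error(
    differential_abundance(tab, tab$sample_id[1:4], tab$sample_id[4:8]),
    "disjoint"
  )
  expect_error(
    differential_abundance(tab, tab$sample_id[1], tab$sample_id[5:8]),
    "at least 2"
  )
})

test_that("Mann-Whitney p equals exhaustive enumeration at n = 4 + 4", {
  set.seed(7)
  for (i in 1:5) {
    xa <- round(rnorm(4), 3)
    xb <- round(rnorm(4, 1), 3)
    tab <- wide_table(cbind(f = c(xa, xb)))
    res <- differential_abundance(tab, tab$sample_id[1:4], tab$sample_id[5:8])
    expect_equal(res$p_value, oracle_mw_exact(xa, xb))
  }
})

test_that("a planted shift is detected in most seeds at effect size 2, n = 10/10", {
  # metabolites carry the planted 2-sigma log shift undistorted (no
  # compositional closure); the Mann-Whitney detection probability at
  # p < 0.01 with n = 10/10 is 0.90, so the margin below only absorbs
  # binomial noise across the 20 x 25 feature draws
  hits <- vapply(1:20, function(seed) {
    cfg <- synth_config(n_patients = 10, n_donor_samples = 10,
      effect_size = 2, n_planted_edges_baseline = 0, n_planted_edges_post = 0,
      seed = seed)
    co <- simulate_cohort(cfg)
    meta <- co$metadata
    res <- differential_abundance(co$metabolites,
      meta$sample_id[meta$timepoint %in% "baseline"],
      meta$sample_id[meta$role == "donor"])
    resp <- intersect(co$truth$response_feature_ids, res$feature)
    mean(res$p_value[match(resp, res$feature)] < 0.01)
  }, numeric(1))
  expect_gte(mean(hits), 0.85)
})

test_that("prevalence filter keeps features at or above the threshold", {
  m <- cbind(in6 = c(rep(1, 6), rep(0, 4)), in5 = c(rep(1, 5), rep(0, 5)),
    dense = rep(2, 10))
  tab <- wide_table(m)
  kept <- prevalence_filter(tab, 0.6)
  expect_named(kept, c("sample_id", "in6", "dense")) # 6/10 inclusive, 5/10 out
  expect_named(prevalence_filter(tab, 1), c("sample_id", "dense"))
  expect_error(prevalence_filter(tab, 0), "min_prevalence")
  expect_error(prevalence_filter(tab, 1.3), "min_prevalence")
})

test_that("three-criterion screen recovers planted features and rejects constructs", {
  cfg <- synth_config(seed = 21)
  co <- simulate_cohort(cfg)
  scr <- screen_cohort(co)
  sel <- c(scr$taxa$feature[scr$taxa$selected],
    scr$metabolites$feature[scr$metabolites$selected])
  truth <- co$truth$response_feature_ids
  expect_gte(sum(sel %in% truth) / length(truth), 0.75)
  expect_true(all(scr$taxa$selected == (scr$taxa$crit1 & scr$taxa$crit2 & scr$taxa$crit3)))

  # construct: differential at baseline but NOT shifted back in responders
  meta <- co$metadata
  n <- nrow(meta)
  base <- meta$timepoint %in% "baseline"
  post <- meta$timepoint %in% "post"
  set.seed(1)
  stuck <- exp(rnorm(n) + 3 * (base | post)) # shifted in all patient samples, always
  flat <- exp(rnorm(n, 5))
  tab <- wide_table(cbind(stuck = stuck, flat = flat), ids = meta$sample_id)
  res <- screen_response_features(tab, meta, feature_class = "metabolite")
  expect_true(res$crit1[res$feature == "stuck"])
  expect_false(res$crit2[res$feature == "stuck"]) # no shift to donor levels
  expect_false(res$selected[res$feature == "stuck"])
  expect_false(res$crit1[res$feature == "flat"]) # not differential at baseline
  expect_false(res$selected[res$feature == "flat"])
})

test_that("screen is invariant to sample and feature order", {
  cfg <- synth_config(n_patients = 8, n_donor_samples = 6, n_taxa = 12,
    n_metabolites = 6, n_response_taxa = 3, n_response_metabolites = 2,
    n_planted_edges_baseline = 0, n_planted_edges_post = 0, seed = 13)
  co <- simulate_cohort(cfg)
  base <- screen_response_features(co$taxa, co$metadata)
  set.seed(99)
  shuf_rows <- co$taxa[sample(nrow(co$taxa)), ]
  shuf_cols <- shuf_rows[c("sample_id", sample(setdiff(names(co$taxa), "sample_id")))]
  perm <- screen_response_features(shuf_cols, co$metadata)
  reord <- perm[match(base$feature, perm$feature), ]
  expect_equal(as.data.frame(reord), as.data.frame(base), ignore_attr = TRUE)
})

test_that("missing strata error, empty non-responder stratum is vacuous", {
  cfg <- synth_config(n_patients = 6, responder_fraction = 1, n_donor_samples = 6,
    n_taxa = 8, n_metabolites = 4, n_response_taxa = 2, n_response_metabolites = 1,
    n_planted_edges_baseline = 0, n_planted_edges_post = 0, seed = 2)
  co <- simulate_cohort(cfg)
  expect_warning(res <- screen_response_features(co$taxa, co$metadata),
    "vacuously")
  expect_true(all(res$crit3))
  meta_nodonor <- dplyr::filter(co$metadata, role != "donor")
  expect_error(
    screen_response_features(co$taxa, meta_nodonor),
    ">= 2 samples"
  )
})
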