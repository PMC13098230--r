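test_that("configuration invariants are enforced", {
  expect_error(synth_config(responder_fraction = 1.2), "responder_fraction")
  expect_error(synth_config(planted_persistence_fraction = -0.1), "persistence")
  expect_error(synth_config(n_response_taxa = 99), "n_response_taxa")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  # planted pairs draw on non-response taxa/metabolites only
  expect_error(
    synth_config(n_taxa = 10, n_metabolites = 10, n_response_taxa = 8,
      n_response_metabolites = 8, n_planted_edges_baseline = 6,
      n_planted_edges_post = 6, planted_persistence_fraction = 0),
    class = "fmtrewire_config_error"
  )
})

test_that("cohort layout matches the configuration", {
  co <- simulate_cohort(synth_config(n_patients = 15, responder_fraction = 0.8,
    seed = 7))
  meta <- co$metadata
  pat <- dplyr::filter(meta, role == "patient", timepoint == "baseline")
  expect_equal(sum(pat$responder == "R"), 12)
  expect_equal(sum(pat$responder == "NR"), 3)
  expect_equal(length(co$truth$responder_ids), 12)
  expect_equal(sum(meta$role == "donor"), 16)
  # one baseline and one post per patient
  expect_equal(
    dplyr::count(dplyr::filter(meta, role == "patient"), subject_id)$n,
    rep(2, 15)
  )
  # single fixed donor in the default configuration
  expect_equal(unique(stats::na.omit(meta$donor_id)), "D01")
})

test_that("taxon rows are a closed composition and values non-negative", {
  co <- simulate_cohort(synth_config(seed = 3))
  m <- as.matrix(co$taxa[-1])
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
  expect_true(all(as.matrix(co$metabolites[-1]) > 0))
})

test_that("identical config and seed give bit-identical output", {
  a <- simulate_cohort(synth_config(seed = 11))
  b <- simulate_cohort(synth_config(seed = 11))
  expect_identical(a, b)
  d <- simulate_cohort(synth_config(seed = 12))
  expect_false(identical(a$taxa, d$taxa))
})

test_that("null configuration plants nothing", {
  co <- simulate_cohort(synth_config(effect_size = 0, n_response_taxa = 0,
    n_response_metabolites = 0, seed = 4))
  expect_length(co$truth$response_feature_ids, 0)
})

test_that("planted edge overlap realizes the persistence fraction up to rounding", {
  for (frac in c(0, 0.07, 0.25, 0.5, 1)) {
    cfg <- synth_config(planted_persistence_fraction = frac, seed = 5)
    co <- simulate_cohort(cfg)
    eb <- co$truth$planted_edges_baseline
    ep <- co$truth$planted_edges_post
    expect_equal(nrow(eb), cfg$n_planted_edges_baseline)
    expect_equal(nrow(ep), cfg$n_planted_edges_post)
    shared <- sum(paste(eb$a, eb$b, eb$sign) %in% paste(ep$a, ep$b, ep$sign))
    expect_equal(shared, round(frac * nrow(eb)))
  }
})

test_that("planted edges exceed the |rho| > 0.6 rule with high probability at n = 30", {
  hits <- c()
  for (seed in 1:8) {
    co <- simulate_cohort(synth_config(n_patients = 30, seed = seed))
    meta <- co$metadata
    rows <- match(meta$sample_id[meta$timepoint %in% "baseline"], co$taxa$sample_id)
    value_of <- function(node, rows) {
      if (node == "crp") return(meta$crp[match(co$taxa$sample_id[rows], meta$sample_id)])
      if (node == "calprotectin") {
        return(meta$calprotectin[match(co$taxa$sample_id[rows], meta$sample_id)])
      }
      tab <- if (node %in% names(co$taxa)) co$taxa else co$metabolites
      tab[[node]][rows]
    }
    eb <- co$truth$planted_edges_baseline
    for (e in seq_len(nrow(eb))) {
      rho <- spearman_cor(value_of(eb$a[e], rows), value_of(eb$b[e], rows))$rho
      hits <- c(hits, abs(rho) > 0.6)
    }
  }
  expect_gte(mean(hits), 0.9)
})

test_that("simulated clinical trajectories satisfy the outcome definitions", {
  cfg_uc <- synth_config(n_patients = 10, responder_fraction = 0.6, seed = 9)
  co <- simulate_cohort(cfg_uc)
  sc <- simulate_clinical_scores(co$metadata, cfg_uc)
  expect_equal(sc$response_w4, ifelse(sc$responder == "R", "R", "NR"))
  expect_equal(sc$remission_w14, ifelse(sc$responder == "R", "R", "NR"))
  nr <- dplyr::filter(sc, responder == "NR")
  # non-responders: partial Mayo reduction < 2
  expect_true(all((nr$mayo_sf_0 + nr$mayo_rb_0 + nr$mayo_pga_0) -
    (nr$mayo_sf_4 + nr$mayo_rb_4 + nr$mayo_pga_4) < 2))
  # responders: markers decline
  r <- dplyr::filter(sc, responder == "R")
  base <- dplyr::filter(co$metadata, timepoint == "baseline")
  expect_true(all(r$crp_w4 < base$crp[match(r$patient_id, base$subject_id)]))
  expect_identical(sc, simulate_clinical_scores(co$metadata, cfg_uc))

  cfg_cd <- synth_config(n_patients = 8, responder_fraction = 0.5,
    cohort = "CD", seed = 10)
  cd <- simulate_cohort(cfg_cd)
  sc_cd <- simulate_clinical_scores(cd$metadata, cfg_cd)
  rcd <- dplyr::filter(sc_cd, responder == "R")
  expect_true(all(rcd$cdai_0 - rcd$cdai_4 >= 100))
  expect_equal(sc_cd$response_w4, ifelse(sc_cd$responder == "R", "R", "NR"))
})

test_that("count-table generator controls dominance", {
  tab <- simulate_count_table(5, n_taxa = 80, depth = 5000,
    dominance_decay = 0.15, seed = 2)
  expect_equal(unname(rowSums(tab[-1])), rep(5000, 5))
  even <- simulate_count_table(5, n_taxa = 80, depth = 5000,
    dominance_decay = 0.02, seed = 2)
  expect_gt(
    mean(apply(as.matrix(tab[-1]), 1, simpson)),
    mean(apply(as.matrix(even[-1]), 1, simpson))
  )
})
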