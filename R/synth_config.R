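#' Configuration for the synthetic FMT cohort generator
#'
#' Collects and validates all tunable parameters of [simulate_cohort()].
#' Defaults emulate the ulcerative-colitis arm of a single-centre FMT
#' monotherapy study: 15 patients with paired baseline/post samples, a
#' responder fraction of 0.8 (12 responders, 3 non-responders), a pooled
#' donor group of 16 stool samples, 14 response-associated genera out of 60,
#' and 25 response-associated metabolites out of a 60-compound quantified
#' panel.
#'
#' @param n_patients Number of patients; each contributes one baseline and
#'   one post-FMT sample.
#' @param responder_fraction Proportion of patients labelled responders
#'   (`R`); the rest are non-responders (`NR`).
#' @param n_donor_samples Number of donor stool samples. With
#'   `per_patient_donors = FALSE` (default) they all come from one fixed
#'   donor shared by every patient; otherwise one donor (one sample) is
#'   assigned per patient and `n_donor_samples` is ignored.
#' @param n_taxa,n_metabolites Number of genus-level taxa / quantified
#'   metabolites.
#' @param n_response_taxa,n_response_metabolites Number of planted
#'   response-associated features per class.
#' @param effect_size Standardized mean shift (in units of `noise_sd`, on the
#'   log scale) separating patient baseline from donor levels for response
#'   features.
#' @param n_planted_edges_baseline,n_planted_edges_post Number of planted
#'   correlation edges realized in baseline / post patient samples.
#' @param planted_persistence_fraction Fraction of baseline planted edges
#'   whose node pair (and sign) recurs among the post planted edges.
#' @param edge_loading Latent-factor loading for planted edges. With the
#'   default 2 and `noise_sd = 1` the induced latent Pearson correlation is
#'   `2^2 / (2^2 + 1) = 0.8`.
#' @param noise_sd Residual log-scale standard deviation of every feature.
#' @param cohort Cohort tag attached to the metadata, `"UC"` or `"CD"`;
#'   controls which activity index [simulate_clinical_scores()] draws.
#' @param per_patient_donors If `TRUE`, assign an individual donor per
#'   patient instead of one shared donor.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_clinical_scores()]
#' @export
#' @examples
#' synth_config(n_patients = 15, responder_fraction = 0.8, seed = 7)
synth_config <- function(n_patients = 15,
                         responder_fraction = 0.8,
                         n_donor_samples = 16,
                         n_taxa = 60,
                         n_metabolites = 60,
                         n_response_taxa = 14,
                         n_response_metabolites = 25,
                         effect_size = 2,
                         n_planted_edges_baseline = 8,
                         n_planted_edges_post = 16,
                         planted_persistence_fraction = 0.25,
                         edge_loading = 2,
                         noise_sd = 1,
                         cohort = c("UC", "CD"),
                         per_patient_donors = FALSE,
                         seed = 1L) {
  cohort <- match.arg(cohort)
  cfg <- list(
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    n_donor_samples = as.integer(n_donor_samples),
    n_taxa = as.integer(n_taxa),
    n_metabolites = as.integer(n_metabolites),
    n_response_taxa = as.integer(n_response_taxa),
    n_response_metabolites = as.integer(n_response_metabolites),
    effect_size = effect_size,
    n_planted_edges_baseline = as.integer(n_planted_edges_baseline),
    n_planted_edges_post = as.integer(n_planted_edges_post),
    planted_persistence_fraction = planted_persistence_fraction,
    edge_loading = edge_loading,
    noise_sd = noise_sd,
    cohort = cohort,
    per_patient_donors = isTRUE(per_patient_donors),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (n_patients < 1) stop_input("`n_patients` must be >= 1")
    if (responder_fraction < 0 || responder_fraction > 1) {
      stop_input("`responder_fraction` must lie in [0, 1]")
    }
    if (planted_persistence_fraction < 0 || planted_persistence_fraction > 1) {
      stop_input("`planted_persistence_fraction` must lie in [0, 1]")
    }
    if (n_response_taxa > n_taxa) {
      stop_input("`n_response_taxa` cannot exceed `n_taxa`")
    }
    if (n_response_metabolites > n_metabolites) {
      stop_input("`n_response_metabolites` cannot exceed `n_metabolites`")
    }
    if (effect_size < 0 || noise_sd <= 0 || edge_loading < 0) {
      stop_input("`effect_size`/`edge_loading` must be >= 0 and `noise_sd` > 0")
    }
    if (n_planted_edges_baseline < 0 || n_planted_edges_post < 0) {
      stop_input("planted edge counts must be >= 0")
    }
  })
  # planted edge capacity: pairs draw on disjoint non-response taxa and
  # metabolites (two clinical markers are usable for the first two pairs)
  n_shared <- planted_shared_count(cfg)
  n_pool <- cfg$n_planted_edges_baseline + cfg$n_planted_edges_post - n_shared
  capacity <- min(
    cfg$n_taxa - cfg$n_response_taxa,
    cfg$n_metabolites - cfg$n_response_metabolites
  )
  if (n_pool >= 2 && (n_pool - 1L) > capacity) {
    stop_input(paste0(
      "requested planted edge counts (", n_pool, " distinct pairs) exceed ",
      "the available non-response node pairs (capacity ", capacity + 1L, ")"
    ), class = "fmtrewire_config_error")
  }
  if (n_pool == 1 && capacity < 1) {
    stop_input("no non-response taxa available for planted edges",
      class = "fmtrewire_config_error"
    )
  }
  invisible(cfg)
}

planted_shared_count <- function(cfg) {
  n_shared <- round(cfg$planted_persistence_fraction * cfg$n_planted_edges_baseline)
  min(n_shared, cfg$n_planted_edges_post)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf(
    "  %d patients (%.0f%% responders), %d donor sample(s), cohort %s\n",
    x$n_patients, 100 * x$responder_fraction, x$n_donor_samples, x$cohort
  ))
  cat(sprintf(
    "  %d taxa (%d response), %d metabolites (%d response), effect size %.2g\n",
    x$n_taxa, x$n_response_taxa, x$n_metabolites, x$n_response_metabolites,
    x$effect_size
  ))
  cat(sprintf(
    "  planted edges: %d baseline, %d post, persistence %.2f; seed %d\n",
    x$n_planted_edges_baseline, x$n_planted_edges_post,
    x$planted_persistence_fraction, x$seed
  ))
  invisible(x)
}
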