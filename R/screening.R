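#' Prevalence filter for feature tables
#'
#' Retains features with a nonzero value in at least `min_prevalence` of
#' samples (inclusive, so a feature present in 6 of 10 samples survives the
#' default 0.6 threshold). Feature order is preserved.
#'
#' @param table Tibble with `sample_id` plus one column per feature.
#' @param min_prevalence Required presence fraction, in (0, 1].
#' @return The filtered table.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.6) {
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1) {
    stop_input("`min_prevalence` must lie in (0, 1]")
  }
  stopifnot("sample_id" %in% names(table), nrow(table) > 0)
  feats <- setdiff(names(table), "sample_id")
  keep <- feats[colMeans(table[feats] > 0) >= min_prevalence]
  table[c("sample_id", keep)]
}

#' Per-feature two-group differential abundance test
#'
#' Applies a two-sided Mann-Whitney U test (default, suited to
#' zero-inflated compositional taxa) or Student's t-test (optionally on
#' log-transformed values, suited to quantified metabolite panels) to every
#' feature between two disjoint sample groups. Features constant across
#' both groups get `p = 1` and are flagged.
#'
#' @param table Tibble with `sample_id` plus feature columns.
#' @param group_a,group_b Character vectors of sample ids (>= 2 each,
#'   disjoint).
#' @param test `"mannwhitney"` or `"ttest"`.
#' @param log_transform Log-transform values before a t-test (a
#'   half-minimum pseudocount guards zeros).
#' @return Tibble with `feature`, `statistic`, `p_value`, `constant`.
#' @export
differential_abundance <- function(table, group_a, group_b,
                                   test = c("mannwhitney", "ttest"),
                                   log_transform = FALSE) {
  test <- match.arg(test)
  if (length(intersect(group_a, group_b)) > 0) {
    stop_input("sample groups must be disjoint")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_input("each group needs at least 2 samples")
  }
  missing_ids <- setdiff(c(group_a, group_b), table$sample_id)
  if (length(missing_ids)) {
    stop_input(paste("samples absent from table:", paste(missing_ids, collapse = ", ")))
  }
  feats <- setdiff(names(table), "sample_id")
  m <- as.matrix(table[feats])
  rownames(m) <- table$sample_id
  if (log_transform) {
    pos <- m[m > 0]
    ps <- if (length(pos)) min(pos) / 2 else 1
    m <- log(m + ps)
  }
  ia <- match(group_a, table$sample_id)
  ib <- match(group_b, table$sample_id)
  res <- purrr::map(feats, function(f) {
    xa <- m[ia, f]
    xb <- m[ib, f]
    if (length(unique(c(xa, xb))) == 1) {
      return(tibble(feature = f, statistic = NA_real_, p_value = 1, constant = TRUE))
    }
    ht <- if (test == "mannwhitney") {
      suppressWarnings(wilcox.test(xa, xb))
    } else {
      tryCatch(t.test(xa, xb), error = function(e) list(statistic = NA_real_, p.value = 1))
    }
    tibble(feature = f, statistic = unname(ht$statistic %||% NA_real_),
      p_value = ht$p.value, constant = FALSE)
  })
  purrr::list_rbind(res)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the step-up false-discovery-rate
#' procedure (via [stats::p.adjust()]), returning q-values in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values (same length and order).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Three-criterion screen for FMT-response-associated features
#'
#' Labels each feature (taxon or metabolite) as response-associated when it
#' satisfies all of:
#' \enumerate{
#'   \item differential abundance between patient baseline and donor
#'     samples, at BH-adjusted `q < alpha`;
#'   \item shift to donor levels in responders: the responder post-FMT
#'     group is not significantly different from donors (`p >= alpha`)
#'     *and* its mean lies on the donor side of the baseline mean (plain
#'     non-significance would also be satisfied by noisy features);
#'   \item persistence of baseline levels in non-responders: the
#'     non-responder post-FMT group is not significantly different from
#'     baseline (`p >= alpha`); the alternative reading -- still
#'     significantly shifted from donors -- is available via
#'     `crit3 = "still_shifted_vs_donor"`.
#' }
#' FDR adjustment is applied within the feature class being screened, so
#' taxa and metabolites are adjusted separately.
#'
#' @param table Feature tibble (`sample_id` + features).
#' @param meta Sample metadata with `sample_id`, `role` (donor/patient),
#'   `timepoint` (baseline/post), `responder` (R/NR).
#' @param alpha Significance level for every criterion (default 0.05).
#' @param feature_class `"taxon"` (Mann-Whitney tests) or `"metabolite"`
#'   (t-tests on log values); controls the default `test`.
#' @param test Override the per-class default test.
#' @param crit3 Operationalization of criterion (iii), see above.
#' @return A tibble of class `fmt_screen`: per feature the baseline-vs-donor
#'   statistic, `p_baseline_vs_donor` and `q_baseline_vs_donor`,
#'   `p_resp_post_vs_donor`, `p_nonresp_post_vs_baseline`, criterion flags
#'   `crit1`-`crit3`, `selected`, and `direction`
#'   (enriched_baseline/depleted_baseline from the sign of the
#'   baseline-minus-donor median difference).
#' @export
screen_response_features <- function(table, meta, alpha = 0.05,
                                     feature_class = c("taxon", "metabolite"),
                                     test = NULL,
                                     crit3 = c("persist_vs_baseline",
                                       "still_shifted_vs_donor")) {
  feature_class <- match.arg(feature_class)
  crit3 <- match.arg(crit3)
  if (is.null(test)) {
    test <- if (feature_class == "taxon") "mannwhitney" else "ttest"
  }
  log_tr <- test == "ttest" && feature_class == "metabolite"

  donors <- meta$sample_id[meta$role == "donor"]
  baseline <- meta$sample_id[meta$role == "patient" & meta$timepoint %in% "baseline"]
  resp_post <- meta$sample_id[meta$role == "patient" & meta$timepoint %in% "post" &
    meta$responder %in% "R"]
  nr_post <- meta$sample_id[meta$role == "patient" & meta$timepoint %in% "post" &
    meta$responder %in% "NR"]
  if (length(donors) < 2 || length(baseline) < 2 || length(resp_post) < 2) {
    stop_input("donor, baseline and responder-post strata each need >= 2 samples")
  }
  crit3_vacuous <- length(nr_post) < 2
  if (crit3_vacuous) {
    warn("non-responder post stratum has < 2 samples; criterion (iii) is vacuously true")
  }

  feats <- setdiff(names(table), "sample_id")
  d1 <- differential_abundance(table, baseline, donors, test = test,
    log_transform = log_tr)
  d2 <- differential_abundance(table, resp_post, donors, test = test,
    log_transform = log_tr)
  d3 <- if (crit3_vacuous) {
    tibble(feature = feats, p_value = NA_real_)
  } else if (crit3 == "persist_vs_baseline") {
    differential_abundance(table, nr_post, baseline, test = test,
      log_transform = log_tr)
  } else {
    differential_abundance(table, nr_post, donors, test = test,
      log_transform = log_tr)
  }

  m <- as.matrix(table[feats])
  rownames(m) <- table$sample_id
  mt <- if (log_tr) {
    pos <- m[m > 0]
    log(m + (if (length(pos)) min(pos) / 2 else 1))
  } else {
    m
  }
  mean_of <- function(ids) colMeans(mt[match(ids, table$sample_id), feats, drop = FALSE])
  med_of <- function(ids) apply(m[match(ids, table$sample_id), feats, drop = FALSE], 2, median)
  mu_d <- mean_of(donors)
  mu_b <- mean_of(baseline)
  mu_rp <- mean_of(resp_post)

  q1 <- bh_adjust(d1$p_value)
  crit1 <- q1 < alpha
  toward_donor <- (mu_d == mu_b) | (sign(mu_rp - mu_b) == sign(mu_d - mu_b))
  crit2 <- (d2$p_value >= alpha) & unname(toward_donor)
  crit3_flag <- if (crit3_vacuous) rep(TRUE, length(feats)) else {
    if (crit3 == "persist_vs_baseline") d3$p_value >= alpha else d3$p_value < alpha
  }
  direction <- ifelse(med_of(baseline) >= med_of(donors),
    "enriched_baseline", "depleted_baseline")

  out <- tibble(
    feature = feats,
    statistic = d1$statistic,
    p_baseline_vs_donor = d1$p_value,
    q_baseline_vs_donor = q1,
    p_resp_post_vs_donor = d2$p_value,
    p_nonresp_post_vs_baseline = d3$p_value,
    crit1 = crit1,
    crit2 = crit2,
    crit3 = crit3_flag,
    selected = crit1 & crit2 & crit3_flag,
    direction = unname(direction)
  )
  structure(out,
    class = c("fmt_screen", class(out)),
    alpha = alpha, feature_class = feature_class, test = test,
    crit3_mode = crit3, crit3_vacuous = crit3_vacuous
  )
}

#' Screen both omics layers of a cohort
#'
#' Convenience wrapper running [screen_response_features()] on the taxon
#' table (Mann-Whitney) and the metabolite table (t-test on logs) of a
#' cohort, with FDR control within each class.
#'
#' @param cohort An `fmt_cohort` (or any list with `taxa`, `metabolites`,
#'   `metadata`).
#' @inheritParams screen_response_features
#' @return List with elements `taxa` and `metabolites`, each an
#'   `fmt_screen` tibble.
#' @export
screen_cohort <- function(cohort, alpha = 0.05,
                          crit3 = c("persist_vs_baseline", "still_shifted_vs_donor")) {
  crit3 <- match.arg(crit3)
  list(
    taxa = screen_response_features(cohort$taxa, cohort$metadata,
      alpha = alpha, feature_class = "taxon", crit3 = crit3),
    metabolites = screen_response_features(cohort$metabolites, cohort$metadata,
      alpha = alpha, feature_class = "metabolite", crit3 = crit3)
  )
}
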