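#' Simulate a paired donor-patient multi-omic FMT cohort
#'
#' Generates genus-level relative abundances, quantified metabolite
#' concentrations and per-sample metadata for a donor group plus paired
#' baseline / post-FMT patient samples, together with the planted ground
#' truth every downstream stage can be validated against.
#'
#' Response-associated features are shifted by `effect_size` (in units of
#' `noise_sd`, on the log scale) in all patient baselines relative to
#' donors, restored to the donor mean in responders' post samples, and held
#' at the baseline mean in non-responders' post samples. Taxa are generated
#' on a log-scale Gaussian and closed to relative abundances last;
#' metabolites are log-normal with no closure (absolute quantification).
#' Planted correlation edges are induced by shared bounded latent factors
#' (uniform, unit variance) added to both endpoints on the log scale, which
#' yields a monotone association detectable by Spearman correlation while
#' keeping compositional spillover through the closure negligible; planted
#' and response taxa are drawn as low-abundance community members for the
#' same reason.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `fmt_cohort` with elements
#'   \describe{
#'     \item{taxa}{tibble, `sample_id` plus one relative-abundance column per
#'       taxon (rows sum to 1).}
#'     \item{metabolites}{tibble, `sample_id` plus one concentration column
#'       per metabolite.}
#'     \item{metadata}{tibble with `sample_id`, `subject_id`, `role`
#'       (donor/patient), `timepoint` (baseline/post/`NA`), `responder`
#'       (R/NR/`NA`), `donor_id`, `cohort`, and per-sample clinical markers
#'       `crp` (mg/dL) and `calprotectin` (ug/g, patients only).}
#'     \item{truth}{list with `response_feature_ids`,
#'       `planted_edges_baseline` / `planted_edges_post` (tibbles with
#'       columns `a`, `b`, `sign`) and `responder_ids`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(synth_config(seed = 7))
#' dplyr::count(cohort$metadata, role, timepoint, responder)
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)

  n_pat <- config$n_patients
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  n_resp <- round(config$responder_fraction * n_pat)
  responder_ids <- sort(sample(patient_ids, n_resp))
  responder <- ifelse(patient_ids %in% responder_ids, "R", "NR")

  if (config$per_patient_donors) {
    donor_of <- setNames(sprintf("D%02d", seq_len(n_pat)), patient_ids)
    donor_subject <- unname(donor_of)
    donor_sample_ids <- paste0(donor_subject, "_s1")
  } else {
    donor_of <- setNames(rep("D01", n_pat), patient_ids)
    donor_subject <- rep("D01", config$n_donor_samples)
    donor_sample_ids <- sprintf("D01_s%02d", seq_len(config$n_donor_samples))
  }
  n_donor <- length(donor_sample_ids)

  taxa_ids <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  met_ids <- sprintf("met_%03d", seq_len(config$n_metabolites))
  resp_taxa <- sort(sample(taxa_ids, config$n_response_taxa))
  resp_mets <- sort(sample(met_ids, config$n_response_metabolites))
  dir_taxa <- setNames(sample(c(1, -1), length(resp_taxa), replace = TRUE), resp_taxa)
  dir_mets <- setNames(sample(c(1, -1), length(resp_mets), replace = TRUE), resp_mets)

  planted <- plan_edges(config, setdiff(taxa_ids, resp_taxa), setdiff(met_ids, resp_mets))

  # base log-means; response and planted taxa are low-abundance community
  # members so that compositional closure leaves other taxa untouched
  mu_taxa <- setNames(rnorm(config$n_taxa, 0, 1), taxa_ids)
  if (length(resp_taxa)) mu_taxa[resp_taxa] <- rnorm(length(resp_taxa), -2, 0.5)
  if (length(planted$taxa_used)) mu_taxa[planted$taxa_used] <- -3
  mu_mets <- setNames(rnorm(config$n_metabolites, 3, 1), met_ids)

  meta <- dplyr::bind_rows(
    tibble(
      sample_id = donor_sample_ids, subject_id = donor_subject,
      role = "donor", timepoint = NA_character_, responder = NA_character_,
      donor_id = NA_character_
    ),
    tibble(
      sample_id = paste0(patient_ids, "_baseline"), subject_id = patient_ids,
      role = "patient", timepoint = "baseline", responder = responder,
      donor_id = unname(donor_of)
    ),
    tibble(
      sample_id = paste0(patient_ids, "_post"), subject_id = patient_ids,
      role = "patient", timepoint = "post", responder = responder,
      donor_id = unname(donor_of)
    )
  )
  n_s <- nrow(meta)
  baseline_rows <- which(meta$timepoint %in% "baseline")
  post_rows <- which(meta$timepoint %in% "post")
  post_nr_rows <- post_rows[responder == "NR"]

  delta <- config$effect_size * config$noise_sd
  log_taxa <- matrix(mu_taxa, n_s, config$n_taxa, byrow = TRUE,
    dimnames = list(meta$sample_id, taxa_ids)) +
    config$noise_sd * matrix(rnorm(n_s * config$n_taxa), n_s)
  log_mets <- matrix(mu_mets, n_s, config$n_metabolites, byrow = TRUE,
    dimnames = list(meta$sample_id, met_ids)) +
    config$noise_sd * matrix(rnorm(n_s * config$n_metabolites), n_s)
  for (f in resp_taxa) {
    log_taxa[baseline_rows, f] <- log_taxa[baseline_rows, f] + dir_taxa[[f]] * delta
    log_taxa[post_nr_rows, f] <- log_taxa[post_nr_rows, f] + dir_taxa[[f]] * delta
  }
  for (f in resp_mets) {
    log_mets[baseline_rows, f] <- log_mets[baseline_rows, f] + dir_mets[[f]] * delta
    log_mets[post_nr_rows, f] <- log_mets[post_nr_rows, f] + dir_mets[[f]] * delta
  }

  # clinical markers (log scale); donors carry no disease markers
  log_crp <- rep(NA_real_, n_s)
  log_cal <- rep(NA_real_, n_s)
  log_crp[baseline_rows] <- log(8) + 0.4 * rnorm(n_pat)
  log_cal[baseline_rows] <- log(150) + 0.6 * rnorm(n_pat)
  post_mu_crp <- ifelse(responder == "R", log(3), log(8))
  post_mu_cal <- ifelse(responder == "R", log(40), log(150))
  log_crp[post_rows] <- post_mu_crp + 0.4 * rnorm(n_pat)
  log_cal[post_rows] <- post_mu_cal + 0.6 * rnorm(n_pat)

  # planted edges: shared bounded latent factor per (edge, sample)
  plant_context <- function(edges, rows) {
    if (is.null(edges) || nrow(edges) == 0) {
      return(invisible(NULL))
    }
    s3 <- sqrt(3)
    z <- matrix(runif(length(rows) * nrow(edges), -s3, s3), length(rows))
    for (e in seq_len(nrow(edges))) {
      sgn <- if (edges$sign[e] == "positive") 1 else -1
      for (side in 1:2) {
        node <- if (side == 1) edges$a[e] else edges$b[e]
        add <- config$edge_loading * z[, e] * (if (side == 1) 1 else sgn)
        if (node == "crp") {
          log_crp[rows] <<- log_crp[rows] + add
        } else if (node == "calprotectin") {
          log_cal[rows] <<- log_cal[rows] + add
        } else if (node %in% taxa_ids) {
          log_taxa[rows, node] <<- log_taxa[rows, node] + add
        } else {
          log_mets[rows, node] <<- log_mets[rows, node] + add
        }
      }
    }
    invisible(NULL)
  }
  plant_context(planted$baseline, baseline_rows)
  plant_context(planted$post, post_rows)

  rel_taxa <- exp(log_taxa)
  rel_taxa <- rel_taxa / rowSums(rel_taxa)

  meta$cohort <- config$cohort
  meta$crp <- exp(log_crp)
  meta$calprotectin <- exp(log_cal)

  structure(list(
    taxa = dplyr::bind_cols(tibble(sample_id = meta$sample_id), as_tibble(rel_taxa)),
    metabolites = dplyr::bind_cols(tibble(sample_id = meta$sample_id), as_tibble(exp(log_mets))),
    metadata = meta,
    truth = list(
      response_feature_ids = c(resp_taxa, resp_mets),
      planted_edges_baseline = planted$baseline,
      planted_edges_post = planted$post,
      responder_ids = responder_ids
    ),
    config = config
  ), class = "fmt_cohort")
}

# Lay out the planted edge pool: the first pair links CRP to a taxon, the
# second links calprotectin to a metabolite, the rest are taxon-metabolite
# pairs; all node pairs are disjoint. The first `n_shared` baseline pairs
# recur (sign preserved) among the post pairs.
plan_edges <- function(config, avail_taxa, avail_mets) {
  n_b <- config$n_planted_edges_baseline
  n_p <- config$n_planted_edges_post
  n_shared <- planted_shared_count(config)
  n_pool <- n_b + n_p - n_shared
  empty <- tibble(a = character(), b = character(), sign = character())
  if (n_pool == 0) {
    return(list(baseline = empty, post = empty, taxa_used = character()))
  }
  n_taxa_used <- max(1L, n_pool - 1L)
  n_mets_used <- max(0L, n_pool - 1L)
  plant_taxa <- sample(avail_taxa, n_taxa_used)
  plant_mets <- if (n_mets_used) sample(avail_mets, n_mets_used) else character()
  a <- character(n_pool)
  b <- character(n_pool)
  for (i in seq_len(n_pool)) {
    if (i == 1) {
      a[i] <- "crp"; b[i] <- plant_taxa[1]
    } else if (i == 2) {
      a[i] <- "calprotectin"; b[i] <- plant_mets[1]
    } else {
      a[i] <- plant_taxa[i - 1]; b[i] <- plant_mets[i - 1]
    }
  }
  pool <- tibble(a = a, b = b,
    sign = sample(c("positive", "negative"), n_pool, replace = TRUE))
  list(
    baseline = pool[seq_len(n_b), ],
    post = pool[c(seq_len(n_shared), n_b + seq_len(n_p - n_shared)), ],
    taxa_used = unique(c(plant_taxa, character()))
  )
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat("<fmt_cohort>\n")
  cat(sprintf(
    "  %d samples (%d donor, %d patients x baseline/post), %d taxa, %d metabolites\n",
    nrow(x$metadata), sum(x$metadata$role == "donor"), x$config$n_patients,
    x$config$n_taxa, x$config$n_metabolites
  ))
  cat(sprintf(
    "  ground truth: %d response features, %d/%d planted baseline/post edges\n",
    length(x$truth$response_feature_ids),
    nrow(x$truth$planted_edges_baseline), nrow(x$truth$planted_edges_post)
  ))
  invisible(x)
}

#' Per-sample clinical marker table for network construction
#'
#' Extracts the clinical feature table (CRP, fecal calprotectin) for patient
#' samples from cohort metadata, in the wide samples-by-features layout the
#' network builder expects.
#'
#' @param metadata Cohort metadata tibble (see [simulate_cohort()]).
#' @return Tibble with `sample_id`, `crp`, `calprotectin`.
#' @export
clinical_markers <- function(metadata) {
  metadata |>
    dplyr::filter(.data$role == "patient") |>
    dplyr::select("sample_id", "crp", "calprotectin")
}

#' Simulate clinical activity-score trajectories
#'
#' Draws baseline / week-4 / week-14 disease-activity scores (partial Mayo
#' subscores for UC, CDAI and SES-CD for CD) for each patient such that
#' responders satisfy the week-4 response definitions (UC: partial Mayo
#' reduction >= 2 with rectal-bleeding subscore decrease >= 1; CD: CDAI
#' decrease >= 100) and reach week-14 remission, while non-responders
#' violate them. CRP and fecal calprotectin decline monotonically for
#' responders and stay elevated for non-responders. Labels are derived by
#' the same classifiers exported for real data
#' ([uc_clinical_response()], [cd_clinical_response()], etc.), never
#' assigned directly.
#'
#' @param metadata Cohort metadata (patients with responder labels).
#' @param config The [synth_config()] used to generate the cohort; supplies
#'   the cohort tag and the RNG seed (offset so score noise is independent
#'   of the feature tables).
#' @return An outcome tibble with one row per patient: score trajectories,
#'   `crp_w4`, `calpro_w4`, `response_w4`, `crp_w14`, `calpro_w14`,
#'   `remission_w14`, `endo_remission_w14`.
#' @export
simulate_clinical_scores <- function(metadata, config) {
  pts <- metadata |>
    dplyr::filter(.data$role == "patient", .data$timepoint == "baseline") |>
    dplyr::select(patient_id = "subject_id", "responder", "cohort",
      crp0 = "crp", cal0 = "calprotectin")
  if (nrow(pts) == 0 || anyNA(pts$responder)) {
    stop_input("metadata must contain patient baseline rows with responder labels")
  }
  set.seed(config$seed + 1L)
  rows <- purrr::pmap(pts, function(patient_id, responder, cohort, crp0, cal0) {
    resp <- identical(responder, "R")
    if (resp) {
      crp_w4 <- crp0 * runif(1, 0.3, 0.8)
      cal_w4 <- cal0 * runif(1, 0.2, 0.7)
      crp_w14 <- crp_w4 * runif(1, 0.5, 1)
      cal_w14 <- cal_w4 * runif(1, 0.5, 1)
    } else {
      crp_w4 <- crp0 * runif(1, 1.2, 2.5)
      cal_w4 <- cal0 * runif(1, 1.2, 2.5)
      crp_w14 <- crp_w4 * runif(1, 0.4, 1.1)
      cal_w14 <- cal_w4 * runif(1, 0.6, 1.2)
    }
    if (cohort == "UC") {
      m0 <- mayo_score(sample(2:3, 1), sample(2:3, 1), sample(2:3, 1), sample(2:3, 1))
      if (resp) {
        m4 <- mayo_score(sample(0:1, 1), sample(0:(m0$rectal_bleeding - 1), 1),
          sample(0:1, 1), NA)
        m14 <- mayo_score(sample(0:1, 1), 0, sample(0:1, 1),
          sample(0:2, 1, prob = c(0.35, 0.35, 0.3)))
      } else {
        m4 <- mayo_score(max(m0$stool_frequency - sample(0:1, 1), 0),
          m0$rectal_bleeding, m0$physician_global, NA)
        m14 <- mayo_score(m0$stool_frequency, m0$rectal_bleeding,
          m0$physician_global, sample(2:3, 1))
      }
      rem <- uc_remission(m14)
      tibble(
        patient_id = patient_id, cohort = cohort, responder = responder,
        mayo_sf_0 = m0$stool_frequency, mayo_rb_0 = m0$rectal_bleeding,
        mayo_pga_0 = m0$physician_global,
        mayo_sf_4 = m4$stool_frequency, mayo_rb_4 = m4$rectal_bleeding,
        mayo_pga_4 = m4$physician_global,
        mayo_sf_14 = m14$stool_frequency, mayo_rb_14 = m14$rectal_bleeding,
        mayo_pga_14 = m14$physician_global, mayo_endo_14 = m14$endoscopic,
        cdai_0 = NA_real_, cdai_4 = NA_real_, cdai_14 = NA_real_,
        ses_cd_14 = NA_real_,
        crp_w4 = crp_w4, calpro_w4 = cal_w4,
        response_w4 = if (uc_clinical_response(m0, m4)) "R" else "NR",
        crp_w14 = crp_w14, calpro_w14 = cal_w14,
        remission_w14 = if (rem$clinical) "R" else "NR",
        endo_remission_w14 = if (isTRUE(rem$endoscopic)) "R" else "NR"
      )
    } else {
      cdai0 <- runif(1, 260, 420)
      if (resp) {
        cdai4 <- cdai0 - runif(1, 110, 200)
        cdai14 <- runif(1, 80, 149)
        ses14 <- sample(0:3, 1, prob = c(0.3, 0.3, 0.25, 0.15))
      } else {
        cdai4 <- cdai0 - runif(1, 0, 80)
        cdai14 <- runif(1, 160, 300)
        ses14 <- sample(4:8, 1)
      }
      a0 <- cd_activity(cdai0)
      a4 <- cd_activity(cdai4)
      rem <- cd_remission(cd_activity(cdai14, ses14))
      tibble(
        patient_id = patient_id, cohort = cohort, responder = responder,
        mayo_sf_0 = NA_integer_, mayo_rb_0 = NA_integer_, mayo_pga_0 = NA_integer_,
        mayo_sf_4 = NA_integer_, mayo_rb_4 = NA_integer_, mayo_pga_4 = NA_integer_,
        mayo_sf_14 = NA_integer_, mayo_rb_14 = NA_integer_,
        mayo_pga_14 = NA_integer_, mayo_endo_14 = NA_integer_,
        cdai_0 = cdai0, cdai_4 = cdai4, cdai_14 = cdai14, ses_cd_14 = ses14,
        crp_w4 = crp_w4, calpro_w4 = cal_w4,
        response_w4 = if (cd_clinical_response(a0, a4)) "R" else "NR",
        crp_w14 = crp_w14, calpro_w14 = cal_w14,
        remission_w14 = if (rem$clinical) "R" else "NR",
        endo_remission_w14 = if (isTRUE(rem$endoscopic)) "R" else "NR"
      )
    }
  })
  purrr::list_rbind(rows)
}

#' Simulate a community count table with tunable dominance
#'
#' Draws per-sample taxon counts from a multinomial over an exponentially
#' decaying rank-abundance curve, with log-normal between-sample wobble.
#' A steeper `dominance_decay` concentrates reads on few taxa -- the
#' dysbiotic pattern of fewer observed taxa, lower richness estimates and a
#' higher Simpson dominance index; a shallow decay gives an even,
#' donor-like community.
#'
#' @param n_samples Number of samples.
#' @param n_taxa Size of the taxon pool.
#' @param depth Sequencing depth (reads per sample).
#' @param dominance_decay Exponential decay rate of the rank-abundance
#'   curve; e.g. 0.04 for a donor-like community, 0.18 for a dysbiotic one.
#' @param sample_sd Log-normal sd of per-sample abundance wobble.
#' @param prefix Sample-id prefix.
#' @param seed Optional integer seed.
#' @return Tibble with `sample_id` plus one integer count column per taxon.
#' @export
#' @examples
#' donor_like <- simulate_count_table(4, dominance_decay = 0.04, seed = 1)
#' rowSums(donor_like[-1])
simulate_count_table <- function(n_samples, n_taxa = 150, depth = 10000,
                                 dominance_decay = 0.04, sample_sd = 0.3,
                                 prefix = "S", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_p <- exp(-dominance_decay * seq_len(n_taxa))
  counts <- vapply(seq_len(n_samples), function(i) {
    p <- base_p * exp(rnorm(n_taxa, 0, sample_sd))
    as.integer(rmultinom(1, depth, p / sum(p)))
  }, integer(n_taxa))
  out <- t(counts)
  colnames(out) <- sprintf("taxon_%03d", seq_len(n_taxa))
  dplyr::bind_cols(
    tibble(sample_id = sprintf("%s%03d", prefix, seq_len(n_samples))),
    as_tibble(out)
  )
}
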