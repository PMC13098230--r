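#' Configuration of an end-to-end pipeline run
#'
#' Bundles the synthetic-cohort configuration (or paths to existing input
#' tables), the analysis thresholds -- which default to the conventions the
#' method reproduces: `alpha = 0.05`, `|rho| > 0.6`, prevalence `>= 0.6`,
#' `VIP > 0.9` -- and the output directory.
#'
#' @param synth A [synth_config()]; the cohort simulated for the run.
#' @param taxa,metabolites,metadata Optional file paths (TSV feature
#'   tables, CSV metadata); when all three are given they replace the
#'   simulated cohort and no ground truth is available.
#' @param outcomes Optional outcomes CSV path or tibble (see
#'   [read_outcomes()]); when `NULL`, score trajectories are simulated for
#'   the cohort.
#' @param alpha Significance level used by every stage.
#' @param rho_threshold,min_prevalence Network edge and prevalence rules.
#' @param vip_threshold PLS-DA VIP cutoff.
#' @param post_samples Build the post network from all patients' post
#'   samples (`"all"`, default) or responders only.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `synth$seed`.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), taxa = NULL, metabolites = NULL,
                       metadata = NULL, outcomes = NULL, alpha = 0.05,
                       rho_threshold = 0.6, min_prevalence = 0.6,
                       vip_threshold = 0.9,
                       post_samples = c("all", "responders"),
                       out_dir = tempfile("fmtrewire_run_"), seed = NULL) {
  post_samples <- match.arg(post_samples)
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must lie in (0, 1)")
  if (rho_threshold < 0 || rho_threshold >= 1) {
    stop_input("`rho_threshold` must lie in [0, 1)")
  }
  if (min_prevalence <= 0 || min_prevalence > 1) {
    stop_input("`min_prevalence` must lie in (0, 1]")
  }
  if (vip_threshold < 0) stop_input("`vip_threshold` must be >= 0")
  if (!is.null(seed)) {
    synth$seed <- as.integer(seed)
  }
  structure(list(
    synth = synth, taxa = taxa, metabolites = metabolites, metadata = metadata,
    outcomes = outcomes, alpha = alpha, rho_threshold = rho_threshold,
    min_prevalence = min_prevalence, vip_threshold = vip_threshold,
    post_samples = post_samples, out_dir = out_dir
  ), class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
      class = "fmtrewire_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> outcomes -> diversity -> screening ->
#' ordination -> networks -> persistence, writing every stage output, a
#' manifest (inputs, seed, thresholds, package version) and a JSON +
#' plain-text report under `config$out_dir`. The persistence fraction in
#' the report is recomputed from the serialized GraphML networks, so the
#' written artifacts are self-consistent. A run is deterministic given the
#' configuration and seed; a failing stage aborts with a stage-named error
#' and retains partial outputs.
#'
#' @param config A [run_config()].
#' @return An `fmt_report` list (invisibly): outcome counts, selected
#'   features per class, diversity group summary, network censuses,
#'   persistence, and the configuration echo.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  # --- inputs -----------------------------------------------------------
  external <- !is.null(config$taxa) && !is.null(config$metabolites) &&
    !is.null(config$metadata)
  cohort <- run_stage("input", {
    if (external) {
      list(
        taxa = read_feature_table(config$taxa),
        metabolites = read_feature_table(config$metabolites),
        metadata = read_metadata(config$metadata),
        truth = NULL, config = config$synth
      )
    } else {
      simulate_cohort(config$synth)
    }
  })
  cohort_tag <- cohort$metadata$cohort[1] %||% config$synth$cohort
  run_stage("input", {
    write_feature_table(cohort$taxa, out("taxa.tsv"))
    write_feature_table(cohort$metabolites, out("metabolites.tsv"))
    write_metadata(cohort$metadata, out("metadata.csv"))
    if (!is.null(cohort$truth)) {
      jsonlite::write_json(cohort$truth, out("ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
    }
  })

  # --- outcomes ---------------------------------------------------------
  outcomes <- run_stage("outcomes", {
    rec <- config$outcomes
    if (is.null(rec)) {
      rec <- simulate_clinical_scores(cohort$metadata, cohort$config)
    } else if (is.character(rec)) {
      rec <- read_outcomes(rec)
    }
    readr::write_csv(rec, out("outcomes.csv"), na = "")
    rec
  })
  outcome_counts <- run_stage("outcomes", {
    purrr::map(unique(outcomes$cohort), ~summarize_outcomes(outcomes, .x)) |>
      purrr::list_rbind()
  })

  # --- diversity --------------------------------------------------------
  diversity <- run_stage("diversity", {
    counts <- suppressWarnings(counts_from_relative(cohort$taxa))
    div <- alpha_diversity(counts)
    readr::write_csv(div, out("diversity.csv"))
    grp <- cohort$metadata |>
      dplyr::mutate(group = dplyr::case_when(
        .data$role == "donor" ~ "donor",
        .data$timepoint == "baseline" ~ "baseline",
        .data$responder == "R" ~ "post_responder",
        TRUE ~ "post_nonresponder"
      )) |>
      dplyr::select("sample_id", "group")
    div |>
      dplyr::left_join(grp, by = "sample_id") |>
      tidyr::pivot_longer(-c("sample_id", "group"),
        names_to = "index", values_to = "value") |>
      dplyr::group_by(.data$group, .data$index) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
        .groups = "drop")
  })

  # --- screening --------------------------------------------------------
  screens <- run_stage("screening", {
    sc <- suppressWarnings(screen_cohort(cohort, alpha = config$alpha))
    readr::write_tsv(as_tibble(sc$taxa), out("screen_taxa.tsv"))
    readr::write_tsv(as_tibble(sc$metabolites), out("screen_metabolites.tsv"))
    sc
  })
  selected <- list(
    taxa = screens$taxa$feature[screens$taxa$selected],
    metabolites = screens$metabolites$feature[screens$metabolites$selected]
  )

  # --- ordination -------------------------------------------------------
  ordination <- run_stage("ordination", {
    meta <- cohort$metadata
    ids <- meta$sample_id[meta$role == "donor" | meta$timepoint %in% "baseline"]
    labels <- ifelse(meta$role[match(ids, meta$sample_id)] == "donor",
      "donor", "baseline")
    tab <- cohort$taxa[match(ids, cohort$taxa$sample_id), ]
    fit <- run_plsda(tab, labels, n_components = 2,
      vip_threshold = config$vip_threshold)
    readr::write_csv(tidy(fit, "vip"), out("plsda_vip.csv"))
    fit
  })

  # --- networks ---------------------------------------------------------
  meta <- cohort$metadata
  baseline_ids <- meta$sample_id[meta$timepoint %in% "baseline"]
  post_ids <- if (config$post_samples == "responders") {
    meta$sample_id[meta$timepoint %in% "post" & meta$responder %in% "R"]
  } else {
    meta$sample_id[meta$timepoint %in% "post"]
  }
  clin <- clinical_markers(meta)
  nets <- run_stage("network", {
    tables <- list(clinical = clin, taxon = cohort$taxa,
      metabolite = cohort$metabolites)
    nb <- build_network(tables, samples = baseline_ids,
      rho_threshold = config$rho_threshold, alpha = config$alpha,
      min_prevalence = config$min_prevalence,
      context = "baseline", cohort = cohort_tag)
    np <- build_network(tables, samples = post_ids,
      rho_threshold = config$rho_threshold, alpha = config$alpha,
      min_prevalence = config$min_prevalence,
      context = "post", cohort = cohort_tag)
    export_network(nb, out("net_baseline.graphml"))
    export_network(np, out("net_post.graphml"))
    list(baseline = nb, post = np)
  })
  persistence <- run_stage("persistence", {
    direct <- edge_persistence(nets$baseline, nets$post)
    reread <- edge_persistence(
      read_network(out("net_baseline.graphml")),
      read_network(out("net_post.graphml"))
    )
    if (!isTRUE(all.equal(direct$fraction, reread$fraction))) {
      stop("persistence recomputed from serialized networks disagrees")
    }
    direct
  })

  # --- report -----------------------------------------------------------
  report <- structure(list(
    cohort = cohort_tag,
    outcome_counts = outcome_counts,
    selected_features = selected,
    diversity_summary = diversity,
    ordination = as.list(glance(ordination)),
    network_census = list(
      baseline = count_class_pairs(nets$baseline),
      post = count_class_pairs(nets$post)
    ),
    persistence = list(
      fraction = persistence$fraction,
      n_baseline = persistence$n_baseline,
      n_post = persistence$n_post,
      n_persisting = nrow(persistence$persisting)
    ),
    version = as.character(packageVersion("fmtrewire")),
    config = list(
      seed = cohort$config$seed, alpha = config$alpha,
      rho_threshold = config$rho_threshold,
      min_prevalence = config$min_prevalence,
      vip_threshold = config$vip_threshold,
      post_samples = config$post_samples
    )
  ), class = "fmt_report")
  run_stage("report", {
    jsonlite::write_json(unclass(report), out("report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(list(
      inputs = if (external) {
        list(taxa = config$taxa, metabolites = config$metabolites,
          metadata = config$metadata)
      } else {
        list(simulated = unclass(cohort$config))
      },
      thresholds = report$config,
      version = report$version,
      files = list.files(config$out_dir)
    ), out("manifest.json"), auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(report)), out("report.txt"))
  })
  invisible(report)
}

#' @export
print.fmt_report <- function(x, ...) {
  cat("== fmtrewire pipeline report (", x$cohort, " cohort) ==\n", sep = "")
  cat("\nOutcomes:\n")
  print(as.data.frame(x$outcome_counts), row.names = FALSE)
  cat(sprintf(
    "\nScreening: %d response-associated taxa, %d metabolites\n",
    length(x$selected_features$taxa), length(x$selected_features$metabolites)
  ))
  cat(sprintf(
    "PLS-DA (baseline vs donor): R2X %.3f, R2Y %.3f, Q2Y %.3f, %d features VIP-selected\n",
    x$ordination$r2x, x$ordination$r2y, x$ordination$q2y,
    x$ordination$n_vip_selected
  ))
  cb <- x$network_census$baseline
  cp <- x$network_census$post
  cat(sprintf(
    "Networks: baseline %d pairs (%d after metabolite-metabolite exclusion), post %d (%d)\n",
    cb$total, cb$total_after_exclusion, cp$total, cp$total_after_exclusion
  ))
  cat(sprintf(
    "Edge persistence: %s (%d of %d baseline edges persist post-FMT)\n",
    ifelse(is.na(x$persistence$fraction), "undefined",
      sprintf("%.3f", x$persistence$fraction)),
    x$persistence$n_persisting, x$persistence$n_baseline
  ))
  cat(sprintf("\nversion %s, seed %d\n", x$version, x$config$seed))
  invisible(x)
}
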