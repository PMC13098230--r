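#' Alpha-diversity estimators
#'
#' Per-sample diversity indices computed from a vector of feature counts:
#' observed richness, bias-corrected Chao1, the ACE estimator of Chao & Lee,
#' Shannon entropy (natural log) and the Simpson index. Simpson is reported
#' in its dominance form `D = sum(p_i^2)` -- the form under which a dysbiotic,
#' dominance-skewed community scores *higher* than a diverse one -- with the
#' complement `1 - D` available via `complement = TRUE`.
#'
#' `chao1()` is `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the
#' singleton/doubleton counts. `ace()` splits features at
#' `rare_cutoff` into rare and abundant classes and estimates
#' `S_abund + S_rare / C_ACE + (F1 / C_ACE) * gamma^2`, where
#' `C_ACE = 1 - F1 / N_rare` is the rare-class sample coverage and
#' `gamma^2` the rare-class coefficient of variation. Two degenerate cases
#' are defined explicitly: with no rare features ACE equals the observed
#' richness, and when every rare individual is a singleton (`C_ACE = 0`)
#' ACE falls back to Chao1 with a warning.
#'
#' @param v Non-negative feature counts (integers for `chao1`/`ace`); at
#'   least one must be positive.
#' @param rare_cutoff Count at or below which a feature belongs to the rare
#'   class (default 10, the conventional choice).
#' @param complement For `simpson()`: return `1 - D` instead of `D`.
#' @return A single numeric value.
#' @export
#' @examples
#' chao1(c(5, 1, 1, 2)) # 4 + 2 * 1 / (2 * 2) = 4.5
#' simpson(c(1, 1, 2)) # 0.375
observed_richness <- function(v) {
  v <- check_counts(v)
  sum(v > 0)
}

#' @rdname observed_richness
#' @export
chao1 <- function(v) {
  v <- check_counts(v, integer = TRUE)
  v <- v[v > 0]
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  length(v) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname observed_richness
#' @export
ace <- function(v, rare_cutoff = 10) {
  v <- check_counts(v, integer = TRUE)
  v <- v[v > 0]
  rare <- v[v <= rare_cutoff]
  s_abund <- sum(v > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) {
    return(s_abund)
  }
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warn("all rare individuals are singletons (C_ACE = 0); falling back to Chao1")
    return(chao1(v))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  i <- seq_len(rare_cutoff)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' @rdname observed_richness
#' @export
shannon <- function(v) {
  v <- check_counts(v)
  p <- v[v > 0] / sum(v)
  -sum(p * log(p))
}

#' @rdname observed_richness
#' @export
simpson <- function(v, complement = FALSE) {
  v <- check_counts(v)
  p <- v / sum(v)
  d <- sum(p^2)
  if (complement) 1 - d else d
}

check_counts <- function(v, integer = FALSE) {
  v <- as.numeric(v)
  if (any(is.na(v)) || any(v < 0)) {
    stop_input("counts must be non-negative and non-missing")
  }
  if (all(v == 0)) stop_input("all-zero count vector")
  if (integer && any(abs(v - round(v)) > 1e-8)) {
    stop_input(paste(
      "richness estimators need integer counts;",
      "see counts_from_relative() for relative-abundance tables"
    ))
  }
  v
}

#' Per-sample alpha-diversity table
#'
#' Applies all five estimators of [observed_richness()] to every row of a
#' samples-by-features count table.
#'
#' @param counts Tibble/data frame with a `sample_id` column followed by
#'   integer feature counts.
#' @param rare_cutoff Passed to [ace()].
#' @return Tibble with columns `sample_id`, `observed`, `chao1`, `ace`,
#'   `shannon`, `simpson_D`.
#' @export
#' @examples
#' alpha_diversity(simulate_count_table(3, seed = 1))
alpha_diversity <- function(counts, rare_cutoff = 10) {
  stopifnot("sample_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
  tibble(
    sample_id = counts$sample_id,
    observed = apply(m, 1, observed_richness),
    chao1 = apply(m, 1, chao1),
    ace = apply(m, 1, ace, rare_cutoff = rare_cutoff),
    shannon = apply(m, 1, shannon),
    simpson_D = apply(m, 1, simpson)
  )
}

#' Rescale relative abundances to pseudo-counts
#'
#' Richness estimators (Chao1, ACE) are defined on counts. When only
#' relative abundances are available this helper multiplies by a nominal
#' library size and rounds, emitting a warning so the approximation is
#' always flagged: abundances below `0.5 / library_size` become zeros, so
#' rare-tail estimates depend on the chosen library size.
#'
#' @param rel Tibble with `sample_id` plus relative-abundance columns
#'   (rows summing to 1), as produced by [simulate_cohort()].
#' @param library_size Nominal reads per sample.
#' @return Count tibble of the same shape.
#' @export
counts_from_relative <- function(rel, library_size = 10000) {
  stopifnot("sample_id" %in% names(rel))
  warn("rescaling relative abundances to pseudo-counts; richness estimates are approximate")
  feats <- setdiff(names(rel), "sample_id")
  out <- rel
  out[feats] <- round(rel[feats] * library_size)
  out
}

#' Two-group diversity comparison
#'
#' Two-sided Mann-Whitney U test between two groups of per-sample diversity
#' values (exact for small untied samples, normal approximation with tie
#' correction otherwise).
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return Tibble with `statistic` (the U statistic for `group_a` vs
#'   `group_b`), `p_value`, `method`.
#' @export
#' @examples
#' compare_diversity(c(120, 130, 125), c(60, 70, 65))
compare_diversity <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_input("each group needs at least 2 values")
  }
  ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = NULL))
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = ht$method
  )
}
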