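# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive each statistic from its definition and stay
# independent of the package code paths they check.

# two-sided Mann-Whitney p by exhaustive enumeration of all group labelings
oracle_mw_exact <- function(xa, xb) {
  pooled <- c(xa, xb)
  na <- length(xa)
  n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  null_u <- apply(utils::combn(n, na), 2, u_of)
  u_obs <- u_of(seq_len(na))
  min(1, 2 * min(mean(null_u <= u_obs), mean(null_u >= u_obs)))
}

# literal step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# literal bias-corrected Chao1
oracle_chao1 <- function(v) {
  v <- v[v > 0]
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  length(v) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# literal Chao & Lee ACE
oracle_ace <- function(v, cutoff = 10) {
  v <- v[v > 0]
  rare <- v[v <= cutoff]
  s_abund <- sum(v > cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  fi <- tabulate(rare, nbins = cutoff)
  i <- seq_len(cutoff)
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

oracle_shannon <- function(v) {
  p <- v[v > 0] / sum(v)
  -sum(p * log(p))
}

oracle_simpson_d <- function(v) {
  p <- v / sum(v)
  sum(p^2)
}

# Spearman rho for untied data from the classical d^2 formula
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact permutation p for Spearman via an enumeration independent of the
# package's recursive generator: filter permutations out of the index grid
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  rho_obs <- cor(rank(x), rank(y))
  ref <- apply(perms, 1, function(idx) cor(rank(x), rank(y)[idx]))
  mean(abs(ref) >= abs(rho_obs) - 1e-12)
}

# hand-build a typed network for census/persistence unit tests
toy_network <- function(edges, context = NA_character_) {
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(id = edges$a, node_class = edges$a_class),
    tibble::tibble(id = edges$b, node_class = edges$b_class)
  ))
  fmtrewire:::new_fmt_network(nodes, tibble::as_tibble(edges), context,
    NA_character_,
    params = list(rho_threshold = 0.6, alpha = 0.05, min_prevalence = 0.6,
      adjust = FALSE, include_clinical_clinical = FALSE, n_samples = 10L))
}

toy_edges <- function(a, a_class, b, b_class, rho) {
  tibble::tibble(
    a = a, a_class = a_class, b = b, b_class = b_class,
    rho = rho, p = 0.001, sign = ifelse(rho > 0, "positive", "negative")
  )
}

# small wide feature table from a matrix
wide_table <- function(m, ids = sprintf("S%02d", seq_len(nrow(m)))) {
  auto <- sprintf("f%02d", seq_len(ncol(m)))
  cn <- colnames(m) %||% auto
  cn[!nzchar(cn)] <- auto[!nzchar(cn)]
  colnames(m) <- cn
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}

`%||%` <- rlang::`%||%`
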