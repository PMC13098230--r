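#' Principal component analysis of a feature table
#'
#' Centred (and optionally unit-variance scaled) singular value
#' decomposition via [stats::prcomp()]. Loadings are orthonormal and scores
#' are the projections of the data onto them; the sign of each component is
#' fixed by forcing its largest-magnitude loading positive. Zero-variance
#' features are dropped (with a warning) under unit-variance scaling.
#'
#' @param table Tibble with `sample_id` plus feature columns.
#' @param scale Unit-variance scale the features.
#' @param n_components Number of components to retain (default
#'   `min(n - 1, p)`).
#' @return An `fmt_ordination` with `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance`
#'   (per-component proportion of total variance), `r2x`, `center`,
#'   `scale`, `method = "pca"`.
#' @export
run_pca <- function(table, scale = TRUE, n_components = NULL) {
  stopifnot("sample_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  if (nrow(m) < 2 || ncol(m) < 2) stop_input("need >= 2 samples and >= 2 features")
  if (scale) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      warn(paste("dropping zero-variance feature(s) under unit-variance scaling:",
        paste(colnames(m)[sds == 0], collapse = ", ")))
      m <- m[, sds > 0, drop = FALSE]
    }
  }
  max_comp <- min(nrow(m) - 1, ncol(m))
  n_components <- n_components %||% max_comp
  if (n_components > max_comp) {
    stop_input("`n_components` cannot exceed min(samples - 1, features)")
  }
  pc <- prcomp(m, center = TRUE, scale. = scale)
  total_var <- sum(pc$sdev^2)
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  structure(list(
    method = "pca",
    scores = scores,
    loadings = loadings,
    explained_variance = pc$sdev[k]^2 / total_var,
    sdev = pc$sdev[k],
    r2x = sum(pc$sdev[k]^2) / total_var,
    r2y = NA_real_, q2y = NA_real_, vip = NULL,
    center = pc$center,
    scale = if (scale) pc$scale else NULL,
    n_components = n_components
  ), class = "fmt_ordination")
}

#' PLS-DA with VIP scores and cross-validated Q2
#'
#' Partial least squares discriminant analysis of a two-class design:
#' NIPALS PLS1 regression of centred/scaled features against the 0/1-coded
#' class labels. Per-feature variable-importance-in-projection scores are
#' `VIP_j = sqrt(p * sum_k(w_jk^2 * SSY_k) / sum_k(SSY_k))` with `p` the
#' feature count, `w` the normalized component weights and `SSY_k` the
#' y-variance captured by component `k`; the mean squared VIP is therefore
#' exactly 1 for any fit, and features with `VIP > 0.9` (strict) are
#' flagged as discriminating. `Q2Y = 1 - PRESS/TSS` is estimated by
#' stratified k-fold cross-validation (default 7 folds, the common
#' chemometrics choice) with a fixed partition seed.
#'
#' @param table Tibble with `sample_id` plus feature columns.
#' @param labels Two-class factor/character vector, one entry per row of
#'   `table` (each class >= 3 samples).
#' @param n_components Number of latent components (default 2).
#' @param cv_folds Cross-validation folds for Q2.
#' @param cv_seed Seed fixing the CV partition.
#' @param scale Feature scaling: unit variance (`"uv"`, default),
#'   `"pareto"` (divide by sqrt of sd), or `"none"`.
#' @param vip_threshold Strict VIP cutoff for the `vip_selected` flag.
#' @return An `fmt_ordination` with scores, loadings, weights, `vip`,
#'   `vip_selected`, `r2x`, `r2y`, `q2y`, `explained_variance` (X-variance
#'   per component), `method = "plsda"`.
#' @export
run_plsda <- function(table, labels, n_components = 2, cv_folds = 7,
                      cv_seed = 1, scale = c("uv", "pareto", "none"),
                      vip_threshold = 0.9) {
  scale <- match.arg(scale)
  stopifnot("sample_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop_input("`labels` must contain exactly 2 classes")
  if (sum(labels == lev[1]) < 3 || sum(labels == lev[2]) < 3) {
    stop_input("each class needs >= 3 samples")
  }
  if (length(labels) != nrow(m)) stop_input("one label per sample required")
  y <- as.numeric(labels == lev[2])
  max_comp <- min(nrow(m) - 1, ncol(m))
  if (n_components > max_comp) {
    stop_input("`n_components` cannot exceed min(samples - 1, features)")
  }

  fit <- pls1_fit(m, y, n_components, scale)
  vip <- pls_vip(fit)

  # stratified k-fold CV for Q2, partition fixed by cv_seed
  n <- nrow(m)
  folds <- integer(n)
  withr::with_seed(cv_seed, {
    for (cl in lev) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
  })
  press <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit_f <- pls1_fit(m[!test, , drop = FALSE], y[!test], n_components, scale)
    press <- press + sum((y[test] - pls1_predict(fit_f, m[test, , drop = FALSE]))^2)
  }
  tss <- sum((y - mean(y))^2)
  q2y <- 1 - press / tss

  structure(list(
    method = "plsda",
    scores = fit$scores,
    loadings = fit$loadings,
    weights = fit$weights,
    explained_variance = fit$r2x_per_comp,
    r2x = sum(fit$r2x_per_comp),
    r2y = fit$r2y,
    q2y = q2y,
    vip = vip,
    vip_selected = vip > vip_threshold,
    vip_threshold = vip_threshold,
    labels = labels,
    levels = lev,
    n_components = n_components,
    cv_folds = cv_folds,
    cv_seed = cv_seed
  ), class = "fmt_ordination")
}

pls1_fit <- function(m, y, n_components, scale) {
  ctr <- colMeans(m)
  scl <- switch(scale,
    uv = apply(m, 2, sd),
    pareto = sqrt(apply(m, 2, sd)),
    none = rep(1, ncol(m))
  )
  scl[scl == 0] <- 1
  xk <- sweep(sweep(m, 2, ctr), 2, scl, `/`)
  ssx_total <- sum(xk^2)
  y_mean <- mean(y)
  yk <- y - y_mean
  ssy_total <- sum(yk^2)
  p_feat <- ncol(m)
  w_mat <- matrix(0, p_feat, n_components, dimnames = list(colnames(m), NULL))
  p_mat <- w_mat
  t_mat <- matrix(0, nrow(m), n_components, dimnames = list(rownames(m), NULL))
  q_vec <- numeric(n_components)
  ssy_k <- numeric(n_components)
  r2x_k <- numeric(n_components)
  for (k in seq_len(n_components)) {
    w <- crossprod(xk, yk)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tk <- drop(xk %*% w)
    tt <- sum(tk^2)
    pk <- drop(crossprod(xk, tk)) / tt
    qk <- sum(yk * tk) / tt
    w_mat[, k] <- w
    p_mat[, k] <- pk
    t_mat[, k] <- tk
    q_vec[k] <- qk
    ssy_k[k] <- qk^2 * tt
    r2x_k[k] <- tt * sum(pk^2) / ssx_total
    xk <- xk - tcrossprod(tk, pk)
    yk <- yk - qk * tk
  }
  colnames(t_mat) <- colnames(p_mat) <- colnames(w_mat) <-
    paste0("comp", seq_len(n_components))
  list(
    scores = t_mat, loadings = p_mat, weights = w_mat, q = q_vec,
    ssy_per_comp = ssy_k, r2y = sum(ssy_k) / ssy_total,
    r2x_per_comp = r2x_k, center = ctr, scale_vec = scl, y_mean = y_mean
  )
}

pls1_predict <- function(fit, m_new) {
  xn <- sweep(sweep(m_new, 2, fit$center), 2, fit$scale_vec, `/`)
  b <- fit$weights %*% solve(crossprod(fit$loadings, fit$weights), fit$q)
  drop(xn %*% b) + fit$y_mean
}

pls_vip <- function(fit) {
  ssy <- fit$ssy_per_comp
  w2 <- fit$weights^2
  p_feat <- nrow(w2)
  vip <- sqrt(p_feat * drop(w2 %*% ssy) / sum(ssy))
  setNames(vip, rownames(fit$weights))
}

#' @export
print.fmt_ordination <- function(x, ...) {
  cat(sprintf("<fmt_ordination> %s, %d component(s)\n", x$method, x$n_components))
  cat(sprintf("  R2X = %.3f", x$r2x))
  if (x$method == "plsda") {
    cat(sprintf(", R2Y = %.3f, Q2Y = %.3f, %d feature(s) with VIP > %.2g",
      x$r2y, x$q2y, sum(x$vip_selected), x$vip_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Tidy methods for ordination results
#'
#' `tidy()` returns a tibble of scores (default), loadings, per-component
#' explained variance, or VIP scores; `glance()` returns the one-row model
#' summary (R2X, R2Y, Q2Y, components).
#'
#' @param x An `fmt_ordination`.
#' @param matrix One of `"scores"`, `"loadings"`, `"variance"`, `"vip"`.
#' @param ... Unused.
#' @method tidy fmt_ordination
#' @export
tidy.fmt_ordination <- function(x, matrix = c("scores", "loadings", "variance", "vip"),
                                ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = {
      out <- as_tibble(x$scores, .name_repair = "minimal")
      out <- dplyr::bind_cols(tibble(sample_id = rownames(x$scores)), out)
      if (!is.null(x$labels)) out$label <- x$labels
      out
    },
    loadings = dplyr::bind_cols(
      tibble(feature = rownames(x$loadings)),
      as_tibble(x$loadings, .name_repair = "minimal")
    ),
    variance = tibble(
      component = seq_along(x$explained_variance),
      explained_variance = x$explained_variance
    ),
    vip = {
      if (is.null(x$vip)) stop_input("VIP scores exist only for PLS-DA fits")
      tibble(feature = names(x$vip), vip = unname(x$vip),
        selected = unname(x$vip_selected))
    }
  )
}

#' @rdname tidy.fmt_ordination
#' @method glance fmt_ordination
#' @export
glance.fmt_ordination <- function(x, ...) {
  tibble(
    method = x$method, n_components = x$n_components,
    r2x = x$r2x, r2y = x$r2y, q2y = x$q2y,
    n_vip_selected = if (is.null(x$vip)) NA_integer_ else sum(x$vip_selected)
  )
}
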