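#' Tie-aware Spearman correlation for one pair of variables
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (so ties
#' are handled), with a two-sided p-value from the t-approximation on
#' `n - 2` degrees of freedom, or from exact enumeration of all `n!` rank
#' permutations when `n <= 7`.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`; neither constant.
#' @return Tibble with `rho`, `p`, `n`, `method`.
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5)) # rho = 0.8
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_input("`x` and `y` must have equal length")
  if (n < 4) stop_input("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop_input("missing values are not supported")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_input("correlation undefined for a constant vector",
      class = "fmtrewire_constant_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7) {
    pm <- rank_permutations(n)
    ref <- apply(pm, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(ref) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- spearman_p_approx(rho, n)
    method <- "t approximation"
  }
  tibble(rho = rho, p = p, n = n, method = method)
}

spearman_p_approx <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tt <- abs(rho) * sqrt((n - 2) / (1 - r2))
  2 * pt(-tt, n - 2)
}

rank_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L))
  }
  sub <- rank_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

class_pair_label <- function(ca, cb) paste(pmin(ca, cb), pmax(ca, cb), sep = "-")

normalize_exclude <- function(exclude) {
  vapply(exclude, function(p) class_pair_label(p[1], p[2]), character(1))
}

#' Build a typed Spearman co-abundance network
#'
#' Tests all unordered pairs of features across (and within) the clinical,
#' taxon and metabolite layers on a shared sample set and keeps an edge
#' when `|rho| > rho_threshold` and `p < alpha` (the published edge rule;
#' edge p-values are not multiplicity-adjusted by default, `adjust = TRUE`
#' applies BH first). Taxa are prevalence-filtered (present in
#' `min_prevalence` of the network samples) before testing.
#' Clinical-clinical pairs are excluded by default because the markers are
#' mutually dependent by construction. Constant features are skipped with a
#' warning.
#'
#' @param tables Named list of feature tibbles (`sample_id` + features);
#'   names give the node class and must be among `"clinical"`, `"taxon"`,
#'   `"metabolite"`.
#' @param samples Sample ids to build on (default: samples shared by all
#'   tables); at least 4.
#' @param rho_threshold Absolute correlation threshold (edges strictly
#'   above it).
#' @param alpha Significance level for edge p-values.
#' @param min_prevalence Prevalence filter applied to the taxon layer.
#' @param include_clinical_clinical Also test clinical-clinical pairs.
#' @param adjust Apply BH adjustment across all tested pairs before the
#'   `alpha` rule.
#' @param context Label, conventionally `"baseline"` or `"post"`.
#' @param cohort Optional cohort tag.
#' @return An `fmt_network`: list with `nodes` (tibble `id`, `node_class`),
#'   `edges` (tibble `a`, `a_class`, `b`, `b_class`, `rho`, `p`, `sign`),
#'   `context`, `cohort`, `params`.
#' @export
build_network <- function(tables, samples = NULL, rho_threshold = 0.6,
                          alpha = 0.05, min_prevalence = 0.6,
                          include_clinical_clinical = FALSE, adjust = FALSE,
                          context = NA_character_, cohort = NA_character_) {
  stopifnot(is.list(tables), length(tables) >= 1)
  bad <- setdiff(names(tables), c("clinical", "taxon", "metabolite"))
  if (length(bad) || is.null(names(tables))) {
    stop_input("`tables` must be named with classes among clinical/taxon/metabolite")
  }
  if (is.null(samples)) {
    samples <- Reduce(intersect, lapply(tables, function(t) t$sample_id))
  }
  if (length(samples) < 4) stop_input("need at least 4 shared samples")

  cols <- list()
  classes <- character()
  for (cls in names(tables)) {
    tab <- tables[[cls]]
    missing_ids <- setdiff(samples, tab$sample_id)
    if (length(missing_ids)) {
      stop_input(paste0("samples absent from ", cls, " table: ",
        paste(missing_ids, collapse = ", ")))
    }
    tab <- tab[match(samples, tab$sample_id), ]
    if (cls == "taxon") tab <- prevalence_filter(tab, min_prevalence)
    feats <- setdiff(names(tab), "sample_id")
    m <- as.matrix(tab[feats])
    cols[[cls]] <- m
    classes <- c(classes, rep(cls, ncol(m)))
  }
  x <- do.call(cbind, unname(cols))
  node_ids <- colnames(x)
  if (anyDuplicated(node_ids)) stop_input("node ids must be unique across layers")

  keep <- apply(x, 2, function(v) length(unique(v)) > 1)
  if (any(!keep)) {
    warn(paste("skipping constant feature(s):",
      paste(node_ids[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  classes <- classes[keep]
  node_ids <- node_ids[keep]
  n <- nrow(x)
  p_feat <- ncol(x)

  nodes <- tibble(id = node_ids, node_class = classes)
  empty_edges <- tibble(a = character(), a_class = character(), b = character(),
    b_class = character(), rho = numeric(), p = numeric(), sign = character())
  params <- list(rho_threshold = rho_threshold, alpha = alpha,
    min_prevalence = min_prevalence, adjust = adjust,
    include_clinical_clinical = include_clinical_clinical, n_samples = n)
  if (p_feat < 2) {
    return(new_fmt_network(nodes, empty_edges, context, cohort, params))
  }

  rk <- apply(x, 2, rank)
  rho_m <- suppressWarnings(cor(rk))
  ij <- which(upper.tri(rho_m), arr.ind = TRUE)
  tested <- tibble(
    a = node_ids[ij[, 1]], b = node_ids[ij[, 2]],
    a_class = classes[ij[, 1]], b_class = classes[ij[, 2]],
    rho = rho_m[ij]
  )
  if (!include_clinical_clinical) {
    tested <- dplyr::filter(tested,
      !(.data$a_class == "clinical" & .data$b_class == "clinical"))
  }
  if (n <= 7) {
    tested$p <- purrr::map2_dbl(tested$a, tested$b, function(a, b) {
      spearman_cor(x[, a], x[, b])$p
    })
  } else {
    tested$p <- spearman_p_approx(tested$rho, n)
  }
  if (adjust) tested$p <- bh_adjust(tested$p)
  edges <- tested |>
    dplyr::filter(abs(.data$rho) > rho_threshold, .data$p < alpha) |>
    dplyr::mutate(sign = ifelse(.data$rho > 0, "positive", "negative")) |>
    dplyr::select("a", "a_class", "b", "b_class", "rho", "p", "sign")
  new_fmt_network(nodes, edges, context, cohort, params)
}

new_fmt_network <- function(nodes, edges, context, cohort, params) {
  structure(
    list(nodes = nodes, edges = as_tibble(edges), context = context,
      cohort = cohort, params = params),
    class = "fmt_network"
  )
}

#' @export
print.fmt_network <- function(x, ...) {
  cat(sprintf(
    "<fmt_network> %s%s: %d nodes, %d edges (|rho| > %.2g, p < %.2g, n = %d)\n",
    ifelse(is.na(x$cohort), "", paste0(x$cohort, " ")),
    ifelse(is.na(x$context), "network", x$context),
    nrow(x$nodes), nrow(x$edges),
    x$params$rho_threshold, x$params$alpha, x$params$n_samples
  ))
  invisible(x)
}

#' @method tidy fmt_network
#' @export
tidy.fmt_network <- function(x, ...) x$edges

#' @method glance fmt_network
#' @export
glance.fmt_network <- function(x, ...) {
  cc <- count_class_pairs(x)
  tibble(
    context = x$context, cohort = x$cohort, n_nodes = nrow(x$nodes),
    n_edges = cc$total, n_edges_after_exclusion = cc$total_after_exclusion,
    n_samples = x$params$n_samples
  )
}

#' Census of network edges by node-class pair
#'
#' Counts the edges of a typed network for every unordered class pair
#' (e.g. taxon-metabolite) and reports the total before and after removing
#' excluded class pairs (by default metabolite-metabolite, the convention
#' used when summarizing ternary host-microbe-metabolite networks).
#'
#' @param net An `fmt_network`.
#' @param exclude List of length-2 character vectors of class pairs to drop
#'   from `total_after_exclusion`.
#' @return List with `pairs` (tibble `class_pair`, `n`), `total`,
#'   `total_after_exclusion`.
#' @export
count_class_pairs <- function(net,
                              exclude = list(c("metabolite", "metabolite"))) {
  stopifnot(inherits(net, "fmt_network"))
  excl <- normalize_exclude(exclude)
  e <- net$edges
  if (nrow(e) == 0) {
    return(list(pairs = tibble(class_pair = character(), n = integer()),
      total = 0L, total_after_exclusion = 0L))
  }
  lab <- class_pair_label(e$a_class, e$b_class)
  pairs <- tibble(class_pair = lab) |>
    dplyr::count(.data$class_pair, name = "n")
  list(
    pairs = pairs,
    total = nrow(e),
    total_after_exclusion = sum(!lab %in% excl)
  )
}

#' Baseline-to-post edge persistence (network rewiring statistic)
#'
#' The fraction of baseline edges (after excluding the given class pairs,
#' by default metabolite-metabolite) whose unordered node pair appears
#' again in the post network -- with matching correlation sign unless
#' `require_sign_match = FALSE`. A fraction near zero means the baseline
#' correlation structure was dissolved ("rewired") by treatment. The
#' exclusion is applied symmetrically to both networks.
#'
#' @param net_baseline,net_post `fmt_network` objects built with identical
#'   thresholds.
#' @param require_sign_match Require the persisting edge to keep its sign.
#' @param exclude Class pairs excluded from both edge sets.
#' @return List with `fraction` (`NA` and a warning when the baseline edge
#'   set is empty after exclusion), `n_baseline`, `n_post`, and the edge
#'   tibbles `persisting`, `baseline_only`, `post_only`.
#' @export
edge_persistence <- function(net_baseline, net_post, require_sign_match = TRUE,
                             exclude = list(c("metabolite", "metabolite"))) {
  stopifnot(inherits(net_baseline, "fmt_network"), inherits(net_post, "fmt_network"))
  if (!identical(net_baseline$params$rho_threshold, net_post$params$rho_threshold) ||
    !identical(net_baseline$params$alpha, net_post$params$alpha)) {
    stop_input("networks must be built with identical thresholds")
  }
  excl <- normalize_exclude(exclude)
  strip <- function(e) {
    if (nrow(e) == 0) return(e)
    e[!class_pair_label(e$a_class, e$b_class) %in% excl, ]
  }
  eb <- strip(net_baseline$edges)
  ep <- strip(net_post$edges)
  key <- function(e) {
    if (nrow(e) == 0) return(character())
    k <- pair_key(e$a, e$b)
    if (require_sign_match) paste(k, e$sign) else k
  }
  kb <- key(eb)
  kp <- key(ep)
  persists <- kb %in% kp
  fraction <- if (nrow(eb) == 0) {
    warn("baseline edge set empty after exclusion; persistence fraction undefined")
    NA_real_
  } else {
    mean(persists)
  }
  list(
    fraction = fraction,
    n_baseline = nrow(eb),
    n_post = nrow(ep),
    persisting = eb[persists, ],
    baseline_only = eb[!persists, ],
    post_only = ep[!kp %in% kb, ]
  )
}

#' Convert a typed network to an igraph object
#'
#' @param net An `fmt_network`.
#' @return An undirected [igraph::graph] with a `node_class` vertex
#'   attribute and `rho`, `p`, `sign` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "fmt_network"))
  g <- igraph::graph_from_data_frame(
    d = net$edges[c("a", "b", "rho", "p", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, node_class = net$nodes$node_class)
  )
  igraph::set_graph_attr(g, "context", as.character(net$context %||% NA)) |>
    igraph::set_graph_attr("cohort", as.character(net$cohort %||% NA))
}

#' Export / import typed networks
#'
#' `export_network()` writes GraphML (loadable by Cytoscape and standard
#' graph libraries) or an edge-list TSV with columns
#' `a, a_class, b, b_class, rho, p, sign`. `read_network()` reads either
#' format back into an `fmt_network` (for the TSV format, isolated nodes
#' are not recoverable).
#'
#' @param net An `fmt_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist-tsv"`.
#' @return `path`, invisibly (`read_network()` returns an `fmt_network`).
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("graphml", "edgelist-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      id = igraph::vertex_attr(g, "name"),
      node_class = igraph::vertex_attr(g, "node_class")
    )
    ed <- igraph::as_data_frame(g, what = "edges")
    cls <- setNames(nodes$node_class, nodes$id)
    edges <- tibble(
      a = ed$from, a_class = unname(cls[ed$from]),
      b = ed$to, b_class = unname(cls[ed$to]),
      rho = ed$rho %||% numeric(nrow(ed)),
      p = ed$p %||% numeric(nrow(ed)),
      sign = ed$sign %||% character(nrow(ed))
    )
    context <- igraph::graph_attr(g, "context") %||% NA_character_
    cohort <- igraph::graph_attr(g, "cohort") %||% NA_character_
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE,
      col_types = readr::cols(rho = "d", p = "d", .default = "c"))
    nodes <- dplyr::bind_rows(
      tibble(id = edges$a, node_class = edges$a_class),
      tibble(id = edges$b, node_class = edges$b_class)
    ) |> dplyr::distinct()
    context <- NA_character_
    cohort <- NA_character_
  }
  new_fmt_network(nodes, as_tibble(edges), context, cohort,
    params = list(rho_threshold = NA_real_, alpha = NA_real_,
      min_prevalence = NA_real_, adjust = NA, include_clinical_clinical = NA,
      n_samples = NA_integer_))
}
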