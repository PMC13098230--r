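test_that("spearman_cor reproduces the classical formula and limits", {
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8) # 1 - 6*4/(5*24)
  expect_equal(res$rho, oracle_spearman_rho(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1) # monotone transform
  expect_equal(spearman_cor(1:8, rev(1:8))$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "fmtrewire_constant_error")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("exact permutation p-values match an independent enumeration", {
  set.seed(5)
  x <- c(0.3, 1.9, 0.7, 2.5, 1.1)
  y <- c(1.2, 0.4, 2.2, 1.7, 0.1)
  res <- spearman_cor(x, y)
  expect_equal(res$method, "exact permutation")
  expect_equal(res$p, oracle_spearman_exact_p(x, y))
})

test_that("large-n p matches the t-approximation used by cor.test", {
  set.seed(6)
  x <- rnorm(20)
  y <- x + rnorm(20)
  res <- spearman_cor(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
})

test_that("network construction keeps planted monotone pairs and little else", {
  set.seed(8)
  n <- 10
  a <- rnorm(n)
  m <- cbind(a = a, b = exp(2 * a), noise1 = rnorm(n), noise2 = rnorm(n))
  net <- build_network(list(metabolite = wide_table(m)))
  expect_true("a|b" %in% fmtrewire:::pair_key(net$edges$a, net$edges$b))
  planted_edge <- net$edges[fmtrewire:::pair_key(net$edges$a, net$edges$b) == "a|b", ]
  expect_equal(planted_edge$rho, 1)
  expect_equal(planted_edge$sign, "positive")

  # independent noise: edge count stays near zero at n = 30
  few <- vapply(1:10, function(seed) {
    set.seed(seed)
    noise <- matrix(rnorm(30 * 20), 30)
    nrow(build_network(list(metabolite = wide_table(noise)))$edges)
  }, numeric(1))
  expect_gte(mean(few <= 2), 0.9)
})

test_that("network construction is rank-invariant and order-invariant", {
  set.seed(9)
  m <- matrix(rnorm(12 * 6), 12)
  m[, 2] <- m[, 1] * 2 + rnorm(12, sd = 0.1)
  tab <- wide_table(m)
  net <- build_network(list(metabolite = tab))
  # strictly monotone transform of a single feature changes nothing
  tab2 <- tab
  tab2$f03 <- exp(tab2$f03)
  net2 <- build_network(list(metabolite = tab2))
  expect_equal(net2$edges, net$edges)
  # sample order invariance
  tab3 <- tab[sample(nrow(tab)), ]
  net3 <- build_network(list(metabolite = tab3), samples = tab$sample_id)
  expect_equal(net3$edges, net$edges)
})

test_that("network construction validates inputs", {
  m <- matrix(rnorm(9), 3)
  expect_error(build_network(list(metabolite = wide_table(m))), "4 shared samples")
  expect_error(build_network(list(wide_table(matrix(rnorm(40), 10)))), "named")
  const <- wide_table(cbind(x = rep(1, 10), y = rnorm(10), z = rnorm(10)))
  expect_warning(net <- build_network(list(metabolite = const)), "constant")
  expect_false("x" %in% net$nodes$id)
})

test_that("clinical-clinical pairs are excluded unless requested", {
  set.seed(10)
  z <- rnorm(12)
  clin <- wide_table(cbind(crp = z, calprotectin = z + rnorm(12, sd = 0.05)))
  net <- build_network(list(clinical = clin))
  expect_equal(nrow(net$edges), 0)
  net_in <- build_network(list(clinical = clin), include_clinical_clinical = TRUE)
  expect_equal(nrow(net_in$edges), 1)
})

test_that("class-pair census counts and exclusion arithmetic", {
  e <- dplyr::bind_rows(
    toy_edges(paste0("m", 1:3), "metabolite", paste0("n", 1:3), "metabolite", c(0.7, 0.8, -0.9)),
    toy_edges(paste0("t", 1:2), "taxon", paste0("m", 1:2), "metabolite", c(0.65, -0.7))
  )
  net <- toy_network(e)
  cc <- count_class_pairs(net)
  expect_equal(cc$total, 5)
  expect_equal(cc$total_after_exclusion, 2)
  expect_equal(cc$pairs$n[cc$pairs$class_pair == "metabolite-metabolite"], 3)
  expect_equal(count_class_pairs(net, exclude = list())$total_after_exclusion, 5)
  empty <- toy_network(toy_edges(character(), character(), character(), character(), numeric()))
  expect_equal(count_class_pairs(empty)$total, 0)
})

test_that("edge persistence hits exact bounds in the trivial cases", {
  e1 <- toy_edges(c("t1", "t2", "crp"), c("taxon", "taxon", "clinical"),
    c("m1", "m2", "t3"), c("metabolite", "metabolite", "taxon"),
    c(0.7, -0.8, 0.9))
  net_b <- toy_network(e1, "baseline")
  expect_equal(edge_persistence(net_b, net_b)$fraction, 1.0)
  e2 <- toy_edges("t9", "taxon", "m9", "metabolite", 0.99)
  expect_equal(edge_persistence(net_b, toy_network(e2, "post"))$fraction, 0.0)
  # sign matching
  flipped <- e1
  flipped$rho <- -flipped$rho
  flipped$sign <- ifelse(flipped$rho > 0, "positive", "negative")
  expect_equal(edge_persistence(net_b, toy_network(flipped))$fraction, 0.0)
  expect_equal(
    edge_persistence(net_b, toy_network(flipped), require_sign_match = FALSE)$fraction,
    1.0
  )
  # metabolite-metabolite edges are excluded from both sides
  mm <- toy_edges("m1", "metabolite", "m2", "metabolite", 0.9)
  expect_warning(res <- edge_persistence(toy_network(mm), net_b), "undefined")
  expect_true(is.na(res$fraction))
})

test_that("persistence fraction stays in [0,1] and partitions the edges", {
  co <- simulate_cohort(synth_config(n_patients = 12, seed = 31))
  meta <- co$metadata
  tabs <- list(clinical = clinical_markers(meta), taxon = co$taxa,
    metabolite = co$metabolites)
  nb <- build_network(tabs, samples = meta$sample_id[meta$timepoint %in% "baseline"])
  np <- build_network(tabs, samples = meta$sample_id[meta$timepoint %in% "post"])
  res <- edge_persistence(nb, np)
  expect_gte(res$fraction, 0)
  expect_lte(res$fraction, 1)
  expect_equal(nrow(res$persisting) + nrow(res$baseline_only), res$n_baseline)
})

test_that("post networks expand when more post edges are planted", {
  expanded <- vapply(1:6, function(seed) {
    cfg <- synth_config(n_patients = 30, n_taxa = 20, n_metabolites = 20,
      n_response_taxa = 0, n_response_metabolites = 0, effect_size = 0,
      n_planted_edges_baseline = 4, n_planted_edges_post = 12,
      planted_persistence_fraction = 0, seed = seed)
    co <- simulate_cohort(cfg)
    meta <- co$metadata
    tabs <- list(clinical = clinical_markers(meta), taxon = co$taxa,
      metabolite = co$metabolites)
    nb <- build_network(tabs, samples = meta$sample_id[meta$timepoint %in% "baseline"])
    np <- build_network(tabs, samples = meta$sample_id[meta$timepoint %in% "post"])
    count_class_pairs(np)$total_after_exclusion -
      count_class_pairs(nb)$total_after_exclusion
  }, numeric(1))
  expect_true(all(expanded > 0))
})

test_that("exported networks round-trip through both formats", {
  e <- toy_edges(c("t1", "crp"), c("taxon", "clinical"), c("m1", "t2"),
    c("metabolite", "taxon"), c(0.72, -0.81))
  net <- toy_network(e, "baseline")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, format = "edgelist-tsv")
  back <- read_network(tsv, format = "edgelist-tsv")
  expect_equal(count_class_pairs(back), count_class_pairs(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  g <- read_network(gml, format = "graphml")
  expect_setequal(g$nodes$id, net$nodes$id)
  expect_equal(
    dplyr::arrange(g$edges, a)[c("a", "b", "rho", "sign")],
    dplyr::arrange(net$edges, a)[c("a", "b", "rho", "sign")]
  )

  empty <- toy_network(e[0, ])
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, f, format = "edgelist-tsv")
  expect_equal(nrow(read_network(f, format = "edgelist-tsv")$edges), 0)
  expect_error(export_network(net, tsv, format = "dot"))
})
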