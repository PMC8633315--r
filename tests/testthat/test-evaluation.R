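test_that("neighbor prediction averages rows and is convex per component", {
  ref <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  1, 0, 0,
                  0.5, 0.5, 0), 4, 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c", "d"), c("t1", "t2", "t3")))
  nn <- knn_exact(ref, 3)
  # a and c are duplicates: k = 1 prediction reproduces the row exactly
  pred_a <- predict_from_neighbors("a", nn, 1, ref)
  expect_equal(unname(pred_a), unname(ref["a", ]))
  expect_equal(l2_error(ref["a", ], pred_a), 0)
  # hand-checked average of two neighbor rows
  pred_b2 <- predict_from_neighbors("b", nn, 2, ref)
  two <- nn$nn_ids["b", 1:2]
  expect_equal(unname(pred_b2), unname((ref[two[1], ] + ref[two[2], ]) / 2))
  # convexity
  for (e in rownames(ref)) {
    p3 <- predict_from_neighbors(e, nn, 3, ref)
    rows <- ref[nn$nn_ids[e, ], ]
    expect_true(all(p3 >= apply(rows, 2, min) - 1e-12))
    expect_true(all(p3 <= apply(rows, 2, max) + 1e-12))
  }
  expect_warning(predict_from_neighbors("a", nn, 10, ref), "clipped")
})

test_that("l2 error matches direct recomputation", {
  expect_identical(l2_error(c(1, 2), c(1, 2)), 0)
  expect_equal(l2_error(c(1, 0), c(0, 1)), sqrt(2))
  set.seed(20)
  u <- rnorm(50); v <- rnorm(50)
  expect_equal(l2_error(u, v), sqrt(sum((u - v)^2)), tolerance = 1e-12)
  expect_error(l2_error(1:3, 1:4), "mismatch")
})

test_that("k calibration finds zero error on degenerate and clustered cohorts", {
  ref <- matrix(0.5, 8, 4, dimnames = list(paste0("e", 1:8), NULL))
  nn <- knn_exact(ref, 7)
  rep0 <- calibrate_k(ref, list(orig = nn), k_grid = 1:5)
  expect_true(all(rep0$mean_error == 0))
  expect_identical(unname(rep0$optimal_k["orig"]), 1L)

  # 5 planted groups of 6 identical rows plus noise rows: averaging within
  # a pure cluster is error-free up to k = 5
  set.seed(21)
  centers <- matrix(runif(5 * 20), 5, 20)
  x <- centers[rep(1:5, each = 6), ]
  x <- rbind(x, matrix(runif(10 * 20, max = 2), 10, 20))
  rownames(x) <- sprintf("e%02d", 1:40)
  nnx <- knn_exact(x, 12)
  repx <- calibrate_k(x, list(orig = nnx), k_grid = 1:10)
  expect_lte(unname(repx$optimal_k["orig"]), 5L)
  # the 30 clustered entities are error-free for every k up to 5
  clustered <- sprintf("e%02d", 1:30)
  expect_true(all(repx$per_entity_error[1, clustered, 1:5] < 1e-12))
  expect_error(calibrate_k(ref, list(orig = nn), k_grid = integer(0)),
               "non-empty")
})

test_that("error strata report box-and-whisker quantiles per bin", {
  s <- stratify_errors(c(0, 1, 2, 3, 4), rep(3, 5), bin_edges = c(0, 5, 10))
  expect_identical(s$q50[1], 2)
  expect_identical(s$n, c(5L, 0L))
  expect_true(is.na(s$q50[2]))
  set.seed(22)
  e <- rexp(200); cnt <- sample(1:30, 200, replace = TRUE)
  s2 <- stratify_errors(e, cnt, bin_edges = c(0, 10, 20, 30))
  sel <- cnt <= 10
  expect_equal(s2$q25[1], unname(quantile(e[sel], 0.25)))
  expect_equal(s2$q95[1], unname(quantile(e[sel], 0.95)))
})

test_that("region enrichment matches exact tables and flags planted signal", {
  ont <- parse_obo(paste("[Term]", "id: T:1", "name: root", sep = "\n"))
  mk <- function(id, annotated) {
    phenotype_profile(id, terms = if (annotated) "T:1" else character(0))
  }
  # table (3,7,10,80)
  cohort <- c(lapply(1:3, function(i) mk(sprintf("in%02d", i), TRUE)),
              lapply(4:10, function(i) mk(sprintf("in%02d", i), FALSE)),
              lapply(1:10, function(i) mk(sprintf("out%02d", i), TRUE)),
              lapply(11:90, function(i) mk(sprintf("out%02d", i), FALSE)))
  res <- fisher_enrichment(sprintf("in%02d", 1:10), cohort, ont)
  expect_identical(c(res$a, res$b, res$c, res$d), c(3L, 7L, 10L, 80L))
  expect_equal(res$p_value, oracle_fisher_p(3, 7, 10, 80),
               tolerance = 1e-10)
  # no association: identical proportions give p = 1
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_error(fisher_enrichment(character(0), cohort, ont), "non-empty")
  all_ids <- vapply(cohort, function(p) p$entity_id, "")
  expect_error(fisher_enrichment(all_ids, cohort, ont), "proper subset")

  # a region made of one gene's models is enriched for its signature
  cfg <- synthetic_config(seed = 23, n_terms = 150, n_genes = 12,
                          multiplicity_exponent = 0.5,
                          multiplicity_max = 12)
  syn <- generate_ontology(cfg)
  coh <- generate_cohort(syn, cfg)
  markers <- vapply(coh, function(p) p$marker_id, "")
  g <- names(which.max(table(markers)))
  region <- names(coh)[markers == g]
  res2 <- fisher_enrichment(region, coh, syn)
  sig <- attr(coh, "signatures")[[g]]
  expect_true(any(res2$significant[res2$term_id %in% sig]))
})

test_that("gene recovery scores exact matches and planted signal", {
  models <- lapply(1:6, function(i) {
    phenotype_profile(sprintf("m%d", i), terms = "T:1", kind = "model",
                      marker_id = sprintf("G%d", i))
  })
  disease <- phenotype_profile("d1", terms = "T:1", kind = "disease",
                               causal_genes = "G4")
  ranked <- list(d1 = c("m4", "m1", "m2"))
  rec <- gene_recovery_at_k(list(disease), models, ranked, k = 1)
  expect_identical(rec$proportion, 1)
  miss <- gene_recovery_at_k(list(disease),
                             models, list(d1 = c("m1", "m2")), k = 2)
  expect_identical(miss$proportion, 0)
  expect_error(gene_recovery_at_k(
    list(phenotype_profile("d2", kind = "disease")), models, ranked),
    "no evaluable")
})

test_that("random neighbor assignment recovers at the analytic k/N rate", {
  # N models, exactly one causal model per disease, k random neighbors:
  # hit probability k/N
  set.seed(24)
  N <- 40; k <- 5; n_dis <- 600
  models <- lapply(1:N, function(i) {
    phenotype_profile(sprintf("m%02d", i), terms = "T:1", kind = "model",
                      marker_id = sprintf("G%02d", i))
  })
  diseases <- lapply(1:n_dis, function(i) {
    phenotype_profile(sprintf("d%03d", i), terms = "T:1", kind = "disease",
                      causal_genes = sprintf("G%02d", sample(N, 1)))
  })
  ranked <- setNames(lapply(1:n_dis, function(i) {
    sprintf("m%02d", sample(N))
  }), sprintf("d%03d", 1:n_dis))
  rec <- gene_recovery_at_k(diseases, models, ranked, k = k)
  p <- k / N
  se <- sqrt(p * (1 - p) / n_dis)
  expect_lt(abs(rec$proportion - p), 3 * se)
})

test_that("same-gene neighbor statistics use the closed-form null", {
  expect_equal(same_gene_null(10, 2, 3), 1 / 3)
  expect_equal(same_gene_null(10, 2, 3),
               1 - choose(8, 3) / choose(9, 3))
  # m = 1 models are excluded from evaluation
  models <- c(
    lapply(1:2, function(i) phenotype_profile(
      sprintf("a%d", i), terms = "T:1", kind = "model", marker_id = "GA")),
    list(phenotype_profile("solo", terms = "T:1", kind = "model",
                           marker_id = "GS")))
  x <- matrix(c(0, 0.1, 5, 0, 0, 5), 3, 2,
              dimnames = list(c("a1", "a2", "solo"), NULL))
  nn <- knn_exact(x, 2)
  sg <- same_gene_neighbor_fraction(models, nn, k = 1)
  expect_identical(sg$overall$n, 2L)     # solo excluded
  expect_identical(sg$overall$observed, 1)
  singles <- lapply(1:5, function(i) phenotype_profile(
    sprintf("s%d", i), terms = "T:1", kind = "model",
    marker_id = sprintf("G%d", i)))
  expect_error(same_gene_neighbor_fraction(
    singles, knn_exact(matrix(rnorm(10), 5, 2,
                              dimnames = list(sprintf("s%d", 1:5), NULL)),
                       2), k = 2), "multiplicity")
})

test_that("per-gene clusters exceed the random-neighbor null in every bin", {
  cfg <- synthetic_config(seed = 25, n_terms = 200, n_genes = 40,
                          noise_rate = 0.5)
  syn <- generate_ontology(cfg)
  coh <- generate_cohort(syn, cfg)
  pri <- term_priors(syn, coh)
  coh_f <- filter_cohort(coh)
  m <- encode_cohort(coh_f, syn, pri)
  nn <- knn_exact(m, 15)
  sg <- same_gene_neighbor_fraction(coh_f, nn, k = 15)
  occupied <- sg$by_bin$n > 0
  expect_true(all(sg$by_bin$observed[occupied] >=
                    sg$by_bin$null[occupied]))
  expect_gt(sg$overall$observed, sg$overall$null)
})

test_that("center bias is detected when present and absent when not", {
  set.seed(26)
  coords <- matrix(rnorm(600), 300, 2)
  expect_warning(cb <- center_bias(coords, rep(5, 300)), "undefined")
  expect_true(is.na(cb$rho))
  # counts independent of positions: small correlation, mostly insignificant
  rhos <- vapply(1:5, function(s) {
    set.seed(100 + s)
    center_bias(matrix(rnorm(600), 300, 2),
                sample(1:50, 300, replace = TRUE))$p_value
  }, numeric(1))
  expect_gte(sum(rhos > 0.05), 3)
})

test_that("neighbor Jaccard matches hand enumeration on a swapped pair", {
  mk_emb <- function(coords) {
    structure(list(ids = rownames(coords), coords = coords,
                   d = ncol(coords), method = "linear",
                   seed = NA_integer_, params = list()),
              class = "embedding")
  }
  A <- matrix(c(0, 1, 2, 3, 0, 0, 0, 0), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  B <- matrix(c(0, 1, 3, 2, 0, 0, 0, 0), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_identical(neighbor_jaccard(mk_emb(A), mk_emb(A), k = 2)$mean, 1)
  j <- neighbor_jaccard(mk_emb(A), mk_emb(B), k = 2)
  expect_equal(unname(j$per_entity[c("a", "b", "c", "d")]),
               c(1 / 3, 1 / 3, 1, 1))
  expect_equal(j$mean, 2 / 3)
  bad <- mk_emb(A[1:3, ])
  expect_error(neighbor_jaccard(mk_emb(A), bad, 2), "differ")
})
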