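# mean silhouette oracle over true labels
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  mean(vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

test_that("nonlinear embedding is deterministic given the seed", {
  set.seed(10)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(paste0("e", 1:60), NULL))
  nn <- knn_exact(x, 10)
  e1 <- embed_nonlinear(nn, d = 2, seed = 99)
  e2 <- embed_nonlinear(nn, d = 2, seed = 99)
  expect_identical(e1$coords, e2$coords)
  e3 <- embed_nonlinear(nn, d = 2, seed = 100)
  expect_false(identical(e1$coords, e3$coords))
  expect_identical(dim(e1$coords), c(60L, 2L))
  expect_true(all(is.finite(e1$coords)))
  expect_error(embed_nonlinear(nn, d = 1), "at least 2")
})

test_that("well-separated planted clusters stay separated in 2-d", {
  set.seed(11)
  n_per <- 60
  x <- rbind(matrix(rnorm(n_per * 50), n_per, 50),
             matrix(rnorm(n_per * 50, mean = 10), n_per, 50))
  rownames(x) <- sprintf("e%03d", seq_len(2 * n_per))
  labels <- rep(c(1, 2), each = n_per)
  emb <- embed_nonlinear(knn_exact(x, 15), d = 2, seed = 1)
  expect_gt(mean_silhouette(emb$coords, labels), 0)
})

test_that("linear embedding preserves exact linear structure", {
  # points on a line in 3-d: 1-d projection reproduces distances exactly
  t <- c(0, 1, 3, 7)
  x <- cbind(2 * t, -t, t) / sqrt(6)
  rownames(x) <- paste0("p", 1:4)
  e1 <- embed_linear(x, d = 1)
  expect_equal(as.matrix(dist(e1$coords)), as.matrix(dist(x)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # full-rank projection is an isometry of the centered data
  set.seed(12)
  y <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(paste0("e", 1:20), NULL))
  ef <- embed_linear(y, d = 6)
  expect_equal(as.matrix(dist(ef$coords)), as.matrix(dist(y)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated rows embed identically; sign convention is deterministic
  y2 <- rbind(y, dup = y[1, ])
  ed <- embed_linear(y2, d = 3)
  expect_equal(ed$coords["dup", ], ed$coords["e1", ], ignore_attr = TRUE)
  expect_identical(embed_linear(y, 3)$coords, embed_linear(y, 3)$coords)
  expect_error(embed_linear(y, d = 10), "rank")
})

test_that("coordinate averaging is linear and shrinks toward the centroid", {
  set.seed(13)
  coords <- matrix(rnorm(400), 200, 2,
                   dimnames = list(sprintf("T:%03d", 1:200), NULL))
  emb <- structure(list(ids = rownames(coords), coords = coords, d = 2,
                        method = "term-average", seed = NA_integer_,
                        params = list()), class = "embedding")
  expect_equal(project_terms_average(emb, "T:005"),
               coords["T:005", ], ignore_attr = TRUE)
  expect_equal(project_terms_average(emb, c("T:001", "T:002")),
               (coords["T:001", ] + coords["T:002", ]) / 2,
               ignore_attr = TRUE)
  # centroid linearity: average of singles equals set projection
  s <- c("T:010", "T:020", "T:030")
  singles <- t(vapply(s, function(t) project_terms_average(emb, t),
                      numeric(2)))
  expect_equal(project_terms_average(emb, s), colMeans(singles),
               ignore_attr = TRUE)
  expect_error(project_terms_average(emb, character(0)), "non-empty")
  expect_error(project_terms_average(emb, "T:999"), "not in embedding")

  centroid <- colMeans(coords)
  mean_dist <- vapply(c(1, 5, 25), function(n) {
    mean(vapply(1:100, function(r) {
      p <- project_terms_average(emb, sample(rownames(coords), n))
      sqrt(sum((p - centroid)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dist) < 0))   # 1/sqrt(n) shrink
})

test_that("disease placement averages nearest models or takes the top text hit", {
  set.seed(14)
  coords <- matrix(rnorm(20), 10, 2,
                   dimnames = list(sprintf("m%02d", 1:10), NULL))
  emb <- structure(list(ids = rownames(coords), coords = coords, d = 2,
                        method = "nonlinear", seed = 1L, params = list()),
                   class = "embedding")
  expect_equal(project_disease_vector(emb, c("m03", "m07"), k = 1),
               coords["m03", ], ignore_attr = TRUE)
  expect_equal(project_disease_vector(emb, c("m03", "m07"), k = 2),
               (coords["m03", ] + coords["m07", ]) / 2, ignore_attr = TRUE)
  expect_error(project_disease_vector(emb, character(0), 1), "no neighbors")

  docs <- c(m01 = "glycogen storage abnormality",
            m02 = "startle reflex absent",
            m03 = "kidney cysts bilateral")
  w <- build_weights(docs, 4)
  bags <- lapply(docs, kmerize, k = 4)
  hit <- project_disease_text(kmerize("bilateral kidney cysts", 4), bags,
                              w, emb)
  expect_equal(hit, coords["m03", ], ignore_attr = TRUE)
  expect_warning(
    none <- project_disease_text(kmerize("zzzz", 4), bags, w, emb),
    "no model")
  expect_true(all(is.na(none)))
})

test_that("embedding TSV round-trips coordinates and metadata", {
  set.seed(15)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("e", 1:20), NULL))
  emb <- embed_nonlinear(knn_exact(x, 5), d = 2, seed = 3, min_dist = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_tsv(emb, path)
  back <- read_embedding_tsv(path)
  expect_identical(back$ids, emb$ids)
  expect_equal(back$coords, emb$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$method, "nonlinear")
  expect_identical(back$seed, 3L)
  expect_equal(back$params$min_dist, 0.2)
})
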