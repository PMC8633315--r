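# Low-dimensional embeddings of encoded cohorts: a nonlinear neighbor-graph
# manifold layout (UMAP-family algorithm operating on precomputed exact
# neighbors, which removes neighbor-search stochasticity) and linear PCA.

new_embedding <- function(ids, coords, method, seed = NA_integer_,
                          params = list()) {
  rownames(coords) <- ids
  structure(list(ids = ids, coords = coords, d = ncol(coords),
                 method = method, seed = seed, params = params),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", length(x$ids), "entities in", x$d, "dimensions,",
      "method =", x$method)
  if (!is.na(x$seed)) cat(", seed =", x$seed)
  cat("\n")
  invisible(x)
}

# fit the low-dimensional similarity kernel 1/(1 + a x^(2b)) to the
# piecewise target curve implied by min_dist and spread
fit_ab <- function(min_dist, spread = 1) {
  x <- seq(1e-3, 3 * spread, length.out = 300)
  y <- ifelse(x < min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- nls(y ~ 1 / (1 + a * x^(2 * b)),
             start = list(a = 1.577, b = 0.8951),
             control = list(maxiter = 200, warnOnly = TRUE))
  as.list(coef(fit))
}

# per-entity smooth-neighbor calibration: local connectivity offset rho
# (distance to the nearest neighbor) and bandwidth sigma chosen by binary
# search so that the membership sum matches log2(k)
smooth_knn_weights <- function(nn_dist) {
  k <- ncol(nn_dist)
  target <- log2(k)
  w <- matrix(0, nrow(nn_dist), k)
  for (i in seq_len(nrow(nn_dist))) {
    d <- nn_dist[i, ]
    pos <- d[d > 0]
    rho <- if (length(pos)) min(pos) else 0
    lo <- 0; hi <- Inf; sigma <- 1
    for (iter in 1:64) {
      s <- sum(exp(-pmax(d - rho, 0) / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) {
        hi <- sigma
        sigma <- (lo + hi) / 2
      } else {
        lo <- sigma
        sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2
      }
    }
    w[i, ] <- exp(-pmax(d - rho, 0) / sigma)
  }
  w
}

# symmetrized fuzzy neighbor graph as a sparse matrix (probabilistic t-conorm)
fuzzy_graph <- function(nn) {
  n <- length(nn$ids)
  w <- smooth_knn_weights(nn$nn_dist)
  j <- match(as.vector(nn$nn_ids), nn$ids)
  i <- rep(seq_len(n), times = nn$k)
  A <- Matrix::sparseMatrix(i = i, j = j, x = as.vector(w),
                            dims = c(n, n))
  P <- A + Matrix::t(A) - A * Matrix::t(A)
  P
}

#' Nonlinear embedding of a precomputed neighbor graph
#'
#' UMAP-family manifold layout: the exact neighbor lists are converted to
#' a fuzzy graph with per-entity bandwidth calibration, symmetrized, and
#' laid out in `d` dimensions by stochastic gradient descent on the fuzzy
#' cross-entropy (attraction along edges, repulsion by negative sampling).
#' Initialization is spectral (normalized-Laplacian eigenvectors of the
#' fuzzy graph) with small seeded jitter. Because neighbors are
#' precomputed and the optimizer uses its own seeded integer RNG, the
#' same inputs and seed give bit-identical coordinates.
#'
#' @param nn a `neighbor_index` (self-excluded) from [knn_exact()] or
#'   [knn_text()].
#' @param d target dimension, at least 2.
#' @param seed integer seed for the layout RNG and jitter.
#' @param min_dist minimum spacing parameter of the low-dimensional
#'   kernel; larger values spread points apart (default 0.2, chosen for
#'   readable scatter layouts).
#' @param n_epochs optimization epochs.
#' @param spread scale of the low-dimensional kernel.
#' @param negative_sample_rate repulsive samples per attractive update.
#' @return An `embedding` with method `"nonlinear"` and all parameters
#'   recorded.
#' @export
embed_nonlinear <- function(nn, d = 2, seed = 1, min_dist = 0.2,
                            n_epochs = 300, spread = 1,
                            negative_sample_rate = 5) {
  if (d < 2) stop("d must be at least 2")
  n <- length(nn$ids)
  P <- fuzzy_graph(nn)
  ab <- fit_ab(min_dist, spread)

  # spectral initialization on the normalized Laplacian, seeded jitter
  deg <- Matrix::rowSums(P)
  deg[deg == 0] <- 1
  Dhalf <- Matrix::Diagonal(x = 1 / sqrt(deg))
  L <- Matrix::Diagonal(n) - Dhalf %*% P %*% Dhalf
  ev <- eigen(as.matrix(Matrix::forceSymmetric(L)), symmetric = TRUE)
  take <- order(ev$values)[seq(2, min(d + 1, n))]
  init <- ev$vectors[, take, drop = FALSE]
  if (ncol(init) < d) {
    init <- cbind(init, matrix(0, n, d - ncol(init)))
  }
  scale <- max(abs(init))
  if (scale > 0) init <- init / scale * 10
  init <- init + with_seed(seed, matrix(rnorm(n * d, sd = 1e-4), n, d))

  # edge sampling schedule proportional to fuzzy weights
  Pt <- methods::as(methods::as(P, "generalMatrix"), "TsparseMatrix")
  keep <- Pt@x > max(Pt@x) / n_epochs
  head <- Pt@i[keep]
  tail <- Pt@j[keep]
  wts <- Pt@x[keep]
  eps <- max(wts) / wts

  coords <- optimize_layout(init, head, tail, eps, ab$a, ab$b,
                            as.integer(n_epochs), 1.0,
                            negative_sample_rate, as.integer(seed))
  new_embedding(nn$ids, coords, "nonlinear", seed,
                list(min_dist = min_dist, spread = spread, a = ab$a,
                     b = ab$b, n_epochs = n_epochs,
                     n_neighbors = nn$k,
                     negative_sample_rate = negative_sample_rate))
}

#' Linear (PCA) embedding of an encoded matrix
#'
#' Projects the row-centered matrix onto its top `d` principal axes.
#' Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results are fully
#' deterministic.
#'
#' @param m numeric matrix with entity rownames.
#' @param d target dimension, at most `min(N, #columns)`.
#' @return An `embedding` with method `"linear"`.
#' @export
embed_linear <- function(m, d = 2) {
  if (d > min(nrow(m), ncol(m))) {
    stop("d exceeds the rank bound min(N, #terms)")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = d)
  flip <- vapply(seq_len(d), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, `*`)
  colnames(coords) <- NULL
  new_embedding(rownames(m), coords, "linear", NA_integer_,
                list(centered = TRUE))
}

#' Project a term set into a term embedding by coordinate averaging
#'
#' Arithmetic per-dimension mean of the terms' coordinates. Note that
#' averaging pulls large term sets toward the embedding centroid (the
#' center-bias effect quantified by [center_bias()]).
#'
#' @param term_embedding an `embedding` whose entities are ontology terms.
#' @param terms non-empty character vector of term ids.
#' @return Numeric coordinate vector of length `d`.
#' @export
project_terms_average <- function(term_embedding, terms) {
  if (!length(terms)) stop("term set must be non-empty")
  missing_t <- setdiff(terms, term_embedding$ids)
  if (length(missing_t)) {
    stop("term not in embedding: ", missing_t[1])
  }
  colMeans(term_embedding$coords[unique(terms), , drop = FALSE])
}

#' Place a disease in a model embedding from its nearest models
#'
#' Initial vector-based placement: the mean of the embedding coordinates
#' of the disease's `k` nearest mouse models (by encoded-vector
#' distance). Optimizer-based refinement of this position is not applied;
#' the averaged placement is the defined contract.
#'
#' @param model_embedding an `embedding` of the model cohort.
#' @param ranked_models character vector of model ids, nearest first
#'   (e.g. one row of [knn_query()] output).
#' @param k number of neighbors to average.
#' @return Numeric coordinate vector.
#' @export
project_disease_vector <- function(model_embedding, ranked_models, k) {
  if (!length(ranked_models)) stop("no neighbors available")
  k <- min(k, length(ranked_models))
  use <- ranked_models[seq_len(k)]
  missing_m <- setdiff(use, model_embedding$ids)
  if (length(missing_m)) stop("model not in embedding: ", missing_m[1])
  colMeans(model_embedding$coords[use, , drop = FALSE])
}

#' Place a disease in a model embedding from text similarity
#'
#' Returns the coordinates of the single most text-similar mouse model
#' (ties broken by smallest entity id). If every similarity is zero, the
#' disease cannot be placed and `NA` coordinates are returned with a
#' warning.
#'
#' @param disease_bag `kmer_bag` of the disease document.
#' @param model_bags named list of model `kmer_bag`s.
#' @param w `kmer_weights`.
#' @param model_embedding an `embedding` of the model cohort.
#' @return Numeric coordinate vector (or NAs if unplaceable).
#' @export
project_disease_text <- function(disease_bag, model_bags, w,
                                 model_embedding) {
  if (!length(model_bags)) stop("model corpus is empty")
  hits <- text_knn(disease_bag, model_bags, w, k = 1)
  if (!nrow(hits) || hits$similarity[1] == 0) {
    warning("no model shares any k-mer with the disease document")
    return(rep(NA_real_, model_embedding$d))
  }
  model_embedding$coords[hits$id[1], ]
}

#' Write / read an embedding as TSV plus a JSON sidecar
#'
#' Coordinates go to `<path>` as TSV (`entity_id`, `x1..xd`); method,
#' seed and parameters go to `<path>.json`.
#'
#' @param emb an `embedding`.
#' @param path TSV output path.
#' @export
write_embedding_tsv <- function(emb, path) {
  df <- data.frame(entity_id = emb$ids, emb$coords)
  names(df)[-1] <- paste0("x", seq_len(emb$d))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = emb$method, seed = emb$seed, d = emb$d,
         params = emb$params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path)
  } else {
    list(method = "unknown", seed = NA_integer_, params = list())
  }
  coords <- as.matrix(df[, -1, drop = FALSE])
  colnames(coords) <- NULL
  new_embedding(df$entity_id, coords, meta$method,
                if (is.null(meta$seed)) NA_integer_ else meta$seed,
                as.list(meta$params))
}
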