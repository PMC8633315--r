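# Exact nearest-neighbor computation. All searches are brute force with a
# deterministic entity-id tie-break, so results are reproducible and can
# serve as the fixed neighbor input for the embedding optimizer.

new_neighbor_index <- function(ids, nn_ids, nn_dist, k, metric,
                               self_excluded) {
  structure(list(ids = ids, nn_ids = nn_ids, nn_dist = nn_dist,
                 k = as.integer(k), metric = metric,
                 self_excluded = self_excluded),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat("neighbor_index:", length(x$ids), "entities, k =", x$k,
      ", metric =", x$metric,
      if (x$self_excluded) "(self excluded)" else "", "\n")
  invisible(x)
}

# direct-difference distances: cancellation-free, so duplicated rows are at
# exactly zero distance (ties then resolve purely by entity id)
euclidean_self <- function(x) {
  as.matrix(stats::dist(x))
}

euclidean_cross <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    out[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  }
  out
}

#' Exact k-nearest neighbors under Euclidean distance
#'
#' Brute-force neighbor search over the rows of a matrix (an encoded
#' cohort matrix, expected unit-normalized, or embedding coordinates).
#' Lists are sorted by distance ascending with ties broken by entity id.
#' If `k >= N` with self-exclusion, `k` is clipped to `N - 1` with a
#' message.
#'
#' @param x numeric matrix with entity ids as rownames, or an `embedding`.
#' @param k number of neighbors, at least 1.
#' @param exclude_self drop each entity from its own list.
#' @return A `neighbor_index`: per-entity ranked neighbor-id and distance
#'   matrices plus the metric and self-exclusion flag.
#' @export
knn_exact <- function(x, k, exclude_self = TRUE) {
  if (inherits(x, "embedding")) x <- x$coords
  if (k < 1) stop("k must be at least 1")
  ids <- rownames(x)
  if (is.null(ids)) stop("matrix must have entity ids as rownames")
  n <- nrow(x)
  kmax <- if (exclude_self) n - 1L else n
  if (k > kmax) {
    message("k clipped from ", k, " to ", kmax)
    k <- kmax
  }
  d <- euclidean_self(x)
  nn_ids <- matrix(NA_character_, n, k)
  nn_dist <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    cand <- if (exclude_self) setdiff(seq_len(n), i) else seq_len(n)
    ord <- cand[order(di[cand], ids[cand])][seq_len(k)]
    nn_ids[i, ] <- ids[ord]
    nn_dist[i, ] <- di[ord]
  }
  rownames(nn_ids) <- rownames(nn_dist) <- ids
  new_neighbor_index(ids, nn_ids, nn_dist, k, "euclidean", exclude_self)
}

#' Rank reference entities for each query entity
#'
#' Cross-cohort exact search (e.g. nearest mouse models for each disease)
#' under Euclidean distance on the shared term axis. No self-exclusion is
#' applied; ties break by reference id.
#'
#' @param query,reference numeric matrices with rownames, same columns.
#' @param k number of reference neighbors per query.
#' @return A `neighbor_index` whose `ids` are the query ids and whose
#'   neighbor lists contain reference ids.
#' @export
knn_query <- function(query, reference, k = nrow(reference)) {
  if (ncol(query) != ncol(reference)) stop("column mismatch")
  k <- min(k, nrow(reference))
  d <- euclidean_cross(query, reference)
  rids <- rownames(reference)
  nn_ids <- matrix(NA_character_, nrow(query), k)
  nn_dist <- matrix(NA_real_, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    ord <- order(d[i, ], rids)[seq_len(k)]
    nn_ids[i, ] <- rids[ord]
    nn_dist[i, ] <- d[i, ord]
  }
  rownames(nn_ids) <- rownames(nn_dist) <- rownames(query)
  new_neighbor_index(rownames(query), nn_ids, nn_dist, k, "euclidean",
                     FALSE)
}

#' Exact k-nearest neighbors by weighted k-mer text similarity
#'
#' Exhaustive pairwise similarity search over a list of k-mer bags.
#' Neighbors are ranked by similarity descending (stored distance is
#' `1 - similarity`), ties broken by entity id.
#'
#' @param bags named list of `kmer_bag` objects.
#' @param w `kmer_weights`.
#' @param k number of neighbors.
#' @param exclude_self drop each entity from its own list.
#' @return A `neighbor_index` with metric `"text-similarity"`.
#' @export
knn_text <- function(bags, w, k, exclude_self = TRUE) {
  ids <- names(bags)
  n <- length(bags)
  kmax <- if (exclude_self) n - 1L else n
  if (k > kmax) {
    message("k clipped from ", k, " to ", kmax)
    k <- kmax
  }
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- if (i == j) 1 else kmer_similarity(bags[[i]], bags[[j]], w)
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  nn_ids <- matrix(NA_character_, n, k)
  nn_dist <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    cand <- if (exclude_self) setdiff(seq_len(n), i) else seq_len(n)
    ord <- cand[order(-sim[i, cand], ids[cand])][seq_len(k)]
    nn_ids[i, ] <- ids[ord]
    nn_dist[i, ] <- 1 - sim[i, ord]
  }
  rownames(nn_ids) <- rownames(nn_dist) <- ids
  new_neighbor_index(ids, nn_ids, nn_dist, k, "text-similarity",
                     exclude_self)
}

#' Write a neighbor index as TSV
#'
#' Long format: one row per (entity, rank) with columns `entity_id`,
#' `rank`, `neighbor_id`, `distance`.
#'
#' @param nn a `neighbor_index`.
#' @param path file path.
#' @export
write_neighbors_tsv <- function(nn, path) {
  df <- data.frame(
    entity_id = rep(nn$ids, each = nn$k),
    rank = rep(seq_len(nn$k), times = length(nn$ids)),
    neighbor_id = as.vector(t(nn$nn_ids)),
    distance = as.vector(t(nn$nn_dist)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neighbors_tsv
#' @param metric,self_excluded metadata to attach on read.
#' @export
read_neighbors_tsv <- function(path, metric = "euclidean",
                               self_excluded = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$entity_id)
  k <- max(df$rank)
  nn_ids <- matrix(df$neighbor_id, ncol = k, byrow = TRUE)
  nn_dist <- matrix(df$distance, ncol = k, byrow = TRUE)
  rownames(nn_ids) <- rownames(nn_dist) <- ids
  new_neighbor_index(ids, nn_ids, nn_dist, k, metric, self_excluded)
}
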