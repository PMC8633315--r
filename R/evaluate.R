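# Quantitative evaluation of encodings and embeddings: neighbor-based
# phenotype prediction with self-supervised k calibration, stratified error
# summaries, Fisher region enrichment, same-gene neighbor statistics with
# an analytic random-neighbor null, disease causal-gene recovery,
# center-bias diagnostics and cross-embedding neighbor Jaccard.

#' Predict an entity's phenotype vector from its neighbors
#'
#' Simple (unrenormalized) arithmetic mean of the `k` nearest neighbors'
#' rows of the reference matrix. Neighbors may come from any source
#' (original vectors, an embedding, text similarity); the reference is
#' conventionally the unit-normalized non-binary matrix so errors from
#' different neighbor sources share a scale.
#'
#' @param entity entity id.
#' @param nn a `neighbor_index` covering `entity`.
#' @param k neighbors to average; clipped with a warning if the index
#'   holds fewer.
#' @param reference numeric matrix with entity rownames.
#' @return Named numeric vector over the reference columns.
#' @export
predict_from_neighbors <- function(entity, nn, k, reference) {
  i <- match(entity, nn$ids)
  if (is.na(i)) stop("entity not in neighbor index: ", entity)
  if (k > nn$k) {
    warning("k clipped to available neighbors: ", nn$k)
    k <- nn$k
  }
  rows <- reference[nn$nn_ids[i, seq_len(k)], , drop = FALSE]
  colMeans(rows)
}

#' Euclidean (L2) prediction error
#'
#' @param truth,prediction numeric vectors of equal length.
#' @return `||truth - prediction||_2`.
#' @export
l2_error <- function(truth, prediction) {
  if (length(truth) != length(prediction)) stop("length mismatch")
  sqrt(sum((truth - prediction)^2))
}

#' Self-supervised calibration of the neighbor count k
#'
#' For each neighbor source and each `k` in the grid, predicts every
#' entity from its `k` nearest neighbors and records the mean L2 error
#' against the entity's own reference row. No ground truth is needed:
#' the optimal `k` per source is the grid value minimizing mean error
#' (smallest `k` on ties).
#'
#' @param reference numeric matrix (unit-normalized non-binary encoding).
#' @param neighbor_sources named list of `neighbor_index` objects, each
#'   covering all reference entities with at least `max(k_grid)`
#'   neighbors.
#' @param k_grid sorted integer vector of neighbor counts (default 1:20).
#' @return A `prediction_report`: mean-error matrix (sources x k),
#'   per-source optimal k, and the per-entity error array.
#' @export
calibrate_k <- function(reference, neighbor_sources, k_grid = 1:20) {
  if (!length(k_grid)) stop("k_grid must be non-empty")
  k_grid <- as.integer(sort(k_grid))
  kmax <- max(k_grid)
  ids <- rownames(reference)
  n <- length(ids)
  errs <- array(NA_real_,
                dim = c(length(neighbor_sources), n, length(k_grid)),
                dimnames = list(names(neighbor_sources), ids, k_grid))
  for (s in seq_along(neighbor_sources)) {
    nn <- neighbor_sources[[s]]
    if (nn$k < kmax) {
      stop("neighbor source '", names(neighbor_sources)[s],
           "' holds fewer than max(k_grid) neighbors")
    }
    idx <- match(ids, nn$ids)
    if (anyNA(idx)) stop("neighbor source does not cover all entities")
    for (e in seq_len(n)) {
      rows <- reference[nn$nn_ids[idx[e], seq_len(kmax)], , drop = FALSE]
      cmean <- apply(rows, 2, cumsum) / seq_len(kmax)
      diff <- cmean - matrix(reference[e, ], kmax, ncol(reference),
                             byrow = TRUE)
      errs[s, e, ] <- sqrt(rowSums(diff^2))[k_grid]
    }
  }
  mean_error <- apply(errs, c(1, 3), mean)
  optimal_k <- apply(mean_error, 1, function(row) {
    k_grid[which.min(row)]
  })
  structure(list(mean_error = mean_error, optimal_k = optimal_k,
                 k_grid = k_grid, per_entity_error = errs),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("prediction_report over k in {", paste(range(x$k_grid),
                                             collapse = ".."), "}\n")
  for (s in rownames(x$mean_error)) {
    cat(sprintf("  %s: optimal k = %d, mean error %.4f\n", s,
                x$optimal_k[[s]],
                min(x$mean_error[s, ])))
  }
  invisible(x)
}

#' Stratify per-entity errors by annotation count
#'
#' Bins entities by their number of annotated terms and summarizes each
#' bin with 5/25/50/75/95 percentiles (the box-and-whisker summary).
#' Empty bins are reported with `n = 0` and NA quantiles.
#'
#' @param errors named numeric vector of per-entity errors.
#' @param counts numeric vector of annotation counts, same entities.
#' @param bin_edges break points passed to [cut()].
#' @return data.frame with one row per bin: `bin`, `n`, `q05`, `q25`,
#'   `q50`, `q75`, `q95`.
#' @export
stratify_errors <- function(errors, counts,
                            bin_edges = c(0, 1, 2, 5, 10, 20, 50, Inf)) {
  if (length(errors) != length(counts)) stop("length mismatch")
  bins <- cut(counts, breaks = bin_edges, include.lowest = TRUE)
  out <- lapply(levels(bins), function(b) {
    e <- errors[!is.na(bins) & bins == b]
    if (!length(e)) {
      data.frame(bin = b, n = 0L, q05 = NA_real_, q25 = NA_real_,
                 q50 = NA_real_, q75 = NA_real_, q95 = NA_real_)
    } else {
      q <- quantile(e, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      data.frame(bin = b, n = length(e), q05 = q[1], q25 = q[2],
                 q50 = q[3], q75 = q[4], q95 = q[5])
    }
  })
  do.call(rbind, out)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] used by
#' [fisher_enrichment()]; exposed so the p-value routine can be checked
#' directly against exact enumeration.
#'
#' @param a,b,c,d cell counts (first column `a`, `b`; second `c`, `d`).
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
}

#' Fisher-test phenotype enrichment of an embedding region
#'
#' Compares ancestor-closed annotations of entities inside a region
#' against the rest of the cohort. For every term annotated in at least
#' one in-region entity, a two-sided Fisher exact test is computed on the
#' 2x2 table (in-region annotated / not, out-region annotated / not).
#' Significance uses Bonferroni correction at family level `alpha`, with
#' the family size equal to the number of tested terms.
#'
#' @param region_entities character vector of entity ids, a proper
#'   non-empty subset of the cohort.
#' @param cohort named list of [phenotype_profile()] objects.
#' @param ontology an `ontology`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns `term_id`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `significant`, ordered by p-value.
#' @export
fisher_enrichment <- function(region_entities, cohort, ontology,
                              alpha = 0.05) {
  cohort <- name_cohort(cohort)
  ids <- names(cohort)
  region_entities <- unique(region_entities)
  if (!length(region_entities) ||
      length(setdiff(region_entities, ids))) {
    stop("region must be a non-empty subset of the cohort")
  }
  if (length(region_entities) == length(ids)) {
    stop("region must be a proper subset of the cohort")
  }
  closures <- lapply(cohort, function(p) {
    if (length(p$terms)) ancestor_closure(ontology, p$terms)
    else character(0)
  })
  in_region <- ids %in% region_entities
  terms <- sort(unique(unlist(closures[in_region], use.names = FALSE)))
  if (!length(terms)) stop("no annotated terms in the region")
  n_in <- sum(in_region)
  n_out <- sum(!in_region)
  m <- length(terms)
  res <- lapply(terms, function(t) {
    has <- vapply(closures, function(s) t %in% s, logical(1))
    a <- sum(has & in_region)
    c_ <- sum(has & !in_region)
    tab <- matrix(c(a, n_in - a, c_, n_out - c_), nrow = 2)
    ft <- fisher.test(tab)
    data.frame(term_id = t, a = a, b = n_in - a, c = c_,
               d = n_out - c_, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value,
               significant = ft$p.value <= alpha / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value, out$term_id), ]
}

#' Convert an axis-aligned rectangle in embedding coordinates to an
#' entity-id set
#'
#' @param embedding an `embedding` (first two dimensions are used).
#' @param xlim,ylim numeric length-2 ranges.
#' @return Character vector of entity ids inside the rectangle.
#' @export
region_from_rectangle <- function(embedding, xlim, ylim) {
  x <- embedding$coords[, 1]
  y <- embedding$coords[, 2]
  embedding$ids[x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]]
}

#' Causal-gene recovery from nearest mouse models
#'
#' A disease scores a hit when at least one of its `k` nearest models
#' carries a mutation in one of its causal genes. Only diseases with both
#' a non-empty term set and non-empty causal-gene set are evaluated.
#'
#' @param diseases named list of disease profiles.
#' @param models named list of model profiles (markers in `marker_id`).
#' @param ranked_models named list (per disease id) of model ids ranked
#'   nearest-first, or a `neighbor_index` from [knn_query()].
#' @param k neighbor depth (default 15).
#' @return List with `proportion`, logical `hits` per evaluated disease,
#'   and `n_evaluated`.
#' @export
gene_recovery_at_k <- function(diseases, models, ranked_models, k = 15) {
  diseases <- name_cohort(diseases)
  models <- name_cohort(models)
  if (inherits(ranked_models, "neighbor_index")) {
    nnm <- ranked_models
    ranked_models <- setNames(
      lapply(seq_along(nnm$ids), function(i) nnm$nn_ids[i, ]), nnm$ids)
  }
  markers <- vapply(models, function(m) m$marker_id, character(1))
  eval_ids <- names(diseases)[vapply(diseases, function(d) {
    length(d$terms) > 0 && length(d$causal_genes) > 0
  }, logical(1))]
  if (!length(eval_ids)) stop("no evaluable diseases")
  hits <- vapply(eval_ids, function(did) {
    ranked <- ranked_models[[did]]
    if (is.null(ranked)) stop("no ranked models for disease: ", did)
    top <- ranked[seq_len(min(k, length(ranked)))]
    any(markers[top] %in% diseases[[did]]$causal_genes)
  }, logical(1))
  list(proportion = mean(hits), hits = hits,
       n_evaluated = length(eval_ids))
}

#' Permutation baseline for causal-gene recovery
#'
#' Shuffles the causal-gene labels across the evaluated diseases while
#' keeping every neighbor list fixed, and returns the mean recovery
#' proportion over permutations. This breaks the disease-gene association
#' and measures how often a random disease's genes appear among another
#' disease's nearest models.
#'
#' @inheritParams gene_recovery_at_k
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `proportion` (mean over permutations) and the
#'   per-permutation values.
#' @export
gene_recovery_permuted <- function(diseases, models, ranked_models,
                                   k = 15, n_perm = 50, seed = 1) {
  diseases <- name_cohort(diseases)
  eval_ids <- names(diseases)[vapply(diseases, function(d) {
    length(d$terms) > 0 && length(d$causal_genes) > 0
  }, logical(1))]
  if (length(eval_ids) < 2) stop("need at least 2 evaluable diseases")
  genes <- lapply(diseases[eval_ids], function(d) d$causal_genes)
  per_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample(length(eval_ids))
      shuffled <- diseases[eval_ids]
      for (i in seq_along(eval_ids)) {
        shuffled[[i]]$causal_genes <- genes[[perm[i]]]
      }
      gene_recovery_at_k(shuffled, models, ranked_models, k)$proportion
    }, numeric(1))
  })
  list(proportion = mean(per_perm), per_permutation = per_perm)
}

#' Analytic null for same-gene neighbor co-occurrence
#'
#' Probability that a model whose gene has `m` models in a cohort of size
#' `N` has at least one same-gene model among `k` uniformly random
#' neighbors: `1 - C(N - m, k) / C(N - 1, k)`.
#'
#' @param N cohort size.
#' @param m number of models for the gene (at least 2).
#' @param k neighbor count.
#' @return Probability in \[0, 1\].
#' @export
same_gene_null <- function(N, m, k) {
  if (k > N - m) return(1)
  1 - exp(lchoose(N - m, k) - lchoose(N - 1, k))
}

#' Observed vs null same-gene neighbor fraction, by gene multiplicity
#'
#' For every model whose gene has multiplicity at least 2, checks whether
#' any of its `k` nearest neighbors shares the same marker, and compares
#' the per-bin observed fraction with the analytic random-neighbor null
#' averaged over bin members.
#'
#' @param models named list of model profiles.
#' @param nn a `neighbor_index` over the models (self excluded).
#' @param k neighbor depth (default 15).
#' @param multiplicity_bins break points for binning gene multiplicity.
#' @return List with `overall` (observed, null, n) and `by_bin`
#'   data.frame.
#' @export
same_gene_neighbor_fraction <- function(models, nn, k = 15,
                                        multiplicity_bins =
                                          c(2, 4, 8, 16, Inf)) {
  models <- name_cohort(models)
  if (k > nn$k) stop("neighbor index holds fewer than k neighbors")
  markers <- vapply(models, function(m) m$marker_id, character(1))
  mult <- table(markers)
  m_per_model <- as.integer(mult[markers])
  N <- length(models)
  eval_idx <- which(m_per_model >= 2)
  if (!length(eval_idx)) stop("no genes with multiplicity >= 2")
  idx_in_nn <- match(names(models), nn$ids)
  observed <- vapply(eval_idx, function(i) {
    any(markers[nn$nn_ids[idx_in_nn[i], seq_len(k)]] == markers[i])
  }, logical(1))
  null <- vapply(eval_idx, function(i) {
    same_gene_null(N, m_per_model[i], k)
  }, numeric(1))
  bins <- cut(m_per_model[eval_idx], breaks = multiplicity_bins,
              include.lowest = TRUE, right = FALSE)
  by_bin <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- bins == b
    data.frame(bin = b, n = sum(sel),
               observed = if (any(sel)) mean(observed[sel]) else NA_real_,
               null = if (any(sel)) mean(null[sel]) else NA_real_)
  }))
  list(overall = list(observed = mean(observed), null = mean(null),
                      n = length(eval_idx)),
       by_bin = by_bin)
}

#' Center-bias diagnostic for averaged projections
#'
#' Computes each entity's Euclidean distance to the centroid of all
#' projections and the Spearman rank correlation between annotation count
#' and that distance. A strongly negative correlation indicates that
#' well-annotated profiles are pulled toward the center, the systematic
#' artifact of coordinate averaging.
#'
#' @param projections numeric matrix of per-entity coordinates.
#' @param counts numeric vector of annotation counts.
#' @param bin_edges break points for the per-count-bin quantile summary.
#' @return List with `rho`, `p_value`, and a `strata` data.frame of
#'   distance quantiles per count bin. With fewer than 3 distinct counts
#'   the correlation is undefined: `rho` is NA with a warning.
#' @export
center_bias <- function(projections, counts,
                        bin_edges = c(0, 1, 2, 5, 10, 20, 50, Inf)) {
  if (nrow(projections) != length(counts)) stop("length mismatch")
  centroid <- colMeans(projections)
  dist <- sqrt(rowSums(sweep(projections, 2, centroid)^2))
  if (length(unique(counts)) < 3) {
    warning("fewer than 3 distinct counts; correlation undefined")
    rho <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(counts, dist, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  list(rho = rho, p_value = p,
       strata = stratify_errors(dist, counts, bin_edges))
}

#' Neighbor-set Jaccard consistency between two embeddings
#'
#' For each entity, extracts its `k` nearest neighbors (self excluded) in
#' each embedding's coordinate space and computes the Jaccard index of
#' the two id sets; returns the mean over entities.
#'
#' @param embA,embB `embedding` objects over the same entity set.
#' @param k neighbor depth (default 15).
#' @return List with `mean` and named `per_entity` Jaccard values.
#' @export
neighbor_jaccard <- function(embA, embB, k = 15) {
  if (!setequal(embA$ids, embB$ids)) stop("entity sets differ")
  nnA <- knn_exact(embA$coords, k, exclude_self = TRUE)
  nnB <- knn_exact(embB$coords[embA$ids, , drop = FALSE], k,
                   exclude_self = TRUE)
  per <- vapply(seq_along(embA$ids), function(i) {
    a <- nnA$nn_ids[i, ]
    b <- nnB$nn_ids[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  names(per) <- embA$ids
  list(mean = mean(per), per_entity = per)
}
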