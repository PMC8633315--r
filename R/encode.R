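# Numeric encodings of phenotype profiles over the ontology term axis.
# The term axis is always the full set of (non-obsolete) ontology terms in
# lexicographic id order, so matrices from the same ontology are conformable.

#' Binary ancestor-closed encoding of a profile
#'
#' `v_t = 1` iff `t` is in the ancestor closure of the profile's terms,
#' else 0. Annotating a term therefore also switches on all of its more
#' general ancestors.
#'
#' @param profile a [phenotype_profile()].
#' @param ontology an `ontology`.
#' @return Named numeric 0/1 vector over all ontology terms.
#' @export
encode_binary <- function(profile, ontology) {
  v <- setNames(numeric(length(ontology$ids)), ontology$ids)
  if (length(profile$terms)) {
    v[ancestor_closure(ontology, profile$terms)] <- 1
  }
  v
}

#' Bayesian update of a term probability given an annotation
#'
#' Treats a direct annotation as a positive test with true-positive rate
#' `tpr` and false-positive rate `fpr`, returning the posterior
#' `prior * tpr / (prior * tpr + (1 - prior) * fpr)`. Strictly increasing
#' in `prior`; never below `prior` when `tpr > fpr`. Vectorized over
#' `prior`.
#'
#' @param prior prior probability (or vector of them) in \[0, 1\].
#' @param tpr true-positive rate, in (fpr, 1\].
#' @param fpr false-positive rate, in (0, tpr).
#' @return Posterior probability, same length as `prior`.
#' @export
bayes_update <- function(prior, tpr = 0.8, fpr = 0.05) {
  if (!is.numeric(tpr) || !is.numeric(fpr) || fpr <= 0 || tpr <= fpr ||
      tpr > 1) {
    stop("require 0 < fpr < tpr <= 1")
  }
  if (any(prior < 0 | prior > 1)) stop("prior must be in [0, 1]")
  prior * tpr / (prior * tpr + (1 - prior) * fpr)
}

#' Real-valued (non-binary) Bayesian encoding of a profile
#'
#' Combines three information sources: the cohort (via term priors), the
#' profile's own annotations (via [bayes_update()] on directly annotated
#' terms) and the ontology hierarchy (via max-propagation toward the
#' roots). Concretely: start from `v_t = prior(t)` for every term, replace
#' `v_a` by the Bayesian posterior for each directly annotated term `a`,
#' then, sweeping terms in reverse topological order, set
#' `v_t = max(v_t, max of v over children of t)`. The result satisfies
#' `v_parent >= v_child` on every edge and `v_t >= prior(t)` everywhere.
#'
#' @param profile a [phenotype_profile()].
#' @param ontology an `ontology`.
#' @param priors named prior vector from [term_priors()] covering all
#'   terms.
#' @param tpr,fpr annotation evidence rates, see [bayes_update()].
#' @return Named numeric vector over all ontology terms.
#' @export
encode_nonbinary <- function(profile, ontology, priors, tpr = 0.8,
                             fpr = 0.05) {
  missing_p <- setdiff(ontology$ids, names(priors))
  if (length(missing_p)) stop("term missing from priors: ", missing_p[1])
  v <- priors[ontology$ids]
  attributes(v) <- list(names = ontology$ids)
  if (!length(profile$terms)) return(v)
  check_terms(ontology, profile$terms)
  v[profile$terms] <- bayes_update(unname(priors[profile$terms]), tpr, fpr)
  # priors are monotone, so only ancestors of annotated terms can change;
  # sweep the closure in reverse topological order pushing maxima upward
  cl <- ancestor_closure(ontology, profile$terms)
  for (t in rev(ontology$order[ontology$order %in% cl])) {
    for (p in ontology$parents[[t]]) {
      if (v[[p]] < v[[t]]) v[[p]] <- v[[t]]
    }
  }
  v
}

#' Scale a vector to unit Euclidean norm
#'
#' @param v finite numeric vector.
#' @return `v / ||v||_2`.
#' @export
unit_normalize <- function(v) {
  if (any(!is.finite(v))) stop("vector must be finite")
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Encode a cohort of profiles as an entities x terms matrix
#'
#' Rows follow the input profile order; columns are all ontology terms in
#' lexicographic id order. With `normalize = TRUE` every row is scaled to
#' unit Euclidean norm (an all-zero binary row raises an error naming the
#' entity; filter empty profiles first).
#'
#' @param profiles named list of [phenotype_profile()] objects.
#' @param ontology an `ontology`.
#' @param priors prior vector, required for `encoding = "nonbinary"`.
#' @param encoding `"binary"` or `"nonbinary"`.
#' @param normalize scale rows to unit norm.
#' @param tpr,fpr see [bayes_update()].
#' @return Numeric matrix with rownames = entity ids, colnames = term ids
#'   and attributes `encoding` and `normalized`.
#' @export
encode_cohort <- function(profiles, ontology, priors = NULL,
                          encoding = c("nonbinary", "binary"),
                          normalize = TRUE, tpr = 0.8, fpr = 0.05) {
  encoding <- match.arg(encoding)
  profiles <- name_cohort(profiles)
  if (encoding == "nonbinary" && is.null(priors)) {
    stop("nonbinary encoding requires priors")
  }
  m <- matrix(0, nrow = length(profiles), ncol = length(ontology$ids),
              dimnames = list(names(profiles), ontology$ids))
  for (i in seq_along(profiles)) {
    row <- if (encoding == "binary") {
      encode_binary(profiles[[i]], ontology)
    } else {
      encode_nonbinary(profiles[[i]], ontology, priors, tpr, fpr)
    }
    if (normalize) {
      if (sum(row^2) == 0) {
        stop("cannot normalize all-zero encoding for entity: ",
             profiles[[i]]$entity_id)
      }
      row <- unit_normalize(row)
    }
    m[i, ] <- row
  }
  attr(m, "encoding") <- encoding
  attr(m, "normalized") <- normalize
  m
}

#' Write / read an encoded matrix as TSV
#'
#' Dense TSV with an `entity_id` first column and term ids as remaining
#' column headers.
#'
#' @param m matrix from [encode_cohort()].
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(entity_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$entity_id
  m
}
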