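# Character k-mer text engine: bags of overlapping k-mers with smoothed
# inverse-document-frequency weights, cosine similarity, exhaustive text
# search and text-based cross-ontology term mapping.

#' Split text into a bag of character k-mers
#'
#' Text is lowercased, non-alphanumeric characters become single spaces,
#' and each whitespace token contributes its overlapping length-`k`
#' substrings; tokens shorter than `k` contribute themselves whole. Counts
#' accumulate across tokens.
#'
#' @param text character vector (elements are concatenated).
#' @param k k-mer length, at least 2.
#' @return An object of class `kmer_bag`: list with `counts` (named
#'   numeric, no zero entries) and `k`.
#' @export
kmerize <- function(text, k = 6L) {
  if (!is.numeric(k) || k < 2) stop("k must be at least 2")
  k <- as.integer(k)
  s <- tolower(paste(text, collapse = " "))
  s <- gsub("[^a-z0-9]+", " ", s)
  tokens <- strsplit(trimws(s), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  kmers <- unlist(lapply(tokens, function(tok) {
    n <- nchar(tok)
    if (n <= k) tok else substring(tok, 1:(n - k + 1), k:n)
  }))
  counts <- if (length(kmers)) {
    tab <- table(kmers)
    setNames(as.numeric(tab), names(tab))
  } else {
    setNames(numeric(0), character(0))
  }
  structure(list(counts = counts, k = k), class = "kmer_bag")
}

#' @export
print.kmer_bag <- function(x, ...) {
  cat("kmer_bag: ", length(x$counts), " distinct ", x$k, "-mers\n",
      sep = "")
  invisible(x)
}

#' Information-content k-mer weights from a corpus
#'
#' Smoothed inverse document frequency: for a corpus of `D` documents,
#' `weight(m) = ln((D + 1) / (df_m + 1)) + 1` where `df_m` is the number
#' of documents containing k-mer `m`. K-mers absent from the corpus get
#' the maximum (unseen) weight `ln(D + 1) + 1`. All weights are strictly
#' positive.
#'
#' @param corpus non-empty character vector of documents.
#' @param k k-mer length.
#' @return Object of class `kmer_weights`: list with `weights`,
#'   `corpus_size`, `k` and `unseen`.
#' @export
build_weights <- function(corpus, k = 6L) {
  if (!length(corpus)) stop("corpus must be non-empty")
  D <- length(corpus)
  df <- table(unlist(lapply(corpus, function(doc) {
    names(kmerize(doc, k)$counts)
  })))
  structure(
    list(weights = setNames(log((D + 1) / (as.numeric(df) + 1)) + 1,
                            names(df)),
         corpus_size = D, k = as.integer(k), unseen = log(D + 1) + 1),
    class = "kmer_weights")
}

#' @export
print.kmer_weights <- function(x, ...) {
  cat("kmer_weights: ", length(x$weights), " ", x$k, "-mers from ",
      x$corpus_size, " documents\n", sep = "")
  invisible(x)
}

kmer_weight_of <- function(kmers, w) {
  x <- w$weights[kmers]
  x[is.na(x)] <- w$unseen
  unname(x)
}

#' Weighted cosine similarity of two k-mer bags
#'
#' Cosine of the weight-scaled count vectors (component `count * weight`
#' per k-mer). Returns 0 when either bag is empty. Symmetric and bounded
#' in \[0, 1\] for non-negative counts.
#'
#' @param a,b `kmer_bag` objects with the same `k`.
#' @param w `kmer_weights` with the same `k`.
#' @return Similarity in \[0, 1\].
#' @export
kmer_similarity <- function(a, b, w) {
  if (a$k != b$k || a$k != w$k) stop("k mismatch between bags/weights")
  if (!length(a$counts) || !length(b$counts)) return(0)
  va <- a$counts * kmer_weight_of(names(a$counts), w)
  vb <- b$counts * kmer_weight_of(names(b$counts), w)
  shared <- intersect(names(va), names(vb))
  if (!length(shared)) return(0)
  sum(va[shared] * vb[shared]) /
    (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Text representation of a phenotype profile
#'
#' `"concise"` concatenates the names of the directly annotated terms;
#' `"complete"` concatenates the names of the full ancestor closure. Each
#' distinct term name is included once, in term-id order, and the result
#' is k-merized.
#'
#' @param profile a [phenotype_profile()].
#' @param ontology an `ontology`.
#' @param mode `"concise"` or `"complete"`.
#' @param k k-mer length.
#' @return A `kmer_bag`.
#' @export
encode_profile_text <- function(profile, ontology,
                                mode = c("concise", "complete"), k = 6L) {
  mode <- match.arg(mode)
  check_terms(ontology, profile$terms)
  terms <- if (mode == "concise") {
    sort(unique(profile$terms))
  } else if (length(profile$terms)) {
    ancestor_closure(ontology, profile$terms)
  } else {
    character(0)
  }
  kmerize(unique(ontology$name[terms]), k)
}

#' Precompute k-mer bags for every ontology term
#'
#' @param ontology an `ontology`.
#' @param k k-mer length.
#' @return Named list of `kmer_bag` objects over [term_text()] strings.
#' @export
ontology_term_bags <- function(ontology, k = 6L) {
  setNames(lapply(ontology$ids, function(t) {
    kmerize(term_text(ontology, t), k)
  }), ontology$ids)
}

#' Map free text onto the best-matching term of a target ontology
#'
#' Returns the target term maximizing weighted k-mer cosine similarity
#' between the source text and [term_text()] of each target term. Ties are
#' broken by lexicographically smallest id; if every similarity is zero,
#' `NA` is returned (no-mapping signal) with a warning.
#'
#' @param source_text character scalar.
#' @param target_ontology an `ontology`.
#' @param w `kmer_weights`.
#' @param target_bags optional precomputed [ontology_term_bags()] to avoid
#'   re-k-merizing the target in repeated calls.
#' @return A single term id, or `NA_character_`.
#' @export
map_term <- function(source_text, target_ontology, w, target_bags = NULL) {
  if (!length(target_ontology$ids)) stop("target ontology is empty")
  if (is.null(target_bags)) {
    target_bags <- ontology_term_bags(target_ontology, w$k)
  }
  q <- kmerize(source_text, w$k)
  sims <- vapply(target_bags, kmer_similarity, numeric(1), b = q, w = w)
  if (max(sims) == 0) {
    warning("no target term shares any k-mer with the source text")
    return(NA_character_)
  }
  best <- names(sims)[sims == max(sims)]
  sort(best)[1]
}

#' Exhaustive k-nearest-neighbor text search
#'
#' Ranks all corpus documents by weighted k-mer cosine similarity to the
#' query, descending, with ties broken by entity id, and returns the top
#' `k`. The search is exact (no approximate index).
#'
#' @param query a `kmer_bag`.
#' @param corpus_bags named list of `kmer_bag` objects.
#' @param w `kmer_weights`.
#' @param k number of hits, at least 1; silently truncated (with a
#'   warning) if larger than the corpus.
#' @return data.frame with columns `id` and `similarity`, best first.
#' @export
text_knn <- function(query, corpus_bags, w, k) {
  if (k < 1) stop("k must be at least 1")
  if (!length(query$counts)) {
    warning("empty query bag; returning no hits")
    return(data.frame(id = character(0), similarity = numeric(0)))
  }
  if (k > length(corpus_bags)) {
    warning("k exceeds corpus size; truncating to ", length(corpus_bags))
    k <- length(corpus_bags)
  }
  sims <- vapply(corpus_bags, kmer_similarity, numeric(1), b = query,
                 w = w)
  ord <- order(-sims, names(sims))[seq_len(k)]
  data.frame(id = names(sims)[ord], similarity = unname(sims[ord]),
             stringsAsFactors = FALSE)
}

#' Assemble the text document describing a disease
#'
#' Fixed-order concatenation of the clinical summary, the names of the
#' disease's (mapped) ontology terms and the curated gene names.
#'
#' @param profile a disease [phenotype_profile()].
#' @param ontology an `ontology` used to resolve term names.
#' @return A character scalar.
#' @export
disease_document <- function(profile, ontology) {
  check_terms(ontology, profile$terms)
  parts <- c(profile$description,
             unique(ontology$name[sort(profile$terms)]),
             profile$causal_genes)
  paste(parts[nzchar(parts)], collapse = " ")
}

#' Write a term-mapping table
#'
#' @param mapping data.frame with columns `source_id`, `target_id`,
#'   `similarity`.
#' @param path file path.
#' @export
write_mapping_tsv <- function(mapping, path) {
  write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
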