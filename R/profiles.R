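# Phenotype profiles: one mouse model or one disease, as a set of ontology
# terms plus metadata. A cohort is a plain (named) list of profiles.

#' Construct a phenotype profile
#'
#' @param entity_id unique entity identifier.
#' @param terms character vector of ontology term ids (may be empty).
#' @param kind `"model"` or `"disease"`.
#' @param marker_id mutated genomic marker / gene id (models).
#' @param zygosity,background,source,life_stage optional categorical
#'   metadata (strain background, curation source, life stage).
#' @param causal_genes character vector of disease-associated gene ids.
#' @param description free-text description.
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(entity_id, terms = character(0),
                              kind = c("model", "disease"),
                              marker_id = NA_character_,
                              zygosity = NA_character_,
                              background = NA_character_,
                              source = NA_character_,
                              life_stage = NA_character_,
                              causal_genes = character(0),
                              description = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(entity_id), length(entity_id) == 1,
            nzchar(entity_id))
  structure(
    list(entity_id = entity_id, kind = kind,
         terms = sort(unique(as.character(terms))),
         marker_id = marker_id, zygosity = zygosity,
         background = background, source = source,
         life_stage = life_stage,
         causal_genes = sort(unique(as.character(causal_genes))),
         description = description),
    class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(x$kind, x$entity_id, "-", length(x$terms), "terms")
  if (!is.na(x$marker_id)) cat(", marker", x$marker_id)
  if (length(x$causal_genes)) {
    cat(", causal genes:", paste(x$causal_genes, collapse = ","))
  }
  cat("\n")
  invisible(x)
}

profile_ids <- function(profiles) {
  vapply(profiles, function(p) p$entity_id, character(1))
}

name_cohort <- function(profiles) {
  ids <- profile_ids(profiles)
  if (anyDuplicated(ids)) {
    stop("duplicate entity_id in cohort: ", ids[duplicated(ids)][1])
  }
  names(profiles) <- ids
  profiles
}

#' Read a cohort from annotation and metadata tables
#'
#' The annotation table is long-format TSV with header columns `entity_id`
#' and `term_id`; the optional metadata table has one row per entity with
#' columns among `entity_id`, `marker_id`, `zygosity`, `background`,
#' `source`, `life_stage`. Entities present only in the metadata table get
#' empty term sets.
#'
#' @param annotations path to the annotation TSV.
#' @param metadata optional path to the metadata TSV.
#' @param kind profile kind for all entities.
#' @return Named list of [phenotype_profile()] objects.
#' @export
read_annotations <- function(annotations, metadata = NULL, kind = "model") {
  ann <- read.delim(annotations, stringsAsFactors = FALSE)
  if (!all(c("entity_id", "term_id") %in% names(ann))) {
    stop("annotation table must have columns entity_id, term_id")
  }
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- read.delim(metadata, stringsAsFactors = FALSE)
    if (!"entity_id" %in% names(meta)) {
      stop("metadata table must have column entity_id")
    }
  }
  ids <- sort(unique(c(ann$entity_id, meta$entity_id)))
  terms_by <- split(ann$term_id, ann$entity_id)
  get_meta <- function(id, col) {
    if (is.null(meta) || !col %in% names(meta)) return(NA_character_)
    v <- meta[[col]][meta$entity_id == id]
    if (length(v)) as.character(v[1]) else NA_character_
  }
  profiles <- lapply(ids, function(id) {
    phenotype_profile(id, terms = terms_by[[id]] %||% character(0),
                      kind = kind,
                      marker_id = get_meta(id, "marker_id"),
                      zygosity = get_meta(id, "zygosity"),
                      background = get_meta(id, "background"),
                      source = get_meta(id, "source"),
                      life_stage = get_meta(id, "life_stage"))
  })
  name_cohort(profiles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort as annotation and metadata tables
#'
#' @param profiles named list of profiles.
#' @param annotations output path for the long-format annotation TSV.
#' @param metadata optional output path for the metadata TSV.
#' @return `annotations`, invisibly.
#' @export
write_annotations <- function(profiles, annotations, metadata = NULL) {
  ann <- do.call(rbind, lapply(profiles, function(p) {
    if (!length(p$terms)) return(NULL)
    data.frame(entity_id = p$entity_id, term_id = p$terms,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(entity_id = character(0), term_id = character(0))
  }
  write.table(ann, annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(metadata)) {
    md <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(entity_id = p$entity_id, marker_id = p$marker_id,
                 zygosity = p$zygosity, background = p$background,
                 source = p$source, life_stage = p$life_stage,
                 stringsAsFactors = FALSE)
    }))
    write.table(md, metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(annotations)
}

#' Read / write disease profiles as JSON
#'
#' Diseases are stored as a JSON array of objects with fields `entity_id`,
#' `terms`, `causal_genes` and `description`.
#'
#' @param path file path.
#' @return `read_diseases` returns a named list of profiles.
#' @export
read_diseases <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  name_cohort(lapply(raw, function(d) {
    phenotype_profile(d$entity_id, terms = unlist(d$terms),
                      kind = "disease",
                      causal_genes = unlist(d$causal_genes),
                      description = d$description %||% "")
  }))
}

#' @rdname read_diseases
#' @param profiles named list of disease profiles.
#' @export
write_diseases <- function(profiles, path) {
  out <- lapply(unname(profiles), function(p) {
    list(entity_id = p$entity_id, terms = as.list(p$terms),
         causal_genes = as.list(p$causal_genes),
         description = p$description)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Filter a cohort for evaluation and visualization
#'
#' Implements the standard exclusions: profiles annotated only with a
#' designated no-phenotype term, profiles with no terms at all, and
#' profiles with fewer than `min_terms` terms. Counts of dropped entities
#' are reported per reason via `message()`. Encodings should be computed on
#' the full cohort; filtering applies to evaluation/visual subsets.
#'
#' @param profiles named list of profiles.
#' @param drop_empty drop profiles with zero terms.
#' @param min_terms minimum number of annotated terms to retain.
#' @param no_phenotype_term optional term id; profiles annotated with only
#'   this term are dropped.
#' @return Filtered named list of profiles.
#' @export
filter_cohort <- function(profiles, drop_empty = TRUE, min_terms = 0,
                          no_phenotype_term = NULL) {
  keep <- rep(TRUE, length(profiles))
  nterm <- vapply(profiles, function(p) length(p$terms), integer(1))
  if (!is.null(no_phenotype_term)) {
    only_np <- vapply(profiles, function(p) {
      length(p$terms) > 0 && all(p$terms == no_phenotype_term)
    }, logical(1))
    if (any(only_np)) {
      message("dropping ", sum(only_np),
              " profile(s) annotated only with the no-phenotype term")
    }
    keep <- keep & !only_np
  }
  if (drop_empty && any(keep & nterm == 0)) {
    message("dropping ", sum(keep & nterm == 0), " empty profile(s)")
    keep <- keep & nterm > 0
  }
  if (min_terms > 0 && any(keep & nterm < min_terms)) {
    message("dropping ", sum(keep & nterm < min_terms),
            " profile(s) with fewer than ", min_terms, " terms")
    keep <- keep & nterm >= min_terms
  }
  if (!any(keep)) stop("all profiles filtered out")
  profiles[keep]
}
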