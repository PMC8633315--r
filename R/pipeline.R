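# End-to-end pipeline: simulate or read inputs, encode, compute neighbors,
# embed, project diseases and evaluate, writing every artifact plus a run
# manifest with seeds, parameters and input checksums.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] to simulate inputs, or `NULL`
#'   to read them from paths.
#' @param ontology_path,annotations_path,metadata_path,diseases_path input
#'   file paths (used when `synthetic` is `NULL`).
#' @param encoding `"nonbinary"` or `"binary"`.
#' @param d embedding dimension.
#' @param embed_seed seed for the embedding layout.
#' @param min_dist,n_neighbors embedding parameters.
#' @param k_grid neighbor-count grid for prediction calibration.
#' @param recovery_k neighbor depth for causal-gene recovery.
#' @param jaccard_k neighbor depth for embedding-consistency Jaccard.
#' @param min_terms,drop_empty evaluation-cohort filters (encodings are
#'   always computed on the full cohort; filters shape the evaluation
#'   subset only).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            ontology_path = NULL, annotations_path = NULL,
                            metadata_path = NULL, diseases_path = NULL,
                            encoding = "nonbinary", d = 2L,
                            embed_seed = 1L, min_dist = 0.2,
                            n_neighbors = 15L, k_grid = 1:20,
                            recovery_k = 15L, jaccard_k = 15L,
                            min_terms = 0L, drop_empty = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or read inputs, encode the cohort (full cohort,
#' unfiltered), compute exact neighbors, embed, project diseases, and
#' evaluate (k calibration, same-gene statistics, causal-gene recovery).
#' All artifacts are written under `out_dir` together with
#' `manifest.json` recording package version, seeds, parameters and md5
#' checksums of every artifact. Identical config and inputs give an
#' identical manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(cfg$synthetic)) {
    ontology <- stage("simulate", generate_ontology(cfg$synthetic))
    cohort <- stage("simulate", generate_cohort(ontology, cfg$synthetic))
    diseases <- stage("simulate",
                      generate_diseases(cohort, ontology, cfg$synthetic))
    write_obo(ontology, file.path(out_dir, "ontology.obo"))
    write_annotations(cohort, file.path(out_dir, "annotations.tsv"),
                      file.path(out_dir, "metadata.tsv"))
    write_diseases(diseases, file.path(out_dir, "diseases.json"))
    jsonlite::write_json(unclass(cfg$synthetic),
                         file.path(out_dir, "synthetic_config.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    ontology <- stage("read", {
      if (is.null(cfg$ontology_path) || !file.exists(cfg$ontology_path)) {
        stop("ontology path missing: ",
             if (is.null(cfg$ontology_path)) "(unset)"
             else cfg$ontology_path)
      }
      parse_obo(cfg$ontology_path)
    })
    cohort <- stage("read",
                    read_annotations(cfg$annotations_path,
                                     cfg$metadata_path))
    diseases <- if (!is.null(cfg$diseases_path)) {
      stage("read", read_diseases(cfg$diseases_path))
    } else {
      list()
    }
  }
  message("cohort: ", length(cohort), " models, ",
          length(unique(vapply(cohort, function(p) p$marker_id,
                               character(1)))), " markers, ",
          sum(vapply(cohort, function(p) length(p$terms), integer(1))),
          " annotations, ",
          length(unique(unlist(lapply(cohort, function(p) p$terms)))),
          " distinct terms")

  priors <- stage("encode", term_priors(ontology, cohort))
  eval_cohort <- stage("encode",
                       filter_cohort(cohort, drop_empty = cfg$drop_empty,
                                     min_terms = cfg$min_terms))
  mat <- stage("encode",
               encode_cohort(eval_cohort, ontology, priors,
                             encoding = cfg$encoding, normalize = TRUE))
  write_matrix_tsv(mat, file.path(out_dir, "encoded_matrix.tsv"))

  kmax <- max(max(cfg$k_grid), cfg$n_neighbors)
  nn <- stage("neighbors", knn_exact(mat, kmax, exclude_self = TRUE))
  write_neighbors_tsv(nn, file.path(out_dir, "neighbors.tsv"))

  emb <- stage("embed",
               embed_nonlinear(nn, d = cfg$d, seed = cfg$embed_seed,
                               min_dist = cfg$min_dist))
  write_embedding_tsv(emb, file.path(out_dir, "embedding.tsv"))

  nn_emb <- stage("neighbors", knn_exact(emb$coords, kmax))
  report <- stage("evaluate",
                  calibrate_k(mat, list(original = nn,
                                        embedding = nn_emb),
                              cfg$k_grid))
  same_gene <- stage("evaluate", same_gene_neighbor_fraction(
    eval_cohort, nn, k = cfg$n_neighbors))

  recovery <- NULL
  disease_proj <- NULL
  if (length(diseases)) {
    eval_dis <- Filter(function(d) length(d$terms) > 0, diseases)
    dmat <- stage("project",
                  encode_cohort(eval_dis, ontology, priors,
                                encoding = cfg$encoding,
                                normalize = TRUE))
    dnn <- stage("project", knn_query(dmat, mat, k = cfg$recovery_k))
    disease_proj <- t(vapply(seq_along(eval_dis), function(i) {
      project_disease_vector(emb, dnn$nn_ids[i, ], k = cfg$recovery_k)
    }, numeric(cfg$d)))
    rownames(disease_proj) <- names(eval_dis)
    write.table(
      data.frame(entity_id = rownames(disease_proj), disease_proj),
      file.path(out_dir, "disease_projection.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    recovery <- stage("evaluate",
                      gene_recovery_at_k(eval_dis, eval_cohort, dnn,
                                         k = cfg$recovery_k))
  }

  summary <- list(
    n_models = length(cohort), n_evaluated = nrow(mat),
    optimal_k = as.list(report$optimal_k),
    mean_error_at_optimal = as.list(apply(report$mean_error, 1, min)),
    same_gene_observed = same_gene$overall$observed,
    same_gene_null = same_gene$overall$null,
    gene_recovery = if (!is.null(recovery)) recovery$proportion else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  artifacts <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenospace")),
    seeds = list(synthetic = if (!is.null(cfg$synthetic))
      cfg$synthetic$seed else NULL, embedding = cfg$embed_seed),
    params = list(encoding = cfg$encoding, d = cfg$d,
                  min_dist = cfg$min_dist, n_neighbors = cfg$n_neighbors,
                  recovery_k = cfg$recovery_k),
    artifacts = as.list(setNames(
      as.character(tools::md5sum(file.path(out_dir, artifacts))),
      artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ontology = ontology, cohort = cohort,
                 diseases = diseases, matrix = mat, neighbors = nn,
                 embedding = emb, report = report,
                 same_gene = same_gene, recovery = recovery,
                 disease_projection = disease_proj,
                 manifest = manifest))
}
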