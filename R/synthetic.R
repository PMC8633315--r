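# Seeded synthetic-data generator: ontologies (rooted is-a DAGs with
# token-structured names), model cohorts (per-gene phenotype signatures,
# skewed multiplicities and annotation counts) and diseases (noisy subsets
# of gene signatures with causal-gene labels and free-text descriptions).
# Same config => identical outputs; all randomness flows from cfg$seed.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the broad shape of curated mouse phenotype cohorts: a
#' few hundred ontology terms, genes with a right-skewed number of models
#' each (truncated power law, mean about 3), per-gene phenotype signatures
#' whose sizes follow a right-skewed (geometric) law so that annotation
#' counts are strongly right-skewed, and diseases whose term sets are
#' noisy subsets of one gene's signature.
#'
#' @param seed integer master seed.
#' @param n_terms number of ontology terms.
#' @param branching tree branching factor of the ontology scaffold.
#' @param extra_parent_prob probability a non-root term gains a second
#'   parent (turns the tree into a DAG).
#' @param n_genes number of genes.
#' @param multiplicity_exponent power-law exponent of models-per-gene.
#' @param multiplicity_max maximum models per gene.
#' @param signature_size mean per-gene signature size (per-gene sizes are
#'   1 + geometric, giving the right-skewed annotation-count law).
#' @param retention_model probability a model keeps each signature term.
#' @param noise_rate mean number of extra uniform random terms per model
#'   (Poisson).
#' @param n_diseases number of diseases.
#' @param retention_disease probability a disease keeps each signature
#'   term.
#' @param disease_noise_rate mean extra random terms per disease.
#' @param translation_swap_prob probability a kept disease term is
#'   replaced by a random sibling (emulating cross-ontology mapping
#'   error).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_terms = 500L, branching = 3L,
                             extra_parent_prob = 0.08, n_genes = 50L,
                             multiplicity_exponent = 1.5,
                             multiplicity_max = 20L, signature_size = 8L,
                             retention_model = 0.8, noise_rate = 1,
                             n_diseases = 100L, retention_disease = 0.8,
                             disease_noise_rate = 0.5,
                             translation_swap_prob = 0.05) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              branching = as.integer(branching),
              extra_parent_prob = extra_parent_prob,
              n_genes = as.integer(n_genes),
              multiplicity_exponent = multiplicity_exponent,
              multiplicity_max = as.integer(multiplicity_max),
              signature_size = as.integer(signature_size),
              retention_model = retention_model, noise_rate = noise_rate,
              n_diseases = as.integer(n_diseases),
              retention_disease = retention_disease,
              disease_noise_rate = disease_noise_rate,
              translation_swap_prob = translation_swap_prob)
  probs <- c(cfg$extra_parent_prob, cfg$retention_model,
             cfg$retention_disease, cfg$translation_swap_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_terms < 1 || cfg$branching < 1 || cfg$n_genes < 1 ||
      cfg$multiplicity_max < 1 || cfg$signature_size < 1 ||
      cfg$n_diseases < 0) {
    stop("sizes must be positive")
  }
  if (cfg$noise_rate < 0 || cfg$disease_noise_rate < 0) {
    stop("noise rates must be non-negative")
  }
  structure(cfg, class = "synthetic_config")
}

syllables <- c("ba", "cor", "del", "fi", "gal", "hu", "ka", "lem", "mi",
               "nor", "pa", "quo", "ris", "su", "tev", "ul", "vo", "wex",
               "yal", "zem", "bro", "cli", "dun", "fer", "gim", "hol",
               "jat", "kel", "lum", "mond")

random_token <- function() {
  paste(sample(syllables, 2, replace = TRUE), collapse = "")
}

#' Generate a synthetic rooted is-a ontology
#'
#' Builds a breadth-first tree with the configured branching factor, then
#' grants each non-root term an extra parent (chosen uniformly among
#' earlier-created terms, which cannot be descendants, keeping the graph
#' acyclic) with probability `extra_parent_prob`. Term names are composed
#' of seeded syllable tokens with one token inherited from the tree
#' parent, so lineage-related terms share text, giving the k-mer text
#' engine a real signal.
#'
#' @param cfg a [synthetic_config()].
#' @return An `ontology` with `cfg$n_terms` terms and a single root.
#' @export
generate_ontology <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_terms
    ids <- sprintf("S:%05d", seq_len(n))
    parents <- setNames(vector("list", n), ids)
    name_tokens <- vector("list", n)
    used_names <- character(0)
    name <- setNames(character(n), ids)
    def <- setNames(character(n), ids)
    for (i in seq_len(n)) {
      if (i == 1) {
        tree_parent <- integer(0)
        inherited <- character(0)
      } else {
        tree_parent <- ((i - 2) %/% cfg$branching) + 1
        inherited <- sample(name_tokens[[tree_parent]], 1)
      }
      repeat {
        toks <- c(inherited, replicate(2, random_token()))
        nm <- paste(toks, collapse = " ")
        if (!nm %in% used_names) break
      }
      used_names <- c(used_names, nm)
      name_tokens[[i]] <- toks
      name[i] <- nm
      def[i] <- paste("A phenotype of", nm, "involving", random_token(),
                      random_token())
      extra <- integer(0)
      if (i > 2 && runif(1) < cfg$extra_parent_prob) {
        cand <- setdiff(seq_len(i - 1), tree_parent)
        if (length(cand)) extra <- cand[sample.int(length(cand), 1)]
      }
      parents[[i]] <- ids[c(tree_parent, extra)]
    }
    new_ontology(ids, name, def, NULL, NULL, parents)
  })
}

sample_terms <- function(ids, size, weights) {
  size <- min(size, length(ids))
  if (size == 0) return(character(0))
  ids[sample.int(length(ids), size, prob = weights)]
}

#' Generate a synthetic cohort of mouse models
#'
#' Genes receive a multiplicity drawn from a truncated power law (many
#' singletons, few heavily studied genes) and a leaf-biased phenotype
#' signature (term sampling probability proportional to
#' `1 / (1 + #descendants)`, favoring specific terms as real curation
#' does). Each model keeps each signature term with probability
#' `retention_model` and gains `Poisson(noise_rate)` uniform random
#' terms; zygosity, background, source and life stage are drawn
#' categorically. The per-gene signatures are attached as the
#' `"signatures"` attribute for downstream disease generation.
#'
#' @param ontology an `ontology`, typically from [generate_ontology()].
#' @param cfg a [synthetic_config()].
#' @return Named list of model [phenotype_profile()]s with attributes
#'   `signatures` (named list per gene) and `genes`.
#' @export
generate_cohort <- function(ontology, cfg) {
  if (cfg$signature_size > length(ontology$ids)) {
    stop("signature_size exceeds the number of ontology terms")
  }
  with_seed(cfg$seed + 1L, {
    candidates <- setdiff(ontology$ids, ontology$roots)
    if (!length(candidates)) candidates <- ontology$ids
    ndesc <- descendant_counts(ontology)[candidates]
    lw <- 1 / (1 + ndesc)
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    mult <- sample(seq_len(cfg$multiplicity_max), cfg$n_genes,
                   replace = TRUE,
                   prob = seq_len(cfg$multiplicity_max) ^
                     (-cfg$multiplicity_exponent))
    sizes <- pmax(1, 1 + stats::rgeom(cfg$n_genes,
                                      prob = 1 / cfg$signature_size))
    signatures <- setNames(lapply(seq_len(cfg$n_genes), function(g) {
      sort(sample_terms(candidates, sizes[g], lw))
    }), genes)
    profiles <- list()
    counter <- 0L
    for (g in seq_len(cfg$n_genes)) {
      for (m in seq_len(mult[g])) {
        counter <- counter + 1L
        keep <- signatures[[g]][runif(length(signatures[[g]])) <
                                  cfg$retention_model]
        extra <- sample_terms(candidates, rpois(1, cfg$noise_rate),
                              NULL)
        profiles[[counter]] <- phenotype_profile(
          sprintf("M%05d", counter),
          terms = union(keep, extra), kind = "model",
          marker_id = genes[g],
          zygosity = sample(c("hom", "het"), 1),
          background = sample(c("C57BL/6N", "129S5", "BALB/c"), 1),
          source = sample(c("literature", "screen"), 1),
          life_stage = sample(c("embryonic", "early-adult",
                                "late-adult"), 1))
      }
    }
    cohort <- name_cohort(profiles)
    attr(cohort, "signatures") <- signatures
    attr(cohort, "genes") <- genes
    cohort
  })
}

#' Generate synthetic diseases with planted causal genes
#'
#' Each disease picks one causal gene uniformly; its term set is the
#' gene's signature sampled at `retention_disease`, plus
#' `Poisson(disease_noise_rate)` uniform random terms, with each kept
#' term replaced by a random sibling with probability
#' `translation_swap_prob` (emulating cross-ontology translation error).
#' The description concatenates term names, the gene id and filler
#' tokens.
#'
#' @param cohort output of [generate_cohort()] (its `signatures`
#'   attribute provides the per-gene signatures).
#' @param ontology the same `ontology`.
#' @param cfg a [synthetic_config()].
#' @return Named list of disease [phenotype_profile()]s.
#' @export
generate_diseases <- function(cohort, ontology, cfg) {
  signatures <- attr(cohort, "signatures")
  if (is.null(signatures)) stop("cohort lacks the signatures attribute")
  genes <- names(signatures)
  with_seed(cfg$seed + 2L, {
    diseases <- lapply(seq_len(cfg$n_diseases), function(i) {
      g <- sample(genes, 1)
      sig <- signatures[[g]]
      keep <- sig[runif(length(sig)) < cfg$retention_disease]
      if (length(keep) && cfg$translation_swap_prob > 0) {
        keep <- vapply(keep, function(t) {
          if (runif(1) < cfg$translation_swap_prob) {
            sibs <- setdiff(unique(unlist(
              ontology$children[ontology$parents[[t]]])), t)
            if (length(sibs)) return(sibs[sample.int(length(sibs), 1)])
          }
          t
        }, character(1), USE.NAMES = FALSE)
      }
      extra <- sample_terms(setdiff(ontology$ids, ontology$roots),
                            rpois(1, cfg$disease_noise_rate), NULL)
      terms <- union(keep, extra)
      descr <- paste("A synthetic disorder of", random_token(),
                     paste(unique(ontology$name[sort(terms)]),
                           collapse = " "),
                     "linked to", g)
      phenotype_profile(sprintf("D%04d", i), terms = terms,
                        kind = "disease", causal_genes = g,
                        description = descr)
    })
    name_cohort(diseases)
  })
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: seed", x$seed, "-", x$n_terms, "terms,",
      x$n_genes, "genes,", x$n_diseases, "diseases\n")
  invisible(x)
}
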