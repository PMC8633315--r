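# Ontology container: an immutable rooted is-a DAG with per-term text fields.
# Terms are kept in lexicographic id order and the topological order and
# reflexive ancestor sets are precomputed at construction, so downstream
# encoders can treat lookups as O(1).

#' Construct an ontology object from per-term fields
#'
#' Low-level constructor used by [parse_obo()] and the synthetic generator.
#' Validates the is-a graph (acyclicity, resolvable parents, at least one
#' root) and precomputes children, a deterministic topological order
#' (parents before children, ties broken by term id) and reflexive ancestor
#' closures.
#'
#' @param ids character vector of unique term ids.
#' @param name named character vector of term labels (names = ids).
#' @param def named character vector of definitions ("" allowed).
#' @param synonyms named list of character vectors of synonyms.
#' @param comment named character vector of comments ("" allowed).
#' @param parents named list of character vectors of is-a parent ids.
#' @return An object of class `ontology`.
#' @export
new_ontology <- function(ids, name, def = NULL, synonyms = NULL,
                         comment = NULL, parents) {
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", ids[duplicated(ids)][1])
  }
  ids <- sort(ids)
  fill_chr <- function(x) {
    out <- setNames(character(length(ids)), ids)
    if (!is.null(x)) out[names(x)] <- unlist(x)
    out
  }
  name <- fill_chr(name)
  def <- fill_chr(def)
  comment <- fill_chr(comment)
  syn <- setNames(vector("list", length(ids)), ids)
  for (i in ids) syn[[i]] <- character(0)
  if (!is.null(synonyms)) for (i in names(synonyms)) syn[[i]] <- synonyms[[i]]
  par <- setNames(vector("list", length(ids)), ids)
  for (i in ids) par[[i]] <- character(0)
  for (i in names(parents)) par[[i]] <- sort(unique(parents[[i]]))
  dangling <- setdiff(unlist(par), ids)
  if (length(dangling)) {
    stop("parent id does not resolve to a term: ", dangling[1])
  }

  children <- setNames(vector("list", length(ids)), ids)
  for (i in ids) children[[i]] <- character(0)
  for (i in ids) for (p in par[[i]]) children[[p]] <- c(children[[p]], i)
  children <- lapply(children, sort)

  # Kahn's algorithm with lexicographic tie-break
  indeg <- vapply(par, length, integer(1))
  ready <- sort(ids[indeg == 0L])
  if (!length(ready)) stop("ontology has no root; cycle involving term: ",
                           ids[1])
  topo <- character(length(ids))
  n_done <- 0L
  while (length(ready)) {
    t <- ready[1]
    ready <- ready[-1]
    n_done <- n_done + 1L
    topo[n_done] <- t
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (n_done < length(ids)) {
    stop("cycle detected in is-a graph involving term: ",
         ids[indeg > 0L][1])
  }

  anc <- setNames(vector("list", length(ids)), ids)
  for (t in topo) {
    anc[[t]] <- sort(unique(c(t, unlist(anc[par[[t]]], use.names = FALSE))))
  }

  structure(
    list(ids = ids, name = name, def = def, synonyms = syn,
         comment = comment, parents = par, children = children,
         roots = sort(ids[vapply(par, length, integer(1)) == 0L]),
         order = topo, ancestors = anc),
    class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", length(x$ids), "terms,",
      sum(lengths(x$parents)), "is-a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Number of terms in an ontology
#' @param x an `ontology`.
#' @export
length.ontology <- function(x) length(x$ids)

strip_obo_quotes <- function(x) {
  # def/synonym payloads are quoted and may carry trailing [xrefs]/scope
  if (grepl('"', x)) {
    x <- sub('^[^"]*"', "", x)
    x <- sub('"[^"]*$', "", x)
  }
  x
}

#' Parse an OBO flat file into an ontology
#'
#' Reads the OBO 1.2/1.4 flat-file format, keeping `[Term]` stanzas only.
#' Only `is_a` tags become edges; `name`, `def`, `synonym` and `comment`
#' payloads are captured verbatim (quotes stripped from def/synonym).
#' Obsolete terms are dropped entirely. Other relationship tags
#' (`relationship:` etc.) are ignored with a warning the first time one is
#' seen.
#'
#' @param x path to an OBO file, or a character vector of OBO text lines
#'   (a single string containing newlines is split).
#' @return An [new_ontology()] object.
#' @export
parse_obo <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  stanza_starts <- grep("^\\[.*\\]$", lines)
  term_ids <- character(0)
  name <- character(0); def <- character(0); comment <- character(0)
  synonyms <- list(); parents <- list()
  other_rel_seen <- FALSE
  n_obsolete <- 0L

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    block <- lines[seq(stanza_starts[s] + 1L, bounds[s + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    tags <- sub(":.*$", "", block)
    vals <- trimws(sub("^[^:]+:", "", block))
    if (any(tags == "is_obsolete" & tolower(vals) == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop("[Term] stanza without id tag")
    term_ids <- c(term_ids, id)
    nm <- vals[tags == "name"]
    name[id] <- if (length(nm)) nm[1] else ""
    df <- vals[tags == "def"]
    def[id] <- if (length(df)) strip_obo_quotes(df[1]) else ""
    cm <- vals[tags == "comment"]
    comment[id] <- if (length(cm)) cm[1] else ""
    synonyms[[id]] <- vapply(vals[tags == "synonym"], strip_obo_quotes,
                             character(1), USE.NAMES = FALSE)
    isa <- vals[tags == "is_a"]
    parents[[id]] <- trimws(sub("!.*$", "", isa))
    if (!other_rel_seen && any(tags == "relationship")) {
      warning("non-is_a relationship tags ignored")
      other_rel_seen <- TRUE
    }
  }
  if (n_obsolete > 0) {
    message("dropped ", n_obsolete, " obsolete term(s)")
  }
  new_ontology(term_ids, name, def, synonyms, comment, parents)
}

#' Write an ontology as a minimal OBO flat file
#'
#' Emits the dialect read back by [parse_obo()]: id, name, def, synonym,
#' comment and is_a tags. Round-trips the term set and edge set exactly.
#'
#' @param ontology an `ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ontology$ids) {
    out <- c("[Term]", paste0("id: ", id))
    if (nzchar(ontology$name[[id]])) {
      out <- c(out, paste0("name: ", ontology$name[[id]]))
    }
    if (nzchar(ontology$def[[id]])) {
      out <- c(out, paste0('def: "', ontology$def[[id]], '" []'))
    }
    for (s in ontology$synonyms[[id]]) {
      out <- c(out, paste0('synonym: "', s, '" EXACT []'))
    }
    if (nzchar(ontology$comment[[id]])) {
      out <- c(out, paste0("comment: ", ontology$comment[[id]]))
    }
    for (p in ontology$parents[[id]]) {
      out <- c(out, paste0("is_a: ", p))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

check_terms <- function(ontology, terms) {
  bad <- setdiff(terms, ontology$ids)
  if (length(bad)) stop("unknown ontology term: ", bad[1])
}

#' Reflexive transitive ancestor closure of a term set
#'
#' Follows is-a edges toward the roots; the input terms are included in the
#' result. A more specific annotation always implies its more general
#' ancestors (e.g. increased heart weight implies abnormal heart weight,
#' which implies a cardiovascular system phenotype).
#'
#' @param ontology an `ontology`.
#' @param terms character vector of term ids.
#' @return Sorted character vector of term ids.
#' @export
ancestor_closure <- function(ontology, terms) {
  terms <- unique(terms)
  check_terms(ontology, terms)
  sort(unique(unlist(ontology$ancestors[terms], use.names = FALSE)))
}

#' Deterministic topological order of an ontology
#'
#' Every parent precedes each of its children; ties are broken by
#' lexicographic term id, so the order is reproducible across runs.
#'
#' @param ontology an `ontology`.
#' @return Character vector of all term ids.
#' @export
topological_order <- function(ontology) ontology$order

#' Concatenated text description of a term
#'
#' Joins name, definition, synonyms and comment with single spaces; empty
#' fields contribute nothing. This is the text used for k-mer based term
#' similarity.
#'
#' @param ontology an `ontology`.
#' @param term a single term id.
#' @return A character scalar.
#' @export
term_text <- function(ontology, term) {
  check_terms(ontology, term)
  parts <- c(ontology$name[[term]], ontology$def[[term]],
             ontology$synonyms[[term]], ontology$comment[[term]])
  paste(parts[nzchar(parts)], collapse = " ")
}

#' Cohort-based term prior probabilities
#'
#' For each ontology term `t`, estimates the probability that a random
#' profile from the cohort is annotated (after ancestor closure) with `t`,
#' using the smoothed estimator `(n_t + a) / (N + 2a)` with pseudocount
#' `a`. Because counting is done on ancestor-closed sets, the result is
#' monotone along is-a edges (`prior(parent) >= prior(child)`) and every
#' prior lies strictly in (0, 1).
#'
#' @param ontology an `ontology`.
#' @param profiles list of [phenotype_profile()] objects (may be empty).
#' @param pseudocount positive smoothing constant; default 1.
#' @return Named numeric vector over all ontology terms, with attributes
#'   `pseudocount` and `cohort_size`.
#' @export
term_priors <- function(ontology, profiles, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0) {
    stop("pseudocount must be a positive number")
  }
  n <- setNames(numeric(length(ontology$ids)), ontology$ids)
  for (p in profiles) {
    if (length(p$terms)) {
      cl <- ancestor_closure(ontology, p$terms)
      n[cl] <- n[cl] + 1
    }
  }
  N <- length(profiles)
  prior <- (n + pseudocount) / (N + 2 * pseudocount)
  attr(prior, "pseudocount") <- pseudocount
  attr(prior, "cohort_size") <- N
  prior
}

# number of strict descendants per term (used for leaf-biased sampling)
descendant_counts <- function(ontology) {
  n <- setNames(integer(length(ontology$ids)), ontology$ids)
  for (t in ontology$ids) {
    anc <- setdiff(ontology$ancestors[[t]], t)
    n[anc] <- n[anc] + 1L
  }
  n
}
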