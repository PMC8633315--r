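# Shared fixtures: tiny hand-written OBO ontologies and profile builders.

chain_obo <- paste(
  "format-version: 1.2", "",
  "[Term]", "id: MP:A", "name: cardiovascular system phenotype", "",
  "[Term]", "id: MP:B", "name: abnormal heart weight", "is_a: MP:A", "",
  "[Term]", "id: MP:C", "name: increased heart weight", "is_a: MP:B", "",
  sep = "\n")

diamond_obo <- paste(
  "format-version: 1.2", "",
  "[Term]", "id: T:A", "name: root", "",
  "[Term]", "id: T:B", "name: left branch", "is_a: T:A", "",
  "[Term]", "id: T:C", "name: right branch", "is_a: T:A", "",
  "[Term]", "id: T:D", "name: leaf", "is_a: T:B", "is_a: T:C", "",
  sep = "\n")

chain_ontology <- function() parse_obo(chain_obo)
diamond_ontology <- function() parse_obo(diamond_obo)

# profile with a random term subset of an ontology
random_profile <- function(id, ontology, n_terms) {
  phenotype_profile(id, terms = sample(ontology$ids,
                                       min(n_terms, length(ontology$ids))))
}

# small synthetic ontology for property checks
small_ontology <- function(seed = 1, n_terms = 120) {
  generate_ontology(synthetic_config(seed = seed, n_terms = n_terms))
}

# independent cosine-similarity oracle for text searches
oracle_cosine <- function(a, b, w) {
  keys <- union(names(a$counts), names(b$counts))
  wt <- ifelse(keys %in% names(w$weights), w$weights[keys], w$unseen)
  va <- ifelse(keys %in% names(a$counts), a$counts[keys], 0) * wt
  vb <- ifelse(keys %in% names(b$counts), b$counts[keys], 0) * wt
  if (all(va == 0) || all(vb == 0)) return(0)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# exact hypergeometric enumeration oracle for two-sided Fisher tests,
# built from binomial-coefficient logs (independent of stats::fisher.test)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(m, k)
  av <- lo:hi
  logp <- lchoose(m, av) + lchoose(n, k - av) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[av == a] * (1 + 1e-7)])
}
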