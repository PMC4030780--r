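#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name` and `is_a` tags — the subset of
#' OBO needed for phenotype-term closure computations. Obsolete terms and
#' relationship types other than `is_a` are ignored.
#'
#' @param path Path to an OBO file.
#' @return A list of class `hpo_ontology`: `terms` (character vector of ids),
#'   `names` (named character vector), `parents` (named list of parent id
#'   vectors) and `roots` (ids with no parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  terms <- character(0); nm <- character(0); parents <- list()
  bounds <- c(term_starts, length(lines) + 1L)
  for (i in seq_along(term_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    if (any(grepl("^is_obsolete: *true", block))) next
    name <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    terms <- c(terms, id)
    nm[id] <- name
    parents[[id]] <- isa
  }
  bad <- setdiff(unlist(parents), terms)
  if (length(bad) > 0) stop("is_a parent(s) not defined: ", paste(bad, collapse = ", "))
  roots <- terms[vapply(parents[terms], length, 0L) == 0]
  structure(list(terms = terms, names = nm, parents = parents, roots = roots),
            class = "hpo_ontology")
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(sprintf("hpo_ontology: %d terms, root(s): %s\n", length(x$terms),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Ancestor closure of a term set
#'
#' The set of the given terms plus all their `is_a` ancestors, excluding the
#' ontology root(s) (every pair of terms shares the root, so it carries no
#' information).
#'
#' @param terms Character vector of term ids.
#' @param ontology An `hpo_ontology`.
#' @return Character vector (sorted, unique) of the closure below the root.
#' @export
term_closure <- function(terms, ontology) {
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown) > 0) stop("unknown ontology term: ", unknown[1])
  seen <- character(0)
  frontier <- unique(terms)
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(ontology$parents[frontier])), seen)
  }
  sort(setdiff(seen, ontology$roots))
}

#' Phenotype overlap between two HPO term sets
#'
#' Overlap is measured on ancestor closures (root excluded):
#' `score = |closure(A) n closure(B)| / min(|closure(A)|, |closure(B)|)`.
#' Identical non-empty sets score 1; sets sharing only the root score 0.
#' Either set empty gives score 0 and no match.
#'
#' @param a_terms,b_terms Character vectors of HPO term ids.
#' @param ontology An `hpo_ontology`.
#' @param cutoff Match threshold on the score.
#' @return List with `score` (in `[0, 1]`) and `match` (logical,
#'   `score >= cutoff`).
#' @export
phenotype_overlap <- function(a_terms, b_terms, ontology, cutoff = 0.5) {
  a_terms <- a_terms[nzchar(a_terms)]
  b_terms <- b_terms[nzchar(b_terms)]
  if (length(a_terms) == 0 || length(b_terms) == 0) {
    return(list(score = 0, match = FALSE))
  }
  ca <- term_closure(a_terms, ontology)
  cb <- term_closure(b_terms, ontology)
  if (length(ca) == 0 || length(cb) == 0) return(list(score = 0, match = FALSE))
  score <- length(intersect(ca, cb)) / min(length(ca), length(cb))
  list(score = score, match = score >= cutoff)
}
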