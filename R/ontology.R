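# Ontology parsing, ancestor sets and term similarities over the is_a DAG.

#' Parse an OBO ontology restricted to subclass (is_a) relationships
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 flat file and builds a directed
#' acyclic graph of terms in which each edge points from a child term to one
#' of its direct `is_a` parents. All other relationship types (`part_of`,
#' `develops_from`, ...) are ignored: similarity is defined over the subclass
#' hierarchy only.
#'
#' Obsolete terms (`is_obsolete: true`) are dropped from the term set by
#' default; with `keep_obsolete = TRUE` they are retained in the term list and
#' flagged, but their outgoing `is_a` edges are still discarded so they never
#' contribute ancestors.
#'
#' @param path Path to an OBO file.
#' @param keep_obsolete Keep obsolete terms in the graph (flagged, edge-less)?
#' @return An object of class `ontology`: a list with elements `terms`
#'   (character vector of term ids), `names` (named character vector of
#'   human-readable labels), `parents` (named list, child id -> character
#'   vector of direct is_a parent ids) and `obsolete` (character vector).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: A:1", "name: root", "",
#'              "[Term]", "id: A:2", "name: child", "is_a: A:1 ! root"), obo)
#' g <- parse_obo(obo)
#' g$parents[["A:2"]]
#' @export
parse_obo <- function(path, keep_obsolete = FALSE) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", trimws(lines))
  if (length(term_starts) == 0L) {
    stop("no [Term] stanzas found in ", path)
  }
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  names(ends) <- stanza_starts
  ids <- character(0)
  labels <- character(0)
  parents <- list()
  obsolete <- character(0)
  for (s in term_starts) {
    e <- ends[as.character(s)]
    body <- lines[seq(s + 1L, length.out = max(0L, e - s))]
    id <- .obo_value(body, "id")
    if (is.na(id)) next
    nm <- .obo_value(body, "name")
    is_a <- .obo_values(body, "is_a")
    # strip trailing "! label" comments and modifier blocks
    is_a <- sub("\\s*(\\{[^}]*\\})?\\s*(!.*)?$", "", is_a)
    is_a <- trimws(is_a)
    is_a <- is_a[nzchar(is_a)]
    obs <- identical(tolower(.obo_value(body, "is_obsolete")), "true")
    if (obs) {
      if (!keep_obsolete) next
      obsolete <- c(obsolete, id)
      is_a <- character(0)
    }
    ids <- c(ids, id)
    if (!is.na(nm)) labels[id] <- nm
    parents[[id]] <- unique(is_a)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # drop dangling parents (terms filtered out, e.g. obsolete or cross-file refs
  # that are not themselves stanzas in this file)
  parents <- lapply(parents, function(p) p[p %in% ids])
  g <- structure(
    list(terms = ids,
         names = labels,
         parents = parents,
         obsolete = obsolete),
    class = "ontology"
  )
  .check_acyclic(g)
  g
}

.obo_value <- function(body, tag) {
  v <- .obo_values(body, tag)
  if (length(v) == 0L) NA_character_ else v[[1L]]
}

.obo_values <- function(body, tag) {
  pat <- paste0("^", tag, ":\\s*")
  hits <- grep(pat, body, value = TRUE)
  trimws(sub(pat, "", hits))
}

# Kahn's algorithm over is_a edges; stops naming a cycle member.
.check_acyclic <- function(graph) {
  indeg <- vapply(graph$parents[graph$terms], length, integer(1))
  names(indeg) <- graph$terms
  children <- .children_map(graph)
  # indeg here counts outgoing parents; peel terms with no unprocessed parents
  remaining <- indeg
  queue <- names(remaining)[remaining == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(graph$terms)) {
    member <- names(remaining)[remaining > 0L][1L]
    stop("cycle detected in is_a relationships involving term ", member)
  }
  invisible(TRUE)
}

# child -> parents inverted to parent -> children
.children_map <- function(graph) {
  children <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (ch in names(graph$parents)) {
    for (p in graph$parents[[ch]]) {
      children[[p]] <- c(children[[p]], ch)
    }
  }
  children
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology graph:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges,",
      length(x$obsolete), "obsolete\n")
  invisible(x)
}

.valid_terms <- function(graph) {
  setdiff(graph$terms, graph$obsolete)
}

#' Ancestor set of an ontology term
#'
#' Returns the reflexive transitive closure of a term over `is_a` edges: the
#' term itself plus every term reachable by repeatedly following subclass
#' links towards the root(s).
#'
#' @param graph An `ontology` object from [parse_obo()] or [make_toy_ontology()].
#' @param term A term id present in the graph.
#' @return Character vector of term ids (includes `term`), sorted.
#' @export
ancestors <- function(graph, term) {
  if (!term %in% graph$terms) {
    stop("unknown term: ", term)
  }
  out <- character(0)
  stack <- term
  while (length(stack) > 0L) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% out) next
    out <- c(out, t)
    stack <- c(stack, graph$parents[[t]])
  }
  sort(out)
}

# Ancestor sets for a set of terms (named list); single pass with memoisation
# in topological-ish order via recursion over the parents map.
.ancestor_sets <- function(graph, terms = graph$terms) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    a <- t
    for (p in graph$parents[[t]]) a <- union(a, get_anc(p))
    memo[[t]] <- a
    a
  }
  stats::setNames(lapply(terms, function(t) sort(get_anc(t))), terms)
}

#' Pairwise term similarity from ancestor sets
#'
#' Similarity between two ontology terms computed from their ancestor sets
#' A(t): `jaccard` is |A(t_i) n A(t_j)| / |A(t_i) u A(t_j)|; `cosine` is the
#' cosine of the binary indicator vectors of the two ancestor sets over the
#' full term axis, which reduces to
#' |A(t_i) n A(t_j)| / sqrt(|A(t_i)| * |A(t_j)|) because entries outside
#' either ancestor set contribute nothing. Both are symmetric, lie in [0, 1],
#' and equal 1 exactly when the ancestor sets coincide.
#'
#' @param graph An `ontology` object.
#' @param t_i,t_j Term ids; must be present and not obsolete.
#' @param measure `"cosine"` (default) or `"jaccard"`.
#' @return A similarity in `[0, 1]`.
#' @export
term_similarity <- function(graph, t_i, t_j, measure = c("cosine", "jaccard")) {
  measure <- match.arg(measure)
  for (t in c(t_i, t_j)) {
    if (!t %in% graph$terms) stop("unknown term: ", t)
    if (t %in% graph$obsolete) stop("obsolete term not allowed: ", t)
  }
  a <- ancestors(graph, t_i)
  b <- ancestors(graph, t_j)
  .set_similarity(a, b, measure)
}

.set_similarity <- function(a, b, measure) {
  inter <- length(intersect(a, b))
  if (measure == "jaccard") {
    inter / length(union(a, b))
  } else {
    inter / sqrt(length(a) * length(b))
  }
}

#' Expected sample-similarity matrix from an ontology mapping
#'
#' Broadcasts term-pair similarities through a sample-to-term mapping: entry
#' (k, l) is the similarity of the terms the two samples map to, so it depends
#' only on the term pair. Term-pair similarities are computed once per
#' unordered pair, guaranteeing an exactly symmetric matrix with unit
#' diagonal.
#'
#' @param graph An `ontology` object.
#' @param mapping A sample mapping data frame (see [read_mapping_tsv()]):
#'   columns `sample_id`, `term_id`, optional `group`, `batch`.
#' @param measure Term similarity measure, `"cosine"` (default) or `"jaccard"`.
#' @return A symmetric numeric matrix with sample ids as dimnames, values in
#'   `[0, 1]`, diagonal 1, with attribute `measure`.
#' @export
expected_similarity_matrix <- function(graph, mapping,
                                       measure = c("cosine", "jaccard")) {
  measure <- match.arg(measure)
  mapping <- validate_mapping(mapping, graph)
  terms <- unique(mapping$term_id)
  anc <- .ancestor_sets(graph, terms)
  nt <- length(terms)
  S <- matrix(1, nt, nt, dimnames = list(terms, terms))
  if (nt > 1L) {
    for (i in seq_len(nt - 1L)) {
      for (j in seq(i + 1L, nt)) {
        s <- .set_similarity(anc[[i]], anc[[j]], measure)
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  O <- S[mapping$term_id, mapping$term_id, drop = FALSE]
  dimnames(O) <- list(mapping$sample_id, mapping$sample_id)
  diag(O) <- 1
  attr(O, "measure") <- measure
  O
}

#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise `1 - sim`; a similarity of 1 (identical terms) maps to
#' distance 0.
#'
#' @param sim Numeric matrix with values in `[0, 1]`.
#' @return Matrix of distances in `[0, 1]` with zero diagonal.
#' @export
similarity_to_distance <- function(sim) {
  if (any(sim < -1e-12 | sim > 1 + 1e-12, na.rm = TRUE)) {
    stop("similarity values must lie in [0, 1]")
  }
  d <- 1 - sim
  if (!is.null(dim(d)) && nrow(d) == ncol(d)) diag(d) <- 0
  attr(d, "measure") <- attr(sim, "measure")
  d
}
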