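#' Ontology handling
#'
#' A minimal reader for OBO-format ontologies restricted to what phenotype
#' matching needs: `[Term]` stanzas with `id`, `name`, `is_a` parents,
#' `alt_id` aliases, `is_obsolete` and `replaced_by`. The is_a graph must
#' be a rooted DAG: acyclic, with every term reaching a single root.
#'
#' @name ontology
NULL

#' Build an ontology from terms and is_a edges
#'
#' @param terms character vector of term ids.
#' @param parents named list: term id -> character vector of is_a parents
#'   (the root has none).
#' @param names optional named character vector of term labels.
#' @param aliases optional named character vector alt_id -> primary id.
#' @return a list with class `ontology`: `terms`, `parents`, `root`,
#'   `names`, `aliases`, plus a memoized ancestor cache.
#' @export
ontology <- function(terms, parents, names = NULL, aliases = NULL) {
  terms <- unique(terms)
  for (t in names(parents)) {
    bad <- setdiff(parents[[t]], terms)
    if (length(bad)) stop("parent(s) of ", t, " not in ontology: ",
                          paste(bad, collapse = ", "))
  }
  roots <- terms[vapply(terms, function(t)
    length(parents[[t]]) == 0, logical(1))]
  if (length(roots) != 1)
    stop("ontology must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  # rootedness + acyclicity: level terms breadth-first from the root; a
  # term is placeable once all its parents are placed. Anything left over
  # sits on a cycle or is disconnected from the root.
  placed <- stats::setNames(rep(FALSE, length(terms)), terms)
  placed[roots] <- TRUE
  repeat {
    ready <- vapply(terms, function(t)
      !placed[[t]] && all(placed[parents[[t]]]), logical(1))
    if (!any(ready)) break
    placed[terms[ready]] <- TRUE
  }
  if (!all(placed))
    stop("is_a graph has a cycle or terms unreachable from the root: ",
         paste(terms[!placed], collapse = ", "))
  structure(list(terms = terms, parents = parents, root = roots,
                 names = names, aliases = aliases,
                 cache = new.env(parent = emptyenv())),
            class = "ontology")
}

#' Ancestors of a term (self-inclusive)
#'
#' @param onto an [ontology()].
#' @param term a term id.
#' @return character vector of ancestor ids, including `term` itself.
#' @export
term_ancestors <- function(onto, term) {
  cached <- onto$cache[[term]]
  if (!is.null(cached)) return(cached)
  seen <- character(0)
  frontier <- term
  steps <- 0
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier])), seen)
    steps <- steps + 1
    if (steps > length(onto$terms) + 1)
      stop("cycle detected in is_a graph near ", term)
  }
  onto$cache[[term]] <- seen
  seen
}

#' Resolve term ids through the alias map
#'
#' Obsolete/alternative ids are mapped to their primary id; unknown ids are
#' rejected with an error listing the offenders (never silently dropped).
#'
#' @param onto an [ontology()].
#' @param ids character vector of term ids.
#' @return character vector of primary ids.
#' @export
resolve_terms <- function(onto, ids) {
  out <- ids
  if (!is.null(onto$aliases)) {
    hit <- ids %in% names(onto$aliases)
    out[hit] <- onto$aliases[ids[hit]]
  }
  unknown <- setdiff(out, onto$terms)
  if (length(unknown))
    stop("unknown ontology term id(s): ", paste(unknown, collapse = ", "))
  out
}

#' Read an OBO-format ontology (is_a edges only)
#'
#' @param path an `.obo` file.
#' @return an [ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0); parents <- list(); labels <- character(0)
  aliases <- character(0)
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return()
    if (isTRUE(cur$obsolete)) {
      if (!is.null(cur$replaced_by))
        aliases[[cur$id]] <<- cur$replaced_by
      return()
    }
    terms <<- c(terms, cur$id)
    parents[[cur$id]] <<- cur$is_a
    if (!is.null(cur$name)) labels[[cur$id]] <<- cur$name
    for (a in cur$alt_id) aliases[[a]] <<- cur$id
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(is_a = character(0),
                                                  alt_id = character(0))
                          in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) < 3) next
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a,
                                          trimws(strsplit(val, "!")[[1]][1]))
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "replaced_by") cur$replaced_by <- val
  }
  flush(cur)
  ontology(terms, parents, names = labels, aliases = aliases)
}

#' Write an ontology in OBO format (fixture support)
#' @param onto an [ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  lines <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t))
    if (!is.null(onto$names) && t %in% names(onto$names))
      lines <- c(lines, paste0("name: ", onto$names[[t]]))
    for (p in onto$parents[[t]])
      lines <- c(lines, paste0("is_a: ", p))
    if (!is.null(onto$aliases)) {
      alts <- names(onto$aliases)[onto$aliases == t]
      for (a in alts) lines <- c(lines, paste0("alt_id: ", a))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read disease models from a TSV (disease_id, term_id)
#'
#' @param path TSV with a header; one row per annotation.
#' @param onto an [ontology()] used to resolve/validate term ids.
#' @return named list disease_id -> character vector of term ids.
#' @export
load_disease_models <- function(path, onto) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("disease_id", "term_id")
  df$term_id <- resolve_terms(onto, df$term_id)
  split(df$term_id, df$disease_id)
}
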