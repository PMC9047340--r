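#' Resnik information content and symmetric phenotype similarity
#'
#' Information content of a term is the negative natural log of its
#' annotation frequency across the disease corpus: `IC(t) = -ln(n_t / N)`
#' where `n_t` counts diseases annotated with `t` or any of its
#' descendants and `N` is the corpus size. The similarity of two terms is
#' the IC of their most informative common ancestor (MICA), and the
#' similarity of a query term set Q to a disease model D is the symmetric
#' Resnik score: each side averages, over its own terms, the best MICA IC
#' against the other side, and the two directions are averaged.
#'
#' @name similarity
NULL

#' Compute the information-content table for a disease corpus
#'
#' Annotations propagate to ancestors: a disease annotated with a term
#' implicitly carries all its ancestors. Terms annotating no disease get a
#' pseudo-count of 1 (IC = ln N) so queries using them stay finite.
#'
#' @param onto an [ontology()].
#' @param diseases named list disease_id -> term ids
#'   ([load_disease_models()]).
#' @param pseudo_count count assigned to unannotated terms.
#' @return a list with class `ic_table`: `ic` (named numeric over all
#'   terms, in nats), `n_diseases`.
#' @export
compute_ic <- function(onto, diseases, pseudo_count = 1) {
  n <- length(diseases)
  if (n == 0) stop("empty disease corpus")
  counts <- stats::setNames(numeric(length(onto$terms)), onto$terms)
  for (terms in diseases) {
    closure <- unique(unlist(lapply(resolve_terms(onto, terms),
                                    function(t) term_ancestors(onto, t))))
    counts[closure] <- counts[closure] + 1
  }
  counts[counts == 0] <- pseudo_count
  structure(list(ic = -log(counts / n), n_diseases = n), class = "ic_table")
}

#' IC of the most informative common ancestor of two terms
#'
#' @param t1,t2 term ids.
#' @param ic an `ic_table` from [compute_ic()].
#' @param onto an [ontology()].
#' @return non-negative IC in nats (0 when the root is the only common
#'   ancestor).
#' @export
mica_ic <- function(t1, t2, ic, onto) {
  key <- if (t1 <= t2) paste0(t1, "\r", t2) else paste0(t2, "\r", t1)
  pre <- onto$cache[[paste0("mica:", key)]]
  if (!is.null(pre)) return(pre)
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  val <- if (length(common)) max(ic$ic[common]) else 0
  onto$cache[[paste0("mica:", key)]] <- val
  val
}

#' Precompute pairwise MICA ICs for a set of terms
#'
#' Populates the memoization cache used by [mica_ic()] for every unordered
#' pair, mirroring the production shortcut of precalculating
#' `IC(MICA(t1, t2))` for all annotation terms.
#'
#' @param terms character vector of term ids.
#' @param ic an `ic_table`.
#' @param onto an [ontology()].
#' @return a symmetric matrix of MICA ICs (terms x terms).
#' @export
precompute_mica <- function(terms, ic, onto) {
  m <- matrix(0, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (i in seq_along(terms))
    for (j in i:length(terms))
      m[i, j] <- m[j, i] <- mica_ic(terms[i], terms[j], ic, onto)
  m
}

#' One-sided semantic similarity sim(Q -> D)
#'
#' The average, over the terms of `q_terms`, of the best MICA IC against
#' any term of `d_terms`. The normalizer is the iterated side's own term
#' count.
#'
#' @param q_terms,d_terms non-empty character vectors of term ids.
#' @param ic an `ic_table`.
#' @param onto an [ontology()].
#' @return non-negative similarity in nats.
#' @export
sim_one_sided <- function(q_terms, d_terms, ic, onto) {
  stopifnot(length(q_terms) > 0, length(d_terms) > 0)
  best <- vapply(q_terms, function(q)
    max(vapply(d_terms, function(d) mica_ic(q, d, ic, onto), numeric(1))),
    numeric(1))
  mean(best)
}

#' Symmetric Resnik phenotype similarity Phi(Q, D)
#'
#' The arithmetic mean of the two one-sided similarities; symmetric under
#' exchange of query and disease.
#'
#' @param q_terms,d_terms non-empty character vectors of term ids.
#' @param ic an `ic_table`.
#' @param onto an [ontology()].
#' @return non-negative similarity in nats.
#' @export
phi_similarity <- function(q_terms, d_terms, ic, onto) {
  (sim_one_sided(q_terms, d_terms, ic, onto) +
     sim_one_sided(d_terms, q_terms, ic, onto)) / 2
}

#' Best disease match for a gene
#'
#' The highest Phi(Q, D) over the diseases associated with the gene. A
#' gene with no associated disease gets Phi = 0, so its weight in the
#' priority score is `exp(0) = 1`: the variant still counts through its
#' sequence score alone.
#'
#' @param q_terms proband term ids.
#' @param gene a [gene_model()].
#' @param diseases named list disease_id -> term ids.
#' @param ic an `ic_table`.
#' @param onto an [ontology()].
#' @return list with `disease_id` (`NA` when none) and `phi`.
#' @export
best_disease_phi <- function(q_terms, gene, diseases, ic, onto) {
  ids <- intersect(gene$disease_ids, names(diseases))
  if (length(ids) == 0) return(list(disease_id = NA_character_, phi = 0))
  phis <- vapply(ids, function(d)
    phi_similarity(q_terms, diseases[[d]], ic, onto), numeric(1))
  best <- which.max(phis)
  list(disease_id = ids[[best]], phi = phis[[best]])
}
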