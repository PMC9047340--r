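#' The phenotype-aware priority score and variant ranking
#'
#' Each variant's score is the sum, over its affected genes, of the gene's
#' sequence deleteriousness weighted by the exponentiated phenotype
#' similarity of the proband terms to the gene's best-matching disease:
#' `PSV = sum_g delta(g) * exp(phi(Q, D_g))`. Variants are ranked by
#' descending score with a deterministic tie-break.
#'
#' @name prioritization
NULL

#' Score one variant from per-gene deltas and phenotype similarities
#'
#' @param v an `sv`.
#' @param delta_scores named list gene_id -> `delta_score`
#'   ([gene_delta()]) or bare numeric deltas.
#' @param phi_per_gene named list gene_id -> list(phi, disease_id) (or bare
#'   numerics; disease then `NA`).
#' @return a list with class `prioritized_sv`: `variant`, `psv`, and
#'   `contributions` sorted by decreasing contribution, each
#'   `(gene_id, delta, phi, disease_id, contribution)`.
#' @export
psv_score <- function(v, delta_scores, phi_per_gene) {
  genes <- names(delta_scores)
  contributions <- lapply(genes, function(g) {
    ds <- delta_scores[[g]]
    delta <- if (is.numeric(ds)) ds else ds$delta
    ph <- phi_per_gene[[g]]
    if (is.null(ph)) ph <- 0
    phi <- if (is.numeric(ph)) ph else ph$phi
    disease <- if (is.list(ph) && !is.null(ph$disease_id)) ph$disease_id
      else NA_character_
    list(gene_id = g, delta = delta, phi = phi, disease_id = disease,
         contribution = delta * exp(phi))
  })
  ord <- order(-vapply(contributions, function(x) x$contribution, numeric(1)),
               genes)
  contributions <- contributions[ord]
  structure(list(variant = v,
                 psv = sum(vapply(contributions, function(x) x$contribution,
                                  numeric(1))),
                 contributions = contributions,
                 rank = NA_integer_, median_rank = NA_real_),
            class = "prioritized_sv")
}

#' @export
print.prioritized_sv <- function(x, ...) {
  cat(sprintf("<prioritized %s PSV=%.4g rank=%s>\n", x$variant$id, x$psv,
              x$rank))
  for (ct in x$contributions)
    cat(sprintf("  %s: delta=%.3g phi=%.4g -> %.4g%s\n", ct$gene_id,
                ct$delta, ct$phi, ct$contribution,
                if (is.na(ct$disease_id)) "" else paste0(" (", ct$disease_id, ")")))
  invisible(x)
}

sort_key <- function(p) {
  v <- p$variant
  if (v$sv_type == "BND")
    c(v$adjacency$left$contig, sprintf("%012.0f", v$adjacency$left$pos), v$id)
  else
    c(v$region$contig, sprintf("%012.0f", v$region$start), v$id)
}

#' Rank scored variants
#'
#' Descending score; ties broken deterministically by (contig, start, id).
#' `rank` is the 1-based position under that order; `median_rank` is the
#' tie-aware rank where every member of a tied score group receives the
#' rank of the group's middle variant, mirroring the convention used when
#' benchmarking against tools with coarse scores.
#'
#' @param scored list of `prioritized_sv` ([psv_score()]).
#' @return the same list, sorted, with `rank` and `median_rank` filled in.
#' @export
rank_variants <- function(scored) {
  if (length(scored) == 0) return(scored)
  keys <- t(vapply(scored, sort_key, character(3)))
  ord <- order(-vapply(scored, function(p) p$psv, numeric(1)),
               keys[, 1], keys[, 2], keys[, 3])
  scored <- scored[ord]
  psvs <- vapply(scored, function(p) p$psv, numeric(1))
  for (i in seq_along(scored)) scored[[i]]$rank <- i
  grp <- cumsum(!duplicated(psvs))
  for (g in unique(grp)) {
    members <- which(grp == g)
    med <- members[ceiling(length(members) / 2)]
    for (i in members) scored[[i]]$median_rank <- med
  }
  scored
}
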