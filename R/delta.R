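#' Sequence deleteriousness score delta(g)
#'
#' Per-gene heuristic score of the predicted effect of an SV on gene
#' function and dosage. Rules differ by SV class:
#'
#' * DEL: whole transcript removed -> 1; coding/splice loss -> 1
#'   (frameshift) or 0.8 (in-frame exon loss); TSS loss -> 1; UTR ->
#'   `min(2 * len_SV / len_UTR, 1)`; intron -> 0; promoter -> 0.4.
#' * DUP/CNV gain: whole transcript duplicated -> copy-number gain (1 per
#'   extra copy, so a triplication scores 2); internal coding/splice
#'   disruption -> 1 (frameshift) or 0.8 (in-frame); tandem duplication
#'   extending beyond a transcript terminus leaves the primary linear
#'   sequence intact -> 0; UTR via the deletion formula; promoter 0.4.
#' * INV: transcript fully contained -> 0 (primary sequence unchanged);
#'   breakpoint disrupting the transcript, or some-but-not-all exons
#'   covered -> 1; wholly intronic -> 0; wholly within a UTR -> UTR
#'   formula; promoter-contained -> 0.4.
#' * INS: coding frameshift (length not a multiple of 3) -> 0.9, in-frame
#'   -> 0.2; splice-boundary insertion -> 0.9; UTR ->
#'   `min(len_INS / len_UTR, 1)`; promoter -> 0.4; elsewhere -> 0.
#' * BND: breakend anywhere in the transcript (coding, UTR or intron) -> 1;
#'   in the promoter -> 0.4. Both breakends of a record are scored.
#'
#' When a variant touches several element classes, the most deleterious
#' applicable score wins (coding/splice > TSS > UTR > promoter > intron).
#' A gene's score is the maximum over its transcripts.
#'
#' @name deleteriousness
NULL

iv_overlap_len <- function(m, s, e) {
  if (!nrow(m)) return(0)
  sum(pmax(0, pmin(m[, 2], e) - pmax(m[, 1], s)))
}

iv_contains_point <- function(m, p, open = FALSE) {
  if (!nrow(m)) return(FALSE)
  if (open) any(m[, 1] < p & p < m[, 2]) else any(m[, 1] <= p & p < m[, 2])
}

# 2 intronic bases flanking each internal exon boundary (donor/acceptor)
splice_regions <- function(tx, width = 2) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    if (i > 1) out <- rbind(out, c(ex[i, 1] - width, ex[i, 1]))  # acceptor side
    if (i < nrow(ex)) out <- rbind(out, c(ex[i, 2], ex[i, 2] + width)) # donor side
  }
  out
}

splice_regions_of_exon <- function(tx, i, width = 2) {
  ex <- tx$exons
  out <- NULL
  if (i > 1) out <- rbind(out, c(ex[i, 1] - width, ex[i, 1]))
  if (i < nrow(ex)) out <- rbind(out, c(ex[i, 2], ex[i, 2] + width))
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Classify the overlap between a variant and one transcript
#'
#' Determines the relationship (variant contains transcript / partial
#' overlap / variant within an element), the most deleterious element class
#' touched, the reading-frame effect, and the lengths feeding the UTR
#' formulas.
#'
#' @param v an `sv` (region-based; breakends are classified per breakend by
#'   [delta_breakend()]).
#' @param tx a [transcript()].
#' @param promoter the transcript's promoter region ([promoter_of()]).
#' @param splice_width intronic bases flanking each exon treated as
#'   canonical splice region.
#' @return a list with class `overlap_context`: `relationship`, `element`
#'   (coding_or_splice, tss, utr, promoter, intron, none), `frame_effect`
#'   (in_frame, frameshift, none), `len_sv`, `len_utr`, `utr_overlap`,
#'   `len_ins`.
#' @export
classify_overlap <- function(v, tx, promoter, splice_width = 2) {
  r <- v$region
  ctx <- list(relationship = "none", element = "none", frame_effect = "none",
              len_sv = region_length(r), len_utr = NA_real_,
              utr_overlap = NA_real_, len_ins = v$ins_length)
  class(ctx) <- "overlap_context"
  if (r$contig != tx$contig) {
    if (r$contig == promoter$contig && overlaps(r, promoter))
      { ctx$relationship <- "partial_overlap"; ctx$element <- "promoter" }
    return(ctx)
  }

  if (v$sv_type == "INS") return(classify_insertion(ctx, v, tx, promoter,
                                                    splice_width))

  in_tx <- overlaps(r, tx$region)
  in_prom <- overlaps(r, promoter)
  if (!in_tx && !in_prom) return(ctx)

  if (contains(r, tx$region)) {
    ctx$relationship <- "variant_contains_transcript"
    ctx$element <- "coding_or_splice"
    return(ctx)
  }
  if (!in_tx) {                               # promoter only
    ctx$relationship <- if (contains(promoter, r)) "variant_within_element"
      else "partial_overlap"
    ctx$element <- "promoter"
    return(ctx)
  }
  ctx$relationship <- if (contains(tx$region, r)) "variant_within_element"
    else "partial_overlap"

  coding_ov <- iv_overlap_len(tx$cds_exons, r$start, r$end)
  # splice sites of exons the variant does not remove outright
  splice_hit <- FALSE
  for (i in seq_len(nrow(tx$exons))) {
    fully <- r$start <= tx$exons[i, 1] && r$end >= tx$exons[i, 2]
    if (fully) next
    sr <- splice_regions_of_exon(tx, i, splice_width)
    if (nrow(sr) && iv_overlap_len(sr, r$start, r$end) > 0) splice_hit <- TRUE
  }
  tss <- tss_position(tx)
  tss_hit <- r$start <= tss && tss < r$end
  u5 <- iv_overlap_len(tx$utr5, r$start, r$end)
  u3 <- iv_overlap_len(tx$utr3, r$start, r$end)

  if (coding_ov > 0 || splice_hit) {
    ctx$element <- "coding_or_splice"
    ctx$frame_effect <- if (splice_hit) "frameshift"
      else if (coding_ov %% 3 == 0) "in_frame" else "frameshift"
  } else if (tss_hit) {
    ctx$element <- "tss"
  } else if (u5 > 0 || u3 > 0) {
    ctx$element <- "utr"
    # score against the UTR with the larger relative loss
    r5 <- if (tx$utr5_length > 0) u5 / tx$utr5_length else 0
    r3 <- if (tx$utr3_length > 0) u3 / tx$utr3_length else 0
    if (r5 >= r3) { ctx$utr_overlap <- u5; ctx$len_utr <- tx$utr5_length }
    else { ctx$utr_overlap <- u3; ctx$len_utr <- tx$utr3_length }
  } else if (in_prom && !contains(tx$region, r)) {
    ctx$element <- "promoter"
  } else {
    ctx$element <- "intron"
  }
  ctx
}

classify_insertion <- function(ctx, v, tx, promoter, splice_width) {
  p <- v$region$start            # inserted between bases p-1 and p
  ctx$relationship <- "variant_within_element"
  sr <- splice_regions(tx, splice_width)
  # boundary-inclusive: an insertion landing exactly on a splice boundary
  # is treated as splice-disrupting
  splice_hit <- nrow(sr) > 0 && any(sr[, 1] <= p & p <= sr[, 2])
  if (iv_contains_point(tx$cds_exons, p, open = TRUE) || splice_hit) {
    ctx$element <- "coding_or_splice"
    ctx$frame_effect <- if (splice_hit) "frameshift"
      else if (v$ins_length %% 3 == 0) "in_frame" else "frameshift"
  } else if (iv_contains_point(tx$utr5, p, open = TRUE)) {
    ctx$element <- "utr"; ctx$len_utr <- tx$utr5_length
  } else if (iv_contains_point(tx$utr3, p, open = TRUE)) {
    ctx$element <- "utr"; ctx$len_utr <- tx$utr3_length
  } else if (p > promoter$start && p < promoter$end &&
             v$region$contig == promoter$contig) {
    ctx$element <- "promoter"
  } else if (p > tx$region$start && p < tx$region$end) {
    ctx$element <- "intron"
  } else {
    ctx$relationship <- "none"
  }
  ctx
}

utr_formula <- function(num, len_utr) {
  if (is.na(len_utr) || len_utr == 0) return(1)
  min(num / len_utr, 1)
}

#' Deletion score from an overlap context
#' @param ctx an `overlap_context` from a DEL.
#' @return delta in `[0, 1]`.
#' @export
delta_deletion <- function(ctx) {
  if (ctx$relationship == "variant_contains_transcript") return(1)
  switch(ctx$element,
         coding_or_splice = if (ctx$frame_effect == "in_frame") 0.8 else 1,
         tss = 1,
         utr = utr_formula(2 * ctx$utr_overlap, ctx$len_utr),
         promoter = 0.4,
         intron = 0,
         0)
}

#' Duplication / copy-number-gain score from an overlap context
#' @param ctx an `overlap_context` from a DUP or CNV gain.
#' @param copy_number_gain extra copies added (1 = duplication).
#' @return delta in `[0, copy_number_gain]`.
#' @export
delta_duplication <- function(ctx, copy_number_gain = 1) {
  if (ctx$relationship == "variant_contains_transcript")
    return(copy_number_gain)
  if (ctx$relationship == "partial_overlap" && ctx$element != "promoter")
    return(0)   # tandem duplication past a terminus: primary sequence intact
  switch(ctx$element,
         coding_or_splice = if (ctx$frame_effect == "in_frame") 0.8 else 1,
         tss = 0,
         utr = utr_formula(2 * ctx$utr_overlap, ctx$len_utr),
         promoter = 0.4,
         intron = 0,
         0)
}

#' Inversion score from an overlap context
#' @param ctx an `overlap_context` from an INV.
#' @param tx the transcript the context was computed against.
#' @param v the variant.
#' @return delta in `[0, 1]`.
#' @export
delta_inversion <- function(ctx, tx = NULL, v = NULL) {
  if (ctx$relationship == "variant_contains_transcript") return(0)
  if (ctx$element == "promoter") return(0.4)
  if (ctx$element == "intron") return(0)
  if (ctx$element == "none") return(0)
  if (ctx$relationship == "partial_overlap") return(1)
  # wholly inside the transcript: a breakpoint in coding sequence or an
  # exon subset inverted disrupts the mature transcript; wholly inside a
  # UTR it rearranges untranslated sequence only
  if (ctx$element == "utr" && !is.null(tx) && !is.null(v) &&
      inv_within_single_utr(v, tx))
    return(utr_formula(2 * ctx$utr_overlap, ctx$len_utr))
  1
}

inv_within_single_utr <- function(v, tx) {
  r <- v$region
  m <- rbind(tx$utr5, tx$utr3)
  any(m[, 1] <= r$start & r$end <= m[, 2])
}

#' Insertion score from an overlap context
#' @param ctx an `overlap_context` from an INS.
#' @return delta in `[0, 1]`.
#' @export
delta_insertion <- function(ctx) {
  switch(ctx$element,
         coding_or_splice = if (ctx$frame_effect == "in_frame") 0.2 else 0.9,
         utr = utr_formula(ctx$len_ins, ctx$len_utr),
         promoter = 0.4,
         0)
}

#' Breakend score against one transcript
#'
#' Each breakend of an adjacency is scored independently: a breakend base
#' falling anywhere inside the transcript (coding, UTR, or intron) scores
#' 1; inside the promoter, 0.4; elsewhere 0. The higher of the two
#' breakends' scores is returned.
#'
#' @param adj an [adjacency()].
#' @param tx a [transcript()].
#' @param promoter the transcript's promoter region.
#' @return delta in `[0, 1]`.
#' @export
delta_breakend <- function(adj, tx, promoter) {
  one <- function(b) {
    pos0 <- b$pos - 1
    if (b$contig == tx$contig && point_in(tx$region, pos0)) return(1)
    if (b$contig == promoter$contig && point_in(promoter, pos0)) return(0.4)
    0
  }
  max(one(adj$left), one(adj$right))
}

#' Gene-level deleteriousness score
#'
#' Computes the class-specific delta for every transcript of the gene and
#' takes the maximum as the gene score.
#'
#' @param v an `sv`.
#' @param gene a [gene_model()].
#' @param promoter_length promoter size in bp.
#' @param splice_width splice-region width in bp.
#' @param assembly optional [assembly()] for promoter clipping.
#' @return a list with class `delta_score`: `gene_id`, `delta`, and
#'   `per_transcript` (tx_id -> list(delta, context)).
#' @export
gene_delta <- function(v, gene, promoter_length = 2000, splice_width = 2,
                       assembly = NULL) {
  per_tx <- list()
  for (tx in gene$transcripts) {
    prom <- promoter_of(tx, promoter_length, assembly)
    if (v$sv_type == "BND") {
      d <- delta_breakend(v$adjacency, tx, prom)
      ctx <- NULL
    } else {
      ctx <- classify_overlap(v, tx, prom, splice_width)
      d <- switch(v$sv_type,
                  DEL = delta_deletion(ctx),
                  DUP = delta_duplication(ctx, v$copy_number_gain),
                  CNV = delta_duplication(ctx, v$copy_number_gain),
                  INV = delta_inversion(ctx, tx, v),
                  INS = delta_insertion(ctx),
                  stop("unknown sv_type: ", v$sv_type))
    }
    per_tx[[tx$tx_id]] <- list(delta = d, context = ctx)
  }
  deltas <- vapply(per_tx, function(x) x$delta, numeric(1))
  structure(list(gene_id = gene$gene_id,
                 delta = if (length(deltas)) max(deltas) else 0,
                 per_transcript = per_tx), class = "delta_score")
}
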