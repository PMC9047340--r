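#' Pre-prioritization filters
#'
#' Common structural variants are removed when they match a frequent panel
#' entry of the same SV class; low-support calls are removed by ALT read
#' depth. Both thresholds are strict ("more than 1% of the population",
#' "greater than 80% reciprocal overlap") and user-adjustable. Breakend
#' records are never frequency-filtered: reciprocal overlap is undefined
#' for an adjacency.
#'
#' @name filtering
NULL

# DUP and CNV gains are considered the same class for panel matching;
# matching across unrelated classes is biologically meaningless.
sv_class_matches <- function(a, b) {
  norm <- function(x) if (x %in% c("DUP", "CNV")) "DUPGAIN" else x
  norm(a) == norm(b)
}

#' Positional/length match between two insertions
#'
#' Interval reciprocal overlap is degenerate for zero-length insertion
#' anchors, so insertions are matched by anchor proximity and length ratio
#' instead: a match requires the anchors within `padding` bp and
#' `min(l1,l2)/max(l1,l2)` strictly above `threshold`.
#'
#' @param pos1,len1 anchor position (0-based) and length of the first INS.
#' @param pos2,len2 same for the second.
#' @param contig1,contig2 contig names.
#' @param padding maximum anchor distance in bp.
#' @param threshold length-ratio threshold (strict).
#' @return logical.
#' @export
insertion_match <- function(pos1, len1, pos2, len2,
                            contig1 = "chr", contig2 = "chr",
                            padding = 100, threshold = 0.80) {
  if (contig1 != contig2) return(FALSE)
  if (abs(pos1 - pos2) > padding) return(FALSE)
  min(len1, len2) / max(len1, len2) > threshold
}

#' Remove common structural variants
#'
#' A variant is removed iff some panel entry has allele frequency strictly
#' above `freq_threshold`, a matching SV class, and reciprocal overlap
#' strictly above `overlap_threshold` (insertions: [insertion_match()]).
#' Panels are combined with OR semantics. BND records always pass.
#'
#' @param variants list of `sv` objects.
#' @param panels a single panel data.frame ([load_common_panel()]) or a
#'   list of them.
#' @param freq_threshold population frequency above which an SV is common.
#' @param overlap_threshold reciprocal-overlap (or length-ratio) threshold.
#' @param ins_padding anchor window for insertion matching, bp.
#' @return list with `kept` (list of `sv`), `removed` (list of `sv`), and
#'   `log` (data.frame: variant id, panel index, panel row, overlap).
#' @export
frequency_filter <- function(variants, panels, freq_threshold = 0.01,
                             overlap_threshold = 0.80, ins_padding = 100) {
  stopifnot(freq_threshold > 0, freq_threshold <= 1,
            overlap_threshold > 0, overlap_threshold <= 1)
  if (is.data.frame(panels)) panels <- list(panels)
  kept <- list(); removed <- list()
  log <- list()
  for (v in variants) {
    hit <- NULL
    if (v$sv_type != "BND") {
      for (pi in seq_along(panels)) {
        panel <- panels[[pi]]
        common <- panel[panel$allele_frequency > freq_threshold &
                          panel$contig == v$region$contig, , drop = FALSE]
        for (ri in seq_len(nrow(common))) {
          row <- common[ri, ]
          if (!sv_class_matches(v$sv_type, row$sv_type)) next
          if (v$sv_type == "INS") {
            matched <- !is.na(row$ins_length) &&
              insertion_match(v$region$start, v$ins_length,
                              row$start, row$ins_length,
                              v$region$contig, row$contig,
                              padding = ins_padding,
                              threshold = overlap_threshold)
            ov <- NA_real_
          } else {
            ov <- reciprocal_overlap(v$region,
                                     gregion(row$contig, row$start, row$end))
            matched <- ov > overlap_threshold
          }
          if (matched) {
            hit <- data.frame(id = v$id, panel = pi,
                              panel_contig = row$contig,
                              panel_start = row$start, panel_end = row$end,
                              panel_af = row$allele_frequency,
                              overlap = ov, stringsAsFactors = FALSE)
            break
          }
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) kept[[length(kept) + 1]] <- v
    else { removed[[length(removed) + 1]] <- v; log[[length(log) + 1]] <- hit }
  }
  list(kept = kept, removed = removed,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(id = character(0), panel = integer(0),
                    panel_contig = character(0), panel_start = numeric(0),
                    panel_end = numeric(0), panel_af = numeric(0),
                    overlap = numeric(0)))
}

#' Remove calls with insufficient ALT read support
#'
#' A variant is removed iff its ALT read count is known and strictly below
#' `min_alt_reads`. Variants with unknown depth are kept.
#'
#' @param variants list of `sv` objects.
#' @param min_alt_reads minimum supporting reads (default 3).
#' @return list with `kept` and `removed`.
#' @export
depth_filter <- function(variants, min_alt_reads = 3) {
  stopifnot(min_alt_reads >= 0)
  low <- vapply(variants, function(v)
    !is.na(v$alt_read_count) && v$alt_read_count < min_alt_reads, logical(1))
  list(kept = variants[!low], removed = variants[low])
}
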