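#' Harmonized structural variants
#'
#' One SV in a notation-independent form. Region-based classes (DEL, DUP,
#' INS, INV, CNV) carry a [gregion()]; breakends (BND) carry an
#' [adjacency()]. An insertion's region is the zero-length anchor at the
#' insertion point, with the inserted length kept separately.
#'
#' @name variants
NULL

SV_TYPES <- c("DEL", "DUP", "INS", "INV", "CNV", "BND")

#' Construct a novel adjacency (one breakend record)
#'
#' Positions are 1-based base coordinates as printed in VCF; each breakend's
#' strand records which side of the base the joined segment extends to
#' ("+" = the segment continues rightward/with increasing coordinates).
#' Adjacencies are treated individually, never grouped by event.
#'
#' @param left_contig,left_pos,left_strand left breakend.
#' @param right_contig,right_pos,right_strand right (mate) breakend.
#' @param inserted_sequence bases inserted at the junction (possibly "").
#' @return a list with class `adjacency`.
#' @export
adjacency <- function(left_contig, left_pos, left_strand,
                      right_contig, right_pos, right_strand,
                      inserted_sequence = "") {
  stopifnot(left_pos >= 1, right_pos >= 1,
            left_strand %in% c("+", "-"), right_strand %in% c("+", "-"))
  structure(list(
    left  = list(contig = left_contig,  pos = left_pos,  strand = left_strand),
    right = list(contig = right_contig, pos = right_pos, strand = right_strand),
    inserted_sequence = inserted_sequence), class = "adjacency")
}

#' Construct a harmonized structural variant
#'
#' @param id variant identifier.
#' @param sv_type one of DEL, DUP, INS, INV, CNV, BND.
#' @param region a [gregion()] (all types except BND). For INS this is the
#'   zero-length anchor at the insertion point.
#' @param ins_length inserted length in bp (INS only).
#' @param copy_number_gain extra copies added (DUP/CNV; 1 = duplication,
#'   2 = triplication).
#' @param adjacency an [adjacency()] (BND only).
#' @param alt_read_count ALT-supporting read count, or `NA` when unknown.
#' @param genotype one of het, hom, hemi, unknown.
#' @param vcf_fields optional named list of the originating VCF fields
#'   (chrom, pos, id, ref, alt, qual, filter, info, format, sample), kept so
#'   output VCFs can mirror input records.
#' @return a list with class `sv`.
#' @export
sv_variant <- function(id, sv_type, region = NULL, ins_length = NA_real_,
                       copy_number_gain = 1L, adjacency = NULL,
                       alt_read_count = NA_real_, genotype = "unknown",
                       vcf_fields = NULL) {
  if (!sv_type %in% SV_TYPES) stop("unknown sv_type: ", sv_type)
  if (sv_type == "BND") {
    if (is.null(adjacency)) stop("BND requires an adjacency")
    region <- NULL
  } else {
    if (is.null(region)) stop(sv_type, " requires a region")
    adjacency <- NULL
    if (sv_type %in% c("DEL", "INV") && region_length(region) < 1)
      stop(sv_type, " region must have length >= 1")
    if (sv_type == "INS") {
      if (is.na(ins_length) || ins_length < 1) stop("INS requires ins_length >= 1")
    }
  }
  if (sv_type %in% c("DUP", "CNV") && copy_number_gain < 1)
    stop("copy_number_gain must be >= 1")
  if (!genotype %in% c("het", "hom", "hemi", "unknown"))
    stop("invalid genotype")
  structure(list(id = id, sv_type = sv_type, region = region,
                 ins_length = ins_length,
                 copy_number_gain = as.integer(copy_number_gain),
                 adjacency = adjacency,
                 alt_read_count = alt_read_count, genotype = genotype,
                 vcf_fields = vcf_fields),
            class = "sv")
}

#' @export
print.sv <- function(x, ...) {
  loc <- if (x$sv_type == "BND") {
    sprintf("%s:%d(%s) ~ %s:%d(%s)",
            x$adjacency$left$contig, x$adjacency$left$pos,
            x$adjacency$left$strand, x$adjacency$right$contig,
            x$adjacency$right$pos, x$adjacency$right$strand)
  } else {
    sprintf("%s:[%s,%s)", x$region$contig,
            format(x$region$start, scientific = FALSE),
            format(x$region$end, scientific = FALSE))
  }
  cat(sprintf("<sv %s %s %s%s>\n", x$id, x$sv_type, loc,
              if (x$sv_type == "INS") sprintf(" +%dbp", x$ins_length) else ""))
  invisible(x)
}

#' Length change carried by a variant
#'
#' The span for DEL/DUP/INV/CNV (`len_SV`), the inserted length for INS
#' (`len_INS`), `NA` for BND.
#'
#' @param v an `sv`.
#' @return base pairs.
#' @export
sv_length <- function(v) {
  if (v$sv_type == "BND") return(NA_real_)
  if (v$sv_type == "INS") return(v$ins_length)
  region_length(v$region)
}

#' Breakend positions of a variant as zero-length anchor points
#'
#' For region-based variants the two ends of the region; for BND the two
#' adjacency positions. Used for breakpoint-vs-element tests.
#'
#' @param v an `sv`.
#' @return list of `genomic_region` point anchors (0-length).
#' @keywords internal
sv_breakpoints <- function(v) {
  if (v$sv_type == "BND") {
    list(gregion(v$adjacency$left$contig, v$adjacency$left$pos - 1,
                 v$adjacency$left$pos),
         gregion(v$adjacency$right$contig, v$adjacency$right$pos - 1,
                 v$adjacency$right$pos))
  } else {
    list(gregion(v$region$contig, v$region$start, v$region$start),
         gregion(v$region$contig, v$region$end, v$region$end))
  }
}
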