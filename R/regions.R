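#' Genomic primitives: assemblies, regions, and interval algebra
#'
#' Internal coordinates are always 0-based, half-open, expressed on the +
#' strand of the contig. All VCF / GFF3 input and output converts at the
#' boundary, so interval arithmetic never has to special-case coordinate
#' systems.
#'
#' @name regions
NULL

#' Define an assembly (set of contigs)
#'
#' @param names character vector of contig names; must be unique.
#' @param lengths integer vector of contig lengths in base pairs (> 0).
#' @return a named numeric vector of contig lengths with class `assembly`.
#' @export
assembly <- function(names, lengths) {
  if (anyDuplicated(names)) stop("contig names must be unique")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  structure(stats::setNames(as.numeric(lengths), names), class = "assembly")
}

#' Construct a genomic region
#'
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `end >= start`.
#' @param strand "+" or "-".
#' @param assembly optional [assembly()] used to validate bounds.
#' @return a list with class `genomic_region`.
#' @export
gregion <- function(contig, start, end, strand = "+", assembly = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end < start)
    stop(sprintf("invalid region [%s,%s) on %s", start, end, contig))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(assembly)) {
    if (!contig %in% names(assembly)) stop("unknown contig: ", contig)
    if (end > assembly[[contig]])
      stop(sprintf("region end %s beyond contig %s length %s",
                   end, contig, assembly[[contig]]))
  }
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s:[%s,%s)(%s)\n", x$contig,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand))
  invisible(x)
}

#' Region length in base pairs
#' @param x a `genomic_region`.
#' @return numeric length (`end - start`, possibly 0).
#' @export
region_length <- function(x) x$end - x$start

#' Flip a region to the opposite strand of its contig
#'
#' Coordinates are mirrored through the contig, so flipping twice is the
#' identity.
#'
#' @param x a `genomic_region`.
#' @param contig_length length of the contig `x` lives on.
#' @return the region expressed on the opposite strand.
#' @export
flip_strand <- function(x, contig_length) {
  gregion(x$contig, contig_length - x$end, contig_length - x$start,
          if (x$strand == "+") "-" else "+")
}

#' Convert between 0-based half-open and 1-based fully-closed coordinates
#'
#' @param start,end interval bounds.
#' @return a list with `start` and `end` in the other system.
#' @export
to_one_based <- function(start, end) list(start = start + 1, end = end)

#' @rdname to_one_based
#' @export
to_zero_based <- function(start, end) list(start = start - 1, end = end)

intersection_length <- function(a, b) {
  if (a$contig != b$contig) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Reciprocal overlap of two regions
#'
#' `min(ov / len(a), ov / len(b))` where `ov` is the length of the
#' intersection. Returns 0 for regions on different contigs, disjoint
#' regions, or when either region has zero length (degenerate case, e.g. an
#' insertion anchor). Strand is ignored.
#'
#' @param a,b `genomic_region` objects on the same assembly.
#' @return a fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  la <- region_length(a); lb <- region_length(b)
  if (la == 0 || lb == 0) return(0)
  ov <- intersection_length(a, b)
  if (ov == 0) return(0)
  min(ov / la, ov / lb)
}

#' Do two regions overlap?
#'
#' Half-open semantics: abutting regions (`[0,10)` vs `[10,20)`) do not
#' overlap.
#'
#' @param a,b `genomic_region` objects.
#' @return logical.
#' @export
overlaps <- function(a, b) intersection_length(a, b) > 0

#' Signed distance between two regions
#'
#' 0 when the regions overlap or abut; otherwise the size of the gap,
#' positive when `b` lies downstream (higher coordinates) of `a`, negative
#' when upstream. `Inf` across contigs.
#'
#' @param a,b `genomic_region` objects.
#' @return signed base pairs.
#' @export
region_distance <- function(a, b) {
  if (a$contig != b$contig) return(Inf)
  if (b$start >= a$end) return(b$start - a$end)
  if (a$start >= b$end) return(-(a$start - b$end))
  0
}

#' Does region `outer` fully contain region `inner`?
#' @param outer,inner `genomic_region` objects.
#' @return logical.
#' @export
contains <- function(outer, inner) {
  outer$contig == inner$contig &&
    outer$start <= inner$start && outer$end >= inner$end
}

point_in <- function(region, pos) {
  pos >= region$start && pos < region$end
}
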