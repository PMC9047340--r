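#' Transcript and gene models
#'
#' Transcripts are stranded exon structures with optional CDS bounds; genes
#' group transcripts and carry disease associations. Internally everything
#' is 0-based half-open in genomic (+ strand) coordinates; exons are stored
#' sorted by genomic position, and transcript-strand (5' to 3') order is
#' derived when needed.
#'
#' Two on-disk dialects are supported: standard GFF3 (gene/mRNA/exon/CDS
#' features, read via rtracklayer) and a compact JSON dialect used by the
#' fixture generator, documented in [load_transcripts()].
#'
#' @name transcripts
NULL

#' Construct a transcript
#'
#' @param tx_id transcript identifier.
#' @param gene_id owning gene identifier.
#' @param contig,strand location.
#' @param exons two-column matrix of 0-based half-open exon intervals,
#'   non-overlapping; any row order.
#' @param cds_start,cds_end genomic CDS bounds (0-based half-open), or `NA`
#'   for a non-coding transcript.
#' @return a list with class `transcript`; carries derived `region`,
#'   `utr5`/`utr3` exonic intervals and their total lengths.
#' @export
transcript <- function(tx_id, gene_id, contig, strand, exons,
                       cds_start = NA, cds_end = NA) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop(tx_id, ": exons overlap")
  if (any(exons[, 2] <= exons[, 1])) stop(tx_id, ": empty exon")
  start <- min(exons[, 1]); end <- max(exons[, 2])
  coding <- !is.na(cds_start) && !is.na(cds_end)
  if (coding && (cds_start < start || cds_end > end || cds_start >= cds_end))
    stop(sprintf("transcript %s: CDS [%s,%s) outside span [%s,%s)",
                 tx_id, cds_start, cds_end, start, end))
  clip <- function(lo, hi) {
    keep <- pmin(exons[, 2], hi) > pmax(exons[, 1], lo)
    m <- cbind(pmax(exons[keep, 1], lo), pmin(exons[keep, 2], hi))
    m[m[, 2] > m[, 1], , drop = FALSE]
  }
  if (coding) {
    left <- clip(start, cds_start)   # exonic bases 5' of CDS in genomic order
    right <- clip(cds_end, end)
    cds_exons <- clip(cds_start, cds_end)
    if (strand == "+") { utr5 <- left; utr3 <- right }
    else { utr5 <- right; utr3 <- left }
  } else {
    utr5 <- utr3 <- cds_exons <- matrix(numeric(0), ncol = 2)
  }
  ivlen <- function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
  structure(list(tx_id = tx_id, gene_id = gene_id, contig = contig,
                 strand = strand,
                 region = gregion(contig, start, end, strand),
                 exons = exons,
                 cds_start = if (coding) cds_start else NA,
                 cds_end = if (coding) cds_end else NA,
                 cds_exons = cds_exons,
                 utr5 = utr5, utr3 = utr3,
                 utr5_length = ivlen(utr5), utr3_length = ivlen(utr3),
                 cds_length = ivlen(cds_exons)),
            class = "transcript")
}

#' Transcription start site of a transcript
#'
#' The first transcribed base: the region start on "+" transcripts, the
#' last base (`end - 1`) on "-" transcripts. 0-based.
#'
#' @param tx a `transcript`.
#' @return a single 0-based position.
#' @export
tss_position <- function(tx) {
  if (tx$strand == "+") tx$region$start else tx$region$end - 1
}

#' Promoter region of a transcript
#'
#' The `length` bases immediately upstream of the TSS on the transcript
#' strand (default 2 kb), clipped at contig bounds.
#'
#' @param tx a `transcript`.
#' @param length promoter length in bp.
#' @param assembly optional [assembly()] for clipping at the contig end.
#' @return a `genomic_region` (returned on the + strand).
#' @export
promoter_of <- function(tx, length = 2000, assembly = NULL) {
  if (tx$strand == "+") {
    s <- max(0, tx$region$start - length)
    gregion(tx$contig, s, tx$region$start)
  } else {
    e <- tx$region$end + length
    if (!is.null(assembly) && tx$contig %in% names(assembly))
      e <- min(e, assembly[[tx$contig]])
    gregion(tx$contig, tx$region$end, e)
  }
}

#' Construct a gene model
#'
#' @param gene_id,symbol identifiers.
#' @param transcripts list of [transcript()] objects, all on one contig.
#' @param disease_ids character vector of associated disease identifiers
#'   (possibly empty).
#' @return a list with class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol = gene_id, transcripts,
                       disease_ids = character(0)) {
  if (length(transcripts) < 1) stop(gene_id, ": at least one transcript required")
  contigs <- unique(vapply(transcripts, function(t) t$contig, character(1)))
  if (length(contigs) != 1)
    stop(gene_id, ": transcripts span multiple contigs")
  structure(list(gene_id = gene_id, symbol = symbol,
                 contig = contigs,
                 start = min(vapply(transcripts, function(t) t$region$start, numeric(1))),
                 end = max(vapply(transcripts, function(t) t$region$end, numeric(1))),
                 transcripts = transcripts,
                 disease_ids = disease_ids), class = "gene_model")
}

#' Load gene models from GFF3 or the fixture JSON dialect
#'
#' The JSON dialect is an object with `contigs` (name -> length) and
#' `genes`: each gene has `gene_id`, `symbol`, and `transcripts`, each
#' transcript `tx_id`, `contig`, `strand`, `exons` (array of `[start, end)`
#' 0-based pairs) and optional `cds` (`[start, end)` pair). GFF3 input uses
#' gene/mRNA-or-transcript/exon/CDS features linked by `ID`/`Parent`, with
#' the usual 1-based inclusive coordinates converted on load.
#'
#' @param path a `.json` or `.gff3`/`.gff` file.
#' @param gene_diseases optional data.frame (gene_id, disease_id) attaching
#'   disease associations, as read by [load_gene_diseases()].
#' @return a list with `genes` (named list of [gene_model()]), `assembly`
#'   (from JSON `contigs`, else `NULL`), and `index` (a prebuilt
#'   GRanges-backed lookup from [build_gene_index()], attached lazily by
#'   callers).
#' @export
load_transcripts <- function(path, gene_diseases = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    res <- load_transcripts_json(path)
  } else {
    res <- load_transcripts_gff3(path)
  }
  if (!is.null(gene_diseases)) {
    for (g in names(res$genes)) {
      hit <- gene_diseases$disease_id[gene_diseases$gene_id == g]
      res$genes[[g]]$disease_ids <- unique(hit)
    }
  }
  res
}

load_transcripts_json <- function(path) {
  j <- jsonlite::read_json(path)
  asm <- NULL
  if (!is.null(j$contigs))
    asm <- assembly(names(j$contigs), unlist(j$contigs))
  genes <- list()
  for (g in j$genes) {
    txs <- lapply(g$transcripts, function(t) {
      exons <- do.call(rbind, lapply(t$exons, unlist))
      cds <- if (!is.null(t$cds)) unlist(t$cds) else c(NA, NA)
      transcript(t$tx_id, g$gene_id, t$contig, t$strand, exons,
                 cds_start = cds[1], cds_end = cds[2])
    })
    sym <- if (!is.null(g$symbol)) g$symbol else g$gene_id
    genes[[g$gene_id]] <- gene_model(g$gene_id, sym, txs)
  }
  list(genes = genes, assembly = asm)
}

load_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1          # to 0-based half-open
  typ <- tolower(as.character(df$type))
  tx_rows <- df[typ %in% c("mrna", "transcript", "ncrna"), , drop = FALSE]
  genes <- list()
  for (i in seq_len(nrow(tx_rows))) {
    tr <- tx_rows[i, ]
    tx_id <- as.character(tr$ID)
    parent <- as.character(unlist(tr$Parent))
    if (length(parent) == 0 || is.na(parent)) parent <- tx_id
    kids <- df[vapply(df$Parent, function(p) tx_id %in% as.character(unlist(p)),
                      logical(1)), , drop = FALSE]
    ktyp <- tolower(as.character(kids$type))
    ex <- kids[ktyp == "exon", , drop = FALSE]
    cds <- kids[ktyp == "cds", , drop = FALSE]
    exons <- if (nrow(ex)) cbind(ex$start0, ex$end) else
      cbind(tr$start0, tr$end)
    cs <- if (nrow(cds)) min(cds$start0) else NA
    ce <- if (nrow(cds)) max(cds$end) else NA
    tx <- transcript(tx_id, parent, as.character(tr$seqnames),
                     as.character(tr$strand), exons, cs, ce)
    genes[[parent]] <- c(genes[[parent]], list(tx))
  }
  gene_rows <- df[typ == "gene", , drop = FALSE]
  out <- list()
  for (g in names(genes)) {
    sym <- g
    gr_row <- gene_rows[as.character(gene_rows$ID) == g, , drop = FALSE]
    if (nrow(gr_row) && "Name" %in% names(gr_row) && !is.na(gr_row$Name[1]))
      sym <- as.character(gr_row$Name[1])
    out[[g]] <- gene_model(g, sym, genes[[g]])
  }
  list(genes = out, assembly = NULL)
}

#' Read a two-column gene-to-disease mapping (TSV: gene_id, disease_id)
#' @param path TSV file with a header.
#' @return data.frame with columns gene_id, disease_id.
#' @export
load_gene_diseases <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "disease_id")
  df
}

#' Build an interval index over genes (transcripts plus promoters)
#'
#' Backed by GenomicRanges; the footprint of each gene is the union of its
#' transcript spans extended by each transcript's promoter.
#'
#' @param genes named list of [gene_model()] objects.
#' @param promoter_length promoter size in bp (see [promoter_of()]).
#' @param assembly optional [assembly()] for promoter clipping.
#' @return a list with `gr` (GRanges of gene footprints), `genes`, and the
#'   parameters used.
#' @export
build_gene_index <- function(genes, promoter_length = 2000, assembly = NULL) {
  if (length(genes) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    rows <- lapply(genes, function(g) {
      lo <- g$start; hi <- g$end
      for (tx in g$transcripts) {
        p <- promoter_of(tx, promoter_length, assembly)
        lo <- min(lo, p$start); hi <- max(hi, p$end)
      }
      data.frame(contig = g$contig, start = lo, end = hi,
                 gene_id = g$gene_id, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$contig,
                                 IRanges::IRanges(df$start + 1, df$end),
                                 gene_id = df$gene_id)
  }
  list(gr = gr, genes = genes, promoter_length = promoter_length,
       assembly = assembly)
}

query_index <- function(index, contig, start0, end0) {
  # zero-length anchors are widened to the containing base pair
  if (end0 <= start0) { start0 <- max(0, start0 - 1); end0 <- start0 + 2 }
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1, end0))
  hits <- GenomicRanges::findOverlaps(q, index$gr)
  unique(S4Vectors::mcols(index$gr)$gene_id[S4Vectors::subjectHits(hits)])
}

#' Genes affected by a variant
#'
#' Genes whose transcript or promoter footprint overlaps the variant (for a
#' breakend: either breakend). For an intergenic variant, the nearest gene
#' upstream and the nearest gene downstream of the variant position on the
#' contig (either may be absent near contig ends). May be empty for a
#' variant on a gene-free contig.
#'
#' @param v an `sv`.
#' @param index from [build_gene_index()].
#' @return character vector of gene ids.
#' @export
genes_for_variant <- function(v, index) {
  if (v$sv_type == "BND") {
    hits <- unique(c(
      query_index(index, v$adjacency$left$contig,
                  v$adjacency$left$pos - 1, v$adjacency$left$pos),
      query_index(index, v$adjacency$right$contig,
                  v$adjacency$right$pos - 1, v$adjacency$right$pos)))
    if (length(hits)) return(hits)
    return(nearest_genes(index, v$adjacency$left$contig,
                         v$adjacency$left$pos - 1))
  }
  hits <- query_index(index, v$region$contig, v$region$start, v$region$end)
  if (length(hits)) return(hits)
  mid <- floor((v$region$start + v$region$end) / 2)
  nearest_genes(index, v$region$contig, mid)
}

nearest_genes <- function(index, contig, pos0) {
  genes <- index$genes
  if (length(genes) == 0) return(character(0))
  on_contig <- Filter(function(g) g$contig == contig, genes)
  if (length(on_contig) == 0) return(character(0))
  up <- NULL; up_d <- Inf; down <- NULL; down_d <- Inf
  for (g in on_contig) {
    if (g$end <= pos0) {           # gene entirely left of the position
      d <- pos0 - g$end
      if (d < up_d) { up_d <- d; up <- g$gene_id }
    } else if (g$start > pos0) {   # entirely right
      d <- g$start - pos0
      if (d < down_d) { down_d <- d; down <- g$gene_id }
    } else return(g$gene_id)       # position inside a gene body
  }
  c(up, down)
}

#' Load a common-SV frequency panel
#'
#' Either a VCF of SV records carrying an `AF` INFO field, or a tab-separated
#' table with a header and columns contig, start, end, sv_type,
#' allele_frequency and optionally ins_length (start/end 0-based half-open;
#' for INS rows start is the insertion point and end equals start).
#'
#' @param path panel file (`.vcf` or TSV).
#' @param assembly optional [assembly()].
#' @return data.frame with columns contig, start, end, sv_type,
#'   allele_frequency, ins_length.
#' @export
load_common_panel <- function(path, assembly = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    res <- read_sv_vcf(path, assembly)
    rows <- lapply(res$variants, function(v) {
      if (v$sv_type == "BND") return(NULL)
      af <- info_num(parse_info(v$vcf_fields$info), "AF")
      data.frame(contig = v$region$contig, start = v$region$start,
                 end = v$region$end, sv_type = v$sv_type,
                 allele_frequency = ifelse(is.na(af), 0, af),
                 ins_length = ifelse(v$sv_type == "INS", v$ins_length, NA),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(df)) df <- data.frame(contig = character(0), start = numeric(0),
                                      end = numeric(0), sv_type = character(0),
                                      allele_frequency = numeric(0),
                                      ins_length = numeric(0))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df)[1:5] <- c("contig", "start", "end", "sv_type",
                        "allele_frequency")
    if (!"ins_length" %in% names(df)) df$ins_length <- NA_real_
  }
  if (any(df$allele_frequency < 0 | df$allele_frequency > 1))
    stop("allele frequencies must lie in [0,1]")
  df
}
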