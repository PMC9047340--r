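#' End-to-end prioritization pipeline
#'
#' read VCF -> depth filter -> common-SV filter -> per-gene scoring ->
#' phenotype weighting -> ranking -> TSV + annotated VCF. Fully
#' deterministic: identical inputs produce byte-identical TSV output.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Every CLI flag mirrors one of these keys; values given to
#' [run_prioritize()] override the defaults.
#'
#' @return named list: `frequency_threshold` (0.01), `overlap_threshold`
#'   (0.80), `min_alt_reads` (3), `promoter_length` (2000 bp),
#'   `splice_width` (2 bp), `ins_padding` (100 bp), `dialect` ("auto"),
#'   `pass_only` (FALSE), `top_n_report` (100).
#' @export
default_config <- function() {
  list(frequency_threshold = 0.01, overlap_threshold = 0.80,
       min_alt_reads = 3, promoter_length = 2000, splice_width = 2,
       ins_padding = 100, dialect = "auto", pass_only = FALSE,
       top_n_report = 100)
}

CURIE_RE <- "^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9.]+$"

#' Read proband phenotype terms
#'
#' Either from a character vector of CURIE-form term ids, or from a
#' phenopacket-style JSON file whose `phenotypicFeatures` entries carry
#' `type$id`; entries flagged `excluded: true` (negated findings) are
#' skipped. Duplicates are removed. Malformed ids are a fatal error
#' listing the offenders.
#'
#' @param terms character vector of term ids (may be `NULL`).
#' @param phenopacket path to a phenopacket-style JSON file (may be
#'   `NULL`).
#' @param onto optional [ontology()]; when given, ids are resolved through
#'   the alias map and unknown ids rejected.
#' @return character vector of term ids (the query Q).
#' @export
read_phenotype_terms <- function(terms = NULL, phenopacket = NULL,
                                 onto = NULL) {
  ids <- as.character(terms %||% character(0))
  if (!is.null(phenopacket)) {
    pp <- jsonlite::read_json(phenopacket)
    feats <- pp$phenotypicFeatures %||% pp$phenotypic_features %||% list()
    for (f in feats) {
      if (isTRUE(f$excluded) || isTRUE(f$negated)) next
      id <- f$type$id %||% f$id
      if (!is.null(id)) ids <- c(ids, id)
    }
  }
  ids <- unique(ids)
  if (length(ids) == 0)
    stop("no phenotype terms supplied; at least one HPO term is required")
  bad <- ids[!grepl(CURIE_RE, ids)]
  if (length(bad))
    stop("malformed term id(s): ", paste(bad, collapse = ", "))
  if (!is.null(onto)) ids <- unique(resolve_terms(onto, ids))
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prioritization pipeline
#'
#' @param vcf input VCF of SV calls.
#' @param transcripts transcript definitions (GFF3 or the JSON dialect).
#' @param panels character vector of common-SV panel files (VCF or TSV);
#'   may be empty.
#' @param obo ontology file.
#' @param disease_annotations TSV disease_id / term_id.
#' @param gene_diseases TSV gene_id / disease_id.
#' @param hpo_terms character vector of proband term ids (or `NULL` when
#'   `phenopacket` is given).
#' @param phenopacket phenopacket-style JSON path (optional).
#' @param out_prefix when non-`NULL`, writes `<prefix>.tsv` and
#'   `<prefix>.vcf`.
#' @param config named list overriding [default_config()] entries.
#' @return a list with `results` (ranked list of `prioritized_sv`),
#'   `table` (the TSV data.frame), and `counts` (parsed, skipped,
#'   depth_filtered, frequency_filtered, scored).
#' @export
run_prioritize <- function(vcf, transcripts, panels = character(0),
                           obo, disease_annotations, gene_diseases,
                           hpo_terms = NULL, phenopacket = NULL,
                           out_prefix = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)

  onto <- read_obo(obo)
  query <- read_phenotype_terms(hpo_terms, phenopacket, onto)
  diseases <- load_disease_models(disease_annotations, onto)
  ic <- compute_ic(onto, diseases)
  g2d <- load_gene_diseases(gene_diseases)
  ann <- load_transcripts(transcripts, gene_diseases = g2d)
  index <- build_gene_index(ann$genes, cfg$promoter_length, ann$assembly)

  parsed <- read_sv_vcf(vcf, ann$assembly, dialect = cfg$dialect,
                        pass_only = cfg$pass_only)
  if (length(parsed$variants) == 0)
    stop("no parseable structural variants in ", vcf)

  df <- depth_filter(parsed$variants, cfg$min_alt_reads)
  panel_dfs <- lapply(panels, load_common_panel, assembly = ann$assembly)
  ff <- if (length(panel_dfs))
    frequency_filter(df$kept, panel_dfs, cfg$frequency_threshold,
                     cfg$overlap_threshold, cfg$ins_padding)
  else list(kept = df$kept, removed = list())

  phi_cache <- new.env(parent = emptyenv())
  gene_phi <- function(g) {
    got <- phi_cache[[g]]
    if (!is.null(got)) return(got)
    val <- best_disease_phi(query, ann$genes[[g]], diseases, ic, onto)
    phi_cache[[g]] <- val
    val
  }

  scored <- lapply(ff$kept, function(v) {
    gene_ids <- genes_for_variant(v, index)
    gene_ids <- gene_ids[gene_ids %in% names(ann$genes)]
    deltas <- stats::setNames(lapply(gene_ids, function(g)
      gene_delta(v, ann$genes[[g]], cfg$promoter_length, cfg$splice_width,
                 ann$assembly)), gene_ids)
    phis <- stats::setNames(lapply(gene_ids, gene_phi), gene_ids)
    psv_score(v, deltas, phis)
  })
  ranked <- rank_variants(scored)

  counts <- list(parsed = parsed$n_records,
                 skipped = length(parsed$skipped),
                 depth_filtered = length(df$removed),
                 frequency_filtered = length(ff$removed),
                 scored = length(ranked))
  message(sprintf(
    "parsed %d records: %d skipped, %d below depth, %d common, %d scored",
    counts$parsed, counts$skipped, counts$depth_filtered,
    counts$frequency_filtered, counts$scored))

  tsv_path <- if (!is.null(out_prefix)) paste0(out_prefix, ".tsv")
  vcf_path <- if (!is.null(out_prefix)) paste0(out_prefix, ".vcf")
  table <- write_results(ranked, tsv_path, vcf_path, ann$assembly)
  list(results = ranked, table = table, counts = counts, query = query)
}
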