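#' Synthetic fixtures: toy annotation, background VCFs, spike-in harness
#'
#' A small deterministic genome (two contigs, eight genes covering every
#' scoring rule: plus/minus strand, coding/non-coding, single/multi-exon,
#' an in-frame-deletable 144-bp exon), a ~30-term rooted DAG ontology,
#' eight synthetic disease models, a gene-disease map, and a common-SV
#' panel. The background generator emits neutral variants (intergenic,
#' intronic, or matching the common panel) in all five SV classes and all
#' three VCF notations, so a spiked-in causal variant with any positive
#' score should rank first. Everything is emitted in the same formats the
#' pipeline consumes.
#'
#' @name fixtures
NULL

toy_gene_specs <- function() {
  list(
    list(gene_id = "GENE1", symbol = "NF1L", contig = "chrA", strand = "+",
         txs = list(list(tx_id = "TX1.1",
                         exons = list(c(10000, 10400), c(12000, 12144),
                                      c(14000, 16000)),
                         cds = c(10200, 15000)))),
    list(gene_id = "GENE2", symbol = "BRPF1L", contig = "chrA", strand = "-",
         txs = list(list(tx_id = "TX2.1",
                         exons = list(c(30000, 31000), c(33000, 34000),
                                      c(35500, 36000)),
                         cds = c(30500, 35800)))),
    list(gene_id = "GENE3", symbol = "DUAL1", contig = "chrA", strand = "+",
         txs = list(list(tx_id = "TX3.1",
                         exons = list(c(50000, 50500), c(51000, 52000)),
                         cds = c(50100, 51800)),
                    list(tx_id = "TX3.2",
                         exons = list(c(50000, 52000)), cds = NULL))),
    list(gene_id = "GENE4", symbol = "CMPT1", contig = "chrA", strand = "+",
         txs = list(list(tx_id = "TX4.1",
                         exons = list(c(60000, 61000)),
                         cds = c(60100, 60900)))),
    list(gene_id = "GENE5", symbol = "UTR1", contig = "chrA", strand = "+",
         txs = list(list(tx_id = "TX5.1",
                         exons = list(c(80000, 84000)),
                         cds = c(80300, 83800)))),
    list(gene_id = "GENE6", symbol = "NCR1", contig = "chrA", strand = "+",
         txs = list(list(tx_id = "TX6.1",
                         exons = list(c(100000, 100500), c(102000, 103000)),
                         cds = NULL))),
    list(gene_id = "GENE7", symbol = "EPI1", contig = "chrB", strand = "+",
         txs = list(list(tx_id = "TX7.1",
                         exons = list(c(50000, 50300), c(52000, 52500),
                                      c(55000, 56000)),
                         cds = c(50200, 55500)))),
    list(gene_id = "GENE8", symbol = "NOPH1", contig = "chrB", strand = "+",
         txs = list(list(tx_id = "TX8.1",
                         exons = list(c(100000, 101500)),
                         cds = c(100200, 101300)))))
}

toy_ontology_edges <- function() {
  # term -> parents; HP:0000001 is the root
  list(
    "HP:0000001" = character(0),
    "HP:0000118" = "HP:0000001",
    "HP:0000707" = "HP:0000118",  # nervous system
    "HP:0001626" = "HP:0000118",  # cardiovascular
    "HP:0000924" = "HP:0000118",  # skeletal
    "HP:0000119" = "HP:0000118",  # genitourinary
    "HP:0001574" = "HP:0000118",  # integument
    "HP:0001871" = "HP:0000118",  # blood
    "HP:0001507" = "HP:0000118",  # growth
    "HP:0001999" = "HP:0000118",  # facial morphology
    "HP:0001250" = "HP:0000707",  # seizure
    "HP:0001249" = "HP:0000707",  # intellectual disability
    "HP:0012758" = "HP:0000707",  # neurodevelopmental delay
    "HP:0004375" = "HP:0000707",  # neoplasm of the nervous system
    "HP:0002197" = "HP:0001250",  # generalized seizure
    "HP:0011097" = "HP:0001250",  # epileptic spasm
    "HP:0010818" = "HP:0002197",  # generalized tonic seizure
    "HP:0009732" = c("HP:0004375", "HP:0001574"),  # plexiform neurofibroma
    "HP:0009735" = "HP:0004375",  # spinal neurofibroma
    "HP:0000957" = "HP:0001574",  # cafe-au-lait macule
    "HP:0007565" = "HP:0000957",  # multiple cafe-au-lait spots
    "HP:0002652" = "HP:0000924",  # skeletal dysplasia
    "HP:0009736" = "HP:0000924",  # tibial pseudarthrosis
    "HP:0001382" = "HP:0000924",  # joint hypermobility
    "HP:0001631" = "HP:0001626",  # septal defect
    "HP:0001635" = "HP:0001626",  # heart failure
    "HP:0000107" = "HP:0000119",  # renal cyst
    "HP:0000083" = "HP:0000119",  # renal insufficiency
    "HP:0001892" = "HP:0001871",  # abnormal bleeding
    "HP:0011869" = "HP:0001892",  # abnormal clotting
    "HP:0004322" = "HP:0001507",  # short stature
    "HP:0000486" = "HP:0001999")  # ptosis
}

toy_disease_annotations <- function() {
  list(
    "OMIM:100001" = c("HP:0009732", "HP:0009735", "HP:0009736", "HP:0007565"),
    "OMIM:100002" = c("HP:0001249", "HP:0001999", "HP:0000486"),
    "OMIM:100003" = c("HP:0001250", "HP:0002197", "HP:0012758"),
    "OMIM:100004" = c("HP:0000107", "HP:0000083"),
    "OMIM:100005" = c("HP:0001892", "HP:0011869"),
    "OMIM:100006" = c("HP:0002197", "HP:0011097", "HP:0012758"),
    "OMIM:100007" = c("HP:0000957", "HP:0004322"),
    "OMIM:100008" = c("HP:0001631", "HP:0001635"))
}

toy_gene_diseases <- function() {
  data.frame(
    gene_id = c("GENE1", "GENE1", "GENE2", "GENE3", "GENE4", "GENE5",
                "GENE7"),
    disease_id = c("OMIM:100001", "OMIM:100007", "OMIM:100002",
                   "OMIM:100003", "OMIM:100004", "OMIM:100005",
                   "OMIM:100006"),
    stringsAsFactors = FALSE)
}

toy_common_panel <- function() {
  data.frame(
    contig = c("chrA", "chrA", "chrB", "chrA", "chrA", "chrA"),
    start = c(300000, 400000, 200000, 500000, 600000, 700000),
    end = c(310000, 401000, 220000, 505000, 600000, 700500),
    sv_type = c("DEL", "DEL", "DUP", "INV", "INS", "DEL"),
    allele_frequency = c(0.12, 0.05, 0.08, 0.20, 0.15, 0.005),
    ins_length = c(NA, NA, NA, NA, 300, NA),
    stringsAsFactors = FALSE)
}

#' Generate the toy annotation fixture set
#'
#' Writes transcripts (JSON dialect), ontology (OBO), disease annotations,
#' gene-disease map, and a common-SV panel into `dir`. The layout is fully
#' deterministic, so the same seed (indeed any seed) reproduces identical
#' files.
#'
#' @param dir output directory (created if needed).
#' @param seed recorded for provenance; the layout is deterministic.
#' @return a list of file paths (`transcripts`, `obo`,
#'   `disease_annotations`, `gene_diseases`, `panel`) plus the in-memory
#'   `genes`, `assembly`, `ontology`, `diseases`.
#' @export
make_toy_annotation <- function(dir = tempfile("toyann"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asm <- assembly(c("chrA", "chrB"), c(1000000, 500000))

  specs <- toy_gene_specs()
  genes_json <- lapply(specs, function(g) {
    list(gene_id = g$gene_id, symbol = g$symbol,
         transcripts = lapply(g$txs, function(t) {
           out <- list(tx_id = t$tx_id, contig = g$contig,
                       strand = g$strand,
                       exons = lapply(t$exons, as.list))
           if (!is.null(t$cds)) out$cds <- as.list(t$cds)
           out
         }))
  })
  tx_path <- file.path(dir, "transcripts.json")
  jsonlite::write_json(list(contigs = as.list(stats::setNames(
    as.numeric(asm), names(asm))), genes = genes_json),
    tx_path, auto_unbox = TRUE, digits = NA)

  edges <- toy_ontology_edges()
  onto <- ontology(names(edges), edges,
                   aliases = c("HP:9999001" = "HP:0001250"))
  obo_path <- file.path(dir, "ontology.obo")
  write_obo(onto, obo_path)

  dis <- toy_disease_annotations()
  da <- data.frame(disease_id = rep(names(dis), lengths(dis)),
                   term_id = unlist(dis), stringsAsFactors = FALSE)
  da_path <- file.path(dir, "disease_annotations.tsv")
  utils::write.table(da, da_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  g2d <- toy_gene_diseases()
  g2d_path <- file.path(dir, "gene_diseases.tsv")
  utils::write.table(g2d, g2d_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  panel <- toy_common_panel()
  panel_path <- file.path(dir, "common_sv.tsv")
  utils::write.table(panel, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ann <- load_transcripts(tx_path, gene_diseases = g2d)
  list(transcripts = tx_path, obo = obo_path,
       disease_annotations = da_path, gene_diseases = g2d_path,
       panel = panel_path, dir = dir, seed = seed,
       genes = ann$genes, assembly = ann$assembly, ontology = onto,
       diseases = dis)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a neutral background VCF
#'
#' Emits `n` records cycling through the five SV classes and the three VCF
#' notations, placed intergenically, intronically, or copying a common
#' panel entry, so every record is either filtered out or scores 0.
#' Depth fields follow the pbsv dialect (FORMAT `GT:AD`); roughly one in
#' ten records gets fewer than 3 supporting reads.
#'
#' @param n number of records.
#' @param seed RNG seed; the same seed reproduces the file byte-for-byte.
#' @param path output VCF path.
#' @param assembly an [assembly()] (defaults to the toy assembly).
#' @return `path`, invisibly.
#' @export
make_background_vcf <- function(n, seed = 1,
                                path = tempfile(fileext = ".vcf"),
                                assembly = NULL) {
  if (is.null(assembly)) assembly <- psvrank::assembly(c("chrA", "chrB"),
                                                       c(1000000, 500000))
  set.seed(seed)
  lines <- vcf_header(assembly, sample = "SAMPLE")
  classes <- c("DEL", "INS", "DUP", "INV", "BND")
  panel <- toy_common_panel()
  # neutral placement zones (0-based): deep intergenic space
  zones <- list(c("chrA", 150000, 280000), c("chrA", 320000, 390000),
                c("chrA", 410000, 490000), c("chrA", 520000, 590000),
                c("chrA", 610000, 690000), c("chrA", 710000, 950000),
                c("chrB", 150000, 490000))
  intron1 <- c(10450, 11950)   # wholly inside GENE1 intron 1
  for (i in seq_len(n)) {
    id <- sprintf("bg%04d", i)
    cls <- classes[(i - 1) %% length(classes) + 1]
    alt_depth <- if (i %% 10 == 0) sample(0:2, 1) else sample(3:15, 1)
    fmt <- sprintf("0/1:%d,%d", sample(3:20, 1), alt_depth)
    z <- zones[[sample(length(zones), 1)]]
    contig <- z[1]
    pos0 <- as.integer(sample(as.integer(z[2]):as.integer(z[3]), 1))
    len <- as.integer(sample(60:5000, 1))
    if (cls == "DEL" && i %% 6 == 0) {
      # exact copy of a common panel deletion: removed by the filter
      row <- panel[1, ]
      line <- sprintf("%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d\tGT:AD\t%s",
                      row$contig, as.integer(row$start), id,
                      as.integer(row$end), as.integer(row$end - row$start),
                      fmt)
    } else if (cls == "DEL" && i %% 4 == 0) {
      # small intronic deletion in sequence notation
      dlen <- sample(50:200, 1)
      s0 <- sample(intron1[1]:(intron1[2] - dlen - 1), 1)
      line <- sprintf("chrA\t%d\t%s\t%s\tN\t.\tPASS\t.\tGT:AD\t%s",
                      s0, id, random_bases(dlen + 1), fmt)
    } else if (cls == "DEL") {
      line <- sprintf("%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d\tGT:AD\t%s",
                      contig, pos0, id, pos0 + len, len, fmt)
    } else if (cls == "INS") {
      if (i %% 2 == 0) {
        ilen <- sample(50:400, 1)
        line <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t.\tGT:AD\t%s",
                        contig, pos0, id, random_bases(ilen + 1), fmt)
      } else {
        line <- sprintf("%s\t%d\t%s\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=%d\tGT:AD\t%s",
                        contig, pos0, id, sample(50:400, 1), fmt)
      }
    } else if (cls == "DUP") {
      line <- sprintf("%s\t%d\t%s\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=%d;SVLEN=%d\tGT:AD\t%s",
                      contig, pos0, id, pos0 + len, len, fmt)
    } else if (cls == "INV") {
      line <- sprintf("%s\t%d\t%s\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=%d\tGT:AD\t%s",
                      contig, pos0, id, pos0 + len, fmt)
    } else {
      mate_pos <- sample(150000:490000, 1)
      line <- sprintf("%s\t%d\t%s\tN\tN[chrB:%d[\t.\tPASS\tSVTYPE=BND\tGT:AD\t%s",
                      contig, pos0, id, mate_pos, fmt)
    }
    lines <- c(lines, line)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Causal test cases for the spike-in benchmark
#'
#' Twenty seeded cases spanning all five SV classes, each a deleterious
#' variant in a disease-associated toy gene together with the proband
#' query terms (the disease's annotations, sometimes a subset). All cases
#' target the unique phenotype-matched gene.
#'
#' @return a list of cases: `id`, `class`, `lines` (VCF body lines for the
#'   causal record(s), allelic depth 5:5), `query`, `gene`.
#' @export
make_spike_cases <- function() {
  dis <- toy_disease_annotations()
  fmt <- "GT:AD\t0/1:5,5"
  del <- function(id, contig, s0, e0) {
    s0 <- as.integer(s0); e0 <- as.integer(e0)
    sprintf("%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d\t%s",
            contig, s0, id, e0, e0 - s0, fmt)
  }
  dup <- function(id, contig, s0, e0, cn = NULL) {
    s0 <- as.integer(s0); e0 <- as.integer(e0)
    sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d%s\t%s",
            contig, s0, id, if (is.null(cn)) "DUP" else "CNV",
            if (is.null(cn)) "DUP" else "CNV", e0, e0 - s0,
            if (is.null(cn)) "" else sprintf(";CN=%d", as.integer(cn)), fmt)
  }
  ins <- function(id, contig, p0, len)
    sprintf("%s\t%d\t%s\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=%d\t%s",
            contig, as.integer(p0), id, as.integer(len), fmt)
  inv <- function(id, contig, s0, e0)
    sprintf("%s\t%d\t%s\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=%d\t%s",
            contig, as.integer(s0), id, as.integer(e0), fmt)
  bnd <- function(id, contig, pos1, mate_contig, mate_pos1)
    sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND\t%s",
            contig, as.integer(pos1), id, mate_contig, as.integer(mate_pos1),
            fmt)
  cases <- list(
    list(class = "DEL", gene = "GENE1", query = dis[["OMIM:100001"]],
         lines = del("case01", "chrA", 12000, 12100)),     # frameshift exon loss
    list(class = "DUP", gene = "GENE4", query = dis[["OMIM:100004"]],
         lines = dup("case02", "chrA", 59500, 61500)),     # whole-gene dup
    list(class = "INS", gene = "GENE4", query = dis[["OMIM:100004"]],
         lines = ins("case03", "chrA", 60500, 35)),        # coding frameshift
    list(class = "INV", gene = "GENE3", query = dis[["OMIM:100003"]],
         lines = inv("case04", "chrA", 50050, 51500)),     # exon-subset inversion
    list(class = "BND", gene = "GENE7", query = dis[["OMIM:100006"]],
         lines = bnd("case05", "chrB", 50250, "chrA", 250123)),
    list(class = "DEL", gene = "GENE2", query = dis[["OMIM:100002"]],
         lines = del("case06", "chrA", 32950, 34050)),     # whole coding exon
    list(class = "DUP", gene = "GENE7", query = dis[["OMIM:100006"]],
         lines = dup("case07", "chrB", 52100, 52350)),     # intra-exonic dup
    list(class = "INS", gene = "GENE7", query = dis[["OMIM:100006"]][1:2],
         lines = ins("case08", "chrB", 52200, 100)),
    list(class = "INV", gene = "GENE7", query = dis[["OMIM:100006"]],
         lines = inv("case09", "chrB", 52200, 58000)),     # partial overlap
    list(class = "BND", gene = "GENE1", query = dis[["OMIM:100001"]],
         lines = bnd("case10", "chrA", 12050, "chrB", 300456)),
    list(class = "DEL", gene = "GENE1", query = dis[["OMIM:100001"]],
         lines = del("case11", "chrA", 11990, 12154)),     # in-frame exon loss
    list(class = "DUP", gene = "GENE4", query = dis[["OMIM:100004"]][1],
         lines = dup("case12", "chrA", 59000, 62000, cn = 4)), # triplication
    list(class = "INS", gene = "GENE5", query = dis[["OMIM:100005"]],
         lines = ins("case13", "chrA", 80100, 400)),       # 5'UTR, >= UTR length
    list(class = "INV", gene = "GENE2", query = dis[["OMIM:100002"]],
         lines = inv("case14", "chrA", 30700, 33500)),     # breaks coding exons
    list(class = "BND", gene = "GENE4", query = dis[["OMIM:100004"]],
         lines = bnd("case15", "chrA", 60450, "chrA", 450789)),
    list(class = "DEL", gene = "GENE5", query = dis[["OMIM:100005"]],
         lines = del("case16", "chrA", 83810, 83950)),     # 3'UTR, >= half UTR
    list(class = "DUP", gene = "GENE1", query = dis[["OMIM:100001"]],
         lines = dup("case17", "chrA", 12020, 12120)),     # frameshift dup
    list(class = "INS", gene = "GENE1", query = dis[["OMIM:100001"]][1:3],
         lines = ins("case18", "chrA", 14500, 200)),       # coding frameshift
    list(class = "INV", gene = "GENE4", query = dis[["OMIM:100004"]],
         lines = inv("case19", "chrA", 60400, 60700)),     # intra-CDS inversion
    list(class = "DEL", gene = "GENE5", query = dis[["OMIM:100005"]],
         lines = del("case20", "chrA", 78500, 79600)))     # promoter deletion
  for (i in seq_along(cases)) cases[[i]]$id <- sprintf("case%02d", i)
  cases
}

#' Spike causal variants into background VCFs and record their rank
#'
#' Runs the full pipeline once per background file with the causal
#' record(s) appended, and reports the best (smallest) rank attained by
#' any causal record in each run plus the median across runs. A causal
#' variant removed by filtering is reported with rank `Inf` and a warning.
#'
#' @param case_lines character vector of VCF body lines for the causal
#'   record(s) (see [make_spike_cases()]).
#' @param case_ids the causal record ids to look for in the ranking.
#' @param background_vcfs character vector of background VCF paths.
#' @param query_terms proband HPO term ids.
#' @param annotation fixture paths as returned by [make_toy_annotation()].
#' @param config pipeline configuration overrides.
#' @return list with `ranks` (per background file) and `median_rank`.
#' @export
spike_in_and_rank <- function(case_lines, case_ids, background_vcfs,
                              query_terms, annotation, config = list()) {
  stopifnot(length(background_vcfs) >= 1)
  ranks <- vapply(background_vcfs, function(bg) {
    merged <- tempfile(fileext = ".vcf")
    writeLines(c(readLines(bg), case_lines), merged)
    res <- suppressMessages(run_prioritize(
      vcf = merged, transcripts = annotation$transcripts,
      panels = annotation$panel, obo = annotation$obo,
      disease_annotations = annotation$disease_annotations,
      gene_diseases = annotation$gene_diseases,
      hpo_terms = query_terms, config = config))
    unlink(merged)
    hit <- which(res$table$id %in% case_ids)
    if (length(hit) == 0) {
      warning("causal variant(s) ", paste(case_ids, collapse = ","),
              " filtered out of ", bg, call. = FALSE)
      return(Inf)
    }
    min(res$table$rank[hit])
  }, numeric(1))
  list(ranks = unname(ranks), median_rank = stats::median(unname(ranks)))
}
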