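test_that("UTR lengths derive correctly from exon/CDS structure", {
  # single-exon transcript with CDS == exon: both UTRs empty
  t1 <- transcript("t1", "g", "c", "+", rbind(c(100, 400)), 100, 400)
  expect_equal(t1$utr5_length, 0)
  expect_equal(t1$utr3_length, 0)
  # 3-exon transcript, CDS starts mid-exon-1: UTR5 = offset
  t2 <- transcript("t2", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)), 40, 450)
  expect_equal(t2$utr5_length, 40)
  expect_equal(t2$utr3_length, 50)
  # same structure on the minus strand swaps the UTRs
  t3 <- transcript("t3", "g", "c", "-",
                   rbind(c(0, 100), c(200, 300), c(400, 500)), 40, 450)
  expect_equal(t3$utr5_length, 50)
  expect_equal(t3$utr3_length, 40)
  # non-coding transcript: no CDS, whole span non-coding
  t4 <- transcript("t4", "g", "c", "+", rbind(c(0, 100)))
  expect_true(is.na(t4$cds_start))
  expect_equal(t4$cds_length, 0)
})

test_that("UTR5 + CDS + UTR3 exonic lengths sum to total exonic length", {
  for (g in toy$genes) for (tx in g$transcripts) {
    if (is.na(tx$cds_start)) next
    total <- sum(tx$exons[, 2] - tx$exons[, 1])
    expect_equal(tx$utr5_length + tx$cds_length + tx$utr3_length, total,
                 info = tx$tx_id)
  }
})

test_that("CDS outside the transcript span is rejected with the tx id", {
  expect_error(transcript("badtx", "g", "c", "+", rbind(c(100, 200)), 50, 150),
               "badtx")
})

test_that("promoters span 2 kb upstream of the TSS, strand-aware and clipped", {
  tp <- transcript("tp", "g", "c", "+", rbind(c(10000, 12000)), 10100, 11900)
  p <- promoter_of(tp)
  expect_equal(c(p$start, p$end), c(8000, 10000))
  tm <- transcript("tm", "g", "c", "-", rbind(c(8000, 10000)), 8100, 9900)
  p <- promoter_of(tm)
  expect_equal(c(p$start, p$end), c(10000, 12000))
  tc <- transcript("tc", "g", "c", "+", rbind(c(500, 900)), 600, 800)
  p <- promoter_of(tc)
  expect_equal(c(p$start, p$end), c(0, 500))
  # minus-strand clip at the contig end
  asm <- assembly("c", 10500)
  tz <- transcript("tz", "g", "c", "-", rbind(c(8000, 10000)), 8100, 9900)
  p <- promoter_of(tz, assembly = asm)
  expect_equal(p$end, 10500)
})

test_that("gene lookup returns overlapping genes, else nearest neighbours", {
  index <- build_gene_index(toy$genes, assembly = toy$assembly)
  # deletion inside an intron of GENE1
  v <- mk_sv("DEL", "chrA", 10500, 11000)
  expect_equal(genes_for_variant(v, index), "GENE1")
  # deletion spanning GENE4 and GENE5
  v <- mk_sv("DEL", "chrA", 60500, 81000)
  expect_setequal(genes_for_variant(v, index), c("GENE4", "GENE5"))
  # intergenic insertion between GENE4 (ends 61000) and GENE5 (promoter 78000)
  v <- mk_sv("INS", "chrA", 70000, ins_length = 100)
  expect_setequal(genes_for_variant(v, index), c("GENE4", "GENE5"))
  # gene-free region on chrB beyond all genes: only an upstream neighbour
  v <- mk_sv("DEL", "chrB", 400000, 400100)
  expect_equal(genes_for_variant(v, index), "GENE8")
  # BND: genes at either breakend
  v <- mk_bnd("chrA", 12050, "chrB", 50250)
  expect_setequal(genes_for_variant(v, index), c("GENE1", "GENE7"))
})

test_that("interval-index lookups agree with a linear scan", {
  index <- build_gene_index(toy$genes, assembly = toy$assembly)
  linear_scan <- function(contig, s, e) {
    hits <- character(0)
    for (g in toy$genes) {
      lo <- g$start; hi <- g$end
      for (tx in g$transcripts) {
        p <- promoter_of(tx, 2000, toy$assembly)
        lo <- min(lo, p$start); hi <- max(hi, p$end)
      }
      if (g$contig == contig && max(s, lo) < min(e, hi))
        hits <- c(hits, g$gene_id)
    }
    hits
  }
  set.seed(11)
  for (i in 1:100) {
    contig <- sample(c("chrA", "chrB"), 1)
    s <- sample(0:150000, 1); e <- s + sample(1:5000, 1)
    got <- psvrank:::query_index(index, contig, s, e)
    expect_setequal(got, linear_scan(contig, s, e))
  }
})

test_that("JSON and GFF3 loaders produce equivalent gene models", {
  # write GENE1 as GFF3 (1-based inclusive) and compare to the JSON fixture
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\ttoy\tgene\t10001\t16000\t.\t+\t.\tID=GENE1;Name=NF1L",
    "chrA\ttoy\tmRNA\t10001\t16000\t.\t+\t.\tID=TX1.1;Parent=GENE1",
    "chrA\ttoy\texon\t10001\t10400\t.\t+\t.\tParent=TX1.1",
    "chrA\ttoy\texon\t12001\t12144\t.\t+\t.\tParent=TX1.1",
    "chrA\ttoy\texon\t14001\t16000\t.\t+\t.\tParent=TX1.1",
    "chrA\ttoy\tCDS\t10201\t10400\t.\t+\t0\tParent=TX1.1",
    "chrA\ttoy\tCDS\t12001\t12144\t.\t+\t1\tParent=TX1.1",
    "chrA\ttoy\tCDS\t14001\t15000\t.\t+\t1\tParent=TX1.1"), gff)
  g <- load_transcripts(gff)$genes$GENE1
  ref <- toy$genes$GENE1$transcripts[[1]]
  got <- g$transcripts[[1]]
  expect_equal(got$exons, ref$exons)
  expect_equal(got$cds_start, ref$cds_start)
  expect_equal(got$cds_end, ref$cds_end)
  expect_equal(got$utr5_length, ref$utr5_length)
  expect_equal(got$utr3_length, ref$utr3_length)
})

test_that("common-SV panels load from TSV with validated frequencies", {
  panel <- load_common_panel(toy$panel)
  expect_true(all(c("contig", "start", "end", "sv_type",
                    "allele_frequency") %in% names(panel)))
  expect_true(all(panel$allele_frequency >= 0 & panel$allele_frequency <= 1))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tstart\tend\tsv_type\tallele_frequency",
               "chrA\t0\t10\tDEL\t1.5"), bad)
  expect_error(load_common_panel(bad), "frequencies")
})
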