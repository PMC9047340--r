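write_vcf_body <- function(lines, sample = TRUE) {
  path <- tempfile(fileext = ".vcf")
  asm <- assembly(c("chr1", "chr2", "chrA", "chrB"),
                  c(1e6, 1e6, 1e6, 5e5))
  writeLines(c(psvrank:::vcf_header(asm, sample = if (sample) "S1"), lines),
             path)
  path
}

test_that("sequence-notation records are decoded per the VCF anchor convention", {
  p <- write_vcf_body("chr1\t100\td1\tACGT\tA\t.\tPASS\t.\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$sv_type, "DEL")
  # POS=100 REF=ACGT ALT=A deletes 1-based bases 101..103 = 0-based [100,103)
  expect_equal(v$region$start, 100)
  expect_equal(v$region$end, 103)
  expect_equal(v$genotype, "het")

  p <- write_vcf_body("chr1\t100\ti1\tA\tACGTCG\t.\tPASS\t.\tGT\t1/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$sv_type, "INS")
  expect_equal(v$ins_length, 5)
  expect_equal(v$region$start, 100)
  expect_equal(region_length(v$region), 0)
  expect_equal(v$genotype, "hom")
})

test_that("symbolic alleles use POS as anchor and END as last base", {
  p <- write_vcf_body("chr1\t100\ts1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=200\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$sv_type, "INV")
  expect_equal(v$region$start, 100)
  expect_equal(v$region$end, 200)

  # END derivable from SVLEN when absent
  p <- write_vcf_body("chr1\t500\ts2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-250\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$region$end, 750)

  # CNV with copy number 4: two extra copies over the diploid baseline
  p <- write_vcf_body("chr1\t100\tc1\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=300;CN=4\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$copy_number_gain, 2L)

  # neither END nor SVLEN: skipped with a warning, counted
  p <- write_vcf_body("chr1\t100\ts3\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP\tGT\t0/1")
  expect_warning(res <- read_sv_vcf(p), "without END or SVLEN")
  expect_length(res$variants, 0)
  expect_length(res$skipped, 1)
})

test_that("breakend ALTs decode to one adjacency per record", {
  p <- write_vcf_body("chr1\t100\tb1\tA\tA[chr2:321682[\t.\tPASS\tSVTYPE=BND\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$sv_type, "BND")
  expect_equal(v$adjacency$left,
               list(contig = "chr1", pos = 100, strand = "+"))
  expect_equal(v$adjacency$right,
               list(contig = "chr2", pos = 321682, strand = "+"))

  # bracket orientation: ]p]t joins upstream-of-POS to decreasing mate coords
  p <- write_vcf_body("chr1\t100\tb2\tA\t]chr2:500]A\t.\tPASS\tSVTYPE=BND\tGT\t0/1")
  v <- suppressWarnings(read_sv_vcf(p))$variants[[1]]
  expect_equal(v$adjacency$left$strand, "-")
  expect_equal(v$adjacency$right$strand, "-")

  # malformed bracket ALT: skipped, not fatal
  p <- write_vcf_body("chr1\t100\tb3\tA\tA[chr2:xx[\t.\tPASS\tSVTYPE=BND\tGT\t0/1")
  expect_warning(res <- read_sv_vcf(p), "malformed breakend")
  expect_length(res$variants, 0)
})

test_that("depth extraction follows the caller dialect", {
  expect_equal(extract_alt_depth(list(), "GT:AD", "0/1:5,7", "pbsv"), 7)
  expect_equal(extract_alt_depth(list(SUPPORT = "9"), NA, NA, "svim"), 9)
  expect_equal(extract_alt_depth(list(), "GT:DV", "0/1:11", "sniffles"), 11)
  expect_equal(extract_alt_depth(list(RE = "4"), "GT", "0/1", "sniffles"), 4)
  expect_true(is.na(extract_alt_depth(list(), "GT", "0/1", "auto")))
  expect_equal(extract_alt_depth(list(SUPPORT = "3"), "GT", "0/1", "auto"), 3)
})

test_that("multi-allelic records process the first ALT with a warning", {
  p <- write_vcf_body("chr1\t100\tm1\tACGT\tA,ACGTACGT\t.\tPASS\t.\tGT\t1/2")
  expect_warning(res <- read_sv_vcf(p), "multi-allelic")
  expect_length(res$variants, 1)
  expect_equal(res$variants[[1]]$sv_type, "DEL")
})

test_that("every record maps to one variant or one logged skip", {
  bg <- make_background_vcf(60, seed = 3, assembly = toy$assembly)
  res <- suppressWarnings(read_sv_vcf(bg))
  expect_equal(length(res$variants) + length(res$skipped), res$n_records)
  expect_equal(res$n_records, 60)
})

test_that("write-read round trip preserves coordinates for all SV types", {
  variants <- list(
    mk_sv("DEL", "chrA", 1000, 2000, id = "d"),
    mk_sv("DUP", "chrA", 5000, 9000, id = "u"),
    mk_sv("INV", "chrB", 100, 400, id = "i"),
    mk_sv("INS", "chrA", 1234, ins_length = 77, id = "n"),
    mk_sv("CNV", "chrA", 20000, 30000, gain = 2, id = "c"),
    mk_bnd("chrA", 555, "chrB", 777, id = "b"))
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(variants, path, toy$assembly)
  back <- suppressWarnings(read_sv_vcf(path))$variants
  expect_length(back, length(variants))
  for (i in seq_along(variants)) {
    v0 <- variants[[i]]; v1 <- back[[i]]
    expect_equal(v1$sv_type, v0$sv_type, info = v0$id)
    if (v0$sv_type == "BND") {
      expect_equal(v1$adjacency$left$pos, v0$adjacency$left$pos)
      expect_equal(v1$adjacency$right$pos, v0$adjacency$right$pos)
    } else {
      expect_equal(v1$region$start, v0$region$start, info = v0$id)
      expect_equal(v1$region$end, v0$region$end, info = v0$id)
    }
    if (v0$sv_type == "INS") expect_equal(v1$ins_length, v0$ins_length)
    if (v0$sv_type == "CNV")
      expect_equal(v1$copy_number_gain, v0$copy_number_gain)
  }
})

test_that("result writer emits ranked TSV rows and PSV/RANK INFO fields", {
  v <- mk_sv("DEL", "chrA", 1000, 2000, id = "top")
  p1 <- psv_score(v, list(G1 = 1), list(G1 = 2))
  ranked <- rank_variants(list(p1))
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  tab <- write_results(ranked, tsv, vcf, toy$assembly)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$rank, 1)
  expect_equal(tab$start, 1001)  # 1-based in emitted files
  expect_equal(tab$end, 2000)
  body <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_match(body, "PSV=")
  expect_match(body, "RANK=1")
  # empty input: header-only TSV
  tab0 <- write_results(list(), tsv, NULL)
  expect_equal(nrow(tab0), 0)
  expect_equal(length(readLines(tsv)), 1)
})
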