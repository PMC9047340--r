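# Gene geometry used throughout (from the toy annotation):
# GENE1 (+): exons [10000,10400) [12000,12144) [14000,16000), CDS 10200-15000,
#            UTR5 200 bp, UTR3 1000 bp, 144-bp fully-coding middle exon.
# GENE4 (+): single exon [60000,61000), CDS 60100-60900.
# GENE5 (+): single exon [80000,84000), CDS 80300-83800, UTR5 300, UTR3 200.

delta_of <- function(v, gene) gene_delta(v, toy$genes[[gene]],
                                         assembly = toy$assembly)$delta

test_that("every scoring cell yields its published constant", {
  cells <- list(
    # DEL: t-in-SV, frameshift exon, in-frame exon, UTR, intron, promoter, TSS
    list(v = mk_sv("DEL", , 9000, 17000), g = "GENE1", exp = 1),
    list(v = mk_sv("DEL", , 12000, 12100), g = "GENE1", exp = 1),
    list(v = mk_sv("DEL", , 11990, 12154), g = "GENE1", exp = 0.8),
    list(v = mk_sv("DEL", , 83810, 83860), g = "GENE5", exp = 0.5),
    list(v = mk_sv("DEL", , 10500, 11900), g = "GENE1", exp = 0),
    list(v = mk_sv("DEL", , 78500, 79600), g = "GENE5", exp = 0.4),
    list(v = mk_sv("DEL", , 79900, 80200), g = "GENE5", exp = 1),   # TSS loss
    # DUP: whole gene, triplication, frameshift coding, in-frame coding,
    #      tandem past a terminus, intron, promoter
    list(v = mk_sv("DUP", , 59500, 61500), g = "GENE4", exp = 1),
    list(v = mk_sv("CNV", , 59000, 62000, gain = 2), g = "GENE4", exp = 2),
    list(v = mk_sv("DUP", , 12020, 12120), g = "GENE1", exp = 1),
    list(v = mk_sv("DUP", , 12021, 12120), g = "GENE1", exp = 0.8), # 99 bp
    list(v = mk_sv("DUP", , 15500, 17000), g = "GENE1", exp = 0),
    list(v = mk_sv("DUP", , 10500, 11900), g = "GENE1", exp = 0),
    list(v = mk_sv("DUP", , 78500, 79600), g = "GENE5", exp = 0.4),
    # INV: contains transcript, partial, coding breakpoint, intron, promoter
    list(v = mk_sv("INV", , 59000, 62000), g = "GENE4", exp = 0),
    list(v = mk_sv("INV", , 60500, 62000), g = "GENE4", exp = 1),
    list(v = mk_sv("INV", , 60400, 60700), g = "GENE4", exp = 1),
    list(v = mk_sv("INV", , 10500, 11900), g = "GENE1", exp = 0),
    list(v = mk_sv("INV", , 78500, 79600), g = "GENE5", exp = 0.4),
    # INS: frameshift, in-frame, UTR (full/partial), intron, promoter, outside
    list(v = mk_sv("INS", , 60500, ins_length = 35), g = "GENE4", exp = 0.9),
    list(v = mk_sv("INS", , 60500, ins_length = 36), g = "GENE4", exp = 0.2),
    list(v = mk_sv("INS", , 83900, ins_length = 200), g = "GENE5", exp = 1),
    list(v = mk_sv("INS", , 83900, ins_length = 50), g = "GENE5", exp = 0.25),
    list(v = mk_sv("INS", , 10700, ins_length = 50), g = "GENE1", exp = 0),
    list(v = mk_sv("INS", , 79000, ins_length = 50), g = "GENE5", exp = 0.4),
    list(v = mk_sv("INS", , 70000, ins_length = 50), g = "GENE4", exp = 0))
  for (cell in cells)
    expect_equal(delta_of(cell$v, cell$g), cell$exp,
                 info = paste(cell$v$sv_type, cell$v$region$start, cell$g))
})

test_that("breakends score 1 anywhere in a transcript and 0.4 in the promoter", {
  expect_equal(delta_of(mk_bnd("chrA", 12050, "chrB", 300456), "GENE1"), 1)
  expect_equal(delta_of(mk_bnd("chrA", 11000, "chrB", 300456), "GENE1"), 1)
  expect_equal(delta_of(mk_bnd("chrA", 15500, "chrB", 300456), "GENE1"), 1)
  expect_equal(delta_of(mk_bnd("chrA", 9000, "chrB", 300456), "GENE1"), 0.4)
  expect_equal(delta_of(mk_bnd("chrA", 300000, "chrB", 300456), "GENE1"), 0)
  # the mate breakend is scored too
  expect_equal(delta_of(mk_bnd("chrB", 300456, "chrA", 12050), "GENE1"), 1)
})

test_that("UTR formulas are scale-invariant and capped at 1", {
  # doubling both the lesion and the UTR leaves the score unchanged
  utr_del <- function(len_sv, len_utr) {
    ctx <- list(relationship = "variant_within_element", element = "utr",
                frame_effect = "none", len_sv = len_sv, len_utr = len_utr,
                utr_overlap = len_sv, len_ins = NA)
    class(ctx) <- "overlap_context"
    delta_deletion(ctx)
  }
  for (len in c(10, 25, 60, 100)) {
    expect_equal(utr_del(len, 200), utr_del(2 * len, 400))
    expect_equal(utr_del(len, 200), min(2 * len / 200, 1))
  }
  expect_equal(utr_del(25, 100), 0.5)
  expect_equal(utr_del(50, 100), 1)
  expect_equal(utr_del(90, 100), 1)
})

test_that("splice-region disruption of a retained exon is frameshift-equivalent", {
  # 3-bp in-frame loss at the edge of GENE1 exon 2 plus its acceptor site
  v <- mk_sv("DEL", , 11997, 12003)  # covers acceptor [11998,12000) + 3 coding
  expect_equal(delta_of(v, "GENE1"), 1)
  # same 3 coding bases wholly inside the exon: in-frame, 0.8
  v <- mk_sv("DEL", , 12050, 12053)
  expect_equal(delta_of(v, "GENE1"), 0.8)
  # insertion landing on a splice boundary
  v <- mk_sv("INS", , 12144, ins_length = 33)
  expect_equal(delta_of(v, "GENE1"), 0.9)
})

test_that("precedence: the most deleterious touched element wins", {
  # deletion spanning promoter + UTR5 + CDS start of GENE5: coding wins
  v <- mk_sv("DEL", , 79000, 80400)
  expect_equal(delta_of(v, "GENE5"), 1)
  # deletion spanning promoter + UTR5 only (TSS included): TSS wins over both
  v <- mk_sv("DEL", , 79000, 80200)
  expect_equal(delta_of(v, "GENE5"), 1)
})

test_that("the gene score is the maximum over transcripts", {
  # GENE3 has a coding and a non-coding transcript; a CDS deletion scores
  # through the coding one only
  v <- mk_sv("DEL", , 50150, 50250)
  ds <- gene_delta(v, toy$genes$GENE3)
  per <- vapply(ds$per_transcript, function(x) x$delta, numeric(1))
  expect_equal(unname(per["TX3.1"]), 1)
  expect_equal(unname(per["TX3.2"]), 0)
  expect_equal(ds$delta, 1)
})

test_that("delta stays within [0, copy gain] and is 0 off-element", {
  set.seed(5)
  index <- build_gene_index(toy$genes, assembly = toy$assembly)
  for (i in 1:100) {
    type <- sample(c("DEL", "DUP", "INS", "INV", "CNV"), 1)
    s <- sample(0:990000, 1)
    gain <- sample(1:3, 1)
    v <- if (type == "INS") mk_sv("INS", "chrA", s, ins_length = sample(50:500, 1))
      else mk_sv(type, "chrA", s, s + sample(50:20000, 1), gain = gain)
    for (g in genes_for_variant(v, index)) {
      d <- gene_delta(v, toy$genes[[g]], assembly = toy$assembly)$delta
      cap <- if (type %in% c("DUP", "CNV")) v$copy_number_gain else 1
      expect_true(d >= 0 && d <= cap,
                  info = sprintf("%s at %d in %s: delta %g", type, s, g, d))
    }
  }
  # variant on a contig with no genes scores nothing
  v <- mk_sv("DEL", "chrA", 900000, 900100)
  expect_true(all(vapply(genes_for_variant(v, index), function(g)
    gene_delta(v, toy$genes[[g]], assembly = toy$assembly)$delta,
    numeric(1)) == 0))
})
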