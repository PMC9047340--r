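toy_panel <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig = r$contig %||% "chrA", start = r$start, end = r$end,
               sv_type = r$type, allele_frequency = r$af,
               ins_length = r$ins %||% NA_real_, stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("frequency filter applies strict overlap and frequency thresholds", {
  v <- list(mk_sv("DEL", "chrA", 0, 1000, id = "d1"))
  # identity overlap with a common DEL: removed
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 1000,
                                            type = "DEL", af = 0.05)))
  expect_length(res$kept, 0)
  expect_equal(res$log$id, "d1")
  # reciprocal overlap 0.79: kept
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 790,
                                            type = "DEL", af = 0.05)))
  expect_length(res$kept, 1)
  # reciprocal overlap exactly 0.80: kept (strictly greater required)
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 800,
                                            type = "DEL", af = 0.05)))
  expect_length(res$kept, 1)
  # 0.81: removed
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 810,
                                            type = "DEL", af = 0.05)))
  expect_length(res$kept, 0)
  # frequency at exactly 1%: kept; just above: removed
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 1000,
                                            type = "DEL", af = 0.01)))
  expect_length(res$kept, 1)
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 1000,
                                            type = "DEL", af = 0.005)))
  expect_length(res$kept, 1)
  res <- frequency_filter(v, toy_panel(list(start = 0, end = 1000,
                                            type = "DEL", af = 0.011)))
  expect_length(res$kept, 0)
})

test_that("SV classes only match within their own class (DUP and CNV pooled)", {
  dup <- list(mk_sv("DUP", "chrA", 0, 1000, id = "u1"))
  res <- frequency_filter(dup, toy_panel(list(start = 0, end = 1000,
                                              type = "DEL", af = 0.5)))
  expect_length(res$kept, 1)
  res <- frequency_filter(dup, toy_panel(list(start = 0, end = 1000,
                                              type = "CNV", af = 0.5)))
  expect_length(res$kept, 0)
  bnd <- list(mk_bnd("chrA", 500, "chrB", 600))
  res <- frequency_filter(bnd, toy_panel(list(start = 0, end = 1000,
                                              type = "DEL", af = 0.9)))
  expect_length(res$kept, 1)  # breakends are never frequency-filtered
})

test_that("insertion matching uses anchor padding and length ratio", {
  expect_true(insertion_match(100, 300, 100, 300))
  expect_false(insertion_match(100, 100, 100, 70))   # ratio 0.7
  expect_false(insertion_match(100, 100, 100, 80))   # ratio exactly 0.8
  expect_false(insertion_match(100, 300, 301, 300))  # 201 bp apart
  expect_true(insertion_match(100, 300, 200, 300))   # exactly at padding
  expect_false(insertion_match(100, 300, 100, 300, "chr1", "chr2"))
  ins <- list(mk_sv("INS", "chrA", 500, ins_length = 300, id = "i1"))
  res <- frequency_filter(ins, toy_panel(list(start = 520, end = 520,
                                              type = "INS", af = 0.2,
                                              ins = 290)))
  expect_length(res$kept, 0)
  res <- frequency_filter(ins, toy_panel(list(start = 520, end = 520,
                                              type = "INS", af = 0.2,
                                              ins = 100)))
  expect_length(res$kept, 1)
})

test_that("depth filter removes only known counts below the threshold", {
  vs <- list(mk_sv("DEL", "chrA", 0, 100, id = "a", depth = 2),
             mk_sv("DEL", "chrA", 0, 100, id = "b", depth = 3),
             mk_sv("DEL", "chrA", 0, 100, id = "c", depth = NA))
  res <- depth_filter(vs, 3)
  expect_equal(vapply(res$kept, function(v) v$id, ""), c("b", "c"))
  expect_equal(vapply(res$removed, function(v) v$id, ""), "a")
})

test_that("filtering is order-independent, monotone in thresholds, and conserves counts", {
  set.seed(9)
  vs <- lapply(1:40, function(i) {
    s <- sample(0:5000, 1)
    mk_sv("DEL", "chrA", s, s + sample(50:500, 1), id = paste0("v", i))
  })
  p1 <- toy_panel(list(start = 0, end = 1000, type = "DEL", af = 0.3),
                  list(start = 2000, end = 2400, type = "DEL", af = 0.02))
  p2 <- toy_panel(list(start = 3000, end = 3600, type = "DEL", af = 0.15))
  ids <- function(x) sort(vapply(x, function(v) v$id, ""))
  r12 <- frequency_filter(vs, list(p1, p2))
  r21 <- frequency_filter(vs, list(p2, p1))
  expect_equal(ids(r12$kept), ids(r21$kept))
  expect_equal(length(r12$kept) + length(r12$removed), length(vs))
  # raising either threshold never removes more variants
  for (ot in c(0.5, 0.8, 0.9, 1.0)) {
    for (ft in c(0.01, 0.05, 0.2)) {
      r <- frequency_filter(vs, list(p1, p2), ft, ot)
      r_higher_ot <- frequency_filter(vs, list(p1, p2), ft, min(1, ot + 0.1))
      r_higher_ft <- frequency_filter(vs, list(p1, p2), min(1, ft + 0.1), ot)
      expect_true(length(r_higher_ot$kept) >= length(r$kept))
      expect_true(length(r_higher_ft$kept) >= length(r$kept))
      expect_true(all(ids(r$kept) %in% ids(r_higher_ot$kept)))
    }
  }
})
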