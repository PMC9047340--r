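# Shared fixtures, built once per test run.

toy <- make_toy_annotation(file.path(tempdir(), "psvrank-toyann"))

mk_sv <- function(type, contig = "chrA", start = NULL, end = NULL,
                  ins_length = NA, gain = 1, id = "v1", depth = NA) {
  if (type == "INS")
    sv_variant(id, "INS", region = gregion(contig, start, start),
               ins_length = ins_length, alt_read_count = depth)
  else
    sv_variant(id, type, region = gregion(contig, start, end),
               copy_number_gain = gain, alt_read_count = depth)
}

mk_bnd <- function(contig1, pos1, contig2, pos2, id = "b1") {
  sv_variant(id, "BND",
             adjacency = adjacency(contig1, pos1, "+", contig2, pos2, "+"))
}

# Per-base brute-force overlap oracle on small contigs.
brute_reciprocal_overlap <- function(a, b) {
  if (a$contig != b$contig) return(0)
  la <- region_length(a); lb <- region_length(b)
  if (la == 0 || lb == 0) return(0)
  ina <- seq_len(1000) - 1
  hits <- sum(ina >= a$start & ina < a$end & ina >= b$start & ina < b$end)
  min(hits / la, hits / lb)
}

# Corpus-scan IC oracle: count diseases annotated with t or a descendant.
brute_ic <- function(term, onto, diseases) {
  n <- sum(vapply(diseases, function(terms)
    any(vapply(terms, function(d) term %in% term_ancestors(onto, d),
               logical(1))), logical(1)))
  if (n == 0) n <- 1
  -log(n / length(diseases))
}

# Brute-force MICA over the full ancestor intersection.
brute_mica <- function(t1, t2, ic, onto) {
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  max(c(0, ic$ic[common]))
}

quiet_run <- function(...) {
  suppressWarnings(suppressMessages(run_prioritize(...)))
}
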