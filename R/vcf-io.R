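#' VCF input/output for structural variants
#'
#' Reading goes through [vcfR::read.vcfR()]; the harmonization of the three
#' SV notations (sequence, symbolic allele, breakend) into [sv_variant()]
#' objects is done here. All emitted coordinates are 1-based per VCF
#' convention; internal regions are 0-based half-open.
#'
#' Coordinate conventions on read:
#' * sequence notation (`REF`/`ALT` both bases, shared prefix anchor):
#'   a net loss is a DEL whose region is the deleted bases,
#'   `[POS-1+len(ALT), POS-1+len(REF))` 0-based; a net gain is an INS
#'   anchored after the last shared base.
#' * symbolic alleles (`<DEL>`, `<DUP>`, `<INS>`, `<INV>`, `<CNV>`): POS is
#'   the base before the event and END its last base, so the region is
#'   `[POS, END)` 0-based. `END` is taken from INFO END, else derived from
#'   `|SVLEN|`.
#' * breakend notation: each record is one novel adjacency; no EVENT
#'   grouping. In `t[p[`-style ALTs, a leading base means the local segment
#'   extends rightward from POS (strand "+"); `[` means the mate joins with
#'   increasing coordinates (strand "+"), `]` with decreasing ("-").
#'
#' @name vcf_io
NULL

parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1) kv[2] else TRUE
  }
  out
}

info_num <- function(info, key) {
  v <- info[[key]]
  if (is.null(v) || isTRUE(v)) return(NA_real_)
  suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1]][1]))
}

format_field <- function(format, sample, key) {
  if (is.na(format) || is.na(sample)) return(NA_character_)
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  vals <- strsplit(sample, ":", fixed = TRUE)[[1]]
  i <- match(key, keys)
  if (is.na(i) || i > length(vals)) return(NA_character_)
  vals[i]
}

parse_genotype <- function(format, sample) {
  gt <- format_field(format, sample, "GT")
  if (is.na(gt)) return("unknown")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 1) {
    if (alleles == "1") return("hemi") else return("unknown")
  }
  if (all(alleles == "1")) return("hom")
  if (any(alleles == "1")) return("het")
  "unknown"
}

#' Extract the ALT-supporting read count from a VCF record
#'
#' Long-read SV callers report depth idiosyncratically; the field used is
#' chosen by the caller dialect: `pbsv` reads the second entry of the sample
#' FORMAT `AD` (ref,alt); `sniffles` reads FORMAT `DV` with INFO `RE` as
#' fallback; `svim` reads INFO `SUPPORT` with FORMAT `AD` as fallback;
#' `auto` probes pbsv, sniffles, svim in that order. Absence is a legal
#' state: the variant is still analyzed, with unknown depth.
#'
#' @param info named list of parsed INFO fields.
#' @param format,sample FORMAT string and first-sample string (or `NA`).
#' @param dialect one of `"pbsv"`, `"sniffles"`, `"svim"`, `"auto"`.
#' @return integer ALT read count, or `NA` when not reported.
#' @export
extract_alt_depth <- function(info, format = NA, sample = NA,
                              dialect = c("auto", "pbsv", "sniffles", "svim")) {
  dialect <- match.arg(dialect)
  ad_alt <- function() {
    ad <- format_field(format, sample, "AD")
    if (is.na(ad)) return(NA_real_)
    parts <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
    if (length(parts) < 2) return(NA_real_)
    parts[2]
  }
  dv <- function() {
    v <- format_field(format, sample, "DV")
    if (is.na(v)) return(info_num(info, "RE"))
    suppressWarnings(as.numeric(v))
  }
  support <- function() {
    v <- info_num(info, "SUPPORT")
    if (is.na(v)) ad_alt() else v
  }
  val <- switch(dialect,
    pbsv = ad_alt(), sniffles = dv(), svim = support(),
    auto = {
      v <- ad_alt()
      if (is.na(v)) v <- dv()
      if (is.na(v)) v <- support()
      v
    })
  if (is.na(val)) NA_real_ else as.numeric(val)
}

parse_breakend_alt <- function(chrom, pos, alt) {
  n_open <- lengths(regmatches(alt, gregexpr("[", alt, fixed = TRUE)))
  n_close <- lengths(regmatches(alt, gregexpr("]", alt, fixed = TRUE)))
  br <- if (n_open == 2 && n_close == 0) "[" else
    if (n_close == 2 && n_open == 0) "]" else return(NULL)
  parts <- strsplit(alt, br, fixed = TRUE)[[1]]
  if (length(parts) < 2) return(NULL)
  pre <- parts[1]; mate <- parts[2]
  post <- if (length(parts) >= 3) parts[3] else ""
  if ((nchar(pre) > 0) == (nchar(post) > 0)) return(NULL) # bases on one side only
  if (!grepl("^[A-Za-z.]*$", pre) || !grepl("^[A-Za-z.]*$", post)) return(NULL)
  ci <- regexpr(":[0-9]+$", mate)
  if (ci < 0) return(NULL)
  mate_chr <- substr(mate, 1, ci - 1)
  mate_pos <- as.numeric(substring(mate, ci + 1))
  left_strand <- if (nchar(pre) > 0) "+" else "-"
  right_strand <- if (br == "[") "+" else "-"
  ins <- if (nchar(pre) > 1) substring(pre, 2) else if (nchar(post) > 1)
    substring(post, 1, nchar(post) - 1) else ""
  adjacency(chrom, pos, left_strand, mate_chr, mate_pos, right_strand,
            inserted_sequence = ins)
}

harmonize_record <- function(chrom, pos, id, ref, alt, qual, filter, info_str,
                             format, sample, dialect, assembly) {
  chrom <- as.character(chrom); id <- as.character(id)
  ref <- as.character(ref); alt <- as.character(alt)
  pos <- as.numeric(pos)
  info <- parse_info(info_str)
  vf <- list(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
             qual = qual, filter = filter, info = info_str,
             format = format, sample = sample)
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  multi <- length(alts) > 1
  a1 <- alts[1]
  depth <- extract_alt_depth(info, format, sample, dialect)
  gt <- parse_genotype(format, sample)
  mk <- function(...) {
    v <- sv_variant(..., alt_read_count = depth, genotype = gt,
                    vcf_fields = vf)
    list(variant = v, warning = if (multi)
      sprintf("record %s: multi-allelic, only first ALT processed", id))
  }

  if (grepl("[", a1, fixed = TRUE) || grepl("]", a1, fixed = TRUE)) { # breakend
    adj <- parse_breakend_alt(chrom, pos, a1)
    if (is.null(adj))
      return(list(skip = sprintf("record %s: malformed breakend ALT '%s'", id, a1)))
    return(mk(id = id, sv_type = "BND", adjacency = adj))
  }

  if (grepl("^<.+>$", a1)) {                        # symbolic allele
    sym <- toupper(sub("^<([^:>]+).*>$", "\\1", a1))
    if (!sym %in% c("DEL", "DUP", "INS", "INV", "CNV"))
      return(list(skip = sprintf("record %s: unsupported symbolic ALT '%s'", id, a1)))
    end <- info_num(info, "END")
    svlen <- abs(info_num(info, "SVLEN"))
    if (sym == "INS") {
      if (is.na(svlen))
        return(list(skip = sprintf("record %s: symbolic INS without SVLEN", id)))
      return(mk(id = id, sv_type = "INS",
                region = gregion(chrom, pos, pos, assembly = assembly),
                ins_length = svlen))
    }
    if (is.na(end)) {
      if (is.na(svlen))
        return(list(skip = sprintf(
          "record %s: symbolic %s without END or SVLEN", id, sym)))
      end <- pos + svlen
    }
    gain <- 1L
    cn <- info_num(info, "CN")
    if (sym == "CNV" && !is.na(cn)) gain <- max(1L, as.integer(cn) - 2L)
    return(mk(id = id, sv_type = sym,
              region = gregion(chrom, pos, end, assembly = assembly),
              copy_number_gain = gain))
  }

  # sequence notation: shared prefix anchor, net length change decides type
  if (!grepl("^[ACGTNacgtn]+$", ref) || !grepl("^[ACGTNacgtn]+$", a1))
    return(list(skip = sprintf("record %s: unparseable REF/ALT '%s'/'%s'",
                               id, ref, a1)))
  lr <- nchar(ref); la <- nchar(a1)
  if (lr > la) {
    return(mk(id = id, sv_type = "DEL",
              region = gregion(chrom, pos - 1 + la, pos - 1 + lr,
                               assembly = assembly)))
  }
  if (la > lr) {
    return(mk(id = id, sv_type = "INS",
              region = gregion(chrom, pos - 1 + lr, pos - 1 + lr,
                               assembly = assembly),
              ins_length = la - lr))
  }
  list(skip = sprintf("record %s: no net length change (not an SV)", id))
}

#' Read structural variants from a VCF file
#'
#' Decodes sequence-, symbolic-, and breakend-notation records into
#' harmonized [sv_variant()] objects. Unparseable records are skipped with a
#' warning and counted, never silently dropped.
#'
#' @param path VCF file (plain or bgzipped).
#' @param assembly optional [assembly()] for bounds checking.
#' @param dialect caller dialect for depth extraction; see
#'   [extract_alt_depth()].
#' @param pass_only if `TRUE`, keep only records with FILTER PASS or ".".
#' @return a list with `variants` (list of `sv`), `skipped` (character
#'   vector of skip messages), and `n_records` (rows read).
#' @export
read_sv_vcf <- function(path, assembly = NULL,
                        dialect = c("auto", "pbsv", "sniffles", "svim"),
                        pass_only = FALSE) {
  dialect <- match.arg(dialect)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  variants <- list(); skipped <- character(0); warnings <- character(0)
  n <- nrow(fix)
  if (is.null(n)) n <- 0
  for (i in seq_len(n)) {
    filt <- fix[i, "FILTER"]
    if (pass_only && !is.na(filt) && !filt %in% c("PASS", "."))
      { skipped <- c(skipped, sprintf("record %s: FILTER %s",
                                      fix[i, "ID"], filt)); next }
    format <- NA_character_; sample <- NA_character_
    if (!is.null(gt) && ncol(gt) >= 2) {
      format <- gt[i, 1]; sample <- gt[i, 2]
    }
    res <- tryCatch(
      harmonize_record(fix[i, "CHROM"], as.numeric(fix[i, "POS"]),
                       if (is.na(fix[i, "ID"])) sprintf("rec%d", i) else fix[i, "ID"],
                       fix[i, "REF"], fix[i, "ALT"], fix[i, "QUAL"],
                       fix[i, "FILTER"], fix[i, "INFO"], format, sample,
                       dialect, assembly),
      error = function(e) list(skip = sprintf("record %s: %s",
                                              fix[i, "ID"], conditionMessage(e))))
    if (!is.null(res$skip)) {
      skipped <- c(skipped, res$skip)
    } else {
      variants[[length(variants) + 1]] <- res$variant
      if (!is.null(res$warning)) warnings <- c(warnings, res$warning)
    }
  }
  for (w in c(skipped, warnings)) warning(w, call. = FALSE)
  list(variants = variants, skipped = skipped, n_records = n)
}

vcf_line_for <- function(v, extra_info = NULL) {
  f <- v$vcf_fields
  if (is.null(f)) f <- synth_vcf_fields(v)
  info <- f$info
  if (!is.null(extra_info)) {
    add <- paste(names(extra_info), unlist(extra_info), sep = "=",
                 collapse = ";")
    info <- if (is.na(info) || info %in% c(".", "")) add else paste(info, add, sep = ";")
  }
  cols <- c(f$chrom, format(f$pos, scientific = FALSE), f$id, f$ref, f$alt,
            ifelse(is.na(f$qual), ".", f$qual),
            ifelse(is.na(f$filter), ".", f$filter), info)
  if (!is.na(f$format)) cols <- c(cols, f$format, f$sample)
  paste(cols, collapse = "\t")
}

# Synthesize VCF fields for a programmatically built variant.
synth_vcf_fields <- function(v) {
  if (v$sv_type == "BND") {
    l <- v$adjacency$left; r <- v$adjacency$right
    mate <- sprintf("%s:%s", r$contig, format(r$pos, scientific = FALSE))
    br <- if (r$strand == "+") sprintf("[%s[", mate) else sprintf("]%s]", mate)
    alt <- if (l$strand == "+") paste0("N", br) else paste0(br, "N")
    return(list(chrom = l$contig, pos = l$pos, id = v$id, ref = "N",
                alt = alt, qual = NA, filter = "PASS", info = "SVTYPE=BND",
                format = NA, sample = NA))
  }
  r <- v$region
  if (v$sv_type == "INS") {
    info <- sprintf("SVTYPE=INS;SVLEN=%d", as.integer(v$ins_length))
    return(list(chrom = r$contig, pos = r$start, id = v$id, ref = "N",
                alt = "<INS>", qual = NA, filter = "PASS", info = info,
                format = NA, sample = NA))
  }
  info <- sprintf("SVTYPE=%s;END=%s;SVLEN=%s", v$sv_type,
                  format(r$end, scientific = FALSE),
                  format((if (v$sv_type == "DEL") -1 else 1) * region_length(r),
                         scientific = FALSE))
  if (v$sv_type == "CNV")
    info <- paste0(info, sprintf(";CN=%d", v$copy_number_gain + 2L))
  list(chrom = r$contig, pos = r$start, id = v$id, ref = "N",
       alt = sprintf("<%s>", v$sv_type), qual = NA, filter = "PASS",
       info = info, format = NA, sample = NA)
}

vcf_header <- function(assembly = NULL, sample = NULL) {
  h <- c("##fileformat=VCFv4.2",
         "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
         "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
         "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
         "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
         "##INFO=<ID=PSV,Number=1,Type=Float,Description=\"Phenotype-aware priority score\">",
         "##INFO=<ID=RANK,Number=1,Type=Integer,Description=\"Priority rank\">",
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
         "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  if (!is.null(assembly))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(assembly),
                      as.integer(assembly)))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) cols <- c(cols, "FORMAT", sample)
  c(h, paste(cols, collapse = "\t"))
}

#' Write prioritized variants as TSV and annotated VCF
#'
#' The TSV carries one row per kept variant: rank, PSV score, variant
#' identity and coordinates (1-based), affected genes with their per-gene
#' deleteriousness and phenotype-similarity scores, and associated
#' diseases. The VCF mirrors the input records with `PSV` and `RANK` added
#' to INFO.
#'
#' @param prioritized list of prioritized variants as returned by
#'   [rank_variants()].
#' @param tsv_path,vcf_path output paths (either may be `NULL` to skip).
#' @param assembly optional [assembly()] for VCF contig header lines.
#' @return invisibly, the TSV as a data.frame.
#' @export
write_results <- function(prioritized, tsv_path = NULL, vcf_path = NULL,
                          assembly = NULL) {
  rows <- lapply(prioritized, function(p) {
    v <- p$variant
    if (v$sv_type == "BND") {
      contig <- v$adjacency$left$contig
      start1 <- v$adjacency$left$pos; end1 <- v$adjacency$left$pos
    } else {
      contig <- v$region$contig
      start1 <- v$region$start + 1
      end1 <- max(v$region$end, start1)  # zero-length INS anchor: point
    }
    fmt_genes <- vapply(p$contributions, function(ct)
      sprintf("%s:%.4g:%.4g", ct$gene_id, ct$delta, ct$phi), character(1))
    diseases <- vapply(p$contributions, function(ct)
      if (is.na(ct$disease_id)) "" else ct$disease_id, character(1))
    data.frame(rank = p$rank, median_rank = p$median_rank,
               psv = round(p$psv, 4), id = v$id, type = v$sv_type,
               contig = contig, start = start1, end = end1,
               genes = paste(vapply(p$contributions, function(ct) ct$gene_id,
                                    character(1)), collapse = ","),
               gene_scores = paste(fmt_genes, collapse = ","),
               diseases = paste(diseases[nzchar(diseases)], collapse = ","),
               stringsAsFactors = FALSE)
  })
  tsv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(0), median_rank = numeric(0), psv = numeric(0),
               id = character(0), type = character(0), contig = character(0),
               start = numeric(0), end = numeric(0), genes = character(0),
               gene_scores = character(0), diseases = character(0))
  if (!is.null(tsv_path))
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(vcf_path)) {
    has_sample <- any(vapply(prioritized, function(p)
      !is.null(p$variant$vcf_fields) && !is.na(p$variant$vcf_fields$format),
      logical(1)))
    lines <- vcf_header(assembly, sample = if (has_sample) "SAMPLE" else NULL)
    for (p in prioritized)
      lines <- c(lines, vcf_line_for(p$variant,
                                     extra_info = list(PSV = sprintf("%.4f", p$psv),
                                                       RANK = p$rank)))
    writeLines(lines, vcf_path)
  }
  invisible(tsv)
}

#' Write harmonized variants to a plain VCF file
#'
#' Used by the fixture generator and the spike-in harness.
#'
#' @param variants list of `sv` objects.
#' @param path output path.
#' @param assembly optional [assembly()] for contig header lines.
#' @param sample sample name when FORMAT fields are present.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(variants, path, assembly = NULL, sample = NULL) {
  if (is.null(sample)) {
    has_sample <- any(vapply(variants, function(v)
      !is.null(v$vcf_fields) && !is.na(v$vcf_fields$format), logical(1)))
    sample <- if (has_sample) "SAMPLE" else NULL
  }
  lines <- vcf_header(assembly, sample = sample)
  for (v in variants) lines <- c(lines, vcf_line_for(v))
  writeLines(lines, path)
  invisible(path)
}
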