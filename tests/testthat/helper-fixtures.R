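# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk except files these helpers write to
# tempfiles.

# One or more trio records with explicit per-sample evidence. NA depth marks
# an absent observation for that role.
make_trios <- function(p_af, x_af, p_alt = round(p_af * 100),
                       x_alt = round(x_af * 100),
                       p_depth = 100L, x_depth = 100L,
                       g_af = NA_real_, g_depth = NA_integer_,
                       g_alt = ifelse(is.na(g_af), NA_integer_, as.integer(round(g_af * ifelse(is.na(g_depth), 100, g_depth)))),
                       mapq = 60, baseq = 30,
                       consequence = "missense_variant",
                       ref = "A", alt = "G", gene = "",
                       model_id = "M1", subtype = "DLBCL") {
  n <- max(length(p_af), length(x_af), length(g_af))
  df <- data.frame(
    patient_id = "P1",
    model_id = rep_len(model_id, n),
    subtype = rep_len(subtype, n),
    chrom = "1",
    pos = seq_len(n) * 100L,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    consequence = rep_len(consequence, n),
    gene = rep_len(gene, n),
    germline_depth = rep_len(as.integer(ifelse(is.na(g_af) & is.na(g_depth), NA, ifelse(is.na(g_depth), 100L, g_depth))), n),
    germline_alt = rep_len(as.integer(g_alt), n),
    germline_af = rep_len(g_af, n),
    germline_mapq = rep_len(mapq, n), germline_baseq = rep_len(baseq, n),
    primary_depth = rep_len(as.integer(p_depth), n),
    primary_alt = rep_len(as.integer(p_alt), n),
    primary_af = rep_len(p_af, n),
    primary_mapq = rep_len(mapq, n), primary_baseq = rep_len(baseq, n),
    pdx_depth = rep_len(as.integer(x_depth), n),
    pdx_alt = rep_len(as.integer(x_alt), n),
    pdx_af = rep_len(x_af, n),
    pdx_mapq = rep_len(mapq, n), pdx_baseq = rep_len(baseq, n),
    stringsAsFactors = FALSE
  )
  # keep the quality columns NA for absent roles
  for (r in c("germline", "primary", "pdx")) {
    absent <- is.na(df[[paste0(r, "_depth")]])
    for (suf in c("_alt", "_af", "_mapq", "_baseq")) {
      df[[paste0(r, suf)]][absent] <- NA
    }
  }
  class(df) <- c("trio_records", "data.frame")
  df
}

# Random trio records for property-style tests (seeded by the caller).
random_trios <- function(n, with_germline = TRUE) {
  depth <- function() sample(c(5L, 9L, 10L, 11L, 50L, 200L), n, replace = TRUE)
  mk_role <- function(d) {
    alt <- vapply(d, function(di) sample.int(di + 1L, 1L) - 1L, integer(1))
    list(depth = d, alt = alt, af = alt / d)
  }
  p <- mk_role(depth()); x <- mk_role(depth())
  g_present <- if (with_germline) runif(n) < 0.7 else rep(FALSE, n)
  g <- mk_role(depth())
  df <- make_trios(p_af = p$af, x_af = x$af, p_alt = p$alt, x_alt = x$alt,
                   p_depth = p$depth, x_depth = x$depth,
                   consequence = sample(c("missense_variant", "stop_gained",
                                          "synonymous_variant", "intron_variant"),
                                        n, replace = TRUE),
                   ref = sample(c("A", "C", "G", "T")[1:2], n, replace = TRUE))
  df$alt <- ifelse(df$ref == "A", "G", "T")
  df$germline_depth <- ifelse(g_present, g$depth, NA_integer_)
  df$germline_alt <- ifelse(g_present, g$alt, NA_integer_)
  df$germline_af <- ifelse(g_present, round(runif(n), 3), NA_real_)
  df$germline_mapq <- ifelse(g_present, sample(c(15, 20, 60), n, replace = TRUE), NA_real_)
  df$germline_baseq <- ifelse(g_present, 30, NA_real_)
  df$primary_mapq <- sample(c(15, 20, 21, 60), n, replace = TRUE)
  df$pdx_mapq <- sample(c(15, 20, 21, 60), n, replace = TRUE)
  df
}

# Minimal single- or multi-sample VCF writer; `rows` is a data frame with
# chrom, pos, ref, alt, dp, ad (comma string "ref,alt[,alt2]"), and optional
# info fields.
write_test_vcf <- function(rows, path, sample = "S1", with_af = FALSE,
                           mq = 60, bq = 30) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
           "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"Consequence\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           if (with_af) "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    info <- sprintf("MQ=%g;BQ=%g", mq, bq)
    if (!is.null(r$gene) && nzchar(r$gene)) info <- paste0(info, ";GENE=", r$gene)
    if (!is.null(r$consequence) && nzchar(r$consequence)) {
      info <- paste0(info, ";CONSEQUENCE=", r$consequence)
    }
    fmt <- if (with_af) "DP:AD:AF" else "DP:AD"
    gt <- if (with_af) paste(r$dp, r$ad, r$af, sep = ":") else paste(r$dp, r$ad, sep = ":")
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info, fmt, gt,
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Independent brute-force re-statement of the classification rule table, kept
# deliberately separate from the package implementation: enumerate which
# samples detect the variant and which support it.
oracle_label <- function(p_af, x_af, p_alt, x_alt,
                         detect_af = 0.1, min_alt = 3) {
  det_p <- p_af >= detect_af
  det_x <- x_af >= detect_af
  sup_p <- p_alt >= min_alt
  sup_x <- x_alt >= min_alt
  if (sup_p && sup_x && (det_p || det_x)) return("shared")
  if (det_x && !det_p) return("newly_detected")
  if (det_p && !det_x) return("newly_undetected")
  if (det_p && det_x) {
    # shared failed on read support; the undersupported sample decides
    if (!sup_p && sup_x) return("newly_detected")
    if (!sup_x && sup_p) return("newly_undetected")
    return("not_comparable")
  }
  "not_comparable"
}

# CNVkit-style segment file writer.
write_test_cns <- function(df, path) {
  write.table(data.frame(chromosome = df$chrom, start = df$start,
                         end = df$end,
                         log2 = if (is.null(df$log2)) NA else df$log2,
                         cn = if (is.null(df$cn)) NA else df$cn),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_test_bed <- function(df, path) {
  writeLines(paste(df$chrom, df$start, df$end, df$gene, sep = "\t"), path)
  path
}
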