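test_that("variant keys are minimized, left-anchored and idempotent", {
  df <- data.frame(chrom = c("chr1", "2", "chrX", "1"),
                   pos = c(100L, 50L, 10L, 200L),
                   ref = c("CTT", "ACGT", "A", "G"),
                   alt = c("CT", "ATGT", "T", "GAA"),
                   stringsAsFactors = FALSE)
  norm <- normalize_variant_keys(df)
  expect_equal(norm$chrom, c("1", "2", "X", "1"))
  # CTT>CT: shared suffix trimmed, anchor base kept
  expect_equal(unlist(norm[1, c("pos", "ref", "alt")], use.names = FALSE),
               c("100", "CT", "C"))
  # ACGT>ATGT: suffix then prefix trimmed to the changed base
  expect_equal(unlist(norm[2, c("pos", "ref", "alt")], use.names = FALSE),
               c("51", "C", "T"))
  # SNV and insertion untouched
  expect_equal(norm$ref[3:4], c("A", "G"))
  expect_identical(normalize_variant_keys(norm), norm)

  expect_error(normalize_variant_keys(
    data.frame(chrom = "1", pos = 1, ref = "A", alt = "<DEL>")), "allele")
  expect_error(normalize_variant_keys(
    data.frame(chrom = "1", pos = 1, ref = "A", alt = "A")), "ref == alt")
})

test_that("normalization is idempotent on random indel keys", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  rand_allele <- function() paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
  df <- data.frame(chrom = "1", pos = sample(1000, 200, TRUE),
                   ref = replicate(200, rand_allele()),
                   alt = replicate(200, rand_allele()),
                   stringsAsFactors = FALSE)
  df <- df[df$ref != df$alt, ]
  once <- normalize_variant_keys(df)
  expect_identical(normalize_variant_keys(once), once)
})

test_that("read_vcf extracts depth, AD-derived AF, and splits multiallelics", {
  vcf <- write_test_vcf(
    data.frame(chrom = c("1", "1"), pos = c(100L, 200L),
               ref = c("A", "C"), alt = c("G", "A,T"),
               dp = c(20L, 30L), ad = c("14,6", "10,12,8"),
               gene = c("GENE1", ""), consequence = c("missense_variant", ""),
               stringsAsFactors = FALSE),
    tempfile(fileext = ".vcf"))
  obs <- read_vcf(vcf)
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$depth[obs$pos == 100], 20L)
  expect_equal(obs$alt_reads[obs$pos == 100], 6L)
  expect_equal(obs$af[obs$pos == 100], 0.3)
  expect_equal(obs$af_source[obs$pos == 100], "ad_derived")
  # multiallelic site splits into two keys sharing chrom/pos/ref
  multi <- obs[obs$pos == 200, ]
  expect_equal(nrow(multi), 2L)
  expect_equal(sort(multi$alt), c("A", "T"))
  expect_equal(multi$alt_reads, c(12L, 8L))
})

test_that("caller AF field takes precedence over AD-derived AF", {
  vcf <- write_test_vcf(
    data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
               dp = 20L, ad = "14,6", af = 0.25, stringsAsFactors = FALSE),
    tempfile(fileext = ".vcf"), with_af = TRUE)
  obs <- read_vcf(vcf)
  expect_equal(obs$af, 0.25)
  expect_equal(obs$af_source, "caller_af")
})

test_that("read_vcf matches an independent line-by-line parse of a fixture", {
  set.seed(7)
  rows <- data.frame(chrom = "1", pos = sort(sample(1e6, 5)),
                     ref = sample(c("A", "C", "G", "T"), 5, TRUE),
                     dp = sample(20:60, 5), stringsAsFactors = FALSE)
  rows$alt <- vapply(rows$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  rows$ad <- paste(rows$dp - 5L, 5L, sep = ",")
  path <- write_test_vcf(rows, tempfile(fileext = ".vcf"))
  obs <- read_vcf(path)
  # oracle: raw text parse
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  fields <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(nrow(obs), length(lines))
  expect_equal(variant_key(obs),
               paste(fields[, 1], fields[, 2], fields[, 4], fields[, 5], sep = ":"))
  expect_equal(obs$depth, as.integer(vapply(strsplit(fields[, 10], ":"),
                                            `[`, character(1), 1)))
})

test_that("read_vcf errors name the missing sample and bad records", {
  vcf <- write_test_vcf(
    data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G", dp = 10L,
               ad = "7,3", stringsAsFactors = FALSE),
    tempfile(fileext = ".vcf"), sample = "TUMOR")
  expect_error(read_vcf(vcf, sample = "NOPE"), "TUMOR")
  expect_silent(suppressWarnings(read_vcf(vcf, sample = "TUMOR")))
})

test_that("join_trio outer-joins on the variant key", {
  obs <- function(pos) {
    data.frame(chrom = "1", pos = pos, ref = "A", alt = "G",
               depth = 50L, alt_reads = 10L, af = 0.2, map_q = 60,
               base_q = 30, consequence = "missense_variant", gene = "",
               stringsAsFactors = FALSE)
  }
  trio <- join_trio(primary = obs(c(100L, 200L)), pdx = obs(c(200L, 300L)),
                    model_id = "M1")
  expect_equal(nrow(trio), 3L)
  expect_equal(has_observation(trio, "pdx"), c(FALSE, TRUE, TRUE))
  expect_equal(has_observation(trio, "primary"), c(TRUE, TRUE, FALSE))
  expect_true(all(!has_observation(trio, "germline")))

  # identical inputs: both observations present with equal AF everywhere
  same <- join_trio(primary = obs(c(1L, 2L)), pdx = obs(c(1L, 2L)))
  expect_true(all(same$primary_af == same$pdx_af))

  expect_error(join_trio(primary = obs(c(100L, 100L)), pdx = obs(100L)),
               "duplicate")
  expect_error(join_trio(germline = obs(1L)), "neither primary nor pdx")
})

test_that("join_trio equals a brute-force dictionary merge on random keys", {
  set.seed(42)
  mk <- function(keys) {
    data.frame(chrom = "1", pos = keys, ref = "A", alt = "G",
               depth = sample(10:100, length(keys), TRUE),
               alt_reads = 3L, af = 0.1, map_q = 60, base_q = 30,
               consequence = "", gene = "", stringsAsFactors = FALSE)
  }
  pool <- sample(1e5, 50)
  p <- mk(sample(pool, 30)); x <- mk(sample(pool, 30)); g <- mk(sample(pool, 20))
  trio <- join_trio(germline = g, primary = p, pdx = x)
  # oracle: named-list merge
  dict <- new.env()
  add <- function(df, role) for (i in seq_len(nrow(df))) {
    k <- as.character(df$pos[i])
    cur <- if (!is.null(dict[[k]])) dict[[k]] else character(0)
    dict[[k]] <- c(cur, role)
  }
  add(g, "g"); add(p, "p"); add(x, "x")
  keys <- ls(dict)
  expect_equal(nrow(trio), length(keys))
  roles <- vapply(as.character(trio$pos), function(k)
    paste(sort(dict[[k]]), collapse = ""), character(1))
  got <- paste0(ifelse(has_observation(trio, "germline"), "g", ""),
                ifelse(has_observation(trio, "primary"), "p", ""),
                ifelse(has_observation(trio, "pdx"), "x", ""))
  expect_equal(got, unname(roles))
  # presence conservation
  expect_equal(sum(has_observation(trio, "germline")) +
                 sum(has_observation(trio, "primary")) +
                 sum(has_observation(trio, "pdx")),
               nrow(g) + nrow(p) + nrow(x))
})

test_that("harmonized table round-trips trio records", {
  set.seed(5)
  trios <- random_trios(40)
  path <- tempfile(fileext = ".tsv")
  write_variant_table(trios, path)
  back <- trios_from_table(read_variant_table(path))
  ord <- function(d) {
    d <- d[order(d$model_id, d$chrom, as.integer(d$pos), d$ref, d$alt), ]
    rownames(d) <- NULL
    d
  }
  a <- ord(as.data.frame(trios)); b <- ord(as.data.frame(back))
  expect_equal(b[, sort(names(b))], a[, sort(names(a))], tolerance = 1e-12)
})

test_that("read_segments handles cn, log2-only and empty files, rejects overlaps", {
  p <- write_test_cns(data.frame(chrom = "chr9", start = 0L, end = 1000L,
                                 cn = 1L, log2 = NA), tempfile())
  seg <- read_segments(p)
  expect_equal(seg$cn, 1L)
  expect_equal(seg$chrom, "9")

  p2 <- write_test_cns(data.frame(chrom = "1", start = 0L, end = 500L,
                                  log2 = -1.05, cn = NA), tempfile())
  # oracle: round(2 * 2^log2)
  expect_equal(read_segments(p2)$cn, as.integer(round(2 * 2^-1.05)))

  p3 <- tempfile()
  writeLines("chromosome\tstart\tend\tlog2\tcn", p3)
  expect_equal(nrow(read_segments(p3)), 0L)

  p4 <- write_test_cns(data.frame(chrom = "1", start = c(0L, 400L),
                                  end = c(500L, 900L), cn = c(2L, 3L),
                                  log2 = NA), tempfile())
  expect_error(read_segments(p4), "overlapping")
})
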