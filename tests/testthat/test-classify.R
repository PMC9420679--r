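test_that("canonical trios get the expected fidelity labels", {
  trios <- make_trios(
    p_af = c(0.30, 0.00, 0.06, 0.25, 0.05),
    x_af = c(0.28, 0.40, 0.35, 0.04, 0.04),
    p_alt = c(12L, 0L, 2L, 25L, 5L),
    x_alt = c(10L, 20L, 18L, 2L, 4L))
  cl <- classify_variants(trios)
  expect_equal(as.character(cl$label),
               c("shared",            # both supported, AF reached
                 "newly_detected",    # absent from primary entirely
                 "newly_detected",    # primary >0 but below threshold
                 "newly_undetected",  # lost in PDX
                 "not_comparable"))   # below threshold on both sides
  expect_equal(cl$below_threshold_in_primary,
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("absent observations are coerced to AF 0 and both-absent errors", {
  trios <- make_trios(p_af = NA_real_, x_af = 0.4, p_alt = NA_integer_,
                      x_alt = 20L, p_depth = NA_integer_)
  cl <- classify_variants(trios)
  expect_equal(as.character(cl$label), "newly_detected")
  expect_equal(cl$primary_af, 0)
  expect_false(cl$below_threshold_in_primary)

  none <- trios
  none$pdx_depth <- NA_integer_
  expect_error(classify_variants(none), "neither primary nor pdx")
})

test_that("labels on a threshold grid match the brute-force rule table", {
  afs <- c(0, 0.02, 0.05, 0.09, 0.1, 0.11, 0.2, 0.5)
  alts <- c(0L, 1L, 2L, 3L, 4L, 10L)
  grid <- expand.grid(p_af = afs, x_af = afs, p_alt = alts, x_alt = alts)
  trios <- make_trios(p_af = grid$p_af, x_af = grid$x_af,
                      p_alt = grid$p_alt, x_alt = grid$x_alt)
  cl <- classify_variants(trios)
  want <- mapply(oracle_label, grid$p_af, grid$x_af, grid$p_alt, grid$x_alt)
  expect_equal(as.character(cl$label), unname(want))
})

test_that("boundaries are inclusive: AF exactly 0.1 and exactly 3 alt reads", {
  trios <- make_trios(p_af = c(0.1, 0.1), x_af = c(0.05, 0.05),
                      p_alt = c(3L, 2L), x_alt = c(3L, 3L))
  cl <- classify_variants(trios)
  expect_equal(as.character(cl$label), c("shared", "newly_undetected"))
})

test_that("swapping primary and pdx swaps N/D and N/U, fixing the rest", {
  set.seed(31)
  trios <- random_trios(400, with_germline = FALSE)
  cl <- classify_variants(trios)
  swapped <- trios
  for (suf in c("_depth", "_alt", "_af", "_mapq", "_baseq")) {
    a <- paste0("primary", suf); b <- paste0("pdx", suf)
    tmp <- swapped[[a]]; swapped[[a]] <- swapped[[b]]; swapped[[b]] <- tmp
  }
  cl2 <- classify_variants(swapped)
  map <- c(shared = "shared", newly_detected = "newly_undetected",
           newly_undetected = "newly_detected",
           not_comparable = "not_comparable")
  expect_equal(as.character(cl2$label), unname(map[as.character(cl$label)]))
})

test_that("every passing variant gets exactly one label and counts partition", {
  set.seed(8)
  trios <- random_trios(500)
  out <- run_filters(trios)
  cl <- classify_variants(out)
  expect_equal(nrow(cl), sum(out$passed))
  expect_false(anyNA(cl$label))
  counts <- summarize_counts(cl)
  expect_equal(sum(counts[, c("shared", "newly_detected", "newly_undetected",
                              "not_comparable")]), nrow(cl))
})

test_that("raising detect_af never increases the shared count", {
  set.seed(12)
  trios <- random_trios(400, with_germline = FALSE)
  n_shared <- vapply(c(0.05, 0.1, 0.2, 0.4), function(d) {
    sum(classify_variants(trios, classify_config(detect_af = d))$label == "shared")
  }, numeric(1))
  expect_true(all(diff(n_shared) <= 0))
})

test_that("count summaries tally per model, zeros included", {
  trios <- make_trios(p_af = c(0.3, 0.3, 0.3, 0, 0, 0.4),
                      x_af = c(0.3, 0.3, 0.3, 0.4, 0.2, 0.02),
                      p_alt = c(30L, 30L, 30L, 0L, 0L, 40L),
                      x_alt = c(30L, 30L, 30L, 40L, 20L, 2L))
  cl <- classify_variants(trios)
  counts <- summarize_counts(cl)
  expect_equal(counts$shared, 3L)
  expect_equal(counts$newly_detected, 2L)
  expect_equal(counts$newly_undetected, 1L)
  # a model with no classified variants yields a zero row
  cl2 <- cl[0, ]
  expect_equal(nrow(summarize_counts(cl2)), 0L)
})

test_that("median AF summary uses the documented sample for each label", {
  trios <- make_trios(p_af = c(0, 0, 0, 0.25, 0.3),
                      x_af = c(0.1, 0.2, 0.4, 0.02, 0.02),
                      p_alt = c(0L, 0L, 0L, 25L, 30L),
                      x_alt = c(10L, 20L, 40L, 2L, 2L))
  cl <- classify_variants(trios)
  s <- median_af_summary(cl)
  all_row <- s[s$group == "All", ]
  expect_equal(all_row$nd_median_af, 0.2)       # odd-n median of pdx AFs
  expect_equal(all_row$nu_median_af, 0.275)     # even-n midpoint of primary AFs
  expect_equal(all_row$n_shared, 0L)
  expect_true(is.na(all_row$shared_median_af_primary))  # empty cell is NA, not 0

  single <- classify_variants(make_trios(p_af = 0, x_af = 0.18,
                                         p_alt = 0L, x_alt = 18L))
  expect_equal(median_af_summary(single)$nd_median_af[1], 0.18)
})

test_that("group medians pool variants within subtype groups", {
  trios <- rbind(
    make_trios(p_af = c(0, 0), x_af = c(0.2, 0.3), p_alt = c(0L, 0L),
               x_alt = c(20L, 30L), model_id = "M1", subtype = "DLBCL"),
    make_trios(p_af = 0, x_af = 0.5, p_alt = 0L, x_alt = 50L,
               model_id = "M2", subtype = "AITL"))
  class(trios) <- c("trio_records", "data.frame")
  s <- median_af_summary(classify_variants(trios), per_model = TRUE)
  expect_equal(s$nd_median_af[s$group == "All"], 0.3)
  expect_equal(s$nd_median_af[s$group == "DLBCL"], 0.25)
  expect_equal(s$nd_median_af[s$group == "T-NHL"], 0.5)
  pm <- attr(s, "per_model")
  expect_equal(sort(pm$model_id), c("M1", "M2"))
})

test_that("gene-list annotation flags exact case-normalized membership", {
  trios <- make_trios(p_af = rep(0, 4), x_af = rep(0.4, 4),
                      p_alt = rep(0L, 4), x_alt = rep(40L, 4),
                      subtype = "AITL")
  trios$gene <- c("STAT1", "znf708", "RHOA", "NOTAGENE")
  cl <- classify_variants(trios)
  lists <- list(`T-NHL` = c("STAT1", "ZNF708", "RHOA"))
  ann <- annotate_gene_list(cl, lists)
  expect_equal(ann$on_gene_list, c(TRUE, TRUE, TRUE, FALSE))
  hits <- gene_list_hits(ann)
  expect_equal(hits$nd_genes, "RHOA, STAT1, ZNF708")
  expect_equal(hits$nu_genes, "0")

  # empty list: all flags FALSE, hit set rendered "0"
  ann0 <- annotate_gene_list(cl, list(`T-NHL` = character(0)))
  expect_false(any(ann0$on_gene_list))
  expect_equal(gene_list_hits(ann0)$nd_genes, "0")

  expect_error(annotate_gene_list(cl, list(DLBCL = "MYC")), "T-NHL")
})

test_that("gene-list flags equal brute-force set membership on random symbols", {
  set.seed(44)
  symbols <- sprintf("G%03d", 1:60)
  listed <- sample(symbols, 20)
  trios <- make_trios(p_af = rep(0.3, 100), x_af = rep(0.3, 100),
                      p_alt = rep(30L, 100), x_alt = rep(30L, 100))
  trios$gene <- sample(symbols, 100, replace = TRUE)
  ann <- annotate_gene_list(classify_variants(trios), list(DLBCL = listed))
  expect_equal(ann$on_gene_list, ann$gene %in% listed)
})

test_that("substitution spectrum separates transitions from transversions", {
  trios <- make_trios(p_af = rep(0, 4), x_af = rep(0.4, 4),
                      p_alt = rep(0L, 4), x_alt = rep(40L, 4))
  trios$ref <- c("A", "C", "G", "AT")
  trios$alt <- c("G", "A", "A", "A")   # ti, tv, ti (G>A ~ C>T), deletion
  cl <- classify_variants(trios)
  sp <- substitution_spectrum(cl, "newly_detected")
  expect_equal(sp$n_snv, 3L)
  expect_equal(sp$n_indel, 1L)
  expect_equal(sp$transitions, 2L)     # A>G and G>A
  expect_equal(sp$transversions, 1L)   # C>A
})

test_that("spectrum classes are pyrimidine-anchored and transitions are A<->G, C<->T", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  trios <- make_trios(p_af = rep(0, nrow(pairs)), x_af = rep(0.4, nrow(pairs)),
                      p_alt = rep(0L, nrow(pairs)), x_alt = rep(40L, nrow(pairs)))
  trios$ref <- pairs$ref
  trios$alt <- pairs$alt
  sp <- substitution_spectrum(classify_variants(trios), "newly_detected")
  expect_equal(sum(sp$counts), 12L)
  # all 12 possible SNVs: 4 transitions (A>G, G>A, C>T, T>C), 8 transversions
  expect_equal(sp$transitions, 4L)
  expect_equal(sp$transversions, 8L)
  expect_equal(sp$transition_fraction, 1 / 3)
  expect_equal(unname(sp$counts[c("C>T", "T>C")]), c(2L, 2L))
})
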