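# Cohort metadata, the central pdx_fidelity() analysis object, and the
# end-to-end report pipeline.

COHORT_SUBTYPES <- c("DLBCL", "tDLBCL", "BL", "MCL", "AITL", "PTCL-NOS", "ALCL")

#' Read and validate cohort metadata
#'
#' The metadata TSV has one row per PDX model with columns patient_id,
#' model_id, subtype, disease_status (Dg or R/R), sample_origin and
#' wes_available (TRUE/FALSE or Yes/No). Duplicate model ids and unknown
#' subtypes are errors. Derived counts (total models, WES-available models,
#' per-subtype-group tallies) are exposed by the print/summary methods.
#'
#' @param path metadata TSV path.
#' @return data frame of class `cohort_metadata`.
#' @export
read_cohort_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "model_id", "subtype", "disease_status",
            "sample_origin", "wes_available")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("cohort metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("cohort metadata file ", path, " is empty")
  dup <- unique(df$model_id[duplicated(df$model_id)])
  if (length(dup) > 0L) {
    stop("duplicate model_id(s): ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(df$subtype), COHORT_SUBTYPES)
  if (length(bad) > 0L) {
    stop("unknown subtype(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(COHORT_SUBTYPES, collapse = ", "))
  }
  if (is.character(df$wes_available)) {
    df$wes_available <- toupper(df$wes_available) %in% c("TRUE", "YES", "Y", "1")
  }
  bad_ds <- setdiff(unique(df$disease_status), c("Dg", "R/R"))
  if (length(bad_ds) > 0L) {
    stop("unknown disease_status value(s): ", paste(bad_ds, collapse = ", "))
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cat("Cohort metadata:", nrow(x), "PDX models,",
      sum(x$wes_available), "with WES\n")
  tab <- table(subtype_group(x$subtype))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Genomic-fidelity analysis of a PDX trio cohort
#'
#' The package's central entry point: applies the somatic filters to the trio
#' records, classifies the passing variants as shared / newly detected /
#' newly undetected, and computes the per-model count table, the median
#' allele-fraction summary, the substitution spectrum of newly detected
#' variants, and (when gene lists are supplied) gene-list annotation and
#' per-model hit sets.
#'
#' @param trios trio-record data frame (from [trios_from_table()],
#'   [join_trio()] or [sample_reads()]).
#' @param gene_lists optional named list of per-group gene symbol vectors.
#' @param filter `filter_config`.
#' @param classify `classify_config`.
#' @param missing_consequence passed to [run_filters()].
#' @return object of class `pdx_fidelity` with elements `filters`
#'   (filter outcomes), `classified`, `counts`, `medians` (with per-model
#'   attribute), `spectrum`, `gene_hits` (NULL without lists), `config`.
#' @export
pdx_fidelity <- function(trios, gene_lists = NULL, filter = filter_config(),
                         classify = classify_config(),
                         missing_consequence = "exclude") {
  outcomes <- run_filters(trios, filter, missing_consequence)
  classified <- classify_variants(outcomes, classify)
  gene_hits <- NULL
  if (!is.null(gene_lists)) {
    classified <- annotate_gene_list(classified, gene_lists)
    gene_hits <- gene_list_hits(classified)
  }
  structure(list(filters = outcomes,
                 classified = classified,
                 counts = summarize_counts(classified),
                 medians = median_af_summary(classified, per_model = TRUE),
                 spectrum = substitution_spectrum(classified, "newly_detected"),
                 gene_hits = gene_hits,
                 config = list(filter = filter, classify = classify)),
            class = "pdx_fidelity")
}

#' @export
print.pdx_fidelity <- function(x, ...) {
  n <- nrow(x$filters)
  cat("PDX genomic-fidelity analysis\n")
  cat(sprintf("  %d trio records in %d model(s); %d passed filters (%.1f%%)\n",
              n, length(unique(x$filters$model_id)), sum(x$filters$passed),
              if (n > 0) 100 * mean(x$filters$passed) else NA))
  tot <- colSums(x$counts[, FIDELITY_LABELS, drop = FALSE])
  cat(sprintf("  labels: %s\n",
              paste(names(tot), tot, sep = "=", collapse = ", ")))
  if (!is.na(x$spectrum$transition_fraction)) {
    cat(sprintf("  N/D transition fraction: %.3f (%d SNVs)\n",
                x$spectrum$transition_fraction, x$spectrum$n_snv))
  }
  invisible(x)
}

#' @export
summary.pdx_fidelity <- function(object, ...) {
  out <- list(counts = object$counts, medians = object$medians,
              spectrum = object$spectrum, gene_hits = object$gene_hits,
              exclusions = table(unlist(strsplit(
                object$filters$reasons[!object$filters$passed], ";"))))
  class(out) <- "summary.pdx_fidelity"
  out
}

#' @export
print.summary.pdx_fidelity <- function(x, ...) {
  cat("Per-model variant counts:\n")
  print(x$counts, row.names = FALSE)
  cat("\nMedian allele fractions by group:\n")
  print(x$medians, row.names = FALSE, digits = 3)
  cat("\nExclusion reasons:\n")
  print(x$exclusions)
  if (!is.null(x$gene_hits)) {
    cat("\nGene-list hits per model:\n")
    print(x$gene_hits, row.names = FALSE)
  }
  invisible(x)
}

LABEL_COLORS <- c(shared = "grey40", newly_detected = "firebrick",
                  newly_undetected = "dodgerblue3", not_comparable = "grey80")

#' Plot a fidelity analysis
#'
#' `which = "scatter"` draws primary vs PDX allele fractions colored by label
#' (gene-list hits, when annotated, are text-labelled); `which = "bars"`
#' draws the per-model stacked bar chart of shared / N-D / N-U counts.
#'
#' @param x `pdx_fidelity` object.
#' @param which "scatter" or "bars".
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.pdx_fidelity <- function(x, which = c("scatter", "bars"), ...) {
  which <- match.arg(which)
  cl <- x$classified
  if (which == "scatter") {
    plot(cl$primary_af, cl$pdx_af, col = LABEL_COLORS[as.character(cl$label)],
         pch = 16, cex = 0.7, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "allele fraction, primary", ylab = "allele fraction, PDX", ...)
    graphics::abline(h = x$config$classify$detect_af,
                     v = x$config$classify$detect_af, lty = 3, col = "grey60")
    if (!is.null(cl$on_gene_list) && any(cl$on_gene_list)) {
      hit <- cl$on_gene_list
      graphics::text(cl$primary_af[hit], cl$pdx_af[hit], cl$gene[hit],
                     pos = 3, cex = 0.6)
    }
    graphics::legend("topleft", legend = names(LABEL_COLORS),
                     col = LABEL_COLORS, pch = 16, cex = 0.7, bty = "n")
  } else {
    m <- t(as.matrix(x$counts[, c("shared", "newly_detected",
                                  "newly_undetected")]))
    colnames(m) <- x$counts$model_id
    graphics::barplot(m, col = LABEL_COLORS[rownames(m)], las = 2,
                      ylab = "variants", ...)
    graphics::legend("topright", legend = rownames(m),
                     fill = LABEL_COLORS[rownames(m)], cex = 0.7, bty = "n")
  }
  invisible(x)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full fidelity pipeline and write a report bundle
#'
#' Reads a harmonized variant table (path or data frame), optionally cohort
#' metadata, a gene list and per-sample copy-number segment files, runs
#' [pdx_fidelity()], and writes per-model and cohort-level TSV tables, plots
#' (PNG; rendering failures are downgraded to warnings) and a JSON run
#' manifest echoing every threshold actually applied. Re-running with
#' identical inputs reproduces byte-identical tables.
#'
#' @param variants harmonized variant table path or long-format data frame.
#' @param out_dir output directory (created if needed).
#' @param metadata optional cohort metadata TSV path.
#' @param gene_list optional gene list path (tabular subtype/gene).
#' @param gene_bed optional BED of gene coordinates for the CNV comparison.
#' @param segments_primary,segments_pdx optional CNVkit-style segment paths.
#' @param filter,classify configuration objects.
#' @param dry_run validate all inputs, write nothing.
#' @return the `pdx_fidelity` object (with a `cnv` element when segments were
#'   given), invisibly.
#' @export
run_pipeline <- function(variants, out_dir, metadata = NULL, gene_list = NULL,
                         gene_bed = NULL, segments_primary = NULL,
                         segments_pdx = NULL, filter = filter_config(),
                         classify = classify_config(), dry_run = FALSE) {
  long <- if (is.character(variants)) read_variant_table(variants) else variants
  meta <- if (!is.null(metadata)) read_cohort_metadata(metadata) else NULL
  lists <- if (!is.null(gene_list)) read_gene_list(gene_list) else NULL
  if (is.character(lists)) lists <- list(ALL = lists)
  genes <- if (!is.null(gene_bed)) read_gene_bed(gene_bed) else NULL
  segs_p <- if (!is.null(segments_primary)) read_segments(segments_primary) else NULL
  segs_x <- if (!is.null(segments_pdx)) read_segments(segments_pdx) else NULL
  if (dry_run) {
    message("dry run: all inputs validated, nothing written")
    return(invisible(NULL))
  }

  trios <- if (inherits(long, "trio_records")) long else trios_from_table(long)
  fit <- pdx_fidelity(trios, gene_lists = lists, filter = filter,
                      classify = classify)
  if (!is.null(genes) && !is.null(segs_p) && !is.null(segs_x)) {
    cmp <- compare_gene_calls(
      segments_to_gene_calls(segs_p, genes, "primary"),
      segments_to_gene_calls(segs_x, genes, "pdx"))
    fit$cnv <- cmp
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_filter_audit(fit$filters, file.path(out_dir, "filter_audit.tsv"))
  cl <- fit$classified
  cl_out <- data.frame(key = variant_key(cl), model_id = cl$model_id,
                       label = as.character(cl$label),
                       primary_af = cl$primary_af, pdx_af = cl$pdx_af,
                       below_threshold_in_primary = cl$below_threshold_in_primary,
                       on_gene_list = if (is.null(cl$on_gene_list)) NA else cl$on_gene_list,
                       gene = cl$gene, stringsAsFactors = FALSE)
  .write_tsv(cl_out, file.path(out_dir, "classified_variants.tsv"))
  .write_tsv(fit$counts, file.path(out_dir, "counts_per_model.tsv"))
  .write_tsv(fit$medians, file.path(out_dir, "median_af_by_group.tsv"))
  .write_tsv(attr(fit$medians, "per_model"),
             file.path(out_dir, "median_af_by_model.tsv"))
  if (!is.null(fit$gene_hits)) {
    .write_tsv(fit$gene_hits, file.path(out_dir, "gene_list_hits.tsv"))
  }
  spec_df <- data.frame(class = names(fit$spectrum$counts),
                        count = fit$spectrum$counts)
  .write_tsv(spec_df, file.path(out_dir, "nd_substitution_spectrum.tsv"))
  if (!is.null(fit$cnv)) {
    .write_tsv(fit$cnv, file.path(out_dir, "cnv_gene_comparison.tsv"))
  }

  for (p in c("scatter", "bars")) {
    tryCatch({
      grDevices::png(file.path(out_dir, paste0("af_", p, ".png")),
                     width = 900, height = 700)
      plot(fit, which = p)
      grDevices::dev.off()
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning("plot '", p, "' failed: ", conditionMessage(e))
    })
  }

  manifest <- list(
    n_records = nrow(trios),
    n_models = length(unique(trios$model_id)),
    n_passed = sum(fit$filters$passed),
    labels = as.list(colSums(fit$counts[, FIDELITY_LABELS, drop = FALSE])),
    filter = fit$config$filter[setdiff(names(fit$config$filter), "class")],
    classify = unclass(fit$config$classify),
    cnv_concordance = if (!is.null(fit$cnv)) attr(fit$cnv, "concordance") else NULL,
    metadata = if (!is.null(meta)) list(n_models = nrow(meta),
                                        n_wes = sum(meta$wes_available)) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("pipeline: %d records -> %d passed -> labels %s",
                  nrow(trios), sum(fit$filters$passed),
                  paste(unlist(manifest$labels), collapse = "/")))
  invisible(fit)
}

#' Reproduce the pooled median-AF summary from a deposited variant list
#'
#' Convenience wrapper for re-deriving the group-level median allele-fraction
#' table from an externally deposited harmonized variant table: reads the
#' table, builds trios, applies the default filters and classifier, and
#' returns [median_af_summary()].
#'
#' @param path harmonized variant table TSV.
#' @param filter,classify configuration objects.
#' @return median-AF summary data frame.
#' @export
reproduce_deposited_summary <- function(path, filter = filter_config(),
                                        classify = classify_config()) {
  fit <- pdx_fidelity(trios_from_table(read_variant_table(path)),
                      filter = filter, classify = classify)
  fit$medians
}
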