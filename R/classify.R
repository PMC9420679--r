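# Fidelity classification: shared / newly-detected (N/D) / newly-undetected
# (N/U) labels for filtered trio variants, with cohort count and median-AF
# summaries, gene-list annotation, and the substitution spectrum of SNVs.

FIDELITY_LABELS <- c("shared", "newly_detected", "newly_undetected",
                     "not_comparable")

#' Classification configuration
#'
#' A variant is *shared* when it is supported by at least `min_alt_reads_both`
#' alternate reads in both the primary and the PDX sample and reaches allele
#' fraction `detect_af` in at least one of them. Failing that, one-sided
#' detection (AF >= `detect_af`) in the PDX labels it newly detected, in the
#' primary newly undetected; when both samples reach the detection AF but one
#' lacks the required read support, the undersupported side decides (so the
#' labels are symmetric under swapping the compared samples); otherwise the
#' variant is not comparable. Both boundaries are inclusive.
#'
#' @param detect_af detection allele-fraction threshold in (0,1), default 0.1.
#' @param min_alt_reads_both minimum alternate reads required in both samples
#'   for the shared call, default 3.
#' @return object of class `classify_config`.
#' @export
classify_config <- function(detect_af = 0.1, min_alt_reads_both = 3L) {
  stopifnot(detect_af > 0, detect_af < 1, min_alt_reads_both >= 1)
  structure(list(detect_af = detect_af,
                 min_alt_reads_both = as.integer(min_alt_reads_both)),
            class = "classify_config")
}

#' Classify filtered trio variants as shared / N-D / N-U
#'
#' Applies the decision procedure of [classify_config()] to each record.
#' Observations absent from the primary or PDX sample are coerced to allele
#' fraction 0 with 0 alternate reads (the locus was not reported there); a
#' record with neither observation is an error. `below_threshold_in_primary`
#' flags newly detected variants that were present in the primary sample at a
#' positive allele fraction below the detection threshold.
#'
#' @param trios trio records; when the result of [run_filters()] is supplied,
#'   only passing records are classified.
#' @param config `classify_config`.
#' @return data frame of classified variants: key and metadata columns plus
#'   `label`, `primary_af`, `pdx_af`, `primary_alt`, `pdx_alt`,
#'   `below_threshold_in_primary`; class `classified_variants`.
#' @export
classify_variants <- function(trios, config = classify_config()) {
  if (!is.null(trios$passed)) trios <- trios[trios$passed, , drop = FALSE]
  if (nrow(trios) > 0L &&
      any(!has_observation(trios, "primary") & !has_observation(trios, "pdx"))) {
    stop("record(s) with neither primary nor pdx observation cannot be classified")
  }
  p_af <- ifelse(has_observation(trios, "primary"), trios$primary_af, 0)
  x_af <- ifelse(has_observation(trios, "pdx"), trios$pdx_af, 0)
  p_alt <- ifelse(has_observation(trios, "primary"), trios$primary_alt, 0L)
  x_alt <- ifelse(has_observation(trios, "pdx"), trios$pdx_alt, 0L)

  d <- config$detect_af
  m <- config$min_alt_reads_both
  shared <- p_alt >= m & x_alt >= m & pmax(p_af, x_af) >= d
  # One-sided detection labels N/D and N/U. When both samples reach the
  # detection AF but the shared criterion fails on read support, the
  # undersupported side decides (keeping the labels symmetric under sample
  # swap); if neither sample has the required support the record is not
  # comparable.
  nd <- !shared & x_af >= d & (p_af < d | (p_alt < m & x_alt >= m))
  nu <- !shared & !nd & p_af >= d & (x_af < d | (x_alt < m & p_alt >= m))
  label <- ifelse(shared, "shared",
           ifelse(nd, "newly_detected",
           ifelse(nu, "newly_undetected", "not_comparable")))

  keep <- c("patient_id", "model_id", "subtype", "chrom", "pos", "ref", "alt",
            "consequence", "gene")
  out <- trios[, intersect(keep, names(trios)), drop = FALSE]
  out$label <- factor(label, levels = FIDELITY_LABELS)
  out$primary_af <- p_af
  out$pdx_af <- x_af
  out$primary_alt <- p_alt
  out$pdx_alt <- x_alt
  out$below_threshold_in_primary <- label == "newly_detected" &
    p_af > 0 & p_af < config$detect_af
  rownames(out) <- NULL
  class(out) <- c("classified_variants", "data.frame")
  out
}

#' Per-model counts of shared / N-D / N-U variants
#'
#' @param classified result of [classify_variants()].
#' @return data frame with one row per model and columns `shared`,
#'   `newly_detected`, `newly_undetected`, `not_comparable`; counts partition
#'   the classified set.
#' @export
summarize_counts <- function(classified) {
  models <- unique(classified$model_id)
  tab <- table(factor(classified$model_id, levels = models),
               classified$label)
  out <- data.frame(model_id = models, as.data.frame.matrix(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out) <- c("model_id", FIDELITY_LABELS)
  out
}

# Collapse cohort subtypes into the reporting groups: DLBCL pools transformed
# DLBCL; T-NHL pools the T-cell entities.
#' Map a cohort subtype to its reporting group
#' @param subtype character vector of subtypes.
#' @return character vector over {DLBCL, MCL, BL, T-NHL}.
#' @export
subtype_group <- function(subtype) {
  map <- c(DLBCL = "DLBCL", tDLBCL = "DLBCL", BL = "BL", Burkitt = "BL",
           MCL = "MCL", AITL = "T-NHL", `PTCL-NOS` = "T-NHL", ALCL = "T-NHL",
           `T-NHL` = "T-NHL")
  out <- unname(map[as.character(subtype)])
  if (anyNA(out)) {
    stop("unknown subtype(s): ",
         paste(unique(subtype[is.na(out)]), collapse = ", "))
  }
  out
}

.median_or_na <- function(x) if (length(x) == 0L) NA_real_ else median(x)

#' Median allele-fraction summary per reporting group
#'
#' For each group (all models pooled, then DLBCL, MCL, T-NHL, BL as present)
#' reports the pooled median allele fraction of newly detected variants
#' measured in the PDX, of newly undetected variants measured in the primary
#' sample, and of shared variants in each of the two samples. Medians use the
#' usual midpoint convention for even counts; empty cells are NA, not 0.
#'
#' @param classified result of [classify_variants()].
#' @param per_model also return per-model medians (attribute "per_model").
#' @return data frame with columns group, n_nd, nd_median_af, n_nu,
#'   nu_median_af, n_shared, shared_median_af_primary, shared_median_af_pdx.
#' @export
median_af_summary <- function(classified, per_model = FALSE) {
  grp <- subtype_group(classified$subtype)
  groups <- c("All", intersect(c("DLBCL", "MCL", "T-NHL", "BL"), unique(grp)))
  one <- function(sub) {
    nd <- sub[sub$label == "newly_detected", , drop = FALSE]
    nu <- sub[sub$label == "newly_undetected", , drop = FALSE]
    sh <- sub[sub$label == "shared", , drop = FALSE]
    data.frame(n_nd = nrow(nd), nd_median_af = .median_or_na(nd$pdx_af),
               n_nu = nrow(nu), nu_median_af = .median_or_na(nu$primary_af),
               n_shared = nrow(sh),
               shared_median_af_primary = .median_or_na(sh$primary_af),
               shared_median_af_pdx = .median_or_na(sh$pdx_af))
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- if (g == "All") classified else classified[grp == g, , drop = FALSE]
    cbind(data.frame(group = g, stringsAsFactors = FALSE), one(sub))
  }))
  rownames(out) <- NULL
  if (per_model) {
    pm <- do.call(rbind, lapply(split(classified, classified$model_id),
                                function(m) cbind(data.frame(model_id = m$model_id[1L]),
                                                  one(m))))
    rownames(pm) <- NULL
    attr(out, "per_model") <- pm
  }
  out
}

#' Annotate classified variants against per-subtype gene lists
#'
#' Sets `on_gene_list` TRUE when the variant's gene symbol (case-normalized)
#' belongs to the list for the model's reporting group. A model whose group
#' has no list is an error naming the group.
#'
#' @param classified result of [classify_variants()].
#' @param gene_lists named list of character vectors, names over
#'   {DLBCL, MCL, BL, T-NHL} (as from [read_gene_list()] on a tabular list).
#' @return `classified` with an `on_gene_list` column.
#' @export
annotate_gene_list <- function(classified, gene_lists) {
  grp <- subtype_group(classified$subtype)
  missing <- setdiff(unique(grp), names(gene_lists))
  if (length(missing) > 0L) {
    stop("no gene list for subtype group(s): ", paste(missing, collapse = ", "))
  }
  gene_lists <- lapply(gene_lists, toupper)
  on <- logical(nrow(classified))
  for (g in unique(grp)) {
    i <- grp == g
    on[i] <- toupper(classified$gene[i]) %in% gene_lists[[g]]
  }
  classified$on_gene_list <- on & !is.na(classified$gene) & classified$gene != ""
  classified
}

#' Per-model gene-list hit sets for N-D and N-U variants
#'
#' @param classified annotated result of [annotate_gene_list()].
#' @return data frame with one row per model: `nd_genes` and `nu_genes` as
#'   comma-joined gene-symbol sets, "0" when empty (the conventional table
#'   notation for "no gene-list variant").
#' @export
gene_list_hits <- function(classified) {
  if (is.null(classified$on_gene_list)) {
    stop("run annotate_gene_list() first")
  }
  fmt <- function(g) if (length(g) == 0L) "0" else paste(sort(unique(g)), collapse = ", ")
  out <- do.call(rbind, lapply(split(classified, classified$model_id), function(m) {
    data.frame(model_id = m$model_id[1L],
               nd_genes = fmt(toupper(m$gene[m$on_gene_list & m$label == "newly_detected"])),
               nu_genes = fmt(toupper(m$gene[m$on_gene_list & m$label == "newly_undetected"])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Substitution spectrum of single-nucleotide variants
#'
#' Counts the six pyrimidine-anchored substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G; purine-reference changes are complemented) for the variants
#' carrying the requested label, and the transition fraction
#' transitions / (transitions + transversions), where transitions are A<->G
#' and C<->T (classes C>T and T>C). Indels and MNVs are excluded from the
#' spectrum and counted separately.
#'
#' @param classified result of [classify_variants()].
#' @param label restrict to one fidelity label (default "newly_detected");
#'   NULL uses all records.
#' @return list with `counts` (named integer vector over the six classes),
#'   `n_snv`, `n_indel`, `transitions`, `transversions`,
#'   `transition_fraction`.
#' @export
substitution_spectrum <- function(classified, label = "newly_detected") {
  sub <- if (is.null(label)) classified else
    classified[classified$label == label, , drop = FALSE]
  snv <- nchar(sub$ref) == 1L & nchar(sub$alt) == 1L
  ref <- sub$ref[snv]; alt <- sub$alt[snv]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- table(factor(paste0(ref, ">", alt), levels = classes))
  ti <- sum(counts[c("C>T", "T>C")])
  tv <- sum(counts) - ti
  list(counts = setNames(as.integer(counts), classes),
       n_snv = sum(snv), n_indel = sum(!snv),
       transitions = as.integer(ti), transversions = as.integer(tv),
       transition_fraction = if (ti + tv > 0) ti / (ti + tv) else NA_real_)
}
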