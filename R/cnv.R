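# Gene-level copy-number categorization and primary-vs-PDX comparison.
# Segmentation itself (CNVkit) is consumed, not re-implemented.

CN_CATEGORIES <- c("0", "1", "2", "3", ">3")

#' Integer copy number from a log2 ratio
#'
#' cn = round(2 * 2^log2), floored at 0. Exact .5 ties round away from the
#' neutral copy number 2 (so 2.5 -> 3 but 1.5 -> 1), keeping borderline
#' segments on the aberrant side. Exact for log2(c/2) with integer c >= 1.
#'
#' @param log2 numeric vector of log2 copy ratios (finite).
#' @return integer copy numbers >= 0.
#' @export
cn_from_log2 <- function(log2) {
  stopifnot(all(is.finite(log2)))
  x <- 2 * 2^log2
  lo <- floor(x)
  frac <- x - lo
  cn <- ifelse(frac > 0.5, lo + 1,
        ifelse(frac < 0.5, lo,
               ifelse(x > 2, lo + 1, lo)))  # ties: away from 2
  as.integer(pmax(cn, 0))
}

#' Categorize an integer copy number
#'
#' Categories follow the conventional ideogram legend: "0" biallelic deletion,
#' "1" monoallelic deletion, "2" neutral, "3" gain of one allele, ">3" gain of
#' more than one allele.
#'
#' @param cn integer vector >= 0.
#' @return character vector over {"0","1","2","3",">3"}.
#' @export
cn_category <- function(cn) {
  stopifnot(all(cn >= 0))
  ifelse(cn >= 4, ">3", as.character(as.integer(cn)))
}

#' Gene-level copy-number calls from segments
#'
#' Intersects each gene interval with the sample's segments. When a gene spans
#' several segments, the call is taken from the segment covering the largest
#' fraction of the gene; ties go to the more extreme category (larger |cn-2|,
#' then the deletion side). Genes with no overlapping segment are called
#' neutral (cn 2) with `covered = FALSE`.
#'
#' @param segments segment data frame (see [read_segments()]).
#' @param genes gene interval data frame (see [read_gene_bed()]).
#' @param sample_role label recorded on every call ("primary" or "pdx").
#' @return data frame with columns gene, sample_role, cn, category, covered.
#' @export
segments_to_gene_calls <- function(segments, genes, sample_role = "primary") {
  stopifnot(nrow(genes) > 0L)
  genes$chrom <- normalize_chrom(genes$chrom)
  if (any(genes$end <= genes$start)) stop("gene interval with end <= start")
  cn <- rep(2L, nrow(genes))
  covered <- rep(FALSE, nrow(genes))
  if (nrow(segments) > 0L) {
    seg_gr <- GenomicRanges::GRanges(
      segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    # genes on chromosomes with no segments are simply uncovered
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
    if (length(hits) > 0L) {
      gi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        gene_gr[gi], seg_gr[si]))
      frac <- ov / (genes$end[gi] - genes$start[gi])
      for (g in unique(gi)) {
        idx <- which(gi == g)
        cand_cn <- segments$cn[si[idx]]
        cand_frac <- frac[idx]
        best <- cand_frac == max(cand_frac)
        if (sum(best) > 1L) {
          extremity <- abs(cand_cn - 2L)
          best <- best & extremity == max(extremity[best])
          if (sum(best) > 1L) best <- best & cand_cn == min(cand_cn[best])
        }
        cn[g] <- cand_cn[which(best)[1L]]
        covered[g] <- TRUE
      }
    }
  }
  data.frame(gene = genes$gene, sample_role = sample_role, cn = cn,
             category = cn_category(cn), covered = covered,
             stringsAsFactors = FALSE)
}

#' Compare primary and PDX gene-level copy-number calls
#'
#' @param primary_calls,pdx_calls call tables from
#'   [segments_to_gene_calls()] over the same gene set; a gene missing from
#'   one side is an error.
#' @return data frame with one row per gene (gene, primary_category,
#'   pdx_category, concordant) and attribute `concordance` = fraction of
#'   genes with exactly matching categories.
#' @export
compare_gene_calls <- function(primary_calls, pdx_calls) {
  missing <- c(setdiff(primary_calls$gene, pdx_calls$gene),
               setdiff(pdx_calls$gene, primary_calls$gene))
  if (length(missing) > 0L) {
    stop("gene(s) present in only one sample's calls: ",
         paste(unique(missing), collapse = ", "))
  }
  idx <- match(primary_calls$gene, pdx_calls$gene)
  out <- data.frame(gene = primary_calls$gene,
                    primary_cn = primary_calls$cn,
                    pdx_cn = pdx_calls$cn[idx],
                    primary_category = primary_calls$category,
                    pdx_category = pdx_calls$category[idx],
                    stringsAsFactors = FALSE)
  out$concordant <- out$primary_category == out$pdx_category
  attr(out, "concordance") <- if (nrow(out) > 0L) mean(out$concordant) else NA_real_
  out
}
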