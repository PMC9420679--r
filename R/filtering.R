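# Somatic filtering: germline-polymorphism, coverage/quality and consequence
# filters applied to trio records, with exhaustive per-record exclusion
# reasons so every count in a report can be audited.

#' Default nonsynonymous consequence vocabulary
#'
#' Sequence-ontology terms counted as nonsynonymous coding changes. The set is
#' configurable through [filter_config()].
#' @export
nonsynonymous_terms_default <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "splice_acceptor_variant", "splice_donor_variant")
}

#' Filter configuration
#'
#' Thresholds follow the conventional trio comparison rules: coverage of at
#' least `min_depth` reads (inclusive) with mapping and base quality strictly
#' greater than `min_map_q`/`min_base_q` in all related samples, exclusion of
#' variants present in germline DNA at allele fraction strictly greater than
#' `germline_af_cutoff`, and restriction to nonsynonymous coding consequences.
#'
#' @param min_depth minimum total depth, inclusive (default 10).
#' @param min_map_q mapping-quality bound, strict (default 20).
#' @param min_base_q base-quality bound, strict (default 20).
#' @param germline_af_cutoff germline allele-fraction bound, strict
#'   (default 0.05).
#' @param nonsynonymous_terms consequence terms that pass the coding filter.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L, min_map_q = 20, min_base_q = 20,
                          germline_af_cutoff = 0.05,
                          nonsynonymous_terms = nonsynonymous_terms_default()) {
  stopifnot(min_depth >= 0, min_map_q >= 0, min_base_q >= 0,
            germline_af_cutoff >= 0, germline_af_cutoff <= 1,
            length(nonsynonymous_terms) > 0)
  structure(list(min_depth = as.integer(min_depth), min_map_q = min_map_q,
                 min_base_q = min_base_q,
                 germline_af_cutoff = germline_af_cutoff,
                 nonsynonymous_terms = nonsynonymous_terms),
            class = "filter_config")
}

#' Read a filter configuration from a YAML file
#' @param path YAML file whose keys mirror [filter_config()] arguments.
#' @return `filter_config` object.
#' @export
read_filter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown filter config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(filter_config, vals)
}

# Exclusion codes, in the order filters are applied (consequence, quality,
# germline); reasons lists always follow this order.
EXCLUSION_CODES <- c("NOT_NONSYNONYMOUS", "LOW_COVERAGE", "LOW_MAPQ",
                     "LOW_BASEQ", "GERMLINE_POLYMORPHISM")

#' Germline-polymorphism filter
#'
#' A record is excluded when a germline observation is present and its allele
#' fraction is strictly greater than the cutoff; an absent germline
#' observation passes.
#'
#' @param trios trio-record data frame.
#' @param cutoff allele-fraction cutoff in [0,1].
#' @return logical vector, TRUE = excluded as germline polymorphism.
#' @export
filter_germline <- function(trios, cutoff = 0.05) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  has_observation(trios, "germline") & !is.na(trios$germline_af) &
    trios$germline_af > cutoff
}

#' Coverage and quality filter
#'
#' Every observation present in the trio (germline included, when present)
#' must have depth >= `min_depth` and mapping/base quality strictly greater
#' than the bounds. Qualities recorded as NA (caller did not annotate them)
#' pass.
#'
#' @param trios trio-record data frame.
#' @param config `filter_config`.
#' @return data frame of logicals: columns LOW_COVERAGE, LOW_MAPQ, LOW_BASEQ.
#' @export
filter_quality <- function(trios, config = filter_config()) {
  fail_cov <- fail_mq <- fail_bq <- rep(FALSE, nrow(trios))
  for (r in TRIO_ROLES) {
    present <- has_observation(trios, r)
    d <- trios[[paste0(r, "_depth")]]
    mq <- trios[[paste0(r, "_mapq")]]
    bq <- trios[[paste0(r, "_baseq")]]
    fail_cov <- fail_cov | (present & d < config$min_depth)
    fail_mq <- fail_mq | (present & !is.na(mq) & mq <= config$min_map_q)
    fail_bq <- fail_bq | (present & !is.na(bq) & bq <= config$min_base_q)
  }
  data.frame(LOW_COVERAGE = fail_cov, LOW_MAPQ = fail_mq, LOW_BASEQ = fail_bq)
}

#' Consequence (nonsynonymous coding) filter
#'
#' @param trios trio-record data frame.
#' @param terms consequence terms that pass.
#' @param missing_action what to do when no observation carries a consequence
#'   annotation: "exclude" (default, with a warning) or "pass".
#' @return logical vector, TRUE = excluded as not nonsynonymous.
#' @export
filter_consequence <- function(trios, terms = nonsynonymous_terms_default(),
                               missing_action = c("exclude", "pass")) {
  missing_action <- match.arg(missing_action)
  csq <- trios$consequence
  missing <- is.na(csq) | csq == ""
  if (any(missing)) {
    warning(sum(missing), " record(s) lack a consequence annotation; ",
            if (missing_action == "exclude") "excluded" else "passed",
            " by configuration")
  }
  fail <- !(csq %in% terms)
  if (missing_action == "pass") fail[missing] <- FALSE
  fail
}

#' Apply all somatic filters to trio records
#'
#' Filters are applied in fixed order — consequence, coverage/quality,
#' germline — and every failing reason is recorded, not just the first, so
#' exclusion tables are exhaustive. `passed` is TRUE iff no reason applies.
#'
#' @param trios trio-record data frame.
#' @param config `filter_config`.
#' @param missing_consequence passed to [filter_consequence()].
#' @return the input with `passed` (logical) and `reasons` (semicolon-joined
#'   exclusion codes, "" when passed) columns appended; class
#'   `filter_outcomes`.
#' @export
run_filters <- function(trios, config = filter_config(),
                        missing_consequence = "exclude") {
  n <- nrow(trios)
  fail <- matrix(FALSE, nrow = n, ncol = length(EXCLUSION_CODES),
                 dimnames = list(NULL, EXCLUSION_CODES))
  if (n > 0L) {
    fail[, "NOT_NONSYNONYMOUS"] <-
      filter_consequence(trios, config$nonsynonymous_terms, missing_consequence)
    q <- filter_quality(trios, config)
    fail[, "LOW_COVERAGE"] <- q$LOW_COVERAGE
    fail[, "LOW_MAPQ"] <- q$LOW_MAPQ
    fail[, "LOW_BASEQ"] <- q$LOW_BASEQ
    fail[, "GERMLINE_POLYMORPHISM"] <-
      filter_germline(trios, config$germline_af_cutoff)
  }
  out <- trios
  out$passed <- rowSums(fail) == 0L
  out$reasons <- apply(fail, 1L, function(f)
    paste(EXCLUSION_CODES[f], collapse = ";"))
  if (n == 0L) out$reasons <- character(0)
  class(out) <- c("filter_outcomes", "data.frame")
  out
}

#' Write a filter audit table
#' @param outcomes result of [run_filters()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(outcomes, path) {
  aud <- data.frame(model_id = outcomes$model_id,
                    key = variant_key(outcomes),
                    passed = outcomes$passed,
                    reasons = outcomes$reasons,
                    stringsAsFactors = FALSE)
  write.table(aud, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
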