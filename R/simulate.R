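# Clonal-engraftment cohort simulator: germline polymorphisms, truncal and
# subclonal somatic variants, stochastic subclone loss at the engraftment
# bottleneck, transition-biased de novo PDX mutations, and binomial read
# sampling at negative-binomial depth. Ground-truth labels make filtering and
# classification testable end-to-end with no external data.

#' Simulator configuration
#'
#' Defaults describe one lymphoma trio with ~500 somatic exonic variants at
#' 200x mean depth: a clonal trunk, two private subclones (60% / 40% of tumor
#' cells) that each survive engraftment with probability 0.9, a Poisson number
#' (mean 30) of PDX-only de novo mutations that are transitions with
#' probability 0.8, tumor purity 0.8 in the primary biopsy and 1.0 in the PDX
#' (xenografts shed human non-malignant cells). With these prevalences every
#' noise-free allele fraction sits at least 0.05 away from the 0.1 detection
#' threshold, so truth labels are recoverable.
#'
#' @param n_trunk truncal somatic variants (carried by all tumor cells).
#' @param n_subclonal subclone-private somatic variants.
#' @param n_germline germline polymorphisms (het or hom).
#' @param de_novo_rate expected count of PDX-only de novo variants (Poisson).
#' @param bottleneck_survival_prob per-subclone survival probability at
#'   engraftment.
#' @param transition_prob probability that a de novo variant is a transition.
#' @param depth_mean mean sequencing depth per observation.
#' @param depth_dispersion negative-binomial dispersion d (variance =
#'   mean + d * mean^2); 0 gives Poisson depths.
#' @param purity_primary,purity_pdx tumor cell fraction per compartment.
#' @param subclone_prevalences primary-compartment prevalences of the private
#'   subclones (must sum to <= 1).
#' @param de_novo_prevalence cellular prevalence of de novo variants in the
#'   PDX compartment.
#' @param hom_germline_prob probability a germline polymorphism is homozygous.
#' @param low_quality_rate fraction of observations contaminated with failing
#'   mapping quality (exercises the quality filter; default 0).
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_trunk = 350L, n_subclonal = 150L, n_germline = 100L,
                       de_novo_rate = 30, bottleneck_survival_prob = 0.9,
                       transition_prob = 0.8, depth_mean = 200,
                       depth_dispersion = 0.05, purity_primary = 0.8,
                       purity_pdx = 1.0, subclone_prevalences = c(0.6, 0.4),
                       de_novo_prevalence = 0.5, hom_germline_prob = 0.2,
                       low_quality_rate = 0, seed = 1L) {
  stopifnot(n_trunk >= 0, n_subclonal >= 0, n_germline >= 0, de_novo_rate >= 0,
            bottleneck_survival_prob >= 0, bottleneck_survival_prob <= 1,
            transition_prob >= 0, transition_prob <= 1, depth_mean > 0,
            depth_dispersion >= 0, purity_primary > 0, purity_primary <= 1,
            purity_pdx > 0, purity_pdx <= 1,
            de_novo_prevalence > 0, de_novo_prevalence <= 1,
            low_quality_rate >= 0, low_quality_rate <= 1)
  if (sum(subclone_prevalences) > 1 + 1e-9) {
    stop("subclone prevalences sum to ", sum(subclone_prevalences), " > 1")
  }
  structure(list(n_trunk = as.integer(n_trunk),
                 n_subclonal = as.integer(n_subclonal),
                 n_germline = as.integer(n_germline),
                 de_novo_rate = de_novo_rate,
                 bottleneck_survival_prob = bottleneck_survival_prob,
                 transition_prob = transition_prob,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 purity_primary = purity_primary, purity_pdx = purity_pdx,
                 subclone_prevalences = subclone_prevalences,
                 de_novo_prevalence = de_novo_prevalence,
                 hom_germline_prob = hom_germline_prob,
                 low_quality_rate = low_quality_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Toy exome: 60 one-kb genes spread over chromosomes 1..22, so positions and
# gene symbols are well-defined and gene-list annotation is exercisable.
.toy_exome <- function() {
  n <- 60L
  data.frame(gene = sprintf("GENE%03d", seq_len(n)),
             chrom = as.character(rep_len(1:22, n)),
             start = 1e6 + 2e6 * (seq_len(n) - 1L),  # 0-based
             stringsAsFactors = FALSE)
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# Draw ref/alt pairs; de novo draws are transitions with prob `ti_prob`,
# everything else picks uniformly among the three non-ref bases.
.draw_alleles <- function(n, ti_prob = NA) {
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- character(n)
  if (is.na(ti_prob)) {
    for (i in seq_len(n)) alt[i] <- sample(setdiff(.BASES, ref[i]), 1L)
  } else {
    is_ti <- runif(n) < ti_prob
    alt[is_ti] <- .TRANSITION_PARTNER[ref[is_ti]]
    for (i in which(!is_ti)) {
      alt[i] <- sample(setdiff(.BASES, c(ref[i], .TRANSITION_PARTNER[ref[i]])), 1L)
    }
  }
  list(ref = ref, alt = alt)
}

#' Simulate one clonal trio cohort with ground truth
#'
#' Builds the clone structure and the noise-free variant table for one
#' germline/primary/PDX trio. The true allele fraction of a somatic variant in
#' a compartment is 0.5 * purity * (summed prevalence of its carrier
#' subclones); germline polymorphisms sit at 0.5 (het) or 1.0 (hom) in every
#' compartment. Each private subclone survives the engraftment bottleneck
#' independently with probability `bottleneck_survival_prob`; truncal cells
#' always engraft, and the PDX tumor is renormalized over truncal background
#' plus surviving subclones (total subclone loss leaves a trunk-only
#' xenograft).
#' De novo PDX variants arrive as Poisson(`de_novo_rate`), each a transition
#' with probability `transition_prob`. Truth labels are the classifier's rules
#' evaluated on the noise-free allele fractions ("recoverable truth"):
#' germline variants are expected to be filtered out; somatic variants are
#' shared when present on both sides with AF >= detect_af in at least one,
#' otherwise newly detected / newly undetected by one-sided detection.
#'
#' Deterministic given `config$seed`.
#'
#' @param config `sim_config`.
#' @param classify `classify_config` whose `detect_af` defines truth labels.
#' @return list of class `clone_cohort`: `subclones` (id, prevalence_primary,
#'   prevalence_pdx, survives_engraftment), `variants` (keys, gene,
#'   consequence, origin, carrier, true VAF per compartment, truth_label),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), classify = classify_config()) {
  set.seed(config$seed)
  q <- config$subclone_prevalences
  k <- length(q)
  survives <- runif(k) < config$bottleneck_survival_prob
  # PDX tumor regrows from truncal-background cells plus surviving private
  # subclones; truncal cells always engraft (a PDX exists by construction),
  # so losing every private subclone leaves a trunk-only xenograft.
  q_raw <- ifelse(survives, q, 0)
  mass <- (1 - sum(q)) + sum(q_raw)
  q_pdx <- if (mass > 0) q_raw / mass else rep(0, k)
  subclones <- data.frame(id = if (k > 0L) sprintf("SC%02d", seq_len(k)) else character(0),
                          prevalence_primary = q, prevalence_pdx = q_pdx,
                          survives_engraftment = survives,
                          stringsAsFactors = FALSE)

  n_dn <- rpois(1L, config$de_novo_rate)
  n_tot <- config$n_trunk + config$n_subclonal + config$n_germline + n_dn
  exome <- .toy_exome()
  # unique (gene, offset) slots so every variant key is distinct and record
  # counts are exactly conserved
  slot <- sample.int(nrow(exome) * 1000L, n_tot, replace = FALSE)
  gi <- (slot - 1L) %/% 1000L + 1L
  offset <- (slot - 1L) %% 1000L + 1L
  origin <- rep(c("trunk", "subclonal", "germline", "pdx_de_novo"),
                c(config$n_trunk, config$n_subclonal, config$n_germline, n_dn))
  al_som <- .draw_alleles(sum(origin != "pdx_de_novo"))
  al_dn <- .draw_alleles(n_dn, ti_prob = config$transition_prob)
  ref <- alt <- character(n_tot)
  ref[origin != "pdx_de_novo"] <- al_som$ref
  alt[origin != "pdx_de_novo"] <- al_som$alt
  ref[origin == "pdx_de_novo"] <- al_dn$ref
  alt[origin == "pdx_de_novo"] <- al_dn$alt

  carrier <- rep(NA_character_, n_tot)
  is_sub <- origin == "subclonal"
  if (any(is_sub) && k > 0L) {
    carrier[is_sub] <- sample(subclones$id, sum(is_sub), replace = TRUE, prob = q)
  }
  sub_idx <- match(carrier, subclones$id)

  vaf_g <- vaf_p <- vaf_x <- numeric(n_tot)
  hom <- runif(n_tot) < config$hom_germline_prob
  g <- origin == "germline"
  vaf_g[g] <- ifelse(hom[g], 1, 0.5)
  vaf_p[g] <- vaf_g[g]
  vaf_x[g] <- vaf_g[g]
  tr <- origin == "trunk"
  vaf_p[tr] <- 0.5 * config$purity_primary
  vaf_x[tr] <- 0.5 * config$purity_pdx
  vaf_p[is_sub] <- 0.5 * config$purity_primary * q[sub_idx[is_sub]]
  vaf_x[is_sub] <- 0.5 * config$purity_pdx * q_pdx[sub_idx[is_sub]]
  dn <- origin == "pdx_de_novo"
  vaf_x[dn] <- 0.5 * config$purity_pdx * config$de_novo_prevalence

  variants <- data.frame(chrom = exome$chrom[gi],
                         pos = as.integer(exome$start[gi] + offset),
                         ref = ref, alt = alt, gene = exome$gene[gi],
                         consequence = "missense_variant",
                         origin = origin, carrier = carrier,
                         true_vaf_germline = vaf_g, true_vaf_primary = vaf_p,
                         true_vaf_pdx = vaf_x, stringsAsFactors = FALSE)

  d <- classify$detect_af
  truth <- with(variants, ifelse(
    origin == "germline", "germline_excluded", ifelse(
      true_vaf_primary > 0 & true_vaf_pdx > 0 &
        pmax(true_vaf_primary, true_vaf_pdx) >= d, "shared", ifelse(
          true_vaf_pdx >= d, "newly_detected", ifelse(
            true_vaf_primary >= d, "newly_undetected", "not_comparable")))))
  variants$truth_label <- truth
  structure(list(subclones = subclones, variants = variants, config = config),
            class = "clone_cohort")
}

#' Sample sequencing reads for a simulated cohort
#'
#' Draws, for each variant and each of the three samples, a depth from a
#' negative binomial with the configured mean and dispersion (Poisson when
#' dispersion is 0) and alternate reads from Binomial(depth, true VAF).
#' Mapping/base qualities are passing (60/30) except for a configurable
#' fraction of observations given failing mapping quality. Deterministic given
#' the configuration seed (a fixed offset of the cohort seed, so cohort
#' structure and reads are reproducible together yet independently).
#'
#' @param cohort `clone_cohort` from [simulate_cohort()].
#' @param patient_id,model_id,subtype metadata stamped onto the records.
#' @return trio-record data frame (all observations present).
#' @export
sample_reads <- function(cohort, patient_id = "P1", model_id = "PDX1",
                         subtype = "DLBCL") {
  config <- cohort$config
  set.seed(config$seed + 1000003L)
  v <- cohort$variants
  n <- nrow(v)
  draw_depth <- function(n) {
    if (config$depth_dispersion == 0) {
      rpois(n, config$depth_mean)
    } else {
      rnbinom(n, mu = config$depth_mean, size = 1 / config$depth_dispersion)
    }
  }
  out <- data.frame(patient_id = patient_id, model_id = model_id,
                    subtype = subtype, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, consequence = v$consequence,
                    gene = v$gene, stringsAsFactors = FALSE)
  vafs <- list(germline = v$true_vaf_germline, primary = v$true_vaf_primary,
               pdx = v$true_vaf_pdx)
  for (r in TRIO_ROLES) {
    depth <- draw_depth(n)
    alt_reads <- rbinom(n, depth, vafs[[r]])
    mapq <- rep(60, n)
    if (config$low_quality_rate > 0) {
      bad <- runif(n) < config$low_quality_rate
      mapq[bad] <- 10
    }
    out[[paste0(r, "_depth")]] <- as.integer(depth)
    out[[paste0(r, "_alt")]] <- as.integer(alt_reads)
    out[[paste0(r, "_af")]] <- ifelse(depth > 0, alt_reads / depth, 0)
    out[[paste0(r, "_mapq")]] <- mapq
    out[[paste0(r, "_baseq")]] <- rep(30, n)
  }
  class(out) <- c("trio_records", "data.frame")
  out
}

# Subtype mix of a 12-model WES cohort: 5 DLBCL, 1 BL, 2 MCL, 4 T-NHL.
.default_cohort_subtypes <- function(n_models) {
  rep_len(c("DLBCL", "DLBCL", "DLBCL", "DLBCL", "DLBCL", "BL",
            "MCL", "MCL", "T-NHL", "T-NHL", "T-NHL", "T-NHL"), n_models)
}

#' Simulate a multi-model trio cohort
#'
#' Runs [simulate_cohort()] + [sample_reads()] once per model with per-model
#' seeds derived from `config$seed`, assigning a subtype mix that mirrors an
#' aggressive-lymphoma WES cohort (5 DLBCL, 1 BL, 2 MCL, 4 T-NHL for 12
#' models).
#'
#' @param n_models number of trios.
#' @param config base `sim_config`; the per-model seed is
#'   `config$seed + 7919 * model index`.
#' @param subtypes optional explicit subtype vector of length `n_models`.
#' @return list with `trios` (row-bound trio records), `truth` (row-bound
#'   truth tables with model_id), `cohorts` (per-model `clone_cohort`s).
#' @export
simulate_trio_cohort <- function(n_models = 12L, config = sim_config(),
                                 subtypes = NULL) {
  if (is.null(subtypes)) subtypes <- .default_cohort_subtypes(n_models)
  stopifnot(length(subtypes) == n_models)
  trios <- truth <- vector("list", n_models)
  cohorts <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * m
    co <- simulate_cohort(cfg)
    model_id <- sprintf("PDX%02d", m)
    trios[[m]] <- sample_reads(co, patient_id = sprintf("P%02d", m),
                               model_id = model_id, subtype = subtypes[m])
    t <- co$variants[, c("chrom", "pos", "ref", "alt", "origin", "truth_label")]
    t$model_id <- model_id
    truth[[m]] <- t
    cohorts[[m]] <- co
  }
  trios <- do.call(rbind, trios)
  class(trios) <- c("trio_records", "data.frame")
  list(trios = trios, truth = do.call(rbind, truth), cohorts = cohorts)
}

#' Confusion matrix of recovered vs true fidelity labels
#'
#' Joins the simulator's truth table with classification output on
#' (model_id, variant key). Somatic truth variants that were removed by the
#' filters appear in an `excluded` column; germline truth variants are
#' tallied separately (`germline_leakage` counts those that were NOT
#' excluded).
#'
#' @param truth truth table (`truth` element of [simulate_trio_cohort()], or
#'   `variants` of a single cohort plus a model_id column).
#' @param classified result of [classify_variants()] on the filtered records.
#' @return list with `confusion` (rows = truth labels, columns = predicted
#'   labels + "excluded"), `per_label_accuracy`, `n_germline_truth`,
#'   `germline_leakage`.
#' @export
evaluate_recovery <- function(truth, classified) {
  tkey <- paste(truth$model_id, truth$chrom, truth$pos, truth$ref, truth$alt)
  ckey <- paste(classified$model_id, classified$chrom, classified$pos,
                classified$ref, classified$alt)
  if (any(!ckey %in% tkey)) {
    stop("classified variant(s) absent from the truth table: key mismatch")
  }
  pred <- as.character(classified$label)[match(tkey, ckey)]
  pred[is.na(pred)] <- "excluded"
  som <- truth$truth_label != "germline_excluded"
  pred_levels <- c(FIDELITY_LABELS, "excluded")
  confusion <- table(truth = factor(truth$truth_label[som],
                                    levels = FIDELITY_LABELS),
                     predicted = factor(pred[som], levels = pred_levels))
  acc <- vapply(FIDELITY_LABELS, function(l) {
    tot <- sum(confusion[l, ])
    if (tot == 0L) NA_real_ else confusion[l, l] / tot
  }, numeric(1))
  list(confusion = confusion, per_label_accuracy = acc,
       n_germline_truth = sum(!som),
       germline_leakage = sum(pred[!som] != "excluded"))
}
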