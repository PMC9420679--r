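#' @importFrom utils read.delim write.table head
#' @importFrom stats median rbinom rpois rnbinom runif aggregate setNames
NULL

# Column layout of a per-sample observation table (output of read_vcf and the
# per-role slices of the harmonized table).
OBS_COLS <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads", "af",
              "map_q", "base_q", "consequence", "gene")

# Sample roles of a trio, in fixed order.
TRIO_ROLES <- c("germline", "primary", "pdx")

#' Normalize chromosome names
#'
#' Strips any "chr" prefix (case-insensitive) so that trios calling against
#' differently styled references join on the same key.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Normalize variant keys to their minimal left-aligned representation
#'
#' A variant key is (chrom, pos, ref, alt) with `pos` the 1-based position of
#' the first REF base. Normalization strips the "chr" prefix, trims the shared
#' suffix and then the shared prefix of REF/ALT (keeping one anchor base for
#' indels), and validates that both alleles are non-empty strings over
#' {A,C,G,T} with ref != alt. Symbolic or breakend alleles are rejected.
#' Normalization is idempotent.
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt` (extra
#'   columns are passed through untouched).
#' @return the data frame with normalized `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant_keys <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  chrom <- normalize_chrom(df$chrom)
  pos <- as.integer(df$pos)
  ref <- toupper(as.character(df$ref))
  alt <- toupper(as.character(df$alt))
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("invalid allele(s) (must be non-empty over {A,C,G,T}): ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("ref == alt at ", sum(ref == alt), " record(s); not a variant")
  }
  need <- which(nchar(ref) > 1L | nchar(alt) > 1L)
  for (i in need) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix, keeping one anchor base
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  df$chrom <- chrom; df$pos <- pos; df$ref <- ref; df$alt <- alt
  df
}

#' String form of a variant key
#' @param df data frame with normalized key columns.
#' @return character vector "chrom:pos:ref:alt".
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read per-sample variant calls from a VCF file
#'
#' Parses a VCF 4.x file and returns one observation per biallelic
#' decomposition of each site: multi-allelic records are split into one record
#' per ALT allele, with per-allele AD when available. Allele fraction is taken
#' from the per-sample AF/VAF FORMAT field when present, otherwise derived as
#' alt_reads/depth; the source is recorded in the `af_source` column. Mean
#' mapping quality is taken from INFO/MQ; base quality from INFO/BQ; gene and
#' consequence annotations from INFO/GENE and INFO/CONSEQUENCE when present.
#' Missing qualities are returned as NA and treated as passing by the filters,
#' with a warning here.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample sample name to extract; may be omitted for single-sample
#'   files. An unknown name raises an error listing the available samples.
#' @return data frame with columns chrom, pos, ref, alt, depth, alt_reads, af,
#'   map_q, base_q, consequence, gene, af_source; keys normalized.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) != 1L) {
      stop("VCF has ", length(samples),
           " samples; specify one of: ", paste(samples, collapse = ", "))
    }
    sample <- samples
  } else if (!sample %in% samples) {
    stop("sample '", sample, "' not in VCF; available: ",
         paste(samples, collapse = ", "))
  }
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) {  # single-record files collapse to a vector
    fix_m <- matrix(fix_m, nrow = 1L, dimnames = list(NULL, names(fix_m)))
  }
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(OBS_COLS) + 1L))
    names(out) <- c(OBS_COLS, "af_source")
    return(out)
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF record(s): non-numeric POS at data line(s) ",
         paste(which(is.na(pos)), collapse = ", "))
  }
  dp <- .num_or_na(vcfR::extract.gt(v, "DP")[, sample])
  ad <- tryCatch(vcfR::extract.gt(v, "AD")[, sample],
                 error = function(e) rep(NA_character_, nrow(fix)))
  aff <- tryCatch(vcfR::extract.gt(v, "AF")[, sample],
                  error = function(e) rep(NA_character_, nrow(fix)))
  info1 <- function(key) {
    x <- tryCatch(vcfR::extract.info(v, key), error = function(e) NULL)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  mq <- .num_or_na(info1("MQ"))
  bq <- .num_or_na(info1("BQ"))
  gene <- info1("GENE")
  csq <- info1("CONSEQUENCE")
  if (all(is.na(mq)) || all(is.na(bq))) {
    warning("mapping and/or base qualities absent from ", basename(path),
            "; missing qualities are treated as passing downstream")
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    alts <- alts[alts != "." & alts != ""]
    if (length(alts) == 0L) next
    ads <- if (!is.na(ad[i])) .num_or_na(strsplit(ad[i], ",", fixed = TRUE)[[1L]]) else NULL
    afs <- if (!is.na(aff[i])) .num_or_na(strsplit(aff[i], ",", fixed = TRUE)[[1L]]) else NULL
    depth_i <- dp[i]
    if (is.na(depth_i) && !is.null(ads)) depth_i <- sum(ads, na.rm = TRUE)
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts,
      depth = depth_i,
      alt_reads = if (!is.null(ads) && length(ads) >= 1L + length(alts)) {
        ads[1L + seq_along(alts)]
      } else NA_real_,
      af = if (!is.null(afs)) afs[pmin(seq_along(alts), length(afs))] else NA_real_,
      map_q = mq[i], base_q = bq[i],
      consequence = if (is.na(csq[i])) "" else csq[i],
      gene = if (is.na(gene[i])) "" else gene[i],
      af_source = if (!is.null(afs)) "caller_af" else "ad_derived",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  # AF precedence: caller AF field > AD-derived
  need_af <- is.na(out$af)
  out$af[need_af] <- ifelse(!is.na(out$depth[need_af]) & out$depth[need_af] > 0,
                            out$alt_reads[need_af] / out$depth[need_af], NA_real_)
  out$af_source[need_af] <- "ad_derived"
  out$depth <- as.integer(out$depth)
  out$alt_reads <- as.integer(out$alt_reads)
  normalize_variant_keys(out)
}

.check_unique_keys <- function(obs, role) {
  if (nrow(obs) == 0L) return(invisible(NULL))
  k <- variant_key(obs)
  d <- unique(k[duplicated(k)])
  if (length(d) > 0L) {
    stop("duplicate variant key(s) within ", role, " sample: ",
         paste(head(d, 5L), collapse = ", "),
         if (length(d) > 5L) ", ..." else "")
  }
  invisible(NULL)
}

#' Join germline, primary and PDX observations into trio records
#'
#' Performs an outer join of the three per-sample observation tables on the
#' normalized variant key. An observation absent from a sample is recorded as
#' NA depth for that role — distinct from a present observation with depth 0,
#' which means the locus was sequenced but carries no alternate reads.
#'
#' @param germline,primary,pdx per-sample observation data frames (as from
#'   [read_vcf()]); any may be empty or NULL.
#' @param patient_id,model_id,subtype cohort metadata attached to every record.
#' @return a trio-record data frame: key columns, metadata, and for each role
#'   `<role>_depth`, `<role>_alt`, `<role>_af`, `<role>_mapq`, `<role>_baseq`,
#'   plus merged `consequence` and `gene` annotations.
#' @export
join_trio <- function(germline = NULL, primary = NULL, pdx = NULL,
                      patient_id = "", model_id = "", subtype = "") {
  empty_obs <- data.frame(matrix(nrow = 0, ncol = length(OBS_COLS)))
  names(empty_obs) <- OBS_COLS
  obs <- list(germline = germline, primary = primary, pdx = pdx)
  obs <- lapply(obs, function(o) {
    if (is.null(o) || nrow(o) == 0L) return(empty_obs)
    normalize_variant_keys(o)
  })
  for (r in TRIO_ROLES) .check_unique_keys(obs[[r]], r)
  if (nrow(obs$primary) == 0L && nrow(obs$pdx) == 0L) {
    stop("trio for model '", model_id, "' has neither primary nor pdx records")
  }

  keys <- unique(do.call(rbind, lapply(obs, function(o)
    o[, c("chrom", "pos", "ref", "alt")])))
  keys <- keys[order(keys$chrom, keys$pos, keys$ref, keys$alt), , drop = FALSE]
  key_str <- variant_key(keys)
  out <- data.frame(patient_id = patient_id, model_id = model_id,
                    subtype = subtype, keys, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$consequence <- ""
  out$gene <- ""
  for (r in TRIO_ROLES) {
    o <- obs[[r]]
    idx <- match(key_str, variant_key(o))
    out[[paste0(r, "_depth")]] <- as.integer(o$depth[idx])
    out[[paste0(r, "_alt")]]   <- as.integer(o$alt_reads[idx])
    out[[paste0(r, "_af")]]    <- as.numeric(o$af[idx])
    out[[paste0(r, "_mapq")]]  <- as.numeric(o$map_q[idx])
    out[[paste0(r, "_baseq")]] <- as.numeric(o$base_q[idx])
    hit <- !is.na(idx)
    take <- hit & out$consequence == "" & !is.na(o$consequence[idx]) & o$consequence[idx] != ""
    out$consequence[take] <- o$consequence[idx][take]
    take <- hit & out$gene == "" & !is.na(o$gene[idx]) & o$gene[idx] != ""
    out$gene[take] <- o$gene[idx][take]
  }
  # a present observation with unreported AF defaults to alt/depth
  for (r in TRIO_ROLES) {
    afc <- paste0(r, "_af"); dc <- paste0(r, "_depth"); ac <- paste0(r, "_alt")
    fix <- !is.na(out[[dc]]) & is.na(out[[afc]])
    out[[afc]][fix] <- ifelse(out[[dc]][fix] > 0,
                              out[[ac]][fix] / out[[dc]][fix], 0)
  }
  class(out) <- c("trio_records", "data.frame")
  out
}

#' Which roles are present in each trio record
#' @param trios trio-record data frame.
#' @param role one of "germline", "primary", "pdx".
#' @return logical vector.
#' @export
has_observation <- function(trios, role) {
  !is.na(trios[[paste0(role, "_depth")]])
}

#' Read a harmonized long-format variant table
#'
#' The harmonized dialect is a TSV with header columns patient_id, model_id,
#' subtype, chrom, pos, ref, alt, sample_role, depth, alt_reads, af, map_q,
#' base_q, consequence, gene — one row per (variant, sample) observation.
#'
#' @param path TSV path.
#' @return long-format data frame with normalized keys.
#' @export
read_variant_table <- function(path) {
  need <- c("patient_id", "model_id", "subtype", "chrom", "pos", "ref", "alt",
            "sample_role", "depth", "alt_reads", "af", "map_q", "base_q",
            "consequence", "gene")
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("harmonized variant table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !df$sample_role %in% TRIO_ROLES
  if (any(bad)) {
    stop("unknown sample_role(s): ", paste(unique(df$sample_role[bad]), collapse = ", "))
  }
  df$consequence[is.na(df$consequence)] <- ""
  df$gene[is.na(df$gene)] <- ""
  normalize_variant_keys(df)
}

#' Build trio records from a harmonized long table, one set per model
#'
#' @param long long-format data frame (see [read_variant_table()]).
#' @return trio-record data frame spanning all models in the table.
#' @export
trios_from_table <- function(long) {
  pieces <- lapply(split(long, long$model_id), function(m) {
    slice <- function(role) {
      s <- m[m$sample_role == role,
             c("chrom", "pos", "ref", "alt", "depth", "alt_reads", "af",
               "map_q", "base_q", "consequence", "gene")]
      rownames(s) <- NULL
      s
    }
    join_trio(germline = slice("germline"), primary = slice("primary"),
              pdx = slice("pdx"),
              patient_id = m$patient_id[1L], model_id = m$model_id[1L],
              subtype = m$subtype[1L])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("trio_records", "data.frame")
  out
}

#' Write trio records to the harmonized long-format TSV
#'
#' Only present observations are written; re-reading with
#' [read_variant_table()] + [trios_from_table()] reproduces the records.
#'
#' @param trios trio-record data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(trios, path) {
  rows <- lapply(TRIO_ROLES, function(r) {
    keep <- has_observation(trios, r)
    if (!any(keep)) return(NULL)
    t <- trios[keep, , drop = FALSE]
    data.frame(patient_id = t$patient_id, model_id = t$model_id,
               subtype = t$subtype, chrom = t$chrom, pos = t$pos,
               ref = t$ref, alt = t$alt, sample_role = r,
               depth = t[[paste0(r, "_depth")]],
               alt_reads = t[[paste0(r, "_alt")]],
               af = t[[paste0(r, "_af")]],
               map_q = t[[paste0(r, "_mapq")]],
               base_q = t[[paste0(r, "_baseq")]],
               consequence = t$consequence, gene = t$gene,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model_id, out$chrom, out$pos, out$ref, out$alt,
                   match(out$sample_role, TRIO_ROLES)), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line, or TSV with subtype and gene columns)
#'
#' Symbols are upper-cased and de-duplicated. A two-column TSV yields one list
#' per subtype group.
#'
#' @param path file path. Lines starting with `#` are ignored.
#' @return named list of character vectors (single unnamed-list element
#'   `list(genes = ...)` collapses to a character vector for the plain format).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(character(0))
  if (grepl("\t", lines[1L])) {
    df <- read.delim(text = paste(lines, collapse = "\n"),
                     stringsAsFactors = FALSE)
    if (!all(c("subtype", "gene") %in% names(df))) {
      stop("tabular gene list must have 'subtype' and 'gene' columns")
    }
    lapply(split(toupper(df$gene), df$subtype), unique)
  } else {
    unique(toupper(trimws(lines)))
  }
}

#' Read gene coordinates from a BED file
#'
#' @param path BED path (at least chrom/start/end/name).
#' @return data frame with columns gene, chrom (normalized), start, end
#'   (0-based half-open).
#' @export
read_gene_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(gr$name)) stop("BED ", path, " lacks a name column for gene symbols")
  data.frame(gene = toupper(gr$name),
             chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a CNVkit-style copy-number segment table
#'
#' Expects tab-separated columns `chromosome`, `start`, `end` plus `cn` and/or
#' `log2`. Coordinates are stored 0-based half-open as given. When only log2
#' ratios are present, integer copy number is derived with [cn_from_log2()].
#' Overlapping segments on one chromosome are an error.
#'
#' @param path segment TSV (.cns) path.
#' @return data frame with columns chrom, start, end, log2, cn.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "chromosome"] <- "chrom"
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("segment file ", path, " needs chromosome/start/end columns")
  }
  if (!("cn" %in% names(df)) && !("log2" %in% names(df))) {
    stop("segment file ", path, " needs a 'cn' and/or 'log2' column")
  }
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), log2 = numeric(0), cn = integer(0)))
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("segment with end <= start in ", path)
  if (!("log2" %in% names(df))) df$log2 <- NA_real_
  if (!("cn" %in% names(df))) df$cn <- NA_integer_
  derive <- is.na(df$cn)
  df$cn[derive] <- cn_from_log2(df$log2[derive])
  df$cn <- as.integer(df$cn)
  # reject overlapping segments per chromosome
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    ov <- which(s$start[-1L] < s$end[-nrow(s)])
    if (length(ov) > 0L) {
      stop("overlapping segments on chromosome ", ch, " in ", path, ": ",
           paste(sprintf("[%d,%d) vs [%d,%d)", s$start[ov], s$end[ov],
                         s$start[ov + 1L], s$end[ov + 1L]), collapse = "; "))
    }
  }
  df[, c("chrom", "start", "end", "log2", "cn")]
}
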