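# Somatic variant filter chain: mapping quality, population allele frequency,
# normal-tissue subtraction, COSMIC cancer-gene rescue. Filters never drop
# rows -- they only accumulate removal reasons -- so the final statuses are
# independent of the order in which flags were applied and every record keeps
# full provenance in the audit table.

variant_required_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                           "variant_class", "qc", "af_gnomad", "af_abraom",
                           "cosmic_role", "status", "removal_reasons")

check_variant_records <- function(records) {
  miss <- setdiff(variant_required_cols, names(records))
  if (length(miss))
    stopf("variant records missing columns: %s", paste(miss, collapse = ", "))
  invisible(records)
}

#' Flag variants with poor mapping quality
#'
#' Records with mapping quality strictly below `min_qc` gain the
#' `low_quality` removal reason; a quality equal to the threshold passes.
#' No records are dropped.
#'
#' @param records variant record data frame.
#' @param min_qc mapping-quality threshold (default 20).
#' @return the records with updated `removal_reasons`.
#' @export
filter_by_quality <- function(records, min_qc = 20) {
  check_variant_records(records)
  if (nrow(records) == 0) return(records)
  if (anyNA(records$qc)) {
    bad <- which(is.na(records$qc))[1]
    stopf("validation error: missing qc for record %d (sample %s, %s:%d)",
          bad, records$sample_id[bad], records$chrom[bad], records$pos[bad])
  }
  flag <- records$qc < min_qc
  records$removal_reasons <- add_reason(records$removal_reasons, flag,
                                        "low_quality")
  records
}

#' Flag variants common in population databases
#'
#' A record is flagged `common_population` when its allele frequency is
#' strictly above `max_af` in gnomAD **or** ABraOM. Missing frequencies mean
#' the variant is absent from the database and are treated as rare.
#'
#' @param records variant record data frame.
#' @param max_af allele-frequency threshold (default 0.001).
#' @return the records with updated `removal_reasons`.
#' @export
filter_by_population_frequency <- function(records, max_af = 0.001) {
  check_variant_records(records)
  if (nrow(records) == 0) return(records)
  for (col in c("af_gnomad", "af_abraom")) {
    v <- records[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stopf("validation error: %s outside [0, 1]", col)
  }
  over <- function(v) !is.na(v) & v > max_af
  flag <- over(records$af_gnomad) | over(records$af_abraom)
  records$removal_reasons <- add_reason(records$removal_reasons, flag,
                                        "common_population")
  records
}

#' Build a normal-tissue variant set
#'
#' Keys are `(chrom, pos, ref, alt)`; duplicates are collapsed. Coordinates
#' are 1-based, VCF-style; alleles are compared verbatim (left-alignment is
#' the upstream caller's job).
#'
#' @param chrom,pos,ref,alt vectors of equal length, or `chrom` may be a data
#'   frame holding all four columns.
#' @return an object of class `normal_variant_set`.
#' @export
normal_variant_set <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom; pos <- df$pos; ref <- df$ref; alt <- df$alt
  }
  keys <- unique(paste(chrom, pos, ref, alt, sep = ":"))
  structure(list(keys = keys), class = "normal_variant_set")
}

#' Derive the normal-tissue set from generator-flagged records
#' @param records variant records with a logical `normal_shared` column.
#' @return a [normal_variant_set()].
#' @export
normal_set_from_flags <- function(records) {
  shared <- records[isTRUE_vec(records$normal_shared), , drop = FALSE]
  normal_variant_set(shared$chrom, shared$pos, shared$ref, shared$alt)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Flag variants also present in normal tissue
#'
#' Records whose `(chrom, pos, ref, alt)` key appears in the normal-tissue
#' set gain the `normal_shared` removal reason.
#'
#' @param records variant record data frame.
#' @param normal a [normal_variant_set()].
#' @return the records with updated `removal_reasons`.
#' @export
subtract_normal_variants <- function(records, normal) {
  check_variant_records(records)
  if (nrow(records) == 0) return(records)
  keys <- paste(records$chrom, records$pos, records$ref, records$alt,
                sep = ":")
  flag <- keys %in% normal$keys
  records$removal_reasons <- add_reason(records$removal_reasons, flag,
                                        "normal_shared")
  records
}

#' Resolve final statuses, rescuing COSMIC cancer-gene variants
#'
#' Flagged records in genes with a COSMIC role (oncogene or TSG) are
#' reimported with status `rescued`; their removal reasons are retained for
#' provenance. Other flagged records become `removed`; unflagged records
#' `pass`.
#'
#' @param records variant record data frame (flag operations already applied).
#' @return the records with final `status` values.
#' @export
rescue_cosmic_variants <- function(records) {
  check_variant_records(records)
  if (nrow(records) == 0) return(records)
  flagged <- n_reasons(records$removal_reasons) > 0
  cosmic <- records$cosmic_role %in% c("oncogene", "TSG")
  records$status <- ifelse(!flagged, "pass",
                           ifelse(cosmic, "rescued", "removed"))
  records
}

#' Run the full variant filter chain
#'
#' Quality, population-frequency and normal-subtraction flags followed by the
#' COSMIC rescue. The three flagging stages commute (each only adds reasons),
#' so the chain order affects provenance text only, never statuses.
#'
#' @param records variant record data frame.
#' @param normal a [normal_variant_set()] (default empty).
#' @param min_qc,max_af thresholds (defaults 20 and 0.001).
#' @return a list with `retained` (status pass or rescued) and `audit` (every
#'   record with final status, reasons, and a `low_quality_rescued` warning
#'   flag for rescued records whose reasons include poor mapping quality).
#' @export
run_variant_filter_chain <- function(records,
                                     normal = normal_variant_set(character(0)),
                                     min_qc = 20, max_af = 0.001) {
  records <- filter_by_quality(records, min_qc)
  records <- filter_by_population_frequency(records, max_af)
  records <- subtract_normal_variants(records, normal)
  records <- rescue_cosmic_variants(records)
  audit <- records
  audit$low_quality_rescued <- audit$status == "rescued" &
    has_reason(audit$removal_reasons, "low_quality")
  list(retained = records[records$status %in% c("pass", "rescued"), ,
                          drop = FALSE],
       audit = audit)
}

#' Write the variant audit table as TSV
#' @param audit audit table from [run_variant_filter_chain()].
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_variant_audit <- function(audit, path, fingerprint = NULL) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
            "variant_class", "qc", "af_gnomad", "af_abraom", "cosmic_role",
            "status", "removal_reasons", "low_quality_rescued")
  write_tsv_stable(audit[, intersect(cols, names(audit))], path, fingerprint)
}

#' Read a minimal VCF into the variant-record layout
#'
#' Quality is taken from `QUAL`; gene, class, population frequencies and
#' COSMIC role from the INFO keys `GENE`, `VC`, `AF_GNOMAD`, `AF_ABRAOM`,
#' `COSMIC_ROLE`. Intended for small annotated call sets, not general VCF.
#'
#' @param path VCF file.
#' @param sample_id sample identifier to attach to every record.
#' @return a variant record data frame.
#' @export
read_variants_vcf <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(planted_driver_variants(data.frame(sample_id = character(0),
                                              archetype = character(0),
                                              driver_status = character(0)))[
      , , drop = FALSE])
  f <- strsplit(lines, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(f, `[`, character(1), 8)
  data.frame(sample_id = sample_id,
             chrom = vapply(f, `[`, character(1), 1),
             pos = as.integer(vapply(f, `[`, character(1), 2)),
             ref = vapply(f, `[`, character(1), 4),
             alt = vapply(f, `[`, character(1), 5),
             gene = info_get(info, "GENE"),
             variant_class = info_get(info, "VC"),
             qc = as.numeric(vapply(f, `[`, character(1), 6)),
             af_gnomad = suppressWarnings(as.numeric(info_get(info, "AF_GNOMAD"))),
             af_abraom = suppressWarnings(as.numeric(info_get(info, "AF_ABRAOM"))),
             cosmic_role = ifelse(is.na(info_get(info, "COSMIC_ROLE")), "none",
                                  info_get(info, "COSMIC_ROLE")),
             status = "pass", removal_reasons = "",
             stringsAsFactors = FALSE)
}
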