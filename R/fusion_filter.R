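# Fusion-call filters: expression support (FFPM, junction/spanning reads)
# and a normal-tissue blacklist, plus per-group fusion-burden summaries.
# As with variants, filters only add removal reasons.

fusion_required_cols <- c("sample_id", "gene5", "gene3", "junction_reads",
                          "spanning_frags", "ffpm", "status",
                          "removal_reasons")

check_fusion_records <- function(records) {
  miss <- setdiff(fusion_required_cols, names(records))
  if (length(miss))
    stopf("fusion records missing columns: %s", paste(miss, collapse = ", "))
  invisible(records)
}

#' Filter fusion calls by expression support
#'
#' A call passes the FFPM clause when its FFPM is strictly above `min_ffpm`,
#' and the support clause when its read support is strictly above
#' `min_support` -- for `support_mode = "each"` both the junction-read and
#' spanning-fragment counts must exceed the threshold; for `"sum"` their sum
#' must. Failing records gain `low_ffpm` / `low_support` reasons and status
#' `removed`; nothing is dropped.
#'
#' @param records fusion record data frame.
#' @param min_ffpm FFPM threshold (default 0.1).
#' @param min_support read-support threshold (default 10).
#' @param support_mode `"each"` (default) or `"sum"`.
#' @return the records with updated reasons and statuses.
#' @export
filter_fusions <- function(records, min_ffpm = 0.1, min_support = 10,
                           support_mode = c("each", "sum")) {
  support_mode <- match.arg(support_mode)
  check_fusion_records(records)
  if (nrow(records) == 0) return(records)
  low_ffpm <- records$ffpm <= min_ffpm
  low_support <- if (support_mode == "each")
    !(records$junction_reads > min_support &
        records$spanning_frags > min_support)
  else !(records$junction_reads + records$spanning_frags > min_support)
  records$removal_reasons <- add_reason(records$removal_reasons, low_ffpm,
                                        "low_ffpm")
  records$removal_reasons <- add_reason(records$removal_reasons, low_support,
                                        "low_support")
  finalize_fusion_status(records)
}

#' Remove fusions seen in normal tissue
#'
#' Records whose ordered `(gene5, gene3)` pair is on the blacklist gain the
#' `normal_artifact` reason. Orientation matters: the reversed pair is a
#' different fusion transcript and is not matched.
#'
#' @param records fusion record data frame.
#' @param blacklist data frame with `gene5`, `gene3` columns (or a character
#'   vector of `"GENE5--GENE3"` names).
#' @return the records with updated reasons and statuses.
#' @export
subtract_normal_fusions <- function(records, blacklist) {
  check_fusion_records(records)
  if (is.character(blacklist)) {
    parts <- strsplit(blacklist, "--", fixed = TRUE)
    blacklist <- data.frame(gene5 = vapply(parts, `[`, character(1), 1),
                            gene3 = vapply(parts, `[`, character(1), 2),
                            stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0) return(records)
  keys <- paste(records$gene5, records$gene3, sep = "--")
  bad <- keys %in% paste(blacklist$gene5, blacklist$gene3, sep = "--")
  records$removal_reasons <- add_reason(records$removal_reasons, bad,
                                        "normal_artifact")
  finalize_fusion_status(records)
}

finalize_fusion_status <- function(records) {
  records$status <- ifelse(n_reasons(records$removal_reasons) > 0,
                           "removed", "pass")
  records
}

#' Mean passing-fusion count per sample, by group
#'
#' Samples with zero passing fusions still count in the denominator, so a
#' group with no fusions anywhere has mean 0, not a missing value.
#'
#' @param records fusion record data frame with statuses assigned.
#' @param groups named character vector mapping every sample to a group.
#' @return a data frame with `group`, `n_samples`, `mean_fusions`.
#' @export
fusion_burden <- function(records, groups) {
  check_fusion_records(records)
  unknown <- setdiff(unique(records$sample_id), names(groups))
  if (length(unknown))
    stopf("validation error: samples without a group: %s",
          paste(unknown, collapse = ", "))
  passing <- records[records$status == "pass", , drop = FALSE]
  per_sample <- stats::setNames(rep(0, length(groups)), names(groups))
  if (nrow(passing)) {
    tab <- table(passing$sample_id)
    per_sample[names(tab)] <- as.numeric(tab)
  }
  res <- lapply(split(per_sample, groups[names(per_sample)]), function(v)
    c(n = length(v), mean = mean(v)))
  data.frame(group = names(res),
             n_samples = vapply(res, `[[`, numeric(1), "n"),
             mean_fusions = vapply(res, `[[`, numeric(1), "mean"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a fusion audit table as TSV
#' @param records fusion records with statuses.
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_fusion_audit <- function(records, path, fingerprint = NULL) {
  cols <- c("sample_id", "gene5", "gene3", "junction_reads",
            "spanning_frags", "ffpm", "status", "removal_reasons")
  write_tsv_stable(records[, intersect(cols, names(records))], path,
                   fingerprint)
}
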