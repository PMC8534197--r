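# Internal helpers: seeded RNG sub-streams, reason-set bookkeeping on
# semicolon-joined columns, config fingerprinting and bit-stable TSV I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream. A `NULL` seed leaves the stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' All randomness in the package flows from one explicit seed; each table or
#' bootstrap replicate gets its own sub-stream so generators can be re-run
#' independently without correlated draws. Kept below 2^31 - 1.
#' @param seed master integer seed.
#' @param label character tag naming the consumer of the sub-stream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, label) {
  h <- fnv1a32(paste0(label, ":", seed))
  as.integer(h %% 2147483629L)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in double precision
# (R has no native unsigned 32-bit integer). Returns a double in [0, 2^32).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # xor on doubles holding 32-bit values
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

#' Fingerprint a resolved configuration
#'
#' A short hexadecimal hash of the deparsed configuration (including seeds),
#' embedded in every output file header so a report can be traced to the
#' exact run that produced it.
#' @param config a list of configuration values.
#' @return a character scalar, eight hex digits.
#' @export
config_fingerprint <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "")
  h <- fnv1a32(txt)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# ---- reason-set bookkeeping -------------------------------------------------

# removal_reasons is stored as a semicolon-joined string ("" = empty set) so
# record tables stay plain data frames that round-trip through TSV.

reason_split <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

reason_join <- function(lst) {
  vapply(lst, paste, character(1), collapse = ";")
}

add_reason <- function(reasons, idx, reason) {
  if (!any(idx)) return(reasons)
  lst <- reason_split(reasons)
  lst[idx] <- lapply(lst[idx], function(v) union(v, reason))
  reason_join(lst)
}

has_reason <- function(reasons, reason) {
  vapply(reason_split(reasons), function(v) reason %in% v, logical(1))
}

n_reasons <- function(reasons) {
  vapply(reason_split(reasons), length, integer(1))
}

# ---- bit-stable TSV I/O -----------------------------------------------------

fmt_num <- function(x) {
  # fixed formatting: 6 significant digits, no scientific drift across runs
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "fg", flag = "#", digits = 6)))
}

#' Write a data frame as a deterministic TSV
#'
#' Fixed column order, numeric columns at six significant digits, LF line
#' endings, and an optional `# config_fingerprint:` header comment.
#' @param df data frame to write.
#' @param path output file.
#' @param fingerprint optional fingerprint string for the header comment.
#' @export
write_tsv_stable <- function(df, path, fingerprint = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  if (!is.null(fingerprint))
    writeLines(paste0("# config_fingerprint: ", fingerprint), con, sep = "\n")
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by this package
#'
#' Skips `# `-prefixed comment lines (but not a `#FusionName`-style header).
#' @param path file to read.
#' @return a data frame.
#' @export
read_tsv_stable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
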