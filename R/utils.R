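# Internal helpers shared across modules.

TIMEPOINTS <- c("DIAGNOSIS", "CMR", "RELAPSE")
ASSAYS <- c("PANEL", "WGS", "GENE_SCAN")

#' Default timepoint alias map
#'
#' Maps common spellings found in variant tables onto the canonical
#' timepoint labels `DIAGNOSIS`, `CMR`, `RELAPSE`.
#'
#' @return Named character vector; names are aliases (upper case), values
#'   canonical labels.
#' @export
defaultTimepointAliases <- function() {
  c(DIAGNOSIS = "DIAGNOSIS", DIAG = "DIAGNOSIS", DX = "DIAGNOSIS",
    D = "DIAGNOSIS", BASELINE = "DIAGNOSIS",
    CMR = "CMR", REMISSION = "CMR", CR = "CMR", MRD = "CMR",
    RELAPSE = "RELAPSE", R = "RELAPSE", REL = "RELAPSE")
}

normalizeTimepoint <- function(x, aliases = defaultTimepointAliases()) {
  key <- toupper(trimws(as.character(x)))
  out <- unname(aliases[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown timepoint label(s): ",
         paste(unique(key[bad]), collapse = ", "))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer-percent rounding used for cohort summaries
pct <- function(num, den) round(100 * num / den)

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(what, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}
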