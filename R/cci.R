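#' Countdown composite coverage index (CCI) weights
#'
#' The CCI is the weighted average of four RMNCH intervention domains:
#' family planning (demand for family planning satisfied with modern methods,
#' DFPSm), maternity care (four or more antenatal visits, ANC4; skilled birth
#' attendance, SBA), immunisation (BCG; three doses of DPT, double-weighted;
#' measles, MSL) and case management of childhood illness (oral rehydration
#' salts, ORS; careseeking for suspected pneumonia, CAREP). Each domain
#' carries weight 1/4; within-domain indicators are averaged, with DPT3
#' counted twice inside the immunisation domain:
#'
#' CCI = 1/4 \[ DFPSm + (ANC4 + SBA)/2 + (BCG + 2 DPT3 + MSL)/4 + (ORS + CAREP)/2 \]
#'
#' @return Named numeric vector of the eight indicator weights (sums to 1).
#' @export
#' @examples
#' sum(cci_weights())
cci_weights <- function() {
  c(
    dfpsm = 1 / 4,
    anc4 = 1 / 8, sba = 1 / 8,
    bcg = 1 / 16, dpt3 = 1 / 8, msl = 1 / 16,
    ors = 1 / 8, carep = 1 / 8
  )
}

cci_indicator_names <- function() names(cci_weights())

validate_indicators <- function(ind, where = "indicator set") {
  need <- cci_indicator_names()
  missing <- setdiff(need, names(ind))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing indicator(s): %s", where,
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  vals <- unlist(ind[need], use.names = TRUE)
  bad <- !is.finite(vals) | vals < 0 | vals > 1
  if (any(bad)) {
    stop(sprintf(
      "%s has value(s) outside [0, 1]: %s", where,
      paste(sprintf("%s = %s", need[bad], format(vals[bad])), collapse = ", ")
    ), call. = FALSE)
  }
  vals
}

#' Compute the composite coverage index for one stratum
#'
#' @param indicators Named numeric vector, list, or one-row data frame with
#'   the eight indicator proportions `dfpsm`, `anc4`, `sba`, `bcg`, `dpt3`,
#'   `msl`, `ors`, `carep`, each in \[0, 1\]. Values are never silently
#'   rescaled; percentage-scale input must be divided by 100 by the caller
#'   (see [batch_cci()]'s `scale` argument).
#'
#' @return A single proportion in \[0, 1\].
#' @export
#' @examples
#' compute_cci(c(
#'   dfpsm = 0.6, anc4 = 0.5, sba = 0.7, bcg = 0.9,
#'   dpt3 = 0.8, msl = 0.85, ors = 0.4, carep = 0.55
#' ))
compute_cci <- function(indicators) {
  if (is.data.frame(indicators)) {
    if (nrow(indicators) != 1) {
      stop("compute_cci() expects a single indicator set; use batch_cci() for tables",
        call. = FALSE
      )
    }
    indicators <- as.list(indicators)
  }
  vals <- validate_indicators(indicators)
  unname(sum(cci_weights() * vals))
}

#' Append a CCI column to a table of indicator sets
#'
#' Row-wise application of [compute_cci()] with validation that names the
#' offending row on failure. Row order is preserved.
#'
#' @param data Data frame with the eight indicator columns (see
#'   [compute_cci()]); other columns are passed through.
#' @param scale Scale of the indicator columns: `"proportion"` (default,
#'   values in \[0, 1\]) or `"percent"` (values in \[0, 100\], divided by 100
#'   before use). Never auto-detected.
#'
#' @return The input as a tibble with a `cci` column appended (proportion
#'   scale).
#' @export
batch_cci <- function(data, scale = c("proportion", "percent")) {
  scale <- match.arg(scale)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, cci = numeric(0)))
  }
  need <- cci_indicator_names()
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop(sprintf(
      "indicator table is missing column(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  ind <- data[need]
  if (scale == "percent") ind <- ind / 100
  cci <- purrr::map_dbl(seq_len(nrow(ind)), function(i) {
    vals <- validate_indicators(as.list(ind[i, ]), where = sprintf("row %d", i))
    sum(cci_weights() * vals)
  })
  dplyr::mutate(data, cci = cci)
}

#' Read / write indicator tables
#'
#' CSV files with the canonical column names `dfpsm`, `anc4`, `sba`, `bcg`,
#' `dpt3`, `msl`, `ors`, `carep` (and `cci` on write).
#'
#' @param path File path.
#' @param data Indicator table (for the writer), typically the output of
#'   [batch_cci()].
#' @param scale Passed to [batch_cci()] validation on read.
#' @return `read_indicators()` returns a tibble; `write_indicators()` returns
#'   `data` invisibly.
#' @export
read_indicators <- function(path, scale = c("proportion", "percent")) {
  scale <- match.arg(scale)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  batch_cci(out, scale = scale)
}

#' @rdname read_indicators
#' @export
write_indicators <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
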