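#' Logit and inverse-logit transforms for coverage proportions
#'
#' Coverage modelling is done on the logit scale so that predictions, once
#' back-transformed, always fall inside the 0-100% range. Proportions at or
#' near the boundary are clipped to `[eps, 1 - eps]` before the transform;
#' surveyed coverage of exactly 0 or 1 is almost always a small-sample
#' artefact at stratum level.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param x Real value(s).
#' @param eps Clipping bound in (0, 0.01\]; default 1e-3.
#'
#' @return `logit()` returns real values; `inv_logit()` returns proportions
#'   strictly inside (0, 1).
#' @export
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.25))
logit <- function(p, eps = 1e-3) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps > 0.01) {
    stop("eps must be a single value in (0, 0.01]", call. = FALSE)
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(sprintf(
      "proportions outside [0, 1]: %s",
      paste(format(p[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  stats::plogis(x)
}
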