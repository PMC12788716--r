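#' Physical-activity pattern labels
#'
#' The four accelerometer-derived weekly physical-activity (PA) patterns used
#' throughout the package, ordered from lowest to highest weekly
#' moderate-to-vigorous PA (MVPA) demand:
#' `baseline` (<150 min/wk MVPA and <1900 min/wk light PA),
#' `active_lpa` (<150 min/wk MVPA, >=1900 min/wk light PA),
#' `active_regular` (>=150 min/wk MVPA, spread over the week), and
#' `active_ww` ("weekend warrior": >=150 min/wk MVPA with >=50% of it in the
#' two highest days).
#'
#' This ordering is also the deterministic tie-break used whenever two
#' patterns give an identical predicted survival probability: ties resolve
#' toward the lower-MVPA pattern, the more conservative recommendation.
#'
#' @return Character vector of the four pattern labels in tie-break order.
#' @export
pa_patterns <- function() {
  c("baseline", "active_lpa", "active_regular", "active_ww")
}

#' @rdname pa_patterns
#' @param x character vector of pattern labels.
#' @return `pa_pattern_factor()` returns `x` as a factor with the canonical
#'   level order (reference level `baseline`).
#' @export
pa_pattern_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), pa_patterns())
  if (length(bad)) {
    stop("unknown PA pattern label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = pa_patterns())
}

# argmax over the four survival probabilities with the lower-MVPA tie-break;
# `surv` is a length-4 vector or n x 4 matrix in pa_patterns() column order.
pattern_argmax <- function(surv) {
  if (is.null(dim(surv))) surv <- matrix(surv, nrow = 1)
  stopifnot(ncol(surv) == 4L)
  # which.max returns the first maximum; columns are already in tie-break order
  idx <- apply(surv, 1L, which.max)
  pa_pattern_factor(pa_patterns()[idx])
}
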