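#' Read and write the package's CSV formats
#'
#' Participant tables are one row per participant with the covariate
#' columns, `pattern`, `time`, `event`. Activity weeks are long-format
#' minute records: `participant_id`, `timestamp` (ISO-8601, UTC),
#' `value`, `wear`.
#'
#' @param x object to write.
#' @param path file path.
#' @return readers return data.frames (`read_activity_csv()` with POSIXct
#'   timestamps and a logical wear column); writers return `path`
#'   invisibly.
#' @name pa_io
NULL

#' @rdname pa_io
#' @export
write_participants_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pa_io
#' @export
read_participants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("pattern" %in% names(df)) df$pattern <- pa_pattern_factor(df$pattern)
  df
}

#' @rdname pa_io
#' @export
write_activity_csv <- function(x, path) {
  out <- data.frame(
    participant_id = x$participant_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    value = x$value,
    wear = as.integer(x$wear)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pa_io
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df$wear <- as.logical(df$wear)
  structure(df, class = c("activity_week", "data.frame"))
}

#' Read a truth configuration from YAML or JSON
#'
#' The file holds the arguments of [truth_config()] (covariates as a named
#' mapping, betas as named mappings, the pattern-assignment matrix as a
#' mapping of pattern name to named coefficient mapping with an
#' `intercept` entry).
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return a `truth_config`.
#' @export
read_truth_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  covs <- lapply(raw$covariates, function(cv) {
    cv$type <- as.character(cv$type)
    cv
  })
  # omitted assignment model: equal shares, unconfounded
  pa <- matrix(0, 4, 1, dimnames = list(pa_patterns(), "(Intercept)"))
  if (!is.null(raw$pattern_assignment)) {
    cols <- unique(c("(Intercept)",
                     unlist(lapply(raw$pattern_assignment,
                                   function(r) setdiff(names(r), "intercept")))))
    pa <- matrix(0, 4, length(cols), dimnames = list(pa_patterns(), cols))
    for (k in names(raw$pattern_assignment)) {
      r <- raw$pattern_assignment[[k]]
      if (!is.null(r$intercept)) pa[k, "(Intercept)"] <- r$intercept
      for (v in setdiff(names(r), "intercept")) pa[k, v] <- r[[v]]
    }
  }
  args <- list(
    n = raw$n,
    covariates = covs,
    pattern_assignment = pa,
    seed = raw$seed %||% 1L
  )
  # a config file describes a self-contained world: effects it does not
  # mention are zero, not the package defaults (which reference the full
  # default covariate set)
  args$beta_covariate <- if (is.null(raw$beta_covariate)) {
    stats::setNames(rep(0, length(covs)), names(covs))
  } else unlist(raw$beta_covariate)
  args$beta_interaction <- if (is.null(raw$beta_interaction)) list()
    else lapply(raw$beta_interaction, unlist)
  if (!is.null(raw$beta_pattern)) args$beta_pattern <- unlist(raw$beta_pattern)
  if (!is.null(raw$baseline_hazard)) args$baseline_hazard <- raw$baseline_hazard
  if (!is.null(raw$censoring)) {
    args$censoring <- list(admin = raw$censoring$admin %||% Inf,
                           dropout = raw$censoring$dropout)
  }
  if (!is.null(raw$horizon)) args$horizon <- raw$horizon
  do.call(truth_config, args)
}
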