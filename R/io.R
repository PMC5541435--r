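# CSV dose-response tables and JSON model configurations.
#
# CSV dialect: comma-separated, UTF-8, '.' decimal, long format; dose
# columns named dose_<label>, effect in `effect` (optional `replicate`).
# Effects are stored internally as fractions; percent files are converted
# at the boundary.

#' Read a dose-response CSV table
#'
#' Expects a header with one `dose*` column per agent and an `effect`
#' column (optional `replicate`). Percent-scale effects are divided by 100
#' on the way in. Validation failures name the offending rows.
#'
#' @param path CSV file path.
#' @param scale `"fraction"` (effects in `[0, 1]`) or `"percent"` (effects
#'   in `[0, 100]`, converted to fractions).
#' @return A tibble with `dose_*` columns and `effect` as fractions;
#'   attribute `n_agents`.
#' @export
read_dose_response_csv <- function(path, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort_usage(sprintf("No such file: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dcols <- grep("^dose", names(tab), value = TRUE)
  if (!length(dcols)) {
    abort_domain("CSV must contain at least one dose column (named 'dose' or 'dose_<agent>').")
  }
  if (!"effect" %in% names(tab)) abort_domain("CSV must contain an 'effect' column.")
  for (cn in c(dcols, "effect")) {
    if (!is.numeric(tab[[cn]])) {
      abort_domain(sprintf("Column '%s' contains non-numeric cells.", cn))
    }
    if (anyNA(tab[[cn]])) {
      abort_domain(sprintf("Column '%s' has missing values in row(s) %s.",
                           cn, paste(head(which(is.na(tab[[cn]])), 5), collapse = ", ")))
    }
  }
  for (cn in dcols) {
    if (any(tab[[cn]] < 0)) {
      abort_domain(sprintf("Negative dose in column '%s', row(s) %s.", cn,
                           paste(head(which(tab[[cn]] < 0), 5), collapse = ", ")))
    }
  }
  hi <- if (scale == "percent") 100 else 1
  bad <- which(tab$effect < 0 | tab$effect > hi)
  if (length(bad)) {
    abort_domain(sprintf(
      "Effects outside [0, %g] on the declared '%s' scale in row(s) %s.",
      hi, scale, paste(head(bad, 5), collapse = ", ")))
  }
  if (scale == "percent") tab$effect <- tab$effect / 100
  structure(tibble::as_tibble(tab), n_agents = length(dcols))
}

#' Write a dose-response table to CSV
#'
#' Inverse of [read_dose_response_csv()]: values are written with full
#' precision (15 significant digits survive a round trip); fractions can be
#' emitted as percent.
#'
#' @param data Data frame with dose columns and effect-like numeric columns.
#' @param path Output path.
#' @param scale `"fraction"` or `"percent"` (multiplies `effect` columns by
#'   100 on the way out).
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(data, path, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  out <- as.data.frame(data)
  if (scale == "percent") {
    for (cn in intersect(c("effect", "effect_true"), names(out))) {
      out[[cn]] <- out[[cn]] * 100
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write mixture-model JSON configurations
#'
#' A configuration is a JSON object with an `agents` array (each with
#' `label`, `emax`, `d50`, `slope` and optional `e0`) and optional scalar
#' settings (`method`, `alpha`, `tol`, `seed`, `level`, grid controls).
#' Unknown keys are rejected with their paths. `write_model_config()`
#' followed by `read_model_config()` is lossless.
#'
#' @param path JSON file path.
#' @return `read_model_config()`: a [mixture_model()] with any extra
#'   settings in the `settings` attribute. `write_model_config()`: `path`,
#'   invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("No such file: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  known_top <- c("agents", "method", "alpha", "tol", "seed", "level",
                 "decades", "n", "sigma", "threshold")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    abort_domain(paste0("Unknown config key(s): ",
                        paste(unknown, collapse = ", "), "."))
  }
  if (is.null(cfg$agents)) abort_domain("Config is missing the 'agents' array.")
  ag <- as.data.frame(cfg$agents)
  known_agent <- c("label", "e0", "emax", "d50", "slope")
  unknown <- setdiff(names(ag), known_agent)
  if (length(unknown)) {
    abort_domain(paste0("Unknown agent key(s): agents.",
                        paste(unknown, collapse = ", agents."), "."))
  }
  for (fld in c("emax", "d50", "slope")) {
    if (is.null(ag[[fld]]) || anyNA(ag[[fld]])) {
      abort_domain(sprintf("Config agents are missing the field '%s'.", fld))
    }
  }
  model <- mixture_model(ag)
  attr(model, "settings") <- cfg[setdiff(names(cfg), "agents")]
  model
}

#' @rdname read_model_config
#' @param model A [mixture_model()].
#' @param settings Optional named list of extra scalar settings to store.
#' @export
write_model_config <- function(model, path, settings = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  cfg <- c(list(agents = as.data.frame(tidy(model))),
           settings %||% attr(model, "settings"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
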