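#' Construct a single-agent Hill dose-response curve
#'
#' A four-parameter logistic dose-response relationship on the linear dose
#' scale: `effect(d) = e0 + emax * m^slope / (1 + m^slope)` with the scaled
#' dose `m = d / d50`. `d50` is the median-effect dose (the dose producing
#' `e0 + emax/2`), `slope` the Hill coefficient (slope of the logistic in
#' log-dose at the inflection point). Effects are fractions: `e0 >= 0`,
#' `emax > 0`, `e0 + emax <= 1`.
#'
#' @param emax Maximum effect above baseline, in (0, 1].
#' @param d50 Median-effect dose, strictly positive, in the same (arbitrary)
#'   units as the doses the curve will be evaluated at.
#' @param slope Hill coefficient, in (0, 200]. The upper bound is a sanity
#'   cap motivated by the steepest dose-response curves reported for real
#'   agents (pyrethroid insecticides reach slopes above 100).
#' @param e0 Baseline effect at dose zero, default 0.
#' @param label Optional agent name.
#'
#' @return An object of class `hill_curve`.
#' @examples
#' crv <- hill_curve(emax = 0.7, d50 = 100, slope = 1, label = "A")
#' hill_effect(data.frame(dose = c(0, 100, 1e6)), crv)
#' @export
hill_curve <- function(emax, d50, slope, e0 = 0, label = NULL) {
  for (nm in c("emax", "d50", "slope", "e0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_domain(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (d50 <= 0) abort_domain("`d50` must be strictly positive.")
  if (slope <= 0 || slope > 200) {
    abort_domain(sprintf("`slope` must lie in (0, 200]; got %g.", slope))
  }
  if (e0 < 0) abort_domain("`e0` must be >= 0.")
  if (emax <= 0) abort_domain("`emax` must be > 0.")
  if (e0 + emax > 1 + 1e-12) {
    abort_domain(sprintf("`e0 + emax` must be <= 1; got %g.", e0 + emax))
  }
  structure(
    list(e0 = e0, emax = emax, d50 = d50, slope = slope,
         label = label %||% "agent"),
    class = "hill_curve"
  )
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("<hill_curve> %s: e0 = %g, emax = %g, d50 = %g, slope = %g\n",
              x$label, x$e0, x$emax, x$d50, x$slope))
  invisible(x)
}

is_hill_curve <- function(x) inherits(x, "hill_curve")

#' Construct a mixture model from component Hill curves
#'
#' An ordered collection of `n >= 1` single-agent Hill curves defining the
#' null-interaction response surface of their mixture. Accepts either a list
#' of [hill_curve()] objects or a data frame with columns `emax`, `d50`,
#' `slope` and optionally `e0` and `label` (or `agent`), one row per
#' component.
#'
#' @param x A list of `hill_curve` objects, a single `hill_curve`, or a data
#'   frame of parameters.
#' @return An object of class `mixture_model`.
#' @examples
#' # the worked binary example used throughout: emax 0.7/1.0, d50 100/1,
#' # slopes 1/2
#' mix <- mixture_model(data.frame(
#'   label = c("A", "B"), emax = c(0.7, 1), d50 = c(100, 1), slope = c(1, 2)
#' ))
#' tidy(mix)
#' @export
mixture_model <- function(x) {
  if (is_hill_curve(x)) x <- list(x)
  if (is.data.frame(x)) {
    need <- c("emax", "d50", "slope")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      abort_domain(paste0("Parameter table is missing column(s): ",
                          paste(miss, collapse = ", "), "."))
    }
    lab <- x[["label"]] %||% x[["agent"]] %||% paste0("agent_", seq_len(nrow(x)))
    e0 <- x[["e0"]] %||% rep(0, nrow(x))
    x <- purrr::pmap(
      list(x$emax, x$d50, x$slope, e0, as.character(lab)),
      function(emax, d50, slope, e0, label) {
        hill_curve(emax = emax, d50 = d50, slope = slope, e0 = e0, label = label)
      }
    )
  }
  if (!is.list(x) || length(x) < 1L || !all(vapply(x, is_hill_curve, logical(1)))) {
    abort_domain("`x` must be one or more `hill_curve` objects or a parameter data frame.")
  }
  labs <- vapply(x, function(c) c$label, character(1))
  if (anyDuplicated(labs)) {
    labs <- make.unique(labs, sep = "_")
    for (i in seq_along(x)) x[[i]]$label <- labs[i]
  }
  structure(list(components = x), class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> %d component(s)\n", n_agents(x)))
  print(tidy(x))
  invisible(x)
}

#' @describeIn mixture_model Number of mixture components.
#' @param model A `mixture_model`.
#' @export
n_agents <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  length(model$components)
}

#' @describeIn mixture_model Component labels.
#' @export
agent_labels <- function(model) {
  vapply(model$components, function(c) c$label, character(1))
}

param_vec <- function(model, what) {
  vapply(model$components, function(c) c[[what]], numeric(1))
}

#' Tidy a mixture model into its parameter table
#'
#' @param x A `mixture_model`.
#' @param ... Unused.
#' @return A tibble with one row per component: `label`, `e0`, `emax`,
#'   `d50`, `slope`.
#' @export
tidy.mixture_model <- function(x, ...) {
  tibble::tibble(
    label = agent_labels(x),
    e0 = param_vec(x, "e0"),
    emax = param_vec(x, "emax"),
    d50 = param_vec(x, "d50"),
    slope = param_vec(x, "slope")
  )
}

#' Rebase a mixture model to zero baseline
#'
#' The mixture surface formulas are defined for curves with zero baseline
#' (`e0 = 0`); the mixing functions have no baseline term. Curves with
#' `e0 > 0` are rebased by subtracting the baseline, leaving `emax`
#' unchanged. A warning records the rebasing.
#'
#' @param model A `mixture_model`.
#' @return A `mixture_model` whose components all have `e0 = 0`.
#' @export
rebase_baseline <- function(model) {
  e0 <- param_vec(model, "e0")
  if (all(e0 == 0)) return(model)
  warn(paste0(
    "Mixture surfaces are defined for zero-baseline curves; subtracting ",
    "baseline(s) e0 = (", paste(format(e0), collapse = ", "),
    ") with emax unchanged."
  ))
  model$components <- lapply(model$components, function(c) { c$e0 <- 0; c })
  model
}
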