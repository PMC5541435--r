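# Seeded synthetic-data generators: single-agent curves and checkerboard
# mixture grids under any implemented reference surface, with additive
# Gaussian noise on the effect fraction, clipped to [0, 1].

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L) {
    abort_domain("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

add_noise <- function(truth, sigma) {
  eff <- truth + rnorm(length(truth), 0, sigma)
  clipped <- sum(eff < 0 | eff > 1)
  list(effect = pmin(pmax(eff, 0), 1), n_clipped = clipped)
}

#' Simulate single-agent dose-response data
#'
#' Draws a log-spaced dose design around the curve's median-effect dose and
#' observes the Hill effect plus additive Gaussian noise on the effect
#' fraction, clipped to `[0, 1]`. The noise model is a pragmatic stand-in
#' for assay error of unknown structure; clipping events are counted in the
#' `n_clipped` attribute. Deterministic for a given `seed`.
#'
#' @param curve A [hill_curve()].
#' @param n_doses Number of dose levels (>= 4; default 8).
#' @param span Total width of the dose design in decades, centred on `d50`
#'   (default 4, i.e. `d50 * 10^(-2..2)`).
#' @param sigma Gaussian noise standard deviation on the effect fraction
#'   (default 0).
#' @param replicates Observations per dose level (default 1).
#' @param seed Random seed (default `NULL`: leave the RNG state alone).
#' @return A tibble with columns `dose`, `effect` and (when
#'   `replicates > 1`) `replicate`; attributes `n_clipped` and `truth`
#'   (the generating curve).
#' @examples
#' crv <- hill_curve(emax = 1, d50 = 2, slope = 3)
#' simulate_curve_data(crv, n_doses = 6, sigma = 0.02, seed = 7)
#' @export
simulate_curve_data <- function(curve, n_doses = 8, span = 4, sigma = 0,
                                replicates = 1, seed = NULL) {
  stopifnot(is_hill_curve(curve))
  if (!is.numeric(n_doses) || n_doses < 4) {
    abort_domain("`n_doses` must be at least 4.")
  }
  if (!is.numeric(span) || span <= 0) abort_domain("`span` must be positive decades.")
  if (!is.numeric(sigma) || sigma < 0) abort_domain("`sigma` must be >= 0.")
  doses <- curve$d50 * 10^seq(-span / 2, span / 2, length.out = n_doses)
  doses <- rep(doses, times = replicates)
  truth <- hill_effect(doses, curve)
  noisy <- with_seed(seed, add_noise(truth, sigma))
  out <- tibble::tibble(dose = doses, effect = noisy$effect)
  if (replicates > 1) out$replicate <- rep(seq_len(replicates), each = n_doses)
  structure(out, n_clipped = noisy$n_clipped, truth = curve)
}

#' Simulate a checkerboard mixture dose-response grid
#'
#' Generates a full-factorial (checkerboard) mixture table whose true
#' effects come from any implemented reference surface, with optional
#' injected synergy through the Greco interaction parameter `alpha`
#' (positive = synergy, negative = antagonism) and additive Gaussian noise.
#' Zero doses are included on the grid edges by default so the same table
#' exercises single-agent boundary rows and supports fitting the component
#' curves from its edges.
#'
#' @param model A [mixture_model()].
#' @param method Generating surface (default `"hill"`); use `"greco"` with
#'   `alpha` to inject interaction.
#' @param doses List of per-agent dose vectors; default: 0 plus `n_doses`
#'   log-spaced doses over `d50 * 10^(-decades..decades)` per agent.
#' @param n_doses,decades Default grid shape (5 positive doses over 2
#'   decades each side).
#' @param sigma Gaussian noise sd on the effect fraction.
#' @param alpha Interaction parameter for `method = "greco"`.
#' @param seed Random seed.
#' @return A tibble with `dose_<label>` columns, `effect`, and
#'   `effect_true`; attribute `n_clipped`. Row order is deterministic
#'   (first axis fastest).
#' @examples
#' mix <- mixture_model(data.frame(emax = c(1, 1), d50 = c(10, 1),
#'                                 slope = c(1, 2)))
#' simulate_mixture_grid(mix, sigma = 0.02, seed = 1)
#' @export
simulate_mixture_grid <- function(model, method = "hill", doses = NULL,
                                  n_doses = 5, decades = 2, sigma = 0,
                                  alpha = 0, seed = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (!is.numeric(sigma) || sigma < 0) abort_domain("`sigma` must be >= 0.")
  if (is.null(doses)) {
    doses <- lapply(param_vec(model, "d50"), function(d50) {
      c(0, d50 * 10^seq(-decades, decades, length.out = n_doses))
    })
  }
  if (length(doses) != n_agents(model)) {
    abort_dimension("`doses` must supply one dose vector per agent.")
  }
  names(doses) <- paste0("dose_", agent_labels(model))
  grid <- tibble::as_tibble(expand.grid(doses, KEEP.OUT.ATTRS = FALSE))
  truth <- eval_surface(method, grid, model, alpha = alpha)
  noisy <- with_seed(seed, add_noise(truth, sigma))
  grid$effect <- noisy$effect
  grid$effect_true <- truth
  structure(grid, n_clipped = noisy$n_clipped, method = method)
}
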