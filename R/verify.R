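# Numeric verification oracles: does an implemented surface actually solve
# the logistic PDE in log-dose coordinates, honour the single-agent boundary
# conditions, and satisfy sham compliance? These checks replace a symbolic
# verification and run on arbitrary parameter draws.

#' Residual of a surface in the mixture logistic PDE
#'
#' The Hill null-interaction surface solves, in log-dose coordinates
#' `x_i = log(d_i)`, the semilinear logistic PDE
#' `sum_i du/dx_i = gamma(m) * u * (1 - u / u_max(m))` with the
#' dose-weighted mixing functions [mix_gamma()] and [mix_umax()]. This
#' oracle estimates the directional derivative by central differences of
#' step `h` in each log-dose coordinate and returns the absolute residual.
#' For the Hill surface the residual is the discretisation error, of order
#' `h^2`; substituting a non-solution (for example the Bliss surface, with
#' the same mixing functions) leaves a residual bounded away from zero.
#'
#' @param doses Dose combination(s), all strictly positive (log coordinates
#'   must be finite); vector or matrix per [dose-input].
#' @param model A [mixture_model()].
#' @param h Central-difference step in log-dose units (default `1e-4`).
#' @param method Surface to test in the PDE (default `"hill"`).
#' @return Absolute residual(s), in effect-fraction units.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' pde_residual(c(100, 1), mix) # ~1e-9: Hill solves the PDE
#' pde_residual(c(100, 1), mix, method = "bliss") # O(0.1): Bliss does not
#' @export
pde_residual <- function(doses, model, h = 1e-4, method = "hill") {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    abort_domain("`h` must be a single positive step.")
  }
  model <- rebase_baseline(model)
  d <- as_dose_matrix(doses, model)
  if (any(d <= 0)) {
    abort_domain(paste0("PDE residuals need strictly positive doses ",
                        "(the boundary is checked by boundary_deviation())."))
  }
  x <- log(d)
  n <- ncol(x)
  u0 <- eval_surface(method, exp(x), model)
  dsum <- 0
  for (i in seq_len(n)) {
    xp <- x; xp[, i] <- xp[, i] + h
    xm <- x; xm[, i] <- xm[, i] - h
    dsum <- dsum +
      (eval_surface(method, exp(xp), model) -
         eval_surface(method, exp(xm), model)) / (2 * h)
  }
  m <- scaled_m(exp(x), model)
  g <- mix_gamma(m, model)
  um <- mix_umax(m, model)
  res <- abs(dsum - g * u0 * (1 - u0 / um))
  effect_out(res, doses)
}

#' Observed convergence order of the PDE residual
#'
#' Evaluates [pde_residual()] at a sequence of shrinking steps and fits the
#' slope of `log(residual)` against `log(h)`. A correct solution evaluated
#' with a second-order stencil converges at order 2 (observed slope close
#' to 2); a surface that does not solve the PDE plateaus at its true
#' residual (slope close to 0).
#'
#' @param doses A single dose combination, all entries positive.
#' @param model A [mixture_model()].
#' @param h Decreasing sequence of steps (default `c(1e-2, 5e-3, 2.5e-3)`).
#' @param method Surface to test.
#' @return A one-row tibble: `order` (fitted slope) and `residuals`
#'   (list-column of the residuals at each `h`).
#' @export
pde_convergence_order <- function(doses, model,
                                  h = c(1e-2, 5e-3, 2.5e-3),
                                  method = "hill") {
  if (length(h) < 2L) abort_domain("Need at least two steps `h`.")
  res <- vapply(h, function(hh) pde_residual(doses, model, h = hh,
                                             method = method), numeric(1))
  if (any(res <= 0)) {
    # residual at rounding level: report as converged beyond measurable order
    return(tibble::tibble(order = Inf, residuals = list(res)))
  }
  fit <- lm(log(res) ~ log(h))
  tibble::tibble(order = unname(coef(fit)[2]), residuals = list(res))
}

#' Sham-compliance deviation of a mixture surface
#'
#' Splits the dose of a single agent across `n` artificial copies of itself
#' with weights `w_i` (summing to 1) and measures how far the mixture
#' surface prediction departs from the agent's own dose-response curve:
#' `max_d |u(w_1 d, ..., w_n d) - a(d)|`. The Hill null-interaction surface
#' satisfies this identity exactly; Bliss independence does not, which is
#' the root of its incompatibility with the logistic surface.
#'
#' @param curve A [hill_curve()] with zero baseline.
#' @param weights Nonnegative weights summing to 1 (within `1e-12`).
#' @param doses Dose grid (default 41 log-spaced points over
#'   `d50 * 10^(-2..2)`).
#' @param method Surface to test (default `"hill"`).
#' @return Maximum absolute deviation over the dose grid.
#' @examples
#' crv <- hill_curve(emax = 1, d50 = 1, slope = 1)
#' sham_deviation(crv, c(0.3, 0.7))                   # ~1e-16
#' sham_deviation(crv, c(0.5, 0.5), method = "bliss") # 0.0625 at d50
#' @export
sham_deviation <- function(curve, weights,
                           doses = curve$d50 * 10^seq(-2, 2, length.out = 41),
                           method = "hill") {
  stopifnot(is_hill_curve(curve))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    abort_domain("`weights` must be nonnegative and sum to 1 (within 1e-12).")
  }
  if (any(doses < 0)) abort_domain("Doses must be >= 0.")
  model <- mixture_model(replicate(length(weights), curve, simplify = FALSE))
  split_doses <- outer(doses, weights)
  u <- eval_surface(method, split_doses, model)
  max(abs(u - hill_effect(doses, curve)))
}

#' Single-agent boundary deviation of a mixture surface
#'
#' Sets every dose except one component's to zero and measures the maximum
#' departure of the mixture surface from that agent's own Hill curve. All
#' implemented reference models satisfy this pure-agent limit.
#'
#' @param model A [mixture_model()] (zero baselines).
#' @param component Index of the component kept active.
#' @param doses Dose grid for the active component (default 41 log-spaced
#'   points around its `d50`).
#' @param method Surface to test.
#' @param alpha Interaction parameter for `method = "greco"`.
#' @return Maximum absolute deviation over the dose grid.
#' @export
boundary_deviation <- function(model, component,
                               doses = NULL, method = "hill", alpha = 0) {
  n <- n_agents(model)
  if (!is.numeric(component) || length(component) != 1L ||
      component < 1 || component > n) {
    abort_domain(sprintf("`component` must index one of the %d components.", n))
  }
  crv <- model$components[[component]]
  if (is.null(doses)) doses <- crv$d50 * 10^seq(-2, 2, length.out = 41)
  d <- matrix(0, length(doses), n)
  d[, component] <- doses
  u <- eval_surface(method, d, model, alpha = alpha)
  max(abs(u - hill_effect(doses, crv)))
}
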