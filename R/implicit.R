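# Implicit reference models solved by bracketed root finding.
#
# Both the Loewe CA and the implicit Greco equations have left sides that
# are strictly decreasing in the effect u on (0, u_cap), so a sign change in
# the bracket guarantees a unique root; stats::uniroot (Brent) does the rest.

# one CA / Greco residual: f(u) = sum_i m_i ((cap_i - u)/u)^(1/gamma_i) [- 1]
ca_lhs <- function(u, m, emax, gamma) {
  sum(m * ((emax - u) / u)^(1 / gamma))
}

solve_decreasing <- function(f, lower, upper, tol, max_iter = 200L) {
  fl <- f(lower); fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu)) {
    abort_numeric(sprintf(
      "Implicit-model residual not finite on bracket [%g, %g].", lower, upper))
  }
  if (fl < 0 || fu > 0) return(NULL) # no sign change: no root in bracket
  r <- uniroot(f, c(lower, upper), tol = tol, maxiter = max_iter)
  if (abs(r$estim.prec) > max(tol * 10, 1e-12) && abs(f(r$root)) > 1e-6) {
    abort_numeric(sprintf(
      "Root finder did not converge on bracket [%g, %g] (residual %g).",
      lower, upper, f(r$root)))
  }
  r$root
}

#' Loewe additivity (concentration addition) surface
#'
#' Solves the implicit concentration-addition equation
#' `1 = sum_i m_i / (u / (emax_i - u))^(1/slope_i)` for the mixture effect
#' `u` by bracketed root finding on `(0, min(emax_i))`. The left side is
#' strictly decreasing in `u`, so the root is unique where it exists.
#' All-zero dose combinations return 0; a single nonzero dose returns that
#' agent's own Hill effect.
#'
#' For unequal maximum effects and doses dominated by the stronger partner
#' the classical CA equation has no solution below the weakest agent's
#' maximum (and is undefined above it, where `emax_i - u` turns negative
#' under a fractional power). Such combinations are reported as the CA cap
#' `min(emax_i)` with a warning.
#'
#' @inheritParams hill_surface_effect
#' @param tol Relative solver tolerance (default `1e-10`).
#' @param max_iter Maximum root-finder iterations.
#' @return Effect fractions below `min(emax_i)`; shape per [dose-input].
#' @examples
#' mix <- mixture_model(data.frame(emax = c(1, 1), d50 = c(1, 1),
#'                                 slope = c(2, 2)))
#' loewe_effect(c(1, 1), mix) # 4/5: equals the equal-parameter Hill surface
#' @export
loewe_effect <- function(doses, model, tol = 1e-10, max_iter = 200L) {
  model <- rebase_baseline(model)
  m <- scaled_m(doses, model)
  emax <- param_vec(model, "emax")
  gamma <- param_vec(model, "slope")
  umin <- min(emax)
  eps <- 1e-14 * umin
  capped <- FALSE
  u <- apply(m, 1L, function(mi) {
    act <- mi > 0
    if (!any(act)) return(0)
    if (sum(act) == 1L) {
      i <- which(act)
      return(hill_effect(mi[i] * model$components[[i]]$d50,
                         model$components[[i]]))
    }
    f <- function(u) ca_lhs(u, mi[act], emax[act], gamma[act]) - 1
    root <- solve_decreasing(f, eps, umin * (1 - 1e-12), tol * umin, max_iter)
    if (is.null(root)) { capped <<- TRUE; return(umin) }
    root
  })
  if (capped) {
    warn(paste0("Some dose combinations exceed the concentration-addition ",
                "domain (no CA effect below min(emax) exists); reported as ",
                "the cap min(emax) = ", format(umin), "."))
  }
  effect_out(u, doses)
}

#' Greco interaction surface (implicit form)
#'
#' Solves Greco's two-agent interaction equation
#' `1 = m_a/(u/(E-u))^(1/ga) + m_b/(u/(E-u))^(1/gb)
#'    + alpha * m_a m_b / (u/(E-u))^((1/ga + 1/gb)/2)`
#' for the effect `u`, where both agents share the maximum effect
#' `E = emax` (the model's stated restriction) but may differ in slope.
#' `alpha = 0` reduces to Loewe CA; for equal slopes the solution matches
#' the explicit form [greco_explicit_effect()].
#'
#' @inheritParams hill_surface_effect
#' @param curve_a,curve_b [hill_curve()]s for the two agents; `emax` must
#'   match.
#' @param alpha Interaction parameter (positive = synergy).
#' @param tol Relative solver tolerance.
#' @param max_iter Maximum root-finder iterations.
#' @return Effect fractions in `(0, emax)`; shape per [dose-input].
#' @examples
#' a <- hill_curve(emax = 1, d50 = 10, slope = 1)
#' b <- hill_curve(emax = 1, d50 = 2, slope = 1)
#' greco_implicit_effect(c(10, 2), a, b, alpha = 1) # 0.75
#' @export
greco_implicit_effect <- function(doses, curve_a, curve_b, alpha = 0,
                                  tol = 1e-10, max_iter = 200L) {
  stopifnot(is_hill_curve(curve_a), is_hill_curve(curve_b))
  if (abs(curve_a$emax - curve_b$emax) > 1e-12) {
    abort_domain(sprintf(
      "Greco's implicit model requires a common maximum effect; got emax_a = %g, emax_b = %g.",
      curve_a$emax, curve_b$emax))
  }
  model <- mixture_model(list(curve_a, curve_b))
  model <- rebase_baseline(model)
  E <- curve_a$emax
  ga <- curve_a$slope; gb <- curve_b$slope
  m <- scaled_m(doses, model)
  eps <- 1e-14 * E
  u <- apply(m, 1L, function(mi) {
    ma <- mi[1]; mb <- mi[2]
    if (ma == 0 && mb == 0) return(0)
    if (mb == 0) return(hill_effect(ma * curve_a$d50, model$components[[1]]))
    if (ma == 0) return(hill_effect(mb * curve_b$d50, model$components[[2]]))
    f <- function(u) {
      r <- (E - u) / u
      ma * r^(1 / ga) + mb * r^(1 / gb) +
        alpha * ma * mb * r^((1 / ga + 1 / gb) / 2) - 1
    }
    root <- solve_decreasing(f, eps, E * (1 - 1e-12), tol * E, max_iter)
    if (is.null(root)) {
      abort_numeric(sprintf(
        "No Greco effect in (0, emax) for m = (%g, %g), alpha = %g.",
        ma, mb, alpha))
    }
    root
  })
  effect_out(u, doses)
}
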