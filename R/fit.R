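# Hill-curve fitting by multi-start nonlinear least squares, mixture
# prediction under any reference surface, and RMSE-based synergy scoring.

check_dr_table <- function(data, need_effect = TRUE) {
  if (!is.data.frame(data)) abort_domain("`data` must be a data frame.")
  if (need_effect) {
    if (!"effect" %in% names(data)) {
      abort_domain("`data` needs an `effect` column.")
    }
    eff <- data$effect
    if (!is.numeric(eff) || anyNA(eff)) {
      abort_domain("`effect` must be numeric with no missing values.")
    }
    if (any(eff < -1e-9 | eff > 1 + 1e-9)) {
      bad <- which(eff < 0 | eff > 1)
      abort_domain(sprintf(
        "Effects must be fractions in [0, 1] (rows %s out of range); use scale = 'percent' when reading percent data.",
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(data)
}

hill_pred <- function(theta, d) {
  # theta on the optimizer scale: (emax, log d50, log slope) + fixed e0
  m <- d / exp(theta[["ld50"]])
  theta[["e0"]] + theta[["emax"]] *
    ifelse(d == 0, 0, plogis(exp(theta[["lslope"]]) * log(m)))
}

#' Fit a Hill curve to single-agent dose-response data
#'
#' Nonlinear least squares on the effect scale, parametrised in
#' `(emax, log d50, log slope)` so positivity needs no constraints, with a
#' fixed multi-start scheme over initial slopes `{0.5, 1, 2, 8}` (observed
#' dose-response slopes span roughly 0.8 to above 100) and `d50` initialised
#' at the dose whose observed effect is nearest half the observed maximum.
#' Any of `emax`, `d50`, `slope` can be held fixed — fixing `slope = 1`
#' reproduces the classical unit-slope workflow next to the free-slope fit.
#' The procedure is fully deterministic: the `seed` argument is accepted for
#' interface compatibility and ignored.
#'
#' @param data Data frame with columns `dose` and `effect` (fractions in
#'   `[0, 1]`; optional `replicate` is carried through). At least 4 distinct
#'   dose levels, at least 3 of them positive.
#' @param fixed Named list of parameters to hold fixed, any of `emax`,
#'   `d50`, `slope`.
#' @param e0 Baseline, fixed (default 0; all bundled workflows run 0 to
#'   max).
#' @param start_slopes Multi-start slope grid.
#' @param seed Ignored; the fit has no random component.
#' @return An object of class `hill_fit` with [tidy()], [glance()],
#'   [augment()] and [autoplot()] methods. Fields include `curve` (the
#'   fitted [hill_curve()]), `rmse_fit`, `cov` (covariance of the free
#'   optimizer-scale parameters) and convergence diagnostics.
#' @examples
#' crv <- hill_curve(emax = 1, d50 = 2, slope = 3)
#' dat <- simulate_curve_data(crv, n_doses = 8, sigma = 0)
#' fit <- fit_hill(dat)
#' tidy(fit)
#' @export
fit_hill <- function(data, fixed = list(), e0 = 0,
                     start_slopes = c(0.5, 1, 2, 8), seed = NULL) {
  check_dr_table(data)
  if (!"dose" %in% names(data)) abort_domain("`data` needs a `dose` column.")
  d <- data$dose
  y <- data$effect
  if (any(d < 0)) abort_domain("Doses must be >= 0.")
  if (length(unique(d)) < 4L) {
    abort_domain("Need at least 4 distinct dose levels to fit a Hill curve.")
  }
  if (sum(unique(d) > 0) < 3L) {
    abort_domain("Need at least 3 distinct positive dose levels.")
  }
  bad_fixed <- setdiff(names(fixed), c("emax", "d50", "slope"))
  if (length(bad_fixed)) {
    abort_domain(paste0("Unknown fixed parameter(s): ",
                        paste(bad_fixed, collapse = ", "), "."))
  }

  # starting values from the data
  emax0 <- min(max(max(y) - e0, 0.05), 1 - e0)
  half <- e0 + emax0 / 2
  pos <- d > 0
  d50_0 <- d[pos][which.min(abs(y[pos] - half))]
  starts <- if ("slope" %in% names(fixed)) 1 else start_slopes

  full_theta <- function(free) {
    th <- c(
      emax = unname(fixed$emax %||% free[["emax"]]),
      ld50 = unname(if (!is.null(fixed$d50)) log(fixed$d50) else free[["ld50"]]),
      lslope = unname(if (!is.null(fixed$slope)) log(fixed$slope) else free[["lslope"]]),
      e0 = e0
    )
    th
  }
  free_names <- setdiff(c("emax", "ld50", "lslope"),
                        c("emax", "ld50", "lslope")[c("emax", "d50", "slope") %in% names(fixed)])
  ssr <- function(free) {
    names(free) <- free_names
    r <- y - hill_pred(as.list(full_theta(as.list(free))), d)
    sum(r * r)
  }
  lower <- c(emax = 1e-6, ld50 = log(d50_0) - 15, lslope = log(1e-3))[free_names]
  upper <- c(emax = 1 - e0, ld50 = log(d50_0) + 15, lslope = log(200))[free_names]

  best <- NULL
  iterations <- 0L
  for (s0 in starts) {
    init <- c(emax = emax0, ld50 = log(d50_0), lslope = log(s0))[free_names]
    res <- tryCatch(
      optim(init, ssr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    iterations <- iterations + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.null(best)) {
    # Gauss-Newton polish of the winning start: quadratic convergence near
    # the optimum, which L-BFGS-B alone does not reach for tiny residuals
    par <- best$par
    val <- best$value
    resid_of <- function(free) {
      names(free) <- free_names
      y - hill_pred(as.list(full_theta(as.list(free))), d)
    }
    for (it in seq_len(25L)) {
      r0 <- resid_of(par)
      J <- matrix(0, length(y), length(par))
      hstep <- 1e-7
      for (j in seq_along(par)) {
        pj <- par; pj[j] <- pj[j] + hstep
        J[, j] <- (resid_of(pj) - r0) / hstep
      }
      step <- tryCatch(qr.solve(J, r0), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- par; improved <- FALSE
      for (damp in c(1, 0.5, 0.25, 0.1)) {
        trial <- pmin(pmax(par - damp * step, lower), upper)
        v <- ssr(trial)
        iterations <- iterations + 1L
        if (v < val) { cand <- trial; val <- v; improved <- TRUE; break }
      }
      if (!improved || sum(step^2) < 1e-28) break
      par <- cand
    }
    best$par <- par
    best$value <- val
  }
  if (is.null(best)) {
    abort_numeric("All multi-start fits failed; check the data scale.")
  }

  th <- full_theta(as.list(stats::setNames(best$par, free_names)))
  curve <- hill_curve(emax = th[["emax"]], d50 = exp(th[["ld50"]]),
                      slope = exp(th[["lslope"]]), e0 = e0,
                      label = attr(data, "label") %||% "agent")
  fitted <- hill_pred(as.list(th), d)
  r <- y - fitted
  n <- length(y); p <- length(free_names)
  sigma2 <- sum(r * r) / max(n - p, 1)

  # Gauss-Newton covariance from a finite-difference Jacobian (free params)
  J <- matrix(0, n, p, dimnames = list(NULL, free_names))
  hstep <- 1e-6
  for (j in seq_len(p)) {
    tp <- th; tp[free_names[j]] <- tp[free_names[j]] + hstep
    tm <- th; tm[free_names[j]] <- tm[free_names[j]] - hstep
    J[, j] <- (hill_pred(as.list(tp), d) - hill_pred(as.list(tm), d)) / (2 * hstep)
  }
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, p, p,
                                             dimnames = list(free_names, free_names)))

  structure(
    list(curve = curve, rmse_fit = sqrt(mean(r * r)),
         sigma = sqrt(sigma2), cov = cov, free = free_names, fixed = fixed,
         n = n, df_residual = n - p, iterations = iterations,
         converged = best$convergence == 0, data = tibble::as_tibble(data)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  print(tidy(x))
  cat(sprintf("RMSE of fit: %.4g (n = %d)\n", x$rmse_fit, x$n))
  invisible(x)
}

#' Tidy, glance at, or augment a fitted Hill curve
#'
#' `tidy()` returns one row per parameter with delta-method standard errors
#' on the natural scale (`d50` and `slope` are optimised as logs);
#' `glance()` returns one-row fit diagnostics; `augment()` returns the data
#' with `.fitted` and `.resid`.
#'
#' @param x,object A `hill_fit`.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  est <- c(emax = x$curve$emax, d50 = x$curve$d50, slope = x$curve$slope)
  se_theta <- sqrt(diag(x$cov))
  se <- c(emax = NA_real_, d50 = NA_real_, slope = NA_real_)
  if ("emax" %in% x$free) se["emax"] <- se_theta[["emax"]]
  if ("ld50" %in% x$free) se["d50"] <- x$curve$d50 * se_theta[["ld50"]]
  if ("lslope" %in% x$free) se["slope"] <- x$curve$slope * se_theta[["lslope"]]
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    fixed = names(est) %in% names(x$fixed)
  )
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    rmse = x$rmse_fit, sigma = x$sigma, n_obs = x$n,
    df_residual = x$df_residual, iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname tidy.hill_fit
#' @export
augment.hill_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- hill_effect(out$dose, x$curve)
  out$.resid <- out$effect - out$.fitted
  out
}

# collect a mixture model from fits, curves, or a ready model
as_mixture_model <- function(x) {
  if (inherits(x, "mixture_model")) return(x)
  if (is_hill_curve(x) || inherits(x, "hill_fit")) x <- list(x)
  if (is.list(x)) {
    curves <- lapply(x, function(el) {
      if (inherits(el, "hill_fit")) el$curve
      else if (is_hill_curve(el)) el
      else abort_domain("Mixture components must be hill_fit or hill_curve objects.")
    })
    return(mixture_model(curves))
  }
  abort_domain("Cannot interpret `model` as a mixture model.")
}

#' Predict mixture effects under a reference surface
#'
#' Evaluates the chosen reference model at every observed dose combination
#' and, when the table carries observed effects, scores the prediction by
#' its root-mean-square error — the synergy indicator for dose-response
#' surfaces: a null-interaction reference that underpredicts the
#' observations systematically points at synergy, overprediction at
#' antagonism.
#'
#' @param data Data frame with one dose column per agent (and optionally
#'   `effect`). Single-agent rows (all other doses zero) are predicted by
#'   the corresponding fitted curve, by the boundary property of every
#'   implemented reference.
#' @param model A [mixture_model()], a list of [hill_curve()]s or
#'   [fit_hill()] results, or a single one of either.
#' @param method Reference model name (see [evaluate_surface()]).
#' @param alpha,tol Passed to the evaluator.
#' @return The input as a tibble with `.pred` (and `.resid` when `effect`
#'   is present), of class `mixture_prediction`; `glance()` gives the RMSE.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' tab <- simulate_mixture_grid(mix, sigma = 0, seed = 1)
#' glance(predict_mixture(tab, mix, method = "hill"))$rmse # 0
#' @export
predict_mixture <- function(data, model, method = "hill", alpha = 0,
                            tol = 1e-10) {
  model <- as_mixture_model(model)
  if (!is.data.frame(data)) abort_domain("`data` must be a data frame.")
  u <- eval_surface(method, data, model, alpha = alpha, tol = tol)
  out <- tibble::as_tibble(data)
  out$.pred <- u
  rmse <- NA_real_
  if ("effect" %in% names(data)) {
    check_dr_table(data)
    out$.resid <- out$effect - out$.pred
    rmse <- sqrt(mean(out$.resid^2))
  }
  structure(out, method = method, rmse = rmse,
            class = c("mixture_prediction", class(out)))
}

#' @export
glance.mixture_prediction <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), rmse = attr(x, "rmse"),
                 n_obs = nrow(x))
}

#' Score observed mixture data against reference surfaces
#'
#' Compares an observed mixture dose-response table against one or more
#' reference surfaces at once: per-point predictions and signed deviations
#' (observed minus predicted) for every model, per-model prediction RMSEs,
#' and a flag marking dose combinations where the first (reference) model
#' and any other disagree by more than `threshold` — the dose regions where
#' synergy classifications depend on the choice of null model and deserve
#' special attention. No interaction index is computed: the null-interaction
#' surface has no free interaction parameter, so deviation from it is the
#' synergy measure.
#'
#' @param data Data frame with dose columns and observed `effect`.
#' @param model As in [predict_mixture()].
#' @param methods Character vector of reference models; the first is the
#'   reference against which the others are compared for flagging.
#' @param threshold Absolute between-model disagreement (effect fraction)
#'   above which a dose combination is flagged (default 0.05).
#' @param alpha,tol Passed to the evaluators.
#' @return A tibble of class `synergy_report`: the doses, `effect`, one
#'   `pred_<method>` and `dev_<method>` column pair per model, and
#'   `flagged`. `glance()` returns per-method RMSEs.
#' @export
synergy_report <- function(data, model, methods = c("hill", "bliss"),
                           threshold = 0.05, alpha = 0, tol = 1e-10) {
  model <- as_mixture_model(model)
  check_dr_table(data)
  if (length(methods) < 1L) abort_domain("Need at least one method.")
  if (!is.numeric(threshold) || threshold < 0) {
    abort_domain("`threshold` must be a nonnegative effect fraction.")
  }
  out <- tibble::as_tibble(data)
  preds <- purrr::map(methods, function(mth) {
    eval_surface(mth, data, model, alpha = alpha, tol = tol)
  })
  names(preds) <- methods
  for (mth in methods) {
    out[[paste0("pred_", mth)]] <- preds[[mth]]
    out[[paste0("dev_", mth)]] <- out$effect - preds[[mth]]
  }
  ref <- preds[[1]]
  gap <- rep(0, nrow(out))
  for (mth in methods[-1]) gap <- pmax(gap, abs(ref - preds[[mth]]))
  out$flagged <- gap > threshold
  rmses <- tibble::tibble(
    method = methods,
    rmse = vapply(preds, function(p) sqrt(mean((out$effect - p)^2)), numeric(1))
  )
  structure(out, rmse = rmses, threshold = threshold, reference = methods[1],
            class = c("synergy_report", class(out)))
}

#' @export
glance.synergy_report <- function(x, ...) attr(x, "rmse")
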