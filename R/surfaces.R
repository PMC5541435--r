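#' @section Dose inputs:
#' All surface evaluators accept doses either as a numeric vector (one dose
#' per agent, a single combination), a numeric matrix (one row per
#' combination), or a data frame with one dose column per agent (columns
#' named `dose_<label>` matching the model, or any all-numeric columns in
#' component order). Data-frame input yields a tibble output with an
#' `.effect` column; numeric input yields a numeric vector.
#' @name dose-input
#' @keywords internal
NULL

# normalize dose input to a numeric matrix with one column per agent
as_dose_matrix <- function(doses, model, require_n = NULL) {
  n <- if (!is.null(model)) n_agents(model) else require_n
  if (is.data.frame(doses)) {
    cols <- dose_columns(doses, model, require_n = n)
    m <- as.matrix(doses[cols])
  } else if (is.matrix(doses)) {
    m <- doses
  } else if (is.numeric(doses)) {
    m <- matrix(doses, nrow = 1L)
  } else {
    abort_domain("Doses must be a numeric vector, matrix, or data frame.")
  }
  storage.mode(m) <- "double"
  if (!is.null(n) && ncol(m) != n) {
    abort_dimension(sprintf(
      "Dose input has %d column(s) but the model has %d component(s).",
      ncol(m), n
    ))
  }
  if (anyNA(m) || any(!is.finite(m))) {
    abort_domain("All doses must be finite and non-missing.")
  }
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)
    abort_domain(sprintf("Doses must be >= 0 (violated in row(s) %s).",
                         paste(head(bad, 5), collapse = ", ")))
  }
  m
}

# find the dose columns of a data frame for a given model
dose_columns <- function(data, model = NULL, require_n = NULL) {
  if (!is.null(model)) {
    named <- paste0("dose_", agent_labels(model))
    if (all(named %in% names(data))) return(named)
  }
  pref <- grep("^dose", names(data), value = TRUE)
  cand <- if (length(pref)) pref else
    names(data)[vapply(data, is.numeric, logical(1)) &
                  !names(data) %in% c("effect", "replicate")]
  n <- require_n %||% length(cand)
  if (length(cand) < n) {
    abort_dimension(sprintf(
      "Expected %d dose column(s); found %s.",
      n, if (length(cand)) paste(cand, collapse = ", ") else "none"
    ))
  }
  cand[seq_len(n)]
}

# wrap a numeric effect vector back into the caller's shape
effect_out <- function(u, doses, col = ".effect") {
  if (is.data.frame(doses)) {
    doses[[col]] <- u
    return(tibble::as_tibble(doses))
  }
  u
}

#' Single-agent Hill effect
#'
#' Evaluates the four-parameter Hill curve
#' `e0 + emax * m^slope / (1 + m^slope)` with `m = dose / d50` at the given
#' doses. Dose 0 returns `e0`; the effect increases monotonically to
#' `e0 + emax`.
#'
#' @param doses Numeric vector of doses (>= 0), or a data frame with a
#'   `dose` column.
#' @param curve A [hill_curve()].
#' @return Numeric vector of effect fractions, or the input tibble with an
#'   `.effect` column added.
#' @examples
#' crv <- hill_curve(emax = 0.7, d50 = 100, slope = 1)
#' hill_effect(c(0, 100, 300), crv) # 0, 0.35, 0.525
#' @export
hill_effect <- function(doses, curve) {
  stopifnot(is_hill_curve(curve))
  d <- if (is.data.frame(doses)) {
    if (!"dose" %in% names(doses)) {
      abort_domain("Data frame input to `hill_effect()` needs a `dose` column.")
    }
    doses[["dose"]]
  } else doses
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d))) {
    abort_domain("Doses must be finite numbers.")
  }
  if (any(d < 0)) abort_domain("Doses must be >= 0.")
  # logistic in log dose: stable for extreme slopes (printed slopes reach 106)
  u <- ifelse(d == 0, 0, plogis(curve$slope * (log(d) - log(curve$d50))))
  effect_out(curve$e0 + curve$emax * u, doses)
}

#' Scale doses by their median-effect doses
#'
#' Returns the dimensionless scaled doses `m_i = d_i / d50_i`, the natural
#' coordinates of all mixture reference models. Zeros stay zero.
#'
#' @inheritParams hill_surface_effect
#' @return A numeric matrix (or vector for a single combination) of scaled
#'   doses, or a tibble with `m_<label>` columns for data-frame input.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' scaled_doses(c(100, 1), mix) # c(1, 1)
#' @export
scaled_doses <- function(doses, model) {
  d <- as_dose_matrix(doses, model)
  m <- sweep(d, 2L, param_vec(model, "d50"), "/")
  if (is.data.frame(doses)) {
    out <- tibble::as_tibble(doses)
    mm <- tibble::as_tibble(as.data.frame(m))
    names(mm) <- paste0("m_", agent_labels(model))
    return(dplyr::bind_cols(out, mm))
  }
  if (is.matrix(doses)) m else drop(m)
}

# dose-weighted mixing functions; rows with all m = 0 give NaN (0/0),
# the all-zero limit is resolved by the callers (effect 0 by continuity)
mix_weighted <- function(m, w) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  as.vector(m %*% w) / rowSums(m)
}

#' Dose-weighted mixture slope and maximum effect
#'
#' The mixing functions of the Hill null-interaction surface: the effective
#' slope `gamma(m) = sum(slope_i * m_i) / sum(m_i)` and effective maximum
#' `u_max(m) = sum(emax_i * m_i) / sum(m_i)`, dose-weighted means of the
#' component parameters. Both interpolate smoothly between the pure-agent
#' values; an all-zero scaled-dose vector is degenerate (0/0) and returns
#' `NaN` — surface evaluators resolve that limit to effect 0 by continuity.
#'
#' @param m Scaled doses: numeric vector (one combination) or matrix (one
#'   row per combination), as produced by [scaled_doses()].
#' @param model A [mixture_model()].
#' @return Numeric vector, one value per dose combination.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' mix_gamma(c(1, 1), mix) # 1.5
#' mix_umax(c(1, 1), mix)  # 0.85
#' @export
mix_gamma <- function(m, model) {
  m <- as_dose_matrix(m, model)
  mix_weighted(m, param_vec(model, "slope"))
}

#' @rdname mix_gamma
#' @export
mix_umax <- function(m, model) {
  m <- as_dose_matrix(m, model)
  mix_weighted(m, param_vec(model, "emax"))
}

#' Hill null-interaction response surface
#'
#' The closed-form n-component response surface
#' `u(m) = u_max(m) * S^gamma(m) / (1 + S^gamma(m))` with `S = sum(m_i)`,
#' where `gamma(m)` and `u_max(m)` are the dose-weighted mixing functions
#' ([mix_gamma()], [mix_umax()]). It solves the logistic partial
#' differential equation in log-dose coordinates, reduces to each
#' single-agent Hill curve when the other doses are zero, and is exactly
#' sham-compliant: splitting one agent's dose across artificial copies of
#' itself leaves the predicted effect unchanged. The logistic factor is
#' evaluated in log space (`plogis(gamma * log(S))`) so that very steep
#' slopes do not overflow.
#'
#' @param doses Dose combinations on the linear dose scale; see
#'   [dose-input]. All doses must be >= 0; an all-zero combination returns
#'   effect 0 (the continuity limit).
#' @param model A [mixture_model()]. Components must have zero baseline;
#'   nonzero baselines are rebased with a warning (see [rebase_baseline()]).
#' @return Effect fractions in `[0, max(emax_i)]`; numeric vector or tibble
#'   per [dose-input].
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' hill_surface_effect(c(100, 1), mix) # 0.85 * 2^1.5 / (1 + 2^1.5) = 0.628
#' @export
hill_surface_effect <- function(doses, model) {
  model <- rebase_baseline(model)
  m <- scaled_m(doses, model)
  S <- rowSums(m)
  u <- numeric(nrow(m))
  pos <- S > 0
  if (any(pos)) {
    g <- mix_weighted(m[pos, , drop = FALSE], param_vec(model, "slope"))
    um <- mix_weighted(m[pos, , drop = FALSE], param_vec(model, "emax"))
    u[pos] <- um * plogis(g * log(S[pos]))
  }
  effect_out(u, doses)
}

scaled_m <- function(doses, model) {
  d <- as_dose_matrix(doses, model)
  sweep(d, 2L, param_vec(model, "d50"), "/")
}

#' Bliss independence (Colby's formula) surface
#'
#' The multiplicative-survival / independent-action reference: the fraction
#' affected by the mixture is `1 - prod(1 - a_i(d_i))`, where `a_i` are the
#' single-agent Hill curves with their own maxima (`emax_i` stays inside
#' each factor). Reduces to the single-agent curve when all other doses are
#' zero, but is not sham-compliant: splitting one agent's dose across
#' copies of itself changes the prediction.
#'
#' @inheritParams hill_surface_effect
#' @return Effect fractions in `[0, 1]`; shape per [dose-input].
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' bliss_effect(c(100, 1), mix) # 0.35 + 0.5 - 0.35*0.5 = 0.675
#' @export
bliss_effect <- function(doses, model) {
  model <- rebase_baseline(model)
  d <- as_dose_matrix(doses, model)
  fu <- matrix(1, nrow(d), ncol(d))
  for (i in seq_len(ncol(d))) {
    fu[, i] <- 1 - hill_effect(d[, i], model$components[[i]])
  }
  effect_out(1 - apply(fu, 1L, prod), doses)
}

#' Generalized concentration addition (GCA) surface
#'
#' The explicit GCA expression `sum(emax_i * m_i) / (1 + sum(emax_i * m_i))`
#' for mixtures of full and partial agonists with unit Hill slopes.
#'
#' Note the printed form places the weighted sum in both numerator and
#' denominator: it coincides with the slope-1 Hill surface only when all
#' `emax_i = 1` (then both reduce to `S / (1 + S)`). For partial agonists
#' the two differ; the GCA formula is implemented verbatim.
#'
#' @inheritParams hill_surface_effect
#' @return Effect fractions in `[0, 1)`; shape per [dose-input].
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 1)))
#' gca_effect(c(50, 0.5), mix) # 0.85/1.85
#' @export
gca_effect <- function(doses, model) {
  model <- rebase_baseline(model)
  m <- scaled_m(doses, model)
  s <- as.vector(m %*% param_vec(model, "emax"))
  effect_out(s / (1 + s), doses)
}

check_umax_gamma <- function(umax, gamma) {
  if (!is.numeric(umax) || length(umax) != 1L || umax <= 0 || umax > 1) {
    abort_domain("`umax` must be a single value in (0, 1].")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort_domain("`gamma` must be a single positive value.")
  }
}

as_m_matrix <- function(m, n = NULL) {
  if (is.data.frame(m)) m <- as.matrix(m[vapply(m, is.numeric, logical(1))])
  if (is.null(dim(m))) m <- matrix(as.numeric(m), nrow = 1L)
  if (!is.null(n) && ncol(m) != n) {
    abort_dimension(sprintf("Expected %d scaled-dose column(s), got %d.",
                            n, ncol(m)))
  }
  if (anyNA(m) || any(m < 0)) abort_domain("Scaled doses must be >= 0.")
  m
}

#' Chou-Talalay median-effect surfaces
#'
#' Shared-parameter median-effect models on scaled doses. The mutually
#' exclusive form is `umax * S^gamma / (1 + S^gamma)` with `S = m_a + m_b`
#' (any number of agents); it equals the Hill surface when all components
#' share `(emax, slope)`. The mutually non-exclusive form (binary only)
#' adds the product term, `S = m_a + m_b + m_a * m_b`; for `gamma = 1` and
#' `umax = 1` it coincides with Bliss independence of two slope-1,
#' full-effect agents.
#'
#' @param m Scaled doses (vector = one combination, or matrix/data frame of
#'   combinations). The non-exclusive form requires exactly two agents.
#' @param umax Common maximum effect, in (0, 1].
#' @param gamma Common Hill slope, positive.
#' @return Effect fractions; numeric vector (or tibble for data-frame input).
#' @examples
#' chou_exclusive_effect(c(1, 1), umax = 0.85, gamma = 1.5) # 0.628
#' chou_nonexclusive_effect(c(1, 1), umax = 1, gamma = 1)   # 0.75
#' @export
chou_exclusive_effect <- function(m, umax, gamma) {
  check_umax_gamma(umax, gamma)
  mm <- as_m_matrix(m)
  S <- rowSums(mm)
  effect_out(ifelse(S == 0, 0, umax * plogis(gamma * log(S))), m)
}

#' @rdname chou_exclusive_effect
#' @export
chou_nonexclusive_effect <- function(m, umax, gamma) {
  check_umax_gamma(umax, gamma)
  mm <- as_m_matrix(m, n = 2L)
  S <- mm[, 1] + mm[, 2] + mm[, 1] * mm[, 2]
  effect_out(ifelse(S == 0, 0, umax * plogis(gamma * log(S))), m)
}

#' Greco interaction surface (explicit form)
#'
#' The explicit two-agent Greco model
#' `umax * S^gamma / (1 + S^gamma)` with
#' `S = m_a + m_b + alpha * m_a * m_b`, valid for components sharing both
#' `umax` and `gamma`. `alpha = 0` reproduces the Chou exclusive model,
#' `alpha = 1` the non-exclusive model; `alpha > 0` injects synergy and
#' `alpha < 0` antagonism. Strongly antagonistic `alpha` that drives the
#' combined-dose argument negative is rejected.
#'
#' @inheritParams chou_exclusive_effect
#' @param alpha Interaction parameter (0 = null interaction in the
#'   median-effect sense).
#' @return Effect fractions; shape as the input.
#' @examples
#' greco_explicit_effect(c(1, 1), umax = 1, gamma = 1, alpha = 2) # 0.8
#' @export
greco_explicit_effect <- function(m, umax, gamma, alpha) {
  check_umax_gamma(umax, gamma)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    abort_domain("`alpha` must be a single finite number.")
  }
  mm <- as_m_matrix(m, n = 2L)
  S <- mm[, 1] + mm[, 2] + alpha * mm[, 1] * mm[, 2]
  if (any(S < 0)) {
    abort_domain(sprintf(
      "alpha = %g makes the combined-dose argument negative for some dose pair.",
      alpha
    ))
  }
  effect_out(ifelse(S == 0, 0, umax * plogis(gamma * log(S))), m)
}

surface_methods <- c("hill", "bliss", "gca", "loewe",
                     "chou_ex", "chou_nex", "greco")

# shared (umax, gamma) of a model, for the shared-parameter methods
common_param <- function(model, what, method) {
  v <- param_vec(model, what)
  if (diff(range(v)) > 1e-12) {
    abort_domain(sprintf(
      "Method '%s' requires all components to share `%s`; got (%s).",
      method, what, paste(format(v), collapse = ", ")
    ))
  }
  v[1]
}

# single dispatch point for evaluating any reference surface on a dose matrix
eval_surface <- function(method, doses, model, alpha = 0, tol = 1e-10) {
  method <- match.arg(method, surface_methods)
  d <- as_dose_matrix(doses, model)
  switch(method,
    hill  = hill_surface_effect(d, model),
    bliss = bliss_effect(d, model),
    gca   = gca_effect(d, model),
    loewe = loewe_effect(d, model, tol = tol),
    chou_ex = chou_exclusive_effect(
      scaled_m(d, model),
      umax = common_param(model, "emax", method),
      gamma = common_param(model, "slope", method)
    ),
    chou_nex = {
      if (n_agents(model) != 2L) abort_dimension("'chou_nex' is binary only.")
      chou_nonexclusive_effect(
        scaled_m(d, model),
        umax = common_param(model, "emax", method),
        gamma = common_param(model, "slope", method)
      )
    },
    greco = {
      if (n_agents(model) != 2L) abort_dimension("'greco' is binary only.")
      sl <- param_vec(model, "slope")
      if (abs(diff(sl)) <= 1e-12) {
        greco_explicit_effect(
          scaled_m(d, model),
          umax = common_param(model, "emax", method),
          gamma = sl[1], alpha = alpha
        )
      } else {
        greco_implicit_effect(d, model$components[[1]], model$components[[2]],
                              alpha = alpha, tol = tol)
      }
    }
  )
}

#' Evaluate a reference response surface on a dose table
#'
#' Tidy front door to every implemented null-interaction / reference model.
#' Takes a data frame of dose combinations (one column per agent) and
#' appends the predicted effect of the chosen model as `.effect`.
#'
#' @param data Data frame with one dose column per model component
#'   (`dose_<label>` preferred, otherwise numeric columns in component
#'   order).
#' @param model A [mixture_model()].
#' @param method One of `"hill"`, `"bliss"`, `"gca"`, `"loewe"`,
#'   `"chou_ex"`, `"chou_nex"`, `"greco"`.
#' @param alpha Interaction parameter, used by `method = "greco"` only.
#' @param tol Relative tolerance for the implicit (root-found) models.
#' @return The input as a tibble with an `.effect` column.
#' @examples
#' mix <- mixture_model(data.frame(label = c("A", "B"), emax = c(0.7, 1),
#'                                 d50 = c(100, 1), slope = c(1, 2)))
#' grid <- expand.grid(dose_A = c(0, 100), dose_B = c(0, 1))
#' evaluate_surface(grid, mix, method = "hill")
#' @export
evaluate_surface <- function(data, model, method = "hill", alpha = 0,
                             tol = 1e-10) {
  if (!is.data.frame(data)) abort_domain("`data` must be a data frame.")
  u <- eval_surface(method, data, model, alpha = alpha, tol = tol)
  if (is.data.frame(u)) u else effect_out(u, data)
}
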