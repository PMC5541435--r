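# Iso-effect geometry: isoboles (binary), iso-surfaces (ternary) and
# difference grids between reference surfaces.

#' Log-spaced dose grid around the median-effect doses
#'
#' Default evaluation grid for surfaces and difference plots: per agent,
#' `n` log-spaced doses spanning `d50 * 10^(-decades)` to
#' `d50 * 10^(+decades)`.
#'
#' @param model A [mixture_model()].
#' @param decades Half-width of the span in decades (default 3).
#' @param n Points per axis (default 61).
#' @param include_zero Prepend dose 0 to each axis (default `FALSE`).
#' @return A tibble: the full factorial grid with columns `dose_<label>`.
#' @export
dose_grid <- function(model, decades = 3, n = 61, include_zero = FALSE) {
  if (!is.numeric(decades) || decades <= 0 || !is.numeric(n) || n < 2) {
    abort_domain("`decades` must be positive and `n` >= 2.")
  }
  axes <- lapply(param_vec(model, "d50"), function(d50) {
    ax <- d50 * 10^seq(-decades, decades, length.out = n)
    if (include_zero) c(0, ax) else ax
  })
  names(axes) <- paste0("dose_", agent_labels(model))
  tibble::as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# find m_y >= 0 with f(m_y) = level by scanning a log grid for a sign change
# and refining with uniroot; NA when the level is unattainable on the ray
solve_iso_coord <- function(eval_at, level, tol,
                            lo = 1e-9, hi = 1e9, n_scan = 121L) {
  # probes may leave an implicit model's domain (e.g. the Loewe cap);
  # those warnings are part of the scan, not of the solved point
  f <- function(my) suppressWarnings(eval_at(my) - level)
  grid <- c(0, 10^seq(log10(lo), log10(hi), length.out = n_scan))
  fv <- vapply(grid, f, numeric(1))
  if (any(abs(fv) <= tol)) return(grid[which.min(abs(fv))])
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
}

#' Extract an isobole (iso-effect curve) of a binary reference surface
#'
#' For each value of the first agent's scaled dose, solves for the second
#' agent's scaled dose at which the chosen model produces `level`. Grid
#' points where the level is unattainable (for instance a level above the
#' first agent's own maximum on the pure-A axis) are omitted and counted in
#' the `n_unattainable` attribute — they are never clamped.
#'
#' For a Hill surface whose components share `(emax, slope)`, the isobole
#' is exactly the line `m_a + m_b = (E / (emax - E))^(1/slope)`.
#'
#' @param model A binary [mixture_model()].
#' @param level Effect level, strictly between 0 and the attainable maximum.
#' @param method Reference model name (see [evaluate_surface()]).
#' @param m_a Scaled doses of agent 1 at which to solve (default 41
#'   log-spaced points over `10^-2 .. 10^2`, plus 0).
#' @param alpha Interaction parameter for `method = "greco"`.
#' @param tol Solver tolerance on the effect scale (default `1e-10`).
#' @return A tibble of class `isobole` with columns `m_a`, `m_b`,
#'   `dose_<label>` for both agents, and `effect` (the re-evaluated model
#'   effect at the solved point). Attributes: `level`, `method`,
#'   `n_unattainable`.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(1, 1), d50 = c(1, 1),
#'                                 slope = c(1, 1)))
#' iso <- isobole(mix, level = 0.5) # the straight line m_a + m_b = 1
#' @export
isobole <- function(model, level, method = "hill",
                    m_a = c(0, 10^seq(-2, 2, length.out = 41)),
                    alpha = 0, tol = 1e-10) {
  if (n_agents(model) != 2L) abort_dimension("Isoboles are defined for binary mixtures.")
  emax <- param_vec(model, "emax")
  umax_att <- max(emax)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= umax_att) {
    abort_domain(sprintf(
      "`level` must lie strictly inside the attainable range (0, %g).", umax_att))
  }
  if (any(m_a < 0)) abort_domain("`m_a` values must be >= 0.")
  d50 <- param_vec(model, "d50")
  pts <- purrr::map(sort(unique(m_a)), function(ma) {
    mb <- solve_iso_coord(function(my) {
      eval_surface(method, c(ma * d50[1], my * d50[2]), model,
                   alpha = alpha, tol = tol)
    }, level, tol)
    if (is.na(mb)) return(NULL)
    eff <- eval_surface(method, c(ma * d50[1], mb * d50[2]), model,
                        alpha = alpha, tol = tol)
    tibble::tibble(m_a = ma, m_b = mb, effect = eff)
  })
  n_miss <- sum(vapply(pts, is.null, logical(1)))
  out <- dplyr::bind_rows(pts)
  if (nrow(out)) {
    out[[paste0("dose_", agent_labels(model)[1])]] <- out$m_a * d50[1]
    out[[paste0("dose_", agent_labels(model)[2])]] <- out$m_b * d50[2]
  }
  structure(out, level = level, method = method, n_unattainable = n_miss,
            class = c("isobole", class(out)))
}

#' Extract a ternary iso-surface of a reference model
#'
#' For each cell of a checkerboard in the first two agents' scaled doses,
#' solves for the third agent's scaled dose at which the model produces
#' `level`. Cells where the level is unattainable are kept with `m_3 = NA`
#' (explicitly marked, never silently zero).
#'
#' In scaled-dose space the iso-surface is planar when all components share
#' the slope and either share the maximum effect or have common slope 1;
#' mixtures of agents with different slopes give non-planar iso-surfaces.
#'
#' @param model A ternary [mixture_model()].
#' @param level Effect level in the attainable range.
#' @param method Reference model name.
#' @param m_1,m_2 Scaled-dose axes of the first two agents (defaults: 21
#'   log-spaced points over `10^-2 .. 10^1`).
#' @param tol Solver tolerance.
#' @return A tibble of class `iso_surface` with columns `m_1`, `m_2`, `m_3`
#'   (NA where unattainable) and `effect`; attributes `level`, `method`.
#' @export
iso_surface <- function(model, level, method = "hill",
                        m_1 = 10^seq(-2, 1, length.out = 21),
                        m_2 = 10^seq(-2, 1, length.out = 21),
                        tol = 1e-10) {
  if (n_agents(model) != 3L) abort_dimension("Iso-surfaces are defined for ternary mixtures.")
  emax <- param_vec(model, "emax")
  if (level <= 0 || level >= max(emax)) {
    abort_domain(sprintf("`level` must lie in (0, %g).", max(emax)))
  }
  d50 <- param_vec(model, "d50")
  grid <- expand.grid(m_1 = m_1, m_2 = m_2, KEEP.OUT.ATTRS = FALSE)
  m3 <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    solve_iso_coord(function(my) {
      eval_surface(method,
                   c(grid$m_1[i] * d50[1], grid$m_2[i] * d50[2], my * d50[3]),
                   model, tol = tol)
    }, level, tol)
  })
  eff <- rep(NA_real_, nrow(grid))
  ok <- !is.na(m3)
  if (any(ok)) {
    dmat <- cbind(grid$m_1[ok] * d50[1], grid$m_2[ok] * d50[2], m3[ok] * d50[3])
    eff[ok] <- eval_surface(method, dmat, model, tol = tol)
  }
  out <- tibble::tibble(m_1 = grid$m_1, m_2 = grid$m_2, m_3 = m3, effect = eff)
  structure(out, level = level, method = method,
            class = c("iso_surface", class(out)))
}

#' Deviation of an iso-surface from the best-fit plane
#'
#' Fits the affine plane `m_3 ~ m_1 + m_2` through the solved iso-surface
#' points by least squares and returns the maximum absolute residual — the
#' planarity diagnostic for ternary mixtures.
#'
#' @param surface An [iso_surface()] result.
#' @return Maximum absolute plane-fit residual in scaled-dose units.
#' @export
plane_deviation <- function(surface) {
  pts <- surface[!is.na(surface$m_3), c("m_1", "m_2", "m_3")]
  if (nrow(pts) < 4L) {
    abort_numeric("Too few solved iso-surface points to fit a plane.")
  }
  fit <- lm(m_3 ~ m_1 + m_2, data = pts)
  max(abs(resid(fit)))
}

#' Difference grid between two reference surfaces
#'
#' Evaluates two reference models on the same dose grid and returns the
#' elementwise difference `u_A - u_B`, the standard way to locate dose
#' regions where independent-action and null-interaction references
#' disagree (and hence where synergy claims deserve scrutiny).
#'
#' @param model A [mixture_model()].
#' @param method_a,method_b Reference model names; the difference is
#'   `method_a - method_b`.
#' @param grid Data frame of dose combinations (default [dose_grid()] with
#'   its defaults).
#' @param alpha,tol Passed to the evaluators.
#' @return A tibble of class `difference_grid`: the grid plus `effect_a`,
#'   `effect_b`, `diff`. Attributes `summary` (a one-row tibble with
#'   `min`, `max`, and the doses and scaled doses at the maximum absolute
#'   difference) and `methods`.
#' @examples
#' mix <- mixture_model(data.frame(emax = c(0.7, 1), d50 = c(100, 1),
#'                                 slope = c(1, 2)))
#' dg <- difference_grid(mix, "bliss", "hill",
#'                       grid = dose_grid(mix, decades = 4, n = 41))
#' attr(dg, "summary")$max # approaches 0.30 but stays below it
#' @export
difference_grid <- function(model, method_a, method_b,
                            grid = dose_grid(model), alpha = 0, tol = 1e-10) {
  if (!is.data.frame(grid)) abort_domain("`grid` must be a data frame.")
  d <- as_dose_matrix(grid, model)
  ua <- eval_surface(method_a, d, model, alpha = alpha, tol = tol)
  ub <- eval_surface(method_b, d, model, alpha = alpha, tol = tol)
  out <- tibble::as_tibble(grid)
  out$effect_a <- ua
  out$effect_b <- ub
  out$diff <- ua - ub
  i <- which.max(abs(out$diff))
  m_at <- drop(scaled_m(d[i, , drop = FALSE], model))
  summ <- tibble::tibble(
    min = min(out$diff), max = max(out$diff),
    argmax_dose = list(d[i, ]), argmax_m = list(m_at)
  )
  structure(out, summary = summ, methods = c(method_a, method_b),
            class = c("difference_grid", class(out)))
}
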