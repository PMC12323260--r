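#' Sigmoid schedule for time-dependent constraint bounds
#'
#' Bounds interpolate between loose initial values and strict final values
#' as sampling progresses, following the logistic
#' `s(t) = 1 / (1 + exp(-beta * (t - t0)))`:
#' `lower(t) = lower_final + (lower_initial - lower_final) * (1 - s(t))`
#' and analogously for the upper bound. Early in sampling (`s ~ 0`) the
#' feasible interval is wide and the constraint barely acts; late
#' (`s ~ 1`) the bounds coincide with their strict final values. `t` is
#' normalized sampling progress in `[0, 1]` (0 = start of generation at the
#' noise prior, 1 = end), regardless of the direction of diffusion time.
#'
#' An infinite initial bound cannot be interpolated directly (Eq.-style
#' linear interpolation against an infinity overflows), so it is handled as
#' an inactive-until-finite sentinel: while `s(t) <= 1e-6` the bound stays
#' infinite (the constraint side does not act), and once `s(t) > 1e-6` it
#' follows the track `final -/+ unbounded_width * (1 - s(t))`, i.e. it
#' tightens toward the final bound from a proxy placed `unbounded_width`
#' away. The default width of 20 (angstrom or degrees) is far outside the
#' scatter of any of the package's noise schedules, so the early regime is
#' effectively unconstrained.
#'
#' @param beta steepness of the transition (default 10).
#' @param t0 midpoint of the transition in normalized progress
#'   (default 0.5).
#' @param lower_initial,upper_initial loose initial bounds (default
#'   `-Inf`/`Inf` = unbounded).
#' @param lower_final,upper_final strict final bounds.
#' @param unbounded_width proxy interpolation width for unbounded initial
#'   endpoints (default 20).
#' @return an object of class `bound_schedule`.
#' @examples
#' sch <- bound_schedule(beta = 10, t0 = 0.5, lower_final = 3.9,
#'                       upper_final = 3.9)
#' bounds_at(1, sch) # c(3.9, 3.9)
#' @export
bound_schedule <- function(beta = 10, t0 = 0.5,
                           lower_initial = -Inf, upper_initial = Inf,
                           lower_final, upper_final,
                           unbounded_width = 20) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (lower_final > upper_final || lower_initial > upper_initial) {
    stop("lower bound exceeds upper bound", call. = FALSE)
  }
  if (unbounded_width <= 0) stop("unbounded_width must be positive",
                                 call. = FALSE)
  structure(
    list(beta = beta, t0 = t0,
         lower_initial = lower_initial, upper_initial = upper_initial,
         lower_final = lower_final, upper_final = upper_final,
         unbounded_width = unbounded_width),
    class = "bound_schedule")
}

#' @rdname bound_schedule
#' @param t normalized sampling progress in `[0, 1]`.
#' @param schedule a `bound_schedule`.
#' @return `schedule_sigmoid`: the logistic value `s(t)` in `(0, 1)`.
#' @export
schedule_sigmoid <- function(t, schedule) {
  1 / (1 + exp(-schedule$beta * (t - schedule$t0)))
}

#' @rdname bound_schedule
#' @return `bounds_at`: numeric `c(lower, upper)` at progress `t`.
#' @export
bounds_at <- function(t, schedule) {
  s <- schedule_sigmoid(t, schedule)
  # endpoint-normalized mixing for the unbounded proxy track: the raw
  # logistic never quite reaches 0/1 on [0, 1], so rescale it to hit both
  # endpoints exactly -- at tau = 1 the proxy width is exactly zero and the
  # bound is strict
  s0 <- schedule_sigmoid(0, schedule)
  s1 <- schedule_sigmoid(1, schedule)
  sn <- min(1, max(0, (s - s0) / (s1 - s0)))
  interp <- function(initial, final, side) {
    if (is.infinite(initial)) {
      if (sn <= 1e-6) return(initial)       # unbounded-until-finite sentinel
      return(final + side * schedule$unbounded_width * (1 - sn))
    }
    final + (initial - final) * (1 - s)
  }
  lo <- interp(schedule$lower_initial, schedule$lower_final, -1)
  up <- interp(schedule$upper_initial, schedule$upper_final, +1)
  if (lo > up) stop("schedule produced lower > upper", call. = FALSE)
  c(lo, up)
}

#' Advance the deterministic bound state
#'
#' The bound variables evolve deterministically alongside the stochastic
#' coordinates. Because the sigmoid interpolation gives their trajectory in
#' closed form, the update simply evaluates the closed form at `t + dt`:
#' the result is exact and independent of how `[t, t + dt]` is partitioned.
#'
#' @param state a list with element `t` (current normalized progress) as
#'   returned by `schedule_state()`, plus the schedules it tracks.
#' @param dt progress increment (`>= 0`).
#' @return the state advanced to `t + dt`, with element `bounds` holding the
#'   per-schedule `c(lower, upper)` at the new time.
#' @examples
#' sch <- bound_schedule(lower_final = 0, upper_final = 0)
#' st <- schedule_state(list(sch), t = 0)
#' zeta_step(st, 0.5)$t
#' @export
zeta_step <- function(state, dt) {
  if (dt < 0) stop("dt must be nonnegative", call. = FALSE)
  state$t <- min(1, state$t + dt)
  state$bounds <- lapply(state$schedules, function(s) bounds_at(state$t, s))
  state
}

#' @rdname zeta_step
#' @param schedules list of [bound_schedule()] objects.
#' @param t initial progress (default 0).
#' @export
schedule_state <- function(schedules, t = 0) {
  st <- list(schedules = schedules, t = t)
  st$bounds <- lapply(schedules, function(s) bounds_at(t, s))
  st
}

constraint_bounds_at <- function(constraint, t) {
  if (!is.null(constraint$schedule)) {
    return(bounds_at(t, constraint$schedule))
  }
  c(constraint$lower_final, constraint$upper_final)
}

#' Resolve the active constraint set at a given progress
#'
#' Bounded constraints act through a slack variable: while the measured
#' value sits strictly inside `[lower(t), upper(t)]` the slack absorbs the
#' deviation and the constraint is inactive (it contributes nothing to the
#' Jacobian). A value outside the interval clamps the slack at its limit,
#' turning the constraint into an equality against the violated bound.
#' When `lower(t) = upper(t)` the constraint is always active (the
#' holonomic limit).
#'
#' @param set a [constraint_set()].
#' @param conf a [conformation()].
#' @param t normalized progress in `[0, 1]`.
#' @return an `active_constraint_view`: list with `active_indices`,
#'   `effective_targets` (per active constraint), `slack_values`
#'   (per-constraint deviation absorbed by the slack), and `bounds`
#'   (per-constraint `c(lower, upper)` at `t`).
#' @export
resolve_active <- function(set, conf, t) {
  conf <- as_conformation(conf)
  A <- length(set)
  active <- integer(0)
  targets <- numeric(0)
  slack <- numeric(A)
  bnds <- vector("list", A)
  for (a in seq_len(A)) {
    cst <- set[[a]]
    b <- constraint_bounds_at(cst, t)
    bnds[[a]] <- b
    if (b[1L] == b[2L]) {          # holonomic limit: always active
      active <- c(active, a)
      targets <- c(targets, b[1L])
      slack[a] <- 0
      next
    }
    v <- measured_value(cst, conf)
    dev <- if (cst$kind == "distance") v - cst$target else
      wrap_angle(v - cst$target)
    if (v > b[2L]) {
      active <- c(active, a)
      targets <- c(targets, b[2L])
      slack[a] <- b[2L] - cst$target
    } else if (v < b[1L]) {
      active <- c(active, a)
      targets <- c(targets, b[1L])
      slack[a] <- b[1L] - cst$target
    } else {
      slack[a] <- dev              # inside bounds: slack absorbs it
    }
  }
  structure(
    list(active_indices = active, effective_targets = targets,
         slack_values = slack, bounds = bnds, t = t),
    class = "active_constraint_view")
}

# Project a trial conformation onto the feasible region defined by the
# scheduled bounds at progress t: resolve the active set, SHAKE-project onto
# the active equalities, and re-resolve in case the correction pushed a
# previously inactive constraint out of bounds.
project_scheduled <- function(trial, set, t, tol = 0.003, max_iter = 100L,
                              on_failure = "error", max_cycles = 3L) {
  conf <- as_conformation(trial)
  total_iter <- 0L
  corr <- 0
  converged <- TRUE
  max_res <- 0
  for (cycle in seq_len(max_cycles)) {
    view <- resolve_active(set, conf, t)
    if (length(view$active_indices) == 0L) {
      return(list(conformation = conf, iterations_used = total_iter,
                  final_max_residual = 0, converged = converged,
                  correction_norm = corr, active = view))
    }
    sub <- set[view$active_indices]
    res <- shake_project(conf, sub, tol = tol, max_iter = max_iter,
                         targets = view$effective_targets,
                         on_failure = on_failure)
    total_iter <- total_iter + res$iterations_used
    corr <- corr + res$correction_norm
    conf <- res$conformation
    converged <- converged && res$converged
    max_res <- res$final_max_residual
    # feasibility check against the *bounds* (not the equality targets)
    viol <- bound_violation(set, conf, t)
    if (max(viol) <= tol) {
      return(list(conformation = conf, iterations_used = total_iter,
                  final_max_residual = max(viol), converged = converged,
                  correction_norm = corr, active = view))
    }
  }
  list(conformation = conf, iterations_used = total_iter,
       final_max_residual = max(bound_violation(set, conf, t)),
       converged = FALSE, correction_norm = corr,
       active = resolve_active(set, conf, t))
}

# Per-constraint violation of the scheduled bounds at progress t
# (0 when inside the interval).
bound_violation <- function(set, conf, t) {
  conf <- as_conformation(conf)
  vapply(seq_along(set), function(a) {
    cst <- set[[a]]
    b <- constraint_bounds_at(cst, t)
    v <- measured_value(cst, conf)
    if (cst$kind != "distance") {
      # compare on the wrapped deviation scale around the target
      v <- cst$target + wrap_angle(v - cst$target)
    }
    max(0, v - b[2L], b[1L] - v)
  }, numeric(1))
}
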