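#' Guidance baseline: harmonic restraint parameters
#'
#' The guidance baseline softly pushes a conformation toward constraint
#' satisfaction by descending the harmonic restraint potential
#' `U(x) = sum_a (k_a / 2) * sigma_a(x)^2` with step size `gamma`,
#' treating every constraint independently (no coupling solve). Defaults
#' (`k = 10`, `gamma = 1e-3`, one inner iteration per diffusion step) keep
#' the updates stable but visibly under-correcting relative to the exact
#' SHAKE projection.
#'
#' @param step_size the gradient step `gamma` (> 0, default `1e-3`).
#' @param force_constants force constant(s) `k`; a scalar is recycled over
#'   constraints (default 10, energy units per squared residual unit).
#' @param inner_iterations gradient steps applied per call (default 1).
#' @return an object of class `guidance_params`.
#' @export
guidance_params <- function(step_size = 1e-3, force_constants = 10,
                            inner_iterations = 1L) {
  if (step_size <= 0) stop("step_size must be positive", call. = FALSE)
  if (any(force_constants <= 0)) {
    stop("force constants must be positive", call. = FALSE)
  }
  if (inner_iterations < 1L) {
    stop("inner_iterations must be at least 1", call. = FALSE)
  }
  structure(list(step_size = step_size, force_constants = force_constants,
                 inner_iterations = as.integer(inner_iterations)),
            class = "guidance_params")
}

guidance_k <- function(params, A) {
  k <- params$force_constants
  if (length(k) == 1L) rep(k, A) else {
    if (length(k) != A) stop("force_constants length must be 1 or A",
                             call. = FALSE)
    k
  }
}

#' Harmonic restraint energy
#'
#' `U(x) = sum_a (k_a / 2) * residual_a^2`, using the linear residual of
#' each constraint (distance residuals in angstrom, angular in degrees).
#'
#' @param set a [constraint_set()].
#' @param conf a [conformation()].
#' @param params a [guidance_params()].
#' @return nonnegative numeric scalar; zero iff every residual is zero.
#' @export
harmonic_energy <- function(set, conf, params = guidance_params()) {
  conf <- as_conformation(conf)
  k <- guidance_k(params, length(set))
  r <- vapply(seq_along(set), function(a)
    linear_residual(set[[a]], conf), numeric(1))
  sum(k / 2 * r^2)
}

#' One guidance update
#'
#' Shifts every atom by `-gamma * grad U(x)` where the harmonic gradient of
#' constraint `a` is `k_a * residual_a * grad sigma_a` -- each constraint
#' contributing independently, with no mechanism to account for their
#' interaction. Repeated `inner_iterations` times.
#'
#' @inheritParams harmonic_energy
#' @return list with `conformation` (updated) and `correction_norm` (total
#'   Euclidean displacement).
#' @examples
#' conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
#' set <- constraint_set(distance_constraint(1, 2, 1.0))
#' guidance_step(conf, set, guidance_params(step_size = 0.1,
#'                                          force_constants = 1))
#' @export
guidance_step <- function(conf, set, params = guidance_params()) {
  conf <- as_conformation(conf)
  if (length(set) == 0L) {
    return(list(conformation = conf, correction_norm = 0))
  }
  k <- guidance_k(params, length(set))
  x0 <- conf_to_vector(conf)
  x <- x0
  cur <- conf
  for (it in seq_len(params$inner_iterations)) {
    g <- numeric(length(x))
    for (a in seq_along(set)) {
      r <- linear_residual(set[[a]], cur)
      g <- g + k[a] * r * constraint_gradient(set[[a]], cur)
    }
    x <- x - params$step_size * g
    cur <- vector_to_conf(x, template = conf)
  }
  list(conformation = cur, correction_norm = sqrt(sum((x - x0)^2)))
}
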