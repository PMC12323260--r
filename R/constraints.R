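#' Geometric constraints
#'
#' A geometric constraint ties an internal coordinate of a conformation --
#' an interatomic distance, a bond angle, or a torsion -- to a target value
#' or to a (possibly time-dependent) interval around it. The residual uses
#' the linear form `sigma(x) = value - target` (angular values wrapped to
#' the shortest arc), whose gradient does not vanish at the solution and so
#' keeps the Lagrange-multiplier Gram system well conditioned near
#' feasibility. A squared form `sigma^2` is available via `form = "squared"`
#' for comparison.
#'
#' Bounds: `lower_final`/`upper_final` are the strict bounds enforced at the
#' end of sampling; `lower_initial`/`upper_initial` (default unbounded) are
#' the loose bounds at the start. A [bound_schedule()] interpolates between
#' them; without one, bounds are constant at their final values.
#'
#' @param i,j,k,l 1-based atom indices (distinct).
#' @param target target value: angstrom for distances, degrees for
#'   angles/torsions.
#' @param lower_final,upper_final final strict bounds (default `target`).
#' @param lower_initial,upper_initial initial loose bounds (default
#'   `-Inf`/`Inf`, i.e. inactive until the schedule tightens them).
#' @param slack_max maximum permitted deviation from `target`; a shorthand
#'   for `lower_final = target - slack_max`, `upper_final = target +
#'   slack_max`. `0` (default) means strict equality.
#' @param schedule optional [bound_schedule()] governing how the bounds
#'   tighten with sampling progress.
#' @param form `"linear"` (default) or `"squared"` residual form.
#' @return an object of class `geometric_constraint`.
#' @examples
#' d <- distance_constraint(1, 4, target = 3.9)
#' d$kind
#' @export
distance_constraint <- function(i, j, target,
                                lower_final = NULL, upper_final = NULL,
                                lower_initial = -Inf, upper_initial = Inf,
                                slack_max = 0, schedule = NULL,
                                form = c("linear", "squared")) {
  new_constraint("distance", c(i, j), target, lower_final, upper_final,
                 lower_initial, upper_initial, slack_max, schedule,
                 match.arg(form))
}

#' @rdname distance_constraint
#' @export
angle_constraint <- function(i, j, k, target,
                             lower_final = NULL, upper_final = NULL,
                             lower_initial = -Inf, upper_initial = Inf,
                             slack_max = 0, schedule = NULL,
                             form = c("linear", "squared")) {
  new_constraint("angle", c(i, j, k), target, lower_final, upper_final,
                 lower_initial, upper_initial, slack_max, schedule,
                 match.arg(form))
}

#' @rdname distance_constraint
#' @export
dihedral_constraint <- function(i, j, k, l, target,
                                lower_final = NULL, upper_final = NULL,
                                lower_initial = -Inf, upper_initial = Inf,
                                slack_max = 0, schedule = NULL,
                                form = c("linear", "squared")) {
  new_constraint("dihedral", c(i, j, k, l), target, lower_final, upper_final,
                 lower_initial, upper_initial, slack_max, schedule,
                 match.arg(form))
}

new_constraint <- function(kind, atoms, target, lower_final, upper_final,
                           lower_initial, upper_initial, slack_max, schedule,
                           form) {
  atoms <- as.integer(atoms)
  if (anyDuplicated(atoms) || any(atoms < 1L)) {
    stop("atom indices must be distinct positive integers", call. = FALSE)
  }
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target)) {
    stop("target must be a single finite number", call. = FALSE)
  }
  if (slack_max < 0) stop("slack_max must be nonnegative", call. = FALSE)
  if (is.null(lower_final)) lower_final <- target - slack_max
  if (is.null(upper_final)) upper_final <- target + slack_max
  if (lower_final > upper_final || lower_initial > upper_initial) {
    stop("lower bound exceeds upper bound", call. = FALSE)
  }
  if (!is.null(schedule) && !inherits(schedule, "bound_schedule")) {
    stop("schedule must be a bound_schedule", call. = FALSE)
  }
  structure(
    list(kind = kind, atoms = atoms, target = target,
         lower_final = lower_final, upper_final = upper_final,
         lower_initial = lower_initial, upper_initial = upper_initial,
         slack_max = slack_max, schedule = schedule, form = form),
    class = "geometric_constraint"
  )
}

#' @export
print.geometric_constraint <- function(x, ...) {
  cat(sprintf("<%s constraint on atoms [%s], target %.4g>\n",
              x$kind, paste(x$atoms, collapse = ","), x$target))
  invisible(x)
}

#' Ordered collection of geometric constraints
#'
#' @param ... `geometric_constraint` objects, or a single list of them.
#' @return an object of class `constraint_set` (a list of constraints).
#' @examples
#' set <- constraint_set(distance_constraint(1, 2, 1.53),
#'                       distance_constraint(2, 3, 1.53))
#' length(set)
#' @export
constraint_set <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) &&
      !inherits(cs[[1]], "geometric_constraint")) {
    cs <- cs[[1]]
  }
  ok <- vapply(cs, inherits, logical(1), "geometric_constraint")
  if (!all(ok)) stop("all elements must be geometric_constraint objects",
                     call. = FALSE)
  structure(cs, class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set: %d constraints (%s)>\n", length(x),
              paste(vapply(unclass(x), `[[`, "", "kind"), collapse = ", ")))
  invisible(x)
}

#' @export
`[.constraint_set` <- function(x, i) {
  constraint_set(unclass(x)[i])
}

check_indices <- function(constraint, conf) {
  if (any(constraint$atoms > conf$n_atoms)) {
    stop(sprintf("constraint references atom %d but conformation has %d atoms",
                 max(constraint$atoms), conf$n_atoms), call. = FALSE)
  }
}

measured_value <- function(constraint, conf) {
  a <- constraint$atoms
  switch(constraint$kind,
    distance = {
      r <- measure_distance(conf, a[1L], a[2L])
      if (r < .degenerate_tol) {
        stop("degenerate geometry: coincident atoms in distance constraint",
             call. = FALSE)
      }
      r
    },
    angle    = measure_angle(conf, a[1L], a[2L], a[3L]),
    dihedral = measure_torsion(conf, a[1L], a[2L], a[3L], a[4L]),
    stop("unknown constraint kind: ", constraint$kind, call. = FALSE)
  )
}

linear_residual <- function(constraint, conf, target = constraint$target) {
  v <- measured_value(constraint, conf)
  if (constraint$kind == "distance") v - target else wrap_angle(v - target)
}

#' Evaluate a constraint residual
#'
#' Residual of a single constraint at a conformation: `value - target` for
#' distances (angstrom), shortest-arc difference in `(-180, 180]` for angles
#' and torsions (degrees). For `form = "squared"` the square of that.
#'
#' @param constraint a [distance_constraint()], [angle_constraint()] or
#'   [dihedral_constraint()].
#' @param conf a [conformation()].
#' @param target override the constraint's target (used internally when a
#'   schedule substitutes the violated bound).
#' @return a single numeric residual (zero when satisfied).
#' @examples
#' conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
#' evaluate_constraint(distance_constraint(1, 2, 1.0), conf) # 1.0
#' @export
evaluate_constraint <- function(constraint, conf, target = constraint$target) {
  conf <- as_conformation(conf)
  check_indices(constraint, conf)
  r <- linear_residual(constraint, conf, target)
  if (constraint$form == "squared") r^2 else r
}

#' Analytic constraint gradient
#'
#' Gradient of the residual with respect to the flattened coordinates,
#' length `3N`. Entries are zero for atoms outside the constraint; the
#' per-atom blocks sum to the zero vector (translation invariance).
#'
#' @inheritParams evaluate_constraint
#' @return numeric vector of length `3N`.
#' @export
constraint_gradient <- function(constraint, conf,
                                target = constraint$target) {
  conf <- as_conformation(conf)
  check_indices(constraint, conf)
  x <- conf$coordinates
  a <- constraint$atoms
  blocks <- switch(constraint$kind,
    distance = grad_distance(x, a[1L], a[2L]),
    angle    = grad_angle(x, a[1L], a[2L], a[3L]),
    dihedral = grad_torsion(x, a[1L], a[2L], a[3L], a[4L])
  )
  g <- numeric(3L * conf$n_atoms)
  for (m in seq_along(a)) {
    idx <- (a[m] - 1L) * 3L + 1:3
    g[idx] <- blocks[[m]]
  }
  if (constraint$form == "squared") {
    g <- 2 * linear_residual(constraint, conf, target) * g
  }
  g
}

#' Stacked constraint Jacobian and residual vector
#'
#' Row `a` of the Jacobian is the gradient of constraint `a`; entry `a` of
#' the residual vector is its residual. This `A x 3N` matrix is the
#' `D_x Sigma` whose rank determines whether the feasible set is a manifold
#' of codimension `A`.
#'
#' @param set a [constraint_set()].
#' @param conf a [conformation()].
#' @param targets optional numeric vector of per-constraint target
#'   overrides.
#' @return list with `jacobian` (`A x 3N`), `residual` (length `A`).
#' @export
constraint_jacobian <- function(set, conf, targets = NULL) {
  conf <- as_conformation(conf)
  A <- length(set)
  J <- matrix(0, nrow = A, ncol = 3L * conf$n_atoms)
  r <- numeric(A)
  for (a in seq_len(A)) {
    tgt <- if (is.null(targets)) set[[a]]$target else targets[a]
    res <- tryCatch({
      r[a] <- evaluate_constraint(set[[a]], conf, target = tgt)
      J[a, ] <- constraint_gradient(set[[a]], conf, target = tgt)
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      stop(sprintf("constraint %d: %s", a, conditionMessage(res)),
           call. = FALSE)
    }
  }
  list(jacobian = J, residual = r)
}

#' Rank diagnostic of the constraint Jacobian
#'
#' Full rank `A` of the Jacobian at a feasible point guarantees (locally)
#' that the feasible set is a smooth manifold of dimension `3N - A` and that
#' the multiplier system is solvable; rank loss signals redundant or
#' degenerate constraints.
#'
#' @inheritParams constraint_jacobian
#' @param tol singular values below `tol * max(singular value)` count as
#'   zero (default `1e-8`).
#' @return a `rank_report`: list with `rank`, `singular_values` (descending),
#'   `condition_estimate`, and `full_rank`.
#' @export
rank_diagnostic <- function(set, conf, tol = 1e-8) {
  jac <- constraint_jacobian(set, conf)
  J <- jac$jacobian
  A <- nrow(J)
  if (A == 0L) {
    return(structure(list(rank = 0L, singular_values = numeric(0),
                          condition_estimate = 1, full_rank = TRUE),
                     class = "rank_report"))
  }
  sv <- svd(J, nu = 0, nv = 0)$d
  rk <- sum(sv > tol * sv[1L])
  structure(
    list(rank = as.integer(rk), singular_values = sv,
         condition_estimate = sv[1L] / max(sv[A], .Machine$double.xmin),
         full_rank = rk == A),
    class = "rank_report"
  )
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("<rank_report: rank %d, full_rank %s, cond %.3g>\n",
              x$rank, x$full_rank, x$condition_estimate))
  invisible(x)
}
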