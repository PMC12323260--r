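#' Solve the Lagrange-multiplier Gram system
#'
#' Given the stacked constraint Jacobian `J` and residual vector `sigma`,
#' solves `(G + regularization * I) lambda = -sigma`, where
#' `G = J J^T` is the Gram matrix of pairwise gradient dot products. All
#' constraints are coupled through `G` and corrected simultaneously, unlike
#' Gauss-Seidel SHAKE variants that sweep one constraint at a time.
#'
#' @param jacobian `A x 3N` constraint Jacobian.
#' @param residual length-`A` residual vector.
#' @param regularization Tikhonov ridge added to the Gram diagonal
#'   (default 0; the projection adds `1e-10 * tr(G)/A` automatically when
#'   plain Cholesky fails).
#' @return numeric vector of `A` multipliers `lambda`.
#' @examples
#' conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
#' set <- constraint_set(distance_constraint(1, 2, 1.0))
#' jac <- constraint_jacobian(set, conf)
#' solve_multipliers(jac$jacobian, jac$residual) # -sigma / |grad sigma|^2
#' @export
solve_multipliers <- function(jacobian, residual, regularization = 0) {
  A <- nrow(jacobian)
  if (A == 0L) return(numeric(0))
  G <- tcrossprod(jacobian)
  if (regularization > 0) G <- G + diag(regularization, A)
  lam <- tryCatch(
    drop(chol2inv(chol(G)) %*% (-residual)),
    error = function(e) NULL
  )
  if (is.null(lam)) {
    # Tikhonov rescue; if that still fails the Jacobian is rank deficient
    eps <- 1e-10 * sum(diag(G)) / A
    lam <- tryCatch(
      drop(solve(G + diag(eps + regularization, A), -residual)),
      error = function(e) NULL
    )
    if (is.null(lam)) {
      cond <- structure(
        class = c("shakediff_rank_error", "error", "condition"),
        list(message = "Gram matrix numerically singular: constraint gradients are linearly dependent",
             call = sys.call(-1))
      )
      stop(cond)
    }
  }
  lam
}

#' SHAKE projection onto the constraint manifold
#'
#' Iteratively corrects a trial conformation until every constraint residual
#' is within tolerance: at each iteration the residuals and Jacobian are
#' evaluated at the current iterate, the coupled multiplier system
#' `G lambda = -sigma` is solved, and every atom is moved by
#' `-sum_a lambda_a grad_a`. For the linear residual form this is a
#' Gauss-Newton step onto the manifold, typically converging in a handful
#' of iterations.
#'
#' @param trial a [conformation()] (the unconstrained trial step).
#' @param set a nonempty [constraint_set()].
#' @param tol convergence tolerance on the maximum absolute residual
#'   (default 0.003; angstrom for distances, degrees times
#'   `angular_weight` for angles/torsions).
#' @param max_iter maximum SHAKE iterations (default 100).
#' @param targets optional per-constraint target overrides (used by the
#'   scheduled active-set machinery).
#' @param on_failure `"error"` (default) or `"warn"`: what to do if the
#'   tolerance is not met after `max_iter` iterations.
#' @param frozen_jacobian if `TRUE`, the Jacobian is evaluated once at the
#'   trial point and reused (classic SHAKE linearization); default `FALSE`
#'   re-evaluates every iteration.
#' @param angular_weight factor converting degrees to the tolerance scale
#'   (default 0.01, i.e. 1 degree counts like 0.01 angstrom).
#' @return a `projection_result`: list with `conformation`,
#'   `iterations_used`, `final_max_residual`, `converged`,
#'   `correction_norm` (Euclidean norm of the total coordinate change) and
#'   `multipliers` (from the last iteration).
#' @examples
#' conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
#' set <- constraint_set(distance_constraint(1, 2, 1.0))
#' res <- shake_project(conf, set)
#' res$conformation$coordinates # atoms moved symmetrically to distance 1
#' @export
shake_project <- function(trial, set, tol = 0.003, max_iter = 100L,
                          targets = NULL,
                          on_failure = c("error", "warn"),
                          frozen_jacobian = FALSE,
                          angular_weight = 0.01) {
  on_failure <- match.arg(on_failure)
  trial <- as_conformation(trial)
  if (length(set) == 0L) {
    return(structure(
      list(conformation = trial, iterations_used = 0L,
           final_max_residual = 0, converged = TRUE,
           correction_norm = 0, multipliers = numeric(0)),
      class = "projection_result"))
  }
  w <- vapply(unclass(set), function(cst)
    if (cst$kind == "distance") 1 else angular_weight, numeric(1))
  x0 <- conf_to_vector(trial)
  x <- x0
  conf <- trial
  jac <- constraint_jacobian(set, conf, targets = targets)
  J <- jac$jacobian
  lam <- numeric(length(set))
  iter <- 0L
  max_res <- max(abs(jac$residual * w))
  while (max_res > tol && iter < max_iter) {
    lam <- solve_multipliers(J, jac$residual)
    # multipliers solve G lambda = -sigma; the descent correction along the
    # constraint gradients is +J^T lambda (a Gauss-Newton step onto the
    # manifold: dx = -J^T (J J^T)^{-1} sigma)
    dx <- drop(crossprod(J, lam))
    step <- 1
    repeat {                       # backtrack if the full step overshoots
      x_new <- x + step * dx
      conf_new <- vector_to_conf(x_new, template = trial)
      jac_new <- tryCatch(
        constraint_jacobian(set, conf_new, targets = targets),
        error = function(e) NULL)
      res_new <- if (is.null(jac_new)) Inf
                 else max(abs(jac_new$residual * w))
      if (res_new < max_res || step < 1 / 64) break
      step <- step / 2
    }
    x <- x_new
    conf <- conf_new
    jac <- jac_new
    iter <- iter + 1L
    if (!frozen_jacobian) J <- jac$jacobian
    max_res <- res_new
  }
  converged <- max_res <= tol
  if (!converged) {
    msg <- sprintf(
      "SHAKE projection did not converge in %d iterations (max residual %.3g > tol %.3g)",
      max_iter, max_res, tol)
    if (on_failure == "error") stop(msg, call. = FALSE) else warning(msg,
                                                            call. = FALSE)
  }
  structure(
    list(conformation = conf, iterations_used = iter,
         final_max_residual = max_res, converged = converged,
         correction_norm = sqrt(sum((x - x0)^2)), multipliers = lam),
    class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "<projection_result: %s in %d iter, max residual %.3g, |dx| %.3g>\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations_used, x$final_max_residual, x$correction_norm))
  invisible(x)
}

#' Project a noise increment onto the constraint tangent space
#'
#' Applies `P = I - J^T (J J^T)^(-1) J` to a noise vector, removing its
#' component along every constraint gradient so the stochastic step stays
#' (infinitesimally) on the constraint manifold. With a single constraint
#' this reduces to `I - grad grad^T / |grad|^2`.
#'
#' @param noise numeric vector of length `3N`.
#' @param set a [constraint_set()].
#' @param conf the [conformation()] at which the tangent space is taken.
#' @param targets optional per-constraint target overrides.
#' @return the projected noise vector (length `3N`), orthogonal to every
#'   constraint gradient.
#' @export
project_noise <- function(noise, set, conf, targets = NULL) {
  if (length(set) == 0L) return(noise)
  jac <- constraint_jacobian(set, conf, targets = targets)
  J <- jac$jacobian
  G <- tcrossprod(J)
  coef <- tryCatch(solve(G, J %*% noise), error = function(e) NULL)
  if (is.null(coef)) {
    cond <- structure(
      class = c("shakediff_rank_error", "error", "condition"),
      list(message = "rank-deficient Jacobian in noise projection",
           call = sys.call()))
    stop(cond)
  }
  drop(noise - crossprod(J, coef))
}

#' Norm of a coordinate correction
#'
#' Euclidean norm of the flattened coordinate difference between two
#' conformations -- the magnitude of a projection or guidance perturbation.
#'
#' @param before,after [conformation()] objects with the same atom count.
#' @return nonnegative numeric scalar.
#' @export
correction_norm <- function(before, after) {
  before <- as_conformation(before)
  after <- as_conformation(after)
  if (before$n_atoms != after$n_atoms) {
    stop("conformations have different atom counts", call. = FALSE)
  }
  sqrt(sum((after$coordinates - before$coordinates)^2))
}
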