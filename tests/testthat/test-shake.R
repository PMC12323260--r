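test_that("multiplier solve matches closed forms", {
  fx <- chain_bond_fixture(3)
  conf <- conformation(fx$conf$coordinates * 1.2)   # stretch all bonds
  jac <- constraint_jacobian(fx$set, conf)
  # feasible point: zero residual -> zero multipliers
  jac0 <- constraint_jacobian(fx$set, fx$conf)
  expect_equal(solve_multipliers(jac0$jacobian, jac0$residual),
               c(0, 0))
  # single constraint: lambda = -sigma / |grad|^2
  one <- constraint_jacobian(fx$set[1], conf)
  lam <- solve_multipliers(one$jacobian, one$residual)
  expect_equal(lam, -one$residual / sum(one$jacobian^2))
  # orthogonal-gradient constraints decouple into per-constraint solves
  sq <- conformation(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0)))
  set <- constraint_set(distance_constraint(1, 2, 1.5),
                        distance_constraint(2, 3, 1.0))
  j2 <- constraint_jacobian(set, sq)
  G <- tcrossprod(j2$jacobian)
  expect_lt(abs(G[1, 2]), 1e-12)   # gradients orthogonal by construction
  lam2 <- solve_multipliers(j2$jacobian, j2$residual)
  expect_equal(lam2,
               -j2$residual / rowSums(j2$jacobian^2), tolerance = 1e-12)
})

test_that("singular but consistent Gram systems are rescued by the ridge", {
  conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
  dup <- constraint_set(distance_constraint(1, 2, 1),
                        distance_constraint(1, 2, 1))
  jac <- constraint_jacobian(dup, conf)
  # exactly singular Gram (identical rows), but the residuals agree, so
  # the Tikhonov rescue yields a usable multiplier vector and the
  # projection still converges to the constraint
  lam <- solve_multipliers(jac$jacobian, jac$residual)
  expect_true(all(is.finite(lam)))
  pr <- shake_project(conf, dup, tol = 1e-8)
  expect_true(pr$converged)
  expect_equal(measure_distance(pr$conformation, 1, 2), 1,
               tolerance = 1e-7)
})

test_that("single-constraint projection matches the analytic answer", {
  conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
  set <- constraint_set(distance_constraint(1, 2, 1.0))
  res <- shake_project(conf, set, tol = 1e-8)
  # both atoms displace 0.5 toward each other along the axis
  expect_equal(res$conformation$coordinates,
               rbind(c(0, 0, 0.5), c(0, 0, 1.5)), tolerance = 1e-6)
  expect_true(res$converged)
  expect_equal(res$correction_norm, sqrt(0.5^2 * 2), tolerance = 1e-6)
  # generic random starts: converged point is the nearest point on the
  # interatomic axis (closed-form oracle)
  set.seed(4)
  for (rep_ in 1:10) {
    x <- matrix(rnorm(6, sd = 2), 2, 3)
    if (sqrt(sum((x[1, ] - x[2, ])^2)) < 0.2) next
    pr <- shake_project(conformation(x), set, tol = 1e-9,
                        max_iter = 200)
    mid <- colMeans(x)
    u <- (x[2, ] - x[1, ]) / sqrt(sum((x[2, ] - x[1, ])^2))
    oracle <- rbind(mid - u / 2, mid + u / 2)
    expect_equal(pr$conformation$coordinates, oracle, tolerance = 1e-6)
  }
})

test_that("projection is idempotent and a no-op on feasible input", {
  fx <- chain_bond_fixture()
  res0 <- shake_project(fx$conf, fx$set)
  expect_identical(res0$conformation$coordinates, fx$conf$coordinates)
  expect_equal(res0$iterations_used, 0L)
  expect_equal(res0$multipliers, rep(0, 5))
  set.seed(9)
  trial <- conformation(fx$conf$coordinates + matrix(rnorm(18, 0, 0.5),
                                                     6, 3))
  p1 <- shake_project(trial, fx$set, tol = 0.003)
  p2 <- shake_project(p1$conformation, fx$set, tol = 0.003)
  expect_lt(correction_norm(p1$conformation, p2$conformation), 0.003 / 10)
})

test_that("projection reaches tolerance from randomized trials", {
  fx <- chain_bond_fixture()
  sub <- fx$set[c(1, 3, 5)]                 # 3 distance constraints
  set.seed(20)
  for (rep_ in 1:200) {
    trial <- conformation(fx$conf$coordinates +
                            matrix(rnorm(18, 0, 0.6), 6, 3))
    pr <- shake_project(trial, sub, tol = 0.003, on_failure = "warn")
    expect_true(pr$converged)
    expect_lte(pr$final_max_residual, 0.003)
    # default tolerance honors the documented acceptance value
    expect_lte(shake_project(trial, sub)$final_max_residual, 0.003)
  }
})

test_that("SHAKE corrections lie in the row space of the Jacobian", {
  fx <- chain_bond_fixture()
  set.seed(13)
  for (rep_ in 1:20) {
    trial <- conformation(fx$conf$coordinates +
                            matrix(rnorm(18, 0, 0.4), 6, 3))
    jac <- constraint_jacobian(fx$set, trial)
    lam <- solve_multipliers(jac$jacobian, jac$residual)
    dx <- drop(crossprod(jac$jacobian, lam))
    # dx is by construction in the row space; verify via least squares
    fit <- qr.solve(t(jac$jacobian), dx)
    expect_lt(sqrt(sum((drop(t(jac$jacobian) %*% fit) - dx)^2)), 1e-8)
    # one-iteration correction norm equals |sum lambda_a grad_a|
    # (a single iteration cannot converge; the warning is expected)
    pr <- suppressWarnings(shake_project(trial, fx$set, max_iter = 1,
                                         tol = 1e-12,
                                         on_failure = "warn"))
    expect_equal(pr$correction_norm, sqrt(sum(dx^2)), tolerance = 1e-10)
  }
})

test_that("projection commutes with global rotation and translation", {
  fx <- chain_bond_fixture()
  mixed <- constraint_set(distance_constraint(1, 2, 1.5),
                          angle_constraint(2, 3, 4, 108),
                          dihedral_constraint(1, 2, 3, 4, 165),
                          distance_constraint(4, 6, 2.4))
  set.seed(41)
  for (rep_ in 1:5) {
    trial <- conformation(fx$conf$coordinates +
                            matrix(rnorm(18, 0, 0.2), 6, 3))
    R <- random_rotation()
    tr <- rnorm(3)
    p_then_move <- transform_conf(
      shake_project(trial, mixed, tol = 1e-9)$conformation, R, tr)
    move_then_p <- shake_project(transform_conf(trial, R, tr), mixed,
                                 tol = 1e-9)$conformation
    expect_equal(move_then_p$coordinates, p_then_move$coordinates,
                 tolerance = 1e-7)
  }
})

test_that("non-convergence raises or warns per policy", {
  conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
  set <- constraint_set(distance_constraint(1, 2, 1.0))
  expect_error(shake_project(conf, set, max_iter = 0L), "converge")
  expect_warning(shake_project(conf, set, max_iter = 0L,
                               on_failure = "warn"), "converge")
})

test_that("noise projection removes all gradient components", {
  fx <- chain_bond_fixture()
  sub <- fx$set[c(1, 3, 5)]
  jac <- constraint_jacobian(sub, fx$conf)
  set.seed(3)
  noise <- rnorm(18)
  pn <- project_noise(noise, sub, fx$conf)
  expect_lt(max(abs(jac$jacobian %*% pn)), 1e-10)
  # idempotence: P^2 = P
  expect_lt(max(abs(project_noise(pn, sub, fx$conf) - pn)), 1e-10)
  # single constraint: noise parallel to the gradient is annihilated
  one <- fx$set[1]
  g <- constraint_jacobian(one, fx$conf)$jacobian[1, ]
  expect_lt(max(abs(project_noise(3 * g, one, fx$conf))), 1e-10)
  # A = 3: matches sequential Gram-Schmidt removal of gradient directions
  Q <- qr.Q(qr(t(jac$jacobian)))
  gs <- noise
  for (q in seq_len(ncol(Q))) gs <- gs - sum(gs * Q[, q]) * Q[, q]
  expect_lt(max(abs(pn - gs)), 1e-10)
  # rank-deficient Jacobian errors
  dup <- constraint_set(fx$set[[1]], fx$set[[1]])
  expect_error(project_noise(noise, dup, fx$conf),
               class = "shakediff_rank_error")
})

test_that("correction norm is the Euclidean coordinate displacement", {
  a <- conformation(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(correction_norm(a, a), 0)
  b <- conformation(rbind(c(3, 4, 0), c(1, 1, 1)))
  expect_equal(correction_norm(a, b), 5)
  expect_error(correction_norm(a, chain_bond_fixture(3)$conf), "atom")
})
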