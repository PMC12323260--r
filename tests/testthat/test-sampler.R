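test_that("gaussian mixture score matches analytic and numeric forms", {
  # single component: score is -(x - mu)/v
  sm <- gaussian_mixture_score(c(1, -2, 0.5), base_variance = 2)
  x <- c(0.3, 0.1, -1)
  expect_equal(sm$fn(x, v_add = 1), -(x - c(1, -2, 0.5)) / 3)
  # two equal components: zero score at the midpoint by symmetry
  two <- gaussian_mixture_score(rbind(c(1, 0), c(-1, 0)),
                                base_variance = 0.5)
  expect_equal(two$fn(c(0, 0), v_add = 0.2), c(0, 0))
  # random mixture: matches the numeric gradient of the log density
  set.seed(8)
  mus <- matrix(rnorm(6), 2, 3)
  w <- c(0.3, 0.7)
  gm <- gaussian_mixture_score(mus, weights = w, base_variance = 0.8)
  logp <- function(x, v) {
    log(sum(w * exp(-colSums((t(mus) - x)^2) / (2 * v))) /
          (2 * pi * v)^(3 / 2))
  }
  for (rep_ in 1:5) {
    x <- rnorm(3, sd = 2)
    v_add <- 0.5
    num <- numeric(3)
    h <- 1e-5
    for (q in 1:3) {
      xp <- x; xm <- x
      xp[q] <- xp[q] + h; xm[q] <- xm[q] - h
      num[q] <- (logp(xp, 1.3) - logp(xm, 1.3)) / (2 * h)
    }
    expect_lt(max(abs(gm$fn(x, v_add = v_add) - num)), 1e-6)
  }
  expect_error(gaussian_mixture_score(matrix(0, 0, 3)), "at least one")
})

test_that("toy Boltzmann score is -grad U / T with annealing and clipping", {
  U <- function(x) 0.5 * sum(x^2)
  gU <- function(x) x
  sm <- toy_boltzmann_score(U, gU, temperature = 2, dim = 3L)
  x <- c(1, -1, 2)
  expect_equal(sm$fn(x, v_add = 0), -x / 2)
  expect_equal(sm$fn(x, v_add = 3), -x / 5)     # annealed temperature
  flat <- toy_boltzmann_score(function(x) 0, function(x) 0 * x,
                              dim = 3L)
  expect_equal(flat$fn(x), c(0, 0, 0))          # zero force: pure Brownian
  # finite-difference fallback agrees with the analytic gradient
  fd <- toy_boltzmann_score(U, temperature = 2, dim = 3L)
  expect_equal(fd$fn(x), sm$fn(x), tolerance = 1e-5)
  # trust-region cap limits the norm
  capped <- toy_boltzmann_score(U, gU, temperature = 1e-4, max_norm = 10,
                                dim = 3L)
  expect_equal(sqrt(sum(capped$fn(x)^2)), 10, tolerance = 1e-12)
})

test_that("sampling is deterministic given a seed", {
  fx <- chain_bond_fixture(4)
  sm <- gaussian_mixture_score(list(fx$conf), base_variance = 0.05)
  cfg <- sampler_config(n_steps = 60, method = "shake", batch_size = 2,
                        seed = 99)
  a <- sample_diffusion(sm, fx$set, cfg, template = fx$conf)
  b <- sample_diffusion(sm, fx$set, cfg, template = fx$conf)
  expect_identical(lapply(a$samples, `[[`, "coordinates"),
                   lapply(b$samples, `[[`, "coordinates"))
  expect_identical(a$trajectory, b$trajectory)
})

test_that("empty constraint sets make shake, guidance and none coincide", {
  sm <- gaussian_mixture_score(rep(0, 9), base_variance = 0.3)
  empty <- constraint_set()
  runs <- lapply(c("shake", "guidance", "none"), function(m) {
    sample_diffusion(sm, empty,
                     sampler_config(n_steps = 80, method = m,
                                    batch_size = 2, seed = 5,
                                    project_noise = FALSE))
  })
  expect_identical(lapply(runs[[1]]$samples, `[[`, "coordinates"),
                   lapply(runs[[3]]$samples, `[[`, "coordinates"))
  expect_identical(lapply(runs[[2]]$samples, `[[`, "coordinates"),
                   lapply(runs[[3]]$samples, `[[`, "coordinates"))
})

test_that("constrained sampling keeps every step within tolerance", {
  fx <- chain_bond_fixture(4)
  sm <- gaussian_mixture_score(list(fx$conf), base_variance = 0.05)
  for (ns in c("ve", "vp")) {
    out <- sample_diffusion(
      sm, fx$set,
      sampler_config(n_steps = 150, method = "shake", batch_size = 3,
                     seed = 21, noise_schedule = ns),
      template = fx$conf)
    expect_lte(max(out$trajectory$max_residual), 0.003)
    expect_equal(nrow(out$trajectory), 150)
    # final samples satisfy the constraints
    for (s in out$samples) {
      res <- vapply(seq_along(fx$set), function(a)
        abs(evaluate_constraint(fx$set[[a]], s)), numeric(1))
      expect_lte(max(res), 0.003)
    }
  }
})

test_that("harmonic well sampled at constant temperature matches the OU law", {
  # U = x^2/2 (k = 1) at temperature T: stationary variance T/k; the
  # annealed temperature tracks the forward-noise variance, which for
  # unit curvature reproduces the exact noised score
  Tval <- 0.7
  sm <- toy_boltzmann_score(function(x) 0.5 * sum(x^2), function(x) x,
                            temperature = Tval, dim = 1L)
  out <- sample_diffusion(sm, constraint_set(),
                          sampler_config(n_steps = 600, method = "none",
                                         batch_size = 1500, seed = 14))
  xs <- unlist(out$samples)
  expect_lt(abs(var(xs) - Tval) / Tval, 0.05)
  # lowering the temperature concentrates the samples
  cold <- toy_boltzmann_score(function(x) 0.5 * sum(x^2),
                              function(x) x,
                              temperature = Tval / 2, dim = 1L)
  out2 <- sample_diffusion(cold, constraint_set(),
                           sampler_config(n_steps = 600, method = "none",
                                          batch_size = 1500, seed = 14))
  expect_lt(var(unlist(out2$samples)), var(xs))
})

test_that("1d particle demo tracks moving and fixed constraints", {
  fixed <- demo_particle_1d(n_steps = 400, seed = 2)
  expect_equal(max(fixed$residual), 0)
  expect_true(all(fixed$x[fixed$upper == 0 & fixed$lower == 0] == 0))
  moving <- demo_particle_1d(n_steps = 400,
                             target_fn = function(tau) sin(2 * pi * tau),
                             seed = 2)
  expect_equal(moving$x, sin(2 * pi * moving$tau), tolerance = 1e-12)
  # interval wider than the walk support: identical to the free walk
  wide <- demo_particle_1d(
    n_steps = 400,
    schedule = bound_schedule(lower_initial = -1e3, upper_initial = 1e3,
                              lower_final = -1e3, upper_final = 1e3),
    seed = 7)
  set.seed(7)
  free <- cumsum(rnorm(400, 0, 0.1))
  expect_equal(wide$x, free, tolerance = 1e-12)
})

test_that("2d density demo confines samples to the final disk", {
  res <- demo_density_2d(n_samples = 150, n_steps = 150, seed = 4)
  expect_equal(res$feasible_fraction, 1)
  r <- sqrt(rowSums(res$samples^2))
  expect_lte(max(r), 1 + res$tol)
  # guidance variant leaves violations under the same budget
  gres <- demo_density_2d(n_samples = 150, n_steps = 150, seed = 4,
                          method = "guidance")
  expect_lt(gres$feasible_fraction, 1)
  # unconstrained variant reproduces the prior within MC error
  free <- demo_density_2d(n_samples = 2000, n_steps = 300, seed = 9,
                          method = "none")
  expect_lt(max(abs(colMeans(free$samples))), 0.1)
  expect_lt(abs(var(free$samples[, 1]) - 1), 0.15)
})

test_that("sampler configuration validates its inputs", {
  expect_error(sampler_config(n_steps = 0), "at least 1")
  expect_error(sampler_config(tol = 0), "positive")
  sm <- gaussian_mixture_score(rep(0, 3))
  expect_error(sample_diffusion(list(), constraint_set()), "score_model")
})
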