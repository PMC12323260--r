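#' Analytic toy score models
#'
#' Score-based samplers need the score `grad log p_t(x)` of the noised data
#' distribution. In place of a trained network the package provides two
#' analytic stand-ins.
#'
#' `gaussian_mixture_score()` is exact: for an isotropic Gaussian mixture
#' prior with component means `mu_k` and variance `base_variance`, the
#' forward process at time `t` (mean scale `m(t)`, added noise variance
#' `v(t)`) keeps the mixture Gaussian, so the score is the
#' responsibility-weighted sum of per-component Gaussian scores
#' `-(x - m mu_k) / (m^2 base_variance + v)`.
#'
#' `toy_boltzmann_score()` is an annealed approximation:
#' `score(x, t) = -grad U(x) / T_eff(t)` with
#' `T_eff(t) = temperature + v(t)` by default, so the effective temperature
#' tracks the forward-noise variance (exact for a unit-curvature harmonic
#' well, a controlled approximation otherwise). It enables energy-based
#' chain experiments without a trained network and is documented as an
#' approximation, not an exact noised score.
#'
#' @param means numeric `K x d` matrix of component means (rows), a single
#'   numeric vector, or a list of [conformation()]s (flattened).
#' @param weights positive component weights summing to 1 (default
#'   uniform).
#' @param base_variance isotropic variance of each component at `t = 0`.
#' @return an object of class `score_model`: list with `fn(x, v_add,
#'   mean_scale, tau)` returning the score vector, and `dim`.
#' @examples
#' sm <- gaussian_mixture_score(rep(0, 3), base_variance = 1)
#' sm$fn(c(1, 0, 0), v_add = 0, mean_scale = 1, tau = 1) # -(x - 0)/1
#' @export
gaussian_mixture_score <- function(means, weights = NULL, base_variance = 1) {
  if (is.list(means)) {
    means <- do.call(rbind, lapply(means, conf_to_vector))
  }
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  K <- nrow(means)
  if (K == 0L) stop("mixture must have at least one component", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  weights <- weights / sum(weights)
  if (base_variance <= 0) stop("base_variance must be positive",
                               call. = FALSE)
  d <- ncol(means)
  fn <- function(x, v_add = 0, mean_scale = 1, tau = NULL) {
    v <- mean_scale^2 * base_variance + v_add
    mu <- mean_scale * means
    lw <- log(weights) - colSums((t(mu) - x)^2) / (2 * v)
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
    (colSums(mu * w) - x) / v
  }
  structure(list(fn = fn, dim = d, kind = "gaussian_mixture",
                 means = means, weights = weights,
                 base_variance = base_variance),
            class = "score_model")
}

#' @rdname gaussian_mixture_score
#' @param energy_fn function of a flattened coordinate vector returning the
#'   energy (or of a [conformation()] if `vectorized = FALSE`).
#' @param gradient_fn optional analytic gradient of `energy_fn`; central
#'   finite differences (`h = 1e-6`) are used when absent.
#' @param temperature base temperature `k_B T` in energy units (default 1).
#' @param anneal if `TRUE` (default) add the forward-noise variance to the
#'   temperature.
#' @param max_norm trust-region cap on the score norm (default 100): steep
#'   repulsive walls (e.g. a Lennard-Jones core hit by a noisy trial point)
#'   otherwise produce unbounded scores that destabilize the
#'   Euler-Maruyama step. Near equilibrium the cap is inactive.
#' @param dim state dimension `3N` (required for `toy_boltzmann_score`).
#' @export
toy_boltzmann_score <- function(energy_fn, gradient_fn = NULL,
                                temperature = 1, anneal = TRUE,
                                max_norm = 100, dim) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.null(gradient_fn)) {
    gradient_fn <- function(x) {
      h <- 1e-6
      g <- numeric(length(x))
      for (q in seq_along(x)) {
        xp <- x; xm <- x
        xp[q] <- xp[q] + h; xm[q] <- xm[q] - h
        g[q] <- (energy_fn(xp) - energy_fn(xm)) / (2 * h)
      }
      g
    }
  }
  fn <- function(x, v_add = 0, mean_scale = 1, tau = NULL) {
    Teff <- if (anneal) temperature + v_add else temperature
    g <- -gradient_fn(x) / Teff
    if (!all(is.finite(g))) stop("non-finite energy gradient", call. = FALSE)
    nrm <- sqrt(sum(g^2))
    if (nrm > max_norm) g <- g * max_norm / nrm
    g
  }
  structure(list(fn = fn, dim = dim, kind = "boltzmann",
                 temperature = temperature, anneal = anneal),
            class = "score_model")
}

#' Sampler configuration
#'
#' @param n_steps number of reverse-SDE Euler-Maruyama steps.
#' @param method constraint handling: `"shake"` (exact projection),
#'   `"guidance"` (harmonic baseline) or `"none"`.
#' @param noise_schedule `"ve"` (variance exploding, default) or `"vp"`
#'   (variance preserving).
#' @param sigma_min,sigma_max VE noise scales (defaults 0.01, 5).
#' @param beta_min,beta_max VP linear beta endpoints (defaults 0.1, 20).
#' @param tol SHAKE constraint-violation acceptance (default 0.003).
#' @param seed integer seed; identical seeds give bit-identical runs.
#' @param batch_size number of independent trajectories.
#' @param project_noise project each noise increment onto the constraint
#'   tangent space before stepping; default `TRUE` for SHAKE, `FALSE`
#'   otherwise.
#' @param guidance a [guidance_params()] (used when `method = "guidance"`).
#' @param max_iter,on_failure SHAKE iteration cap and non-convergence
#'   policy (see [shake_project()]); the sampler defaults to
#'   `"warn"` so a hard step during the schedule ramp-in does not abort a
#'   run (final-step feasibility is what the trajectory log certifies).
#' @param horizon diffusion time horizon `T` (default 1).
#' @param keep_trajectory_positions store thinned positions every this many
#'   steps (0 = never).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(n_steps = 1000L,
                           method = c("shake", "guidance", "none"),
                           noise_schedule = c("ve", "vp"),
                           sigma_min = 0.01, sigma_max = 5,
                           beta_min = 0.1, beta_max = 20,
                           tol = 0.003, seed = 1L, batch_size = 1L,
                           project_noise = NULL,
                           guidance = guidance_params(),
                           max_iter = 100L,
                           on_failure = c("warn", "error"),
                           horizon = 1,
                           keep_trajectory_positions = 0L) {
  method <- match.arg(method)
  noise_schedule <- match.arg(noise_schedule)
  if (n_steps < 1L) stop("n_steps must be at least 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (is.null(project_noise)) project_noise <- method == "shake"
  structure(
    list(n_steps = as.integer(n_steps), method = method,
         noise_schedule = noise_schedule,
         sigma_min = sigma_min, sigma_max = sigma_max,
         beta_min = beta_min, beta_max = beta_max,
         tol = tol, seed = as.integer(seed),
         batch_size = as.integer(batch_size),
         project_noise = isTRUE(project_noise), guidance = guidance,
         max_iter = as.integer(max_iter),
         on_failure = match.arg(on_failure), horizon = horizon,
         keep_trajectory_positions = as.integer(keep_trajectory_positions)),
    class = "sampler_config")
}

# noise-schedule helpers: mean scale m(t), added variance v(t), g(t)^2,
# drift f(x,t)
ve_terms <- function(t, config) {
  ratio <- config$sigma_max / config$sigma_min
  sig <- config$sigma_min * ratio^(t / config$horizon)
  list(m = 1, v_add = sig^2, g2 = sig^2 * 2 * log(ratio) / config$horizon,
       drift = function(x) 0)
}

vp_terms <- function(t, config) {
  s <- t / config$horizon
  beta <- config$beta_min + (config$beta_max - config$beta_min) * s
  ib <- (config$beta_min * s + (config$beta_max - config$beta_min) *
           s^2 / 2) * config$horizon
  m <- exp(-ib / 2)
  list(m = m, v_add = 1 - m^2, g2 = beta,
       drift = function(x) -beta / 2 * x)
}

schedule_terms <- function(t, config) {
  if (config$noise_schedule == "ve") ve_terms(t, config)
  else vp_terms(t, config)
}

#' Constrained reverse-diffusion sampling
#'
#' Integrates the reverse SDE
#' `dx = [f(x,t) - g(t)^2 grad log p_t(x)] dt + g(t) dW` from the noise
#' prior back to `t = 0` with Euler-Maruyama, interleaving constraint
#' handling at every step: (1) the deterministic bound state advances
#' (normalized progress `tau` runs 0 to 1 as `t` runs `T` to 0); (2) the
#' noise increment is optionally projected onto the tangent space of the
#' active constraints; (3) the unconstrained trial step is taken; (4) the
#' trial point is SHAKE-projected onto the feasible region at the new
#' `tau` (or nudged by a guidance step, or left alone). The per-step
#' trajectory log of residuals, correction norms and iteration counts is
#' the surface on which the package's feasibility guarantees are checked.
#'
#' @param score a `score_model` (see [gaussian_mixture_score()]).
#' @param set a [constraint_set()] (may be empty).
#' @param config a [sampler_config()].
#' @param template optional [conformation()] supplying atom count and
#'   element labels for the output.
#' @return list with `samples` (list of `batch_size` conformations),
#'   `trajectory` (data frame: `step`, `t`, `tau`, `max_residual`,
#'   `mean_residual`, `shake_norm`, `guidance_norm`, `iterations` --
#'   residuals are violations of the scheduled bounds, aggregated over the
#'   batch), and `config`.
#' @examples
#' sm <- gaussian_mixture_score(rep(0, 6), base_variance = 0.25)
#' cfg <- sampler_config(n_steps = 50, method = "none", batch_size = 2,
#'                       seed = 7)
#' out <- sample_diffusion(sm, constraint_set(), cfg)
#' length(out$samples)
#' @export
sample_diffusion <- function(score, set = constraint_set(),
                             config = sampler_config(), template = NULL) {
  stopifnot(inherits(score, "score_model"))
  d <- score$dim
  if (d %% 3L != 0L && is.null(template)) {
    # non-molecular state (demos); conformation output suppressed
  }
  set.seed(config$seed)
  n <- config$n_steps
  dt <- config$horizon / n
  A <- length(set)
  has_constraints <- A > 0L
  use_template <- !is.null(template)

  # prior draw at t = T
  init <- schedule_terms(config$horizon, config)
  center <- if (score$kind == "gaussian_mixture") {
    colMeans(score$means * init$m)
  } else rep(0, d)
  sd0 <- sqrt(init$m^2 * (if (score$kind == "gaussian_mixture")
    score$base_variance else 1) + init$v_add)

  max_res <- matrix(0, nrow = n, ncol = config$batch_size)
  mean_res <- matrix(0, nrow = n, ncol = config$batch_size)
  shake_nrm <- matrix(0, nrow = n, ncol = config$batch_size)
  guid_nrm <- matrix(0, nrow = n, ncol = config$batch_size)
  iters <- matrix(0L, nrow = n, ncol = config$batch_size)
  samples <- vector("list", config$batch_size)

  to_conf <- function(x) {
    if (d %% 3L == 0L) vector_to_conf(x, template = template)
    else stop("state dimension is not 3N; no conformation view",
              call. = FALSE)
  }

  for (el in seq_len(config$batch_size)) {
    x <- center + stats::rnorm(d, 0, sd0)
    for (stp in seq_len(n)) {
      t_cur <- config$horizon * (n - stp + 1L) / n
      t_new <- config$horizon * (n - stp) / n
      tau_new <- 1 - t_new / config$horizon     # zeta update (closed form)
      tm <- schedule_terms(t_cur, config)
      sc <- score$fn(x, v_add = tm$v_add, mean_scale = tm$m,
                     tau = 1 - t_cur / config$horizon)
      if (!all(is.finite(sc))) stop("score returned non-finite values",
                                    call. = FALSE)
      eta <- stats::rnorm(d)
      if (config$project_noise && has_constraints && d %% 3L == 0L) {
        view <- resolve_active(set, to_conf(x), tau_new)
        if (length(view$active_indices) > 0L) {
          eta <- project_noise(eta, set[view$active_indices], to_conf(x),
                               targets = view$effective_targets)
        }
      }
      x <- x + (-tm$drift(x) + tm$g2 * sc) * dt + sqrt(tm$g2 * dt) * eta
      if (has_constraints && config$method == "shake") {
        pr <- project_scheduled(to_conf(x), set, tau_new, tol = config$tol,
                                max_iter = config$max_iter,
                                on_failure = config$on_failure)
        x <- conf_to_vector(pr$conformation)
        shake_nrm[stp, el] <- pr$correction_norm
        iters[stp, el] <- pr$iterations_used
      } else if (has_constraints && config$method == "guidance") {
        gs <- guidance_step(to_conf(x), set, config$guidance)
        x <- conf_to_vector(gs$conformation)
        guid_nrm[stp, el] <- gs$correction_norm
      }
      if (has_constraints && d %% 3L == 0L) {
        viol <- bound_violation(set, to_conf(x), tau_new)
        max_res[stp, el] <- max(viol)
        mean_res[stp, el] <- mean(viol)
      }
    }
    samples[[el]] <- if (d %% 3L == 0L) to_conf(x) else x
  }

  traj <- data.frame(
    step = seq_len(n),
    t = config$horizon * (n - seq_len(n)) / n,
    tau = 1 - (n - seq_len(n)) / n,
    max_residual = apply(max_res, 1L, max),
    mean_residual = rowMeans(mean_res),
    shake_norm = rowMeans(shake_nrm),
    guidance_norm = rowMeans(guid_nrm),
    iterations = rowMeans(iters)
  )
  list(samples = samples, trajectory = traj, config = config)
}

#' One-dimensional constrained random walk demo
#'
#' A Brownian particle in one dimension subject to a scheduled interval
#' constraint: after each unconstrained increment the position is projected
#' (clamped) onto the feasible interval `[lower(tau), upper(tau)]`, the
#' one-dimensional analogue of the manifold projection. With
#' `target_fn` supplied, the interval degenerates to the moving point
#' `target_fn(tau)` and the walk tracks it exactly.
#'
#' @param n_steps number of steps (default 1000).
#' @param schedule a [bound_schedule()] for the interval (ignored when
#'   `target_fn` is given).
#' @param target_fn optional function of progress `tau` returning a moving
#'   equality target.
#' @param step_sd standard deviation of each Brownian increment.
#' @param seed integer seed.
#' @return data frame: `step`, `tau`, `x` (post-projection), `lower`,
#'   `upper`, `residual` (violation after projection, 0 by construction).
#' @export
demo_particle_1d <- function(n_steps = 1000L,
                             schedule = bound_schedule(lower_final = 0,
                                                       upper_final = 0),
                             target_fn = NULL, step_sd = 0.1, seed = 1L) {
  set.seed(seed)
  x <- 0
  out <- data.frame(step = seq_len(n_steps), tau = seq_len(n_steps) / n_steps,
                    x = NA_real_, lower = NA_real_, upper = NA_real_,
                    residual = NA_real_)
  for (stp in seq_len(n_steps)) {
    tau <- stp / n_steps
    x <- x + stats::rnorm(1L, 0, step_sd)
    if (!is.null(target_fn)) {
      b <- rep(target_fn(tau), 2L)
    } else {
      b <- bounds_at(tau, schedule)
    }
    x <- min(max(x, b[1L]), b[2L])
    out$x[stp] <- x
    out$lower[stp] <- b[1L]
    out$upper[stp] <- b[2L]
    out$residual[stp] <- max(0, x - b[2L], b[1L] - x)
  }
  out
}

#' Two-dimensional constrained density demo
#'
#' Reverse-diffusion samples from a 2D Gaussian whose feasible region is a
#' shrinking disk: a radial bound schedule tightens from unbounded to
#' `radius_final`, and each trial point outside the current disk is
#' projected radially back onto it (the exact nearest-point projection for
#' a single radial distance bound). The guidance variant applies a harmonic
#' radial nudge instead and typically leaves a violation fraction.
#'
#' @param n_samples number of samples (default 500).
#' @param n_steps diffusion steps per sample (default 300).
#' @param radius_final final disk radius (default 1).
#' @param center disk center, length-2 (default origin).
#' @param method `"shake"`, `"guidance"` or `"none"`.
#' @param beta,t0 radial bound schedule parameters.
#' @param guidance a [guidance_params()] for the guidance variant.
#' @param seed integer seed.
#' @return list with `samples` (`n_samples x 2` matrix), `feasible_fraction`
#'   (share of final samples inside the disk within `tol`), and `tol`.
#' @export
demo_density_2d <- function(n_samples = 500L, n_steps = 300L,
                            radius_final = 1, center = c(0, 0),
                            method = c("shake", "guidance", "none"),
                            beta = 10, t0 = 0.5,
                            guidance = guidance_params(), seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  tol <- 0.003
  sch <- bound_schedule(beta = beta, t0 = t0, lower_initial = 0,
                        upper_initial = Inf, lower_final = 0,
                        upper_final = radius_final)
  sigma_min <- 0.01; sigma_max <- 5
  ratio <- sigma_max / sigma_min
  xs <- matrix(stats::rnorm(2L * n_samples, 0, sqrt(1 + sigma_max^2)),
               ncol = 2L, byrow = TRUE)
  dt <- 1 / n_steps
  for (stp in seq_len(n_steps)) {
    t_cur <- (n_steps - stp + 1L) / n_steps
    tau_new <- stp / n_steps
    sig <- sigma_min * ratio^t_cur
    g2 <- sig^2 * 2 * log(ratio)
    v <- 1 + sig^2
    up <- bounds_at(tau_new, sch)[2L]
    for (s in seq_len(n_samples)) {
      x <- xs[s, ]
      x <- x + g2 * (-(x) / v) * dt + sqrt(g2 * dt) * stats::rnorm(2L)
      r <- sqrt(sum((x - center)^2))
      if (is.finite(up) && r > up) {
        if (method == "shake") {
          x <- center + (x - center) * up / r
        } else if (method == "guidance") {
          # harmonic nudge toward the disk boundary
          x <- x - guidance$step_size * guidance$force_constants[1L] *
            (r - up) * (x - center) / r
        }
      }
      xs[s, ] <- x
    }
  }
  r_fin <- sqrt(rowSums((xs - matrix(center, n_samples, 2L,
                                     byrow = TRUE))^2))
  list(samples = xs,
       feasible_fraction = mean(r_fin <= radius_final + tol),
       tol = tol)
}
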