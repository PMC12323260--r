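# shared helpers for the test suite

# central finite-difference gradient of a constraint residual
fd_gradient <- function(cst, conf, h = 1e-6) {
  x0 <- conf_to_vector(conf)
  g <- numeric(length(x0))
  for (q in seq_along(x0)) {
    xp <- x0; xm <- x0
    xp[q] <- xp[q] + h
    xm[q] <- xm[q] - h
    g[q] <- (evaluate_constraint(cst, vector_to_conf(xp)) -
               evaluate_constraint(cst, vector_to_conf(xm))) / (2 * h)
  }
  g
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_conf <- function(conf, R, t = c(0, 0, 0)) {
  conformation(sweep(conf$coordinates %*% t(R), 2, -t),
               elements = conf$elements)
}

# non-degenerate random conformation: chain geometry plus jitter
random_chain_conf <- function(n, seed = NULL, jitter = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  torsions <- if (n >= 4) runif(n - 3, -150, 150) else numeric(0)
  angles <- if (n >= 3) runif(n - 2, 95, 130) else numeric(0)
  ch <- build_chain(runif(n - 1, 1.3, 1.7), angles, torsions)
  conformation(ch$coordinates + matrix(rnorm(3 * n, 0, jitter), n, 3))
}

# 6-atom chain with consecutive-bond distance constraints
chain_bond_fixture <- function(n = 6, bond = 1.5) {
  ch <- build_chain(rep(bond, n - 1), rep(110, n - 2),
                    if (n >= 4) rep(180, n - 3) else numeric(0))
  set <- constraint_set(lapply(seq_len(n - 1), function(b)
    distance_constraint(b, b + 1, bond)))
  list(conf = ch, set = set)
}

# two-mode decane-like chain specs for mining tests
two_mode_specs <- function(n = 6) {
  t_a <- rep(180, n - 3)
  t_b <- rep(180, n - 3)
  t_b[1] <- 60
  if (n >= 5) t_b[length(t_b)] <- -60
  list(
    list(bond_lengths = rep(1.53, n - 1), bond_angles = rep(112.5, n - 2),
         torsions = t_a),
    list(bond_lengths = rep(1.53, n - 1), bond_angles = rep(112.5, n - 2),
         torsions = t_b)
  )
}
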