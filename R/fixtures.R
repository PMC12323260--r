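#' Build a chain from internal coordinates
#'
#' Places `n` atoms from `n - 1` bond lengths (angstrom), `n - 2` bond
#' angles and `n - 3` torsions (degrees) using the standard natural
#' extension reference frame: atom 1 at the origin, atom 2 on +x, atom 3 in
#' the xy-plane (positive y), and each further atom positioned to realize
#' its bond/angle/torsion relative to the three preceding atoms. Measured
#' internals round-trip to the specification to high precision.
#'
#' @param bond_lengths numeric vector of `n - 1` positive bond lengths.
#' @param bond_angles numeric vector of `n - 2` angles in `(0, 180)`
#'   degrees.
#' @param torsions numeric vector of `n - 3` torsions in degrees.
#' @param elements optional element symbols, length `n`.
#' @return a [conformation()] of `n` atoms.
#' @examples
#' # butane carbon skeleton, anti conformation
#' bu <- build_chain(rep(1.53, 3), rep(112.5, 2), 180)
#' measure_distance(bu, 1, 4) # about 3.92
#' @export
build_chain <- function(bond_lengths, bond_angles = numeric(0),
                        torsions = numeric(0), elements = NULL) {
  n <- length(bond_lengths) + 1L
  if (n >= 3L && length(bond_angles) != n - 2L) {
    stop("need n - 2 bond angles", call. = FALSE)
  }
  if (n >= 4L && length(torsions) != n - 3L) {
    stop("need n - 3 torsions", call. = FALSE)
  }
  if (any(bond_lengths <= 0)) stop("bond lengths must be positive",
                                   call. = FALSE)
  if (length(bond_angles) && any(bond_angles <= 0 | bond_angles >= 180)) {
    stop("bond angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  x <- matrix(0, nrow = n, ncol = 3L)
  if (n >= 2L) x[2L, ] <- c(bond_lengths[1L], 0, 0)
  if (n >= 3L) {
    th <- bond_angles[1L] / DEG
    x[3L, ] <- x[2L, ] + bond_lengths[2L] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4L) {
    for (m in 4:n) {
      x[m, ] <- nerf_place(x[m - 3L, ], x[m - 2L, ], x[m - 1L, ],
                           bond_lengths[m - 1L], bond_angles[m - 2L],
                           torsions[m - 3L])
    }
  }
  conformation(x, elements = elements)
}

# place atom D given A, B, C and internal coordinates (bond C-D, angle
# B-C-D, torsion A-B-C-D)
nerf_place <- function(A, B, C, bond, angle, torsion) {
  th <- angle / DEG
  ph <- torsion / DEG
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- C - B
  bc_hat <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc_hat)
  nn <- sqrt(sum(n^2))
  if (nn < .degenerate_tol) {
    stop("degenerate frame: collinear atoms in chain builder", call. = FALSE)
  }
  n_hat <- n / nn
  m_hat <- cross3(n_hat, bc_hat)
  C + d_local[1L] * bc_hat + d_local[2L] * m_hat + d_local[3L] * n_hat
}

#' Toy molecular energy for chain fixtures
#'
#' A minimal classical energy: harmonic bonds `k_r/2 (r - r0)^2`, harmonic
#' angles `k_theta/2 (theta - theta0)^2` (degrees), and Lennard-Jones
#' `4 eps ((s/r)^12 - (s/r)^6)` on atom pairs separated by three or more
#' bonds along the chain (1-4 and beyond). It is not a force field: it only
#' supports ordering-level statements (e.g. the anti butane skeleton is
#' lower in energy than the eclipsed one through the 1-4 LJ term).
#'
#' @param n_atoms chain length.
#' @param k_bond,r0 bond force constant (energy per square angstrom) and
#'   equilibrium length (angstrom).
#' @param k_angle,theta0 angle force constant (energy per square degree)
#'   and equilibrium angle (degrees).
#' @param epsilon,sigma_lj LJ well depth (energy) and size parameter
#'   (angstrom); the LJ minimum sits at `2^(1/6) * sigma_lj`.
#' @return a `toy_energy_params` list with `bonds`, `angles`, `lj_pairs`
#'   data frames.
#' @export
chain_energy_params <- function(n_atoms, k_bond = 300, r0 = 1.53,
                                k_angle = 0.02, theta0 = 112.5,
                                epsilon = 0.3, sigma_lj = 3.9 / 2^(1 / 6)) {
  stopifnot(k_bond > 0, k_angle > 0, epsilon > 0)
  bonds <- if (n_atoms >= 2L) {
    data.frame(i = 1:(n_atoms - 1L), j = 2:n_atoms, k = k_bond, r0 = r0)
  } else data.frame(i = integer(0), j = integer(0), k = numeric(0),
                    r0 = numeric(0))
  angles <- if (n_atoms >= 3L) {
    data.frame(i = 1:(n_atoms - 2L), j = 2:(n_atoms - 1L), k = 3:n_atoms,
               kt = k_angle, theta0 = theta0)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    kt = numeric(0), theta0 = numeric(0))
  pr <- which(outer(1:n_atoms, 1:n_atoms, function(a, b) b - a >= 3L),
              arr.ind = TRUE)
  lj <- if (nrow(pr) > 0L) {
    data.frame(i = pr[, 1L], j = pr[, 2L], epsilon = epsilon,
               sigma = sigma_lj)
  } else {
    data.frame(i = integer(0), j = integer(0), epsilon = numeric(0),
               sigma = numeric(0))
  }
  structure(list(bonds = bonds, angles = angles, lj_pairs = lj),
            class = "toy_energy_params")
}

#' @rdname chain_energy_params
#' @param conf a [conformation()].
#' @param params a `toy_energy_params`.
#' @return `toy_energy`: the scalar energy; `toy_energy_gradient`: its
#'   analytic gradient, length `3N`.
#' @export
toy_energy <- function(conf, params) {
  conf <- as_conformation(conf)
  x <- conf$coordinates
  e <- 0
  b <- params$bonds
  for (m in seq_len(nrow(b))) {
    r <- sqrt(sum((x[b$i[m], ] - x[b$j[m], ])^2))
    e <- e + b$k[m] / 2 * (r - b$r0[m])^2
  }
  an <- params$angles
  for (m in seq_len(nrow(an))) {
    th <- measure_angle(conf, an$i[m], an$j[m], an$k[m])
    e <- e + an$kt[m] / 2 * (th - an$theta0[m])^2
  }
  lj <- params$lj_pairs
  for (m in seq_len(nrow(lj))) {
    r <- sqrt(sum((x[lj$i[m], ] - x[lj$j[m], ])^2))
    if (r < .degenerate_tol) stop("zero interatomic distance in LJ term",
                                  call. = FALSE)
    sr6 <- (lj$sigma[m] / r)^6
    e <- e + 4 * lj$epsilon[m] * (sr6^2 - sr6)
  }
  e
}

#' @rdname chain_energy_params
#' @export
toy_energy_gradient <- function(conf, params) {
  conf <- as_conformation(conf)
  x <- conf$coordinates
  g <- numeric(3L * conf$n_atoms)
  add <- function(g, atom, v) {
    idx <- (atom - 1L) * 3L + 1:3
    g[idx] <- g[idx] + v
    g
  }
  b <- params$bonds
  for (m in seq_len(nrow(b))) {
    d <- x[b$i[m], ] - x[b$j[m], ]
    r <- sqrt(sum(d^2))
    coef <- b$k[m] * (r - b$r0[m]) / r
    g <- add(g, b$i[m], coef * d)
    g <- add(g, b$j[m], -coef * d)
  }
  an <- params$angles
  for (m in seq_len(nrow(an))) {
    # at a collinear frame the angle-gradient direction is undefined; the
    # harmonic angle force is skipped there (measure zero in the dynamics)
    gb <- tryCatch(grad_angle(x, an$i[m], an$j[m], an$k[m]),
                   error = function(e) NULL)
    if (is.null(gb)) next
    th <- measure_angle(conf, an$i[m], an$j[m], an$k[m])
    coef <- an$kt[m] * (th - an$theta0[m])
    g <- add(g, an$i[m], coef * gb[[1L]])
    g <- add(g, an$j[m], coef * gb[[2L]])
    g <- add(g, an$k[m], coef * gb[[3L]])
  }
  lj <- params$lj_pairs
  for (m in seq_len(nrow(lj))) {
    d <- x[lj$i[m], ] - x[lj$j[m], ]
    r <- sqrt(sum(d^2))
    sr6 <- (lj$sigma[m] / r)^6
    dUdr <- 4 * lj$epsilon[m] * (-12 * sr6^2 + 6 * sr6) / r
    g <- add(g, lj$i[m], dUdr * d / r)
    g <- add(g, lj$j[m], -dUdr * d / r)
  }
  g
}

#' Synthetic two-mode conformer ensemble
#'
#' Draws conformers from a small number of internal-coordinate "modes"
#' (e.g. anti vs gauche torsional states of a chain), adding Gaussian
#' jitter to torsions, bond lengths and angles. The generating mode of each
#' conformer is recorded, giving ground truth for the constraint-mining
#' recovery tests.
#'
#' @param mode_specs list of mode specifications, each a list with
#'   `bond_lengths`, `bond_angles`, `torsions` as for [build_chain()].
#' @param M number of conformers (assigned to modes uniformly at random).
#' @param torsion_sd Gaussian jitter on torsions (degrees, default 5).
#' @param bond_sd jitter on bond lengths (angstrom, default 0.005).
#' @param angle_sd jitter on bond angles (degrees, default 0.5).
#' @param seed integer seed for reproducibility.
#' @return list of [conformation()]s with attribute `mode` (integer vector
#'   of generating mode per conformer).
#' @export
make_two_mode_ensemble <- function(mode_specs, M = 500L, torsion_sd = 5,
                                   bond_sd = 0.005, angle_sd = 0.5,
                                   seed = 1L) {
  stopifnot(length(mode_specs) >= 1L, M >= 2L, torsion_sd >= 0)
  set.seed(seed)
  modes <- sample.int(length(mode_specs), M, replace = TRUE)
  out <- vector("list", M)
  for (idx in seq_len(M)) {
    sp <- mode_specs[[modes[idx]]]
    bl <- sp$bond_lengths + stats::rnorm(length(sp$bond_lengths), 0, bond_sd)
    ba <- sp$bond_angles + stats::rnorm(length(sp$bond_angles), 0, angle_sd)
    to <- sp$torsions + stats::rnorm(length(sp$torsions), 0, torsion_sd)
    out[[idx]] <- build_chain(bl, ba, to)
  }
  attr(out, "mode") <- modes
  out
}

#' Butane carbon-skeleton fixture
#'
#' A four-carbon chain (C-C 1.53 angstrom, C-C-C 112.5 degrees) with two
#' ready-made constraint sets: the staggered (anti) set fixing the C1-C4
#' end-to-end distance at 3.9 angstrom and the eclipsed set fixing it at
#' 3.15 angstrom, each together with the three C-C covalent bond
#' constraints at the equilibrium length (without which a lone end-to-end
#' constraint can drag the bonded geometry out of shape). Toy energy
#' parameters for the same skeleton are included.
#'
#' @param explicit_hydrogens if `TRUE`, ten hydrogens are added at
#'   tetrahedral positions (C-H 1.09 angstrom); constraint indices still
#'   refer to the four carbons, which come first.
#' @param schedule optional [bound_schedule()] template applied to every
#'   constraint of both sets (bounds tighten to the per-constraint strict
#'   target), so early sampling is effectively unconstrained.
#' @return list with `template` (anti conformation), `staggered` and
#'   `eclipsed` ([constraint_set()]s of 4 constraints each), and
#'   `energy_params`.
#' @examples
#' fx <- butane_fixture()
#' length(fx$staggered) # 4: one end-to-end + three C-C bonds
#' @export
butane_fixture <- function(explicit_hydrogens = FALSE, schedule = NULL) {
  template <- build_chain(rep(1.53, 3), rep(112.5, 2), 180,
                          elements = rep("C", 4))
  if (explicit_hydrogens) template <- add_butane_hydrogens(template)
  with_schedule <- function(i, j, target) {
    if (is.null(schedule)) return(distance_constraint(i, j, target))
    sch <- bound_schedule(beta = schedule$beta, t0 = schedule$t0,
                          lower_initial = schedule$lower_initial,
                          upper_initial = schedule$upper_initial,
                          lower_final = target, upper_final = target,
                          unbounded_width = schedule$unbounded_width)
    distance_constraint(i, j, target, schedule = sch)
  }
  make_set <- function(end_target) {
    constraint_set(c(list(with_schedule(1, 4, end_target)),
                     lapply(1:3, function(b)
                       with_schedule(b, b + 1L, 1.53))))
  }
  list(template = template,
       staggered = make_set(3.9),
       eclipsed = make_set(3.15),
       energy_params = chain_energy_params(4))
}

# tetrahedral explicit-hydrogen decoration of the 4-carbon skeleton
add_butane_hydrogens <- function(skel) {
  x <- skel$coordinates
  hs <- list()
  ch <- 1.09
  for (c_idx in 1:4) {
    nb <- switch(c_idx, `1` = 2L, `2` = c(1L, 3L), `3` = c(2L, 4L),
                 `4` = 3L)
    n_h <- 4L - length(nb)
    # local frame from bonded neighbours
    vs <- lapply(nb, function(m) {
      v <- x[m, ] - x[c_idx, ]; v / sqrt(sum(v^2))
    })
    avg <- -Reduce(`+`, vs) / length(vs)
    avg <- avg / sqrt(sum(avg^2))
    ref <- if (abs(avg[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- cross3(avg, ref); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(avg, e1)
    half <- (180 - 109.47) / DEG   # spread of H fan around the avg axis
    for (h in seq_len(n_h)) {
      ang <- 2 * pi * (h - 1) / n_h
      dirn <- cos(half) * avg + sin(half) * (cos(ang) * e1 + sin(ang) * e2)
      hs[[length(hs) + 1L]] <- x[c_idx, ] + ch * dirn
    }
  }
  conformation(rbind(x, do.call(rbind, hs)),
               elements = c(rep("C", 4), rep("H", length(hs))))
}
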