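# Low-level internal-coordinate geometry: measurements and analytic
# gradients shared by the constraint and fixture layers. Angles are degrees
# in every user-facing value; radians only inside these helpers.

DEG <- 180 / pi
.degenerate_tol <- 1e-8  # interatomic distance below this is an error

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap an angular difference to the shortest arc
#'
#' Maps any angle difference in degrees into `(-180, 180]`.
#'
#' @param d numeric vector of angular differences (degrees).
#' @return wrapped differences in `(-180, 180]`.
#' @export
wrap_angle <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w <= -180] <- 180
  w
}

#' Geometric measurements on a conformation
#'
#' Interatomic distance (angstrom), bond angle and torsion (degrees, IUPAC
#' sign convention, wrapped to `(-180, 180]`).
#'
#' @param conf a [conformation()].
#' @param i,j,k,l 1-based atom indices.
#' @return a single numeric value.
#' @examples
#' tri <- conformation(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
#' measure_angle(tri, 1, 2, 3) # 90
#' @export
measure_distance <- function(conf, i, j) {
  x <- conf$coordinates
  sqrt(sum((x[i, ] - x[j, ])^2))
}

#' @rdname measure_distance
#' @export
measure_angle <- function(conf, i, j, k) {
  x <- conf$coordinates
  u <- x[i, ] - x[j, ]
  v <- x[k, ] - x[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .degenerate_tol || nv < .degenerate_tol) {
    stop("degenerate geometry: coincident atoms in angle frame", call. = FALSE)
  }
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * DEG
}

#' @rdname measure_distance
#' @export
measure_torsion <- function(conf, i, j, k, l) {
  x <- conf$coordinates
  b1 <- x[j, ] - x[i, ]
  b2 <- x[k, ] - x[j, ]
  b3 <- x[l, ] - x[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < .degenerate_tol ||
      sqrt(sum(n1^2)) < .degenerate_tol || sqrt(sum(n2^2)) < .degenerate_tol) {
    stop("degenerate geometry: collinear torsion frame", call. = FALSE)
  }
  phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  wrap_angle(phi * DEG)
}

# --- analytic gradients (per-atom 3-vectors, value units per angstrom) ----

# distance i-j: d|xi - xj|; returns list of two 3-vectors (atoms i, j)
grad_distance <- function(x, i, j) {
  d <- x[i, ] - x[j, ]
  r <- sqrt(sum(d^2))
  if (r < .degenerate_tol) {
    stop("degenerate geometry: coincident atoms in distance constraint",
         call. = FALSE)
  }
  u <- d / r
  list(u, -u)
}

# angle i-j-k in DEGREES; returns list of three 3-vectors
grad_angle <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]
  v <- x[k, ] - x[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .degenerate_tol || nv < .degenerate_tol) {
    stop("degenerate geometry: coincident atoms in angle frame", call. = FALSE)
  }
  uh <- u / nu; vh <- v / nv
  ct <- min(1, max(-1, sum(uh * vh)))
  st <- sqrt(1 - ct^2)
  if (st < .degenerate_tol) {
    stop("degenerate geometry: collinear angle frame", call. = FALSE)
  }
  gi <- (ct * uh - vh) / (nu * st) * DEG
  gk <- (ct * vh - uh) / (nv * st) * DEG
  list(gi, -(gi + gk), gk)
}

# torsion i-j-k-l in DEGREES; Blondel-Karplus analytic form
grad_torsion <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]
  b2 <- x[k, ] - x[j, ]
  b3 <- x[l, ] - x[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  if (nb2 < .degenerate_tol || n1sq < .degenerate_tol^2 ||
      n2sq < .degenerate_tol^2) {
    stop("degenerate geometry: collinear torsion frame", call. = FALSE)
  }
  g1 <- -(nb2 / n1sq) * n1
  g4 <- (nb2 / n2sq) * n2
  c1 <- sum(b1 * b2) / nb2^2
  c3 <- sum(b3 * b2) / nb2^2
  g2 <- -(1 + c1) * g1 + c3 * g4
  g3 <- -(g1 + g2 + g4)
  lapply(list(g1, g2, g3, g4), function(g) g * DEG)
}
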