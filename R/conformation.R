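#' Molecular conformation
#'
#' A conformation is a set of `N` atomic positions in Cartesian space
#' (angstrom), optionally labelled with element symbols. It is the state
#' `x` in `R^(3N)` that every other function in the package operates on.
#'
#' @param coordinates numeric `N x 3` matrix of positions (angstrom). A
#'   length-3 vector is accepted for a single atom.
#' @param elements optional character vector of element symbols, length `N`.
#' @return an object of class `conformation`: a list with `coordinates`
#'   (`N x 3` matrix), `n_atoms`, and `elements` (possibly `NULL`).
#' @examples
#' conf <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)), elements = c("C", "C"))
#' conf$n_atoms
#' @export
conformation <- function(coordinates, elements = NULL) {
  if (is.null(dim(coordinates))) {
    coordinates <- matrix(coordinates, ncol = 3L, byrow = TRUE)
  }
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) {
    stop("coordinates must be an N x 3 matrix", call. = FALSE)
  }
  storage.mode(coordinates) <- "double"
  if (!all(is.finite(coordinates))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  n <- nrow(coordinates)
  if (!is.null(elements)) {
    elements <- as.character(elements)
    if (length(elements) != n) {
      stop("elements must have one entry per atom", call. = FALSE)
    }
  }
  dimnames(coordinates) <- NULL
  structure(
    list(coordinates = coordinates, n_atoms = n, elements = elements),
    class = "conformation"
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation: %d atoms>\n", x$n_atoms))
  invisible(x)
}

#' Flatten / unflatten conformation coordinates
#'
#' The sampler and projection machinery work on the flattened state vector
#' `x in R^(3N)` (row-major: atom 1 x,y,z, atom 2 x,y,z, ...).
#'
#' @param conf a [conformation()].
#' @return `conf_to_vector`: numeric vector of length `3N`.
#' @export
conf_to_vector <- function(conf) {
  as.numeric(t(conf$coordinates))
}

#' @rdname conf_to_vector
#' @param x numeric vector of length `3N`.
#' @param template optional conformation supplying element labels.
#' @return `vector_to_conf`: a [conformation()].
#' @export
vector_to_conf <- function(x, template = NULL) {
  coords <- matrix(x, ncol = 3L, byrow = TRUE)
  conformation(coords, elements = if (!is.null(template)) template$elements)
}

as_conformation <- function(x) {
  if (inherits(x, "conformation")) x else conformation(x)
}
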