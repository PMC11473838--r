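#' Atomic masses (amu) for elements used by the toy surfaces
#'
#' A small standard-atomic-weight table sufficient for the potentials shipped
#' with the package.  The pseudo-element \code{"X"} (a structureless particle,
#' used by the 2D benchmark surface) has mass 1.
#' @keywords internal
.atomic_masses <- c(
  X = 1.0, H = 1.008, He = 4.0026, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.9
)

#' Covalent radii (Angstrom) used for bond perception
#'
#' Values from the widely used Cordero compilation; \code{"X"} is given a
#' nominal 0.5 Angstrom radius.
#' @keywords internal
.covalent_radii <- c(
  X = 0.5, H = 0.31, He = 0.28, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

#' Construct a molecular geometry
#'
#' A geometry is the basic container passed to every potential, optimizer and
#' analysis function: element symbols, Cartesian coordinates in Angstrom, and
#' atomic masses in amu.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#'   A length-3N vector is accepted and reshaped row-wise per atom.
#' @param masses optional numeric vector of atomic masses (amu); defaults to
#'   standard atomic weights looked up from the element symbols.
#' @param frame_id optional label carried through I/O round trips.
#' @return An object of class \code{"geometry"}: a list with fields
#'   \code{elements}, \code{coords}, \code{masses}, \code{frame_id}.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' g$masses
#' @export
geometry <- function(elements, coords, masses = NULL, frame_id = NULL) {
  elements <- as.character(elements)
  if (is.null(dim(coords))) {
    if (length(coords) != 3L * length(elements))
      stop("coords vector length must be 3 * number of atoms")
    coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns")
  if (nrow(coords) != length(elements))
    stop("number of coordinate rows (", nrow(coords),
         ") does not match number of elements (", length(elements), ")")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  if (is.null(masses)) {
    masses <- .atomic_masses[elements]
    if (anyNA(masses))
      stop("no tabulated mass for element(s): ",
           paste(unique(elements[is.na(masses)]), collapse = ", "))
    masses <- unname(masses)
  }
  masses <- as.numeric(masses)
  if (length(masses) != length(elements))
    stop("masses length must equal number of atoms")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite")
  structure(list(elements = elements, coords = coords, masses = masses,
                 frame_id = frame_id),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry>", n_atoms(x), "atoms:",
      paste(x$elements, collapse = " "),
      if (!is.null(x$frame_id)) paste0("[", x$frame_id, "]") else "", "\n")
  m <- cbind(x$coords, mass = x$masses)
  dimnames(m) <- list(x$elements, c("x", "y", "z", "mass"))
  print(round(m, 6), ...)
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a \code{geometry}.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Flatten geometry coordinates to a 3N vector (atom-major)
#' @param geom a \code{geometry}.
#' @return numeric vector of length 3N: (x1, y1, z1, x2, ...).
#' @export
coords_vector <- function(geom) as.numeric(t(geom$coords))

#' Replace the coordinates of a geometry
#' @param geom a \code{geometry}.
#' @param x numeric 3N vector (atom-major) or N x 3 matrix.
#' @return a new \code{geometry} with the same elements/masses.
#' @export
set_coords <- function(geom, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  geometry(geom$elements, x, masses = geom$masses, frame_id = geom$frame_id)
}

#' Pairwise interatomic distance
#' @param geom a \code{geometry}.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(geom, i, j) {
  sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
}

# Mass-repeated 3N vector (m1,m1,m1,m2,...), used for mass weighting.
mass_vector <- function(geom) rep(geom$masses, each = 3L)
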