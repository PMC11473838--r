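# Molecular connectivity graphs, element-aware VF2 isomorphism, outcome
# classification (2-end / 1-end / none; chemical vs conformational) and
# Kabsch-aligned optimization path lengths.

#' Build a molecular connectivity graph from a geometry
#'
#' Two atoms are bonded when their distance does not exceed
#' \code{scale} times the sum of their covalent radii (Cordero radii;
#' default scale 1.2, exposed as a tool parameter).
#'
#' @param geometry a \code{geometry}.
#' @param scale bond-detection scale on the covalent-radius sum.
#' @return object of class \code{"molecular_graph"}: list with
#'   \code{elements}, \code{edges} (two-column matrix of bonded pairs,
#'   i < j) and \code{scale}.
#' @export
build_graph <- function(geometry, scale = 1.2) {
  radii <- .covalent_radii[geometry$elements]
  if (anyNA(radii))
    stop("no tabulated covalent radius for element(s): ",
         paste(unique(geometry$elements[is.na(radii)]), collapse = ", "))
  n <- n_atoms(geometry)
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom_distance(geometry, i, j) <= scale * (radii[i] + radii[j]))
      edges <- rbind(edges, c(i, j))
  }
  structure(list(elements = geometry$elements, edges = edges,
                 scale = scale),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", length(x$elements), "atoms,",
      nrow(x$edges), "bonds:",
      if (nrow(x$edges)) paste(apply(x$edges, 1, function(e)
        paste0(x$elements[e[1]], e[1], "-", x$elements[e[2]], e[2])),
        collapse = " ") else "(none)", "\n")
  invisible(x)
}

.as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' Element-preserving graph isomorphism (VF2)
#'
#' Decides whether two molecular graphs are isomorphic under a mapping that
#' preserves element labels, using the VF2 algorithm.
#'
#' @param g1,g2 \code{molecular_graph} objects.
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$elements) != length(g2$elements)) return(FALSE)
  lev <- sort(unique(c(g1$elements, g2$elements)))
  igraph::isomorphic(
    .as_igraph(g1), .as_igraph(g2), method = "vf2",
    vertex.color1 = match(g1$elements, lev),
    vertex.color2 = match(g2$elements, lev))
}

#' Classify a TS optimization outcome against the intended reaction
#'
#' Compares the connectivity graphs of the two IRC endpoints with the
#' intended reactant/product graphs (as an unordered pair):
#' \code{two_end} when both endpoints match the two intended graphs,
#' \code{one_end} when exactly one endpoint matches either intended graph,
#' \code{none} otherwise.  The TS is \code{conformational} iff the two
#' endpoint graphs are isomorphic to each other, else \code{chemical}.
#'
#' @param irc an \code{irc_pair} (or list with \code{forward$endpoint},
#'   \code{backward$endpoint}).
#' @param intended_reactant,intended_product \code{geometry} objects (or
#'   prebuilt \code{molecular_graph}s).
#' @param scale bond-detection scale passed to \code{\link{build_graph}}.
#' @return list with \code{match} (factor-like string), \code{ts_type},
#'   \code{endpoints_converged}.
#' @export
classify_outcome <- function(irc, intended_reactant, intended_product,
                             scale = 1.2) {
  as_graph <- function(x)
    if (inherits(x, "molecular_graph")) x else build_graph(x, scale)
  gr <- as_graph(intended_reactant)
  gp <- as_graph(intended_product)
  e1 <- irc$forward$endpoint; e2 <- irc$backward$endpoint
  conv <- isTRUE(attr(e1, "converged")) && isTRUE(attr(e2, "converged"))
  g1 <- as_graph(e1); g2 <- as_graph(e2)
  ts_type <- if (graphs_isomorphic(g1, g2)) "conformational" else "chemical"
  if (!conv)
    return(list(match = "none", ts_type = ts_type,
                endpoints_converged = FALSE))
  two_end <- (graphs_isomorphic(g1, gr) && graphs_isomorphic(g2, gp)) ||
    (graphs_isomorphic(g1, gp) && graphs_isomorphic(g2, gr))
  if (two_end) {
    match <- "two_end"
  } else {
    hits <- sum(graphs_isomorphic(g1, gr) || graphs_isomorphic(g1, gp),
                graphs_isomorphic(g2, gr) || graphs_isomorphic(g2, gp))
    match <- if (hits == 1) "one_end" else "none"
  }
  list(match = match, ts_type = ts_type, endpoints_converged = conv)
}

#' Kabsch-aligned Cartesian path length of a trajectory
#'
#' Sums, over consecutive frames, the Cartesian distance after optimal
#' proper-rotation (Kabsch) superposition of each frame onto its
#' predecessor; rigid translations and rotations therefore contribute
#' nothing.
#'
#' @param frames list of N x 3 coordinate matrices (or \code{geometry}s)
#'   with consistent atom count and order.
#' @return total path length (Angstrom).
#' @export
kabsch_path_length <- function(frames) {
  coords <- lapply(frames, function(f)
    if (inherits(f, "geometry")) f$coords else as.matrix(f))
  if (length(coords) < 2) stop("need at least 2 frames")
  dims <- vapply(coords, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("frame shape mismatch")
  total <- 0
  for (k in 2:length(coords)) {
    al <- kabsch_align(coords[[k]], coords[[k - 1]])
    total <- total + al$distance
  }
  total
}
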