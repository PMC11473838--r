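# XYZ / extended-XYZ readers and writers.  The extended flavour stores
# per-frame energy as `energy=...` in the comment line and per-atom forces
# as three extra columns declared through a `Properties=` key
# (species:S:1:pos:R:3[:forces:R:3]).  Forces follow the convention
# force = -gradient.

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write geometries to an (extended) XYZ file
#'
#' @param geoms a \code{geometry}, a list of them, or a
#'   \code{configuration_set} (whose energies/forces are then written as
#'   extended-XYZ fields).
#' @param path output file path.
#' @param energies optional per-frame energies.
#' @param forces optional list of per-frame force vectors (length 3N).
#' @return invisibly, the path.
#' @export
write_xyz <- function(geoms, path, energies = NULL, forces = NULL) {
  if (inherits(geoms, "configuration_set")) {
    energies <- vapply(geoms$records, function(r) r$energy, 0)
    forces <- lapply(geoms$records, function(r) r$forces)
    geoms <- lapply(geoms$records, function(r) r$geometry)
  }
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    n <- n_atoms(g)
    has_f <- !is.null(forces) && !is.null(forces[[k]])
    props <- if (has_f) "species:S:1:pos:R:3:forces:R:3" else
      "species:S:1:pos:R:3"
    comment <- paste0("Properties=", props)
    if (!is.null(energies) && !is.na(energies[k]))
      comment <- paste0("energy=", .fmt_num(energies[k]), " ", comment)
    if (!is.null(g$frame_id))
      comment <- paste0(comment, " frame_id=", g$frame_id)
    writeLines(c(as.character(n), comment), con)
    Fm <- if (has_f) matrix(forces[[k]], ncol = 3, byrow = TRUE) else NULL
    for (i in seq_len(n)) {
      line <- paste(c(g$elements[i], .fmt_num(g$coords[i, ]),
                      if (has_f) .fmt_num(Fm[i, ])), collapse = " ")
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read geometries from an (extended) XYZ file
#'
#' Honors `energy=` and a `Properties=...forces:R:3` declaration in the
#' comment line; coordinates round-trip losslessly at full double
#' precision.  Malformed headers or truncated frames raise an error naming
#' the offending line.
#'
#' @param path input file path.
#' @param as \code{"list"} (list of \code{geometry} with attributes) or
#'   \code{"configuration_set"} (requires energies and forces on every
#'   frame).
#' @return list of geometries (each with optional \code{attr(, "energy")} /
#'   \code{attr(, "forces")}), or a \code{configuration_set}.
#' @export
read_xyz <- function(path, as = c("list", "configuration_set")) {
  as <- match.arg(as)
  lines <- readLines(path)
  out <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 0)
      stop("line ", ln, ": expected an atom count, got '", lines[ln], "'")
    if (ln + 1L + n > length(lines))
      stop("line ", ln, ": frame declares ", n, " atoms but file ends at ",
           "line ", length(lines))
    comment <- lines[ln + 1L]
    has_forces <- grepl("forces:R:3", comment, fixed = TRUE)
    energy <- NA_real_
    em <- regmatches(comment, regexec("energy=([^ ]+)", comment))[[1]]
    if (length(em) == 2) energy <- as.numeric(em[2])
    fid <- NULL
    fm <- regmatches(comment, regexec("frame_id=([^ ]+)", comment))[[1]]
    if (length(fm) == 2) fid <- fm[2]
    elements <- character(n)
    coords <- matrix(0, n, 3)
    forces <- if (has_forces) numeric(3 * n) else NULL
    for (i in seq_len(n)) {
      ll <- ln + 1L + i
      tok <- strsplit(trimws(lines[ll]), "\\s+")[[1]]
      need <- if (has_forces) 7L else 4L
      if (length(tok) < need)
        stop("line ", ll, ": expected ", need, " fields, got ",
             length(tok))
      elements[i] <- tok[1]
      coords[i, ] <- as.numeric(tok[2:4])
      if (has_forces) forces[(3 * i - 2):(3 * i)] <- as.numeric(tok[5:7])
    }
    if (anyNA(coords))
      stop("non-numeric coordinates in frame starting at line ", ln)
    g <- geometry(elements, coords, frame_id = fid)
    attr(g, "energy") <- energy
    attr(g, "forces") <- forces
    out[[length(out) + 1L]] <- g
    ln <- ln + 2L + n
  }
  if (as == "configuration_set") {
    recs <- lapply(out, function(g) {
      if (is.na(attr(g, "energy")) || is.null(attr(g, "forces")))
        stop("configuration_set requires energy and forces on every frame")
      list(geometry = g, energy = attr(g, "energy"),
           forces = attr(g, "forces"))
    })
    return(configuration_set(recs, provenance = list(source = path)))
  }
  out
}

#' Write an IRC branch as multi-frame extended XYZ
#'
#' Frames carry per-frame energy and cumulative mass-weighted arc length.
#' @param irc an \code{irc_path}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_irc_xyz <- function(irc, path) {
  geoms <- irc$frames
  for (k in seq_along(geoms))
    geoms[[k]]$frame_id <- paste0("arc=", .fmt_num(irc$arc_length[k]))
  write_xyz(geoms, path, energies = irc$energies)
}
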