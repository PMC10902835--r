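#' Solvent frame
#'
#' One snapshot of a simulation: particle coordinates, the orthorhombic
#' periodic box and the current cavity center.  Coordinates are wrapped into
#' `[0, L)` on construction.
#'
#' @param positions numeric matrix (N x 3) of coordinates in Angstrom
#' @param box_lengths 3-vector of box edge lengths (Angstrom), all > 0
#' @param cavity_center 3-vector, wrapped into the box
#' @return an object of class `solvent_frame`
#' @export
solvent_frame <- function(positions, box_lengths,
                          cavity_center = box_lengths / 2) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  box_lengths <- as.numeric(box_lengths)
  if (length(box_lengths) == 1) box_lengths <- rep(box_lengths, 3)
  stopifnot(length(box_lengths) == 3, all(box_lengths > 0),
            length(cavity_center) == 3)
  positions <- wrap_positions(positions, box_lengths)
  cavity_center <- as.numeric(cavity_center) %% box_lengths
  structure(list(positions = positions, box_lengths = box_lengths,
                 cavity_center = cavity_center),
            class = "solvent_frame")
}

#' @export
print.solvent_frame <- function(x, ...) {
  cat(sprintf("solvent_frame: %d particles, box %.3f x %.3f x %.3f A\n",
              nrow(x$positions), x$box_lengths[1], x$box_lengths[2],
              x$box_lengths[3]))
  invisible(x)
}

#' Wrap coordinates into the periodic box
#' @param positions N x 3 matrix
#' @param box_lengths 3-vector
#' @return wrapped matrix
#' @export
wrap_positions <- function(positions, box_lengths) {
  sweep(positions, 2, box_lengths, `%%`)
}

#' Minimum-image distances to a point
#'
#' @param positions N x 3 matrix
#' @param point 3-vector
#' @param box_lengths 3-vector
#' @return vector of N minimum-image distances
#' @export
min_image_dist <- function(positions, point, box_lengths) {
  d <- sweep(positions, 2, as.numeric(point))
  d <- d - sweep(round(sweep(d, 2, box_lengths, `/`)), 2, box_lengths, `*`)
  sqrt(rowSums(d^2))
}

#' Write frames to an extended-XYZ file
#'
#' Dialect: the comment line carries `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`,
#' `cavity="x y z"` and `Properties=species:S:1:pos:R:3`; every particle is
#' written as species `W`.
#'
#' @param frames a `solvent_frame` or list of them
#' @param path output file
#' @export
write_extxyz <- function(frames, path) {
  if (inherits(frames, "solvent_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    L <- fr$box_lengths
    cc <- fr$cavity_center
    writeLines(as.character(n), con)
    writeLines(sprintf(
      paste0('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" cavity="%.10g %.10g ',
             '%.10g" Properties=species:S:1:pos:R:3'),
      L[1], L[2], L[3], cc[1], cc[2], cc[3]), con)
    if (n > 0)
      writeLines(sprintf("W %.10g %.10g %.10g", fr$positions[, 1],
                         fr$positions[, 2], fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read frames from an extended-XYZ file
#'
#' @param path input file written by [write_extxyz()] (or the same dialect)
#' @return list of [solvent_frame()] objects
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed extended-XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]*)"', comment))[[1]][2]
    cav <- regmatches(comment, regexec('cavity="([^"]*)"', comment))[[1]][2]
    if (is.na(lat)) stop("missing Lattice in extended-XYZ comment line")
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    L <- latv[c(1, 5, 9)]
    cc <- if (is.na(cav)) L / 2 else as.numeric(strsplit(trimws(cav), "\\s+")[[1]])
    pos <- matrix(numeric(0), ncol = 3)
    if (n > 0) {
      body <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(body), "\\s+")
      pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    }
    frames[[length(frames) + 1L]] <- solvent_frame(pos, L, cc)
    i <- i + 2L + n
  }
  frames
}
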