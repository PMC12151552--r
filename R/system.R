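#' Particle system container
#'
#' A non-periodic collection of point charges in a rectangular box: the
#' object whose electrostatic energy and forces the package computes.
#' Positions are in Angstrom, charges in units of the elementary charge.
#'
#' @param positions numeric matrix (n x 3), each coordinate in `[0, box)`.
#' @param charges numeric vector of length n.
#' @param box numeric length-3 vector of box edge lengths (Angstrom); a
#'   scalar is recycled to a cube.
#' @param labels character element symbols (defaults to `"X"`).
#' @return An object of class `particle_system` with fields `n_atoms`,
#'   `positions`, `charges`, `labels`, `box`.
#' @export
particle_system <- function(positions, charges, box, labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop_arg("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (n < 1) stop_arg("a particle system needs at least one atom")
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop_arg("box must be 3 positive edge lengths")
  if (length(charges) != n) stop_arg("charges must match the number of atoms")
  for (d in 1:3) {
    if (any(positions[, d] < 0 | positions[, d] >= box[d]))
      stop_arg("position out of bounds on axis ", d,
               " (all coordinates must lie in [0, box); no periodic wrapping)")
  }
  labels <- labels %||% rep("X", n)
  structure(list(n_atoms = n, positions = unname(positions),
                 charges = as.numeric(charges), labels = as.character(labels),
                 box = as.numeric(box)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d atoms in %.6g x %.6g x %.6g A box, net charge %.6g e\n",
              x$n_atoms, x$box[1], x$box[2], x$box[3], sum(x$charges)))
  invisible(x)
}

#' Read an extended-XYZ file with charges
#'
#' Line 1: atom count. Line 2: comment carrying the box as
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`. Then one `element x y z charge` row per
#' atom (whitespace-delimited; the charge column is mandatory).
#'
#' @param path file path.
#' @return A [particle_system].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_arg("not an extended-XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop_arg("bad atom count on line 1 of ", path)
  if (length(lines) < 2 + n) stop_arg("file truncated: expected ", n, " atom rows")
  m <- regmatches(lines[2], regexec('Lattice="([^"]+)"', lines[2]))[[1]]
  if (length(m) < 2) stop_arg("comment line lacks a Lattice=\"...\" box specification")
  lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  if (length(lat) != 9 || any(is.na(lat)))
    stop_arg("Lattice must contain 9 numbers")
  if (any(abs(lat[c(2, 3, 4, 6, 7, 8)]) > 0))
    stop_arg("only rectangular (diagonal) boxes are supported")
  box <- lat[c(1, 5, 9)]
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 5)
  if (length(bad))
    stop_arg("format error: atom row ", bad[1], " lacks the mandatory charge column")
  tab <- do.call(rbind, lapply(fields, function(f) f[1:5]))
  pos <- matrix(as.numeric(tab[, 2:4]), ncol = 3)
  ch <- as.numeric(tab[, 5])
  if (any(is.na(pos)) || any(is.na(ch))) stop_arg("non-numeric coordinate or charge field")
  particle_system(pos, ch, box, labels = tab[, 1])
}

#' Write a particle system as extended XYZ
#'
#' @param system a [particle_system].
#' @param path output file path.
#' @param comment optional extra text appended to the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, comment = "") {
  b <- system$box
  hdr <- sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3:charge:R:1%s%s',
                 b[1], b[2], b[3], if (nzchar(comment)) " " else "", comment)
  rows <- sprintf("%s %.10f %.10f %.10f %.6f", system$labels,
                  system$positions[, 1], system$positions[, 2],
                  system$positions[, 3], system$charges)
  writeLines(c(as.character(system$n_atoms), hdr, rows), path)
  invisible(path)
}
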