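# Synthetic neutral salt-water benchmark boxes. A fixed-charge 3-site water
# (O-H 0.9572 A, H-O-H 104.52 deg; q_O = -0.834, q_H = +0.417) plus Na+ and
# Cl- point ions; molecule anchor sites are placed by seeded rejection
# sampling with a minimum heavy-atom separation. The electrostatics
# benchmark depends only on charge magnitudes and spatial density, not on
# liquid ordering, so no equilibration is attempted (the boxes are
# synthetic stand-ins for the benchmark compositions, not real liquid
# structures).

water_geometry <- function() {
  half <- (104.52 / 2) * pi / 180
  roh <- 0.9572
  rbind(c(0, 0, 0),
        roh * c(sin(half), cos(half), 0),
        roh * c(-sin(half), cos(half), 0))
}

# uniform random rotation matrices from quaternions, one per molecule
random_rotations <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
  lapply(seq_len(n), function(i) {
    a <- q[i, 1]; b <- q[i, 2]; cc <- q[i, 3]; d <- q[i, 4]
    matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
             2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d + a * b),
             2 * (b * d + a * cc), 2 * (cc * d - a * b), a^2 - b^2 - cc^2 + d^2),
           3, 3)
  })
}

#' Build a neutral salt-water benchmark box
#'
#' Places `n_water` rigid 3-site waters and `n_nacl` Na+/Cl- ion pairs in a
#' rectangular box by seeded rejection sampling: molecule anchor sites
#' (water oxygens and ions) keep a minimum separation, water orientations
#' are uniform random rotations. Deterministic for a fixed seed; net charge
#' is exactly zero.
#'
#' @param n_water number of water molecules.
#' @param n_nacl number of NaCl ion pairs.
#' @param box box edges (Angstrom; scalar recycled to a cube).
#' @param seed integer seed.
#' @param min_separation minimum heavy-atom (anchor) separation (Angstrom).
#' @return A [particle_system] with `3 n_water + 2 n_nacl` atoms.
#' @export
build_salt_water_box <- function(n_water, n_nacl, box, seed = 1,
                                 min_separation = 2.0) {
  if (length(box) == 1) box <- rep(box, 3)
  n_sites <- n_water + 2 * n_nacl
  if (n_sites < 1) stop_arg("empty recipe")
  margin <- 1.0  # keeps hydrogens (O-H 0.9572 A) inside the box
  if (any(box <= 2 * margin)) stop_arg("box too small for placement margin")
  with_seed(seed, {
    sites <- cpp_place_points(n_sites, box, margin, min_separation, 20000L)
    rot <- if (n_water > 0) random_rotations(n_water) else list()
    geom <- water_geometry()
    pos <- matrix(0, 3 * n_water + 2 * n_nacl, 3)
    if (n_water > 0) {
      for (i in seq_len(n_water)) {
        block <- geom %*% t(rot[[i]])
        pos[(3 * i - 2):(3 * i), ] <- sweep(block, 2, sites[i, ], `+`)
      }
    }
    if (n_nacl > 0)
      pos[(3 * n_water + 1):nrow(pos), ] <-
        sites[(n_water + 1):n_sites, , drop = FALSE]
    # hydrogens may poke past a face only if margin < O-H; clamp guard
    pos <- pmin(pmax(pos, 0), matrix(rep(box, each = nrow(pos)),
                                     ncol = 3) - 1e-9)
    charges <- c(rep(c(-0.834, 0.417, 0.417), n_water),
                 rep(1, n_nacl), rep(-1, n_nacl))
    labels <- c(rep(c("O", "H", "H"), n_water),
                rep("Na", n_nacl), rep("Cl", n_nacl))
    particle_system(pos, charges, box, labels = labels)
  })
}

#' Benchmark box compositions
#'
#' The eleven neutral salt-water compositions used for benchmarking: number
#' of waters, NaCl pairs, resulting atom count and cubic box edge, from 38
#' atoms in an 8 A box up to 1,588,868 atoms in a 256 A box.
#'
#' @return A data.frame with columns `n_water`, `n_nacl`, `n_atoms`,
#'   `box_edge`.
#' @export
table1_recipes <- function() {
  df <- data.frame(
    n_water = c(12L, 115L, 979L, 8172L, 65275L, 101212L, 159746L, 222303L,
                316376L, 411904L, 526044L),
    n_nacl = c(1L, 2L, 11L, 84L, 667L, 1033L, 1631L, 2269L, 3229L, 4204L,
               5368L),
    box_edge = c(8, 16, 32, 64, 128, 148, 172, 192, 216, 236, 256))
  df$n_atoms <- 3L * df$n_water + 2L * df$n_nacl
  df[, c("n_water", "n_nacl", "n_atoms", "box_edge")]
}

#' Two-point-charge test fixture
#'
#' Two charges on the x axis, centered in a cubic box. Combined with a
#' chosen cutoff this lands the pair in cells at any desired Chebyshev
#' separation.
#'
#' @param q1,q2 charges (e).
#' @param separation distance between the charges (Angstrom, > 0).
#' @param box cubic box edge (default `2 * (separation + 2)`).
#' @return A [particle_system] with 2 atoms.
#' @export
fixture_dimer <- function(q1, q2, separation, box = NULL) {
  if (separation <= 0) stop_arg("separation must be positive")
  box <- box %||% (2 * (separation + 2))
  b <- rep(box[1], 3)
  x0 <- (b[1] - separation) / 2
  particle_system(rbind(c(x0, b[2] / 2, b[3] / 2),
                        c(x0 + separation, b[2] / 2, b[3] / 2)),
                  c(q1, q2), b, labels = c("X", "X"))
}
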