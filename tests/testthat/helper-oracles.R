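# Independent brute-force references used across the tests. These stay
# deliberately naive (plain R, all pairs, no cell machinery) so they cannot
# share a defect with the fast paths they check.

KE <- 332.0637141

# all-pairs Coulomb in plain R: list(total, per_atom (half-share), forces)
naive_coulomb <- function(pos, q, ke = KE) {
  n <- nrow(pos)
  E <- numeric(n)
  Fm <- matrix(0, n, 3)
  total <- 0
  for (a in seq_len(max(n - 1, 0))) {
    for (b in (a + 1):n) {
      d <- pos[a, ] - pos[b, ]
      r <- sqrt(sum(d^2))
      e <- ke * q[a] * q[b] / r
      total <- total + e
      E[a] <- E[a] + e / 2
      E[b] <- E[b] + e / 2
      g <- e / r^2
      Fm[a, ] <- Fm[a, ] + g * d
      Fm[b, ] <- Fm[b, ] - g * d
    }
  }
  list(total = total, per_atom = E, forces = Fm)
}

# pairwise sums restricted to cell pairs at Chebyshev separation <= 1
naive_short_range <- function(pos, q, box, cutoff, ke = KE) {
  grid <- build_cell_grid(box, cutoff)
  nx <- grid$n_cells
  idx3 <- function(p) pmin(nx - 1L, as.integer(floor(p / grid$cell_edge)))
  cells <- t(apply(pos, 1, idx3))
  n <- nrow(pos)
  E <- numeric(n)
  total <- 0
  for (a in seq_len(max(n - 1, 0))) {
    for (b in (a + 1):n) {
      if (max(abs(cells[a, ] - cells[b, ])) <= 1) {
        r <- sqrt(sum((pos[a, ] - pos[b, ])^2))
        e <- ke * q[a] * q[b] / r
        total <- total + e
        E[a] <- E[a] + e / 2
        E[b] <- E[b] + e / 2
      }
    }
  }
  list(total = total, per_atom = E)
}

# cubature kernel by direct per-node summation in R
naive_kernel <- function(cubature, r_vec) {
  sum(cubature$weights * cos(as.numeric(cubature$k %*% as.numeric(r_vec))))
}

# random particle system in a box (margin keeps positions strictly inside)
random_system <- function(n, box, seed, neutralize = FALSE) {
  set.seed(seed)
  pos <- cbind(runif(n, 0.2, box - 0.2), runif(n, 0.2, box - 0.2),
               runif(n, 0.2, box - 0.2))
  q <- round(runif(n, -1, 1), 3)
  if (neutralize) q <- q - mean(q)
  particle_system(pos, q, rep(box, 3))
}

# two charges placed at the centers of cells at a given Chebyshev separation
cellsep_pair <- function(q1, q2, cutoff, sep, n_cells = max(5, sep + 2)) {
  box <- rep(cutoff * n_cells, 3)
  c0 <- cutoff / 2
  particle_system(rbind(c(c0, c0, c0), c(c0 + sep * cutoff, c0, c0)),
                  c(q1, q2), box)
}

octahedron_points <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

icosahedron_points <- function() {
  phi <- (1 + sqrt(5)) / 2
  p <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  p / sqrt(1 + phi^2)
}
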