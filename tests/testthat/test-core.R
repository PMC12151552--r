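# shared small calibration reused across blocks (session-cached)
cal_small <- calibrate_cubature(3.2, 17, 0.75, 1e-4)

test_that("basis functions satisfy their pointwise identities", {
  cub <- cal_small$cubature
  b0 <- compute_basis(c(1.3, 0.2, 2.5), 0, cub)
  expect_true(all(b0$C == 0) && all(b0$S == 0))
  bq <- compute_basis(c(0, 0, 0), -0.7, cub)
  expect_equal(bq$C, rep(-0.7, cub$n_nodes))
  expect_equal(bq$S, rep(0, cub$n_nodes))
  br <- compute_basis(c(1.3, 0.2, 2.5), -0.7, cub)
  expect_equal(br$C^2 + br$S^2, rep(0.49, cub$n_nodes), tolerance = 1e-13)
})

test_that("cell structure factors equal per-atom loop sums", {
  # one atom per cell
  s <- particle_system(rbind(c(1, 1, 1), c(5, 5, 5)), c(0.5, -1.2), rep(8, 3))
  g <- assign_atoms_to_cells(s, build_cell_grid(s$box, 4))
  sf <- compute_cell_structure_factors(g, cal_small$cubature)
  b1 <- compute_basis(c(1, 1, 1), 0.5, cal_small$cubature)
  expect_equal(as.numeric(sf$C[1, ]), b1$C, tolerance = 1e-14)
  expect_equal(as.numeric(sf$S[1, ]), b1$S, tolerance = 1e-14)

  # opposite charges at the same position cancel exactly
  s <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1)), c(2, -2), rep(8, 3))
  g <- assign_atoms_to_cells(s, build_cell_grid(s$box, 4))
  sf <- compute_cell_structure_factors(g, cal_small$cubature)
  expect_true(all(abs(sf$C) < 1e-14) && all(abs(sf$S) < 1e-14))

  # random 50-atom cell vs naive loop, and linearity over cells
  s <- random_system(50, 6.4, seed = 31)
  g <- assign_atoms_to_cells(s, build_cell_grid(s$box, 3.2))
  sf <- compute_cell_structure_factors(g, cal_small$cubature)
  cub <- cal_small$cubature
  loopC <- matrix(0, 8, cub$n_nodes); loopS <- matrix(0, 8, cub$n_nodes)
  for (a in seq_len(50)) {
    b <- compute_basis(s$positions[a, ], s$charges[a], cub)
    cell <- g$cell_of_atom[a]
    loopC[cell, ] <- loopC[cell, ] + b$C
    loopS[cell, ] <- loopS[cell, ] + b$S
  }
  scale <- max(abs(loopC))
  expect_lt(max(abs(sf$C - loopC)) / scale, 1e-12)
  expect_lt(max(abs(sf$S - loopS)) / scale, 1e-12)
  sysC <- colSums(sf$C)  # linearity: cells sum to the whole-system factor
  direct <- Reduce(`+`, lapply(seq_len(50), function(a)
    compute_basis(s$positions[a, ], s$charges[a], cub)$C))
  expect_equal(sysC, direct, tolerance = 1e-12)
})

test_that("remote structure-factor sums respect the shell classification", {
  s <- random_system(80, 25.6, seed = 32, neutralize = TRUE)
  grid <- assign_atoms_to_cells(s, build_cell_grid(s$box, 6.4))  # 4^3 cells
  groups <- glst:::calibrate_groups(build_alpha_groups(grid, 1e-3))
  nl <- build_cell_neighbor_list(grid, groups)
  sf <- compute_cell_structure_factors(grid, groups[[1]])

  # exhaustive small-grid check: remote sum equals the sum over the
  # classified cells, and never includes self or the 26-neighborhood
  for (cell in c(1, 14, 33, 64)) {
    rem <- sum_remote_structure_factors(cell, nl, sf, 1)
    idx <- nl$long[[1]][[cell]]
    expect_false(cell %in% idx)
    expect_true(all(!idx %in% nl$short[[cell]]))
    if (length(idx)) {
      expect_equal(rem$C, colSums(sf$C[idx, , drop = FALSE]), tolerance = 1e-13)
    } else {
      expect_equal(rem$C, numeric(sf$n_nodes))
    }
  }
  # weighted double-counting identity: sum over cells of (SF_cell . remote)
  # equals the symmetric pairwise cell-cell sum, node-wise
  pairsum <- 0; remsum <- 0
  for (cell in seq_len(64)) {
    rem <- sum_remote_structure_factors(cell, nl, sf, 1)
    remsum <- remsum + sum(sf$C[cell, ] * rem$C + sf$S[cell, ] * rem$S)
  }
  for (c1 in seq_len(64)) for (c2 in nl$long[[1]][[c1]])
    pairsum <- pairsum + sum(sf$C[c1, ] * sf$C[c2, ] + sf$S[c1, ] * sf$S[c2, ])
  expect_equal(remsum, pairsum, tolerance = 1e-12)
})

test_that("long-range energies match the erf pair kernel across cells", {
  # neutral-pair system in cells at Chebyshev separation 2
  co <- 3.2
  s <- cellsep_pair(0.8, -0.5, co, 2)
  grid <- assign_atoms_to_cells(s, build_cell_grid(s$box, co))
  groups <- glst:::calibrate_groups(build_alpha_groups(grid, 1e-5))
  lr <- long_range_energy_forces(grid, groups)
  g1 <- groups[[1]]
  r <- 2 * co
  e_ref <- KE * 0.8 * (-0.5) * pracma::erf(g1$alpha * r) / r
  tol <- KE * abs(0.8 * 0.5) * groups[[1]]$calibration$certified_error * 1.5
  expect_lt(abs(lr$per_atom_energy[1] - e_ref), tol)
  expect_lt(abs(lr$per_atom_energy[2] - e_ref), tol)
  expect_lt(abs(lr$total - e_ref), tol)
  # force equals the analytic derivative of the erf kernel; the pair
  # attracts, so atom 1 (left) is pulled along +x
  dkern <- (2 * g1$alpha / sqrt(pi)) * exp(-(g1$alpha * r)^2) / r -
    pracma::erf(g1$alpha * r) / r^2
  f_ref <- KE * 0.8 * (-0.5) * dkern
  expect_gt(f_ref, 0)
  expect_lt(abs(lr$forces[1, 1] - f_ref), 2 * tol)
  expect_equal(lr$forces[1, ], -lr$forces[2, ], tolerance = 1e-9)

  # all charges zero
  s0 <- particle_system(s$positions, c(0, 0), s$box)
  grid0 <- assign_atoms_to_cells(s0, build_cell_grid(s0$box, co))
  lr0 <- long_range_energy_forces(grid0, groups)
  expect_true(all(lr0$per_atom_energy == 0) && all(lr0$forces == 0))
})

test_that("prefix-sum remote summation equals the explicit neighbor-list route", {
  s <- random_system(120, 19.2, seed = 33, neutralize = TRUE)  # 6^3 cells
  grid <- assign_atoms_to_cells(s, build_cell_grid(s$box, 3.2))
  groups <- glst:::calibrate_groups(build_alpha_groups(grid, 1e-3))
  nl <- build_cell_neighbor_list(grid, groups)
  lr <- long_range_energy_forces(grid, groups, ke = 1)

  E_ref <- numeric(120)
  for (gi in seq_along(groups)) {
    cub <- groups[[gi]]$cubature
    sf <- compute_cell_structure_factors(grid, groups[[gi]])
    for (a in seq_len(120)) {
      cell <- grid$cell_of_atom[a]
      rem <- sum_remote_structure_factors(cell, nl, sf, gi)
      b <- compute_basis(s$positions[a, ], s$charges[a], cub)
      E_ref[a] <- E_ref[a] + sum(cub$weights * (b$C * rem$C + b$S * rem$S))
    }
  }
  expect_equal(lr$per_atom_energy, E_ref, tolerance = 1e-11)
})

test_that("short-range stage covers exactly the 27-cell neighborhood", {
  # two unit charges 1 A apart in one cell
  s <- particle_system(rbind(c(2, 2, 2), c(3, 2, 2)), c(1, 1), rep(12, 3))
  grid <- assign_atoms_to_cells(s, build_cell_grid(s$box, 4))
  sr <- short_range_energy_forces(grid)
  expect_equal(sr$total, KE, tolerance = 1e-12)
  expect_equal(sr$forces[1, ], c(-KE, 0, 0), tolerance = 1e-10)
  expect_equal(sr$forces[2, ], c(KE, 0, 0), tolerance = 1e-10)

  # a pair at separation >= 2 contributes nothing here
  s2 <- cellsep_pair(1, 1, 3, 2)
  grid2 <- assign_atoms_to_cells(s2, build_cell_grid(s2$box, 3))
  sr2 <- short_range_energy_forces(grid2)
  expect_equal(sr2$total, 0)
  expect_equal(sr2$n_pairs, 0)

  # 100-atom two-cell slab vs a naive classified loop
  set.seed(34)
  pos <- cbind(runif(100, 0.1, 12.7), runif(100, 0.1, 6.3),
               runif(100, 0.1, 6.3))
  q <- round(runif(100, -1, 1), 3)
  s3 <- particle_system(pos, q, c(32, 32, 32))
  grid3 <- assign_atoms_to_cells(s3, build_cell_grid(s3$box, 6.4))
  sr3 <- short_range_energy_forces(grid3)
  ref <- naive_short_range(pos, q, c(32, 32, 32), 6.4)
  expect_equal(sr3$total, ref$total, tolerance = 1e-12)
  expect_equal(sr3$per_atom_energy, ref$per_atom, tolerance = 1e-12)

  # coincident charged atoms trigger a singularity error naming the pair
  s4 <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, -1), rep(8, 3))
  grid4 <- assign_atoms_to_cells(s4, build_cell_grid(s4$box, 4))
  expect_error(short_range_energy_forces(grid4), "singularity.*1.*2")
})

test_that("the full pipeline reduces to direct Coulomb on small grids", {
  s <- build_salt_water_box(12, 1, 8, seed = 1)
  expect_equal(s$n_atoms, 38)
  res <- compute_total(s, 8, 1e-4)       # single cell
  ref <- direct_coulomb(s)
  expect_equal(res$per_atom_energy, ref$per_atom_energy, tolerance = 1e-13)
  expect_equal(res$forces, ref$forces, tolerance = 1e-13)
  expect_equal(res$meta$n_nodes_total, 0)

  res3 <- compute_total(s, 2.7, 1e-4)    # 2^3 grid, still no alpha groups
  expect_equal(res3$total_energy, ref$total_energy, tolerance = 1e-10)
})

test_that("energies scale quadratically and results are order-independent", {
  s <- random_system(150, 25.6, seed = 35, neutralize = TRUE)
  cfg <- list(kernel_epsilon = 1e-6)
  res <- compute_total(s, 6.4, 1e-4, cfg)
  # charge scaling: lambda^2 on energies and forces, exactly
  s2 <- particle_system(s$positions, 3 * s$charges, s$box)
  res2 <- compute_total(s2, 6.4, 1e-4, cfg)
  expect_equal(res2$per_atom_energy, 9 * res$per_atom_energy,
               tolerance = 1e-12)
  expect_equal(res2$forces, 9 * res$forces, tolerance = 1e-12)

  # atom order: results map back through the cell sort
  perm <- sample(150)
  s3 <- particle_system(s$positions[perm, ], s$charges[perm], s$box)
  res3 <- compute_total(s3, 6.4, 1e-4, cfg)
  expect_equal(res3$per_atom_energy, res$per_atom_energy[perm],
               tolerance = 1e-10)
  expect_equal(res3$forces, res$forces[perm, ], tolerance = 1e-10)

  # invariants of the result container
  expect_equal(sum(res$per_atom_energy), res$total_energy, tolerance = 1e-10)
  expect_equal(res$breakdown$short + sum(res$breakdown$long_groups),
               res$total_energy, tolerance = 1e-10)
})

test_that("translating the whole system changes energies only within tolerance", {
  set.seed(36)
  pos <- matrix(runif(180, 1.5, 24), 60, 3)
  q <- round(runif(60, -1, 1), 3); q <- q - mean(q)
  s <- particle_system(pos, q, rep(25.6, 3))
  cfg <- list(kernel_epsilon = 1e-4)
  res <- compute_total(s, 6.4, 1e-4, cfg)
  shift <- c(0.771, 0.411, 0.513)
  s2 <- particle_system(s$positions + rep(shift, each = 60), s$charges, s$box)
  res2 <- compute_total(s2, 6.4, 1e-4, cfg)
  # pairs reclassify across cell faces under translation, but exact trig
  # identities make the kernel depend only on pair separations: the total can
  # move by at most the certified residual times the pairwise charge scale
  qsum <- sum(abs(s$charges))
  cert <- max(res$meta$groups$certified_error,
              res2$meta$groups$certified_error)
  expect_lt(abs(res2$total_energy - res$total_energy), KE * cert * qsum^2)
})

test_that("net-force projection removes the translational component", {
  f <- matrix(rnorm(60), 20, 3)
  pf <- remove_net_force(f)
  expect_lt(max(abs(colSums(pf))), 1e-12 * max(abs(f)))
  expect_equal(pf, f - rep(colMeans(f), each = 20), tolerance = 1e-14)
  f0 <- f - rep(colMeans(f), each = 20)
  expect_equal(remove_net_force(f0), f0, tolerance = 1e-14)
  fc <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_true(all(abs(remove_net_force(fc)) < 1e-15))
})

test_that("operation counts double no faster than 2.2x with system size", {
  # doubling at fixed density and cutoff, far enough from the small-grid
  # regime that the shell structure stays stable (counts only, no passes)
  cfg <- list(kernel_epsilon = 1e-4)
  s1 <- build_salt_water_box(65275, 667, 128, seed = 5)
  p1 <- glst:::pipeline_groups(s1, 6.4, 1e-4, cfg)
  o1 <- glst:::count_operations(p1$grid, p1$groups)
  s2 <- build_salt_water_box(130550, 1334, 128 * 2^(1 / 3), seed = 6)
  p2 <- glst:::pipeline_groups(s2, 6.4, 1e-4, cfg)
  o2 <- glst:::count_operations(p2$grid, p2$groups)
  expect_equal(s2$n_atoms / s1$n_atoms, 2, tolerance = 0.01)
  expect_lt(o2$long_ops / o1$long_ops, 2.2)
})

test_that("single-precision trigonometry broadens errors without breaking them", {
  s <- random_system(80, 25.6, seed = 37, neutralize = TRUE)
  res_d <- compute_total(s, 6.4, 1e-4, list(kernel_epsilon = 1e-4))
  res_f <- compute_total(s, 6.4, 1e-4, list(kernel_epsilon = 1e-4,
                                            single_precision_trig = TRUE))
  dev <- res_f$per_atom_energy - res_d$per_atom_energy
  expect_gt(max(abs(dev)), 0)            # rounding is visible...
  expect_lt(max(abs(dev)), 1e-2)         # ...but stays at single-eps scale
  expect_lt(abs(res_f$total_energy - res_d$total_energy) /
              abs(res_d$total_energy), 1e-6)
})
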