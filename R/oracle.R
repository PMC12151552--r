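#' Brute-force all-pairs Coulomb reference
#'
#' O(N^2) evaluation of `ke q_a q_b / r` over every pair, with exact forces.
#' Per-atom energies are half-shares of the pair energies (the same
#' convention as the fast path, so comparisons are convention-free).
#'
#' @param system a [particle_system].
#' @param ke Coulomb constant (kcal*A/(mol*e^2)).
#' @return A `glst_result` (method `"direct"`).
#' @export
direct_coulomb <- function(system, ke = coulomb_constant()) {
  res <- cpp_direct_coulomb(system$positions, system$charges, ke)
  if (res$err_a > 0)
    stop_arg("singularity: atoms ", res$err_a, " and ", res$err_b,
             " are coincident with nonzero charge product")
  new_glst_result(per_atom_energy = res$energy, forces = res$force,
                  breakdown = list(short = sum(res$energy),
                                   long_groups = numeric(0)),
                  meta = list(n_atoms = system$n_atoms,
                              short_pairs = system$n_atoms * (system$n_atoms - 1) / 2),
                  method = "direct")
}

#' Brute-force atom-to-cell erf energy
#'
#' The literal long-range sum `q_a sum_b q_b erf(alpha r_ab) / r_ab` of an
#' atom against a set of remote atoms, in internal units (no Coulomb
#' constant). Used to test the cubature machinery independently of the full
#' pipeline.
#'
#' @param atom_position length-3 position (Angstrom).
#' @param atom_charge charge (e).
#' @param cell_positions m x 3 positions of the remote cell's atoms.
#' @param cell_charges their charges.
#' @param alpha Ewald convergence parameter (1/Angstrom).
#' @return The energy in e^2/Angstrom.
#' @export
direct_erf_energy <- function(atom_position, atom_charge, cell_positions,
                              cell_charges, alpha) {
  cell_positions <- as.matrix(cell_positions)
  d <- sweep(cell_positions, 2, as.numeric(atom_position))
  r <- sqrt(rowSums(d^2))
  atom_charge * sum(cell_charges * pracma::erf(alpha * r) / r)
}

#' Error metrics between two energy/force results
#'
#' Per-atom RMSE of energies and of each force component, normalized
#' variants (RMSE divided by the RMS of the reference quantity), signed
#' per-atom deviations, and a histogram of the energy deviations
#' (Freedman-Diaconis bins, falling back to a fixed count for degenerate
#' spreads). Also reports the single total-energy deviation.
#'
#' @param test,reference `glst_result` objects (or lists with
#'   `per_atom_energy` and `forces`) over the same atoms in the same order.
#' @return A `glst_error_report`.
#' @export
error_report <- function(test, reference) {
  if (length(test$per_atom_energy) != length(reference$per_atom_energy))
    stop_arg("results have different atom counts")
  de <- test$per_atom_energy - reference$per_atom_energy
  df <- test$forces - reference$forces
  rms <- function(x) sqrt(mean(x^2))
  rmse_f <- apply(df, 2, rms)
  ref_rms_e <- rms(reference$per_atom_energy)
  ref_rms_f <- rms(reference$forces)
  br <- tryCatch(graphics::hist(de, breaks = "FD", plot = FALSE),
                 error = function(e) NULL)
  if (is.null(br) || length(br$breaks) < 3)
    br <- graphics::hist(de, breaks = 20, plot = FALSE)
  structure(list(
    rmse_energy = rms(de),
    rmse_force = setNames(rmse_f, c("x", "y", "z")),
    normalized_rmse_energy = rms(de) / ref_rms_e,
    normalized_rmse_force = rms(as.numeric(df)) / ref_rms_f,
    total_energy_error = sum(test$per_atom_energy) - sum(reference$per_atom_energy),
    per_atom_energy_errors = de,
    per_atom_force_errors = df,
    histogram = list(breaks = br$breaks, counts = br$counts)),
    class = "glst_error_report")
}

#' @export
print.glst_error_report <- function(x, ...) {
  cat("error report (test vs reference)\n")
  cat(sprintf("  per-atom energy RMSE  %.4g kcal/mol (normalized %.4g)\n",
              x$rmse_energy, x$normalized_rmse_energy))
  cat(sprintf("  force RMSE x/y/z      %.4g / %.4g / %.4g kcal/mol/A\n",
              x$rmse_force[1], x$rmse_force[2], x$rmse_force[3]))
  cat(sprintf("  total energy error    %.4g kcal/mol\n", x$total_energy_error))
  invisible(x)
}
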