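#' Write per-atom results as tab-separated text
#'
#' Columns: id, element, charge, energy (kcal/mol), fx, fy, fz (kcal/mol/A).
#'
#' @param result a `glst_result`.
#' @param system the [particle_system] it was computed for (same order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, system, path) {
  df <- data.frame(id = seq_len(system$n_atoms), element = system$labels,
                   charge = system$charges,
                   energy = result$per_atom_energy,
                   fx = result$forces[, 1], fy = result$forces[, 2],
                   fz = result$forces[, 3])
  write.table(format(df, digits = 12, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

kv_block <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste0(prefix, nm)
    if (is.data.frame(v)) {
      for (i in seq_len(nrow(v)))
        out <- c(out, kv_block(as.list(v[i, ]), paste0(key, ".", i, ".")))
    } else if (is.list(v)) {
      out <- c(out, kv_block(v, paste0(key, ".")))
    } else if (!is.null(v)) {
      out <- c(out, paste0(key, " = ", paste(format(v, digits = 12), collapse = " ")))
    }
  }
  out
}

#' Write run metadata as a key-value text block
#'
#' Groups, alpha and zeta values, node counts, certified errors and
#' operation counts of a run, one `key = value` per line.
#'
#' @param result a `glst_result` from [compute_total()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(result, path) {
  lines <- c(sprintf("method = %s", result$method),
             sprintf("total_energy = %.12g", result$total_energy),
             sprintf("short_range_energy = %.12g", result$breakdown$short),
             sprintf("long_range_energy = %.12g",
                     sum(result$breakdown$long_groups)),
             kv_block(result$meta, "meta."))
  writeLines(lines, path)
  invisible(path)
}

#' Write an error report as tab-separated text plus a key-value block
#'
#' @param report a `glst_error_report`.
#' @param path output path for the summary block; histogram bins and counts
#'   are appended.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  lines <- c(sprintf("rmse_energy = %.12g", report$rmse_energy),
             sprintf("rmse_force_x = %.12g", report$rmse_force[1]),
             sprintf("rmse_force_y = %.12g", report$rmse_force[2]),
             sprintf("rmse_force_z = %.12g", report$rmse_force[3]),
             sprintf("normalized_rmse_energy = %.12g",
                     report$normalized_rmse_energy),
             sprintf("normalized_rmse_force = %.12g",
                     report$normalized_rmse_force),
             sprintf("total_energy_error = %.12g", report$total_energy_error),
             "histogram_breaks = " |> paste0(paste(
               format(report$histogram$breaks, digits = 8), collapse = " ")),
             "histogram_counts = " |> paste0(paste(report$histogram$counts,
                                                   collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
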