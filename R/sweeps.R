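# Benchmark sweeps. Performance is reported as hardware-independent
# operation counts: the long-range count is atom x node products over the
# two passes (structure factors + energy), 2 * N * total nodes; the
# short-range count is the exact number of interacting pairs.

count_operations <- function(grid, groups) {
  n <- grid$system$n_atoms
  nodes <- vapply(groups, function(g) g$cubature$n_nodes, 0)
  short_pairs <- if (max(grid$n_cells) < 4L) n * (n - 1) / 2 else
    cpp_short_pair_count(grid$n_cells, as.integer(grid$cell_count))
  list(n_nodes_total = sum(nodes), nodes_per_group = nodes,
       long_ops = 2 * n * sum(nodes), short_pairs = short_pairs,
       total_ops = 2 * n * sum(nodes) + short_pairs)
}

fit_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2 || length(unique(x[ok])) < 2)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                degenerate = TRUE))
  fit <- lm(y[ok] ~ x[ok])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, degenerate = FALSE)
}

new_sweep <- function(axis, rows, fit = NULL) {
  structure(list(axis = axis, rows = rows, fit = fit), class = "glst_sweep")
}

#' @export
print.glst_sweep <- function(x, ...) {
  cat(sprintf("glst_sweep over %s (%d points)\n", x$axis, nrow(x$rows)))
  print(x$rows, row.names = FALSE)
  if (!is.null(x$fit) && !isTRUE(x$fit$degenerate))
    cat(sprintf("linear fit: ops = %.4g * N + %.4g, R^2 = %.5f\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  else if (!is.null(x$fit))
    cat("linear fit: degenerate (needs >= 2 distinct points)\n")
  invisible(x)
}

run_validation <- function(system, cutoff, epsilon, config) {
  res <- compute_total(system, cutoff, epsilon, config)
  ref <- direct_coulomb(system, ke = config$ke %||% coulomb_constant())
  error_report(res, ref)
}

#' Sweep over system size
#'
#' Builds each recipe's box, calibrates the cubatures, and records node and
#' operation counts; optionally validates against the O(N^2) direct oracle
#' for systems up to `oracle_max_n` atoms (larger ones are skipped with a
#' note). A linear fit of the long-range operation count versus N quantifies
#' the O(N) scaling hardware-independently.
#'
#' @param recipes data.frame with columns `n_water`, `n_nacl`, `box_edge`
#'   (rows of [table1_recipes()]).
#' @param epsilon target error threshold.
#' @param cutoff direct-space cutoff (Angstrom), or a function of the box
#'   edge returning one.
#' @param seed base seed (row i uses `seed + i`).
#' @param validate also run the energy passes and the direct oracle.
#' @param oracle_max_n largest system the oracle is run on.
#' @param config passed to [compute_total()].
#' @return A `glst_sweep` over `n_atoms` with a linear fit of `long_ops`.
#' @export
sweep_size <- function(recipes, epsilon, cutoff, seed = 1, validate = FALSE,
                       oracle_max_n = 30000, config = list()) {
  rows <- lapply(seq_len(nrow(recipes)), function(i) {
    rec <- recipes[i, ]
    co <- if (is.function(cutoff)) cutoff(rec$box_edge) else cutoff
    sys <- build_salt_water_box(rec$n_water, rec$n_nacl, rec$box_edge,
                                seed = seed + i)
    pipe <- pipeline_groups(sys, co, epsilon, config)
    ops <- count_operations(pipe$grid, pipe$groups)
    row <- data.frame(n_atoms = sys$n_atoms, box_edge = rec$box_edge,
                      cutoff = co, n_groups = length(pipe$groups),
                      n_nodes_total = ops$n_nodes_total,
                      long_ops = ops$long_ops, short_pairs = ops$short_pairs,
                      total_ops = ops$total_ops,
                      rmse_energy = NA_real_, rmse_force = NA_real_,
                      note = "")
    if (validate) {
      if (sys$n_atoms <= oracle_max_n) {
        rep <- run_validation(sys, co, epsilon, config)
        row$rmse_energy <- rep$rmse_energy
        row$rmse_force <- max(rep$rmse_force)
      } else row$note <- "oracle skipped (n_atoms above oracle_max_n)"
    }
    row
  })
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$n_atoms), ]
  new_sweep("n_atoms", rows, fit_line(rows$n_atoms, rows$long_ops))
}

#' Sweep over the target error threshold
#'
#' For a fixed system and cutoff, calibrates at each threshold and records
#' node counts; optionally compares against the direct oracle. Node counts
#' are non-increasing as the threshold loosens, and the measured RMSE is
#' non-increasing as it tightens (until the double-precision floor).
#'
#' @param system a [particle_system].
#' @param cutoff direct-space cutoff (Angstrom).
#' @param epsilons thresholds to test.
#' @param validate also run the energy passes and the direct oracle.
#' @param config passed to [compute_total()].
#' @return A `glst_sweep` over `epsilon`.
#' @export
sweep_threshold <- function(system, cutoff, epsilons, validate = TRUE,
                            config = list()) {
  ref <- if (validate) direct_coulomb(system,
                                      ke = config$ke %||% coulomb_constant())
  rows <- lapply(sort(epsilons), function(eps) {
    row <- data.frame(epsilon = eps, n_groups = NA_integer_,
                      n_nodes_total = NA_real_, long_ops = NA_real_,
                      rmse_energy = NA_real_, rmse_force = NA_real_,
                      note = "")
    ok <- tryCatch({
      pipe <- pipeline_groups(system, cutoff, eps, config)
      ops <- count_operations(pipe$grid, pipe$groups)
      row$n_groups <- length(pipe$groups)
      row$n_nodes_total <- ops$n_nodes_total
      row$long_ops <- ops$long_ops
      if (validate) {
        res <- compute_total(system, cutoff, eps, config)
        rep <- error_report(res, ref)
        row$rmse_energy <- rep$rmse_energy
        row$rmse_force <- max(rep$rmse_force)
      }
      TRUE
    }, error = function(e) {
      row$note <<- conditionMessage(e)
      FALSE
    })
    row
  })
  new_sweep("epsilon", do.call(rbind, rows))
}

#' Sweep over the direct-space cutoff
#'
#' Splits the operation count into the short-range pair count and the
#' long-range atom x node count per cutoff, exposing the U-shaped total cost
#' curve with its interior optimum. Cutoffs larger than a box edge are
#' recorded as invalid points rather than errors.
#'
#' @param system a [particle_system].
#' @param epsilon target error threshold.
#' @param cutoffs cutoff distances to test (Angstrom).
#' @param validate also compare against the direct oracle per cutoff.
#' @param config passed to [compute_total()].
#' @return A `glst_sweep` over `cutoff`.
#' @export
sweep_cutoff <- function(system, epsilon, cutoffs, validate = FALSE,
                         config = list()) {
  ref <- if (validate) direct_coulomb(system,
                                      ke = config$ke %||% coulomb_constant())
  rows <- lapply(sort(cutoffs), function(co) {
    row <- data.frame(cutoff = co, n_cells_max = NA_integer_,
                      n_groups = NA_integer_, n_nodes_total = NA_real_,
                      long_ops = NA_real_, short_pairs = NA_real_,
                      total_ops = NA_real_, rmse_energy = NA_real_,
                      rmse_force = NA_real_, note = "")
    if (co > min(system$box)) {
      row$note <- "invalid: cutoff exceeds box"
      return(row)
    }
    pipe <- pipeline_groups(system, co, epsilon, config)
    ops <- count_operations(pipe$grid, pipe$groups)
    row$n_cells_max <- max(pipe$grid$n_cells)
    row$n_groups <- length(pipe$groups)
    row$n_nodes_total <- ops$n_nodes_total
    row$long_ops <- ops$long_ops
    row$short_pairs <- ops$short_pairs
    row$total_ops <- ops$total_ops
    if (validate) {
      rep <- run_validation(system, co, epsilon, config)
      row$rmse_energy <- rep$rmse_energy
      row$rmse_force <- max(rep$rmse_force)
    }
    row
  })
  new_sweep("cutoff", do.call(rbind, rows))
}
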