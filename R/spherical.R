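# Angular component of the cubature: antipodally symmetric point sets on the
# unit sphere with weights summing to 1, stored as the upper hemisphere (the
# lower half is implied by symmetry; even integrands only need one half).
# An equal-weight set certified to integrate all spherical harmonics through
# degree t is a spherical t-design; the general constructor used by
# calibration is a weighted Gauss-Legendre (in cos theta) x equispaced
# azimuth product rule with the same exactness and node economy.

# upper-hemisphere membership under the deterministic tie rule:
# z > 0, or z == 0 and (y > 0, or y == 0 and x > 0)
upper_hemisphere <- function(points, tol = 1e-12) {
  z <- points[, 3]; y <- points[, 2]; x <- points[, 1]
  z > tol | (abs(z) <= tol & (y > tol | (abs(y) <= tol & x > 0)))
}

new_spherical_rule <- function(points, weights, strength, kind) {
  points <- as.matrix(points)
  nrm <- sqrt(rowSums(points^2))
  points <- points / nrm
  structure(list(strength = as.integer(strength),
                 m_hemisphere = nrow(points),
                 points = unname(points),
                 weights = as.numeric(weights),
                 equal_weight = max(abs(weights - mean(weights))) < 1e-12,
                 kind = kind),
            class = "spherical_design")
}

#' @export
print.spherical_design <- function(x, ...) {
  cat(sprintf("spherical_design (%s): strength %d, %d hemisphere points%s\n",
              x$kind, x$strength, x$m_hemisphere,
              if (x$equal_weight) ", equal weights" else ", weighted"))
  invisible(x)
}

# full antipodal set (point and mate) with weights halved; used by the
# harmonic certification
full_symmetric_set <- function(design) {
  list(points = rbind(design$points, -design$points),
       weights = rep(design$weights / 2, 2))
}

# real orthonormal spherical harmonics of degree l at unit points;
# returns a (2l+1) x M matrix. Uses the associated Legendre functions from
# pracma (Condon-Shortley phase; irrelevant for residual magnitudes).
real_harmonics <- function(l, points) {
  z <- pmin(1, pmax(-1, points[, 3]))
  phi <- atan2(points[, 2], points[, 1])
  P <- pracma::legendre(l, z)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(z))
  out <- matrix(0, 2 * l + 1, length(z))
  norm0 <- sqrt((2 * l + 1) / (4 * pi))
  out[1, ] <- norm0 * P[1, ]
  if (l >= 1) {
    for (m in 1:l) {
      nm <- norm0 * exp(0.5 * (lgamma(l - m + 1) - lgamma(l + m + 1)))
      out[2 * m, ] <- sqrt(2) * nm * P[m + 1, ] * cos(m * phi)
      out[2 * m + 1, ] <- sqrt(2) * nm * P[m + 1, ] * sin(m * phi)
    }
  }
  out
}

#' Certify the integration strength of a spherical point set
#'
#' Computes, over the full antipodally symmetric set, the weighted mean of
#' every real spherical harmonic of degree 1..t and returns the maximum
#' absolute value. A true t-design (or exact product rule) gives residuals at
#' machine precision; odd degrees vanish identically by antipodal symmetry
#' (asserted).
#'
#' @param design a `spherical_design`.
#' @param strength degree t up to which to test.
#' @return Maximum absolute harmonic residual (the caller compares it to a
#'   tolerance), with per-degree values in attribute `"by_degree"`.
#' @export
validate_design <- function(design, strength) {
  if (!inherits(design, "spherical_design") || design$m_hemisphere < 1)
    stop_arg("design must be a nonempty spherical_design")
  full <- full_symmetric_set(design)
  by_degree <- numeric(strength)
  for (l in seq_len(strength)) {
    Y <- real_harmonics(l, full$points)
    r <- as.numeric(Y %*% full$weights)
    by_degree[l] <- max(abs(r))
    if (l %% 2 == 1 && by_degree[l] > 1e-10)
      stop("antipodal symmetry violated: odd degree ", l,
           " harmonic mean is ", signif(by_degree[l], 3), call. = FALSE)
  }
  structure(max(by_degree, 0), by_degree = by_degree)
}

#' Weighted spherical product rule exact through degree t
#'
#' Gauss-Legendre nodes in cos(theta) crossed with an even number of
#' equispaced azimuths: integrates every spherical harmonic of degree <= t
#' exactly, is antipodally symmetric, and has about (t+1)^2/2 points on the
#' hemisphere -- the same economy as a symmetric t-design, but constructible
#' deterministically at any strength.
#'
#' @param strength target exactness degree t >= 1.
#' @return A `spherical_design` with per-point weights (kind `"product"`).
#' @export
spherical_product_rule <- function(strength) {
  t <- as.integer(strength)
  if (t < 1) stop_arg("strength must be >= 1")
  L <- ceiling((t + 1) / 2)
  gl <- pracma::gaussLegendre(L, -1, 1)
  nphi <- t + 1L
  if (nphi %% 2L == 1L) nphi <- nphi + 1L
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi + pi / (2 * nphi)  # avoid axis ties
  z <- rep(gl$x, each = nphi)
  w <- rep(gl$w / 2, each = nphi) / nphi   # full-sphere mean weights, sum 1
  s <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(s * cos(rep(phi, L)), s * sin(rep(phi, L)), z)
  keep <- upper_hemisphere(pts)
  new_spherical_rule(pts[keep, , drop = FALSE], 2 * w[keep], t, "product")
}

#' Load a spherical design from a text point file
#'
#' One `x y z` unit vector per line (the convention of published design
#' tables), full sphere or hemisphere. Full-sphere files must be antipodally
#' symmetric; points are collapsed to the upper hemisphere.
#'
#' @param path file path (or connection readable by [read.table()]).
#' @param strength if given, the design is certified to this strength at
#'   tolerance 1e-9 (error if it fails); if `NULL` the largest certifiable
#'   strength up to 30 is determined.
#' @return A `spherical_design` with equal weights.
#' @export
load_spherical_design <- function(path, strength = NULL) {
  tab <- as.matrix(read.table(path))
  if (ncol(tab) != 3) stop_arg("format error: expected three columns x y z")
  nrm <- sqrt(rowSums(tab^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_arg("format error: point ", which(abs(nrm - 1) > 1e-6)[1],
             " has norm ", signif(nrm[which(abs(nrm - 1) > 1e-6)[1]], 6),
             " (not a unit vector)")
  pts <- tab / nrm
  n <- nrow(pts)
  # pair up antipodes
  mate <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(pts, 2, -pts[i, ])^2))
    j <- which(d < 1e-8)
    mate[i] <- if (length(j)) j[1] else 0L
  }
  if (any(mate > 0)) {
    if (any(mate == 0))
      stop_arg("symmetry error: point ", which(mate == 0)[1],
               " has no antipodal mate in a symmetric full-sphere file")
    keep <- upper_hemisphere(pts)
    if (sum(keep) * 2 != n)
      stop_arg("symmetry error: antipodal pairing is inconsistent")
    hemi <- pts[keep, , drop = FALSE]
  } else {
    flip <- !upper_hemisphere(pts)
    pts[flip, ] <- -pts[flip, , drop = FALSE]
    hemi <- pts
  }
  M <- nrow(hemi)
  des <- new_spherical_rule(hemi, rep(1 / M, M), 0L, "design")
  if (!is.null(strength)) {
    res <- validate_design(des, strength)
    if (res > 1e-9)
      stop_arg("design fails certification at strength ", strength,
               " (residual ", signif(res, 3), ")")
    des$strength <- as.integer(strength)
  } else {
    t_ok <- 0L
    for (t in 1:30) {
      if (as.numeric(validate_design(des, t)) <= 1e-9) t_ok <- t else break
    }
    if (t_ok == 0L) stop_arg("point set is not even a 1-design at tolerance 1e-9")
    des$strength <- t_ok
  }
  des
}

#' Generate an equal-weight spherical t-design by seeded optimization
#'
#' Minimizes the sum of squared harmonic means of degrees 1..t over an
#' antipodally symmetric equal-weight point set (hemisphere points
#' parameterized by spherical angles), restarting from random
#' configurations and growing the point count when infeasible. The result is
#' certified by [validate_design()] at tolerance 1e-9 and is deterministic
#' for a fixed seed. Practical for small strengths (roughly t <= 9); the
#' calibration pipeline uses [spherical_product_rule()] at large strengths.
#'
#' @param strength target design strength t >= 1.
#' @param n_points_hint starting hemisphere point count (default
#'   `ceiling((t+1)^2/4)`, near the minimal symmetric size).
#' @param seed integer seed.
#' @param max_restarts random restarts per point count.
#' @param max_grow how many times the point count may be increased.
#' @return A `spherical_design` with equal weights (kind `"design"`).
#' @export
generate_spherical_design <- function(strength, n_points_hint = NULL, seed = 0,
                                      max_restarts = 25, max_grow = 4) {
  t <- as.integer(strength)
  if (t < 1) stop_arg("strength must be >= 1")
  M <- max(1L, as.integer(n_points_hint %||% ceiling((t + 1)^2 / 4)))
  evens <- seq(2, t, by = 2)
  objective <- function(par) {
    theta <- par[1:(length(par) / 2)]
    phi <- par[-(1:(length(par) / 2))]
    st <- sin(theta)
    pts <- cbind(st * cos(phi), st * sin(phi), cos(theta))
    tot <- 0
    for (l in evens) {
      Y <- real_harmonics(l, pts)
      tot <- tot + sum((rowMeans(Y))^2)
    }
    tot
  }
  search <- function() {
    best_residual <- Inf
    for (grow in 0:max_grow) {
      for (restart in seq_len(max_restarts)) {
        par0 <- c(acos(runif(M, -1, 1)), runif(M, 0, 2 * pi))
        opt <- optim(par0, objective, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-16))
        if (opt$value < 1e-22) {
          theta <- opt$par[1:M]; phi <- opt$par[-(1:M)]
          st <- sin(theta)
          pts <- cbind(st * cos(phi), st * sin(phi), cos(theta))
          flip <- !upper_hemisphere(pts)
          pts[flip, ] <- -pts[flip, , drop = FALSE]
          des <- new_spherical_rule(pts, rep(1 / M, M), t, "design")
          res <- as.numeric(validate_design(des, t))
          best_residual <- min(best_residual, res)
          if (res <= 1e-9) return(des)
        } else {
          best_residual <- min(best_residual, sqrt(opt$value))
        }
      }
      M <<- M + 1L
    }
    stop_arg("design generation failed for strength ", t,
             ": best residual ", signif(best_residual, 3),
             " after ", max_restarts, " restarts x ", max_grow + 1,
             " point counts")
  }
  with_seed(seed, search())
}
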