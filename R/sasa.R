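## Solvent-accessible surface areas.
##
## sasa_exact(): Lee-Richards construction -- each atom's accessible
## area is the integral over z of R * alpha(z), where alpha(z) is the
## accessible arc (radians) of the atom's expanded circle at height z
## after removing arcs covered by neighbouring expanded spheres.  The
## z-integral is evaluated by adaptive quadrature on intervals split
## at geometric breakpoints (neighbour sphere extents and
## tangency heights located by root finding), so two-body systems are
## resolved essentially to machine precision.
##
## sasa_pairwise_approx(): Street-Mayo style contact-area
## approximation -- A_i = A_isolated - sum_j b_ij with b_ij the
## analytic two-sphere lens (buried cap) area.  Exact for isolated
## atoms and any two-body system; with multiple mutual overlaps the
## buried areas double-count, which is the price of a strictly
## pairwise decomposition.

sasa_radii <- function(atoms, probe) atoms$radius + probe

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gl_rule <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    rule <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
    cache[[key]] <<- rule
    rule
  }
})

## Adaptive quadrature by interval bisection with embedded 15/31 point
## Gauss-Legendre rules; robust to the kinked integrands that arise
## from arc-coverage functions.
adaptive_gl <- function(f, a, b, tol = 1e-9, depth = 0) {
  r1 <- gl_rule(15); r2 <- gl_rule(31)
  mid <- (a + b) / 2; half <- (b - a) / 2
  v1 <- half * sum(r1$w * f(mid + half * r1$x))
  v2 <- half * sum(r2$w * f(mid + half * r2$x))
  if (abs(v2 - v1) < max(tol, 1e-8) || depth >= 5)
    return(v2)
  adaptive_gl(f, a, mid, 0.7 * tol, depth + 1) +
    adaptive_gl(f, mid, b, 0.7 * tol, depth + 1)
}

## Analytic area of the cap of sphere (c1, R1) buried inside sphere
## (c2, R2); centers distance d apart.
cap_buried_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(0)
  if (d <= abs(R1 - R2)) {
    if (R2 >= R1) return(4 * pi * R1^2)  # fully engulfed
    return(0)                            # neighbour inside: no burial
  }
  x <- (d^2 + R1^2 - R2^2) / (2 * d)
  h <- R1 - x
  2 * pi * R1 * h
}

#' Exact solvent-accessible surface area (Lee-Richards)
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `radius` (A).
#' @param probe probe radius, A (default 1.4).
#' @param analytic_pairs when an atom's expanded sphere intersects
#'   exactly one neighbour, evaluate the slice integral in its exact
#'   closed form (a spherical cap) instead of by quadrature (default
#'   TRUE; set FALSE to force quadrature everywhere, e.g. to
#'   cross-check the closed form).
#' @return numeric vector of per-atom accessible areas, A^2.
#' @export
sasa_exact <- function(atoms, probe = 1.4, analytic_pairs = TRUE) {
  n <- nrow(atoms)
  if (is.null(n) || n == 0) return(numeric(0))
  R <- sasa_radii(atoms, probe)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- R[i]
    ci <- xyz[i, ]
    ## neighbours whose expanded spheres can intersect atom i's
    d3 <- sqrt(colSums((t(xyz) - ci)^2))
    nb <- which(d3 < Ri + R & seq_len(n) != i)
    ## engulfed by any single neighbour?
    if (any(d3[nb] + Ri <= R[nb])) { out[i] <- 0; next }
    if (length(nb) == 0) { out[i] <- 4 * pi * Ri^2; next }
    if (length(nb) == 1 && analytic_pairs) {
      ## one neighbour: the slice integral reduces exactly to the
      ## analytic spherical-cap (lens) area
      out[i] <- 4 * pi * Ri^2 - cap_buried_area(Ri, R[nb], d3[nb])
      next
    }
    cj <- xyz[nb, , drop = FALSE]
    Rj <- R[nb]
    dxy <- sqrt((cj[, 1] - ci[1])^2 + (cj[, 2] - ci[2])^2)
    zj <- cj[, 3]
    theta_nb <- atan2(cj[, 2] - ci[2], cj[, 1] - ci[1])
    alpha <- function(z) {
      ## accessible arc (radians) of atom i's circle at height z
      rho_i2 <- Ri^2 - (z - ci[3])^2
      if (rho_i2 <= 0) return(2 * pi)
      rho_i <- sqrt(rho_i2)
      rho_j2 <- Rj^2 - (z - zj)^2
      act <- rho_j2 > 0
      if (!any(act)) return(2 * pi)
      rho_j <- sqrt(rho_j2[act])
      d <- dxy[act]
      if (any(d + rho_i <= rho_j)) return(0)   # circle fully covered
      occ <- d < rho_i + rho_j & d + rho_j > rho_i
      if (!any(occ)) return(2 * pi)
      cv <- (d[occ]^2 + rho_i^2 - rho_j[occ]^2) / (2 * d[occ] * rho_i)
      cv[cv > 1] <- 1; cv[cv < -1] <- -1
      phi <- acos(cv)
      theta <- theta_nb[act][occ]
      ## union length of angular intervals on the circle
      lo_a <- (theta - phi) %% (2 * pi)
      hi_a <- (theta + phi) %% (2 * pi)
      wrap <- lo_a > hi_a
      sa <- c(lo_a, if (any(wrap)) rep(0, sum(wrap)))
      sb <- c(ifelse(wrap, 2 * pi, hi_a), if (any(wrap)) hi_a[wrap])
      o <- base::order(sa)
      sa <- sa[o]; sb <- sb[o]
      tot <- 0; cur_a <- sa[1]; cur_b <- sb[1]
      if (length(sa) > 1) for (r in 2:length(sa)) {
        if (sa[r] <= cur_b) cur_b <- max(cur_b, sb[r])
        else { tot <- tot + (cur_b - cur_a); cur_a <- sa[r]; cur_b <- sb[r] }
      }
      tot <- tot + (cur_b - cur_a)
      max(0, 2 * pi - tot)
    }
    lo <- ci[3] - Ri; hi <- ci[3] + Ri
    ## breakpoints: neighbour sphere extents + tangency heights
    brk <- c(zj - Rj, zj + Rj)
    for (k in seq_along(nb)) {
      g1 <- function(z) sqrt(max(0, Ri^2 - (z - ci[3])^2)) +
        sqrt(max(0, Rj[k]^2 - (z - zj[k])^2)) - dxy[k]
      g2 <- function(z) abs(sqrt(max(0, Ri^2 - (z - ci[3])^2)) -
        sqrt(max(0, Rj[k]^2 - (z - zj[k])^2))) - dxy[k]
      for (g in list(g1, g2)) {
        zs <- seq(lo, hi, length.out = 101)
        gv <- vapply(zs, g, numeric(1))
        sc <- which(diff(sign(gv)) != 0)
        for (s in sc) {
          r <- try(stats::uniroot(g, c(zs[s], zs[s + 1]),
                                  tol = 1e-12)$root, silent = TRUE)
          if (!inherits(r, "try-error")) brk <- c(brk, r)
        }
      }
    }
    brk <- sort(unique(base::pmax(lo, base::pmin(hi, brk))))
    brk <- c(lo, brk[brk > lo & brk < hi], hi)
    ## integrate in latitude t (z = z_i + R sin t): removes the
    ## square-root behaviour of the integrand at the sphere poles
    tbrk <- asin(base::pmax(-1, base::pmin(1, (brk - ci[3]) / Ri)))
    f_t <- function(tv)
      vapply(tv, function(t) alpha(ci[3] + Ri * sin(t)) * cos(t),
             numeric(1))
    area <- 0
    for (s in seq_len(length(tbrk) - 1)) {
      if (tbrk[s + 1] - tbrk[s] < 1e-12) next
      area <- area + adaptive_gl(f_t, tbrk[s], tbrk[s + 1], tol = 1e-7)
    }
    out[i] <- Ri^2 * area
  }
  out
}

#' Pairwise contact-area approximation to the accessible surface
#'
#' A_i = A_isolated,i - sum_j b_ij, with b_ij the analytic buried-cap
#' (lens) area of atom i against neighbour j, clamped at zero.  The
#' burial sum decomposes exactly over atom (and hence residue) pairs,
#' which is what makes a pairwise surface energy matrix possible.
#'
#' @param atoms data.frame with `x`, `y`, `z`, `radius`.
#' @param probe probe radius, A.
#' @param clamp clamp per-atom areas at zero (default TRUE).
#' @return numeric vector of per-atom areas, A^2.
#' @export
sasa_pairwise_approx <- function(atoms, probe = 1.4, clamp = TRUE) {
  n <- nrow(atoms)
  if (is.null(n) || n == 0) return(numeric(0))
  R <- sasa_radii(atoms, probe)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  iso <- 4 * pi * R^2
  out <- iso
  if (n > 1) {
    dm <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        out[i] <- out[i] - cap_buried_area(R[i], R[j], dm[i, j])
      }
    }
  }
  if (clamp) out <- base::pmax(0, out)
  out
}

## sigma-weighted buried-area cross term between two atom groups:
## sum over i in A, j in B of sigma_i b_ij + sigma_j b_ji.
## The (negative of the) scale times this is the pair surface energy.
surface_cross_burial <- function(atoms_a, atoms_b, probe = 1.4) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) return(0)
  Ra <- sasa_radii(atoms_a, probe); Rb <- sasa_radii(atoms_b, probe)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  tot <- 0
  for (i in seq_len(nrow(atoms_a))) {
    d <- sqrt(rowSums((xb - matrix(xa[i, ], nrow(xb), 3, byrow = TRUE))^2))
    for (j in seq_len(nrow(atoms_b))) {
      if (d[j] >= Ra[i] + Rb[j]) next
      tot <- tot + atoms_a$sigma_solv[i] * cap_buried_area(Ra[i], Rb[j], d[j]) +
                   atoms_b$sigma_solv[j] * cap_buried_area(Rb[j], Ra[i], d[j])
    }
  }
  tot
}

## Linear (unclamped) surface energy of one atom group:
## sum_i sigma_i A_iso,i minus all intra-group sigma-weighted burials.
surface_self_energy <- function(atoms, probe = 1.4) {
  if (nrow(atoms) == 0) return(0)
  R <- sasa_radii(atoms, probe)
  e <- sum(atoms$sigma_solv * 4 * pi * R^2)
  if (nrow(atoms) > 1) {
    dm <- as.matrix(stats::dist(as.matrix(atoms[, c("x", "y", "z")])))
    for (i in seq_len(nrow(atoms)))
      for (j in seq_len(nrow(atoms)))
        if (i != j)
          e <- e - atoms$sigma_solv[i] * cap_buried_area(R[i], R[j], dm[i, j])
  }
  e
}

#' Surface (solvation) energy from areas and atom classes
#'
#' @param areas per-atom accessible areas, A^2.
#' @param classes atom class labels (see [SOLVATION_SIGMA]) or a
#'   numeric vector of per-atom coefficients.
#' @param surface_scale overall scale factor.
#' @return kcal/mol.
#' @export
surface_energy <- function(areas, classes, surface_scale = 1) {
  if (any(areas < 0)) stop("negative area")
  sig <- if (is.numeric(classes)) classes
         else unname(SOLVATION_SIGMA[classes])
  surface_scale * sum(sig * areas)
}
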