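# Backbone dihedrals, Ramachandran tabulation and Boltzmann-weighted angle
# summaries.
#
# phi_i = C(i-1)-N(i)-CA(i)-C(i);  psi_i = N(i)-CA(i)-C(i)-N(i+1).
# Angles are reported in degrees in (-180, 180], IUPAC sign convention;
# phi is undefined at the amino terminus and psi at the carboxy terminus.

#' Signed torsion angle of four points
#'
#' atan2 formulation of the IUPAC torsion; degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstroms.
#' @return angle in degrees.
#' @export
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # trans: 180
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop2("dihedral: collinear points, torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  wrap180(rad2deg(atan2(y, x)))
}

#' Backbone phi/psi dihedrals of a conformer
#'
#' @param conformer a `"conformer"` with a complete backbone map.
#' @return `data.frame` of class `"dihedral_set"` with columns `residue`,
#'   `phi`, `psi` (degrees; `NA` at the termini).
#' @export
phi_psi <- function(conformer) {
  bb <- conformer$backbone
  if (is.null(bb)) stop2("phi_psi: conformer has no backbone map")
  xyz <- coords(conformer)
  res <- bb$residues
  n <- nrow(res)
  at <- function(i) {
    if (is.na(i)) stop2("phi_psi: missing backbone atom")
    xyz[i + 1L, ]
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C"))
      if (is.na(res[[nm]][i]))
        stop2("phi_psi: missing backbone atom ", nm, " in residue ", i)
    if (i > 1)
      phi[i] <- dihedral(at(res$C[i - 1]), at(res$N[i]), at(res$CA[i]),
                         at(res$C[i]))
    if (i < n)
      psi[i] <- dihedral(at(res$N[i]), at(res$CA[i]), at(res$C[i]),
                         at(res$N[i + 1]))
  }
  structure(data.frame(residue = seq_len(n), phi = phi, psi = psi),
            class = c("dihedral_set", "data.frame"))
}

#' Weighted circular mean of angles
#'
#' Angles are mapped to unit vectors, combined as a weighted vector sum and
#' mapped back with atan2 -- the correct average at the +/-180 degree seam,
#' where an arithmetic mean breaks (170 and -170 average to 180, not 0).
#'
#' @param angles degrees.
#' @param weights non-negative weights, positive sum.
#' @return mean angle in degrees in (-180, 180], or `NA` when the resultant
#'   vector vanishes (antipodal tie).
#' @export
circular_weighted_mean <- function(angles, weights) {
  ok <- !is.na(angles)
  angles <- angles[ok]; weights <- weights[ok]
  if (!length(angles)) return(NA_real_)
  th <- deg2rad(angles)
  x <- sum(weights * cos(th))
  y <- sum(weights * sin(th))
  if (sqrt(x^2 + y^2) < 1e-12 * sum(weights)) return(NA_real_)
  wrap180(rad2deg(atan2(y, x)))
}

#' Ramachandran points and Boltzmann-weighted angle summary
#'
#' Collects (phi, psi) for every conformer and residue together with the
#' conformer's Boltzmann weight, and computes per-residue Boltzmann-weighted
#' mean angles.  The default averaging is the weighted circular (vector)
#' mean; `method = "arithmetic"` is available for comparison but breaks at
#' the +/-180 seam.
#'
#' @param weighted a `"weighted_ensemble"` whose conformers carry backbone
#'   maps over the same residues.
#' @param method `"circular"` (default) or `"arithmetic"`.
#' @return object of class `"ramachandran_summary"`: list with `points`
#'   (data.frame: conformer, residue, phi, psi, weight, region) and
#'   `weighted_angles` (data.frame: residue, phi, psi).
#' @export
ramachandran_summary <- function(weighted,
                                 method = c("circular", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(inherits(weighted, "weighted_ensemble"))
  confs <- weighted$ensemble$conformers
  pts <- do.call(rbind, lapply(seq_along(confs), function(i) {
    ds <- phi_psi(confs[[i]])
    data.frame(conformer = confs[[i]]$id, residue = ds$residue,
               phi = ds$phi, psi = ds$psi, weight = weighted$weights[i],
               letter = strsplit(confs[[i]]$sequence, "")[[1]][ds$residue])
  }))
  pts$region <- mapply(rama_region, pts$phi, pts$psi, pts$letter)
  n_res <- max(pts$residue)
  avg <- function(a, w) {
    if (method == "circular") circular_weighted_mean(a, w)
    else if (all(is.na(a))) NA_real_
    else weighted_mean(a[!is.na(a)], w[!is.na(a)])
  }
  wa <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    sel <- pts$residue == r
    data.frame(residue = r,
               phi = avg(pts$phi[sel], pts$weight[sel]),
               psi = avg(pts$psi[sel], pts$weight[sel]))
  }))
  structure(list(points = pts, weighted_angles = wa,
                 fragment = weighted$ensemble$fragment, method = method),
            class = "ramachandran_summary")
}

#' Label a Ramachandran point
#'
#' `"alpha"` for phi in (-90, -30) and psi in (-77, -17) (the alpha-helical
#' region); `"restricted"` for points near (+120, -120), a region normally
#' reachable only by glycine -- G residues are exempt from that flag;
#' `"other"` otherwise.  Labels are descriptive only, never used to filter.
#'
#' @param phi,psi degrees.
#' @param letter one-letter residue code (G is exempt from "restricted").
#' @return character label.
#' @export
rama_region <- function(phi, psi, letter = "") {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (phi > -90 && phi < -30 && psi > -77 && psi < -17) return("alpha")
  if (phi > 60 && psi < -60 && !identical(letter, "G")) return("restricted")
  "other"
}

#' @export
print.ramachandran_summary <- function(x, ...) {
  cat("<ramachandran_summary>", x$fragment, "(", x$method, "mean )\n")
  print(x$weighted_angles)
  invisible(x)
}

#' Write Ramachandran points as CSV
#'
#' @param x a `"ramachandran_summary"`.
#' @param path output CSV (conformer, residue, phi, psi, weight, region).
#' @return `path`, invisibly.
#' @export
write_ramachandran_csv <- function(x, path) {
  utils::write.csv(x$points, path, row.names = FALSE)
  invisible(path)
}

#' Ramachandran plot of an ensemble
#'
#' Base-graphics scatter of all conformer (phi, psi) points, sized by
#' Boltzmann weight, with the weighted mean angles overplotted.
#'
#' @param x a `"ramachandran_summary"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ramachandran_summary <- function(x, ...) {
  graphics::plot(x$points$phi, x$points$psi, xlim = c(-180, 180),
                 ylim = c(-180, 180),
                 cex = 0.5 + 2 * x$points$weight,
                 xlab = expression(phi ~ "(deg)"),
                 ylab = expression(psi ~ "(deg)"), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::points(x$weighted_angles$phi, x$weighted_angles$psi, pch = 17,
                   col = "red")
  invisible(x)
}
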