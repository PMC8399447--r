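# Intramolecular hydrogen bonds and charge-transfer aggregation.
#
# A natural-population analysis upstream supplies, per bond, the magnitude
# of charge transferred through the bond (delta_q, electrons).  Per
# conformer the raw total is qT_raw = sum(delta_q); the ensemble total is
# the Boltzmann sum q_BT = sum_i N_i * qT_raw_i.  The tabulated reference
# data store per-conformer qT already Boltzmann-weighted; raw and weighted
# forms are kept separate here to avoid double weighting.

#' Geometric hydrogen-bond criteria
#'
#' The underlying analysis states no geometric criteria; these defaults
#' follow common structural-biology practice and are fully configurable.
#'
#' @param max_donor_acceptor_distance D...A cutoff, Angstroms (default 3.5).
#' @param min_dha_angle D-H...A angle cutoff, degrees (default 120).
#' @param max_h_acceptor_distance H...A cutoff, Angstroms (default 2.7).
#' @return object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5,
                           min_dha_angle = 120,
                           max_h_acceptor_distance = 2.7) {
  if (max_donor_acceptor_distance <= 0 || max_h_acceptor_distance <= 0)
    stop2("hbond_criteria: distances must be > 0")
  if (min_dha_angle <= 0 || min_dha_angle > 180)
    stop2("hbond_criteria: min_dha_angle must be in (0, 180]")
  structure(
    list(max_donor_acceptor_distance = max_donor_acceptor_distance,
         min_dha_angle = min_dha_angle,
         max_h_acceptor_distance = max_h_acceptor_distance),
    class = "hbond_criteria"
  )
}

#' Detect intramolecular hydrogen bonds geometrically
#'
#' Donors are N/O atoms with a covalently bound hydrogen (bond length
#' < 1.2 A); acceptors are any other N/O.  A donor-H...acceptor triple is
#' kept when the H...A and D...A distances and the D-H...A angle all meet
#' the criteria.  Only intramolecular bonds exist here (one molecule per
#' conformer).
#'
#' @param conformer a `"conformer"` with coordinates and element symbols.
#' @param criteria an [hbond_criteria()].
#' @return an [hbond_table()] (possibly empty) with `delta_q` unset and
#'   extra columns `h_acceptor_distance`, `donor_acceptor_distance`,
#'   `dha_angle`.
#' @export
detect_hbonds <- function(conformer, criteria = hbond_criteria()) {
  xyz <- coords(conformer)
  el <- conformer$atoms$element
  polar <- which(el %in% c("N", "O"))
  hyd <- which(el == "H")
  out <- hbond_table()
  extras <- data.frame(h_acceptor_distance = numeric(),
                       donor_acceptor_distance = numeric(),
                       dha_angle = numeric())
  for (h in hyd) {
    dcand <- polar[vapply(polar, function(d)
      vnorm(xyz[h, ] - xyz[d, ]) < 1.2, logical(1))]
    if (!length(dcand)) next
    d <- dcand[which.min(vapply(dcand, function(dd)
      vnorm(xyz[h, ] - xyz[dd, ]), numeric(1)))]
    for (a in setdiff(polar, d)) {
      rha <- vnorm(xyz[a, ] - xyz[h, ])
      rda <- vnorm(xyz[a, ] - xyz[d, ])
      if (rha < 1.2) next  # a is itself covalently bound to this H
      if (rha > criteria$max_h_acceptor_distance) next
      if (rda > criteria$max_donor_acceptor_distance) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ang <- rad2deg(acos(max(-1, min(1,
        sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
      if (ang < criteria$min_dha_angle) next
      out <- rbind(out, hbond_table(d - 1L, h - 1L, a - 1L))
      extras <- rbind(extras,
                      data.frame(h_acceptor_distance = rha,
                                 donor_acceptor_distance = rda,
                                 dha_angle = ang))
    }
  }
  cbind(out, extras)
}

#' Charge transferred through one hydrogen bond
#'
#' Convention (the natural-population bookkeeping is ambiguous about which
#' two atoms and about sign): the absolute difference between the natural
#' electron densities of the bridging hydrogen and the acceptor atom.
#' Isolated here so it can be swapped in one place.  When the interchange
#' file already carries `delta_q` -- the normal case, population analysis
#' being upstream -- this function validates the stored value and returns
#' it, warning on disagreement with the recomputed one.
#'
#' @param conformer a `"conformer"` whose atoms carry densities.
#' @param bond one row of an [hbond_table()].
#' @param tol validation tolerance, e- (default 1e-6).
#' @return delta_q in electrons (>= 0).
#' @export
hbond_delta_q <- function(conformer, bond, tol = 1e-6) {
  rho <- conformer$atoms$density
  for (role in c("hydrogen", "acceptor")) {
    i <- bond[[role]] + 1L
    if (is.na(rho[i]))
      stop2("hbond_delta_q: missing natural_electron_density for ", role,
            " atom ", bond[[role]], " of ", conformer$id)
  }
  computed <- abs(rho[bond$acceptor + 1L] - rho[bond$hydrogen + 1L])
  stored <- bond$delta_q
  if (!is.null(stored) && length(stored) && !is.na(stored)) {
    if (abs(stored - computed) > tol)
      warning("hbond_delta_q: stored delta_q (", signif(stored, 3),
              ") disagrees with density difference (",
              signif(computed, 3), ") for ", conformer$id, call. = FALSE)
    return(stored)
  }
  computed
}

#' Per-conformer and ensemble hydrogen-bond charge transfer
#'
#' For each conformer: the bond count, the raw total `qT_raw = sum(delta_q)`
#' and the Boltzmann-weighted `qT = N_i * qT_raw`.  The ensemble total is
#' `q_BT = sum_i N_i * qT_raw_i`, reported to 3 decimals.
#'
#' @param weighted a `"weighted_ensemble"` whose conformers carry hydrogen
#'   bonds with `delta_q` set (from file or [hbond_delta_q()]).
#' @return object of class `"charge_transfer_report"`: list with `fragment`,
#'   `table` (per-conformer data.frame) and `q_bt` (e-).
#' @export
charge_transfer_report <- function(weighted) {
  stopifnot(inherits(weighted, "weighted_ensemble"))
  confs <- weighted$ensemble$conformers
  qt_raw <- vapply(confs, function(cf) {
    dq <- cf$hbonds$delta_q
    if (nrow(cf$hbonds) && anyNA(dq))
      dq <- vapply(seq_len(nrow(cf$hbonds)), function(i)
        hbond_delta_q(cf, cf$hbonds[i, ]), numeric(1))
    sum(dq)
  }, numeric(1))
  tab <- data.frame(
    id = conformer_ids(weighted),
    n_hbonds = vapply(confs, function(cf) nrow(cf$hbonds), integer(1)),
    weight = weighted$weights,
    qt_raw = qt_raw,
    qt_weighted = weighted$weights * qt_raw
  )
  new_ct_report(weighted$ensemble$fragment, tab)
}

new_ct_report <- function(fragment, tab) {
  structure(
    list(fragment = fragment, table = tab,
         q_bt = round(sum(tab$qt_weighted), 3)),
    class = "charge_transfer_report"
  )
}

#' Charge-transfer report for one fragment of the reference table
#'
#' The reference table stores per-conformer qT already Boltzmann-weighted;
#' the ensemble total is their plain sum, and the raw per-conformer totals
#' are recovered as `qT / N_i`.
#'
#' @param table1 a [load_table1_fixture()] table.
#' @param fragment fragment label.
#' @return a `"charge_transfer_report"`.
#' @export
charge_transfer_from_fixture <- function(table1, fragment) {
  rows <- table1[table1$fragment == fragment, ]
  if (!nrow(rows))
    stop2("charge_transfer_from_fixture: unknown fragment '", fragment, "'")
  tab <- data.frame(
    id = rows$structure,
    n_hbonds = rows$hbs,
    weight = rows$n_i,
    qt_raw = rows$qt / rows$n_i,
    qt_weighted = rows$qt
  )
  new_ct_report(fragment, tab)
}

#' @export
print.charge_transfer_report <- function(x, ...) {
  cat("<charge_transfer_report>", x$fragment, " q_BT:", x$q_bt, "e-\n")
  print(x$table)
  invisible(x)
}

#' Write charge-transfer reports as CSV
#'
#' @param reports list of `"charge_transfer_report"` objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_charge_transfer_csv <- function(reports, path) {
  rows <- lapply(reports, function(r)
    cbind(fragment = r$fragment, r$table, q_bt = r$q_bt))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
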