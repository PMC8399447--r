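# Band assignment: which normal mode is the amide I nu(C=O) of the first
# peptide bond, and which is the C-terminal carboxylate nu(C=O)?
#
# "Amide I" here always means the peptide bond nearest the protonated amino
# terminus (physically furthest from the alpha-COO- terminal), the convention
# used throughout the fragment series.  A candidate mode is scored by its
# bond-stretch amplitude on the target C=O pair(s): the relative displacement
# of O against C projected on the C->O axis.  For the carboxylate both C-O
# bonds are projected (the ~1600-1645 cm-1 band is the antisymmetric
# stretch, so the two projections typically carry opposite signs; squaring
# makes the score sign-free).

band_pairs <- function(conformer, band_label) {
  bb <- conformer$backbone
  if (is.null(bb))
    stop2("assign_band: conformer ", conformer$id, " has no backbone map")
  if (band_label == "amide_I") {
    list(c(bb$residues$C[1], bb$residues$O[1]))
  } else {
    list(c(bb$cterm_C, bb$cterm_O1), c(bb$cterm_C, bb$cterm_O2))
  }
}

# squared stretch amplitudes of one mode on a list of (C, O) 0-based pairs
stretch_projection <- function(xyz, disp, pairs) {
  sum(vapply(pairs, function(p) {
    ci <- p[1] + 1L; oi <- p[2] + 1L
    axis <- unitv(xyz[oi, ] - xyz[ci, ])
    sum((disp[oi, ] - disp[ci, ]) * axis)^2
  }, numeric(1)))
}

#' Assign the amide I or alpha-COO- band of a conformer
#'
#' Among modes whose scaled frequency falls in the search window, selects the
#' mode with the largest squared C=O stretch projection for the target
#' bond(s).  The localization score is that projection normalized by twice
#' the total squared displacement norm, so a pure two-atom C=O stretch scores
#' 1.  Scores below `score_threshold` flag a delocalized/coupled mode: a
#' warning is raised but the assignment is still returned.  For protonated
#' conformers the "alpha-COO-" target falls back to the same C-terminal
#' carbonyl pair (now a neutral acid C=O) and the assignment is flagged.
#'
#' @param conformer a `"conformer"` with a backbone map and displacements.
#' @param band_label `"amide_I"` or `"alphaCOO"`.
#' @param config a [broadening_config()]; supplies the scaling factor.
#' @param window scaled-frequency search window, cm-1 (default
#'   `c(1550, 1750)`, wide enough for the +81 cm-1 carboxylate outlier).
#' @param score_threshold localization warning threshold (default 0.2).
#' @return object of class `"band_assignment"`: list with `band_label`,
#'   `mode_index`, `position` (scaled, cm-1), `localization_score`,
#'   `flagged`.
#' @export
assign_band <- function(conformer, band_label = c("amide_I", "alphaCOO"),
                        config = broadening_config(),
                        window = c(1550, 1750), score_threshold = 0.2) {
  band_label <- match.arg(band_label)
  scaled <- scale_frequencies(conformer$modes$frequency,
                              config$scaling_factor)
  in_win <- which(scaled >= window[1] & scaled <= window[2])
  if (!length(in_win))
    stop2("assign_band: no candidate band for ", conformer$id, " (",
          band_label, ") in window [", window[1], ", ", window[2], "] cm-1")
  pairs <- band_pairs(conformer, band_label)
  xyz <- coords(conformer)
  proj <- vapply(in_win, function(k)
    stretch_projection(xyz, conformer$displacements[[k]], pairs),
    numeric(1))
  best <- in_win[which.max(proj)]
  total <- sum(conformer$displacements[[best]]^2)
  score <- if (total > 0) min(1, max(proj) / (2 * total)) else 0
  flagged <- score < score_threshold || conformer$protonated
  if (score < score_threshold)
    warning("assign_band: ", conformer$id, " ", band_label,
            " localization score ", signif(score, 3), " < ",
            score_threshold, " (delocalized or coupled mode)",
            call. = FALSE)
  structure(
    list(band_label = band_label, mode_index = best,
         position = scaled[best], localization_score = score,
         flagged = flagged, conformer = conformer$id),
    class = "band_assignment"
  )
}

#' Per-conformer and Boltzmann-summed band positions for an ensemble
#'
#' Assigns the requested band in every conformer (or uses positions supplied
#' directly, e.g. from the packaged reference table) and forms the
#' Boltzmann-weighted mean position, renormalized over the supplied weights
#' and rounded to the nearest integer cm-1 (ties away from zero).
#'
#' @param weighted a `"weighted_ensemble"`, or `NULL` when `positions` and
#'   `weights` are given directly.
#' @param band_label `"amide_I"` or `"alphaCOO"`.
#' @param positions optional numeric vector of per-conformer band positions
#'   (cm-1) overriding assignment, named by conformer id or in conformer
#'   order.
#' @param weights optional weights accompanying `positions` when `weighted`
#'   is `NULL`.
#' @param fragment fragment label when `weighted` is `NULL`.
#' @param experimental optional experimental band position, cm-1.
#' @param ... passed to [assign_band()].
#' @return object of class `"band_report"`: list with `fragment`,
#'   `band_label`, `positions` (named, cm-1), `weights`, `boltzmann_sum`
#'   (integer cm-1), `experimental`.
#' @export
band_report <- function(weighted = NULL,
                        band_label = c("amide_I", "alphaCOO"),
                        positions = NULL, weights = NULL, fragment = NULL,
                        experimental = NA_real_, ...) {
  band_label <- match.arg(band_label)
  if (is.null(positions)) {
    stopifnot(inherits(weighted, "weighted_ensemble"))
    fragment <- weighted$ensemble$fragment
    weights <- weighted$weights
    failures <- character()
    positions <- vapply(weighted$ensemble$conformers, function(cf) {
      p <- tryCatch(assign_band(cf, band_label, ...)$position,
                    error = function(e) {
                      failures <<- c(failures, cf$id)
                      NA_real_
                    })
      p
    }, numeric(1))
    if (length(failures))
      stop2("band_report: assignment failed for conformer(s): ",
            paste(failures, collapse = ", "))
    names(positions) <- conformer_ids(weighted)
  } else {
    if (!is.null(weighted)) {
      weights <- weights %||% weighted$weights
      fragment <- fragment %||% weighted$ensemble$fragment
      if (is.null(names(positions)))
        names(positions) <- conformer_ids(weighted)
    }
    if (is.null(weights))
      stop2("band_report: weights required when positions are supplied")
  }
  bsum <- round_half_away(weighted_mean(positions, weights,
                                        renormalize = TRUE))
  structure(
    list(fragment = fragment, band_label = band_label,
         positions = positions, weights = weights,
         boltzmann_sum = bsum, experimental = experimental),
    class = "band_report"
  )
}

#' Band report for one fragment of the packaged reference table
#'
#' Fixture path of [band_report()]: per-conformer absolute positions come
#' from the resolved reference table and the weights are the printed
#' populations (whose rounded sum is only approximately 1; the weighted mean
#' renormalizes).
#'
#' @param table1 a [load_table1_fixture()] table.
#' @param fragment fragment label, e.g. `"EGEDEA"`.
#' @param band_label `"amide_I"` or `"alphaCOO"`.
#' @param experimental optional experimental position, cm-1.
#' @return a `"band_report"`.
#' @export
band_report_from_fixture <- function(table1, fragment,
                                     band_label = c("amide_I", "alphaCOO"),
                                     experimental = NA_real_) {
  band_label <- match.arg(band_label)
  rows <- table1[table1$fragment == fragment, ]
  if (!nrow(rows))
    stop2("band_report_from_fixture: unknown fragment '", fragment, "'")
  col <- if (band_label == "amide_I") "amide_I_position" else "acoo_position"
  positions <- stats::setNames(rows[[col]], rows$structure)
  band_report(band_label = band_label, positions = positions,
              weights = rows$n_i, fragment = fragment,
              experimental = experimental)
}

#' @export
print.band_report <- function(x, ...) {
  cat("<band_report>", x$fragment, x$band_label,
      "Boltzmann sum:", x$boltzmann_sum, "cm-1",
      if (!is.na(x$experimental)) paste0("(exp: ", x$experimental, ")"),
      "\n")
  invisible(x)
}

#' Write a set of band reports as a table-style CSV
#'
#' One row per fragment and band with per-conformer positions, the Boltzmann
#' sum and the experimental position, mirroring the ensemble-sum table
#' layout.
#'
#' @param reports list of `"band_report"` objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_band_report_csv <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    data.frame(fragment = r$fragment, band = r$band_label,
               conformer = names(r$positions) %||%
                 seq_along(r$positions),
               position = as.numeric(r$positions),
               weight = r$weights,
               boltzmann_sum = r$boltzmann_sum,
               experimental = r$experimental)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
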