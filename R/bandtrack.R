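# Cross-fragment band tracking: assemble an ordered fragment series, compute
# pairwise shifts and classify the trend.  Blue shift = positive wavenumber
# step (higher energy); tolerance +/-2 cm-1 treats steps below the integer
# rounding granularity of reported positions as flat.

#' Assemble a cross-fragment band-position series
#'
#' @param band_reports list of `"band_report"` objects (amide I and/or
#'   alpha-COO-) covering every fragment in `order`.
#' @param ct_reports optional list of `"charge_transfer_report"` objects.
#' @param order fragment labels in series order (residue counts 2-6).
#' @return `data.frame` of class `"fragment_series"` with columns
#'   `fragment`, `n`, `amide_I`, `acoo`, `q_bt`, `amide_I_exp`, `acoo_exp`.
#' @export
build_series <- function(band_reports, ct_reports = NULL, order) {
  pick <- function(frag, band) {
    for (r in band_reports)
      if (identical(r$fragment, frag) && identical(r$band_label, band))
        return(r)
    NULL
  }
  rows <- lapply(order, function(frag) {
    am <- pick(frag, "amide_I")
    ac <- pick(frag, "alphaCOO")
    if (is.null(am) && is.null(ac))
      stop2("build_series: no band report for fragment '", frag, "'")
    qb <- NA_real_
    for (r in ct_reports %||% list())
      if (identical(r$fragment, frag)) qb <- r$q_bt
    data.frame(
      fragment = frag, n = nchar(frag),
      amide_I = if (is.null(am)) NA_real_ else am$boltzmann_sum,
      acoo = if (is.null(ac)) NA_real_ else ac$boltzmann_sum,
      q_bt = qb,
      amide_I_exp = if (is.null(am)) NA_real_ else am$experimental,
      acoo_exp = if (is.null(ac)) NA_real_ else ac$experimental
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$n < 2 | out$n > 6))
    stop2("build_series: residue counts must be in [2, 6]")
  structure(out, class = c("fragment_series", "data.frame"))
}

#' Classify the band-position trend along a fragment series
#'
#' Computes signed pairwise steps (later minus earlier, cm-1) and classifies:
#' all steps >= +tolerance is a blue shift, all <= -tolerance a red shift,
#' all |step| < tolerance flat, anything else mixed.
#'
#' @param series a `"fragment_series"` (or data.frame with the band column).
#' @param band_label `"amide_I"` or `"alphaCOO"`.
#' @param tolerance flat-step tolerance, cm-1 (default 2, below the integer
#'   rounding granularity of reported positions).
#' @return object of class `"trend_report"`: list with `series_name`,
#'   `band_label`, `steps` (named by "from->to"), `classification`.
#' @export
classify_trend <- function(series, band_label = c("amide_I", "alphaCOO"),
                           tolerance = 2) {
  band_label <- match.arg(band_label)
  if (nrow(series) < 2) stop2("classify_trend: series length must be >= 2")
  col <- if (band_label == "amide_I") "amide_I" else "acoo"
  v <- series[[col]]
  if (anyNA(v)) stop2("classify_trend: missing positions for band ",
                      band_label)
  steps <- diff(v)
  names(steps) <- paste(utils::head(series$fragment, -1),
                        utils::tail(series$fragment, -1), sep = "->")
  classification <-
    if (all(steps >= tolerance)) "blue_shift"
    else if (all(steps <= -tolerance)) "red_shift"
    else if (all(abs(steps) < tolerance)) "flat"
    else "mixed"
  structure(
    list(series_name = paste(series$fragment, collapse = "-"),
         band_label = band_label, steps = steps,
         classification = classification, tolerance = tolerance),
    class = "trend_report"
  )
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report>", x$band_label, "over", x$series_name, ":",
      x$classification, "\n  steps (cm-1):",
      paste(sprintf("%+g", x$steps), collapse = ", "), "\n")
  invisible(x)
}

#' Write series and trend reports as CSV
#'
#' @param series a `"fragment_series"`.
#' @param trends list of `"trend_report"` objects.
#' @param path output CSV for the series; trends go to `<path>` with a
#'   `.trends.csv` suffix replacing `.csv`.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, trends, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  trows <- lapply(trends, function(t)
    data.frame(series = t$series_name, band = t$band_label,
               step = names(t$steps), shift = as.numeric(t$steps),
               classification = t$classification))
  utils::write.csv(do.call(rbind, trows),
                   sub("\\.csv$", ".trends.csv", path), row.names = FALSE)
  invisible(path)
}

#' Band-position versus fragment-length plot
#'
#' @param x a `"fragment_series"`.
#' @param band_label `"amide_I"` or `"alphaCOO"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_series <- function(x, band_label = c("amide_I", "alphaCOO"), ...) {
  band_label <- match.arg(band_label)
  col <- if (band_label == "amide_I") "amide_I" else "acoo"
  graphics::plot(x$n, x[[col]], type = "b", pch = 19,
                 xlab = "fragment length n (residues)",
                 ylab = expression(paste("band position (", cm^-1, ")")),
                 ...)
  graphics::text(x$n, x[[col]], labels = x$fragment, pos = 3, cex = 0.7)
  invisible(x)
}
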