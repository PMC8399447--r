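# Maxwell-Boltzmann conformer populations and Boltzmann-weighted scalar
# aggregation.
#
# The population of conformer i at temperature T is
#
#     N_i = exp(-E_i / kT) / sum_j exp(-E_j / kT)
#
# with E_i the relative electronic energy (kcal/mol) and kT expressed through
# the molar gas constant so that energies in kcal/mol divide cleanly.  The
# minimum energy is subtracted before exponentiation (log-sum-exp style), so
# spreads up to the 50 kcal/mol window used for ensemble collection stay
# numerically exact.

#' Molar gas constant in kcal/(mol K)
#'
#' Default thermal-energy constant: per-mole form of the Boltzmann constant,
#' matching relative energies tabulated in kcal/mol.  Pass a different value
#' to [boltzmann_weights()] for full CODATA precision if desired.
#'
#' @export
R_KCAL_MOL <- 1.987204e-3

#' Maxwell-Boltzmann conformer populations
#'
#' Computes the absolute occupation probability of each conformer state from
#' its relative energy at a given temperature.
#'
#' @param relative_energies numeric vector, kcal/mol; finite.  Energies are
#'   re-referenced internally to a zero minimum, so only differences matter.
#' @param temperature temperature in K (> 0); default 298.
#' @param gas_constant kcal/(mol K); default [R_KCAL_MOL].
#' @return numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' boltzmann_weights(c(0, 2.39, 3.03, 3.65, 4.04, 8.91))  # EG fragment
boltzmann_weights <- function(relative_energies, temperature = 298,
                              gas_constant = R_KCAL_MOL) {
  if (!length(relative_energies))
    stop2("boltzmann_weights: empty energy list")
  if (!all(is.finite(relative_energies)))
    stop2("boltzmann_weights: energies must be finite")
  if (!is_number(temperature) || temperature <= 0)
    stop2("boltzmann_weights: temperature must be > 0")
  kT <- gas_constant * temperature
  e <- relative_energies - min(relative_energies)
  w <- exp(-e / kT)
  w / sum(w)
}

#' Boltzmann-weighted mean of a scalar property
#'
#' Weighted average `sum(w * v) / sum(w)` (or unnormalized `sum(w * v)` with
#' `renormalize = FALSE`).  Renormalization is the default so that printed,
#' rounded populations -- whose sum is only approximately 1 -- still yield the
#' tabulated ensemble band positions.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, same length, positive sum.
#' @param renormalize divide by `sum(weights)` (default `TRUE`).
#' @return scalar.
#' @export
weighted_mean <- function(values, weights, renormalize = TRUE) {
  if (length(values) != length(weights))
    stop2("weighted_mean: values and weights lengths differ (",
          length(values), " vs ", length(weights), ")")
  if (any(weights < 0) || !all(is.finite(weights)))
    stop2("weighted_mean: weights must be finite and >= 0")
  s <- sum(weights)
  if (s <= 0) stop2("weighted_mean: weights sum to zero")
  if (renormalize) sum(weights * values) / s else sum(weights * values)
}

#' Boltzmann weights in the zero- and infinite-temperature limits
#'
#' As T -> 0+ the population collapses onto the minimum-energy conformer
#' (ties split uniformly); as T -> Inf it becomes uniform.  Useful as a
#' numerical sanity check on [boltzmann_weights()].
#'
#' @param x an `"ensemble"`, or a numeric vector of relative energies.
#' @param tie_tol energies within this of the minimum count as degenerate
#'   (kcal/mol).
#' @return list with elements `zero_temperature` and `infinite_temperature`.
#' @export
boltzmann_limits <- function(x, tie_tol = 1e-9) {
  e <- if (is.numeric(x)) x else relative_energies(x)
  if (!length(e)) stop2("boltzmann_limits: empty ensemble")
  lo <- abs(e - min(e)) <= tie_tol
  list(
    zero_temperature = lo / sum(lo),
    infinite_temperature = rep(1 / length(e), length(e))
  )
}

#' Attach Boltzmann weights to an ensemble
#'
#' @param x an `"ensemble"`.
#' @param temperature K; defaults to the ensemble's own temperature.
#' @param gas_constant kcal/(mol K); default [R_KCAL_MOL].
#' @return object of class `"weighted_ensemble"`: list with `ensemble`,
#'   `weights` (in conformer order), `temperature` and `kT` (kcal/mol).
#' @export
weight_ensemble <- function(x, temperature = NULL,
                            gas_constant = R_KCAL_MOL) {
  stopifnot(inherits(x, "ensemble"))
  temperature <- temperature %||% x$temperature
  w <- boltzmann_weights(relative_energies(x), temperature, gas_constant)
  structure(
    list(ensemble = x, weights = w, temperature = temperature,
         kT = gas_constant * temperature),
    class = "weighted_ensemble"
  )
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat("<weighted_ensemble>", x$ensemble$fragment, "at", x$temperature, "K\n")
  print(data.frame(id = conformer_ids(x),
                   dE = relative_energies(x),
                   N_i = signif(x$weights, 3)))
  invisible(x)
}
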