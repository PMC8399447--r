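# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties broken away from zero (so 0.5 -> 1,
#' -0.5 -> -1), unlike [base::round()]'s round-half-even rule.  Used for the
#' final integer rounding of Boltzmann-summed band positions only.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop2("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle (degrees) into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Place atom D given atoms A, B, C, the C-D bond length, the B-C-D angle and
# the A-B-C-D torsion (degrees).  Standard internal-coordinate (NeRF-style)
# construction; the torsion sign matches dihedral().
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# evaluate expr with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards (no global random state leaks)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
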