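#' Physical constants used throughout the package
#'
#' The gas constant in kcal mol^-1 K^-1 and the Celsius/Kelvin offset.
#' All thermodynamic expressions in the package evaluate temperatures in
#' kelvin internally; user-facing temperatures are degrees Celsius.
#'
#' @format `GAS_CONSTANT_KCAL` is a single numeric value,
#'   1.9872e-3 kcal mol^-1 K^-1. `KELVIN_OFFSET` is 273.15.
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' @rdname GAS_CONSTANT_KCAL
#' @export
KELVIN_OFFSET <- 273.15

#' Convert between Celsius and kelvin
#'
#' @param tC,tK temperatures in degrees Celsius / kelvin.
#' @return numeric vector of converted temperatures.
#' @examples
#' celsiusToKelvin(25)   # 298.15
#' kelvinToCelsius(300)  # 26.85
#' @export
celsiusToKelvin <- function(tC) tC + KELVIN_OFFSET

#' @rdname celsiusToKelvin
#' @export
kelvinToCelsius <- function(tK) tK - KELVIN_OFFSET

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package route their randomness through
## this helper so that the same seed yields bit-identical output.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Additive homoscedastic Gaussian noise; sd in signal units.
addNoise <- function(y, sd, seed) {
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(y)
  withSeed(seed, y + stats::rnorm(length(y), mean = 0, sd = sd))
}

## Strictly increasing numeric grid check shared by the generators.
checkGrid <- function(grid, what = "grid") {
  if (length(grid) == 0L) stop(what, " is empty")
  if (anyNA(grid) || !is.numeric(grid)) stop(what, " must be numeric without NA")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop(what, " must be strictly increasing")
  as.numeric(grid)
}

## --- small 3D geometry helpers (used by the helix builder and H-bond
##     detector); vectors are length-3 numerics ------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) v / vnorm(v)

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle A-B-C in radians.
angle3 <- function(a, b, c) {
  u <- unitv(a - b); w <- unitv(c - b)
  acos(max(-1, min(1, sum(u * w))))
}

## Place atom D given chain A-B-C with bond length |C-D|, angle B-C-D (rad)
## and torsion A-B-C-D (rad); the standard internal-coordinate (NeRF) step.
placeAtom <- function(a, b, c, bond, theta, chi) {
  bc <- unitv(c - b)
  n <- unitv(crossp(b - a, bc))
  m <- crossp(n, bc)
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Derive a reproducible child seed from a root seed and a stage label
#'
#' All pipeline randomness flows from one root seed; each stage (or
#' acceptance target) derives its own sub-seed deterministically from the
#' root seed and a text label. The result is a valid 32-bit R integer.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return an integer seed.
#' @examples
#' deriveSeed(1, "dsc")
#' @export
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
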