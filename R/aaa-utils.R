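#' @keywords internal
"_PACKAGE"

## Mean Earth radius (IUGG), km.  All geodesic computations in the package
## use this sphere; see geodesic_km() for the ellipsoidal caveat.
EARTH_RADIUS_KM <- 6371.0088

#' Derive a reproducible child seed from a root seed
#'
#' All randomness in the package flows from a single root seed; each stage
#' (environment noise, station placement per year/season, catch draws per
#' species) uses a child seed derived deterministically from the root and a
#' set of integer tags.  The derivation is a small multiplicative hash kept
#' below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed integer root seed.
#' @param ... additional integer tags (year, season index, stage id, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  stopifnot(length(tags) >= 1, all(is.finite(tags)))
  h <- 0
  for (t in as.numeric(tags)) {
    h <- (h * 69069 + (t %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

## run code under a child seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
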