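#' Worm-like chain parameters
#'
#' Bundle the constants of the interpolated worm-like chain (WLC) model of
#' entropic polymer elasticity: persistence length, contour length, and
#' thermal energy.
#'
#' @param persistence_length Persistence length Lp in nm (ssDNA: ~1 nm).
#' @param contour_length Contour length Lc in nm.
#' @param kBT Thermal energy in pN nm. Default 4.09 pN nm (296 K, 23 C).
#'
#' @return An object of class `"wlc_params"`.
#' @seealso [wlc_force()], [wlc_extension()]
#' @export
#' @examples
#' p <- wlc_params(persistence_length = 1, contour_length = 32.45)
#' wlc_force(16.2, p)
wlc_params <- function(persistence_length, contour_length, kBT = 4.09) {
  stopifnot(
    is.numeric(persistence_length), length(persistence_length) == 1L,
    persistence_length > 0,
    is.numeric(contour_length), length(contour_length) == 1L,
    contour_length > 0,
    is.numeric(kBT), length(kBT) == 1L, kBT > 0
  )
  structure(
    list(
      persistence_length = persistence_length,
      contour_length = contour_length,
      kBT = kBT
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf(
    "WLC parameters: Lp = %g nm, Lc = %g nm, kBT = %g pN nm\n",
    x$persistence_length, x$contour_length, x$kBT
  ))
  invisible(x)
}

#' Worm-like chain force at a given extension
#'
#' Interpolated WLC force law
#' \deqn{F Lp / kBT = \frac14 (1 - x/Lc)^{-2} - \frac14 + x/Lc}
#' A slack chain (extension below zero) carries no tension, so negative
#' extensions return zero force; the force diverges as the extension
#' approaches the contour length, which is a domain error here.
#'
#' @param extension Extension x in nm (vectorized). Must be `< Lc`.
#' @param params A [wlc_params()] object.
#'
#' @return Force in pN, same length as `extension`.
#' @export
wlc_force <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(extension))
  Lc <- params$contour_length
  if (any(extension >= Lc)) {
    stop("extension >= contour length: WLC force diverges", call. = FALSE)
  }
  rel <- pmax(extension, 0) / Lc
  (params$kBT / params$persistence_length) *
    (0.25 * (1 - rel)^-2 - 0.25 + rel)
}

#' Worm-like chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]. The WLC force law is strictly
#' increasing on `[0, Lc)`, so the inverse is unique; it is found by
#' Brent root bracketing.
#'
#' @param force Force in pN (vectorized, non-negative).
#' @param params A [wlc_params()] object.
#' @param tol Absolute tolerance on the extension root, in nm.
#'
#' @return Extension in nm, in `[0, Lc)`.
#' @export
wlc_extension <- function(force, params, tol = 1e-12) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(force))
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  Lc <- params$contour_length
  vapply(force, function(f) {
    if (f == 0) return(0)
    # bracket: force is monotone, diverges at Lc
    upper <- Lc * (1 - 1e-12)
    stats::uniroot(
      function(x) wlc_force(x, params) - f,
      lower = 0, upper = upper, tol = tol
    )$root
  }, numeric(1))
}
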