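#' Tether geometry for the force-jump mechanical circuit
#'
#' The force-jump tether behaves as two nonlinear entropic springs in
#' parallel: a "loading" strand (two non-annealed 12-nt ssDNA segments in
#' series with the inextensible bound protein pair) and a ssDNA "bridge"
#' strand (55 or 70 nt unpaired). Because the proteins sit on the loading
#' path, the bridge starts pre-stretched by the protein length `L_prot`
#' relative to the loading-strand extension coordinate.
#'
#' @param bridge_nt Number of single-stranded nucleotides in the bridge
#'   (55 or 70 in the standard constructs).
#' @param loading_nt Number of non-annealed nucleotides in the loading
#'   strand (default 24: two 12-nt segments).
#' @param nm_per_nt Contour length per nucleotide of ssDNA, nm (default 0.59).
#' @param L_prot Inextensible length of the bound protein pair, nm
#'   (default 8).
#' @param persistence_length ssDNA persistence length, nm (default 1).
#' @param kBT Thermal energy, pN nm (default 4.09, i.e. 23 C).
#'
#' @return An object of class `"tether_geometry"` with derived contour
#'   lengths `Lc_bridge` and `Lc_loading`.
#' @export
#' @examples
#' g55 <- tether_geometry(bridge_nt = 55)
#' predict_delta_x(6, g55)
tether_geometry <- function(bridge_nt, loading_nt = 24, nm_per_nt = 0.59,
                            L_prot = 8, persistence_length = 1,
                            kBT = 4.09) {
  stopifnot(
    bridge_nt > 0, loading_nt > 0, nm_per_nt > 0, L_prot >= 0,
    persistence_length > 0, kBT > 0
  )
  Lc_bridge <- bridge_nt * nm_per_nt
  Lc_loading <- loading_nt * nm_per_nt
  if (Lc_bridge <= L_prot) {
    stop("bridge contour length must exceed the protein length", call. = FALSE)
  }
  structure(
    list(
      bridge_nt = bridge_nt, loading_nt = loading_nt,
      nm_per_nt = nm_per_nt, L_prot = L_prot,
      persistence_length = persistence_length, kBT = kBT,
      Lc_bridge = Lc_bridge, Lc_loading = Lc_loading
    ),
    class = "tether_geometry"
  )
}

#' @export
print.tether_geometry <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Force-jump tether geometry\n",
      "  bridge:  %d nt (Lc = %.2f nm)\n",
      "  loading: %d nt (Lc = %.2f nm) + L_prot = %g nm (inextensible)\n",
      "  Lp = %g nm, kBT = %g pN nm\n"
    ),
    x$bridge_nt, x$Lc_bridge, x$loading_nt, x$Lc_loading, x$L_prot,
    x$persistence_length, x$kBT
  ))
  invisible(x)
}

wlc_of <- function(geom, which = c("bridge", "loading")) {
  which <- match.arg(which)
  Lc <- if (which == "bridge") geom$Lc_bridge else geom$Lc_loading
  wlc_params(geom$persistence_length, Lc, geom$kBT)
}

force_partition <- function(F_Tot, F_Load, F_Bridge, x, delta_x = NA_real_,
                            bound = TRUE) {
  structure(
    list(
      F_Tot = F_Tot, F_Load = F_Load, F_Bridge = F_Bridge,
      x = x, delta_x = delta_x, bound = bound
    ),
    class = "force_partition"
  )
}

#' @export
print.force_partition <- function(x, ...) {
  cat(sprintf(
    "Force partition (%s): F_Tot = %.3f pN, F_Load = %.3f pN, F_Bridge = %.3f pN, x = %.3f nm\n",
    if (x$bound) "bound" else "unbound", x$F_Tot, x$F_Load, x$F_Bridge, x$x
  ))
  if (!is.na(x$delta_x)) cat(sprintf("  predicted delta x = %.3f nm\n", x$delta_x))
  invisible(x)
}

#' Solve the bound-state force partition
#'
#' With the protein pair bound, total trap force is carried by two
#' parallel springs: `F_Tot(x) = F_Bridge(x + L_prot) + F_Load(x)`, where
#' `x` is extension along the loading-strand coordinate. The summed
#' force-extension curve is strictly increasing, so the root is unique and
#' found by Brent bracketing. If even at `x = 0` the pre-stretched bridge
#' already carries more than `F_Tot`, the loading strand is slack: the
#' bound state degenerates to the unbound geometry with `F_Load = 0`.
#'
#' @param F_Tot Total applied force, pN (scalar, non-negative).
#' @param geom A [tether_geometry()] object.
#' @param tol Absolute root tolerance on `x`, nm.
#'
#' @return A `"force_partition"` object with fields `F_Tot`, `F_Load`,
#'   `F_Bridge`, `x`, `bound`.
#' @export
solve_bound_state <- function(F_Tot, geom, tol = 1e-9) {
  stopifnot(inherits(geom, "tether_geometry"),
            is.numeric(F_Tot), length(F_Tot) == 1L, F_Tot >= 0)
  bridge <- wlc_of(geom, "bridge")
  loading <- wlc_of(geom, "loading")
  Lprot <- geom$L_prot

  total_force <- function(x) {
    wlc_force(x + Lprot, bridge) + wlc_force(x, loading)
  }

  # slack loading strand: bridge alone at extension L_prot exceeds F_Tot
  if (wlc_force(Lprot, bridge) >= F_Tot) {
    unb <- solve_unbound_state(F_Tot, geom)
    return(force_partition(F_Tot, 0, F_Tot, unb$x, bound = TRUE))
  }

  upper <- min(geom$Lc_loading, geom$Lc_bridge - Lprot) * 0.999
  if (total_force(upper) < F_Tot) {
    stop(sprintf(
      "F_Tot = %g pN exceeds the solvable range for this geometry (max ~%.3g pN at x = %.3g nm)",
      F_Tot, total_force(upper), upper
    ), call. = FALSE)
  }
  x <- stats::uniroot(function(x) total_force(x) - F_Tot,
                      lower = 0, upper = upper, tol = tol)$root
  F_Load <- wlc_force(x, loading)
  force_partition(F_Tot, F_Load, F_Tot - F_Load, x, bound = TRUE)
}

#' Solve the unbound-state geometry
#'
#' After the proteins dissociate the whole trap force sits on the bridge:
#' `F_Tot(x) = F_Bridge(x + L_prot)`. The extension coordinate stays the
#' same as in the bound state, so `x = wlc_extension(F_Tot, bridge) -
#' L_prot` (negative at very low force: the reference configuration is
#' slack).
#'
#' @inheritParams solve_bound_state
#' @return A `"force_partition"` object with `F_Load = 0`, `bound = FALSE`.
#' @export
solve_unbound_state <- function(F_Tot, geom) {
  stopifnot(inherits(geom, "tether_geometry"),
            is.numeric(F_Tot), length(F_Tot) == 1L, F_Tot >= 0)
  bridge <- wlc_of(geom, "bridge")
  x_bridge <- wlc_extension(F_Tot, bridge)
  force_partition(F_Tot, 0, F_Tot, x_bridge - geom$L_prot, bound = FALSE)
}

#' Predicted rupture step size
#'
#' The position change on dissociation at constant total force: the
#' difference between the unbound and bound equilibrium extensions,
#' `delta_x = x_unbound - x_bound`. Zero when the loading strand is
#' already slack in the bound state (the two configurations coincide).
#'
#' @inheritParams solve_bound_state
#' @return Step size in nm (vectorized over `F_Tot`), always `>= 0`.
#' @export
predict_delta_x <- function(F_Tot, geom) {
  stopifnot(is.numeric(F_Tot), all(F_Tot > 0))
  vapply(F_Tot, function(f) {
    b <- solve_bound_state(f, geom)
    u <- solve_unbound_state(f, geom)
    max(u$x - b$x, 0)
  }, numeric(1))
}

#' Protein load and step size over a grid of total forces
#'
#' Maps plateau total forces to the load actually borne by the protein
#' pair (and the predicted rupture step), the quantity on which lifetime
#' data from different bridge constructs are pooled.
#'
#' @param F_Tot_grid Increasing vector of positive total forces, pN.
#' @param geom A [tether_geometry()] object.
#'
#' @return A data.frame with columns `F_Tot`, `F_Load`, `F_Bridge`,
#'   `delta_x`.
#' @export
f_load_curve <- function(F_Tot_grid, geom) {
  stopifnot(is.numeric(F_Tot_grid), all(F_Tot_grid > 0),
            !is.unsorted(F_Tot_grid, strictly = FALSE))
  rows <- lapply(F_Tot_grid, function(f) {
    b <- solve_bound_state(f, geom)
    data.frame(
      F_Tot = f, F_Load = b$F_Load, F_Bridge = b$F_Bridge,
      delta_x = predict_delta_x(f, geom)
    )
  })
  do.call(rbind, rows)
}
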