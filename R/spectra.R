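#' Decadic absorbance from transmittance
#'
#' `A = -log10(T)`. Non-positive transmittances (total extinction or
#' numerical underflow) are masked to `NA` with a warning rather than
#' clamped to a fake value.
#'
#' @param T_spec transmittance vector.
#' @return absorbance vector with `NA` at masked points.
#' @export
absorbance <- function(T_spec) {
  T_spec <- as.numeric(T_spec)
  bad <- !is.finite(T_spec) | T_spec <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive transmittance value(s) masked to NA", sum(bad)),
            call. = FALSE)
    T_spec[bad] <- NA_real_
  }
  -log10(T_spec)
}

#' Beer-Lambert absorbance baseline
#'
#' `A_BL = 4 pi nu n'' (d / cos theta) / ln 10` with `d` in micrometres
#' converted internally to cm. The `d/cos(theta)` path scaling is the
#' oblique-incidence optical thickness; it ignores interference and
#' polarization mixing and is exact only in their absence.
#'
#' @param n_imag imaginary part of the refractive index on the grid.
#' @param d_um film thickness in micrometres (`> 0`).
#' @param nu wavenumber grid in cm^-1.
#' @param theta_deg incidence angle in degrees, `0 <= theta < 90`.
#' @return decadic absorbance vector.
#' @export
beer_lambert_absorbance <- function(n_imag, d_um, nu, theta_deg = 0) {
  nu <- check_wavenumbers(nu)
  stopifnot(is.numeric(d_um), length(d_um) == 1L, d_um > 0)
  if (!is.numeric(theta_deg) || length(theta_deg) != 1L ||
      theta_deg < 0 || theta_deg >= 90) {
    stop("theta_deg must be in [0, 90)", call. = FALSE)
  }
  4 * pi * nu * as.numeric(n_imag) * (d_um * 1e-4 / cos(theta_deg * pi / 180)) / log(10)
}

#' VCD from helicity transmittances
#'
#' `VCD = -log10(T_minus / T_plus) = A_minus - A_plus` (decadic absorbance
#' units). With `Im(kappa) > 0` at a resonance the `+` helicity is absorbed
#' more strongly, so the VCD lobes at the absorption bands are negative.
#' Swapping the two transmittances (enantiomer exchange) flips the sign
#' exactly. Non-positive transmittances are masked to `NA`.
#'
#' @param T_plus,T_minus helicity transmittance vectors.
#' @return VCD vector.
#' @export
vcd_from_transmittances <- function(T_plus, T_minus) {
  T_plus <- as.numeric(T_plus); T_minus <- as.numeric(T_minus)
  bad <- !is.finite(T_plus) | !is.finite(T_minus) | T_plus <= 0 | T_minus <= 0
  out <- rep(NA_real_, length(T_plus))
  out[!bad] <- -log10(T_minus[!bad] / T_plus[!bad])
  out
}

#' Alternative VCD measure Delta-T over mean-T
#'
#' `(T_plus - T_minus) / ((T_plus + T_minus) / 2)`. For small differences
#' this equals `ln(10)` times the log-ratio VCD of
#' [vcd_from_transmittances()] to first order; it is exposed under its own
#' name and never silently substituted.
#'
#' @inheritParams vcd_from_transmittances
#' @return dimensionless vector.
#' @export
vcd_alternative <- function(T_plus, T_minus) {
  T_plus <- as.numeric(T_plus); T_minus <- as.numeric(T_minus)
  Tbar <- (T_plus + T_minus) / 2
  bad <- !is.finite(Tbar) | Tbar <= 0
  out <- rep(NA_real_, length(T_plus))
  out[!bad] <- (T_plus[!bad] - T_minus[!bad]) / Tbar[!bad]
  out
}

#' Beer-Lambert VCD baseline of a chiral material
#'
#' Helicity-resolved Beer-Lambert model: absorbances from
#' `n''_plus = Im(sqrt(eps mu) + kappa)` and `n''_minus` with the
#' `d/cos(theta)` path, converted to transmittances and combined with the
#' log-ratio VCD. Algebraically this collapses to the closed form
#' `VCD_BL = -8 pi nu (d/cos theta) Im(kappa) / ln 10`
#' (equivalently `+4 pi nu (d/cos theta) (n''_minus - n''_plus) / ln 10`),
#' which the implementation matches to round-off.
#'
#' @param material a [chiral_material()].
#' @inheritParams beer_lambert_absorbance
#' @return VCD vector (decadic absorbance units).
#' @export
beer_lambert_vcd <- function(material, d_um, nu, theta_deg = 0) {
  ev <- material_eval(chiral_material(material), check_wavenumbers(nu))
  A_plus <- beer_lambert_absorbance(Im(ev$n_plus), d_um, nu, theta_deg)
  A_minus <- beer_lambert_absorbance(Im(ev$n_minus), d_um, nu, theta_deg)
  vcd_from_transmittances(10^(-A_plus), 10^(-A_minus))
}

#' VCD from copolarized transmission only
#'
#' Suppresses helicity conversion by zeroing the cross terms
#' (`t_pm = t_mp = 0`) before forming `T_plus = |t_pp|^2`,
#' `T_minus = |t_mm|^2` and the log-ratio VCD. At normal incidence the
#' cross terms already vanish, so this equals the full VCD there.
#'
#' @param t a 2x2 complex Jones transmission matrix, or a list with vectors
#'   `t_pp` and `t_mm` (e.g. the result of [stack_response()]).
#' @return VCD vector.
#' @export
copolarized_vcd <- function(t) {
  if (is.matrix(t)) t <- list(t_pp = t[1, 1], t_mm = t[2, 2])
  vcd_from_transmittances(Mod(t$t_pp)^2, Mod(t$t_mm)^2)
}

#' Simulate a helicity-resolved spectrum for a stack
#'
#' Runs the full 4x4 pipeline at one incidence angle and assembles the
#' standard spectrum table.
#'
#' @param stack an [optical_stack()].
#' @param nu wavenumber grid in cm^-1.
#' @param theta_in incidence angle in degrees.
#' @return data.frame of class `"spectrum_set"` with columns
#'   `wavenumber_cm.1` (cm^-1), `T_plus`, `T_minus`, `A_plus`, `A_minus`,
#'   `vcd`.
#' @export
#' @examples
#' stk <- optical_stack(chiral_material(1), layer(ideal_absorber(), 25))
#' sp <- simulate_spectrum(stk, seq(400, 600, by = 10))
#' head(sp)
simulate_spectrum <- function(stack, nu, theta_in = 0) {
  rs <- stack_response(stack, nu, theta_in)
  out <- data.frame(wavenumber_cm.1 = rs$nu,
                    T_plus = rs$T_plus, T_minus = rs$T_minus)
  out$A_plus <- suppressWarnings(absorbance(rs$T_plus))
  out$A_minus <- suppressWarnings(absorbance(rs$T_minus))
  out$vcd <- vcd_from_transmittances(rs$T_plus, rs$T_minus)
  attr(out, "theta_in") <- theta_in
  class(out) <- c("spectrum_set", "data.frame")
  out
}

single_chiral_layer <- function(stack) {
  if (length(stack$layers) != 1L) {
    stop("deviation maps are defined for a single-layer stack", call. = FALSE)
  }
  stack$layers[[1L]]
}

#' Angular-spectral decomposition of VCD artifacts
#'
#' For every `(theta, nu)` cell computes three VCD models of increasing
#' rigor: the Beer-Lambert baseline `vcd_bl` (intrinsic material response),
#' the copolarized transfer-matrix solution `vcd_parallel` (interference,
#' but no helicity conversion), and the full 4x4 solution `vcd_full`. The
#' relative deviation maps
#' `dev_itf = (vcd_bl - vcd_parallel) / vcd_bl` and
#' `dev_cpl = (vcd_full - vcd_parallel) / vcd_bl`
#' isolate thin-film interference and LCP-RCP coupling contributions.
#' Cells where `|vcd_bl| < floor * max |vcd_bl|` are masked (`NA` in the
#' deviation maps): the baseline changes sign within a band and the ratio
#' is meaningless near its zero crossings.
#'
#' @param stack a single-layer [optical_stack()].
#' @param theta_grid incidence angles in degrees.
#' @param nu_grid wavenumber grid in cm^-1.
#' @param floor relative masking floor in `(0, 1)`; default `1e-3`.
#' @return object of class `"angular_map"`: list with `theta_grid`,
#'   `nu_grid`, matrices (`theta` x `nu`) `vcd_bl`, `vcd_parallel`,
#'   `vcd_full`, `dev_itf`, `dev_cpl`, and logical `mask` (TRUE = masked).
#' @export
deviation_maps <- function(stack, theta_grid, nu_grid, floor = 1e-3) {
  stopifnot(inherits(stack, "optical_stack"))
  if (length(theta_grid) == 0L || length(nu_grid) == 0L) {
    stop("theta_grid and nu_grid must be non-empty", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("floor must be a positive scalar", call. = FALSE)
  }
  ly <- single_chiral_layer(stack)
  nt <- length(theta_grid); nn <- length(nu_grid)
  vcd_bl <- vcd_par <- vcd_full <- matrix(NA_real_, nt, nn)
  for (i in seq_len(nt)) {
    th <- theta_grid[i]
    vcd_bl[i, ] <- beer_lambert_vcd(ly$material, ly$thickness_um, nu_grid, th)
    rs <- stack_response(stack, nu_grid, th)
    vcd_par[i, ] <- copolarized_vcd(rs)
    vcd_full[i, ] <- vcd_from_transmittances(rs$T_plus, rs$T_minus)
  }
  peak <- max(abs(vcd_bl), na.rm = TRUE)
  mask <- if (!is.finite(peak) || peak == 0) {
    matrix(TRUE, nt, nn)  # achiral baseline: the normalization is undefined everywhere
  } else {
    !is.finite(vcd_bl) | abs(vcd_bl) < floor * peak
  }
  if (all(mask)) warning("all map cells are masked (achiral baseline?)", call. = FALSE)
  dev_itf <- (vcd_bl - vcd_par) / vcd_bl
  dev_cpl <- (vcd_full - vcd_par) / vcd_bl
  dev_itf[mask] <- NA_real_
  dev_cpl[mask] <- NA_real_
  structure(list(theta_grid = as.numeric(theta_grid),
                 nu_grid = as.numeric(nu_grid),
                 vcd_bl = vcd_bl, vcd_parallel = vcd_par, vcd_full = vcd_full,
                 dev_itf = dev_itf, dev_cpl = dev_cpl, mask = mask,
                 floor = floor),
            class = "angular_map")
}

#' @export
print.angular_map <- function(x, ...) {
  cat(sprintf("<angular_map> %d angle(s) x %d wavenumber(s), %d/%d cells masked (floor %g)\n",
              length(x$theta_grid), length(x$nu_grid), sum(x$mask),
              length(x$mask), x$floor))
  invisible(x)
}
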