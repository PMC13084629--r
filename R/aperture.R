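#' Illumination/collection aperture configuration
#'
#' Focused illumination is modeled as an incoherent superposition of plane
#' waves within the acceptance cone `theta in [0, arcsin(NA))` of the
#' illumination objective; the detection objective accepts transmitted rays
#' within its own cone. Angles are sampled uniformly in `theta` (not in
#' solid angle), with `theta = 0` always the first sample; the incoherent
#' mean uses trapezoid end weights so that refining the angular grid
#' converges at second order to the continuous cone average.
#'
#' @param na_in,na_out illumination and collection numerical apertures in
#'   `(0, 1)`.
#' @param n_in,n_out number of angular samples per cone (`>= 1`);
#'   default 64.
#' @return object of class `"aperture_config"`.
#' @export
aperture_config <- function(na_in, na_out, n_in = 64L, n_out = n_in) {
  stopifnot(is.numeric(na_in), length(na_in) == 1L,
            is.numeric(na_out), length(na_out) == 1L)
  if (na_in <= 0 || na_in >= 1 || na_out <= 0 || na_out >= 1) {
    stop("numerical apertures must lie strictly in (0, 1)", call. = FALSE)
  }
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  if (n_in < 1L || n_out < 1L) stop("angular sample counts must be >= 1", call. = FALSE)
  structure(list(na_in = na_in, na_out = na_out, n_in = n_in, n_out = n_out),
            class = "aperture_config")
}

theta_samples <- function(theta_max_deg, n) {
  if (n == 1L) 0 else seq(0, theta_max_deg, length.out = n)
}

# trapezoid weights on a uniform theta grid (plain mean for n <= 2)
theta_weights <- function(n) {
  if (n <= 2L) return(rep(1 / n, n))
  w <- c(0.5, rep(1, n - 2L), 0.5)
  w / sum(w)
}

materials_match <- function(a, b, nu) {
  ea <- material_eval(a, nu); eb <- material_eval(b, nu)
  isTRUE(all.equal(ea$eps, eb$eps)) && isTRUE(all.equal(ea$mu, eb$mu)) &&
    isTRUE(all.equal(ea$kappa, eb$kappa))
}

#' Aperture-averaged helicity transmittances
#'
#' Incoherent mean of the plane-wave transmittances over the sampled
#' angles. When ambient and exit media match (the symmetric
#' air-sample-air case) each transmitted ray leaves at its incidence
#' angle, so the double sum over illumination and detection angles
#' collapses to a single sum over
#' `theta in [0, min(arcsin(na_in), arcsin(na_out))]`, which is the path
#' taken. For asymmetric half-spaces the full double sum is used with an
#' output-cone acceptance test: a ray contributes only if its exit angle
#' (from the generalized Snell invariant, mean index) falls inside the
#' collection cone.
#'
#' @param stack an [optical_stack()].
#' @param nu wavenumber grid in cm^-1.
#' @param cfg an [aperture_config()].
#' @return list with vectors `T_plus`, `T_minus`, the angles used
#'   (`theta_deg`), and per-angle weights.
#' @export
na_averaged_transmittances <- function(stack, nu, cfg) {
  stopifnot(inherits(stack, "optical_stack"), inherits(cfg, "aperture_config"))
  nu <- check_wavenumbers(nu)
  th_in_max <- asin(cfg$na_in) * 180 / pi
  th_out_max <- asin(cfg$na_out) * 180 / pi
  symmetric <- materials_match(stack$ambient, stack$exit, nu)
  if (symmetric) {
    thetas <- theta_samples(min(th_in_max, th_out_max), cfg$n_in)
    weights <- theta_weights(length(thetas))
  } else {
    thetas <- theta_samples(th_in_max, cfg$n_in)
    # acceptance per transmitted angle in the exit medium, mean-index Snell
    ev_in <- material_eval(stack$ambient, nu)
    ev_out <- material_eval(stack$exit, nu)
    n1 <- Re(ev_in$n_bar[1]); n2 <- Re(ev_out$n_bar[1])
    sin_out <- n1 * sin(thetas * pi / 180) / n2
    accept <- abs(sin_out) <= sin(th_out_max * pi / 180) + 1e-12
    if (!any(accept)) {
      stop("no illumination angle refracts into the collection cone", call. = FALSE)
    }
    w <- theta_weights(length(thetas)) * as.numeric(accept)
    thetas <- thetas[w > 0]
    weights <- w[w > 0] / sum(w)
  }
  Tp <- Tm <- rep(0, length(nu))
  for (i in seq_along(thetas)) {
    rs <- stack_response(stack, nu, thetas[i])
    Tp <- Tp + weights[i] * rs$T_plus
    Tm <- Tm + weights[i] * rs$T_minus
  }
  list(T_plus = Tp, T_minus = Tm, theta_deg = thetas, weights = weights)
}

#' Aperture-averaged VCD spectrum
#'
#' Average-then-log, in that order: the helicity transmittances are first
#' averaged incoherently over the aperture cone and the log-ratio VCD is
#' then applied to the means. This is the physically measured quantity
#' (detectors sum intensity before any logarithm) and differs from
#' averaging per-angle VCD curves for thick films.
#'
#' @inheritParams na_averaged_transmittances
#' @return VCD vector on `nu`.
#' @export
na_averaged_vcd <- function(stack, nu, cfg) {
  av <- na_averaged_transmittances(stack, nu, cfg)
  vcd_from_transmittances(av$T_plus, av$T_minus)
}
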