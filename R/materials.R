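#' Complex square root with non-negative imaginary part
#'
#' Branch used for the background index \eqn{\sqrt{\epsilon\mu}} of a passive
#' medium under the \eqn{e^{-i\omega t}} time convention: forward-decaying
#' waves require \eqn{\mathrm{Im}\,n \ge 0}.
#'
#' @param z complex vector.
#' @return complex vector, principal square root sign-flipped where needed so
#'   that `Im(result) >= 0` (ties broken towards `Re(result) >= 0`).
#' @keywords internal
csqrt_im_pos <- function(z) {
  w <- sqrt(as.complex(z))
  flip <- Im(w) < 0 | (Im(w) == 0 & Re(w) < 0)
  w[flip] <- -w[flip]
  w
}

#' Complex square root with non-negative real part
#'
#' Branch used for the impedance \eqn{\eta = \sqrt{\mu/\epsilon}}.
#' @param z complex vector.
#' @return complex vector with `Re(result) >= 0`.
#' @keywords internal
csqrt_re_pos <- function(z) {
  w <- sqrt(as.complex(z))
  flip <- Re(w) < 0 | (Re(w) == 0 & Im(w) < 0)
  w[flip] <- -w[flip]
  w
}

check_wavenumbers <- function(nu) {
  if (!is.numeric(nu) || length(nu) == 0L || any(!is.finite(nu)) || any(nu <= 0)) {
    stop("wavenumbers must be finite and strictly positive (cm^-1)", call. = FALSE)
  }
  as.numeric(nu)
}

#' Lorentz-oscillator parameter set
#'
#' Bundles the parameters of a multi-resonance Lorentz model for the complex
#' permittivity of a molecular film, plus a Pasteur chirality scale used by
#' the companion chirality dispersion model.
#'
#' @param eps_inf high-frequency dielectric constant (dimensionless, `>= 1`).
#' @param nu_p effective plasma wavenumber in cm^-1 (`> 0`).
#' @param kappa_0 dimensionless chirality scale; sign selects the enantiomer,
#'   `0` gives an achiral material.
#' @param nu_0 resonance wavenumbers in cm^-1, one per oscillator (`> 0`).
#' @param f oscillator strengths (dimensionless, `>= 0`), same length.
#' @param gamma damping constants in cm^-1 (`> 0`), same length.
#' @return object of class `"oscillator_set"`.
#' @seealso [ideal_absorber()], [lorentz_permittivity()], [pasteur_chirality()]
#' @export
#' @examples
#' osc <- oscillator_set(eps_inf = 2.25, nu_p = 100, kappa_0 = 1e-5,
#'                       nu_0 = 1650, f = 0.4, gamma = 30)
#' lorentz_permittivity(osc, c(1600, 1650, 1700))
oscillator_set <- function(eps_inf, nu_p, kappa_0, nu_0, f, gamma) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L,
            is.numeric(nu_p), length(nu_p) == 1L,
            is.numeric(kappa_0), length(kappa_0) == 1L)
  if (eps_inf < 1) stop("eps_inf must be >= 1", call. = FALSE)
  if (nu_p <= 0) stop("nu_p must be > 0", call. = FALSE)
  n <- length(nu_0)
  if (length(f) != n || length(gamma) != n) {
    stop("nu_0, f, gamma must have equal length", call. = FALSE)
  }
  if (n > 0L) {
    if (any(nu_0 <= 0)) stop("all resonance wavenumbers nu_0 must be > 0", call. = FALSE)
    if (any(gamma <= 0)) stop("all damping constants gamma must be > 0", call. = FALSE)
    if (any(f < 0)) stop("all oscillator strengths f must be >= 0", call. = FALSE)
  }
  structure(list(eps_inf = as.numeric(eps_inf), nu_p = as.numeric(nu_p),
                 kappa_0 = as.numeric(kappa_0),
                 nu_0 = as.numeric(nu_0), f = as.numeric(f),
                 gamma = as.numeric(gamma)),
            class = "oscillator_set")
}

#' @export
print.oscillator_set <- function(x, ...) {
  cat(sprintf("<oscillator_set> %d oscillator(s), eps_inf = %g, nu_p = %g cm-1, kappa_0 = %g\n",
              length(x$nu_0), x$eps_inf, x$nu_p, x$kappa_0))
  if (length(x$nu_0)) {
    print(data.frame(nu_0 = x$nu_0, f = x$f, gamma = x$gamma), row.names = TRUE)
  }
  invisible(x)
}

#' Lorentzian complex permittivity
#'
#' Evaluates the multi-oscillator Lorentz dielectric function
#' \deqn{\epsilon(\bar\nu) = \epsilon_\infty + \sum_j
#'   \frac{f_j \bar\nu_p^2}{\bar\nu_{0,j}^2 - \bar\nu^2 - i\gamma_j\bar\nu}}
#' Under the \eqn{e^{-i\omega t}} convention the imaginary part is
#' non-negative for every positive wavenumber (passive medium).
#'
#' @param osc an [oscillator_set()].
#' @param nu wavenumber grid in cm^-1, strictly positive.
#' @return complex vector of the same length as `nu`.
#' @export
lorentz_permittivity <- function(osc, nu) {
  stopifnot(inherits(osc, "oscillator_set"))
  nu <- check_wavenumbers(nu)
  eps <- rep(as.complex(osc$eps_inf), length(nu))
  for (j in seq_along(osc$nu_0)) {
    eps <- eps + osc$f[j] * osc$nu_p^2 /
      (osc$nu_0[j]^2 - nu^2 - 1i * osc$gamma[j] * nu)
  }
  eps
}

#' Lorentzian Pasteur chirality parameter
#'
#' Evaluates the chirality (Pasteur) dispersion sharing the resonances of the
#' permittivity model:
#' \deqn{\kappa(\bar\nu) = \kappa_0 \sum_j
#'   \frac{f_j \bar\nu_p^2 \,\bar\nu}{\bar\nu_{0,j}
#'   (\bar\nu_{0,j}^2 - \bar\nu^2 - i\gamma_j\bar\nu)}}
#' `Re(kappa)` drives optical rotation, `Im(kappa)` circular dichroism.
#' The result is exactly linear (and odd) in `kappa_0`.
#'
#' @inheritParams lorentz_permittivity
#' @return complex vector of the same length as `nu`.
#' @export
pasteur_chirality <- function(osc, nu) {
  stopifnot(inherits(osc, "oscillator_set"))
  nu <- check_wavenumbers(nu)
  kap <- rep(0 + 0i, length(nu))
  for (j in seq_along(osc$nu_0)) {
    kap <- kap + osc$f[j] * osc$nu_p^2 * nu /
      (osc$nu_0[j] * (osc$nu_0[j]^2 - nu^2 - 1i * osc$gamma[j] * nu))
  }
  osc$kappa_0 * kap
}

#' Tabulated complex dispersion
#'
#' Carrier for externally tabulated optical constants: a strictly increasing
#' wavenumber grid with complex permittivity, chirality and (optional)
#' permeability per point. Queries between grid points are linearly
#' interpolated (real and imaginary parts independently); out-of-range
#' queries are an error, never an extrapolation.
#'
#' @param nu strictly increasing wavenumbers in cm^-1, length `>= 2`.
#' @param eps complex permittivity per grid point (`Im(eps) >= 0`).
#' @param kappa complex Pasteur parameter per grid point; default 0.
#' @param mu complex permeability per grid point; default 1.
#' @return object of class `"dispersion_table"`.
#' @seealso [read_dispersion_csv()]
#' @export
dispersion_table <- function(nu, eps, kappa = 0 + 0i, mu = 1 + 0i) {
  nu <- as.numeric(nu)
  if (length(nu) < 2L) stop("dispersion table needs at least 2 grid points", call. = FALSE)
  if (any(!is.finite(nu)) || any(diff(nu) <= 0)) {
    stop("dispersion grid must be finite and strictly increasing", call. = FALSE)
  }
  n <- length(nu)
  expand <- function(x, what) {
    x <- as.complex(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(sprintf("'%s' must have length 1 or %d", what, n), call. = FALSE)
    if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", what), call. = FALSE)
    x
  }
  eps <- expand(eps, "eps"); kappa <- expand(kappa, "kappa"); mu <- expand(mu, "mu")
  if (any(Im(eps) < -1e-12)) {
    stop("Im(eps) must be >= 0 on the grid (passive medium)", call. = FALSE)
  }
  structure(list(nu = nu, eps = eps, kappa = kappa, mu = mu),
            class = "dispersion_table")
}

interp_complex <- function(x, y, xout) {
  complex(real = stats::approx(x, Re(y), xout, rule = 1)$y,
          imaginary = stats::approx(x, Im(y), xout, rule = 1)$y)
}

#' Chiral optical material
#'
#' A dispersive isotropic Pasteur medium: anything that can report
#' \eqn{(\epsilon, \mu, \kappa)} at a requested wavenumber. Sources:
#' an [oscillator_set()] (Lorentz models for \eqn{\epsilon} and
#' \eqn{\kappa}, \eqn{\mu = 1}), a [dispersion_table()], or constants.
#'
#' @param source an `oscillator_set`, a `dispersion_table`, or a numeric /
#'   complex constant permittivity.
#' @param mu,kappa constant permeability and chirality, used only when
#'   `source` is a constant permittivity. `mu` defaults to 1.
#' @param name optional label used in printing and config round-trips.
#' @return object of class `"chiral_material"`.
#' @export
#' @examples
#' air <- chiral_material(1)
#' glass <- chiral_material(2.25)
#' film <- chiral_material(ideal_absorber_oscillators())
chiral_material <- function(source, mu = 1, kappa = 0, name = NULL) {
  if (inherits(source, "chiral_material")) return(source)
  if (inherits(source, "oscillator_set")) {
    m <- list(type = "oscillators", osc = source)
  } else if (inherits(source, "dispersion_table")) {
    m <- list(type = "table", table = source)
  } else if (is.numeric(source) || is.complex(source)) {
    stopifnot(length(source) == 1L, length(mu) == 1L, length(kappa) == 1L)
    m <- list(type = "constant", eps = as.complex(source),
              mu = as.complex(mu), kappa = as.complex(kappa))
  } else {
    stop("unsupported material source", call. = FALSE)
  }
  m$name <- name
  structure(m, class = "chiral_material")
}

#' @export
print.chiral_material <- function(x, ...) {
  lbl <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("<chiral_material%s> source: %s\n", lbl, x$type))
  invisible(x)
}

#' Evaluate a material on a wavenumber grid
#'
#' @param mat a [chiral_material()].
#' @param nu wavenumber grid in cm^-1.
#' @return list with complex vectors `eps`, `mu`, `kappa` and the derived
#'   `n_bar = sqrt(eps * mu)` (branch `Im >= 0`), `eta = sqrt(mu/eps)`
#'   (branch `Re >= 0`), and eigenmode indices `n_plus`, `n_minus`.
#' @export
material_eval <- function(mat, nu) {
  stopifnot(inherits(mat, "chiral_material"))
  nu <- check_wavenumbers(nu)
  n <- length(nu)
  if (mat$type == "oscillators") {
    eps <- lorentz_permittivity(mat$osc, nu)
    kappa <- pasteur_chirality(mat$osc, nu)
    mu <- rep(1 + 0i, n)
  } else if (mat$type == "table") {
    tb <- mat$table
    if (any(nu < tb$nu[1] | nu > tb$nu[length(tb$nu)])) {
      stop(sprintf("wavenumber query outside tabulated range [%g, %g] cm^-1",
                   tb$nu[1], tb$nu[length(tb$nu)]), call. = FALSE)
    }
    eps <- interp_complex(tb$nu, tb$eps, nu)
    kappa <- interp_complex(tb$nu, tb$kappa, nu)
    mu <- interp_complex(tb$nu, tb$mu, nu)
  } else {
    eps <- rep(mat$eps, n); mu <- rep(mat$mu, n); kappa <- rep(mat$kappa, n)
  }
  n_bar <- csqrt_im_pos(eps * mu)
  list(eps = eps, mu = mu, kappa = kappa,
       n_bar = n_bar, eta = csqrt_re_pos(mu / eps),
       n_plus = n_bar + kappa, n_minus = n_bar - kappa)
}

#' Circular-eigenmode refractive indices
#'
#' The two helicities of an isotropic Pasteur medium propagate with
#' \eqn{n_\pm = \sqrt{\epsilon\mu} \pm \kappa} (square-root branch with
#' `Im >= 0`); the split `n_plus - n_minus = 2 kappa` is exact.
#'
#' @inheritParams material_eval
#' @return list with complex vectors `n_plus` and `n_minus`.
#' @export
eigen_indices <- function(mat, nu) {
  ev <- material_eval(mat, nu)
  list(n_plus = ev$n_plus, n_minus = ev$n_minus)
}

#' The packaged ideal-absorber preset
#'
#' Eight equidistant Lorentz oscillators (resonances 500, 1000, ..., 4000
#' cm^-1) tuned so that the thin-film Beer-Lambert absorbance shows evenly
#' spaced peaks of nearly equal amplitude; a synthetic reference material
#' designed to make spectral artifacts stand out against an "ideal"
#' absorption ladder. `eps_inf = 2.15`, `nu_p = 107` cm^-1 and, by default,
#' `kappa_0 = 1e-5`.
#'
#' @param kappa_0 chirality scale; `0` gives the achiral reference material,
#'   a negative value the opposite enantiomer.
#' @return `ideal_absorber()` returns a [chiral_material()];
#'   `ideal_absorber_oscillators()` the underlying [oscillator_set()].
#' @export
#' @examples
#' mat <- ideal_absorber()
#' str(eigen_indices(mat, 1500))
ideal_absorber <- function(kappa_0 = 1e-5) {
  chiral_material(ideal_absorber_oscillators(kappa_0), name = "ideal_absorber")
}

#' @rdname ideal_absorber
#' @export
ideal_absorber_oscillators <- function(kappa_0 = 1e-5) {
  oscillator_set(
    eps_inf = 2.15, nu_p = 107, kappa_0 = kappa_0,
    nu_0  = c(500, 1000, 1500, 2000, 2500, 3000, 3500, 4000),
    f     = c(0.3000, 0.4119, 0.6374, 0.2882, 0.5695, 0.2043, 0.3678, 0.5413),
    gamma = c(26.91, 37.17, 57.56, 26.18, 51.47, 18.51, 33.28, 48.91)
  )
}
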