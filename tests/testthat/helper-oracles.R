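# Independent oracles, deliberately kept free of package internals.

# complex cosine of the refraction angle with the passive-decay branch
oracle_cos <- function(n, s) {
  w <- sqrt(as.complex(1 - (s / n)^2))
  nw <- n * w
  flip <- Im(nw) < 0 | (Im(nw) == 0 & Re(nw) < 0)
  w[flip] <- -w[flip]
  w
}

# textbook scalar 2x2 transfer matrix for an isotropic multilayer,
# per linear polarization ("s" or "p"), vectorized over nu.
# media: list of complex index vectors (ambient, layers..., exit);
# d_um: thicknesses of the interior layers. Returns |t|^2 and |r|^2.
# Amplitude conventions cancel for symmetric ambient/exit, which is the
# regime the oracle is used in.
scalar_tmm <- function(media, d_um, nu, theta_deg, pol) {
  s <- media[[1]] * sin(theta_deg * pi / 180)
  coss <- lapply(media, oracle_cos, s = s)
  q <- function(i) if (pol == "s") media[[i]] * coss[[i]] else media[[i]] / coss[[i]]
  nmed <- length(media)
  m11 <- rep(1 + 0i, length(nu)); m12 <- m21 <- rep(0 + 0i, length(nu)); m22 <- m11
  for (i in seq_len(nmed - 1L)) {
    q1 <- q(i); q2 <- q(i + 1L)
    r <- (q1 - q2) / (q1 + q2)
    tt <- 2 * q1 / (q1 + q2)
    a11 <- 1 / tt; a12 <- r / tt; a21 <- r / tt; a22 <- 1 / tt
    n11 <- m11 * a11 + m12 * a21; n12 <- m11 * a12 + m12 * a22
    n21 <- m21 * a11 + m22 * a21; n22 <- m21 * a12 + m22 * a22
    m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
    if (i < nmed - 1L) {
      phi <- 2 * pi * nu * media[[i + 1L]] * coss[[i + 1L]] * d_um[i] * 1e-4
      pf <- exp(-1i * phi); pb <- exp(1i * phi)
      m11 <- m11 * pf; m12 <- m12 * pb
      m21 <- m21 * pf; m22 <- m22 * pb
    }
  }
  list(t = 1 / m11, r = m21 / m11, T = Mod(1 / m11)^2, R = Mod(m21 / m11)^2)
}

# circular-basis transmittance of an achiral stack: equal mix of s and p power
scalar_circular_T <- function(media, d_um, nu, theta_deg) {
  Ts <- scalar_tmm(media, d_um, nu, theta_deg, "s")$T
  Tp <- scalar_tmm(media, d_um, nu, theta_deg, "p")$T
  (Ts + Tp) / 2
}

# closed-form Fabry-Perot (Airy) amplitude transmission of a single slab in
# air at normal incidence, index n (complex), e^{-i omega t} convention
airy_t <- function(n, d_um, nu) {
  t12 <- 2 / (1 + n)
  t21 <- 2 * n / (n + 1)
  r <- (1 - n) / (1 + n)  # air -> slab; slab -> air is -r
  phi <- 2 * pi * nu * n * d_um * 1e-4
  t12 * t21 * exp(1i * phi) / (1 - r^2 * exp(2i * phi))
}

# exact Fabry-Perot transmission of a chiral slab in air at normal incidence,
# from the multiple-beam sum: the impedance (hence every Fresnel factor) is
# helicity-independent, eta = 1/n_bar, and each internal reflection flips
# helicity, so the round-trip phase is phi_signal + phi_other.
airy_chiral_t <- function(n_bar, n_signal, n_other, d_um, nu) {
  r <- (n_bar - 1) / (n_bar + 1)          # inside-looking-out Fresnel amplitude
  t12t21 <- 4 * n_bar / (1 + n_bar)^2
  phs <- 2 * pi * nu * n_signal * d_um * 1e-4
  pho <- 2 * pi * nu * n_other * d_um * 1e-4
  t12t21 * exp(1i * phs) / (1 - r^2 * exp(1i * (phs + pho)))
}

# Reference copy of the ideal-absorber parameters, written out independently of the
# packaged constructor so preset regressions are caught.
IA_REF <- list(
  eps_inf = 2.15, nu_p = 107, kappa_0 = 1e-5,
  nu_0  = c(500, 1000, 1500, 2000, 2500, 3000, 3500, 4000),
  f     = c(0.3000, 0.4119, 0.6374, 0.2882, 0.5695, 0.2043, 0.3678, 0.5413),
  gamma = c(26.91, 37.17, 57.56, 26.18, 51.47, 18.51, 33.28, 48.91)
)

band_centers <- IA_REF$nu_0

air <- function() chiral_material(1, name = "air")

film_stack <- function(d_um, kappa_0 = 1e-5) {
  optical_stack(air(), layer(ideal_absorber(kappa_0), d_um), air())
}
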