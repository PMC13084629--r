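#' A homogeneous layer of finite thickness
#'
#' @param material a [chiral_material()].
#' @param thickness_um layer thickness in micrometres (`> 0`). Converted
#'   internally to cm so that phases \eqn{2\pi\bar\nu n d} are dimensionless.
#' @return object of class `"tmm_layer"`.
#' @export
layer <- function(material, thickness_um) {
  material <- chiral_material(material)
  stopifnot(is.numeric(thickness_um), length(thickness_um) == 1L)
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("layer thickness must be finite and > 0 (um)", call. = FALSE)
  }
  structure(list(material = material, thickness_um = as.numeric(thickness_um)),
            class = "tmm_layer")
}

#' A stratified stack: ambient half-space, layers, exit half-space
#'
#' Zero layers (a bare interface between the two half-spaces) is allowed.
#'
#' @param ambient,exit [chiral_material()] half-spaces (entrance / exit side).
#' @param layers a single [layer()], a list of layers, or `NULL`.
#' @return object of class `"optical_stack"`.
#' @export
#' @examples
#' stk <- optical_stack(chiral_material(1), layer(ideal_absorber(), 10),
#'                      chiral_material(1))
optical_stack <- function(ambient, layers = NULL, exit = ambient) {
  ambient <- chiral_material(ambient)
  exit <- chiral_material(exit)
  if (inherits(layers, "tmm_layer")) layers <- list(layers)
  if (is.null(layers)) layers <- list()
  if (!all(vapply(layers, inherits, logical(1), "tmm_layer"))) {
    stop("'layers' must be layer() objects", call. = FALSE)
  }
  structure(list(ambient = ambient, layers = layers, exit = exit),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("<optical_stack> ambient | %d layer(s) | exit\n", length(x$layers)))
  for (ly in x$layers) {
    cat(sprintf("  layer: %s, d = %g um\n",
                if (is.null(ly$material$name)) ly$material$type else ly$material$name,
                ly$thickness_um))
  }
  invisible(x)
}

# ---- vectorized 2x2 complex block algebra (entries are wavenumber vectors) ----

m2 <- function(e11, e12, e21, e22) list(e11 = e11, e12 = e12, e21 = e21, e22 = e22)

m2_mul <- function(a, b) {
  m2(a$e11 * b$e11 + a$e12 * b$e21, a$e11 * b$e12 + a$e12 * b$e22,
     a$e21 * b$e11 + a$e22 * b$e21, a$e21 * b$e12 + a$e22 * b$e22)
}

m2_det <- function(a) a$e11 * a$e22 - a$e12 * a$e21

m2_inv <- function(a, context = NULL) {
  d <- m2_det(a)
  bad <- !is.finite(d) | Mod(d) == 0
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" at ", context(which(bad)[1]))
    stop("numerically singular forward block of the transfer matrix", where,
         call. = FALSE)
  }
  m2(a$e22 / d, -a$e12 / d, -a$e21 / d, a$e11 / d)
}

m2_diag <- function(x, y) m2(x, rep(0 + 0i, length(x)), rep(0 + 0i, length(x)), y)

m4_mul <- function(x, y) {
  list(A = m2_add(m2_mul(x$A, y$A), m2_mul(x$B, y$C)),
       B = m2_add(m2_mul(x$A, y$B), m2_mul(x$B, y$D)),
       C = m2_add(m2_mul(x$C, y$A), m2_mul(x$D, y$C)),
       D = m2_add(m2_mul(x$C, y$B), m2_mul(x$D, y$D)))
}

m2_add <- function(a, b) m2(a$e11 + b$e11, a$e12 + b$e12, a$e21 + b$e21, a$e22 + b$e22)

m2_at <- function(a, i) matrix(c(a$e11[i], a$e21[i], a$e12[i], a$e22[i]), 2, 2)

m4_at <- function(x, i) {
  rbind(cbind(m2_at(x$A, i), m2_at(x$B, i)),
        cbind(m2_at(x$C, i), m2_at(x$D, i)))
}

# ---- angles ----

snell_cosines <- function(ev, s_plus, s_minus) {
  branch <- function(n, s) {
    rad <- 1 - (s / n)^2
    w <- sqrt(rad)
    nw <- n * w
    flip <- Im(nw) < 0 | (Im(nw) == 0 & Re(nw) < 0)
    w[flip] <- -w[flip]
    list(cos = w, evanescent = Re(rad) < 0 | Mod(s / n) > 1)
  }
  p <- branch(ev$n_plus, s_plus)
  m <- branch(ev$n_minus, s_minus)
  list(cos_plus = p$cos, cos_minus = m$cos,
       evanescent_plus = p$evanescent, evanescent_minus = m$evanescent)
}

angle_state <- function(ev, ang, nu) {
  structure(list(
    cos_theta_plus = ang$cos_plus, cos_theta_minus = ang$cos_minus,
    k_plus = 2 * pi * nu * ev$n_plus, k_minus = 2 * pi * nu * ev$n_minus,
    evanescent_plus = ang$evanescent_plus, evanescent_minus = ang$evanescent_minus),
    class = "angle_state")
}

#' Generalized Snell refraction for the circular eigenmodes
#'
#' Each helicity conserves its own transverse invariant
#' \eqn{n_\pm \sin\theta_\pm} across media. The transmitted cosine is
#' \eqn{\cos\theta_{2\pm} = [1 - (k_{1\pm}/k_{2\pm})^2 \sin^2\theta_1]^{1/2}}
#' with the square-root branch chosen so that the transmitted field does not
#' grow along the propagation direction in a passive medium
#' (`Im(n cos theta) >= 0`, ties towards forward propagation). The
#' `evanescent_*` flags mark total-internal-reflection / complex-angle
#' conditions (negative real radicand or sine argument exceeding 1).
#'
#' @param mat1,mat2 incidence- and transmission-side [chiral_material()]s.
#' @param nu wavenumber grid in cm^-1.
#' @param theta_in incidence angle in degrees, `0 <= theta_in < 90`.
#' @return list with `angle_state` objects `medium1` and `medium2`, each
#'   holding complex `cos_theta_plus/minus`, wave vectors `k_plus/minus`
#'   (rad cm^-1) and evanescent flags.
#' @export
refract <- function(mat1, mat2, nu, theta_in) {
  nu <- check_wavenumbers(nu)
  if (!is.numeric(theta_in) || length(theta_in) != 1L ||
      theta_in < 0 || theta_in >= 90) {
    stop("theta_in must be a single angle in [0, 90) degrees", call. = FALSE)
  }
  ev1 <- material_eval(chiral_material(mat1), nu)
  ev2 <- material_eval(chiral_material(mat2), nu)
  st <- sin(theta_in * pi / 180)
  s_plus <- ev1$n_plus * st
  s_minus <- ev1$n_minus * st
  list(medium1 = angle_state(ev1, snell_cosines(ev1, s_plus, s_minus), nu),
       medium2 = angle_state(ev2, snell_cosines(ev2, s_plus, s_minus), nu))
}

# ---- interface and propagation matrices ----

# M_T (upper signs) and M_R (lower signs):
#   1/4 [ (1+h)(1 +/- c2p/c1p)   (h-1)(1 -/+ c2m/c1p) ]
#       [ (h-1)(1 -/+ c2p/c1m)   (1+h)(1 +/- c2m/c1m) ]
# with h = eta1/eta2 and c = cos(theta).
interface_m2 <- function(eta1, eta2, c1p, c1m, c2p, c2m, nu, theta) {
  # within ~1e-7 of an exactly-critical/grazing geometry the cosine ratios
  # exceed 1e7 and the extraction is numerically meaningless
  if (any(Mod(c1p) < 1e-7) || any(Mod(c1m) < 1e-7)) {
    stop(sprintf("grazing singularity: cos(theta_1) = 0 at theta = %g deg", theta),
         call. = FALSE)
  }
  h <- eta1 / eta2
  rpp <- c2p / c1p; rmp <- c2m / c1p; rpm <- c2p / c1m; rmm <- c2m / c1m
  list(M_T = m2(0.25 * (1 + h) * (1 + rpp), 0.25 * (h - 1) * (1 - rmp),
                0.25 * (h - 1) * (1 - rpm), 0.25 * (1 + h) * (1 + rmm)),
       M_R = m2(0.25 * (1 + h) * (1 - rpp), 0.25 * (h - 1) * (1 + rmp),
                0.25 * (h - 1) * (1 + rpm), 0.25 * (1 + h) * (1 - rmm)))
}

#' Interface submatrices M_T and M_R
#'
#' Builds the 2x2 transmission- and reflection-type submatrices of the 4x4
#' interface transfer matrix from the impedance ratio and the per-helicity
#' incidence/refraction cosines. At normal incidence both are free of
#' cross-helicity off-diagonal terms only in `M_T`; reflection flips
#' helicity, so the achiral normal-incidence `M_R` is anti-diagonal.
#'
#' @inheritParams refract
#' @param angle_states the list returned by [refract()] for the same
#'   `(mat1, mat2, nu, theta)`.
#' @param theta_in incidence angle in degrees (used for diagnostics).
#' @return list with 2x2 complex matrices `M_T` and `M_R` when `nu` is
#'   scalar, otherwise lists of entry vectors (`e11`, `e12`, `e21`, `e22`).
#' @export
interface_matrices <- function(mat1, mat2, nu, angle_states, theta_in = NA_real_) {
  nu <- check_wavenumbers(nu)
  ev1 <- material_eval(chiral_material(mat1), nu)
  ev2 <- material_eval(chiral_material(mat2), nu)
  st1 <- angle_states$medium1; st2 <- angle_states$medium2
  mm <- interface_m2(ev1$eta, ev2$eta,
                     st1$cos_theta_plus, st1$cos_theta_minus,
                     st2$cos_theta_plus, st2$cos_theta_minus,
                     nu, theta_in)
  if (length(nu) == 1L) {
    list(M_T = m2_at(mm$M_T, 1L), M_R = m2_at(mm$M_R, 1L))
  } else mm
}

phase_blocks <- function(n_plus, n_minus, cos_plus, cos_minus, nu, d_um) {
  d_cm <- d_um * 1e-4
  phi_p <- 2 * pi * nu * n_plus * cos_plus * d_cm
  phi_m <- 2 * pi * nu * n_minus * cos_minus * d_cm
  # forward entries e^{-i phi} may legitimately exceed 1 in modulus (the
  # transfer matrix maps exit-side to entrance-side amplitudes); guard only
  # against double-precision overflow.
  big <- pmax(abs(Im(phi_p)), abs(Im(phi_m)))
  if (any(big > 700)) {
    warning("propagation phase exponent exceeds 700; clipping to avoid overflow",
            call. = FALSE)
    clip <- function(phi) complex(real = Re(phi), imaginary = pmin(pmax(Im(phi), -700), 700))
    phi_p <- clip(phi_p); phi_m <- clip(phi_m)
  }
  list(forward = m2_diag(exp(-1i * phi_p), exp(-1i * phi_m)),
       backward = m2_diag(exp(1i * phi_p), exp(1i * phi_m)))
}

#' Propagation matrix of a layer
#'
#' Diagonal 4x4 factor `diag(exp(-i phi+), exp(-i phi-), exp(+i phi+),
#' exp(+i phi-))` with the layer-normal phase
#' \eqn{\phi_\pm = 2\pi\bar\nu n_\pm \cos\theta_\pm d}, encoding both phase
#' accumulation and absorption of the two circular eigenmodes. At normal
#' incidence this reduces to \eqn{\phi_\pm = 2\pi\bar\nu n_\pm d}.
#'
#' @param ly a [layer()].
#' @param nu scalar wavenumber in cm^-1.
#' @param angle_state the `angle_state` of this layer's medium (from
#'   [refract()] against the layer material).
#' @return 4x4 complex matrix.
#' @export
propagation_matrix <- function(ly, nu, angle_state) {
  stopifnot(inherits(ly, "tmm_layer"), length(nu) == 1L)
  nu <- check_wavenumbers(nu)
  ev <- material_eval(ly$material, nu)
  pb <- phase_blocks(ev$n_plus, ev$n_minus,
                     angle_state$cos_theta_plus, angle_state$cos_theta_minus,
                     nu, ly$thickness_um)
  zero <- matrix(0 + 0i, 2, 2)
  rbind(cbind(m2_at(pb$forward, 1L), zero), cbind(zero, m2_at(pb$backward, 1L)))
}

# evaluate every medium of the stack once on the grid and build the full
# transfer matrix, vectorized over nu
stack_blocks <- function(stack, nu, theta_deg) {
  nu <- check_wavenumbers(nu)
  if (theta_deg < 0 || theta_deg >= 90) {
    stop("incidence angle must be in [0, 90) degrees", call. = FALSE)
  }
  mats <- c(list(stack$ambient), lapply(stack$layers, `[[`, "material"),
            list(stack$exit))
  evs <- lapply(mats, material_eval, nu = nu)
  st <- sin(theta_deg * pi / 180)
  s_plus <- evs[[1]]$n_plus * st
  s_minus <- evs[[1]]$n_minus * st
  angs <- lapply(evs, snell_cosines, s_plus = s_plus, s_minus = s_minus)

  iface <- function(i) {
    mm <- interface_m2(evs[[i]]$eta, evs[[i + 1]]$eta,
                       angs[[i]]$cos_plus, angs[[i]]$cos_minus,
                       angs[[i + 1]]$cos_plus, angs[[i + 1]]$cos_minus,
                       nu, theta_deg)
    zero <- rep(0 + 0i, length(nu))
    list(A = mm$M_T, B = mm$M_R, C = mm$M_R, D = mm$M_T)
  }

  total <- iface(1L)
  for (j in seq_along(stack$layers)) {
    ev <- evs[[j + 1L]]; ang <- angs[[j + 1L]]
    pb <- phase_blocks(ev$n_plus, ev$n_minus, ang$cos_plus, ang$cos_minus,
                       nu, stack$layers[[j]]$thickness_um)
    zero2 <- m2_diag(rep(0 + 0i, length(nu)), rep(0 + 0i, length(nu)))
    prop <- list(A = pb$forward, B = zero2, C = zero2, D = pb$backward)
    total <- m4_mul(total, prop)
    total <- m4_mul(total, iface(j + 1L))
  }
  list(blocks = total, nu = nu, theta_deg = theta_deg, evs = evs, angs = angs)
}

#' Total 4x4 transfer matrix of a stack
#'
#' Ordered product of interface and propagation factors,
#' `T = M(ambient,1) P(1) M(1,2) P(2) ... M(N,exit)`; for zero layers the
#' bare-interface matrix. The matrix maps exit-side circular amplitudes
#' `(E>+, E>-, E<+, E<-)` to entrance-side amplitudes.
#'
#' @param stack an [optical_stack()].
#' @param nu scalar wavenumber in cm^-1.
#' @param theta_in incidence angle in degrees.
#' @return 4x4 complex matrix.
#' @export
total_transfer <- function(stack, nu, theta_in = 0) {
  stopifnot(inherits(stack, "optical_stack"), length(nu) == 1L)
  sb <- stack_blocks(stack, nu, theta_in)
  m4_at(sb$blocks, 1L)
}

#' Extract circular-basis transmission and reflection from a transfer matrix
#'
#' With no incoming wave on the exit side, the 2x2 circular transmission
#' operator is the inverse of the forward-forward block and the reflection
#' operator is `(backward-forward block) %*% transmission`.
#'
#' @param T_total a 4x4 complex transfer matrix (from [total_transfer()]).
#' @return list with 2x2 complex matrices `t` and `r`; rows index output
#'   helicity `(+, -)`, columns input helicity.
#' @export
transmission_reflection <- function(T_total) {
  stopifnot(is.matrix(T_total), all(dim(T_total) == c(4L, 4L)))
  A <- T_total[1:2, 1:2, drop = FALSE]
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (!is.finite(d) || Mod(d) == 0) {
    stop("numerically singular forward block of the transfer matrix", call. = FALSE)
  }
  t <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / d
  r <- T_total[3:4, 1:2, drop = FALSE] %*% t
  dimnames(t) <- dimnames(r) <- list(c("+", "-"), c("+", "-"))
  list(t = t, r = r)
}

#' Helicity-resolved transmittances
#'
#' Total transmitted intensity per incident helicity: preserved plus
#' converted power, `T_+ = |t_{++}|^2 + |t_{-+}|^2` and
#' `T_- = |t_{--}|^2 + |t_{+-}|^2` (first index output, second input).
#' No flux-projection cosine factors are applied.
#'
#' @param t 2x2 complex transmission matrix (as from
#'   [transmission_reflection()]), or a list with vectors `t_pp`, `t_pm`,
#'   `t_mp`, `t_mm`.
#' @return list with `T_plus` and `T_minus`.
#' @export
helicity_transmittances <- function(t) {
  if (is.matrix(t)) {
    t <- list(t_pp = t[1, 1], t_pm = t[1, 2], t_mp = t[2, 1], t_mm = t[2, 2])
  }
  list(T_plus = Mod(t$t_pp)^2 + Mod(t$t_mp)^2,
       T_minus = Mod(t$t_mm)^2 + Mod(t$t_pm)^2)
}

#' Full helicity response of a stack on a wavenumber grid
#'
#' Vectorized pipeline: one evaluation of every material on the grid, then
#' the 4x4 transfer-matrix product, transmission/reflection extraction and
#' helicity intensity sums per grid point.
#'
#' @param stack an [optical_stack()].
#' @param nu wavenumber grid in cm^-1.
#' @param theta_in incidence angle in degrees.
#' @return list with complex Jones entries `t_pp, t_pm, t_mp, t_mm`,
#'   `r_pp, r_pm, r_mp, r_mm`, intensity sums `T_plus, T_minus, R_plus,
#'   R_minus`, and the inputs `nu`, `theta_in`.
#' @export
stack_response <- function(stack, nu, theta_in = 0) {
  stopifnot(inherits(stack, "optical_stack"))
  sb <- stack_blocks(stack, nu, theta_in)
  A <- sb$blocks$A
  d <- m2_det(A)
  bad <- !is.finite(d) | Mod(d) == 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("numerically singular forward block at nu = %g cm^-1, theta = %g deg",
                 sb$nu[i], theta_in), call. = FALSE)
  }
  if (isTRUE(getOption("vcdtmm.verbose", FALSE))) {
    nrmA <- sqrt(Mod(A$e11)^2 + Mod(A$e12)^2 + Mod(A$e21)^2 + Mod(A$e22)^2)
    cond <- nrmA^2 / Mod(d)  # Frobenius-based bound for 2x2
    if (any(cond > 1e8)) {
      message(sprintf("conditioning: %d grid point(s) with cond > 1e8 at theta = %g deg",
                      sum(cond > 1e8), theta_in))
    }
  }
  t <- m2(A$e22 / d, -A$e12 / d, -A$e21 / d, A$e11 / d)
  r <- m2_mul(sb$blocks$C, t)
  out <- list(t_pp = t$e11, t_pm = t$e12, t_mp = t$e21, t_mm = t$e22,
              r_pp = r$e11, r_pm = r$e12, r_mp = r$e21, r_mm = r$e22)
  out$T_plus <- Mod(out$t_pp)^2 + Mod(out$t_mp)^2
  out$T_minus <- Mod(out$t_mm)^2 + Mod(out$t_pm)^2
  out$R_plus <- Mod(out$r_pp)^2 + Mod(out$r_mp)^2
  out$R_minus <- Mod(out$r_mm)^2 + Mod(out$r_pm)^2
  out$nu <- sb$nu
  out$theta_in <- theta_in
  out
}
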