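test_that("refract implements the generalized Snell law with the documented branch", {
  glass <- chiral_material(2.25)
  # normal incidence: unit cosines in both media, exactly
  st <- refract(air(), glass, 1000, 0)
  expect_identical(st$medium2$cos_theta_plus, 1 + 0i)
  expect_identical(st$medium1$cos_theta_minus, 1 + 0i)

  # scalar Snell closed form at 30 degrees
  st <- refract(air(), glass, 1000, 30)
  expect_equal(st$medium2$cos_theta_plus,
               as.complex(sqrt(1 - (sin(pi / 6) / 1.5)^2)), tolerance = 1e-14)
  expect_false(st$medium2$evanescent_plus)

  # beyond the critical angle into a rarer medium: evanescent, complex cosine
  rare <- chiral_material(0.25)   # n = 0.5
  st <- refract(air(), rare, 1000, 45)
  expect_true(st$medium2$evanescent_plus && st$medium2$evanescent_minus)
  expect_gt(abs(Im(st$medium2$cos_theta_plus)), 0)
  # decaying branch: Im(n cos theta) >= 0
  expect_gte(Im(0.5 * st$medium2$cos_theta_plus), 0)

  expect_error(refract(air(), glass, 1000, 90), "90")
  expect_error(refract(air(), glass, 1000, -1), "90")
})

test_that("Snell invariant n sin(theta) is conserved per helicity across media", {
  mat2 <- ideal_absorber()
  for (th in c(10, 35, 70)) {
    st <- refract(air(), mat2, c(480, 1500, 3990), th)
    n2p <- st$medium2$k_plus / (2 * pi * c(480, 1500, 3990))
    n2m <- st$medium2$k_minus / (2 * pi * c(480, 1500, 3990))
    # compare squared invariants to dodge the sine sign ambiguity
    s2p <- n2p^2 * (1 - st$medium2$cos_theta_plus^2)
    s2m <- n2m^2 * (1 - st$medium2$cos_theta_minus^2)
    expect_equal(s2p, as.complex(rep(sin(th * pi / 180)^2, 3)), tolerance = 1e-12)
    expect_equal(s2m, as.complex(rep(sin(th * pi / 180)^2, 3)), tolerance = 1e-12)
  }
})

test_that("interface matrices reduce correctly in degenerate geometries", {
  glass <- chiral_material(2.25)
  # identical media: M_T = identity, M_R = 0
  st <- refract(air(), air(), 1000, 25)
  mm <- interface_matrices(air(), air(), 1000, st, 25)
  expect_equal(mm$M_T, diag(2) + 0i, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(mm$M_R, matrix(0 + 0i, 2, 2), tolerance = 1e-14, ignore_attr = TRUE)

  # normal incidence: no cross-helicity terms in M_T for any media pair
  st <- refract(air(), ideal_absorber(), 700, 0)
  mm <- interface_matrices(air(), ideal_absorber(), 700, st, 0)
  expect_equal(mm$M_T[1, 2], 0 + 0i, tolerance = 1e-14)
  expect_equal(mm$M_T[2, 1], 0 + 0i, tolerance = 1e-14)

  # achiral air -> glass at normal incidence: Fresnel amplitude t = 0.8
  st <- refract(air(), glass, 1000, 0)
  mm <- interface_matrices(air(), glass, 1000, st, 0)
  expect_equal(solve(mm$M_T), 0.8 * diag(2) + 0i, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("grazing singularity (cos theta = 0 in a layer) is an explicit error", {
  # exactly at the critical angle of an n = 0.5 layer: sin(30 deg) = n
  stk <- optical_stack(air(), layer(chiral_material(0.25), 5), air())
  expect_error(stack_response(stk, 1000, 30), "grazing")
})

test_that("propagation matrix is diagonal with the layer-normal phase", {
  glass <- chiral_material(2.25)
  ly <- layer(glass, 3)
  st <- refract(air(), glass, 1000, 0)
  P <- propagation_matrix(ly, 1000, st$medium2)
  expect_true(all(P[row(P) != col(P)] == 0))
  # lossless, normal incidence: pure phase
  expect_equal(Mod(diag(P)), rep(1, 4), tolerance = 1e-14)
  expect_equal(P[1, 1], exp(-1i * 2 * pi * 1000 * 1.5 * 3e-4), tolerance = 1e-14)

  # vanishing thickness: continuous limit to the identity
  Peps <- propagation_matrix(layer(glass, 1e-9), 1000, st$medium2)
  expect_equal(Peps, diag(4) + 0i, tolerance = 1e-8)

  # absorbing layer: the extracted transmission decays with thickness
  lossy <- chiral_material(2.25 + 0.5i)
  T5 <- helicity_transmittances(transmission_reflection(
    total_transfer(optical_stack(air(), layer(lossy, 5), air()), 1000, 0))$t)
  T10 <- helicity_transmittances(transmission_reflection(
    total_transfer(optical_stack(air(), layer(lossy, 10), air()), 1000, 0))$t)
  expect_lt(T10$T_plus, T5$T_plus)
  expect_lt(T5$T_plus, 1)
})

test_that("total transfer and extraction reproduce Fresnel and Airy closed forms", {
  glass <- chiral_material(2.25)
  # zero layers, identical media: identity
  expect_equal(total_transfer(optical_stack(air(), NULL, air()), 1000, 40),
               diag(4) + 0i, tolerance = 1e-14, ignore_attr = TRUE)
  tr <- transmission_reflection(diag(4) + 0i)
  expect_equal(tr$t, diag(2) + 0i, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(tr$r, matrix(0 + 0i, 2, 2), tolerance = 1e-15, ignore_attr = TRUE)

  # bare air | glass interface at normal incidence: t = 0.8 on the diagonal;
  # reflection flips helicity (anti-diagonal) with amplitude 0.2 and energy
  # reflectance 0.04
  tr <- transmission_reflection(total_transfer(optical_stack(air(), NULL, glass), 1000, 0))
  expect_equal(tr$t, 0.8 * diag(2) + 0i, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(Mod(tr$r), matrix(c(0, 0.2, 0.2, 0), 2, 2), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(Mod(tr$r[2, 1])^2 + Mod(tr$r[1, 1])^2, 0.04, tolerance = 1e-14)

  # half-wave transparency: phi = pi at nu = 1000, n = 1.5 -> d = 10/3 um
  d_hw <- 1e4 / (2 * 1000 * 1.5)
  tr <- transmission_reflection(total_transfer(
    optical_stack(air(), layer(glass, d_hw), air()), 1000, 0))
  ht <- helicity_transmittances(tr$t)
  expect_equal(ht$T_plus, 1, tolerance = 1e-12)

  # chiral slab at normal incidence: decoupled helicities, Fabry-Perot oracle.
  # The exact closed form takes the Fresnel factors from the
  # helicity-independent impedance 1/n_bar and the round-trip phase from
  # phi_plus + phi_minus (internal reflections flip helicity); the naive
  # single-index Airy form is accurate only to O(kappa).
  nu <- seq(300, 4400, by = 50)
  ev <- material_eval(ideal_absorber(), nu)
  rs <- stack_response(film_stack(12), nu, 0)
  expect_lt(max(Mod(rs$t_pp - airy_chiral_t(ev$n_bar, ev$n_plus, ev$n_minus, 12, nu)) /
                  Mod(rs$t_pp)), 1e-10)
  expect_lt(max(Mod(rs$t_mm - airy_chiral_t(ev$n_bar, ev$n_minus, ev$n_plus, 12, nu)) /
                  Mod(rs$t_mm)), 1e-10)
  expect_lt(max(Mod(rs$t_pp - airy_t(ev$n_plus, 12, nu)) / Mod(rs$t_pp)), 1e-5)
  expect_true(all(Mod(rs$t_pm) < 1e-12) && all(Mod(rs$t_mp) < 1e-12))
})

test_that("helicity transmittances sum preserved and converted power", {
  expect_equal(helicity_transmittances(diag(2) + 0i),
               list(T_plus = 1, T_minus = 1))
  t <- matrix(c(0.6 + 0i, 0.3 + 0i, 0 + 0i, 0 + 0i), 2, 2)
  expect_equal(helicity_transmittances(t)$T_plus, 0.45)
  expect_equal(helicity_transmittances(t)$T_minus, 0)
})

test_that("achiral 4x4 limit agrees with the independent scalar s/p oracle", {
  nu <- seq(250, 4450, by = 30)
  evn <- material_eval(ideal_absorber(0), nu)$n_bar
  stk <- optical_stack(air(), layer(ideal_absorber(0), 8), air())
  for (th in c(0, 30, 50, 80)) {
    rs <- stack_response(stk, nu, th)
    T_oracle <- scalar_circular_T(list(rep(1 + 0i, length(nu)), evn,
                                       rep(1 + 0i, length(nu))), 8, nu, th)
    expect_equal(rs$T_plus, T_oracle, tolerance = 1e-10)
    # helicity degeneracy is exact
    expect_identical(rs$T_plus, rs$T_minus)
  }
})

test_that("lossless achiral slab conserves energy at propagating angles", {
  glass <- chiral_material(2.25)
  stk <- optical_stack(air(), layer(glass, 7), air())
  nu <- seq(400, 4000, by = 100)
  for (th in c(0, 20, 45, 75)) {
    rs <- stack_response(stk, nu, th)
    expect_equal(rs$T_plus + rs$R_plus, rep(1, length(nu)), tolerance = 1e-10)
    expect_equal(rs$T_minus + rs$R_minus, rep(1, length(nu)), tolerance = 1e-10)
  }
})

test_that("enantiomer exchange swaps the helicity channels at every angle", {
  nu <- seq(400, 4200, by = 75)
  for (th in c(0, 40, 72)) {
    rs_p <- stack_response(film_stack(15, 1e-5), nu, th)
    rs_m <- stack_response(film_stack(15, -1e-5), nu, th)
    expect_equal(rs_m$t_pp, rs_p$t_mm, tolerance = 1e-14)
    expect_equal(rs_m$t_pm, rs_p$t_mp, tolerance = 1e-14)
    expect_equal(rs_m$T_plus, rs_p$T_minus, tolerance = 1e-13)
    expect_equal(rs_m$T_minus, rs_p$T_plus, tolerance = 1e-13)
  }
})

test_that("multilayer stacks compose: two half-thickness layers equal one layer", {
  mat <- ideal_absorber()
  one <- optical_stack(air(), layer(mat, 10), air())
  two <- optical_stack(air(), list(layer(mat, 4), layer(mat, 6)), air())
  nu <- seq(450, 3900, by = 150)
  for (th in c(0, 55)) {
    a <- stack_response(one, nu, th)
    b <- stack_response(two, nu, th)
    expect_equal(a$t_pp, b$t_pp, tolerance = 1e-12)
    expect_equal(a$T_minus, b$T_minus, tolerance = 1e-12)
  }
})
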