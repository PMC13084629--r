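Package: vcdtmm
Title: Transfer-Matrix Simulation of Mid-Infrared Vibrational Circular
    Dichroism in Chiral Thin Films
Version: 0.1.0
Authors@R: person("vcdtmm", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rigorous 4x4 transfer-matrix simulator for mid-infrared
    absorbance and vibrational circular dichroism (VCD) of homogeneous
    isotropic chiral layers. Materials are described by Lorentz-oscillator
    dispersion for the complex permittivity and a Pasteur chirality
    parameter, or by tabulated optical constants. The pipeline covers
    oblique incidence with coupling between left- and right-circularly
    polarized waves, Beer-Lambert baselines, decomposition of
    interference and polarization-coupling artifacts into angular-spectral
    deviation maps, and incoherent numerical-aperture averaging for
    focused illumination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
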