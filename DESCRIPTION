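Package: aortaflow
Title: Valvular and Ascending Aortic Hemodynamics from 4D Flow MRI and
    Doppler Echocardiography
Version: 0.1.0
Authors@R:
    person("Aortaflow", "Developers", email = "maintainer@aortaflow.dev",
           role = c("aut", "cre"))
Description: Quantitative hemodynamic analysis of the thoracic aorta from
    time-resolved three-dimensional phase-contrast MRI (4D flow MRI) velocity
    fields and transthoracic Doppler echocardiography.  Computes voxelwise
    viscous energy loss rate (VELR) and vorticity maps at peak systole with
    ascending-aorta region-of-interest summaries (total VELR, VELR density,
    mean vorticity magnitude), traces massless-particle pathlines through the
    time-resolved field, and derives Doppler valvular metrics (transvalvular
    peak velocity, pressure gradients by simplified Bernoulli,
    continuity-equation effective orifice area, indexed EOA and discharge
    coefficient).  Ships analytic flow phantoms (Poiseuille, solid-body
    rotation, Lamb-Oseen vortex, uniform, linear shear) with closed-form
    ground truth for verification, a cohort simulator, and the group
    comparison procedure (Lilliefors normality gate, ANOVA or Kruskal-Wallis
    omnibus, Bonferroni-adjusted pairwise tests).
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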