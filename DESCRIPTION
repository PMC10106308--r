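Package: annulokin
Title: Mitral Annular Geometry and Deformational Kinematics from Sonomicrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the mitral annulus from time-resolved 3D positions of
    eight sonomicrometry crystals (or from their pairwise distances via
    classical multidimensional scaling), fits a closed periodic cubic spline,
    and computes per-frame annular geometry: projected annular area on the
    least-squares plane, intercommissural width and septolateral diameter from
    principal axes, annular circularity index, and non-planarity angle.
    Segments geometry time series into heartbeats from left-ventricular
    pressure and volume, derives per-beat deformational kinematics (maximal
    cyclical reduction, average deformation velocity, time-normalized cycle
    curves, fractional change), summarizes hemodynamics (two-axis ellipsoid
    volumes, ED/ES detection, body-surface-area indexing), estimates
    ventricular contractility as the slope of the end-systolic
    pressure-volume relationship during caval constriction, and relates
    annular kinematics to contractility by linear regression. Ships a
    ground-truthed synthetic-data generator (deforming saddle annulus coupled
    to a time-varying-elastance ventricle with preload/afterload intervention
    protocols) so every stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
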