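Package: inflamtraj
Title: Growth-Curve Trajectories of Depressive Symptoms by Baseline
    Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel polynomial growth-curve modelling of repeated
    depressive-symptom scores stratified by baseline interleukin-6 (IL-6)
    tertile, in the style of life-course cohort analyses. Provides a
    seeded synthetic-cohort generator emulating bounded symptom
    instruments, skewed serum biomarkers, person-level random
    intercept/slope structure and configurable attrition mechanisms;
    cohort preparation (CRP-based exclusion, tertile assignment,
    covariate transforms, age centering); maximum-likelihood mixed-model
    fitting via 'lme4' with a polynomial-order selection ladder and a
    random-structure convergence fallback; delta-method contrasts of
    predicted trajectory scores at an age grid with Benjamini-Hochberg
    false-discovery-rate adjustment and cross-cohort standardisation;
    and a sensitivity battery (sex-split tertiles, continuous
    inverse-normal-transformed exposure, flag-based exclusions,
    attrition regression, minimum-assessment refits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
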