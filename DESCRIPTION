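Package: ef1hemo
Title: First-Phase Ejection Fraction and Ventricular-Arterial Coupling
    from Aortic Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives left-ventricular systolic indices from single-beat
    aortic root pressure and flow waveforms: first-phase ejection fraction
    (EF1, the fraction of end-diastolic volume ejected up to peak aortic
    flow), left-ventricular ejection fraction (LVEF) estimated from the
    pressure wave alone via a lumped time-varying-elastance / two-element
    Windkessel model, end-systolic pressure at the dicrotic notch, and the
    ventricular-arterial coupling indices Ea, Ees and Ea/Ees.  Includes a
    time-varying-elastance Windkessel beat simulator for generating virtual
    cohorts with known ground truth, cohort file readers/writers, and the
    statistical layer used to compare EF1 with LVEF: z-scored linear
    regression with diagnostics, Pearson correlations with Fisher-z
    confidence intervals, and Dunn-Clark tests for overlapping dependent
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    pracma,
    car,
    lmtest,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
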