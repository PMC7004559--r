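Package: chronopump
Title: Pump-to-Patient Drug Transport and Semi-Physiological
    Pharmacokinetics for Chronomodulated Hepatic Artery Infusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fate of anticancer drug solutions from a
    programmable chronomodulated infusion pump to the patient's blood.
    Solves the one-dimensional advection of drug along the infusion line
    (method of characteristics and upwind finite differences), quantifies
    the tube fill delay and the glucose-rinse delivery spike, and designs
    corrected three-part pump programs (bolus, truncated sinusoid,
    rate-matched rinse) that deliver the clinically intended profile.
    Includes semi-physiological Liver/Blood/Organs compartmental models
    for irinotecan/SN38, oxaliplatin (free and protein-bound platinum)
    and 5-fluorouracil with patient-individualised compartment volumes,
    weighted least-squares fitting by a covariance matrix adaptation
    evolution strategy under clearance-route constraints, Sobol and
    likelihood-profile identifiability diagnostics, unbiased
    coefficient-of-variation summaries, fuzzy c-means patient clustering
    with the Fukuyama-Sugeno validity index, and a synthetic-cohort
    generator reproducing trial sampling schedules with proportional
    measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
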