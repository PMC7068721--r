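Package: oddballerp
Title: Infant Auditory-Oddball ERP Pipeline with Synthetic Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses infant auditory-oddball EEG studies with
    three stimulus conditions (Frequent, Infrequent, Trial Unique). Provides a
    synthetic-data generator with known ground truth (stimulus sequences,
    continuous multi-channel EEG with embedded event-related potential
    components, habituation decay, cohort tables with outcome coupling), a
    preprocessing chain (zero-phase Blackman FIR band-pass filtering, timing
    offset correction, epoching, peak-to-peak and flatline artifact rejection,
    trial-count equalization, dataset inclusion rules), age-specific component
    quantification at Fz (window mean amplitudes, peak latencies, jackknife
    leave-one-out latency tests with corrected statistics), derived markers
    (within-session habituation difference score, developmental delta-P3
    change score), and a statistical layer (repeated-measures mixed ANOVA with
    partial eta squared, paired contrasts with Cohen's d, Fisher r-to-z
    comparison of correlations, hierarchical regression with R-squared change,
    Benjamini-Hochberg false-discovery-rate correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
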