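Package: quenchmap
Title: Temperature Mapping of Non-Photochemical Quenching from
    Pulse-Amplitude-Modulated Fluorescence
Version: 0.1.0
Authors@R:
    person("Quenchmap", "Developers", email = "quenchmap@example.org",
           role = c("aut", "cre"))
Description: Deconvolutes pulse-amplitude-modulated (PAM) chlorophyll
    fluorescence saturating-pulse traces into non-photochemical quenching
    (NPQ) components (fast-relaxing qE-type, slow-relaxing, state-transition
    qT1/qT2-type) and photosystem II yields (Y(II), Fv/Fm, Kramer energy
    partition), using a dynamic selection of the dark-phase maximum and
    minimum Fm'.  Assembles per-well values measured under overlapping
    96-well plate temperature gradients into thermal-response curves, fits
    them with cubic polynomial or biphasic Hill models, and extracts
    peak/dip temperatures and amplitudes with bootstrap uncertainties.
    Includes a synthetic trace generator emulating the measurement protocol
    (far-red pre-illumination, 5 min actinic light, 5 min dark, 1-min
    saturating pulses) for end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
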