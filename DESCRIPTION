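Package: pacstim
Title: Brain-Mimetic Phase-Amplitude-Coupled Stimulation and iEEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesis of dithered, phase-amplitude-coupled biphasic
    pulse-train stimulation waveforms (plus mono-rhythmic and kindling
    controls) for deep-brain-stimulation experiments, together with the
    matching intracranial-EEG analysis stack: complex Morlet continuous
    wavelet scalograms, baseline z-scoring with stimulation-epoch gating,
    Tort-style phase-amplitude-coupling comodulograms, and an interictal
    delta-suppression dose-response biomarker. A built-in synthetic iEEG
    simulator with known ground truth (pink-noise background, interictal
    spikes, seizure-like events with termination-phase delta-HFO coupling,
    and a planted stimulation dose-response) makes every analysis stage
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
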