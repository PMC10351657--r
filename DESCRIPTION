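Package: pulvfp
Title: Spectral Fingerprinting and Ambulatory Seizure Detection from Pulvinar iEEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies a seizure-discriminating 5-Hz frequency band
    ("spectral fingerprint") from intracranial EEG using baseline
    z-normalized Morlet wavelet power, and deploys it for seizure detection
    from windowed power-in-band timelines, including an emulation of the
    Percept DBS BrainSense Timeline sensing mode (250 Hz local field
    potentials, one band-power value per window via the Fourier transform).
    Ships a seeded synthetic two-channel pulvinar iEEG generator (1/f
    background plus planted narrowband ictal rhythms and optional broadband
    high-frequency components) so the whole pipeline is testable without
    patient recordings, plus EDF and CSV readers/writers and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
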