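Package: neoecg
Title: Wavelet-Based Neonatal ECG Monitoring: Denoising, Bradycardia
    Alarms, HRV and Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for single-lead neonatal (preterm infant)
    electrocardiograms built on the undecimated (stationary) wavelet
    transform with the Daubechies-8 mother wavelet. Provides baseline
    drift removal from the deep approximation band, adaptive per-level
    soft-threshold denoising, personalized R-peak detection with a 70%
    adaptive amplitude reference, RR-interval and relative-RR analysis
    with bradycardia and tachycardia alarms, RMSSD/SDNN/SDANN heart rate
    variability metrics, and sparsity-based compression of thresholded
    wavelet coefficients with 8-bit quantization. Operates on streamed
    1000-sample blocks with detector state carried across block
    boundaries. Reads WFDB and CSV records and includes a synthetic
    neonatal ECG generator with ground-truth beat positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
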