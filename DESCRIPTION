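Package: pupilAAS
Title: Pupil-Linked Ascending Arousal System Coupling in Resting-State fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the coupling between spontaneous pupil-size
    fluctuations and BOLD activity in ascending arousal system (AAS) nuclei
    during rest. Implements the full analysis chain: pupil preprocessing
    (blink interpolation, derivative, temporal shift, TR-binned resampling
    with outlier rejection), a 33-column movement plus RETROICOR
    physiological nuisance model, first-level GLMs with DCT high-pass and
    AR(1) prewhitening, a double-gamma HRF family with adjustable
    time-to-peak and a systematic TTP sweep, blind point-process HRF
    deconvolution with Wiener recovery of the neural signal, lagged
    cross-correlation and Welch cross-spectral density of unconvolved pupil
    and BOLD series, second-level group statistics with FDR control, and
    data-quality metrics (tSNR, contrast-to-noise, partial correlations
    among nuclei). A synthetic-session generator with known ground-truth
    coupling makes every stage verifiable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'hrf.R'
    'glm.R'
    'coupling.R'
    'deconvolve.R'
    'groupstats.R'
    'qc.R'
    'nuisance.R'
    'pupil.R'
    'simulate.R'
    'io.R'
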