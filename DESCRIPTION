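Package: swdsync
Title: Wavelet Phase Synchronization Analysis and Detection of Absence
    Seizures in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying scalp-EEG phase synchronization with the
    complex Morlet continuous wavelet transform and for detecting generalized
    spike-and-wave discharges (absence seizures) from it.  Provides pairwise,
    channel and global phase-synchronization indices on sliding 1-s windows,
    a two-feature (global synchronization, normalized amplitude) k-nearest
    neighbour seizure detector with leave-one-subject-out cross-validation,
    overlap/false-positive performance metrics, a seizure-fragmentation
    statistic for disorganized discharges, EDF and annotation I/O, and a
    synthetic multichannel spike-and-wave EEG simulator for end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
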