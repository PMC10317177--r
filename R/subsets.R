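#' Standard 10-20 channel subsets
#'
#' The four electrode subsets used throughout the analysis.  `S19` is the
#' full 10-20 setup; the reduced subsets correspond to electrode layouts
#' achievable with low-cost EEG headsets (frontal/temporal/occipital):
#' `S4` = Fp1, Fp2, T5, T6; `S6` = Fp1, Fp2, F7, F8, O1, O2;
#' `S12` adds F3, F4, P3, P4 and T5, T6 to `S6`.
#'
#' @param name One of `"S19"`, `"S12"`, `"S6"`, `"S4"`.
#' @return Character vector of 10-20 channel labels.
#' @export
#' @examples
#' channel_subset("S6")
channel_subset <- function(name = c("S19", "S12", "S6", "S4")) {
  name <- match.arg(name)
  switch(name,
    S4  = c("Fp1", "Fp2", "T5", "T6"),
    S6  = c("Fp1", "Fp2", "F7", "F8", "O1", "O2"),
    S12 = c("Fp1", "Fp2", "F7", "F8", "F3", "F4",
            "P3", "P4", "T5", "T6", "O1", "O2"),
    S19 = montage_10_20()
  )
}

#' @rdname channel_subset
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}
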