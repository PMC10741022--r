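#' Published per-area connectivity reference profile
#'
#' A published reference table from a sentence-reading fMRI study: the evolved
#' reservoir connectivity around each of 20 selected input voxels (grouped by
#' brain region of interest) for two classes of trials, reading negative
#' (`Neg`) versus affirmative (`Aff`) sentences, together with the per-class
#' average as printed in the source table.  Useful as a worked example for
#' [profile_class_means()] and for sanity-checking connectivity arithmetic.
#' Note the printed `Neg` average (1.7) does not equal the arithmetic mean of
#' its 20 values (~1.08); the `Aff` average (0.6) does.  This package always
#' computes the arithmetic mean.
#'
#' @return A tibble with columns `class`, `position`, `area`, `value`,
#'   `printed_avg`.
#' @export
sentence_connectivity_reference <- function() {
  path <- system.file("extdata", "sentence_connectivity_reference.csv",
                      package = "stamcube", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
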