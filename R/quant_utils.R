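#' Bead-corrected absolute cell count
#'
#' Flow-cytometry counting beads added at a known total allow converting a
#' counted (acquired) fraction into an absolute count:
#' `viable_cells * total_beads / counted_beads`. The result is returned
#' unrounded.
#'
#' @param viable number of viable cells acquired.
#' @param total_beads beads spiked into the sample.
#' @param counted_beads beads acquired alongside the cells (> 0).
#' @return Absolute cell count (real-valued).
#' @export
bead_corrected_count <- function(viable, total_beads, counted_beads) {
  if (any(counted_beads <= 0)) stop("`counted_beads` must be > 0")
  as.numeric(viable) * as.numeric(total_beads) / as.numeric(counted_beads)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Classical qPCR fold change with amplification efficiency fixed at 2:
#' `ddct = (Ct_target - Ct_reference)_sample - (Ct_target - Ct_reference)_calibrator`
#' and the fold change is `2^-ddct`. The reference gene (e.g. beta-actin)
#' normalizes input amounts; the calibrator (e.g. control group) anchors the
#' scale so its own fold change is 1.
#'
#' @param ct_target_sample,ct_reference_sample Ct values in the sample.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator.
#' @return Fold change relative to the calibrator.
#' @export
relative_expression <- function(ct_target_sample, ct_reference_sample,
                                ct_target_calibrator, ct_reference_calibrator) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_calibrator, ct_reference_calibrator)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Cells per gram of tissue
#'
#' @param absolute_count absolute cell count (e.g. from
#'   [bead_corrected_count()]).
#' @param tissue_mass_g tissue mass in grams (> 0).
#' @return Cells per gram.
#' @export
per_gram_density <- function(absolute_count, tissue_mass_g) {
  if (any(tissue_mass_g <= 0)) stop("`tissue_mass_g` must be > 0")
  absolute_count / tissue_mass_g
}
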