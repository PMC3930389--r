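#' Jaccard overlap index between two ROI masks
#'
#' `J = |A intersect B| / |A union B|`, in `[0, 1]`; 1 means the two ROIs
#' overlap completely (no geometric distortion between the modalities they
#' were drawn on). Two empty masks are defined to agree vacuously (`J = 1`,
#' with a warning) rather than returning `NaN`.
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of the same shape.
#' @return Jaccard index, dimensionless.
#' @export
jaccard_index <- function(mask_a, mask_b) {
  stopifnot_same_grid(mask_a, mask_b, "masks")
  a <- mask_a != 0
  b <- mask_b != 0
  uni <- sum(a | b)
  if (uni == 0L) {
    warning("both masks empty; Jaccard index defined as 1 (vacuous agreement)",
            call. = FALSE)
    return(1)
  }
  sum(a & b) / uni
}

#' Overlap quality gate
#'
#' Passes when the Jaccard index strictly exceeds the threshold (0.6 by
#' default, the conventional cutoff for a strong degree of overlap). A value
#' exactly at the threshold fails.
#'
#' @param j Jaccard index in `[0, 1]`.
#' @param threshold gate threshold.
#' @param verbose log the decision.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_gate <- function(j, threshold = 0.6, verbose = TRUE) {
  if (any(j < 0 | j > 1)) stop("`j` must be in [0, 1]", call. = FALSE)
  pass <- j > threshold
  if (verbose)
    message(sprintf("qc_gate: J = %.3f vs threshold %.2f -> %s",
                    j, threshold, ifelse(pass, "pass", "fail")))
  pass
}
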