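#' Label connected components of a binary mask
#'
#' 8-connectivity by default (diagonal neighbours belong to the same
#' component, appropriate for blob-like stained vessels): a fast 4-connected
#' labelling pass is followed by union-find merging of labels that touch
#' diagonally.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- (mask != 0) * 1L
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1L) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    nr <- nrow(lab); nc <- ncol(lab)
    for (off in list(c(1, 1), c(1, -1))) {
      a <- lab[seq_len(nr - 1), seq_len(nc - 1) + (off[2] < 0), drop = FALSE]
      b <- lab[seq_len(nr - 1) + 1,
               seq_len(nc - 1) + (off[2] > 0), drop = FALSE]
      touch <- which(a > 0L & b > 0L & a != b)
      for (i in touch) {
        ra <- find(a[i]); rb <- find(b[i])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    relabel <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
    nlab <- length(unique(root))
  } else if (connectivity != 4 && connectivity != 8) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(lab, n_components = as.integer(nlab))
}

#' Microvessel metrics from a binary vessel mask
#'
#' Counts 8-connected components of the vessel mask inside the tissue mask
#' and reports the standard vascularity summaries: vessel density (vessels
#' per mm^2 of tissue), mean vessel size (mm^2 per vessel), and area ratio
#' (vessel area / tissue area). The identity
#' `area_ratio == vessel_density * vessel_size` holds exactly. With zero
#' vessels, density and ratio are 0 and size is the sentinel `NA`.
#'
#' @param vessel_mask logical matrix; must be contained in `tissue_mask`.
#' @param tissue_mask non-empty logical matrix of the analysed tissue area.
#' @param pixel_size_mm pixel edge length, mm.
#' @param min_area_px optional minimum component area (pixels); smaller
#'   components are dropped before counting (no filtering by default).
#' @return a list of class `vessel_metrics`: `n_vessels`, `vessel_density`
#'   (1/mm^2), `vessel_size` (mm^2), `area_ratio`, `tissue_area_mm2`.
#' @export
vessel_metrics <- function(vessel_mask, tissue_mask, pixel_size_mm,
                           min_area_px = 0L) {
  stopifnot_same_grid(vessel_mask, tissue_mask, "vessel and tissue masks")
  if (pixel_size_mm <= 0) stop("`pixel_size_mm` must be > 0", call. = FALSE)
  vm <- vessel_mask != 0
  tm <- tissue_mask != 0
  if (!any(tm)) stop("tissue mask is empty", call. = FALSE)
  if (any(vm & !tm))
    stop("vessel mask extends outside the tissue mask", call. = FALSE)
  px_area <- pixel_size_mm^2
  lab <- label_components(vm, connectivity = 8)
  n <- attr(lab, "n_components")
  if (min_area_px > 0L && n > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_area_px)
    vm <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    n <- length(keep)
  }
  tissue_area <- sum(tm) * px_area
  vessel_area <- sum(vm) * px_area
  structure(list(
    n_vessels = n,
    vessel_density = n / tissue_area,
    vessel_size = if (n > 0L) vessel_area / n else NA_real_,
    area_ratio = vessel_area / tissue_area,
    tissue_area_mm2 = tissue_area),
    class = "vessel_metrics")
}
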