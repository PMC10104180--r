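#' Label parcellation regions as resected or spared
#'
#' Overlays a binary resection mask (in pre-operative voxel space) on a
#' parcellation label volume and computes, per region, the fraction of its
#' voxels falling inside the mask. A region is resected when that fraction
#' strictly exceeds the threshold (default 0.10, i.e. >10% regional volume
#' loss; 0.25 and 0.50 are the usual robustness alternatives).
#'
#' @param parcellation 3D integer label array or `RNifti` image.
#' @param mask Binary 3D array or `RNifti` image of the same shape.
#' @param threshold Volume-loss fraction above which a region counts as
#'   resected (strict inequality).
#' @return Data frame of class `resection_labeling`: `region_id`,
#'   `n_voxels`, `n_masked`, `fraction`, `resected`, with the threshold as
#'   attribute. Regions with zero voxels are flagged via `NA` fraction.
#' @export
label_resections <- function(parcellation, mask, threshold = 0.10) {
  p_img <- inherits(parcellation, "niftiImage")
  m_img <- inherits(mask, "niftiImage")
  if (p_img && m_img &&
      !isTRUE(all.equal(RNifti::xform(parcellation), RNifti::xform(mask),
                        tolerance = 1e-6)))
    stop("parcellation and mask affines differ")
  parc <- as.array(parcellation)
  msk <- as.array(mask)
  if (!identical(dim(parc), dim(msk)))
    stop("parcellation and mask shapes differ")
  if (!all(msk %in% c(0, 1)))
    stop("resection mask must be binary")
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  regions <- sort(setdiff(unique(as.vector(parc)), 0))
  n_vox <- vapply(regions, function(r) sum(parc == r), integer(1))
  n_msk <- vapply(regions, function(r) sum(parc == r & msk == 1), integer(1))
  frac <- ifelse(n_vox > 0, n_msk / n_vox, NA_real_)
  out <- data.frame(region_id = as.character(regions), n_voxels = n_vox,
                    n_masked = n_msk, fraction = frac,
                    resected = !is.na(frac) & frac > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("resection_labeling", "data.frame")
  out
}

#' Write a resection labeling to CSV and a JSON summary
#' @param labeling A `resection_labeling`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_resection_labeling <- function(labeling, csv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(labeling, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(threshold = attr(labeling, "threshold"),
           n_regions = nrow(labeling),
           n_resected = sum(labeling$resected),
           resected_regions = labeling$region_id[labeling$resected]),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(labeling)
}
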