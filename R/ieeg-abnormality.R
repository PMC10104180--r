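#' Canonical iEEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-80 Hz. Band
#' edges are half-open `[low, high)` so shared edges are not counted twice.
#'
#' @return Data frame with columns `band`, `low`, `high` (Hz).
#' @export
ieeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 80),
             stringsAsFactors = FALSE)
}

#' Construct an iEEG recording
#'
#' @param samples Numeric matrix, contacts x samples (microvolts).
#' @param fs Sampling rate (Hz).
#' @param contact_ids Contact labels; default `c1..cN`.
#' @return Object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(samples, fs, contact_ids = NULL) {
  samples <- as.matrix(samples)
  if (is.null(contact_ids))
    contact_ids <- rownames(samples) %||% paste0("c", seq_len(nrow(samples)))
  if (length(contact_ids) != nrow(samples))
    stop("contact_ids must match the number of rows (contacts)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  rownames(samples) <- contact_ids
  structure(list(samples = samples, fs = fs,
                 contact_ids = as.character(contact_ids),
                 duration = ncol(samples) / fs),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d contacts, %.1f s @ %g Hz\n",
              nrow(x$samples), x$duration, x$fs))
  invisible(x)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across included contacts from each
#' contact. Idempotent; undefined for a single contact.
#'
#' @param recording An `ieeg_recording`.
#' @param exclude Contact ids to leave out of the average (they are still
#'   re-referenced).
#' @return Re-referenced `ieeg_recording`.
#' @export
common_average_reference <- function(recording, exclude = NULL) {
  stopifnot(inherits(recording, "ieeg_recording"))
  keep <- !(recording$contact_ids %in% exclude)
  if (sum(keep) < 2L)
    stop("common average reference requires >=2 included contacts")
  avg <- colMeans(recording$samples[keep, , drop = FALSE])
  recording$samples <- sweep(recording$samples, 2, avg)
  recording
}

#' Welch power spectral density
#'
#' Mean-averaged modified periodogram over Hamming-tapered segments with
#' 50% overlap. One-sided density in (units^2)/Hz.
#'
#' @param x Numeric matrix (contacts x samples) or vector.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution so the 1 Hz delta edge is resolved within a 70 s window).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (contacts x frequencies).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nseg <- round(window_s * fs)
  if (ncol(x) < nseg)
    stop("signal shorter than one Welch segment")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, ncol(x) - nseg + 1L, by = step)
  nsg <- length(starts)
  nch <- nrow(x)
  w <- signal::hamming(nseg)
  scale <- fs * sum(w^2)
  nf <- nseg %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nseg
  seg_idx <- outer(seq_len(nseg), starts - 1L, "+")
  # stack every segment of every channel into one matrix, FFT once
  segs <- matrix(t(x)[as.vector(seg_idx), , drop = FALSE],
                 nrow = nseg) * w
  P <- abs(stats::mvfft(segs)[seq_len(nf), , drop = FALSE])^2 / scale
  pw <- rowsum(t(P), rep(seq_len(nch), each = nsg)) / nsg
  # one-sided: double everything except DC (and Nyquist when present)
  mult <- rep(2, nf)
  mult[1] <- 1
  if (nseg %% 2L == 0L) mult[nf] <- 1
  psd <- pw * rep(mult, each = nch)
  rownames(psd) <- rownames(x)
  list(freq = freq, psd = psd)
}

#' Raw band power per contact
#'
#' Welch PSD followed by trapezoidal integration over each half-open
#' canonical band `[low, high)`.
#'
#' @param recording An `ieeg_recording` (fs > 160 Hz, duration >= 10 s).
#' @param bands Band definition table, default [ieeg_bands()].
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @return A `band_power_table`: contacts x bands matrix with attribute
#'   `stage = "raw"`.
#' @export
band_power <- function(recording, bands = ieeg_bands(),
                       window_s = 2, overlap = 0.5) {
  stopifnot(inherits(recording, "ieeg_recording"))
  if (recording$fs <= 160)
    stop("sampling rate must exceed 160 Hz to resolve the gamma band")
  if (recording$duration < 10)
    stop("recording shorter than 10 s")
  if (anyNA(recording$samples)) {
    bad <- rowSums(is.na(recording$samples)) > 0
    stop(sprintf("NaN/NA samples in contact(s): %s",
                 paste(recording$contact_ids[bad], collapse = ", ")))
  }
  ps <- welch_psd(recording$samples, recording$fs,
                  window_s = window_s, overlap = overlap)
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- ps$freq >= bands$low[b] & ps$freq < bands$high[b]
    apply(ps$psd[, sel, drop = FALSE], 1, function(p)
      trapz(ps$freq[sel], p))
  }, numeric(nrow(recording$samples)))
  out <- matrix(out, nrow = nrow(recording$samples),
                dimnames = list(recording$contact_ids, bands$band))
  structure(out, stage = "raw", class = c("band_power_table", "matrix", "array"))
}

#' Relative band power
#'
#' Default order follows the literal normative-mapping recipe: band powers
#' are log10-transformed, then normalised to sum to 1 per contact. The log
#' is only meaningful when every raw band power exceeds 1 in its native
#' units; a guard enforces this. The alternative order
#' (`"normalize-then-log"`) first divides by the total power, then takes
#' log10 and renormalises the (all-negative) logs to sum to 1.
#'
#' @param raw A raw-stage `band_power_table`.
#' @param order `"log-then-normalize"` (default) or `"normalize-then-log"`.
#' @return A `band_power_table` with attribute `stage = "relative"`; rows
#'   sum to 1.
#' @export
relative_band_power <- function(raw,
                                order = c("log-then-normalize",
                                          "normalize-then-log")) {
  order <- match.arg(order)
  stopifnot(inherits(raw, "band_power_table"),
            identical(attr(raw, "stage"), "raw"))
  m <- unclass(raw)
  attr(m, "stage") <- NULL
  if (order == "log-then-normalize") {
    if (any(m <= 1))
      stop("raw band power <= 1 found; rescale the signal so all band powers exceed 1 (log10 would be non-positive), or use order = 'normalize-then-log'")
    v <- log10(m)
  } else {
    v <- log10(m / rowSums(m))
  }
  rel <- v / rowSums(v)
  structure(rel, stage = "relative",
            class = c("band_power_table", "matrix", "array"))
}

#' Assign electrode contacts to parcellation regions
#'
#' Assigns each contact to the grey-matter region whose nearest voxel
#' centre lies closest in world (mm) space, provided that distance is
#' below `max_dist` (default 5 mm); otherwise the contact is unassigned.
#' Distance ties are broken by the lowest region id.
#'
#' @param contacts Data frame with columns `contact_id`, `x`, `y`, `z`
#'   (mm, in the volume's world frame).
#' @param parcellation 3D integer label array or `RNifti` image.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). For an
#'   `RNifti` image the stored xform is used by default.
#' @param grey_region_ids Region labels eligible for assignment; default
#'   all positive labels.
#' @param max_dist Assignment radius in mm.
#' @return Data frame: `contact_id`, `region_id` (`NA` if unassigned),
#'   `distance` (mm).
#' @export
assign_contacts <- function(contacts, parcellation, affine = NULL,
                            grey_region_ids = NULL, max_dist = 5) {
  arr <- if (inherits(parcellation, "niftiImage")) {
    if (is.null(affine)) affine <- RNifti::xform(parcellation)
    as.array(parcellation)
  } else as.array(parcellation)
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) stop("affine is non-invertible")
  if (is.null(grey_region_ids))
    grey_region_ids <- sort(setdiff(unique(as.vector(arr)), 0))
  vox <- which(array(arr %in% grey_region_ids, dim(arr)), arr.ind = TRUE)
  labs <- arr[vox]
  world <- t(affine %*% rbind(t(vox) - 1, 1))[, 1:3, drop = FALSE]
  res <- lapply(seq_len(nrow(contacts)), function(ci) {
    p <- as.numeric(contacts[ci, c("x", "y", "z")])
    d2 <- (world[, 1] - p[1])^2 + (world[, 2] - p[2])^2 + (world[, 3] - p[3])^2
    dmin <- sqrt(min(d2))
    if (dmin >= max_dist) return(list(region = NA, dist = dmin))
    cand <- labs[d2 <= min(d2) + 1e-9]
    list(region = sort(cand)[1], dist = dmin)
  })
  data.frame(contact_id = contacts$contact_id,
             region_id = vapply(res, function(r)
               if (is.na(r$region[1])) NA_character_ else as.character(r$region),
               character(1)),
             distance = vapply(res, function(r) r$dist, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Regional relative band power
#'
#' Means the relative band powers of the contacts assigned to each region;
#' unassigned contacts are ignored.
#'
#' @param relative A relative-stage `band_power_table`.
#' @param assignment Data frame from [assign_contacts()] (or with columns
#'   `contact_id`, `region_id`).
#' @return Matrix regions x bands with attribute `n_contacts` (named
#'   integer vector).
#' @export
regional_band_power <- function(relative, assignment) {
  stopifnot(identical(attr(relative, "stage"), "relative"))
  asg <- assignment[!is.na(assignment$region_id), , drop = FALSE]
  asg <- asg[asg$contact_id %in% rownames(relative), , drop = FALSE]
  regs <- sort(unique(asg$region_id))
  out <- t(vapply(regs, function(r) {
    colMeans(unclass(relative)[asg$contact_id[asg$region_id == r], ,
                               drop = FALSE])
  }, numeric(ncol(relative))))
  rownames(out) <- regs
  attr(out, "n_contacts") <- stats::setNames(
    as.integer(table(asg$region_id)[regs]), regs)
  out
}

#' Build a normative band-power map
#'
#' Per region and band, the mean and sample SD of regional relative band
#' power across normative subjects. Regions observed in fewer than
#' `min_subjects` subjects, and cells with SD below 1e-8, are flagged
#' unusable.
#'
#' @param regional_tables List of regions x bands matrices (one per
#'   normative subject), rownames = region ids.
#' @param min_subjects Minimum subjects per retained region (default 5).
#' @return Object of class `normative_band_map`: `mu`, `sigma` (regions x
#'   bands), `n_subjects` (per region), `usable` (logical matrix).
#' @export
build_normative_band_map <- function(regional_tables, min_subjects = 5) {
  bands <- colnames(regional_tables[[1]])
  regs <- sort(unique(unlist(lapply(regional_tables, rownames))))
  nr <- length(regs)
  nb <- length(bands)
  counts <- stats::setNames(integer(nr), regs)
  sums <- matrix(0, nr, nb, dimnames = list(regs, bands))
  sq <- sums
  for (tab in regional_tables) {
    r <- rownames(tab)
    counts[r] <- counts[r] + 1L
    sums[r, ] <- sums[r, ] + tab
    sq[r, ] <- sq[r, ] + tab^2
  }
  mu <- sums / counts
  v <- (sq - counts * mu^2) / (counts - 1)
  v[v < 0] <- 0
  sigma <- sqrt(v)
  usable <- (counts >= min_subjects) & (sigma >= 1e-8)
  structure(list(mu = mu, sigma = sigma, n_subjects = counts,
                 usable = usable, bands = bands, min_subjects = min_subjects),
            class = "normative_band_map")
}

#' Serialise / restore a normative band map as JSON
#' @param map A `normative_band_map`.
#' @param path File path.
#' @export
write_normative_band_map <- function(map, path) {
  jsonlite::write_json(
    list(mu = map$mu, sigma = map$sigma, n_subjects = map$n_subjects,
         usable = map$usable, bands = map$bands, regions = rownames(map$mu),
         min_subjects = map$min_subjects),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_normative_band_map
#' @export
read_normative_band_map <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(p$regions, p$bands)
  structure(list(mu = matrix(p$mu, ncol = length(p$bands), byrow = FALSE,
                             dimnames = dn),
                 sigma = matrix(p$sigma, ncol = length(p$bands), dimnames = dn),
                 n_subjects = stats::setNames(p$n_subjects, p$regions),
                 usable = matrix(p$usable, ncol = length(p$bands), dimnames = dn),
                 bands = p$bands, min_subjects = p$min_subjects),
            class = "normative_band_map")
}

#' Regional iEEG band-power abnormality
#'
#' z-scores a patient's regional relative band powers against the
#' normative band map, band by band, and summarises each region by the
#' maximum absolute z across bands: B = max_f |z_f|. Regions with fewer
#' than `min_usable_bands` usable normative cells are excluded.
#'
#' @param regional Patient regions x bands matrix (relative band power).
#' @param map A `normative_band_map`.
#' @param min_usable_bands Minimum usable bands for B to be reported
#'   (default 3, keeping the max-abs summary meaningful).
#' @return Data frame of class `regional_ieeg_profile`: `region_id`, one
#'   `z_<band>` column per band, `B`, `n_usable_bands`.
#' @export
ieeg_abnormality <- function(regional, map, min_usable_bands = 3) {
  stopifnot(inherits(map, "normative_band_map"))
  regs <- intersect(rownames(regional), rownames(map$mu))
  regs <- regs[rowSums(map$usable[regs, , drop = FALSE]) >= 1]
  if (length(regs) == 0L)
    stop("no patient regions are usable in the normative band map")
  z <- (regional[regs, , drop = FALSE] - map$mu[regs, , drop = FALSE]) /
    map$sigma[regs, , drop = FALSE]
  z[!map$usable[regs, , drop = FALSE]] <- NA_real_
  n_us <- rowSums(!is.na(z))
  B <- apply(abs(z), 1, max, na.rm = TRUE)
  keep <- n_us >= min_usable_bands
  out <- data.frame(region_id = regs[keep],
                    z[keep, , drop = FALSE],
                    B = B[keep], n_usable_bands = n_us[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:(1 + ncol(z))] <- paste0("z_", colnames(z))
  class(out) <- c("regional_ieeg_profile", "data.frame")
  out
}

#' Full iEEG abnormality stage for one patient recording
#'
#' Common average reference, Welch band power, relative band power,
#' contact-to-region averaging and normative z-scoring in one call.
#'
#' @param recording An `ieeg_recording`.
#' @param assignment Contact-to-region assignment (see [assign_contacts()]).
#' @param map A `normative_band_map`.
#' @param order Band-power transform order, see [relative_band_power()].
#' @param ... Passed to [ieeg_abnormality()].
#' @return A `regional_ieeg_profile`.
#' @export
ieeg_abnormalities <- function(recording, assignment, map,
                               order = "log-then-normalize", ...) {
  rec <- common_average_reference(recording)
  rel <- relative_band_power(band_power(rec), order = order)
  reg <- regional_band_power(rel, assignment)
  ieeg_abnormality(reg, map, ...)
}
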