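#' Configuration for a synthetic two-modality cohort
#'
#' Defines the statistical structure of a simulated surgical-epilepsy
#' cohort: healthy-control connectomes with site/age/sex structure,
#' patients with planted epileptogenic (EZ) effects in both modalities
#' (FA reductions on EZ-incident connections; band-power shifts at EZ
#' regions), partial electrode coverage, resection sets and outcomes
#' coupled noisily to whether the planted regions were resected.
#'
#' Defaults mirror a two-site study of 96 controls and 43 patients on a
#' 128-region parcellation. With `resect_covers_ez_prob = 0.6` and
#' `outcome_noise = 0.1` the expected seizure-freedom rate is
#' 0.6*0.9 + 0.4*0.1 = 0.58.
#'
#' @param n_controls,n_patients,n_regions,n_sites Cohort sizes.
#' @param edge_density Fraction of region pairs connected, in (0, 1].
#' @param fa_mean,fa_sd Per-connection FA baseline location and
#'   subject-level noise SD (FA units, each in (0, 1)).
#' @param age_slope FA change per year of age.
#' @param sex_offset FA offset for female subjects.
#' @param site_additive,site_multiplicative Per-site batch effects: an
#'   additive FA offset and a multiplier on the noise SD (length
#'   `n_sites`).
#' @param ez_regions_per_patient Number of planted epileptogenic regions.
#' @param ez_fa_reduction Planted FA decrease on EZ-incident connections,
#'   in units of `fa_sd` (z-units of the control distribution).
#' @param ez_band_shift Planted log10 band-power shift at EZ regions:
#'   either a scalar (applied to the delta band, emulating pathological
#'   slowing) or a named length-5 vector over the canonical bands.
#' @param coverage_fraction Fraction of regions implanted with iEEG.
#' @param ez_coverage_prob Probability each EZ region is included in the
#'   implantation.
#' @param resect_covers_ez_prob Probability the resection covers all
#'   planted EZ regions.
#' @param outcome_noise Probability the outcome label is flipped.
#' @param n_ieeg_normative Normative iEEG subjects (full regional
#'   coverage) used to build the band-power map.
#' @param contacts_per_region Electrode contacts per implanted region.
#' @param fs,duration_s Recording sampling rate (Hz) and length (s).
#' @param voxels_per_region Voxels per parcellation region (perfect cube).
#' @param age_range Uniform age range (years); reference age is 30.
#' @param seed Master seed; identical configs generate bit-identical
#'   cohorts.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 96, n_patients = 43,
                          n_regions = 128, n_sites = 2,
                          edge_density = 0.3,
                          fa_mean = 0.45, fa_sd = 0.04,
                          age_slope = -0.001, sex_offset = 0.01,
                          site_additive = NULL, site_multiplicative = NULL,
                          ez_regions_per_patient = 2,
                          ez_fa_reduction = 2.5, ez_band_shift = 1,
                          coverage_fraction = 0.25, ez_coverage_prob = 0.9,
                          resect_covers_ez_prob = 0.6, outcome_noise = 0.1,
                          n_ieeg_normative = 20, contacts_per_region = 2,
                          fs = 256, duration_s = 70,
                          voxels_per_region = 27,
                          age_range = c(18, 65), seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$site_additive))
    cfg$site_additive <- c(0, rep(0.03, n_sites - 1))
  if (is.null(cfg$site_multiplicative))
    cfg$site_multiplicative <- c(1, rep(1.25, n_sites - 1))
  chk_count <- function(f) if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
                               cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
    stop_cfg(f, "must be a positive integer")
  for (f in c("n_controls", "n_patients", "n_regions", "n_sites",
              "ez_regions_per_patient", "n_ieeg_normative",
              "contacts_per_region", "voxels_per_region")) chk_count(f)
  chk_frac <- function(f) if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0) ||
                              any(cfg[[f]] > 1))
    stop_cfg(f, "must lie in [0, 1]")
  for (f in c("coverage_fraction", "ez_coverage_prob",
              "resect_covers_ez_prob", "outcome_noise")) chk_frac(f)
  if (cfg$edge_density <= 0 || cfg$edge_density > 1)
    stop_cfg("edge_density", "must lie in (0, 1]")
  for (f in c("fa_mean", "fa_sd"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop_cfg(f, "must lie in (0, 1)")
  if (length(cfg$site_additive) != n_sites)
    stop_cfg("site_additive", "must have one value per site")
  if (length(cfg$site_multiplicative) != n_sites)
    stop_cfg("site_multiplicative", "must have one value per site")
  if (cfg$fs < 200) stop_cfg("fs", "must be >= 200 Hz")
  if (cfg$n_controls < 2 * n_sites)
    stop_cfg("n_controls", "requires >= 2 controls per site")
  bands <- ieeg_bands()$band
  if (length(cfg$ez_band_shift) == 1L) {
    cfg$ez_band_shift <- stats::setNames(
      c(cfg$ez_band_shift, 0, 0, 0, 0), bands)
  } else if (length(cfg$ez_band_shift) == 5L) {
    cfg$ez_band_shift <- stats::setNames(as.numeric(cfg$ez_band_shift), bands)
  } else stop_cfg("ez_band_shift", "must be a scalar or length-5 vector")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

# Shared scaffold derived deterministically from the config: connection
# presence mask, per-connection baseline FA means, and region geometry.
cohort_scaffold <- function(config) {
  n <- config$n_regions
  with_seed(derive_seed(config$seed, 0L), {
    npairs <- n * (n - 1) / 2
    present_ut <- stats::runif(npairs) <= config$edge_density
    base <- pmin(0.9, pmax(0.1,
      stats::rnorm(npairs, config$fa_mean, 0.05)))
    present <- matrix(FALSE, n, n)
    present[upper.tri(present)] <- present_ut
    present <- present | t(present)
    edges <- which(upper.tri(present) & present, arr.ind = TRUE)
    list(present = present,
         edges = data.frame(i = edges[, 1], j = edges[, 2]),
         base_all = base,
         region_ids = as.character(seq_len(n)))
  })
}

# vector of baseline means over present edges
scaffold_base <- function(scaffold) {
  scaffold$base_all[which(scaffold$present[upper.tri(scaffold$present)])]
}

# one subject's connection-weight vector under the control model
draw_weights <- function(config, scaffold, site, age, sex) {
  ne <- nrow(scaffold$edges)
  eps <- stats::rnorm(ne, 0, config$fa_sd)
  w <- scaffold_base(scaffold) +
    config$age_slope * (age - 30) +
    config$sex_offset * (sex == "F") +
    config$site_additive[site] +
    eps * config$site_multiplicative[site]
  pmin(1 - 1e-3, pmax(1e-3, w))
}

weights_to_matrix <- function(w, scaffold) {
  n <- length(scaffold$region_ids)
  m <- matrix(NA_real_, n, n)
  m[cbind(scaffold$edges$i, scaffold$edges$j)] <- w
  m[cbind(scaffold$edges$j, scaffold$edges$i)] <- w
  connectivity_matrix(m, region_ids = scaffold$region_ids)
}

#' Generate healthy-control connectomes
#'
#' Controls share a binary connection scaffold; each present connection
#' weight is the per-connection baseline plus age, sex and site effects
#' plus site-scaled Gaussian noise, clipped to (0, 1).
#'
#' @param config A [cohort_config()].
#' @return List of control subjects, each a list with `id`, `group`,
#'   `site`, `age`, `sex` and `connectivity` (a `connectivity_matrix`).
#' @export
generate_controls <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  scaffold <- cohort_scaffold(config)
  with_seed(derive_seed(config$seed, 1L), {
    lapply(seq_len(config$n_controls), function(i) {
      site <- ((i - 1L) %% config$n_sites) + 1L
      age <- stats::runif(1, config$age_range[1], config$age_range[2])
      # period-2*n_sites alternation keeps sex balanced within every site
      sex <- if ((i - 1L) %/% config$n_sites %% 2L == 0L) "M" else "F"
      list(id = sprintf("ctrl%03d", i), group = "control",
           site = site, age = age, sex = sex,
           connectivity = weights_to_matrix(
             draw_weights(config, scaffold, site, age, sex), scaffold))
    })
  })
}

#' Generate a synthetic multichannel interictal iEEG signal
#'
#' Channels are realisations of a coloured-noise process (1/f^2 spectrum
#' with a white floor) synthesised in the frequency domain with random
#' phases. Planted effects multiply the PSD inside a canonical band by
#' 10^shift, so the expected log10 band power moves by exactly the
#' requested shift. The baseline amplitude is scaled so every expected
#' band power comfortably exceeds 1 in native units (required by the
#' log-then-normalise transform).
#'
#' @param band_log_shifts Length-5 vector of log10 band-power shifts (one
#'   per canonical band), or an `n_channels` x 5 matrix for per-channel
#'   shifts.
#' @param n_channels Number of contacts.
#' @param fs Sampling rate, >= 200 Hz (>= 160 Hz is the hard floor for the
#'   30-80 Hz gamma band).
#' @param duration_s Recording length in seconds (default 70).
#' @param seed RNG seed.
#' @return Numeric matrix, channels x samples.
#' @export
generate_signal <- function(band_log_shifts, n_channels, fs,
                            duration_s = 70, seed = 1) {
  if (fs < 160)
    stop("fs must be >= 160 Hz: the 30-80 Hz gamma band violates the Nyquist margin")
  bands <- ieeg_bands()
  if (is.matrix(band_log_shifts)) {
    stopifnot(nrow(band_log_shifts) == n_channels,
              ncol(band_log_shifts) == 5L)
    shifts <- band_log_shifts
  } else {
    stopifnot(length(band_log_shifts) == 5L)
    shifts <- matrix(rep(as.numeric(band_log_shifts), each = n_channels),
                     n_channels, 5)
  }
  n <- round(duration_s * fs)
  nf <- n %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / n
  base_psd <- 1 / (1 + (freq / 3)^2) + 0.01
  # scale so the smallest expected baseline band power is 1000
  bp0 <- vapply(seq_len(5), function(b) {
    sel <- freq >= bands$low[b] & freq < bands$high[b]
    trapz(freq[sel], base_psd[sel])
  }, numeric(1))
  base_psd <- base_psd * 1000 / min(bp0)
  with_seed(seed, {
    out <- matrix(0, n_channels, n)
    groups <- split(seq_len(n_channels),
                    apply(shifts, 1, paste, collapse = ","))
    for (chs in groups) {
      psd <- base_psd
      for (b in seq_len(5)) {
        sel <- freq >= bands$low[b] & freq < bands$high[b]
        psd[sel] <- psd[sel] * 10^shifts[chs[1], b]
      }
      amp <- sqrt(psd * fs * n / 2)
      nch <- length(chs)
      Zh <- matrix(complex(real = stats::rnorm(nf * nch),
                           imaginary = stats::rnorm(nf * nch)) / sqrt(2),
                   nf, nch) * amp
      Zh[1, ] <- 0                      # zero mean
      if (n %% 2L == 0L) Zh[nf, ] <- Re(Zh[nf, ]) * sqrt(2)
      Z <- rbind(Zh, Conj(Zh[rev(seq(2, nf - 1L)), , drop = FALSE]))
      out[chs, ] <- t(Re(stats::mvfft(Z, inverse = TRUE)) / n)
    }
    out
  })
}

# region geometry: cubic blocks of side s on a g^3 grid, 1 mm voxels,
# 0-based voxel-to-world affine = identity
region_geometry <- function(n_regions, voxels_per_region) {
  side <- round(voxels_per_region^(1 / 3))
  if (side^3 != voxels_per_region)
    stop("voxels_per_region must be a perfect cube")
  g <- ceiling(n_regions^(1 / 3))
  dims <- rep(g * side, 3)
  k <- seq_len(n_regions) - 1L
  ix <- k %% g
  iy <- (k %/% g) %% g
  iz <- k %/% (g * g)
  start <- cbind(ix, iy, iz) * side          # 0-based block origin
  centers <- start + (side - 1) / 2          # 0-based voxel coords == mm
  list(side = side, grid = g, dims = dims, start = start,
       centers = centers, affine = diag(4))
}

#' Generate a parcellation volume and resection mask
#'
#' Builds a 3D label volume of contiguous cubic region blocks (1 mm
#' voxels, identity voxel-to-world affine) and a binary mask that removes
#' `round(fraction * voxels)` randomly chosen voxels from each region.
#'
#' @param n_regions Number of regions.
#' @param voxels_per_region Voxels per region (perfect cube, e.g. 27).
#' @param resected_fraction_map Numeric vector (length `n_regions`) of
#'   per-region masked-voxel fractions in [0, 1].
#' @param seed RNG seed for voxel selection.
#' @return List: `parcellation` (integer array), `mask` (0/1 array),
#'   `affine`, `centers` (region-centre world coordinates, mm).
#' @export
generate_resection_volumes <- function(n_regions, voxels_per_region,
                                       resected_fraction_map, seed = 1) {
  if (length(resected_fraction_map) != n_regions)
    stop("resected_fraction_map must have one fraction per region")
  if (any(resected_fraction_map < 0 | resected_fraction_map > 1))
    stop("resected fractions must lie in [0, 1]")
  geo <- region_geometry(n_regions, voxels_per_region)
  parc <- array(0L, geo$dims)
  mask <- array(0L, geo$dims)
  with_seed(seed, {
    for (k in seq_len(n_regions)) {
      rng <- lapply(1:3, function(d) geo$start[k, d] + seq_len(geo$side))
      parc[rng[[1]], rng[[2]], rng[[3]]] <- k
      n_rm <- round(resected_fraction_map[k] * voxels_per_region)
      if (n_rm > 0) {
        block <- array(0L, rep(geo$side, 3))
        block[sample(voxels_per_region, n_rm)] <- 1L
        mask[rng[[1]], rng[[2]], rng[[3]]] <- block
      }
    }
  })
  list(parcellation = parc, mask = mask, affine = geo$affine,
       centers = geo$centers)
}

#' Generate one synthetic patient
#'
#' Starts from the control connectome model, lowers every EZ-incident
#' connection by `ez_fa_reduction * fa_sd`, draws an implantation that
#' covers each EZ region with probability `ez_coverage_prob`, places
#' contacts at implanted region centres, synthesises an interictal
#' recording with the planted band shifts on EZ contacts, draws a
#' resection that covers the EZ with probability `resect_covers_ez_prob`,
#' and labels the outcome good (ILAE 1-2) iff the EZ was fully resected,
#' flipped with probability `outcome_noise`. Outcomes are generated at the
#' EZ-coverage level only, never from abnormality scores, so downstream
#' recovery of outcome structure is a genuine test.
#'
#' @param config A [cohort_config()].
#' @param ez_regions Integer ids of planted epileptogenic regions.
#' @param id Patient identifier.
#' @param seed RNG seed (defaults to a value derived from the config
#'   seed and `id`).
#' @param signals Generate the iEEG recording (set `FALSE` to skip the
#'   costly signal synthesis when only the connectome is needed).
#' @return Patient subject list: demographics, `connectivity`,
#'   `ez_regions`, `implanted_regions`, `contacts`, `recording`,
#'   `resected_regions`, `outcome` (ILAE class), `good_outcome`.
#' @export
generate_patient <- function(config, ez_regions, id = 1L, seed = NULL,
                             signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  ez_regions <- as.integer(ez_regions)
  if (length(ez_regions) == 0L)
    stop("ez_regions must be non-empty")
  if (any(ez_regions < 1L | ez_regions > config$n_regions))
    stop("ez region outside the parcellation range")
  if (is.null(seed)) seed <- derive_seed(config$seed, 100L + as.integer(id))
  scaffold <- cohort_scaffold(config)
  geo <- region_geometry(config$n_regions, config$voxels_per_region)
  with_seed(seed, {
    site <- sample.int(config$n_sites, 1)
    age <- stats::runif(1, config$age_range[1], config$age_range[2])
    sex <- sample(c("M", "F"), 1)
    w <- draw_weights(config, scaffold, site, age, sex)
    hit <- scaffold$edges$i %in% ez_regions | scaffold$edges$j %in% ez_regions
    w[hit] <- pmax(1e-3, w[hit] - config$ez_fa_reduction * config$fa_sd)

    all_regions <- seq_len(config$n_regions)
    n_impl <- max(4L, round(config$coverage_fraction * config$n_regions))
    ez_in <- ez_regions[stats::runif(length(ez_regions)) < config$ez_coverage_prob]
    implanted <- ez_in
    pool <- setdiff(all_regions, ez_regions)
    implanted <- c(implanted,
                   sample(pool, min(length(pool), n_impl - length(implanted))))

    extra <- 4L
    covers <- stats::runif(1) < config$resect_covers_ez_prob
    if (covers) {
      resected <- c(ez_regions,
                    sample(setdiff(all_regions, ez_regions), extra))
    } else {
      dropped <- sample(ez_regions, 1)
      resected <- sample(setdiff(all_regions, dropped),
                         length(ez_regions) + extra)
    }
    # implantation must sample both resected and to-be-spared tissue
    need_res <- setdiff(resected, implanted)
    n_res_in <- sum(implanted %in% resected)
    if (n_res_in < 2L && length(need_res) > 0L) {
      add <- utils::head(need_res, 2L - n_res_in)
      drop_pool <- setdiff(implanted, c(resected, ez_regions))
      implanted <- c(setdiff(implanted,
                             utils::head(drop_pool, length(add))), add)
    }
    if (sum(!(implanted %in% resected)) < 2L) {
      add <- utils::head(setdiff(all_regions, c(implanted, resected)), 2L)
      implanted <- c(implanted, add)
    }
    implanted <- sort(unique(implanted))
    resected <- sort(unique(resected))

    good <- all(ez_regions %in% resected)
    if (stats::runif(1) < config$outcome_noise) good <- !good
    ilae <- if (good) sample(1:2, 1, prob = c(0.8, 0.2)) else sample(3:5, 1)

    contacts <- do.call(rbind, lapply(implanted, function(r) {
      data.frame(
        contact_id = sprintf("p%s_r%03d_c%d", id, r,
                             seq_len(config$contacts_per_region)),
        region = r,
        x = geo$centers[r, 1] + stats::runif(config$contacts_per_region, -0.4, 0.4),
        y = geo$centers[r, 2] + stats::runif(config$contacts_per_region, -0.4, 0.4),
        z = geo$centers[r, 3] + stats::runif(config$contacts_per_region, -0.4, 0.4))
    }))
    recording <- NULL
    if (signals) {
      shifts <- matrix(0, nrow(contacts), 5)
      in_ez <- contacts$region %in% ez_regions
      shifts[in_ez, ] <- matrix(rep(config$ez_band_shift, each = sum(in_ez)),
                                ncol = 5)
      recording <- ieeg_recording(
        generate_signal(shifts, nrow(contacts), config$fs,
                        config$duration_s,
                        seed = derive_seed(seed, 7L)),
        fs = config$fs, contact_ids = contacts$contact_id)
    }
    list(id = sprintf("pat%03d", as.integer(id)), group = "patient",
         site = site, age = age, sex = sex,
         mri_lesional = stats::runif(1) < 0.5,
         connectivity = weights_to_matrix(w, scaffold),
         ez_regions = sort(ez_regions),
         implanted_regions = implanted,
         contacts = contacts, recording = recording,
         resected_regions = resected,
         outcome = ilae, good_outcome = good)
  })
}

# normative iEEG subject: full coverage, one contact per region, no shifts
generate_normative_ieeg_subject <- function(config, id, seed) {
  geo <- region_geometry(config$n_regions, config$voxels_per_region)
  n <- config$n_regions
  rec <- ieeg_recording(
    generate_signal(rep(0, 5), n, config$fs, config$duration_s, seed = seed),
    fs = config$fs,
    contact_ids = sprintf("norm%03d_r%03d", id, seq_len(n)))
  assignment <- data.frame(contact_id = rec$contact_ids,
                           region_id = as.character(seq_len(n)),
                           stringsAsFactors = FALSE)
  list(id = sprintf("norm%03d", id), recording = rec,
       assignment = assignment)
}

#' Generate a full synthetic cohort
#'
#' Controls, patients with planted EZ effects, a designated normative
#' iEEG subject set (full regional coverage, unshifted spectra, emulating
#' a pooled normative map), and the parcellation geometry.
#'
#' @param config A [cohort_config()].
#' @param signals Generate iEEG recordings (see [generate_patient()]).
#' @return List of class `synthetic_cohort`: `config`, `controls`,
#'   `patients`, `normative_ieeg`, `geometry`.
#' @export
generate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  controls <- generate_controls(config)
  ez_sets <- with_seed(derive_seed(config$seed, 2L), {
    lapply(seq_len(config$n_patients), function(i)
      sort(sample.int(config$n_regions, config$ez_regions_per_patient)))
  })
  patients <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, ez_sets[[i]], id = i, signals = signals))
  normative <- if (signals) {
    lapply(seq_len(config$n_ieeg_normative), function(i)
      generate_normative_ieeg_subject(config, i,
                                      seed = derive_seed(config$seed, 10000L + i)))
  } else list()
  structure(list(config = config, controls = controls, patients = patients,
                 normative_ieeg = normative,
                 geometry = region_geometry(config$n_regions,
                                            config$voxels_per_region)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d controls, %d patients, %d regions, %d site(s)\n",
              length(x$controls), length(x$patients),
              x$config$n_regions, x$config$n_sites))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Connectivity TSVs, contacts TSVs, recordings as flat float64 binary
#' with a JSON sidecar (`fs`, channel names), parcellation and per-patient
#' resection masks as NIfTI, and a subjects manifest CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @param resected_fraction Fraction of each resected region's voxels
#'   placed inside that patient's mask (default 0.8).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, resected_fraction = 0.8) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in c("", "connectivity", "contacts", "recordings", "masks"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  subj <- c(cohort$controls, cohort$patients)
  for (s in subj)
    write_connectivity_tsv(s$connectivity,
                           file.path(dir, "connectivity",
                                     paste0(s$id, ".tsv")))
  cfg <- cohort$config
  vols <- generate_resection_volumes(cfg$n_regions, cfg$voxels_per_region,
                                     rep(0, cfg$n_regions),
                                     seed = derive_seed(cfg$seed, 3L))
  RNifti::writeNifti(RNifti::asNifti(vols$parcellation),
                     file.path(dir, "parcellation.nii.gz"))
  write_rec <- function(rec, id) {
    con <- file(file.path(dir, "recordings", paste0(id, ".bin")), "wb")
    writeBin(as.vector(t(rec$samples)), con, size = 8)
    close(con)
    jsonlite::write_json(
      list(fs = rec$fs, n_samples = ncol(rec$samples),
           channels = rec$contact_ids),
      file.path(dir, "recordings", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  for (p in cohort$patients) {
    utils::write.table(p$contacts[, c("contact_id", "x", "y", "z")],
                       file.path(dir, "contacts", paste0(p$id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(p$recording)) write_rec(p$recording, p$id)
    frac <- rep(0, cfg$n_regions)
    frac[p$resected_regions] <- resected_fraction
    pv <- generate_resection_volumes(cfg$n_regions, cfg$voxels_per_region,
                                     frac,
                                     seed = derive_seed(cfg$seed, 4L))
    RNifti::writeNifti(RNifti::asNifti(pv$mask),
                       file.path(dir, "masks", paste0(p$id, ".nii.gz")))
  }
  geo <- cohort$geometry
  for (s in cohort$normative_ieeg) {
    ct <- data.frame(contact_id = s$assignment$contact_id,
                     x = geo$centers[, 1], y = geo$centers[, 2],
                     z = geo$centers[, 3])
    utils::write.table(ct, file.path(dir, "contacts", paste0(s$id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_rec(s$recording, s$id)
  }
  manifest <- do.call(rbind, lapply(subj, function(s)
    data.frame(id = s$id, group = s$group, site = s$site,
               age = s$age, sex = s$sex,
               outcome = if (s$group == "patient") s$outcome else NA_integer_,
               mri_lesional = if (s$group == "patient") s$mri_lesional else NA,
               stringsAsFactors = FALSE)))
  if (length(cohort$normative_ieeg) > 0L)
    manifest <- rbind(manifest,
                      data.frame(id = vapply(cohort$normative_ieeg,
                                             function(s) s$id, character(1)),
                                 group = "normative", site = NA, age = NA,
                                 sex = NA, outcome = NA_integer_,
                                 mri_lesional = NA))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a flat-binary recording and its JSON sidecar
#' @param bin_path Path to the float64 binary (channel-major).
#' @param json_path Sidecar path; defaults to `bin_path` with `.json`.
#' @return An `ieeg_recording`.
#' @export
read_recording <- function(bin_path, json_path = sub("\\.bin$", ".json",
                                                     bin_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_samples * length(meta$channels),
               size = 8)
  ieeg_recording(matrix(x, nrow = length(meta$channels),
                        byrow = TRUE),
                 fs = meta$fs, contact_ids = meta$channels)
}
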