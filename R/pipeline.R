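#' Analyse a two-modality cohort
#'
#' Core analysis used by [run_pipeline()] and directly on in-memory
#' cohorts: builds the normative connectome model and band-power map,
#' derives per-patient regional abnormality profiles in both modalities,
#' and computes the localisation statistics — per-patient D_RS for each
#' modality, SVM separability with the maximal-abnormality-resected call,
#' the chi-squared/odds-ratio association between maximal-abnormality
#' resection and seizure freedom, outcome ROC AUCs, the D_RS modality
#' correlation, the constrained decision tree and its leave-one-out
#' cross-validation.
#'
#' @param cohort A `synthetic_cohort` (or an equivalently shaped list read
#'   from disk).
#' @param sign_mode Connectivity abnormality sign convention, see
#'   [regional_abnormality()].
#' @param band_order Band-power transform order, see
#'   [relative_band_power()].
#' @param joint Harmonise patients jointly with controls (see
#'   [connectome_abnormalities()]).
#' @param min_normative_subjects Minimum subjects per region in the
#'   normative band map.
#' @param use_assignment If `"geometric"` (default), contacts are assigned
#'   to regions by the <5 mm rule against the cohort parcellation;
#'   `"declared"` trusts the contact table's intended regions.
#' @param subgroup `"all"`, `"mri_positive"` or `"mri_negative"` patient
#'   filter (lesional / non-lesional MRI).
#' @return List of class `cohort_analysis`: `patients` (per-patient data
#'   frame), `cohort` (statistics list), `connectome` (model + profiles),
#'   `band_map`.
#' @export
analyse_cohort <- function(cohort,
                           sign_mode = "reduction",
                           band_order = "log-then-normalize",
                           joint = TRUE,
                           min_normative_subjects = 5,
                           use_assignment = c("geometric", "declared"),
                           subgroup = c("all", "mri_positive", "mri_negative")) {
  use_assignment <- match.arg(use_assignment)
  subgroup <- match.arg(subgroup)
  patients <- cohort$patients
  if (subgroup != "all") {
    want <- subgroup == "mri_positive"
    patients <- Filter(function(p) isTRUE(p$mri_lesional) == want, patients)
  }
  if (length(patients) < 3L)
    stop("fewer than 3 patients after subgroup filtering")
  info <- function(subjects) data.frame(
    site = vapply(subjects, function(s) s$site, numeric(1)),
    age = vapply(subjects, function(s) s$age, numeric(1)),
    sex = vapply(subjects, function(s) s$sex, character(1)),
    stringsAsFactors = FALSE)

  conn <- connectome_abnormalities(
    lapply(cohort$controls, function(s) s$connectivity),
    lapply(patients, function(p) p$connectivity),
    info(cohort$controls), info(patients),
    joint = joint, sign_mode = sign_mode)

  have_ieeg <- length(cohort$normative_ieeg) > 0L &&
    !is.null(patients[[1]]$recording)
  band_map <- NULL
  parc <- NULL
  if (have_ieeg) {
    norm_tabs <- lapply(cohort$normative_ieeg, function(s) {
      rec <- common_average_reference(s$recording)
      rel <- relative_band_power(band_power(rec), order = band_order)
      regional_band_power(rel, s$assignment)
    })
    band_map <- build_normative_band_map(norm_tabs,
                                         min_subjects = min_normative_subjects)
    if (use_assignment == "geometric") {
      parc <- if (!is.null(cohort$config)) {
        cfg <- cohort$config
        generate_resection_volumes(cfg$n_regions, cfg$voxels_per_region,
                                   rep(0, cfg$n_regions),
                                   seed = 0L)$parcellation
      } else as.array(cohort$parcellation)
    }
  }

  rows <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    prof <- conn$profiles[[i]]
    resected_all <- prof$region_id %in% as.character(p$resected_regions)
    drs_conn <- compute_drs(prof$score, resected_all)
    drs_ieeg <- NA_real_
    sep <- list(evaluable = FALSE, separable = NA, maximal_resected = NA)
    if (have_ieeg) {
      assignment <- if (use_assignment == "geometric")
        assign_contacts(p$contacts, parc)
      else data.frame(contact_id = p$contacts$contact_id,
                      region_id = as.character(p$contacts$region))
      iprof <- ieeg_abnormalities(p$recording, assignment, band_map,
                                  order = band_order)
      res_i <- iprof$region_id %in% as.character(p$resected_regions)
      if (any(res_i) && any(!res_i))
        drs_ieeg <- compute_drs(iprof$B, res_i)
      cs <- prof$score[match(iprof$region_id, prof$region_id)]
      sep <- svm_separation(iprof$B, cs, res_i)
    }
    data.frame(id = p$id,
               drs_conn = drs_conn, drs_ieeg = drs_ieeg,
               evaluable = sep$evaluable %||% FALSE,
               separable = sep$separable %||% NA,
               maximal_resected = sep$maximal_resected %||% NA,
               good_outcome = p$good_outcome, outcome = p$outcome,
               stringsAsFactors = FALSE)
  })
  pt <- do.call(rbind, rows)

  stats <- list(n_patients = nrow(pt),
                seizure_free_pct = 100 * mean(pt$good_outcome))
  sep_ok <- !is.na(pt$separable) & pt$separable
  stats$n_separable <- sum(sep_ok)
  if (sum(sep_ok) >= 4L) {
    tab <- matrix(c(sum(sep_ok & pt$maximal_resected & pt$good_outcome),
                    sum(sep_ok & pt$maximal_resected & !pt$good_outcome),
                    sum(sep_ok & !pt$maximal_resected & pt$good_outcome),
                    sum(sep_ok & !pt$maximal_resected & !pt$good_outcome)),
                  2, 2, byrow = TRUE)
    stats$maximal_table <- tab
    stats$odds_ratio <- odds_ratio(tab)
    stats$chi_squared <- tryCatch(association_test(tab),
                                  error = function(e) NULL)
  }
  stats$auc_conn <- outcome_auc(pt$drs_conn, pt$good_outcome)
  has_i <- is.finite(pt$drs_ieeg)
  if (any(has_i) && length(unique(pt$good_outcome[has_i])) == 2L)
    stats$auc_ieeg <- outcome_auc(pt$drs_ieeg[has_i], pt$good_outcome[has_i])
  both <- is.finite(pt$drs_conn) & is.finite(pt$drs_ieeg)
  if (sum(both) >= 3L)
    stats$drs_correlation <- tryCatch(
      modality_correlation(pt$drs_conn[both], pt$drs_ieeg[both]),
      error = function(e) NULL)
  if (sum(both) >= 4L && length(unique(pt$good_outcome[both])) == 2L) {
    tree <- suppressWarnings(
      constrained_decision_tree(pt$drs_ieeg[both], pt$drs_conn[both],
                                pt$good_outcome[both]))
    stats$tree <- tree
    stats$loocv <- loocv_evaluate(pt$drs_ieeg[both], pt$drs_conn[both],
                                  pt$good_outcome[both])
  }
  structure(list(patients = pt, cohort = stats,
                 connectome = conn, band_map = band_map),
            class = "cohort_analysis")
}

#' Read a cohort from the on-disk layout written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param resection_threshold Volume-loss threshold used to recover
#'   resected regions from the per-patient masks.
#' @return A `synthetic_cohort`-shaped list ready for [analyse_cohort()].
#' @export
read_cohort <- function(dir, resection_threshold = 0.10) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  parc <- RNifti::readNifti(file.path(dir, "parcellation.nii.gz"))
  read_subj <- function(id) {
    list(id = id,
         connectivity = read_connectivity_tsv(
           file.path(dir, "connectivity", paste0(id, ".tsv"))))
  }
  controls <- lapply(manifest$id[manifest$group == "control"], function(id) {
    s <- read_subj(id)
    row <- manifest[manifest$id == id, ]
    c(s, list(group = "control", site = row$site, age = row$age,
              sex = row$sex))
  })
  patients <- lapply(manifest$id[manifest$group == "patient"], function(id) {
    s <- read_subj(id)
    row <- manifest[manifest$id == id, ]
    contacts <- utils::read.delim(file.path(dir, "contacts",
                                            paste0(id, ".tsv")))
    rec_bin <- file.path(dir, "recordings", paste0(id, ".bin"))
    rec <- if (file.exists(rec_bin)) read_recording(rec_bin) else NULL
    mask <- RNifti::readNifti(file.path(dir, "masks", paste0(id, ".nii.gz")))
    lab <- label_resections(parc, mask, threshold = resection_threshold)
    c(s, list(group = "patient", site = row$site, age = row$age,
              sex = row$sex, contacts = contacts, recording = rec,
              resected_regions = as.integer(lab$region_id[lab$resected]),
              outcome = row$outcome, good_outcome = row$outcome <= 2,
              mri_lesional = if ("mri_lesional" %in% names(row))
                row$mri_lesional else NA))
  })
  normative <- lapply(manifest$id[manifest$group == "normative"],
                      function(id) {
    contacts <- utils::read.delim(file.path(dir, "contacts",
                                            paste0(id, ".tsv")))
    rec <- read_recording(file.path(dir, "recordings", paste0(id, ".bin")))
    list(id = id, recording = rec,
         assignment = data.frame(contact_id = contacts$contact_id,
                                 region_id = as.character(
                                   seq_len(nrow(contacts))),
                                 stringsAsFactors = FALSE))
  })
  n_regions <- length(unique(as.vector(as.array(parc)))) - 1L
  structure(list(config = NULL, controls = controls, patients = patients,
                 normative_ieeg = normative,
                 geometry = NULL, parcellation = parc,
                 n_regions = n_regions),
            class = "synthetic_cohort")
}

#' Validate pipeline inputs
#'
#' Non-mutating consistency checks over an on-disk cohort: manifest
#' completeness, connectivity matrix symmetry, region-id consistency
#' across subjects, contact/recording channel alignment and
#' parcellation/mask shape agreement. Each check reports pass/fail with a
#' detail message; nothing is modified.
#'
#' @param dir Cohort directory (layout of [write_cohort()]).
#' @return Data frame with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(dir) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    add("manifest", FALSE, "manifest.csv missing")
    return(do.call(rbind, checks))
  }
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  need <- c("id", "group", "site", "age", "sex", "outcome")
  add("manifest", all(need %in% names(manifest)),
      paste("columns:", paste(intersect(need, names(manifest)),
                              collapse = ",")))
  ids0 <- NULL
  sym_fail <- character(0)
  reg_fail <- character(0)
  for (id in manifest$id[manifest$group %in% c("control", "patient")]) {
    f <- file.path(dir, "connectivity", paste0(id, ".tsv"))
    if (!file.exists(f)) { sym_fail <- c(sym_fail, id); next }
    cm <- tryCatch(read_connectivity_tsv(f), error = function(e) NULL)
    if (is.null(cm)) { sym_fail <- c(sym_fail, id); next }
    if (is.null(ids0)) ids0 <- cm$region_ids
    else if (!identical(cm$region_ids, ids0)) reg_fail <- c(reg_fail, id)
  }
  add("connectivity_symmetric", length(sym_fail) == 0L,
      if (length(sym_fail)) paste("failed:", paste(sym_fail, collapse = ","))
      else "")
  add("region_ids_consistent", length(reg_fail) == 0L,
      if (length(reg_fail)) paste("failed:", paste(reg_fail, collapse = ","))
      else "")
  chan_fail <- character(0)
  for (id in manifest$id[manifest$group == "patient"]) {
    ct_f <- file.path(dir, "contacts", paste0(id, ".tsv"))
    js_f <- file.path(dir, "recordings", paste0(id, ".json"))
    if (!file.exists(ct_f) || !file.exists(js_f)) next
    contacts <- utils::read.delim(ct_f)
    meta <- jsonlite::read_json(js_f, simplifyVector = TRUE)
    if (!all(contacts$contact_id %in% meta$channels))
      chan_fail <- c(chan_fail, id)
  }
  add("contacts_match_recordings", length(chan_fail) == 0L,
      if (length(chan_fail)) paste("failed:",
                                   paste(chan_fail, collapse = ","))
      else "")
  parc_f <- file.path(dir, "parcellation.nii.gz")
  if (file.exists(parc_f)) {
    parc <- RNifti::readNifti(parc_f)
    shape_fail <- character(0)
    for (id in manifest$id[manifest$group == "patient"]) {
      m_f <- file.path(dir, "masks", paste0(id, ".nii.gz"))
      if (!file.exists(m_f)) next
      msk <- RNifti::readNifti(m_f)
      if (!identical(dim(as.array(parc)), dim(as.array(msk))))
        shape_fail <- c(shape_fail, id)
    }
    add("mask_shapes_match", length(shape_fail) == 0L,
        if (length(shape_fail)) paste("failed:",
                                      paste(shape_fail, collapse = ","))
        else "")
  } else add("parcellation_present", FALSE, "parcellation.nii.gz missing")
  do.call(rbind, checks)
}

#' Run the full two-modality localisation pipeline
#'
#' Orchestrates synthesise/ingest, abnormality mapping in both
#' modalities, resection labeling and the localisation statistics, writing
#' per-patient result tables, a cohort statistics report and a provenance
#' record. Rerunning with an identical configuration reproduces the
#' statistics byte for byte.
#'
#' @param config Named list, or path to a YAML/JSON file, with fields:
#'   `out_dir` (required); either `simulate` (a list of [cohort_config()]
#'   arguments) or `input_dir` (an on-disk cohort); and optional
#'   `resection_threshold` (default 0.10), `sign_mode`, `band_order`,
#'   `joint`, `min_normative_subjects`, `subgroup`, `write_inputs`.
#' @return The `cohort_analysis`, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    cfg <- do.call(cohort_config, as.list(config$simulate))
    cohort <- generate_cohort(cfg)
    if (isTRUE(config$write_inputs))
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
  } else if (!is.null(config$input_dir)) {
    cohort <- read_cohort(config$input_dir,
                          resection_threshold =
                            config$resection_threshold %||% 0.10)
  } else stop("config must provide either 'simulate' or 'input_dir'")
  res <- analyse_cohort(
    cohort,
    sign_mode = config$sign_mode %||% "reduction",
    band_order = config$band_order %||% "log-then-normalize",
    joint = config$joint %||% TRUE,
    min_normative_subjects = config$min_normative_subjects %||% 5,
    subgroup = config$subgroup %||% "all")
  utils::write.csv(res$patients,
                   file.path(config$out_dir, "patient_results.csv"),
                   row.names = FALSE)
  report <- res$cohort
  report$tree <- if (!is.null(report$tree)) unclass(report$tree) else NULL
  report$loocv$predictions <- NULL
  report$parameters <- list(
    resection_threshold = config$resection_threshold %||% 0.10,
    sign_mode = config$sign_mode %||% "reduction",
    band_order = config$band_order %||% "log-then-normalize",
    joint = config$joint %||% TRUE,
    subgroup = config$subgroup %||% "all")
  jsonlite::write_json(report,
                       file.path(config$out_dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  cfg_file <- tempfile()
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, force = TRUE)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(cfg_file)),
         timestamp = format(Sys.time(), tz = "UTC"),
         r_version = R.version.string),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
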