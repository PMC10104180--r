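#' Harmonise connection weights across acquisition sites
#'
#' Removes site/scanner batch effects from a subjects-by-connections table
#' with a ComBat-style per-connection location/scale model, preserving age
#' and sex effects through the covariate design. Two estimators are
#' provided: `"none"` (default) uses the per-connection batch estimates
#' directly, so the empirical between-site difference of every connection
#' is removed; `"eb"` applies the classic parametric empirical-Bayes
#' shrinkage of batch parameters across connections (via `sva::ComBat`),
#' which deliberately leaves a shrunken fraction of each connection's
#' apparent batch difference in place. With a single site the table is
#' returned unchanged. Connections with zero variance across subjects are
#' excluded from harmonisation, passed through unchanged, and flagged.
#'
#' @param table Numeric matrix, subjects x connections.
#' @param site Factor or vector of site labels, one per subject.
#' @param age,sex Covariates (numeric years; sex any two-level vector)
#'   protected during standardisation.
#' @param shrinkage `"none"` (direct location/scale adjustment) or `"eb"`
#'   (parametric empirical-Bayes shrinkage).
#' @param ref_batch Optional site level to use as reference batch
#'   (`"eb"` mode only).
#' @return List with `table` (harmonised, same shape), `excluded` (integer
#'   indices of zero-variance connections) and `params` (sites, mode,
#'   reference batch).
#' @export
combat_harmonize <- function(table, site, age = NULL, sex = NULL,
                             shrinkage = c("none", "eb"),
                             ref_batch = NULL) {
  shrinkage <- match.arg(shrinkage)
  site <- droplevels(as.factor(site))
  if (length(site) != nrow(table))
    stop("site labels must match table rows")
  if (nlevels(site) == 1L) {
    return(list(table = table, excluded = integer(0),
                params = list(sites = levels(site), mode = "single-site")))
  }
  tab <- tabulate(site)
  if (any(tab < 2L))
    stop(sprintf("site '%s' has a single subject; >=2 required per site",
                 levels(site)[which(tab < 2L)[1]]))
  sds <- apply(table, 2, stats::sd)
  excluded <- which(sds < 1e-12)
  keep <- setdiff(seq_len(ncol(table)), excluded)
  covs <- NULL
  if (!is.null(age)) {
    covs <- cbind(age = age)
    if (!is.null(sex))
      covs <- cbind(covs, sex = as.numeric(as.factor(sex)) - 1)
  }
  out <- table
  if (shrinkage == "eb") {
    mod <- if (is.null(covs)) NULL else stats::model.matrix(~covs)
    harm <- suppressMessages(
      sva::ComBat(dat = t(table[, keep, drop = FALSE]), batch = site,
                  mod = mod, ref.batch = ref_batch))
    out[, keep] <- t(harm)
  } else {
    out[, keep] <- combat_direct(table[, keep, drop = FALSE], site, covs)
  }
  list(table = out, excluded = excluded,
       params = list(sites = levels(site), mode = "combat",
                     shrinkage = shrinkage, ref_batch = ref_batch))
}

# ComBat location/scale model with batch parameters used unshrunk:
# fit grand + covariate + batch means by OLS, standardise, remove each
# batch's residual mean and scale, restore the covariate structure.
combat_direct <- function(Y, site, covs) {
  n <- nrow(Y)
  B1 <- stats::model.matrix(~ 0 + site)
  D <- if (is.null(covs)) B1 else cbind(B1, covs)
  beta <- qr.coef(qr(D), Y)
  k <- nlevels(site)
  w <- tabulate(site) / n
  alpha <- drop(w %*% beta[seq_len(k), , drop = FALSE])
  cov_part <- if (is.null(covs)) 0
              else covs %*% beta[-seq_len(k), , drop = FALSE]
  sig <- sqrt(colSums((Y - D %*% beta)^2) / n)
  z <- sweep(Y - cov_part, 2, alpha) / rep(sig, each = n)
  for (b in levels(site)) {
    rows <- site == b
    g <- colMeans(z[rows, , drop = FALSE])
    d <- sqrt(colMeans(sweep(z[rows, , drop = FALSE], 2, g)^2))
    d[d < 1e-12] <- 1
    z[rows, ] <- sweep(z[rows, , drop = FALSE], 2, g) / rep(d, each = sum(rows))
  }
  sweep(z, 2, sig, "*") + rep(alpha, each = n) + cov_part
}

#' Robust age/sex covariate model for control connectomes
#'
#' Fits, per connection, a robust linear model (Huber M-estimation,
#' tuning constant 1.345, iterated reweighting to relative convergence
#' 1e-6 or 50 iterations) of connection weight on centred age and sex in
#' healthy controls. Connections whose robust fit fails to converge fall
#' back to ordinary least squares with a warning. The fitted coefficients
#' are later applied unchanged to patients.
#'
#' @param table Control subjects x connections matrix (harmonised).
#' @param age Numeric ages in years.
#' @param sex Two-level vector; the second factor level carries the offset.
#' @param age_ref Reference age subtracted before fitting (years).
#' @return List of class `covariate_model`: `coef` (connections x 3 matrix:
#'   intercept, age slope, sex offset), `corrected` (table with age/sex
#'   effects removed, intercept retained), `age_ref`, `sex_levels`,
#'   `n_ols_fallback`.
#' @export
fit_covariate_model <- function(table, age, sex, age_ref = 30) {
  if (nrow(table) < 10L)
    stop("covariate model requires >=10 control subjects")
  sex <- as.factor(sex)
  if (nlevels(sex) < 2L)
    stop("both sexes must be represented in the control cohort")
  a <- age - age_ref
  s <- as.numeric(sex) - 1
  X <- cbind(1, a, s)
  nc <- ncol(table)
  coefs <- matrix(NA_real_, nc, 3,
                  dimnames = list(colnames(table),
                                  c("intercept", "age", "sex")))
  n_fallback <- 0L
  for (k in seq_len(nc)) {
    y <- table[, k]
    fit <- tryCatch(
      MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                acc = 1e-6, maxit = 50),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      n_fallback <- n_fallback + 1L
      coefs[k, ] <- stats::lm.fit(X, y)$coefficients
    } else {
      coefs[k, ] <- stats::coef(fit)
    }
  }
  if (n_fallback > 0L)
    warning(sprintf("robust fit did not converge for %d connection(s); OLS fallback used",
                    n_fallback))
  corrected <- table - outer(a, coefs[, "age"]) - outer(s, coefs[, "sex"])
  structure(list(coef = coefs, corrected = corrected, age_ref = age_ref,
                 sex_levels = levels(sex), n_ols_fallback = n_fallback),
            class = "covariate_model")
}

#' Apply a fitted covariate model to new subjects
#'
#' @param model A `covariate_model` from [fit_covariate_model()].
#' @param table Subjects x connections matrix on the same connection set.
#' @param age,sex Covariates of the new subjects.
#' @return Corrected table (age/sex effects removed, intercept retained).
#' @export
apply_covariate_model <- function(model, table, age, sex) {
  stopifnot(inherits(model, "covariate_model"))
  a <- age - model$age_ref
  s <- as.numeric(factor(sex, levels = model$sex_levels)) - 1
  if (anyNA(s)) {
    if (any(model$coef[, "sex"] != 0))
      stop("sex level not seen in the control cohort")
    s[is.na(s)] <- 0
  }
  table - outer(a, model$coef[, "age"]) - outer(s, model$coef[, "sex"])
}

#' Build a normative connectome model from healthy controls
#'
#' Pipeline order is fixed: harmonise across sites, correct age/sex with a
#' robust linear model, then compute the per-connection normative mean and
#' standard deviation (sample SD, denominator n-1). Connections with SD
#' below 1e-8 are flagged unusable, never silently dropped.
#'
#' @param controls List of `connectivity_matrix` objects sharing a presence
#'   scaffold, or a list as returned by [connectome_table()].
#' @param site,age,sex Per-control covariates.
#' @param harmonize Set `FALSE` if the table is already harmonised (e.g.
#'   jointly with patients).
#' @param covariate_correct Set `FALSE` to skip the age/sex model (e.g.
#'   for a reference cohort with no covariate structure); coefficients are
#'   then zero.
#' @param age_ref Reference age (years).
#' @return Object of class `normative_connectome`: `mu`, `sigma`, `usable`,
#'   `covariates` (the fitted `covariate_model`), `edges`, `region_ids`,
#'   `harmonization`.
#' @export
build_normative_model <- function(controls, site, age, sex,
                                  harmonize = TRUE, covariate_correct = TRUE,
                                  age_ref = 30) {
  ct <- if (is.list(controls) && !is.null(controls$table)) controls
        else connectome_table(controls)
  tab <- ct$table
  harm_params <- list(mode = "none")
  if (harmonize) {
    h <- combat_harmonize(tab, site, age = age, sex = sex)
    tab <- h$table
    harm_params <- h$params
  }
  cm <- if (covariate_correct) {
    fit_covariate_model(tab, age, sex, age_ref = age_ref)
  } else {
    structure(list(coef = matrix(0, ncol(tab), 3,
                                 dimnames = list(colnames(tab),
                                                 c("intercept", "age", "sex"))),
                   corrected = tab, age_ref = age_ref,
                   sex_levels = c("M", "F"), n_ols_fallback = 0L),
              class = "covariate_model")
  }
  mu <- colMeans(cm$corrected)
  sigma <- apply(cm$corrected, 2, stats::sd)
  structure(list(mu = mu, sigma = sigma, usable = sigma >= 1e-8,
                 covariates = cm, edges = ct$edges,
                 region_ids = ct$region_ids,
                 harmonization = harm_params),
            class = "normative_connectome")
}

#' Serialise / restore a normative connectome model as JSON
#' @param model A `normative_connectome`.
#' @param path File path.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_connectome"))
  payload <- list(mu = model$mu, sigma = model$sigma,
                  usable = model$usable,
                  coef = model$covariates$coef,
                  age_ref = model$covariates$age_ref,
                  sex_levels = model$covariates$sex_levels,
                  edges = model$edges, region_ids = model$region_ids,
                  harmonization = model$harmonization)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- structure(list(coef = matrix(p$coef, ncol = 3,
                                      dimnames = list(NULL, c("intercept", "age", "sex"))),
                        corrected = NULL, age_ref = p$age_ref,
                        sex_levels = p$sex_levels, n_ols_fallback = 0L),
                   class = "covariate_model")
  structure(list(mu = p$mu, sigma = p$sigma, usable = p$usable,
                 covariates = cov, edges = as.data.frame(p$edges),
                 region_ids = p$region_ids, harmonization = p$harmonization),
            class = "normative_connectome")
}

#' Per-connection abnormality z-scores for one patient
#'
#' z-scores each present, usable connection of a (harmonised) patient
#' connectome against the normative model after applying the
#' control-fitted age/sex correction: A = (C - mu) / sigma.
#'
#' @param patient A `connectivity_matrix` (already harmonised with the same
#'   parameters as the controls), or a numeric vector over the model's
#'   connection index.
#' @param model A `normative_connectome`.
#' @param age,sex Patient covariates.
#' @return Numeric vector of z-scores over the model's connections; `NA`
#'   where the connection is absent in the patient or unusable in the
#'   model. The count of such exclusions is attached as attribute
#'   `n_excluded`.
#' @export
connection_abnormality <- function(patient, model, age, sex) {
  stopifnot(inherits(model, "normative_connectome"))
  w <- if (inherits(patient, "connectivity_matrix")) {
    if (!identical(patient$region_ids, model$region_ids))
      stop("patient region ordering does not match the normative model")
    patient$weights[cbind(model$edges$i, model$edges$j)]
  } else as.numeric(patient)
  if (length(w) != length(model$mu))
    stop("patient connection vector does not match model connections")
  corr <- apply_covariate_model(model$covariates, matrix(w, nrow = 1),
                                age, sex)[1, ]
  z <- (corr - model$mu) / model$sigma
  bad <- !model$usable | is.na(w)
  if (any(is.na(w) & model$usable))
    warning(sprintf("%d model connection(s) absent in patient; excluded",
                    sum(is.na(w) & model$usable)))
  z[bad] <- NA_real_
  attr(z, "n_excluded") <- sum(bad)
  z
}

#' Regional connectivity abnormality profile
#'
#' Averages per-connection z-scores over the connections incident to each
#' region (each connection contributes to both of its endpoint regions).
#' The default sign convention treats FA reductions as abnormal: the
#' reported abnormality score is the negated mean z, so larger scores mean
#' greater FA reduction.
#'
#' @param z Numeric vector of connection z-scores (`NA` = excluded).
#' @param edges Data frame with columns `i`, `j` (region indices), as in a
#'   `normative_connectome`.
#' @param region_ids Ordered region labels.
#' @param sign_mode One of `"reduction"` (default, score = -mean z),
#'   `"raw"` (score = mean z) or `"absolute"` (score = |mean z|).
#' @return Data frame of class `regional_connectivity_profile` with columns
#'   `region_id`, `R` (mean incident z), `n` (contributing connections),
#'   `score`. Regions with no usable incident connection have `NA` values
#'   and `n = 0`.
#' @export
regional_abnormality <- function(z, edges, region_ids,
                                 sign_mode = c("reduction", "raw", "absolute")) {
  sign_mode <- match.arg(sign_mode)
  nr <- length(region_ids)
  ok <- !is.na(z)
  idx <- c(edges$i[ok], edges$j[ok])
  vals <- c(z[ok], z[ok])
  sums <- rowsum(vals, factor(idx, levels = seq_len(nr)))[, 1]
  ns <- tabulate(idx, nbins = nr)
  R <- ifelse(ns > 0, sums / ns, NA_real_)
  score <- switch(sign_mode,
                  reduction = -R, raw = R, absolute = abs(R))
  out <- data.frame(region_id = region_ids, R = R, n = ns, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "sign_mode") <- sign_mode
  class(out) <- c("regional_connectivity_profile", "data.frame")
  out
}

#' Connectivity abnormality profiles for a patient cohort
#'
#' End-to-end connectome stage: stacks controls and patients into one
#' connection table, harmonises across sites (jointly by default, matching
#' a study design where both cohorts are scanned at the same sites), fits
#' the robust age/sex model on controls only, builds the normative
#' per-connection mean/SD, and returns per-patient connection z-maps and
#' regional profiles.
#'
#' @param controls,patients Lists of `connectivity_matrix` objects.
#' @param control_info,patient_info Data frames with columns `site`, `age`,
#'   `sex` (and optionally `id`).
#' @param joint If `TRUE` (default) patients enter the ComBat fit together
#'   with controls; if `FALSE` the model is estimated from controls alone
#'   and patients are passed through with the control-estimated reference.
#' @param sign_mode Passed to [regional_abnormality()].
#' @param age_ref Reference age (years).
#' @return List with `model`, `z` (patients x connections matrix) and
#'   `profiles` (list of regional profiles, one per patient).
#' @export
connectome_abnormalities <- function(controls, patients, control_info,
                                     patient_info, joint = TRUE,
                                     sign_mode = "reduction", age_ref = 30) {
  ct_c <- connectome_table(controls)
  ct_p <- connectome_table(patients)
  if (!identical(ct_c$region_ids, ct_p$region_ids))
    stop("controls and patients use different region orderings")
  n_c <- nrow(ct_c$table)
  n_p <- nrow(ct_p$table)
  site_all <- c(as.character(control_info$site), as.character(patient_info$site))
  multi_site <- length(unique(site_all)) > 1L
  if (joint && multi_site) {
    h <- combat_harmonize(rbind(ct_c$table, ct_p$table), site_all,
                          age = c(control_info$age, patient_info$age),
                          sex = c(as.character(control_info$sex),
                                  as.character(patient_info$sex)))
    tab_c <- h$table[seq_len(n_c), , drop = FALSE]
    tab_p <- h$table[n_c + seq_len(n_p), , drop = FALSE]
    harm <- h$params
  } else if (multi_site) {
    hc <- combat_harmonize(ct_c$table, control_info$site,
                           age = control_info$age, sex = control_info$sex)
    hp <- combat_harmonize(ct_p$table, patient_info$site,
                           age = patient_info$age, sex = patient_info$sex)
    tab_c <- hc$table
    tab_p <- hp$table
    harm <- list(mode = "separate")
  } else {
    tab_c <- ct_c$table
    tab_p <- ct_p$table
    harm <- list(mode = "single-site")
  }
  model <- build_normative_model(list(table = tab_c, edges = ct_c$edges,
                                      region_ids = ct_c$region_ids),
                                 site = control_info$site,
                                 age = control_info$age,
                                 sex = control_info$sex,
                                 harmonize = FALSE, age_ref = age_ref)
  model$harmonization <- harm
  z <- t(vapply(seq_len(n_p), function(p)
    suppressWarnings(
      connection_abnormality(tab_p[p, ], model,
                             age = patient_info$age[p],
                             sex = patient_info$sex[p])),
    numeric(length(model$mu))))
  rownames(z) <- rownames(ct_p$table)
  profiles <- lapply(seq_len(n_p), function(p)
    regional_abnormality(z[p, ], model$edges, model$region_ids,
                         sign_mode = sign_mode))
  names(profiles) <- rownames(ct_p$table)
  list(model = model, z = z, profiles = profiles)
}
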