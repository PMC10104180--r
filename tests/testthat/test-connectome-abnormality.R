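make_table <- function(n, nc, mean = 0.45, sd = 0.04, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(n * nc, mean, sd), n, nc))
}

test_that("harmonisation is a no-op for a single site", {
  tbl <- make_table(12, 30)
  h <- combat_harmonize(tbl, rep("A", 12), age = runif(12, 20, 60),
                        sex = rep(c("M", "F"), 6))
  expect_identical(h$table, tbl)
  expect_identical(h$params$mode, "single-site")
})

test_that("harmonisation removes planted additive and multiplicative site effects", {
  set.seed(10)
  n <- 80; nc <- 300
  site <- rep(1:2, each = 40)
  age <- runif(n, 18, 65)
  sex <- rep(c("M", "F"), 40)
  tbl <- make_table(n, nc, seed = 10)
  tbl[site == 2, ] <- tbl[site == 2, ] + 0.05
  h <- combat_harmonize(tbl, site, age, sex)
  d <- colMeans(h$table[site == 2, ]) - colMeans(h$table[site == 1, ])
  expect_gte(mean(abs(d) < 0.005), 0.95)

  tbl2 <- make_table(n, nc, seed = 11)
  tbl2[site == 2, ] <- 0.45 + (tbl2[site == 2, ] - 0.45) * sqrt(2)
  h2 <- combat_harmonize(tbl2, site, age, sex)
  vr <- apply(h2$table[site == 2, ], 2, var) /
    apply(h2$table[site == 1, ], 2, var)
  expect_gte(mean(vr > 0.8 & vr < 1.25), 0.95)
})

test_that("zero-variance connections are excluded and singleton sites rejected", {
  tbl <- make_table(12, 10)
  tbl[, 3] <- 0.5
  h <- combat_harmonize(tbl, rep(1:2, 6), age = runif(12, 20, 60),
                        sex = rep(c("M", "F"), 6))
  expect_identical(h$excluded, 3L)
  expect_identical(h$table[, 3], tbl[, 3])
  expect_error(combat_harmonize(tbl, c(rep(1, 11), 2)), "single subject")
})

test_that("robust covariate model recovers a planted age slope", {
  set.seed(21)
  ages <- runif(100, 18, 65)
  sexes <- rep(c("M", "F"), 50)
  w <- matrix(0.5 - 0.002 * (ages - 30) + 0.01 * (sexes == "F"),
              100, 50) + matrix(rnorm(100 * 50, 0, 0.02), 100, 50)
  cm <- fit_covariate_model(w, ages, sexes)
  expect_true(all(abs(cm$coef[, "age"] + 0.002) < 5e-4))
  # sex coefficient is the offset of the second factor level ("M" here),
  # so a planted +0.01 female offset appears as -0.01
  expect_true(all(abs(cm$coef[, "sex"] + 0.01) < 0.02))
})

test_that("null covariate effects stay within sampling error", {
  set.seed(22)
  ages <- runif(80, 18, 65)
  sexes <- rep(c("M", "F"), 40)
  w <- make_table(80, 100, sd = 0.03, seed = 22)
  cm <- fit_covariate_model(w, ages, sexes)
  se_slope <- 0.03 / (sd(ages) * sqrt(79))
  expect_gte(mean(abs(cm$coef[, "age"]) < 2 * se_slope), 0.9)
})

test_that("robust fit beats OLS under gross outlier contamination", {
  set.seed(23)
  ages <- runif(100, 18, 65)
  sexes <- rep(c("M", "F"), 50)
  truth <- -0.002
  nc <- 60
  w <- matrix(0.5 + truth * (ages - 30), 100, nc) +
    matrix(rnorm(100 * nc, 0, 0.02), 100, nc)
  out_rows <- sample(100, 10)
  w[out_rows, ] <- w[out_rows, ] + 0.3
  cm <- fit_covariate_model(w, ages, sexes)
  X <- cbind(1, ages - 30, as.numeric(sexes == "F"))
  ols <- apply(w, 2, function(y) stats::lm.fit(X, y)$coefficients[2])
  closer <- abs(cm$coef[, "age"] - truth) < abs(ols - truth)
  expect_gte(mean(closer), 0.8)
})

test_that("normative model reproduces hand-computed mean and SD", {
  w <- matrix(NA_real_, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  mats <- lapply(c(0.5, 0.6, 0.7), function(v) {
    m <- matrix(NA_real_, 3, 3)
    m[1, 2] <- m[2, 1] <- v
    connectivity_matrix(m)
  })
  model <- build_normative_model(mats, site = rep(1, 3), age = rep(30, 3),
                                 sex = c("M", "F", "M"),
                                 harmonize = FALSE, covariate_correct = FALSE)
  expect_equal(unname(model$mu), 0.6)
  expect_equal(unname(model$sigma), 0.1)
  expect_true(model$usable)
})

test_that("identical controls flag every connection unusable", {
  m <- matrix(0.5, 4, 4); diag(m) <- NA
  mats <- replicate(12, connectivity_matrix(m), simplify = FALSE)
  model <- build_normative_model(mats, site = rep(1, 12),
                                 age = runif(12, 20, 60),
                                 sex = rep(c("M", "F"), 6),
                                 harmonize = FALSE,
                                 covariate_correct = FALSE)
  expect_true(all(!model$usable))
})

test_that("mismatched region orderings are refused", {
  m <- matrix(0.5, 3, 3); diag(m) <- NA
  a <- connectivity_matrix(m, region_ids = c("r1", "r2", "r3"))
  b <- connectivity_matrix(m, region_ids = c("r3", "r2", "r1"))
  expect_error(connectome_table(list(a, b)), "region orderings")
})

test_that("connection z-scores follow (C - mu) / sigma with covariate transfer", {
  mats <- lapply(c(0.5, 0.6, 0.7), function(v) {
    m <- matrix(NA_real_, 3, 3)
    m[1, 2] <- m[2, 1] <- v
    connectivity_matrix(m)
  })
  model <- build_normative_model(mats, rep(1, 3), rep(30, 3),
                                 c("M", "F", "M"), harmonize = FALSE,
                                 covariate_correct = FALSE)
  pm <- matrix(NA_real_, 3, 3); pm[1, 2] <- pm[2, 1] <- 0.4
  z <- connection_abnormality(connectivity_matrix(pm), model, 30, "M")
  expect_equal(as.vector(z), -2)
  pm[1, 2] <- pm[2, 1] <- 0.6
  z0 <- connection_abnormality(connectivity_matrix(pm), model, 30, "M")
  expect_equal(as.vector(z0), 0)
})

test_that("a held-out control z-scores to approximately standard normal", {
  cfg <- tiny_config(n_controls = 41, n_regions = 45, n_sites = 1, seed = 3)
  ctrl <- generate_controls(cfg)
  model <- suppressWarnings(build_normative_model(
    lapply(ctrl[1:40], `[[`, "connectivity"),
    site = rep(1, 40),
    age = vapply(ctrl[1:40], `[[`, numeric(1), "age"),
    sex = vapply(ctrl[1:40], `[[`, character(1), "sex"),
    harmonize = FALSE))
  held <- ctrl[[41]]
  z <- connection_abnormality(held$connectivity, model, held$age, held$sex)
  expect_gte(sum(!is.na(z)), 200)
  expect_lt(abs(mean(z, na.rm = TRUE)), 0.1)
  expect_true(sd(z, na.rm = TRUE) > 0.85 && sd(z, na.rm = TRUE) < 1.15)
})

test_that("serialised normative models give identical downstream z-scores", {
  cfg <- tiny_config(n_controls = 20, n_regions = 15, n_sites = 1, seed = 9)
  ctrl <- generate_controls(cfg)
  model <- suppressWarnings(build_normative_model(
    lapply(ctrl, `[[`, "connectivity"), rep(1, 20),
    vapply(ctrl, `[[`, numeric(1), "age"),
    vapply(ctrl, `[[`, character(1), "sex"), harmonize = FALSE))
  f <- tempfile(fileext = ".json")
  write_normative_model(model, f)
  model2 <- read_normative_model(f)
  pat <- generate_patient(cfg, 4, id = 1, signals = FALSE)
  z1 <- connection_abnormality(pat$connectivity, model, pat$age, pat$sex)
  w <- pat$connectivity$weights[cbind(model2$edges$i, model2$edges$j)]
  z2 <- connection_abnormality(w, model2, pat$age, pat$sex)
  expect_equal(unname(z1), unname(z2), tolerance = 1e-12)
})

test_that("regional averaging matches hand arithmetic and sign conventions", {
  edges <- data.frame(i = c(1, 1), j = c(2, 3))
  z <- c(-1, -3)
  prof <- regional_abnormality(z, edges, c("1", "2", "3"))
  expect_equal(prof$R[1], -2)
  expect_equal(prof$score[1], 2)   # reduction mode negates
  expect_equal(prof$n, c(2L, 1L, 1L))
  raw <- regional_abnormality(z, edges, c("1", "2", "3"), sign_mode = "raw")
  expect_equal(raw$score[1], -2)
  zero <- regional_abnormality(c(0, 0), edges, c("1", "2", "3"))
  expect_true(all(zero$R == 0))
})

test_that("regional averaging agrees with a brute-force edge loop", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 10
    pres <- matrix(runif(n * n) < 0.5, n, n)
    pres[lower.tri(pres, diag = TRUE)] <- FALSE
    edges <- which(pres, arr.ind = TRUE)
    edges <- data.frame(i = edges[, 1], j = edges[, 2])
    z <- rnorm(nrow(edges))
    prof <- regional_abnormality(z, edges, as.character(1:n))
    manual <- vapply(1:n, function(k) {
      zz <- z[edges$i == k | edges$j == k]
      if (length(zz) == 0) NA_real_ else mean(zz)
    }, numeric(1))
    expect_equal(prof$R, manual)
  }
})

test_that("region permutation round trip leaves regional abnormality unchanged", {
  cfg <- tiny_config(n_controls = 16, n_regions = 12, n_sites = 1, seed = 13)
  ctrl <- generate_controls(cfg)
  pat <- generate_patient(cfg, 3, id = 1, signals = FALSE)
  run <- function(mats, pmat) {
    suppressWarnings(connectome_abnormalities(
      mats, list(pmat), subject_info(ctrl),
      data.frame(site = pat$site, age = pat$age, sex = pat$sex)))$profiles[[1]]
  }
  base <- run(lapply(ctrl, `[[`, "connectivity"), pat$connectivity)
  perm <- sample(12)
  permute <- function(cm) {
    connectivity_matrix(cm$weights[perm, perm],
                        region_ids = cm$region_ids[perm])
  }
  prof_p <- run(lapply(ctrl, function(s) permute(s$connectivity)),
                permute(pat$connectivity))
  back <- prof_p[match(base$region_id, prof_p$region_id), ]
  expect_equal(back$R, base$R, tolerance = 1e-10)
})

test_that("reordering harmonisation and covariate stages changes the z-scores", {
  set.seed(41)
  n <- 40; nc <- 60
  site <- rep(1:2, each = 20)
  age <- runif(n, 18, 65)
  sex <- rep(c("M", "F"), 20)
  tbl <- make_table(n, nc, seed = 41) - 0.002 * (age - 30) +
    outer(as.numeric(site == 2), rep(0.05, nc))
  standard <- {
    h <- combat_harmonize(tbl, site, age, sex)
    cm <- fit_covariate_model(h$table, age, sex)
    (cm$corrected[1, ] - colMeans(cm$corrected)) /
      apply(cm$corrected, 2, sd)
  }
  reordered <- {
    cm <- fit_covariate_model(tbl, age, sex)
    h <- combat_harmonize(cm$corrected, site, age, sex)
    (h$table[1, ] - colMeans(h$table)) / apply(h$table, 2, sd)
  }
  expect_gt(max(abs(standard - reordered)), 1e-6)
})
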