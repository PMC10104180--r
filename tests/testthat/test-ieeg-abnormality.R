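toy_rec <- function(samples, fs = 256) ieeg_recording(samples, fs)

test_that("common average reference zeroes shared signal and is idempotent", {
  s <- matrix(rep(sin(seq(0, 10, length.out = 512)), 3), 3, byrow = TRUE)
  rec <- toy_rec(s)
  out <- common_average_reference(rec)
  expect_true(all(abs(out$samples) < 1e-12))

  set.seed(1)
  r2 <- toy_rec(matrix(rnorm(4 * 512), 4))
  car1 <- common_average_reference(r2)
  expect_true(all(abs(colMeans(car1$samples)) < 1e-10))
  car2 <- common_average_reference(car1)
  expect_equal(car1$samples, car2$samples, tolerance = 1e-12)

  opp <- toy_rec(rbind(s[1, ], -s[1, ]))
  expect_equal(common_average_reference(opp)$samples, opp$samples,
               tolerance = 1e-12)
  expect_error(common_average_reference(toy_rec(s[1, , drop = FALSE])),
               ">=2")
})

test_that("band power picks out a planted sinusoid and scales quadratically", {
  set.seed(2)
  t <- seq(1 / 512, 70, by = 1 / 512)
  x <- sin(2 * pi * 10 * t) + 0.01 * rnorm(length(t))
  bp <- band_power(toy_rec(matrix(x, 1), fs = 512))
  expect_identical(colnames(bp)[which.max(bp)], "alpha")

  bp2 <- band_power(toy_rec(matrix(2 * x, 1), fs = 512))
  expect_equal(as.numeric(bp2 / bp), rep(4, 5), tolerance = 1e-10)
})

test_that("white-noise band power is approximately proportional to bandwidth", {
  set.seed(3)
  bp <- band_power(toy_rec(matrix(rnorm(70 * 512), 1), fs = 512))
  bw <- c(3, 4, 5, 17, 50)
  ratio <- as.numeric(bp) / bw
  expect_lt(max(ratio) / min(ratio), 1.2)
})

test_that("band power rejects bad sampling rates and NaN contacts", {
  set.seed(4)
  expect_error(band_power(toy_rec(matrix(rnorm(2000), 1), fs = 150)),
               "160")
  s <- matrix(rnorm(2 * 70 * 256), 2)
  s[2, 100] <- NaN
  expect_error(band_power(ieeg_recording(s, 256, c("a", "b"))), "b")
})

test_that("relative band power follows the log-then-normalise arithmetic", {
  raw <- structure(matrix(c(100, 100, 100, 100, 10000), 1,
                          dimnames = list("c1", ieeg_bands()$band)),
                   stage = "raw", class = c("band_power_table", "matrix",
                                            "array"))
  rel <- relative_band_power(raw)
  expect_equal(as.numeric(rel), c(1, 1, 1, 1, 2) / 6)

  eq <- structure(matrix(50, 2, 5,
                         dimnames = list(c("a", "b"), ieeg_bands()$band)),
                  stage = "raw", class = c("band_power_table", "matrix",
                                           "array"))
  expect_equal(as.numeric(relative_band_power(eq)), rep(0.2, 10))

  low <- eq; low[1, 1] <- 0.5
  expect_error(relative_band_power(low), "exceed 1")
  alt <- relative_band_power(low, order = "normalize-then-log")
  expect_equal(rowSums(alt), c(a = 1, b = 1), tolerance = 1e-9)
})

test_that("contacts are assigned to the nearest grey region within 5 mm", {
  vols <- generate_resection_volumes(8, 27, rep(0, 8))
  centers <- vols$centers
  contacts <- data.frame(contact_id = c("on", "far"),
                         x = c(centers[3, 1], -20),
                         y = c(centers[3, 2], -20),
                         z = c(centers[3, 3], -20))
  asg <- assign_contacts(contacts, vols$parcellation)
  expect_identical(asg$region_id, c("3", NA_character_))
  expect_equal(asg$distance[1], 0)
})

test_that("contact assignment agrees with a brute-force all-voxel scan", {
  set.seed(5)
  arr <- array(sample(0:4, 20^3, replace = TRUE), c(20, 20, 20))
  contacts <- data.frame(contact_id = paste0("c", 1:15),
                         x = runif(15, -2, 21), y = runif(15, -2, 21),
                         z = runif(15, -2, 21))
  asg <- assign_contacts(contacts, arr)
  vox <- which(arr > 0, arr.ind = TRUE)
  labs <- arr[vox]
  for (ci in 1:15) {
    p <- as.numeric(contacts[ci, c("x", "y", "z")])
    d <- sqrt(colSums((t(vox) - 1 - p)^2))
    if (min(d) >= 5) {
      expect_true(is.na(asg$region_id[ci]))
    } else {
      best <- min(labs[d <= min(d) + 1e-9])
      expect_identical(asg$region_id[ci], as.character(best))
      expect_equal(asg$distance[ci], min(d))
    }
  }
})

test_that("regional band power averages assigned contacts and keeps unit sums", {
  rel <- structure(matrix(c(0.2, 0.4, 0.3, 0.2, 0.1, 0.2, 0.2, 0.1,
                            0.2, 0.1), 2,
                          dimnames = list(c("c1", "c2"), ieeg_bands()$band)),
                   stage = "relative",
                   class = c("band_power_table", "matrix", "array"))
  asg <- data.frame(contact_id = c("c1", "c2"), region_id = c("7", "7"))
  out <- regional_band_power(rel, asg)
  expect_equal(out["7", "delta"], 0.3)
  expect_equal(unname(rowSums(out)), 1, tolerance = 1e-9)

  asg2 <- data.frame(contact_id = c("c1", "c2"), region_id = c("7", NA))
  out2 <- regional_band_power(rel, asg2)
  expect_equal(unname(out2["7", ]), unname(rel[1, ]))
})

test_that("normative band map computes per-cell mean and sample SD with flags", {
  bands <- ieeg_bands()$band
  mk <- function(v) matrix(v, 1, 5, dimnames = list("r1", bands))
  map <- build_normative_band_map(
    c(replicate(3, mk(0.25), simplify = FALSE),
      replicate(3, mk(0.35), simplify = FALSE)), min_subjects = 5)
  expect_equal(unname(map$mu["r1", "delta"]), 0.30)
  expect_equal(unname(map$sigma["r1", "delta"]),
               sd(c(0.25, 0.25, 0.25, 0.35, 0.35, 0.35)))
  ident <- build_normative_band_map(
    replicate(6, mk(0.2), simplify = FALSE), min_subjects = 5)
  expect_true(all(!ident$usable))
  few <- build_normative_band_map(
    c(replicate(2, mk(0.25), simplify = FALSE),
      replicate(2, mk(0.35), simplify = FALSE)), min_subjects = 5)
  expect_true(all(!few$usable))
})

test_that("two-subject map cell matches hand-computed mean and SD", {
  bands <- ieeg_bands()$band
  mk <- function(v) matrix(v, 1, 5, dimnames = list("r1", bands))
  map <- build_normative_band_map(list(mk(0.25), mk(0.35)),
                                  min_subjects = 2)
  expect_equal(unname(map$mu["r1", "alpha"]), 0.30)
  expect_equal(unname(map$sigma["r1", "alpha"]), 0.0707, tolerance = 1e-3)
})

test_that("iEEG abnormality is the maximum absolute band z-score", {
  bands <- ieeg_bands()$band
  mu <- matrix(0.3, 2, 5, dimnames = list(c("r1", "r2"), bands))
  sigma <- matrix(0.05, 2, 5, dimnames = list(c("r1", "r2"), bands))
  map <- structure(list(mu = mu, sigma = sigma,
                        n_subjects = c(r1 = 10, r2 = 10),
                        usable = mu > 0, bands = bands, min_subjects = 5),
                   class = "normative_band_map")
  pat <- mu
  prof0 <- ieeg_abnormality(pat, map)
  expect_equal(prof0$B, c(0, 0))

  pat2 <- mu
  pat2["r1", ] <- 0.3 + 0.05 * c(-3, 1, 0.5, 2, -1)
  prof <- ieeg_abnormality(pat2, map)
  expect_equal(prof$B[prof$region_id == "r1"], 3)

  pat3 <- mu
  pat3["r2", "delta"] <- 0.45
  prof3 <- ieeg_abnormality(pat3, map)
  expect_equal(prof3$B[prof3$region_id == "r2"], 3)
  expect_equal(prof3$z_delta[prof3$region_id == "r2"], 3)
  expect_true(all(prof3$B >= 0))
})

test_that("map serialisation round-trips to identical z-scores", {
  cfg <- tiny_config(n_regions = 8, n_ieeg_normative = 6,
                     contacts_per_region = 1)
  tabs <- lapply(1:6, function(i) {
    s <- eznorm:::generate_normative_ieeg_subject(cfg, i, seed = i)
    regional_band_power(
      relative_band_power(band_power(common_average_reference(s$recording))),
      s$assignment)
  })
  map <- build_normative_band_map(tabs, min_subjects = 5)
  f <- tempfile(fileext = ".json")
  write_normative_band_map(map, f)
  map2 <- read_normative_band_map(f)
  prof1 <- ieeg_abnormality(tabs[[1]], map)
  prof2 <- ieeg_abnormality(tabs[[1]], map2)
  expect_equal(prof1$B, prof2$B, tolerance = 1e-12)
})

test_that("planted band shifts raise regional abnormality above unshifted regions", {
  cfg <- tiny_config(n_regions = 8, n_ieeg_normative = 8,
                     contacts_per_region = 1)
  tabs <- lapply(1:8, function(i) {
    s <- eznorm:::generate_normative_ieeg_subject(cfg, i, seed = 40 + i)
    regional_band_power(
      relative_band_power(band_power(common_average_reference(s$recording))),
      s$assignment)
  })
  map <- build_normative_band_map(tabs, min_subjects = 5)
  shifts <- matrix(0, 8, 5)
  shifts[2, 3] <- 1   # alpha shift at region 2
  rec <- ieeg_recording(generate_signal(shifts, 8, 256, seed = 99), 256,
                        paste0("c", 1:8))
  asg <- data.frame(contact_id = paste0("c", 1:8),
                    region_id = as.character(1:8))
  prof <- ieeg_abnormalities(rec, asg, map)
  expect_identical(prof$region_id[which.max(prof$B)], "2")
})
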