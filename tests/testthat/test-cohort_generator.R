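test_that("cohort generation is deterministic and has the printed subtype split", {
  spec <- default_cohort_spec()
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$subtype == "dcSSc"), 38L)
  expect_equal(sum(a$subtype == "lcSSc"), 41L)
  expect_equal(nrow(a), 79L)
  expect_true(all(a$warrick_reader1 %in% 0:30))
  expect_true(all(a$warrick_reader2 %in% 0:30))
  expect_true(all(a$cam_extent_pct >= 0 & a$cam_extent_pct <= 100))
  expect_true(all(a$fvc_pct > 0 & a$fev1_pct > 0 & a$dlco_pct > 0))
  expect_equal(a$warrick_mean, (a$warrick_reader1 + a$warrick_reader2) / 2)
})

test_that("identity target correlation yields near-independent columns", {
  spec <- cohort_spec(n_dcssc = 5000L, n_lcssc = 5000L, corr = diag(5),
                      seed = 7)
  coh <- generate_cohort(spec)
  cols <- cbind(coh$cam_extent_pct, coh$warrick_mean, coh$fvc_pct,
                coh$fev1_pct, coh$dlco_pct)
  cm <- cor(cols)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.03)
})

test_that("clipping moves fewer than 1% of draws at the published parameters", {
  spec <- cohort_spec(n_dcssc = 50000L, n_lcssc = 50000L, seed = 3)
  coh <- generate_cohort(spec)
  # 6 bounded columns per patient
  expect_lt(attr(coh, "n_clipped") / (6 * nrow(coh)), 0.01)
})

test_that("column moments are recovered within 3 standard errors", {
  spec <- default_cohort_spec()
  coh <- generate_cohort(spec, seed = 9)
  n <- nrow(coh)
  cols <- list(cam = coh$cam_extent_pct, warrick = coh$warrick_mean,
               fvc = coh$fvc_pct, fev1 = coh$fev1_pct, dlco = coh$dlco_pct)
  for (v in names(cols)) {
    m <- unname(spec$mean_sd[[v]][["mean"]])
    s <- unname(spec$mean_sd[[v]][["sd"]])
    expect_lt(abs(mean(cols[[v]]) - m), 3 * s / sqrt(n))
    expect_lt(abs(sd(cols[[v]]) - s), 3 * s / sqrt(2 * n))
  }
})

test_that("reader columns recover the target ICC at large n", {
  spec <- cohort_spec(n_dcssc = 4000L, n_lcssc = 4000L, seed = 5)
  coh <- generate_cohort(spec)
  icc <- icc_two_way(cbind(coh$warrick_reader1, coh$warrick_reader2))
  expect_lt(abs(icc - 0.81), 0.02)
})

test_that("dcSSc patients average higher CaM extent", {
  coh <- generate_cohort(cohort_spec(n_dcssc = 2000L, n_lcssc = 2000L,
                                     seed = 2))
  gap <- mean(coh$cam_extent_pct[coh$subtype == "dcSSc"]) -
    mean(coh$cam_extent_pct[coh$subtype == "lcSSc"])
  expect_gt(gap, 3)
})

test_that("correlation matrix completion and PSD repair behave", {
  spec <- default_cohort_spec()
  # single-factor completion: r[i,j] = r[cam,i] r[cam,j]
  expect_equal(spec$corr["warrick", "fvc"], 0.829 * -0.490)
  expect_equal(spec$corr["fev1", "dlco"], -0.675 * -0.653)
  expect_true(all(eigen(spec$corr, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(spec$calibration$sigma_lat,
                        symmetric = TRUE)$values > 0))
  # mildly non-PSD matrices are repaired
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.9; m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.5  # smallest eigenvalue ~ -0.02
  expect_lt(min(eigen(m)$values), 0)
  r <- nearest_psd(m)
  expect_gte(min(eigen(r)$values), 0)
  expect_equal(diag(r), rep(1, 3))
  # irreparable matrices are rejected, naming the eigenvalue
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 0.95
  bad[1, 3] <- bad[3, 1] <- 0.95; bad[2, 3] <- bad[3, 2] <- -0.5
  expect_error(nearest_psd(bad), "eigenvalue",
               class = "ctild_config_error")
})

test_that("cohort spec validation rejects bad input", {
  expect_error(cohort_spec(reader_icc = 1.5), class = "ctild_config_error")
  bad_ms <- list(cam = c(mean = 19, sd = -1), warrick = c(mean = 12, sd = 7),
                 fvc = c(mean = 90, sd = 10), fev1 = c(mean = 84, sd = 9),
                 dlco = c(mean = 70, sd = 16))
  expect_error(cohort_spec(mean_sd = bad_ms), class = "ctild_config_error")
})
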