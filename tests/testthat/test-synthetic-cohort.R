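test_that("identical configurations give identical outputs", {
  cfg <- qc_config(n = 120, seed = 77)
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  q1 <- generate_quality(c1, cfg); q2 <- generate_quality(c2, cfg)
  expect_identical(q1, q2)
  k1 <- generate_connectomes(c1, q1, cfg, modalities = "SC")
  k2 <- generate_connectomes(c2, q2, cfg, modalities = "SC")
  expect_identical(k1$sc[[5]]$weights, k2$sc[[5]]$weights)
  # generating one modality reproduces that modality of a joint run
  k12 <- generate_connectomes(c1, q1, cfg)
  expect_identical(k12$sc[[5]]$weights, k1$sc[[5]]$weights)
})

test_that("cohort marginals match the configured population", {
  cfg <- qc_config(n = 5110, seed = 2)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$age >= 40 & ch$age <= 75))
  expect_equal(mean(ch$age), 59.4, tolerance = 0.01)     # ~3 SEM slack
  expect_equal(sd(ch$age), 8.7, tolerance = 0.02)
  expect_equal(mean(ch$sex), 0.494, tolerance = 0.05)
  expect_equal(mean(ch$bmi), 26.6, tolerance = 0.02)
  expect_true(all(ch$wmh_rel > 0))
  expect_true(all(ch$education %in% 1:3) && all(ch$diabetes %in% 0:3))
  expect_gt(cor(ch$age, log10(ch$wmh_rel)), 0.3)         # configured 0.4
})

test_that("zero-variance configuration yields identical records at the means", {
  cfg <- qc_config(
    n = 2, seed = 1,
    covariate_params = list(
      age = list(mean = 60, sd = 0, min = 40, max = 75),
      sex = list(p_female = 1),
      education = list(p = c(low = 0, middle = 1, high = 0)),
      bmi = list(mean = 25, sd = 0),
      diabetes = list(p = c(no = 1, prediabetes = 0, t2dm = 0, other = 0)),
      cvd = list(p_yes = 0),
      wmh = list(median = 0.02, q25 = 0.02, q75 = 0.02),
      age_wmh_cor = 0
    ))
  ch <- generate_cohort(cfg)
  expect_equal(unlist(ch[1, -1]), unlist(ch[2, -1]), ignore_attr = TRUE)
  expect_equal(ch$age, c(60, 60))
  expect_equal(ch$sex, c(1, 1))
  expect_equal(ch$education, c(2, 2))
  expect_equal(ch$wmh_rel, c(0.02, 0.02))
})

test_that("log-normal WMH calibration reproduces median and quartiles", {
  # analytic fit: mu = log10(median), sigma from the quartile ratio; check
  # by Monte Carlo at large n
  cfg <- qc_config(n = 1e5, seed = 3)
  ch <- generate_cohort(cfg)
  qs <- quantile(ch$wmh_rel, c(0.25, 0.5, 0.75))
  expect_equal(unname(qs[2]), 0.016, tolerance = 0.05)
  expect_equal(unname(qs[1]), 0.005, tolerance = 0.05)
  expect_equal(unname(qs[3]), 0.050, tolerance = 0.05)
})

test_that("invalid proportions are rejected", {
  expect_error(qc_config(covariate_params = list(sex = list(p_female = 1.2))),
               "\\[0, 1\\]")
  expect_error(qc_config(covariate_params = list(
    education = list(p = c(low = 0.5, middle = 0.4, high = 0.4)))),
    "sum to 1")
})

test_that("quality metrics carry the configured regression structure", {
  cfg <- qc_config(n = 5110, seed = 9)
  ch <- generate_cohort(cfg)
  q <- generate_quality(ch, cfg)
  z <- covariate_zmatrix(ch)
  fit <- standardized_regression(q$dmri_motion, z)
  expect_equal(fit$beta[fit$term == "age"], 0.368, tolerance = 0.1)
  expect_equal(fit$beta[fit$term == "sex"], -0.279, tolerance = 0.15)
  # observed-scale calibration
  expect_equal(mean(q$dmri_motion), 0.64, tolerance = 0.01)
  expect_equal(sd(q$dmri_motion), 0.16, tolerance = 0.02)
  expect_equal(mean(q$fmri_isnr), -39, tolerance = 0.02)
  # configured cross-metric correlations on the observed scale
  expect_equal(cor(q$fmri_isnr, q$fmri_motion), 0.522, tolerance = 0.1)
  expect_equal(cor(q$dmri_isnr, q$dmri_motion), 0.298, tolerance = 0.15)
})

test_that("a null generator yields quality independent of covariates", {
  cfg <- qc_config(n = 4000, seed = 4, preset = "null")
  ch <- generate_cohort(cfg)
  q <- generate_quality(ch, cfg)
  z <- covariate_zmatrix(ch)
  fit <- standardized_regression(q$dmri_motion, z)
  expect_true(all(abs(fit$beta) < 0.06))
  expect_lt(attr(fit, "r2"), 0.01)
})

test_that("residual correlation equals the observed correlation under a null model", {
  # with all coefficients zero the metric correlation is purely residual
  cfg <- qc_config(n = 5110, seed = 6, preset = "null")
  cfg$quality_cor_targets$r <- c(0.298, 0.522)
  ch <- generate_cohort(cfg)
  q <- generate_quality(ch, cfg)
  expect_equal(cor(q$fmri_isnr, q$fmri_motion), 0.522, tolerance = 0.06)
  expect_equal(cor(q$dmri_isnr, q$dmri_motion), 0.298, tolerance = 0.1)
})

test_that("coefficient sets implying explained variance >= 1 are rejected", {
  cfg <- qc_config(n = 200, seed = 1)
  cfg$quality_coeffs$dmri$motion <- c(0.9, 0.9, 0.9, 0.9, 0, 0, 0)
  ch <- generate_cohort(cfg)
  expect_error(generate_quality(ch, cfg), ">= 1")
})

test_that("degenerate generator shares the base template across participants", {
  cfg <- qc_config(n = 20, seed = 5, preset = "null")
  ch <- generate_cohort(cfg)
  q <- generate_quality(ch, cfg)
  cn <- generate_connectomes(ch, q, cfg)
  for (mod in c("sc", "fc")) {
    ws <- lapply(cn[[mod]], function(c) c$weights)
    for (w in ws[-1]) expect_identical(w, ws[[1]])
  }
  tmpl <- connectome_template(cfg)
  base <- tmpl$w_sc * (tmpl$p >= 0.5)
  w1 <- cn$sc[[1]]$weights
  expect_equal(w1 / max(w1), base / max(base), tolerance = 1e-12)
})

test_that("generated overall connectivity recovers the configured model", {
  # Monte-Carlo parameter recovery: the generating equation is the oracle
  terms <- c("sex", "bmi", "isnr", "motion")
  true <- c(0.213, 0.109, -0.120, -0.249)
  errs <- matrix(0, 6, length(terms))
  for (s in 1:6) {
    cfg <- qc_config(n = 4000, seed = 300 + s)
    ch <- generate_cohort(cfg)
    q <- generate_quality(ch, cfg)
    cn <- generate_connectomes(ch, q, cfg, modalities = "SC")
    oc <- vapply(cn$sc, overall_connectivity, numeric(1))
    if (s == 1) {
      expect_equal(mean(oc), 5.3e-3, tolerance = 0.02)
      expect_equal(sd(oc), 0.6e-3, tolerance = 0.1)
    }
    conn <- data.frame(participant_id = ch$participant_id, overall = oc)
    led <- fit_model1_model2(conn, ch, q, modality = "dmri")
    b2 <- led[led$outcome == "overall", ]
    errs[s, ] <- b2$beta2[match(terms, b2$term)] - true
  }
  expect_true(all(abs(colMeans(errs)) < 0.03))
})

test_that("FC weights stay inside [0, 1] and clipping is counted", {
  cfg <- qc_config(n = 40, seed = 21)
  ch <- generate_cohort(cfg)
  q <- generate_quality(ch, cfg)
  cn <- generate_connectomes(ch, q, cfg, modalities = "FC")
  for (c in cn$fc) {
    expect_true(all(c$weights >= 0 & c$weights <= 1))
    expect_true(isSymmetric(c$weights))
    expect_true(all(diag(c$weights) == 0))
  }
  expect_true(is.numeric(attr(cn, "n_clipped")))
})

test_that("volume fixtures carry a recomputable ground truth", {
  fx <- generate_volume_fixture(n_volumes = 4, snr_target = 22,
                                motion_per_volume = 0.5,
                                mismatch_target = 0.1, seed = 8)
  # motion and mismatch are exact by construction
  expect_equal(head_motion(fx$trace), fx$truth$motion)
  expect_equal(fx$truth$motion, 0.5)
  expect_equal(atlas_mismatch(fx$brain_mask, fx$atlas_mask),
               fx$truth$mismatch)
  expect_lt(abs(fx$truth$mismatch - 0.1), 0.005)   # integer-count resolution
  # iSNR within estimator tolerance
  est <- isnr(fx$volumes[, , , 1], fx$volumes[, , , 2], fx$brain_mask)
  expect_lt(abs(est - (-22)) / 22, 0.10)
  # static head
  fx0 <- generate_volume_fixture(motion_per_volume = 0, seed = 8)
  expect_equal(fx0$truth$motion, 0)
  expect_error(generate_volume_fixture(mismatch_target = 0.99999),
               "nearest achievable")
})

test_that("fixtures round-trip through NIfTI and motion-parameter files", {
  fx <- generate_volume_fixture(n_volumes = 3, snr_target = 39,
                                motion_per_volume = 1,
                                mismatch_target = 0.05, seed = 12)
  dir <- file.path(tempdir(), "fixture_rt")
  write_volume_fixture(fx, dir)
  qt <- quality_from_files(dir)
  expect_equal(qt$motion, fx$truth$motion)
  expect_equal(qt$mismatch, fx$truth$mismatch)
  expect_lt(abs(qt$isnr - fx$truth$isnr) / abs(fx$truth$isnr), 0.10)
  back <- read_volume_fixture(dir)
  expect_equal(back$trace$translations, fx$trace$translations,
               ignore_attr = TRUE)
  expect_equal(sum(back$brain_mask), sum(fx$brain_mask))
})

test_that("configurations round-trip through YAML with identical output", {
  cfg <- qc_config(n = 60, seed = 19)
  path <- tempfile(fileext = ".cfg")
  write_qc_config(cfg, path)
  cfg2 <- read_qc_config(path)
  expect_equal(generate_cohort(cfg2), generate_cohort(cfg))
  q1 <- generate_quality(generate_cohort(cfg), cfg)
  q2 <- generate_quality(generate_cohort(cfg2), cfg2)
  expect_equal(q1, q2, ignore_attr = TRUE)
})

test_that("shipped presets load and generate", {
  for (preset in c("maastricht.cfg", "null.cfg")) {
    path <- system.file("extdata", preset, package = "connqc")
    expect_true(nzchar(path))
    cfg <- read_qc_config(path)
    cfg$n <- 50L
    expect_silent(generate_cohort(cfg))
  }
})
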