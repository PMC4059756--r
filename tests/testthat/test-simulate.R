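test_that("gamma-variate evaluates the closed form and its analytic peak", {
  # peak at t0 + a*b with value (a*b)^a * exp(-a)
  expect_equal(gamma_variate(30.5, 26, 3, 1.5), 4.5369, tolerance = 1e-4)
  expect_equal(gamma_variate(26, 26, 3, 1.5), 0)
  expect_equal(gamma_variate(27, 26, 3, 1.5), exp(-2 / 3), tolerance = 1e-12)
  expect_error(gamma_variate(NaN, 26, 3, 1.5))

  # analytic maximum vs fine-grid maximisation oracle
  tf <- seq(26, 45, by = 1e-4)
  expect_equal(max(gamma_variate(tf, 26, 3, 1.5)),
               (3 * 1.5)^3 * exp(-3), tolerance = 1e-6)
})

test_that("true AIF is causal and peaks at the gamma-variate maximum", {
  g <- time_grid()
  ca <- make_true_aif(g)
  expect_true(all(ca >= 0))
  expect_identical(ca[g$time < 26], rep(0, sum(g$time < 26)))

  # peak of the 1 s curve, read through linear upsampling, within 2 %
  sm <- shape_metrics(ca, g, upsample_dt = 0.01)
  expect_equal(sm$h_p, 4.5369, tolerance = 0.02)

  # recirculation pushed beyond the scan window leaves the plain gamma
  p <- aif_params(recirc_delay = 1000)
  expect_equal(make_true_aif(g, p), gamma_variate(g$time, 26, 3, 1.5))
})

test_that("false arterial curves cover the full t0 x delay grid", {
  g <- time_grid()
  fa <- make_false_aifs(g)
  expect_equal(nrow(fa$curves), 16)
  expect_setequal(interaction(fa$params$t0, fa$params$recirc_delay),
                  interaction(expand.grid(t0 = 27:30, d = 9:12)$t0,
                              expand.grid(t0 = 27:30, d = 9:12)$d))
  # later onset than the true AIF
  ca <- make_true_aif(g)
  onset <- function(y) g$time[which(y > 0)[1]]
  expect_true(all(apply(fa$curves, 1, onset) > onset(ca)))
})

test_that("residue function obeys the central volume theorem", {
  g <- time_grid()
  r4 <- residue_function(g, 4)
  expect_equal(r4[1], 1)
  expect_true(all(diff(r4) <= 0))
  expect_gt(trapz_auc(r4, g$dt), 3.92)
  expect_lt(trapz_auc(r4, g$dt), 4.08)
  r10 <- residue_function(g, 10)
  expect_equal(trapz_auc(r10, g$dt), 10, tolerance = 0.02)
  expect_true(all(r10[-1] >= r4[-1]))
  expect_error(residue_function(g, -1))

  # non-exponential member still integrates to the MTT
  r_box <- residue_function(g, 6, shape = 3)
  expect_equal(r_box[1], 1)
  expect_true(all(diff(r_box) <= 1e-12))
  expect_equal(trapz_auc(r_box, g$dt), 6, tolerance = 0.02)
})

test_that("tissue concentration is a causal, linear functional of the AIF", {
  g <- time_grid()
  ca <- make_true_aif(g)
  ct <- tissue_concentration(ca, 4, 4, g)
  expect_true(all(ct >= 0))
  expect_equal(ct[1], 0)
  expect_lt(max(ct), max(ca))
  expect_gt(g$time[which.max(ct)], g$time[which.max(ca)])
  expect_equal(tissue_concentration(rep(0, g$n), 4, 4, g), rep(0, g$n))
  expect_equal(tissue_concentration(ca, 8, 4, g), 2 * ct)
  expect_error(tissue_concentration(ca[1:10], 4, 4, g))
})

test_that("calibration produces the prescribed grey-matter signal trough", {
  g <- time_grid()
  ca <- make_true_aif(g)
  acq <- acquisition_params()
  k <- calibrate_k(g, ca, acq = acq)
  acq$k_const <- k
  ct_gm <- tissue_concentration(ca, 4, 4, g)
  s <- concentration_to_signal(ct_gm, acq)
  expect_equal(min(s), 60, tolerance = 1e-9)
  expect_equal(concentration_to_signal(rep(0, g$n), acq), rep(100, g$n))

  # k is inversely proportional to the concentration peak
  k2 <- calibrate_k(g, 2 * ca, acq = acq)
  expect_equal(k2, k / 2, tolerance = 1e-9)
})

test_that("partial-volume mixing is a convex signal combination", {
  a <- c(100, 50, 10)
  t <- c(100, 90, 80)
  expect_equal(mix_pve(a, t, 1), a)
  expect_equal(mix_pve(a, t, 0), t)
  expect_equal(mix_pve(a, t, 0.5), (a + t) / 2)
  expect_error(mix_pve(a, t, 1.2))
})

test_that("noise injection is seeded, targeted, and at the stated amplitude", {
  set.seed(99)
  sig <- matrix(100, 400, 90)
  sp <- noise_spec(snr = 20, n_noisy_curves = 100)
  out1 <- add_noise(sig, sp, s0 = 100, seed = 7)
  out2 <- add_noise(sig, sp, s0 = 100, seed = 7)
  expect_identical(out1, out2)
  expect_length(out1$noisy_rows, 100)
  untouched <- setdiff(seq_len(400), out1$noisy_rows)
  expect_identical(out1$signals[untouched, ], sig[untouched, ])
  # SD = S0/SNR = 5 (signals are far from zero so |.| changes nothing)
  resid <- out1$signals[out1$noisy_rows, ] - 100
  expect_equal(sd(as.numeric(resid)), 5, tolerance = 0.1)

  out0 <- add_noise(sig, noise_spec(20, 0), s0 = 100, seed = 7)
  expect_identical(out0$signals, sig)
})

test_that("the default dataset reproduces the stated voxel population", {
  ds <- build_dataset(seed = 3)
  expect_equal(nrow(ds$signals$values), 1902)
  counts <- table(ds$labels$class)
  expect_equal(as.numeric(counts[c("true_arterial", "false_arterial",
                                   "normal_GM", "path_GM", "WM", "pve_mix")]),
               c(6, 16, 440, 440, 600, 400))
  expect_true(all(is.na(ds$labels$mix_weight) | ds$labels$class == "pve_mix"))
  expect_true(all(!is.na(ds$labels$mix_weight[ds$labels$class == "pve_mix"])))

  # identical seeds -> bit-identical builds
  expect_identical(build_dataset(seed = 3)$signals$values, ds$signals$values)

  # noise-free build: the 6 true arterial rows are identical curves
  cfg0 <- sim_config(noise = noise_spec(20, 0))
  ds0 <- build_dataset(cfg0, seed = 3)
  tr <- ds0$signals$values[ds0$labels$class == "true_arterial", ]
  expect_true(all(apply(tr, 2, function(col) all(col == col[1]))))

  # arterial rows do not depend on the seed (only jitter/mix/noise streams do)
  ds4 <- build_dataset(seed = 4)
  art <- ds$labels$class %in% c("true_arterial", "false_arterial")
  noisy_art <- intersect(which(art), union(ds$noisy_rows, ds4$noisy_rows))
  clean <- setdiff(which(art), noisy_art)
  expect_identical(ds$signals$values[clean, ], ds4$signals$values[clean, ])
})
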