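make_signal_set <- function(values, dt = 1) {
  curve_set(values, time_grid(duration = ncol(values) * dt, dt = dt),
            kind = "signal")
}

test_that("signal-to-concentration conversion inverts the signal model", {
  g <- time_grid()
  flat <- make_signal_set(matrix(100, 3, 90))
  conc <- signal_to_concentration(flat, te = 0.030)
  expect_equal(unname(conc$values), matrix(0, 3, 90))

  # S = 60 on an S0 = 100 baseline: C = -log(0.6)/TE
  s <- matrix(100, 1, 90); s[1, 40] <- 60
  conc <- signal_to_concentration(make_signal_set(s), te = 0.030)
  expect_equal(unname(conc$values[1, 40]), -log(0.6) / 0.030,
               tolerance = 1e-12)

  # simulator roundtrip identity (noise-free, with the calibrated constant)
  ds <- build_dataset(sim_config(noise = noise_spec(20, 0)), seed = 1)
  conc <- signal_to_concentration(ds$signals, te = ds$acq$te,
                                  k_const = ds$k_const)
  art <- conc$values[1, ]
  expect_equal(art, ds$true_aif, tolerance = 1e-9)

  # invalid baseline -> curve excluded and recorded
  bad <- rbind(rep(100, 90), rep(0, 90))
  conc <- signal_to_concentration(make_signal_set(bad), te = 0.030)
  expect_equal(nrow(conc$values), 1)
  expect_equal(attr(conc, "trace")$removed, "v0002")
})

test_that("the area filter removes the stated count, smallest areas first", {
  set.seed(1)
  vals <- matrix(rexp(100 * 30), 100, 30)
  cs <- make_signal_set(vals)
  out <- auc_filter(cs, 0.90)
  expect_equal(nrow(out$values), 10)
  auc <- apply(vals, 1, trapz_auc)
  expect_setequal(out$ids, cs$ids[order(auc, decreasing = TRUE)[1:10]])
  # survivors keep their original relative order
  expect_identical(out$ids, cs$ids[cs$ids %in% out$ids])

  big <- make_signal_set(matrix(rexp(1902 * 30), 1902, 30))
  expect_equal(nrow(auc_filter(big, 0.90)$values), 1902 - floor(0.9 * 1902))
  expect_identical(auc_filter(cs, 0)$values, cs$values)
  tr <- attr(out, "trace")
  expect_equal(tr$n_in - length(tr$removed), tr$n_out)
})

test_that("roughness is the integrated squared second difference", {
  tt <- 0:19
  expect_equal(roughness(3 * tt + 2), 0)
  expect_equal(roughness(tt^2), 4 * (20 - 2))
  smooth <- sin(tt / 5)
  set.seed(2)
  expect_gt(mean(replicate(20, roughness(smooth + rnorm(20, 0, 0.5)))),
            roughness(smooth))
  expect_error(roughness(c(1, 2)))
})

test_that("the roughness filter discards noise-corrupted curves", {
  g <- time_grid()
  base <- gamma_variate(g$time, 26, 3, 1.5) + 0.5
  set.seed(5)
  clean <- t(replicate(30, base * runif(1, 0.5, 2)))
  corrupt <- t(replicate(10, abs(base + rnorm(90, 0, 1))))
  cs <- make_signal_set(rbind(clean, corrupt))
  out <- roughness_filter(cs, 0.25)   # removes floor(0.25*40) = 10
  removed <- setdiff(cs$ids, out$ids)
  expect_length(removed, 10)
  expect_true(all(removed %in% cs$ids[31:40]))

  expect_identical(roughness_filter(cs, 0)$values, cs$values)
  big <- make_signal_set(matrix(rexp(191 * 30), 191, 30))
  expect_equal(nrow(roughness_filter(big, 0.25)$values), 144)
})

test_that("the first-passage gamma fit recovers known parameters", {
  g <- time_grid()

  # well-specified case: pure gamma bolus, no recirculation
  pure <- gamma_variate(g$time, 26, 3, 1.5)
  f <- fit_gamma_first_passage(pure, g)
  expect_true(f$converged)
  expect_equal(f$a, 3, tolerance = 0.05)
  expect_equal(f$b, 1.5, tolerance = 0.05)
  expect_equal(f$auc_first, gamma(4) * 1.5^4, tolerance = 0.02)

  # full AIF: recirculation contaminates the fit window tail, but the
  # fitted first-passage area still matches the closed form within 2 %
  ca <- make_true_aif(g)
  f2 <- fit_gamma_first_passage(ca, g)
  expect_true(f2$converged)
  expect_equal(f2$auc_first, 30.375, tolerance = 0.02)

  # amplitude linearity: scaling the curve scales the area, not the shape
  f3 <- fit_gamma_first_passage(2 * ca, g)
  expect_equal(f3$auc_first / f2$auc_first, 2, tolerance = 1e-6)
  expect_equal(f3$a, f2$a, tolerance = 1e-6)
  expect_equal(f3$b, f2$b, tolerance = 1e-6)

  # flat curve: reported, not raised
  expect_false(fit_gamma_first_passage(rep(0, 90), g)$converged)
})

test_that("steady-state start is the first sub-threshold post-peak sample", {
  gg <- time_grid(duration = 6, dt = 1)
  # peak 4 at t = 2; first later sample < 1.2 is t = 4 (value 1)
  expect_equal(steady_state_start(c(0, 1, 4, 2, 1, 0.5), gg), 5)  # 1-based
  expect_true(is.na(steady_state_start(1:6, gg)))
  # threshold is strict: a sample exactly at 0.3 * max does not qualify
  expect_equal(steady_state_start(c(0, 10, 3, 3, 2.9, 0), gg), 5)
})

test_that("the PVE ratio filter rejects curves with anomalous tails", {
  g <- time_grid()
  ca <- make_true_aif(g)
  vals <- t(replicate(12, ca))
  cs <- curve_set(vals, g, kind = "concentration")

  # identical curves: every ratio equals the mean, all kept
  out <- pve_ratio_filter(cs)
  expect_equal(nrow(out$values), 12)

  # pure scaling leaves the ratio unchanged
  vals2 <- vals
  vals2[3, ] <- 5 * vals2[3, ]
  out2 <- pve_ratio_filter(curve_set(vals2, g, kind = "concentration"))
  r <- attr(out2, "ratios")
  expect_equal(unname(r[3]), unname(r[1]), tolerance = 1e-6)

  # doubling only the steady-state tail doubles the ratio -> excluded
  f <- fit_gamma_first_passage(ca, g)
  vals3 <- vals
  tail_idx <- (f$ss_index + 1):g$n
  vals3[5, tail_idx] <- 2 * vals3[5, tail_idx]
  out3 <- pve_ratio_filter(curve_set(vals3, g, kind = "concentration"))
  expect_false("v0005" %in% out3$ids)
  expect_true(all(setdiff(cs$ids, "v0005") %in% out3$ids))
})

test_that("filter traces reconcile along the whole chain", {
  ds <- build_dataset(small_sim_config(), seed = 2)
  conc <- signal_to_concentration(ds$signals, te = ds$acq$te,
                                  k_const = ds$k_const)
  n0 <- nrow(conc$values)
  a <- auc_filter(conc, 0.90)
  b <- roughness_filter(a, 0.25)
  expect_equal(nrow(a$values), n0 - floor(0.9 * n0))
  expect_equal(nrow(b$values), nrow(a$values) - floor(0.25 * nrow(a$values)))
  for (st in list(attr(a, "trace"), attr(b, "trace"))) {
    expect_equal(st$n_in - length(st$removed), st$n_out)
  }
  # each stage returns an ordered subset with no duplicates
  expect_true(all(b$ids %in% a$ids))
  expect_identical(b$ids, a$ids[a$ids %in% b$ids])
  expect_false(anyDuplicated(b$ids) > 0)
})
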