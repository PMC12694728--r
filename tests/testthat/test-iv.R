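make_sweep <- function(t, I) tibble::tibble(t_ms = t, I_pA = I)

test_that("epoch mean of a constant trace is that constant", {
  sw <- make_sweep(seq(0.05, 100, by = 0.1), rep(3.7, 1000))
  expect_equal(epoch_mean(sw, 10, 20), 3.7)
})

test_that("epoch mean of a linear ramp is the value at the window midpoint", {
  t <- seq(0.05, 100, by = 0.1)
  sw <- make_sweep(t, 0.4 + 2 * t)
  expect_equal(epoch_mean(sw, 10, 20), 0.4 + 2 * 15)
})

test_that("invalid epoch windows are rejected with the window named", {
  sw <- make_sweep(seq(0.05, 100, by = 0.1), rnorm(1000))
  expect_error(epoch_mean(sw, 20, 10), "t0")
  expect_error(epoch_mean(sw, 150, 160), "outside the sweep")
})

test_that("epoch means are invariant to sample permutation within the window", {
  set.seed(3)
  t <- seq(0.05, 100, by = 0.1)
  sw <- make_sweep(t, rnorm(length(t)))
  shuffled <- sw[sample(nrow(sw)), ]
  expect_equal(epoch_mean(shuffled, 10, 60), epoch_mean(sw, 10, 60))
})

test_that("build_iv yields one point per sweep at the command level", {
  ss <- synthesize_sweeps(step_protocol(dt_ms = 0.2), std_light(),
                          fast_kinetics(), seed = 1)
  iv <- build_iv(ss, c(125, 150), epoch = "uv")
  expect_equal(nrow(iv), 14L)
  expect_equal(iv$V_mV, seq(-130, 130, by = 20)) # sorted by voltage
  expect_identical(attr(iv, "epoch"), "uv")
})

test_that("build_iv rejects windows that straddle the voltage step", {
  ss <- synthesize_sweeps(step_protocol(dt_ms = 0.2), std_light(),
                          fast_kinetics(), seed = 1)
  expect_error(build_iv(ss, c(40, 60)), "not constant")
})

test_that("replicate aggregation carries SD and n", {
  ivs <- lapply(1:3, function(s) {
    ss <- synthesize_sweeps(step_protocol(dt_ms = 0.25), std_light(),
                            fast_kinetics(),
                            nf = noise_filter_spec(noise_sd_pA = 2), seed = s)
    build_iv(ss, c(125, 150), epoch = "uv")
  })
  agg <- aggregate_iv(ivs)
  expect_true(all(c("SD_pA", "n") %in% names(agg)))
  expect_true(all(agg$n == 3L))
  expect_true(all(agg$SD_pA >= 0))
})

test_that("noiseless supralinear curves round-trip exactly", {
  V <- seq(-130, 130, by = 20)
  g0 <- 1; alpha <- 2; o <- 0
  iv <- iv_curve(V, g0 * (1 + alpha * (V / 1000)^2) * V + o)
  fit <- fit_supralinear(iv)
  expect_equal(fit$g0_nS, g0, tolerance = 1e-6)
  expect_equal(fit$alpha_per_V2, alpha, tolerance = 1e-6)
  expect_equal(fit$offset_pA, o, tolerance = 1e-6)
  expect_true(all(eigen(fit$cov, only.values = TRUE)$values > -1e-12))
})

test_that("ohmic special case: fixed alpha = 0 on a line through the origin", {
  V <- seq(-100, 100, by = 20)
  fit <- fit_supralinear(iv_curve(V, 1 * V), fix_alpha = 0)
  expect_equal(fit$g0_nS, 1, tolerance = 1e-12)
  expect_equal(fit$offset_pA, 0, tolerance = 1e-12)
  expect_equal(fit$alpha_per_V2, 0)
})

test_that("underdetermined or single-polarity I-V fits are rejected", {
  expect_error(fit_supralinear(iv_curve(c(-10, 0, 10), c(-1, 0, 1))), ">= 4")
  expect_error(fit_supralinear(iv_curve(c(10, 20, 30, 40), 1:4)), "polarities")
})

test_that("Wald 95% CIs cover the generating parameters in most replicates", {
  V <- seq(-130, 130, by = 20)
  g0 <- 1; alpha <- 2; o <- 0.5; sd_I <- 2
  truth <- c(g0, alpha, o)
  set.seed(42)
  cover <- matrix(FALSE, 200, 3)
  for (r in 1:200) {
    I <- g0 * (1 + alpha * (V / 1000)^2) * V + o + rnorm(length(V), sd = sd_I)
    fit <- fit_supralinear(iv_curve(V, I))
    est <- c(fit$g0_nS, fit$alpha_per_V2, fit$offset_pA)
    se <- sqrt(diag(fit$cov))
    cover[r, ] <- abs(est - truth) <= 1.96 * se
  }
  expect_true(all(colMeans(cover) >= 0.90))
})

test_that("scale equivariance: currents x k scale g0 and offset, leave alpha and V_r", {
  V <- seq(-130, 130, by = 20)
  I <- 1.3 * (1 + 5 * (V / 1000)^2) * V + 2
  for (k in c(0.5, 3, 10)) {
    f1 <- fit_supralinear(iv_curve(V, I))
    f2 <- fit_supralinear(iv_curve(V, k * I))
    expect_equal(f2$g0_nS, k * f1$g0_nS, tolerance = 1e-9)
    expect_equal(f2$offset_pA, k * f1$offset_pA, tolerance = 1e-9)
    expect_equal(f2$alpha_per_V2, f1$alpha_per_V2, tolerance = 1e-9)
    expect_equal(reversal_potential(iv_curve(V, k * I)),
                 reversal_potential(iv_curve(V, I)), tolerance = 1e-12)
  }
})

test_that("weighted linear fit matches the closed-form WLS normal equations", {
  set.seed(8)
  V <- seq(-130, 130, by = 20)
  sd <- runif(length(V), 0.5, 4)
  I <- 0.012 * V + 0.3 + rnorm(length(V), sd = sd)
  iv <- iv_curve(V, I, SD_pA = sd)
  fit <- fit_linear_weighted(iv)
  # independent oracle: weighted normal equations
  w <- 1 / sd^2
  X <- cbind(1, V)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * I))
  expect_equal(fit$offset_pA, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope_nS, beta[2], tolerance = 1e-9)
})

test_that("equal SDs reduce weighted fit to ordinary least squares", {
  V <- seq(-100, 100, by = 25)
  I <- 0.02 * V + 1 + c(0.1, -0.2, 0.05, 0, -0.1, 0.2, -0.05, 0.1, 0)
  ols <- stats::coef(stats::lm(I ~ V))
  fit <- fit_linear_weighted(iv_curve(V, I, SD_pA = rep(1.5, length(V))))
  expect_equal(fit$offset_pA, unname(ols[1]), tolerance = 1e-12)
  expect_equal(fit$slope_nS, unname(ols[2]), tolerance = 1e-12)
})

test_that("two weighted points give the exact interpolating line", {
  fit <- fit_linear_weighted(iv_curve(c(-50, 50), c(-1, 3), SD_pA = c(1, 2)))
  expect_equal(fit$slope_nS, 0.04, tolerance = 1e-12)
  expect_equal(fit$offset_pA, 1, tolerance = 1e-12)
})

test_that("zero SDs are rejected with an unweighted fallback proposed", {
  iv <- iv_curve(c(-50, 0, 50), c(-1, 0, 1), SD_pA = c(1, 0, 1))
  expect_error(fit_linear_weighted(iv), "unweighted")
  expect_error(fit_linear_weighted(iv_curve(c(-50, 0, 50), c(-1, 0, 1))), "SD")
})

test_that("reversal potential of a line is its root", {
  V <- seq(-130, 130, by = 20)
  expect_equal(reversal_potential(iv_curve(V, 0.5 * (V + 59.2))), -59.2,
               tolerance = 1e-9)
})

test_that("reversal potential of bi-ionic curves is found at 20 mV spacing", {
  V <- seq(-130, 130, by = 20)
  # two-conductance bi-ionic superposition: K+ (Nernstian at -59.2 mV)
  # plus a small ohmic background reversing at 0 mV
  e_k <- nernst_potential(0.150, 0.015)
  g_k <- 2; g_bg <- 0.1
  vr_true <- g_k * e_k / (g_k + g_bg) # zero of g_k (V - E_k) + g_bg V
  iv <- iv_curve(V, g_k * (V - e_k) + g_bg * V)
  expect_lt(abs(reversal_potential(iv) - vr_true), 0.5)
  # constant-field (GHK current equation) curvature biases interpolation by
  # well under the 20 mV grid pitch
  u_of <- function(v) 96485.33212 * (v / 1000) / (8.314462618 * 298.15)
  I_ghk <- function(v, c1 = 0.150, c2 = 0.015) {
    u <- u_of(v)
    ifelse(abs(u) < 1e-9, c1 - c2, u * (c1 - c2 * exp(-u)) / (1 - exp(-u)))
  }
  est <- reversal_potential(iv_curve(V, I_ghk(V)))
  expect_lt(abs(est - e_k), 1)
})

test_that("curves without a sign change yield NA with a warning", {
  V <- seq(-100, 100, by = 20)
  expect_warning(vr <- reversal_potential(iv_curve(V, V^2 + 10)), "no sign change")
  expect_true(is.na(vr))
})

test_that("state ratio of a fit set against itself is exactly 1 with SEM 0", {
  fits <- lapply(1:4, function(i) structure(list(g0_nS = i), class = "iv_fit"))
  sr <- state_ratio(fits, fits)
  expect_equal(sr$ratio_mean, 1)
  expect_equal(sr$ratio_sem, 0)
})

test_that("single-replicate ratios report an absent SEM", {
  f <- list(structure(list(g0_nS = 2), class = "iv_fit"))
  g <- list(structure(list(g0_nS = 1), class = "iv_fit"))
  sr <- state_ratio(f, g)
  expect_equal(sr$ratio_mean, 2)
  expect_true(is.na(sr$ratio_sem))
})

test_that("state ratio rejects zero denominators and unpaired lengths", {
  f <- lapply(1:2, function(i) structure(list(g0_nS = 1), class = "iv_fit"))
  z <- lapply(c(1, 0), function(g) structure(list(g0_nS = g), class = "iv_fit"))
  expect_error(state_ratio(f, z), "0")
  expect_error(state_ratio(f, f[1]), "unpaired")
})

test_that("4-replicate experiments usually recover the generating ratio within 2 SEM", {
  # generating ratio g_cis/g_trans = 7.5; noise as in the synthetic recordings
  n_hit <- 0
  for (rep in 1:10) {
    fits <- lapply(1:4, function(k) simulate_uv_blue_fits(1000 * rep + k))
    sr <- state_ratio(lapply(fits, `[[`, "uv"), lapply(fits, `[[`, "blue"))
    if (abs(sr$ratio_mean - 7.5) <= 2 * sr$ratio_sem) n_hit <- n_hit + 1
  }
  # a 2-SEM interval with 3 degrees of freedom covers ~86% of the time
  expect_gte(n_hit, 7)
})

test_that("percent change matches its definition and rejects zero baselines", {
  expect_equal(round(percent_change(12.1, 20.7)), 71)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(2, 4), 100)
  expect_error(percent_change(0, 1), "zero baseline")
})
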