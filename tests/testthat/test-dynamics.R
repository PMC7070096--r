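test_that("aEIF derivatives reduce to the expected terms at rest", {
  p <- toy_params(I_bg_pA = 0)
  # at V = E_L the leak vanishes; only the exponential term drives V
  d <- aeif_derivatives(p$E_L_mV, 0, p)
  expected <- p$g_L_nS * p$Delta_T_mV *
    exp((p$E_L_mV - p$V_th_mV) / p$Delta_T_mV) / p$C_m_pF
  expect_equal(d$dV, expected)
  expect_gt(d$dV, 0)
  expect_equal(d$dw, 0)
  # with w = w0 > 0, adaptation relaxes at rate -w0/tau_w
  d2 <- aeif_derivatives(p$E_L_mV, 12, p)
  expect_equal(d2$dw, -12 / p$tau_w_ms)
  expect_error(aeif_derivatives(NaN, 0, p), "non-finite")
})

test_that("small slope factor recovers the leaky integrate-and-fire limit", {
  # independent leaky-IF oracle: dV = (-gL (V-EL) + I - w) / C
  lif <- function(V, w, p, I) (-p$g_L_nS * (V - p$E_L_mV) + I - w) / p$C_m_pF
  for (V in c(-70, -60, -55)) {
    p <- toy_params(Delta_T_mV = 1e-6, I_bg_pA = 120)
    d <- aeif_derivatives(V, 3, p)
    expect_equal(d$dV, lif(V, 3, p, 120), tolerance = 1e-6)
  }
})

test_that("reset rule fires only past the ceiling and increments adaptation", {
  p <- toy_params(b_pA = 20)
  r <- apply_reset(p$V_peak_mV + 0.1, 10, p)
  expect_true(r$spiked)
  expect_equal(r$V, p$V_r_mV)
  expect_equal(r$w, 30)
  # below threshold: unchanged
  r2 <- apply_reset(p$V_r_mV, 10, p)
  expect_false(r2$spiked)
  expect_equal(r2$V, p$V_r_mV)
  expect_equal(r2$w, 10)
  # two consecutive crossings accumulate 2b
  r3 <- apply_reset(p$V_peak_mV + 1, r$w, p)
  expect_equal(r3$w, 10 + 2 * p$b_pA)
})

test_that("NMDA gate follows the sigmoid and other receptors are ungated", {
  expect_equal(nmda_gate(-55, "AMPA"), 1)
  expect_equal(nmda_gate(30, "GABAA"), 1)
  expect_equal(nmda_gate(0, "NMDA"), 1.08 / 1.19)
  expect_equal(nmda_gate(1e6, "NMDA"), 1.08)
  # strictly increasing and bounded in (0, 1.08]
  v <- seq(-90, 60, by = 1)
  g <- nmda_gate(v, "NMDA")
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g <= 1.08))
})

test_that("synaptic kernel vanishes at onset, at zero driving force, and peaks per closed form", {
  spec <- list(g_max_nS = 1.5, E_rev_mV = 0, tau_on_ms = 0.5,
               tau_off_ms = 2, tau_D_ms = 1, receptor = "AMPA")
  # onset instant: both exponentials equal 1
  expect_equal(synaptic_current(spec, 10, 1, 11, -60), 0)
  # zero driving force
  expect_equal(synaptic_current(spec, 10, 1, 15, 0), 0)
  # peak time: closed form against a dense numerical scan of the kernel
  tpk <- kernel_peak_time(spec$tau_on_ms, spec$tau_off_ms)
  ts <- seq(0.001, 10, by = 0.001)
  kern <- exp(-ts / spec$tau_off_ms) - exp(-ts / spec$tau_on_ms)
  expect_equal(tpk, ts[which.max(kern)], tolerance = 1e-3)
  curr_at <- function(t) synaptic_current(spec, 10, 1, t, -60)
  expect_gt(abs(curr_at(10 + spec$tau_D_ms + tpk)),
            abs(curr_at(10 + spec$tau_D_ms + tpk + 0.5)))
  expect_gt(abs(curr_at(10 + spec$tau_D_ms + tpk)),
            abs(curr_at(10 + spec$tau_D_ms + tpk - 0.3)))
  # misconfiguration
  bad <- spec; bad$tau_on_ms <- 3
  expect_error(synaptic_current(bad, 10, 1, 12, -60), "tau_on")
})

test_that("kernel is non-negative, zero before onset, and integrates to tau_off - tau_on", {
  tau_on <- 0.5; tau_off <- 8
  f <- function(t) exp(-t / tau_off) - exp(-t / tau_on)
  ts <- seq(0, 200, by = 0.001)
  expect_true(all(f(ts) >= 0))
  q <- stats::integrate(f, 0, Inf)
  expect_equal(q$value, tau_off - tau_on, tolerance = 1e-3 * (tau_off - tau_on))
  spec <- list(g_max_nS = 1, E_rev_mV = 0, tau_on_ms = tau_on,
               tau_off_ms = tau_off, tau_D_ms = 2, receptor = "AMPA")
  expect_equal(synaptic_current(spec, 5, 1, 6.9, -60), 0)
})

test_that("STP initialization conventions give the stated first efficacies", {
  prm <- list(U = 0.25, tau_facil_ms = 500, tau_rec_ms = 200)
  st <- stp_init(prm)
  expect_equal(st$u, 0.25)
  expect_equal(st$R, 1)
  expect_equal(stp_advance(st, prm, 0)$efficacy, 0.25)
  # complement convention: a1 = U (1 - U)
  st2 <- stp_init(prm, r1_complement = TRUE)
  expect_equal(stp_advance(st2, prm, 0)$efficacy, 0.25 * 0.75)
  # any U: first efficacy equals U under the default convention
  for (U in c(0.1, 0.5, 0.9)) {
    prmU <- list(U = U, tau_facil_ms = 500, tau_rec_ms = 200)
    expect_equal(stp_advance(stp_init(prmU), prmU, 5)$efficacy, U)
  }
})

test_that("STP recurrence matches direct evaluation and its limits", {
  prm <- list(U = 0.25, tau_facil_ms = 500, tau_rec_ms = 200)
  # second spike at dt = 500 ms: direct evaluation of the u update
  effs <- stp_train(prm, c(0, 500))
  u2 <- 0.25 * exp(-1) + 0.25 * (1 - 0.25 * exp(-1))
  R2 <- 1 * (1 - u2) * exp(-500 / 200) + 1 - exp(-500 / 200)
  expect_equal(effs[2], u2 * R2, tolerance = 1e-12)
  expect_equal(u2, 0.3190, tolerance = 1e-4)
  # dt -> infinity: full recovery to (U, 1)
  eff_far <- stp_train(prm, c(0, 1e9))
  expect_equal(eff_far[2], 0.25, tolerance = 1e-9)
  # ordering fault
  st <- stp_init(prm)
  st <- stp_advance(st, prm, 10)$state
  expect_error(stp_advance(st, prm, 10), "increasing")
})

test_that("STP sequences stay in their invariant ranges on random trains", {
  prm <- list(U = 0.25, tau_facil_ms = 500, tau_rec_ms = 200)
  set.seed(42)
  for (rep in 1:20) {
    times <- cumsum(stats::rexp(50, rate = 1 / 30))
    st <- stp_init(prm)
    us <- numeric(50); Rs <- numeric(50)
    for (i in seq_along(times)) {
      res <- stp_advance(st, prm, times[i])
      st <- res$state
      us[i] <- st$u; Rs[i] <- st$R
      expect_true(res$efficacy > 0 && res$efficacy < 1)
    }
    expect_true(all(us >= prm$U & us < 1))
    expect_true(all(Rs > 0 & Rs <= 1))
    expect_gt(us[2], us[1])              # utilization always facilitates
  }
  # depression: in a recovery-dominant regime the 2nd spike at short dt
  # is weaker than the 1st
  prm_dep <- list(U = 0.5, tau_facil_ms = 50, tau_rec_ms = 800)
  eff <- stp_train(prm_dep, c(0, 5))
  expect_lt(eff[2], eff[1])
})
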