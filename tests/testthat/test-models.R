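test_that("Rescorla-Wagner trace follows the delta rule with prior convention", {
  # alternating CS+ (reinforced first) and CS-
  sq <- toy_seq(c("+", "-", "+", "-", "+"), c(1, 0, 0, 0, 1))
  tr <- model_trace(sq, "RW", eta = 0.3)
  expect_equal(tr$z[1], 0.5)           # initial value, either CS
  expect_equal(tr$z[2], 0.5)
  expect_equal(tr$z[3], 0.5 + 0.3 * (1 - 0.5)) # 0.65 after one reinforcement
  expect_equal(tr$z, tr$x)
  # CS- value decays toward 0 under u = 0
  cs_minus <- model_trace(toy_seq(rep("-", 6), rep(0, 6)), "RW", eta = 0.4)
  expect_true(all(diff(cs_minus$z) <= 0))
  # near-degenerate learning rate: prediction tracks the previous outcome
  sq2 <- default_seq(2)
  trd <- model_trace(sq2, "RW", eta = 1 - 1e-12)
  ip <- which(sq2$cs == "CS+")
  expect_equal(trd$z[ip][-1], as.numeric(sq2$us[ip][-length(ip)]),
               tolerance = 1e-9)
  expect_error(model_trace(sq, "RW", eta = 1), "eta")
  expect_error(model_trace(sq, "RW"), "eta")
})

test_that("hybrid trace updates value with the previous associability", {
  sq <- toy_seq(c("+", "+"), c(1, 0))
  tr <- model_trace(sq, "HM1", k = 0.6)
  # direct substitution after one reinforced CS+:
  # eta' = 0.6*|0.5-1| + 0.4*0.5 = 0.5 ; x' = 0.5 + 0.5*(1-0.5) = 0.75
  expect_equal(tr$eta_t[2], 0.5)
  expect_equal(tr$x[2], 0.75)
  expect_equal(tr$z, tr$eta_t)
  expect_equal(model_trace(sq, "HM2", k = 0.6)$z, tr$x)

  # k -> 0 limit: associability frozen at eta0, value follows RW(eta0)
  sq2 <- default_seq(4)
  tr0 <- model_trace(sq2, "HM2", k = 1e-12, eta0 = 0.37)
  rw <- model_trace(sq2, "RW", eta = 0.37)
  expect_equal(tr0$x, rw$x, tolerance = 1e-8)
  expect_true(all(abs(tr0$eta_t - 0.37) < 1e-8))

  # long unreinforced run: once |x - u| < eta, associability decays
  # monotonically (checked against an independent reference recursion)
  u <- rep(0, 60)
  got <- model_trace(toy_seq(rep("-", 60), u), "HM1", k = 0.5)
  ref <- ref_hybrid(u, k = 0.5)
  expect_equal(got$eta_t, ref$eta, tolerance = 1e-14)
  expect_equal(got$x, ref$x, tolerance = 1e-14)
  start <- which(abs(ref$x) < ref$eta)[1]
  expect_true(all(diff(got$eta_t[start:60]) < 0))
  expect_error(model_trace(sq, "HM1", k = 0), "k")
})

test_that("beta-binomial trace carries the ideal observer's prior state", {
  sq <- toy_seq(c("+", "-", "+", "+"), c(1, 0, 0, 1))
  tr <- model_trace(sq, "BM")
  # Beta(1,1) prior on the first trial of either CS
  expect_equal(tr$prior_mean[1], 0.5)
  expect_equal(tr$v[1], -log(2))
  expect_equal(tr$prior_mean[2], 0.5)
  # after one reinforced CS+ trial -> Beta(2,1), mean 2/3
  expect_equal(tr$prior_mean[3], 2 / 3)
  # after n CS- omissions -> Beta(1, n+1), mean 1/(n+2)
  n <- 9
  trm <- model_trace(toy_seq(rep("-", n + 1), rep(0, n + 1)), "BM")
  expect_equal(trm$prior_mean[n + 1], 1 / (n + 2))
  # pseudo-count invariants: a,b >= 1 and a+b = 2 + trials seen of that CS
  sq2 <- default_seq(5)
  tr2 <- model_trace(sq2, "BC")
  for (lev in c("CS+", "CS-")) {
    i <- which(sq2$cs == lev)
    expect_true(all(tr2$alpha[i] >= 1 & tr2$beta[i] >= 1))
    expect_equal(tr2$alpha[i] + tr2$beta[i], 2 + seq_along(i) - 1)
    expect_true(all(diff(tr2$v[i]) < 0)) # uncertainty strictly shrinks
  }
  # BC observation variable is uncertainty plus prior mean
  expect_equal(tr2$z, tr2$v + tr2$prior_mean)
})

test_that("terminal CS+ posterior equals Beta(41, 41) on the default design", {
  # 40 US in 80 CS+ trials force the terminal posterior mean to 1/2
  for (seed in c(1, 2, 3)) {
    sq <- default_seq(seed)
    tr <- model_trace(sq, "BM")
    last <- max(which(sq$cs == "CS+"))
    a_post <- tr$alpha[last] + sq$us[last]
    b_post <- tr$beta[last] + 1 - sq$us[last]
    expect_equal(c(a_post, b_post), c(41, 41))
    expect_equal(a_post / (a_post + b_post), 0.5)
  }
})

test_that("prior-mean increments follow a decaying-rate delta rule", {
  # E_{n+1} - E_n = (u_n - E_n) / (alpha_n + beta_n + 1), per CS
  for (seed in 1:5) {
    sq <- default_seq(seed)
    tr <- model_trace(sq, "BM")
    for (lev in c("CS+", "CS-")) {
      i <- which(sq$cs == lev)
      e <- tr$prior_mean[i]; u <- sq$us[i]
      s <- tr$alpha[i] + tr$beta[i]
      inc <- (u - e) / (s + 1)
      expect_equal(diff(e), inc[-length(inc)], tolerance = 1e-12)
    }
  }
})

test_that("null models behave as specified", {
  sq <- default_seq(6)
  nl <- observation_variable("NL", sq)
  expect_true(all(nl[sq$cs == "CS+"] == 1))
  expect_true(all(nl[sq$cs == "CS-"] == 0))
  un <- observation_variable("UN", sq)
  expect_equal(un[1], -log(2))
  # brute-force pooled count accumulation as oracle
  cnt <- 2
  ref <- numeric(nrow(sq))
  for (t in seq_len(nrow(sq))) { ref[t] <- -log(cnt); cnt <- cnt + 1 }
  expect_equal(un, ref)
  expect_equal(un, -log(seq_len(160) + 1))
  expect_true(all(diff(un) < 0))
})

test_that("observation_variable dispatch mirrors the model table", {
  sq <- default_seq(7)
  expect_equal(observation_variable("BM", sq), model_trace(sq, "BM")$prior_mean)
  expect_equal(observation_variable("HM2", sq, k = 0.3),
               model_trace(sq, "HM2", k = 0.3)$x)
  expect_equal(sort(unique(observation_variable("NL", sq))), c(0, 1))
  expect_error(observation_variable("XX", sq))
})

test_that("traces match independent reference recursions and stay bounded", {
  for (seed in 1:5) {
    sq <- default_seq(seed)
    ip <- which(sq$cs == "CS+"); im <- which(sq$cs == "CS-")
    rw <- model_trace(sq, "RW", eta = 0.23)
    expect_equal(rw$z[ip], ref_rw(sq$us[ip], 0.23), tolerance = 1e-12)
    expect_equal(rw$z[im], ref_rw(sq$us[im], 0.23), tolerance = 1e-12)
    bm <- model_trace(sq, "BM")
    expect_equal(bm$prior_mean[ip], ref_beta_prior(sq$us[ip])$prior_mean)
    # prediction-type variables live in the unit interval
    for (z in list(rw$z, model_trace(sq, "HM2", k = 0.7)$x, bm$z))
      expect_true(all(z >= 0 & z <= 1))
    # BC's variable sits within one unit above the pure uncertainty term
    bc <- model_trace(sq, "BC")
    expect_true(all(bc$z >= bc$v & bc$z <= bc$v + 1))
    # determinism: identical inputs give bit-identical traces
    expect_identical(model_trace(sq, "HM1", k = 0.4),
                     model_trace(sq, "HM1", k = 0.4))
  }
})

test_that("average traces show the qualitative group-level shapes", {
  # averages over 100 random sequences: BM's CS+ prediction hovers at the
  # true rate 0.5; BC's CS+ variable decays; CS- associability decays
  n_seq <- 100
  bm_p <- bc_p <- hm_m <- matrix(NA_real_, n_seq, 80)
  for (s in seq_len(n_seq)) {
    sq <- default_seq(1000 + s)
    ip <- which(sq$cs == "CS+"); im <- which(sq$cs == "CS-")
    bm_p[s, ] <- model_trace(sq, "BM")$z[ip]
    bc_p[s, ] <- model_trace(sq, "BC")$z[ip]
    hm_m[s, ] <- model_trace(sq, "HM1", k = 0.5)$z[im]
  }
  bm_avg <- colMeans(bm_p)
  # early presentations are pulled up by the reinforced first trial of the
  # block; from a handful of observations on, the prediction sits at the
  # true 50% reinforcement rate
  expect_true(all(abs(bm_avg[5:80] - 0.5) < 0.1))
  expect_lt(abs(mean(bm_avg[40:80]) - 0.5), 0.03)
  expect_true(all(diff(colMeans(bc_p)) < 0))   # uncertainty-driven decay
  hm_avg <- colMeans(hm_m)
  expect_true(all(diff(hm_avg[5:80]) < 0))     # associability habituates
  expect_lt(hm_avg[80], hm_avg[1] / 2)
})
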