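test_that("rss_objective sums squared residuals over US-omission trials only", {
  sq <- toy_seq(c("+", "-", "+"), c(0, 0, 0))
  y <- c(1, 2, 3); z <- c(0, 1, 0)
  expect_equal(rss_objective(y, sq, z, beta1 = 1, beta0 = 1), 4) # (0,0,2)^2
  # exact linear data -> zero residual
  expect_equal(rss_objective(2 * z + 1, sq, z, 2, 1), 0)
  # slope zero at the mean -> total sum of squares
  expect_equal(rss_objective(y, sq, z, 0, mean(y)), sum((y - mean(y))^2))
  # reinforced trials are masked
  sq2 <- toy_seq(c("+", "-", "+"), c(1, 0, 0))
  expect_equal(rss_objective(y, sq2, z, 1, 1), sum((c(2, 1) - c(2, 3))^2))
  expect_error(rss_objective(y[1:2], sq, z, 1, 1), "per trial")
})

test_that("BIC follows p*ln(T) + T*ln(RSS/T)", {
  expect_equal(bic(rss = 120, T = 120, p = 2), 2 * log(120))
  expect_equal(bic(rss = 30, T = 120, p = 2), 2 * log(120) + 120 * log(0.25))
  # one extra parameter at equal fit costs ln(T)
  expect_equal(bic(50, 100, 3) - bic(50, 100, 2), log(100))
  expect_warning(b <- bic(0, 120, 2, floor = 1e-12), "floor")
  expect_true(is.finite(b))
})

test_that("profiled OLS attains the dense 2-D grid-search minimum", {
  sq <- toy_seq(rep(c("+", "-"), 10), rep(0, 20))
  set.seed(42)
  z <- observation_variable("BC", sq)
  y <- 1.7 * z + 0.4 + rnorm(20, 0, 0.3)
  fit <- fit_model(y, sq, "BC")
  # oracle: exhaustive search over the observation-parameter plane
  b0g <- seq(-1, 2, length.out = 301)
  b1g <- seq(-1, 4, length.out = 501)
  rss_grid <- outer(b0g, b1g, function(b0, b1)
    colSums(matrix((rep(b1, each = 20) * z + rep(b0, each = 20) - y)^2,
                   nrow = 20)))
  expect_lte(fit$rss, min(rss_grid) + 1e-8)
})

test_that("each model refits its own noiseless data exactly", {
  sq <- default_seq(11)
  pars <- list(RW = list(eta = 0.3), HM1 = list(k = 0.45),
               HM2 = list(k = 0.45), BM = list(), BC = list(), UN = list(),
               NL = list())
  for (m in model_space()) {
    y <- do.call(simulate_participant,
                 c(list(sq, m, beta0 = 1, beta1 = 2, sigma = 0), pars[[m]]))
    fit <- fit_model(y, sq, m)
    expect_lt(fit$rss, 1e-10)
    expect_equal(fit$beta1, 2, tolerance = 1e-4)
    expect_equal(fit$beta0, 1, tolerance = 1e-4)
    expect_equal(fit$p, 2L + n_learning_params(m))
  }
})

test_that("fitted learning rate matches an exhaustive fine-grid oracle", {
  # oracle: independent RW recursion over a 1e-4-resolution learning-rate
  # grid, profiled OLS at each point
  oracle_eta <- function(y, sq) {
    idx <- unreinforced_indices(sq)
    ip <- which(sq$cs == "CS+"); im <- which(sq$cs == "CS-")
    etas <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    best <- c(Inf, NA)
    z <- numeric(nrow(sq))
    for (e in etas) {
      z[ip] <- ref_rw(sq$us[ip], e); z[im] <- ref_rw(sq$us[im], e)
      r <- sum(resid(lm.fit(cbind(1, z[idx]), y[idx]))^2)
      if (r < best[1]) best <- c(r, e)
    }
    best
  }
  sq <- default_seq(12)
  y0 <- simulate_participant(sq, "RW", beta0 = 1, beta1 = 2, sigma = 0,
                             eta = 0.3)
  fit0 <- fit_model(y0, sq, "RW")
  expect_equal(fit0$eta, 0.3, tolerance = 1e-3)
  # noisy participants: fitted optimum at least as good as the grid oracle
  set.seed(99)
  for (i in 1:3) {
    eta_true <- runif(1, 0.1, 0.9)
    y <- simulate_participant(sq, "RW", beta0 = 1, beta1 = 2, sigma = 0.5,
                              eta = eta_true)
    fit <- fit_model(y, sq, "RW")
    orc <- oracle_eta(y, sq)
    expect_lte(fit$rss, orc[1] + 1e-8)
    expect_equal(fit$eta, orc[2], tolerance = 0.02)
  }
})

test_that("the step-model fit equals CS-conditional means on analysed trials", {
  sq <- default_seq(13)
  set.seed(5)
  y <- rnorm(nrow(sq), mean = ifelse(sq$cs == "CS+", 3, 1))
  fit <- fit_model(y, sq, "NL")
  idx <- unreinforced_indices(sq)
  m_minus <- mean(y[idx][sq$cs[idx] == "CS-"])
  m_plus <- mean(y[idx][sq$cs[idx] == "CS+"])
  expect_equal(fit$beta0, m_minus, tolerance = 1e-10)
  expect_equal(fit$beta0 + fit$beta1, m_plus, tolerance = 1e-10)
})

test_that("explained variance is 1 minus RSS/TSS on analysed trials", {
  sq <- default_seq(14)
  y <- simulate_participant(sq, "BM", beta0 = 1, beta1 = 2, sigma = 0)
  fit <- fit_model(y, sq, "BM")
  expect_equal(explained_variance(y, sq, fit), 1, tolerance = 1e-9)
  expect_equal(fit$r2, explained_variance(y, sq, fit))
  # flat data: undefined
  fit2 <- fit_model(y, sq, "NL")
  expect_warning(ev <- explained_variance(rep(1, nrow(sq)), sq, fit2), "zero")
  expect_true(is.na(ev))
})

test_that("BIC ordering is invariant to a constant amplitude shift", {
  sq <- default_seq(15)
  set.seed(7)
  y <- simulate_participant(sq, "BC", beta0 = 1, beta1 = 1.5, sigma = 1)
  t1 <- fit_all_models(y, sq)
  t2 <- fit_all_models(y + 10, sq)
  expect_equal(t2$bic, t1$bic, tolerance = 1e-6)
  expect_equal(t2$beta1, t1$beta1, tolerance = 1e-6)
  expect_equal(t2$beta0, t1$beta0 + 10, tolerance = 1e-6)
  expect_equal(t1$p, c(3L, 3L, 3L, 2L, 2L, 2L, 2L))
})

test_that("residualizing the habituation null removes its contribution", {
  sq <- default_seq(16, id = "R1")
  set.seed(21)
  # data generated purely by the pooled habituation model
  y <- simulate_participant(sq, "UN", beta0 = 1, beta1 = 2, sigma = 0.4)
  un_fit <- fit_model(y, sq, "UN")
  res <- residualize(y, sq, un_fit)
  idx <- unreinforced_indices(sq)
  expect_lt(abs(mean(res[idx])), 1e-10)        # OLS residuals centre at 0
  bm_fit <- fit_model(res, sq, "BM")
  expect_lt(abs(bm_fit$beta1), 0.2)            # no learning signal remains
  # slope-free null: residuals are a pure intercept shift
  un0 <- un_fit; un0$beta1 <- 0
  expect_equal(residualize(y, sq, un0), y - un0$beta0)
  # guards
  expect_error(residualize(y, sq, bm_fit), "UN")
  sq2 <- default_seq(16, id = "OTHER")
  expect_error(residualize(y, sq2, un_fit), "mismatch")
})

test_that("fit_model rejects degenerate input", {
  sq <- toy_seq(c("+", "+", "+"), c(1, 1, 0))
  expect_error(fit_model(c(1, 2, 3), sq, "BM"), "at least 3")
  sq2 <- default_seq(17)
  expect_error(fit_model(rep(NA_real_, 160), sq2, "BM"), "finite")
  expect_error(fit_model(1:10, sq2, "BM"), "per trial")
})

test_that("fit_dataset reproduces per-participant fits from long tables", {
  ds <- simulate_experiment(generator_config("NL", n_participants = 3,
                                             seed = 8))
  tab <- fit_dataset(ds$data, models = c("BM", "NL"))
  expect_equal(nrow(tab), 6L)
  d1 <- ds$data[ds$data$participant == "P01", ]
  direct <- fit_model(d1$amplitude, ds$sequences[["P01"]], "NL")
  expect_equal(tab$bic[tab$participant == "P01" & tab$model == "NL"],
               direct$bic)
  L <- evidence_matrix(tab)
  expect_equal(dim(L), c(3L, 2L))
  expect_equal(unname(L["P01", "NL"]), -direct$bic / 2)
})
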