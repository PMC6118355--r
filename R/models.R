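#' The model space
#'
#' Seven candidate accounts of trial-by-trial anticipatory autonomic
#' responses, each defined by a learning rule plus the model variable
#' `z_t` entering the linear observation function `y_t = b1*z_t + b0 + e_t`:
#'
#' * `RW` — Rescorla-Wagner: associative strength `x_t`, fixed learning
#'   rate `eta` (1 learning parameter).
#' * `HM1` — hybrid Rescorla-Wagner/Pearce-Hall: associability `eta_t`
#'   (dynamic learning rate tracking unsigned prediction errors), scaling
#'   parameter `k` (1 parameter).
#' * `HM2` — the same hybrid rule, but observing associative strength `x_t`.
#' * `BM` — beta-binomial Bayesian ideal observer: prior mean `E[theta]`
#'   of the per-CS Beta belief over US probability (0 parameters).
#' * `BC` — the same observer, observing prior uncertainty plus prior mean,
#'   `v_t + E[theta]` with `v_t = -ln(alpha + beta)`.
#' * `UN` — non-learning habituation null: pooled observation count over
#'   all trials regardless of CS, `z_t = -ln(t + 1)`.
#' * `NL` — non-learning discrimination null: `z = 1` on CS+ trials,
#'   `z = 0` on CS- trials.
#'
#' @return Character vector of model identifiers, in canonical order.
#' @seealso [model_trace()], [observation_variable()], [model_families()]
#' @export
model_space <- function() c("RW", "HM1", "HM2", "BM", "BC", "UN", "NL")

#' Model families
#'
#' Partition of the model space by the type of quantity the observation
#' function reads out: expected outcome (`O`: RW, HM2, BM), surprise /
#' model update (`S`: HM1), a combination of outcome and uncertainty
#' (`C`: BC), and null (`N`: UN, NL).
#'
#' @return Named character vector mapping each model id to its family label.
#' @export
model_families <- function() {
  c(RW = "O", HM1 = "S", HM2 = "O", BM = "O", BC = "C", UN = "N", NL = "N")
}

#' Number of learning parameters per model
#'
#' RW and the hybrid read-outs carry one fitted learning parameter
#' (`eta` or `k`); the probabilistic and null models carry none. The two
#' observation-function parameters are counted separately at fit time.
#'
#' @param model_id One of [model_space()].
#' @return Integer count (0 or 1).
#' @export
n_learning_params <- function(model_id) {
  model_id <- match.arg(model_id, model_space())
  if (model_id %in% c("RW", "HM1", "HM2")) 1L else 0L
}

## ---- per-CS recursions (internal) -------------------------------------
## All observation variables use the *prior* convention: the value reported
## on a presentation is the state held before that presentation's outcome.

# Rescorla-Wagner prior values over one CS's presentations.
# x[1] = 0.5; x[n+1] = x[n] + eta * (u[n] - x[n]) — a linear recursion,
# evaluated with a recursive filter.
rw_values <- function(u, eta, x0 = 0.5) {
  n <- length(u)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(x0)
  c(x0, stats::filter(eta * u[-n], 1 - eta, method = "recursive", init = x0))
}

# Same recursion for a whole grid of learning rates at once: returns an
# n x length(etas) matrix (rows = presentations, columns = candidate eta).
rw_values_grid <- function(u, etas, x0 = 0.5) {
  n <- length(u)
  out <- matrix(x0, n, length(etas))
  if (n < 2L) return(out)
  x <- rep(x0, length(etas))
  for (i in seq_len(n - 1L)) {
    x <- x + etas * (u[i] - x)
    out[i + 1L, ] <- x
  }
  out
}

# Hybrid RW/Pearce-Hall prior values over one CS's presentations.
# Value update uses the associability held before the trial:
#   x[n+1]   = x[n] + eta[n] * (u[n] - x[n])
#   eta[n+1] = k * |x[n] - u[n]| + (1 - k) * eta[n]
hybrid_values <- function(u, k, eta0 = 0.5, x0 = 0.5) {
  n <- length(u)
  x_out <- eta_out <- numeric(n)
  x <- x0; e <- eta0
  for (i in seq_len(n)) {
    x_out[i] <- x; eta_out[i] <- e
    pe <- u[i] - x
    x <- x + e * pe
    e <- k * abs(pe) + (1 - k) * e
  }
  list(x = x_out, eta = eta_out)
}

# Grid version over candidate k values: two n x length(ks) matrices.
hybrid_values_grid <- function(u, ks, eta0 = 0.5, x0 = 0.5) {
  n <- length(u); g <- length(ks)
  x_out <- eta_out <- matrix(0, n, g)
  x <- rep(x0, g); e <- rep(eta0, g)
  for (i in seq_len(n)) {
    x_out[i, ] <- x; eta_out[i, ] <- e
    pe <- u[i] - x
    x <- x + e * pe
    e <- ks * abs(pe) + (1 - ks) * e
  }
  list(x = x_out, eta = eta_out)
}

# Beta-binomial prior state over one CS's presentations, from the
# uninformative Beta(1, 1) prior. Before presentation n the observer holds
# alpha = 1 + #US seen, beta = 1 + #omissions seen, alpha + beta = n + 1.
beta_prior_values <- function(u) {
  n <- length(u)
  seen_us <- c(0, cumsum(u))[seq_len(n)]
  alpha <- 1 + seen_us
  beta <- 1 + (seq_len(n) - 1L) - seen_us
  list(alpha = alpha, beta = beta,
       prior_mean = alpha / (alpha + beta),
       v = -log(alpha + beta))
}

# Scatter per-CS presentation series back onto session trial order.
per_cs_apply <- function(seq, fn) {
  z <- numeric(nrow(seq))
  for (lev in levels(seq$cs)) {
    idx <- which(seq$cs == lev)
    if (length(idx)) z[idx] <- fn(seq$us[idx])
  }
  z
}

## ---- traces ------------------------------------------------------------

#' Trial-by-trial latent trace of a learning model
#'
#' Runs one model over a trial sequence and returns the per-trial latent
#' quantities together with the observation variable `z`. State is kept
#' separately per CS (except for `UN`, which pools all trials), and every
#' reported value is the state held *before* the trial's outcome, so that
#' `z_t` is a genuine prediction.
#'
#' @param seq A `trial_sequence` from [generate_design()].
#' @param model_id One of [model_space()].
#' @param eta Rescorla-Wagner learning rate in (0, 1); required for `RW`.
#' @param k Hybrid scaling parameter in (0, 1); required for `HM1`/`HM2`.
#' @param eta0 Initial associability of the hybrid model (fixed, not
#'   fitted; default 0.5, matching the `x0 = 0.5` starting value).
#' @return A data frame aligned with `seq`: columns `trial`, `cs`, `us`,
#'   `x` (associative strength), `eta_t` (associability), `alpha`, `beta`
#'   (Beta pseudo-counts), `prior_mean`, `v` (prior uncertainty) and `z`;
#'   columns not defined for a model are `NA`.
#' @examples
#' seq <- generate_design(design_config(), seed = 1)
#' tr <- model_trace(seq, "BC")
#' head(tr[, c("trial", "cs", "prior_mean", "v", "z")])
#' @export
model_trace <- function(seq, model_id, eta = NULL, k = NULL, eta0 = 0.5) {
  model_id <- match.arg(model_id, model_space())
  n <- nrow(seq)
  tr <- data.frame(trial = seq$trial, cs = seq$cs, us = seq$us,
                   x = NA_real_, eta_t = NA_real_, alpha = NA_real_,
                   beta = NA_real_, prior_mean = NA_real_, v = NA_real_,
                   z = NA_real_)
  if (model_id == "RW") {
    if (is.null(eta) || eta <= 0 || eta >= 1)
      stop("RW requires a learning rate `eta` in (0, 1)", call. = FALSE)
    tr$x <- per_cs_apply(seq, function(u) rw_values(u, eta))
    tr$z <- tr$x
  } else if (model_id %in% c("HM1", "HM2")) {
    if (is.null(k) || k <= 0 || k >= 1)
      stop("hybrid models require a scaling parameter `k` in (0, 1)",
           call. = FALSE)
    for (lev in levels(seq$cs)) {
      idx <- which(seq$cs == lev)
      if (!length(idx)) next
      hv <- hybrid_values(seq$us[idx], k, eta0)
      tr$x[idx] <- hv$x; tr$eta_t[idx] <- hv$eta
    }
    tr$z <- if (model_id == "HM1") tr$eta_t else tr$x
  } else if (model_id %in% c("BM", "BC")) {
    for (lev in levels(seq$cs)) {
      idx <- which(seq$cs == lev)
      if (!length(idx)) next
      bp <- beta_prior_values(seq$us[idx])
      tr$alpha[idx] <- bp$alpha; tr$beta[idx] <- bp$beta
      tr$prior_mean[idx] <- bp$prior_mean; tr$v[idx] <- bp$v
    }
    tr$z <- if (model_id == "BM") tr$prior_mean else tr$v + tr$prior_mean
  } else if (model_id == "UN") {
    # pooled observation count, blind to CS identity: before trial t the
    # observer has seen t - 1 outcomes on top of the Beta(1, 1) prior
    tr$v <- -log(seq_len(n) + 1)
    tr$z <- tr$v
  } else { # NL
    tr$z <- as.numeric(seq$cs == "CS+")
  }
  tr
}

#' Observation variable of a model
#'
#' Convenience dispatcher returning just the per-trial `z` series that a
#' model maps onto measured amplitudes (the designated trace column for
#' each model: `x` for RW/HM2, `eta_t` for HM1, `prior_mean` for BM,
#' `v + prior_mean` for BC, pooled `-ln(t+1)` for UN, the CS indicator for
#' NL).
#'
#' @inheritParams model_trace
#' @param params Optional list with elements `eta`, `k`, `eta0` (an
#'   alternative to passing them individually).
#' @return Numeric vector, one `z` per trial.
#' @export
observation_variable <- function(model_id, seq, params = list(),
                                 eta = params$eta, k = params$k,
                                 eta0 = params$eta0 %||% 0.5) {
  model_trace(seq, model_id, eta = eta, k = k, eta0 = eta0)$z
}
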