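#' Configuration of the synthetic amplitude generator
#'
#' Describes a ground-truth simulation standing in for a cohort of
#' participants whose single-trial anticipatory amplitudes arise from one
#' known learning model through the linear observation function
#' `y_t = beta1 * z_t + beta0 + e_t`, `e_t ~ N(0, sigma^2)`.
#'
#' Per participant, exactly the parameters the true model needs are drawn:
#' `eta` (RW) or `k` (HM1/HM2) uniform on `eta_range`/`k_range`, the slope
#' `beta1` log-normal (median `exp(beta1_meanlog)`), the intercept `beta0`
#' normal. Noise is calibrated per participant so that the true model's
#' population explained variance on the non-reinforced trials equals
#' `target_r2` (default 0.2, the magnitude observed for the winning models
#' on real skin-conductance data), unless an explicit `sigma` is given.
#'
#' @param true_model One of [model_space()].
#' @param n_participants Cohort size (default 20, one typical experiment).
#' @param design A [design_config()].
#' @param target_r2 Target population explained variance in (0, 1)
#'   (default 0.2); ignored when `sigma` is supplied.
#' @param sigma Optional fixed noise SD overriding the calibration.
#' @param eta_range,k_range Uniform supports for the learning parameters
#'   (default `c(0.05, 0.95)`).
#' @param beta1_meanlog,beta1_sdlog Log-normal slope parameters (default
#'   meanlog 0, sdlog 0.5: positive, median 1).
#' @param beta0_mean,beta0_sd Normal intercept parameters (default 1, 0.3).
#' @param eta0 Fixed hybrid initial associability (0.5).
#' @param seed Root seed; every random quantity in the dataset flows from
#'   it through per-participant child seeds.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(true_model, n_participants = 20L,
                             design = design_config(), target_r2 = 0.2,
                             sigma = NULL, eta_range = c(0.05, 0.95),
                             k_range = c(0.05, 0.95), beta1_meanlog = 0,
                             beta1_sdlog = 0.5, beta0_mean = 1,
                             beta0_sd = 0.3, eta0 = 0.5, seed = 1L) {
  true_model <- match.arg(true_model, model_space())
  if (is.null(sigma)) {
    if (!(target_r2 > 0 && target_r2 < 1))
      stop("target_r2 must lie in (0, 1)", call. = FALSE)
  } else if (sigma < 0) {
    stop("sigma must be non-negative", call. = FALSE)
  }
  structure(list(true_model = true_model,
                 n_participants = as.integer(n_participants),
                 design = design, target_r2 = target_r2, sigma = sigma,
                 eta_range = eta_range, k_range = k_range,
                 beta1_meanlog = beta1_meanlog, beta1_sdlog = beta1_sdlog,
                 beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 eta0 = eta0, seed = as.integer(seed)),
            class = "generator_config")
}

#' Calibrate observation noise to a target explained variance
#'
#' For the linear observation function, the population explained variance
#' on the analysed trials is `R = beta1^2 Var(z) / (beta1^2 Var(z) +
#' sigma^2)`; solving for the noise gives
#' `sigma^2 = beta1^2 * Var(z) * (1 - R) / R`.
#'
#' @param z Model variable on the non-reinforced trials.
#' @param beta1 Observation slope.
#' @param target_r2 Target explained variance in (0, 1).
#' @return Noise standard deviation `sigma`.
#' @export
calibrate_noise <- function(z, beta1, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  vz <- stats::var(z)
  if (!is.finite(vz) || vz <= 0)
    stop("`z` must vary on the analysed trials to calibrate noise",
         call. = FALSE)
  sqrt(beta1^2 * vz * (1 - target_r2) / target_r2)
}

#' Simulate one participant's amplitude series
#'
#' Applies the observation function to a model's trial-by-trial variable:
#' `y_t = beta1 * z_t + beta0 + e_t` with i.i.d. Gaussian noise, on every
#' trial (reinforced trials included; they are masked later at fit time).
#'
#' @param seq A `trial_sequence`.
#' @param model_id True model, one of [model_space()].
#' @param beta0,beta1 Observation parameters.
#' @param sigma Noise SD (>= 0).
#' @param eta,k,eta0 Learning parameters, as required by the model.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Numeric amplitude vector aligned with `seq`.
#' @export
simulate_participant <- function(seq, model_id, beta0, beta1, sigma,
                                 eta = NULL, k = NULL, eta0 = 0.5,
                                 seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  z <- observation_variable(model_id, seq, eta = eta, k = k, eta0 = eta0)
  noise <- if (is.null(seed)) stats::rnorm(length(z), 0, sigma)
           else with_seed(seed, stats::rnorm(length(z), 0, sigma))
  beta1 * z + beta0 + noise
}

#' Simulate a full ground-truth experiment
#'
#' Generates a cohort: per participant a fresh randomized trial sequence,
#' freshly drawn model and observation parameters, noise calibrated to the
#' configured explained variance, and the resulting amplitude series. The
#' root seed is split into per-participant child seeds, so the dataset is
#' bit-reproducible and any participant subset can be regenerated.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_dataset`: `data` (long data frame
#'   `participant`, `trial`, `cs`, `us`, `block`, `amplitude`), `truth`
#'   (per-participant ground-truth parameters incl. `sigma`), `sequences`
#'   (list of `trial_sequence`), and the `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  seeds <- derive_seeds(config$seed, n)
  rows <- vector("list", n)
  truth <- vector("list", n)
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%02d", i)
    res <- with_seed(seeds[i], {
      sq <- generate_design(config$design, seed = NULL, participant_id = pid)
      eta <- if (config$true_model == "RW")
        stats::runif(1, config$eta_range[1], config$eta_range[2]) else NA_real_
      k <- if (config$true_model %in% c("HM1", "HM2"))
        stats::runif(1, config$k_range[1], config$k_range[2]) else NA_real_
      beta1 <- stats::rlnorm(1, config$beta1_meanlog, config$beta1_sdlog)
      beta0 <- stats::rnorm(1, config$beta0_mean, config$beta0_sd)
      z <- observation_variable(config$true_model, sq,
                                eta = if (is.na(eta)) NULL else eta,
                                k = if (is.na(k)) NULL else k,
                                eta0 = config$eta0)
      sigma <- config$sigma %||%
        calibrate_noise(z[unreinforced_indices(sq)], beta1, config$target_r2)
      y <- beta1 * z + beta0 + stats::rnorm(length(z), 0, sigma)
      list(sq = sq, y = y, eta = eta, k = k, beta0 = beta0, beta1 = beta1,
           sigma = sigma)
    })
    seqs[[i]] <- res$sq
    rows[[i]] <- data.frame(participant = pid, trial = res$sq$trial,
                            cs = res$sq$cs, us = res$sq$us,
                            block = res$sq$block, amplitude = res$y)
    truth[[i]] <- data.frame(participant = pid, model = config$true_model,
                             eta = res$eta, k = res$k, beta0 = res$beta0,
                             beta1 = res$beta1, sigma = res$sigma,
                             target_r2 = if (is.null(config$sigma))
                               config$target_r2 else NA_real_)
  }
  structure(list(data = do.call(rbind, rows),
                 truth = do.call(rbind, truth),
                 sequences = stats::setNames(seqs, vapply(truth, function(t)
                   t$participant, character(1))),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: true model %s, %d participants x %d trials (seed %d)\n",
              x$config$true_model, x$config$n_participants,
              nrow(x$sequences[[1L]]), x$config$seed))
  if (is.null(x$config$sigma))
    cat(sprintf("  noise calibrated to R2 = %.2f on non-reinforced trials\n",
                x$config$target_r2))
  invisible(x)
}
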