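#' Control parameters for per-participant model fitting
#'
#' The learning parameter (`eta` for RW, `k` for the hybrid read-outs) is
#' searched on a dense grid over the open unit interval followed by bounded
#' local refinement from the best grid points; the observation parameters
#' `(beta0, beta1)` are profiled out in closed form by ordinary least
#' squares at every candidate, which attains the same minimum as a joint
#' search but is deterministic and seed-free.
#'
#' @param grid_size Number of grid points (default 101).
#' @param lower,upper Open-interval endpoints of the grid (0.005 / 0.995).
#' @param n_refine Number of best grid points seeding local refinement (3).
#' @param tol Parameter tolerance of the local refinement (`1e-7`).
#' @param eta0 Fixed initial associability of the hybrid model (0.5).
#' @param rss_floor_rel Relative floor for the residual sum of squares,
#'   `rss_floor_rel * TSS`, keeping the BIC finite on (near-)noiseless data.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(grid_size = 101L, lower = 0.005, upper = 0.995,
                        n_refine = 3L, tol = 1e-7, eta0 = 0.5,
                        rss_floor_rel = 1e-12) {
  stopifnot(grid_size >= 2L, lower > 0, upper < 1, lower < upper)
  structure(list(grid_size = as.integer(grid_size), lower = lower,
                 upper = upper, n_refine = as.integer(n_refine), tol = tol,
                 eta0 = eta0, rss_floor_rel = rss_floor_rel),
            class = "fit_control")
}

#' Residual sum of squares of the observation function
#'
#' Computes `sum((beta1 * z_t + beta0 - y_t)^2)` over the trials not paired
#' with a US. The model variable `z` must be computed over *all* trials
#' (reinforced trials drive learning), but reinforced trials are masked
#' from the objective to avoid contamination by the US-evoked response.
#'
#' @param y Per-trial amplitude estimates, aligned with `seq`.
#' @param seq A `trial_sequence`.
#' @param z Per-trial model variable, aligned with `seq`.
#' @param beta1,beta0 Observation-function slope and intercept.
#' @return Non-negative scalar.
#' @export
rss_objective <- function(y, seq, z, beta1, beta0) {
  if (length(y) != nrow(seq) || length(z) != nrow(seq))
    stop("`y` and `z` must have one value per trial of `seq`", call. = FALSE)
  idx <- unreinforced_indices(seq)
  sum((beta1 * z[idx] + beta0 - y[idx])^2)
}

# Closed-form OLS of y on a single regressor; returns slope/intercept/rss.
ols_profile <- function(z, y) {
  zm <- mean(z); ym <- mean(y)
  zc <- z - zm
  szz <- sum(zc^2)
  syy <- sum((y - ym)^2)
  if (szz < 1e-14 * max(1, zm^2) * length(z)) {
    return(list(beta1 = 0, beta0 = ym, rss = syy))
  }
  szy <- sum(zc * (y - ym))
  beta1 <- szy / szz
  rss <- max(syy - beta1 * szy, 0)
  list(beta1 = beta1, beta0 = ym - beta1 * zm, rss = rss)
}

# Column-wise profiled-OLS RSS for a T x G matrix of candidate z series.
ols_profile_grid <- function(Z, y) {
  Tn <- length(y)
  ym <- mean(y)
  yc <- y - ym
  syy <- sum(yc^2)
  zm <- colMeans(Z)
  Zc <- sweep(Z, 2L, zm, check.margin = FALSE)
  szz <- colSums(Zc^2)
  szy <- as.vector(crossprod(Zc, yc))
  beta1 <- ifelse(szz > 1e-14 * Tn, szy / szz, 0)
  pmax(syy - beta1 * szy, 0)
}

# Full-sequence z matrix over a parameter grid for RW / HM1 / HM2.
z_grid_matrix <- function(model_id, seq, grid, eta0) {
  n <- nrow(seq)
  Z <- matrix(0, n, length(grid))
  for (lev in levels(seq$cs)) {
    idx <- which(seq$cs == lev)
    if (!length(idx)) next
    u <- seq$us[idx]
    Z[idx, ] <- switch(model_id,
      RW  = rw_values_grid(u, grid),
      HM1 = hybrid_values_grid(u, grid, eta0)$eta,
      HM2 = hybrid_values_grid(u, grid, eta0)$x)
  }
  Z
}

#' Bayesian Information Criterion from a residual sum of squares
#'
#' `BIC = p * ln(T) + T * ln(RSS / T)`, the model-evidence approximation
#' for a Gaussian observation model with `p` free parameters fitted to `T`
#' observations. A non-positive RSS is clamped to `floor` with a warning so
#' the criterion stays finite.
#'
#' @param rss Residual sum of squares over the `T` analysed trials.
#' @param T Number of analysed (non-reinforced) trials.
#' @param p Total free-parameter count (at least 2: slope and intercept).
#' @param floor Positive clamp applied when `rss <= floor`.
#' @return Scalar BIC (lower = stronger evidence).
#' @examples
#' bic(rss = 30, T = 120, p = 2) # 2*log(120) + 120*log(0.25)
#' @export
bic <- function(rss, T, p, floor = .Machine$double.xmin) {
  stopifnot(T > 0, p >= 2)
  if (rss <= floor) {
    warning("RSS at or below floor; clamping for BIC", call. = FALSE)
    rss <- floor
  }
  p * log(T) + T * log(rss / T)
}

#' Fit one learning model to one participant
#'
#' Minimises the residual sum of squares of the linear observation function
#' over the non-reinforced trials. For RW/HM1/HM2 the learning parameter is
#' searched by a dense grid plus bounded local refinement (see
#' [fit_control()]); `(beta0, beta1)` are profiled out by OLS throughout.
#' Parameter-free models reduce to a single OLS solve. The procedure is
#' deterministic.
#'
#' @param y Per-trial amplitudes aligned with `seq` (reinforced trials
#'   present but excluded from the objective).
#' @param seq A `trial_sequence`.
#' @param model_id One of [model_space()].
#' @param control A [fit_control()].
#' @return An object of class `pav_fit`: list with `model`, `eta`, `k`
#'   (NA when not applicable), `beta0`, `beta1`, `rss`, `T`, `p`, `bic`,
#'   `r2`, `rss_clamped` and the participant id.
#' @export
fit_model <- function(y, seq, model_id, control = fit_control()) {
  model_id <- match.arg(model_id, model_space())
  if (length(y) != nrow(seq))
    stop("`y` must have one amplitude per trial of `seq`", call. = FALSE)
  if (any(!is.finite(y)))
    stop("amplitudes must be finite", call. = FALSE)
  idx <- unreinforced_indices(seq)
  Tn <- length(idx)
  if (Tn < 3L)
    stop("need at least 3 non-reinforced trials to fit", call. = FALSE)
  y_u <- y[idx]
  tss <- sum((y_u - mean(y_u))^2)

  par_val <- NA_real_
  if (n_learning_params(model_id) == 0L) {
    z <- observation_variable(model_id, seq, eta0 = control$eta0)
    sol <- ols_profile(z[idx], y_u)
  } else {
    # lightweight per-CS state for the inner objective (no trace frames)
    n <- nrow(seq)
    cs_idx <- lapply(levels(seq$cs), function(l) which(seq$cs == l))
    us_by <- lapply(cs_idx, function(i) seq$us[i])
    z_at <- function(par) {
      z <- numeric(n)
      for (j in seq_along(cs_idx)) {
        ij <- cs_idx[[j]]
        if (!length(ij)) next
        z[ij] <- switch(model_id,
          RW  = rw_values(us_by[[j]], par),
          HM1 = hybrid_values(us_by[[j]], par, control$eta0)$eta,
          HM2 = hybrid_values(us_by[[j]], par, control$eta0)$x)
      }
      z
    }
    obj <- function(par) ols_profile(z_at(par)[idx], y_u)$rss
    grid <- seq.int(control$lower, control$upper,
                    length.out = control$grid_size)
    Z <- z_grid_matrix(model_id, seq, grid, control$eta0)[idx, , drop = FALSE]
    rss_grid <- ols_profile_grid(Z, y_u)
    ord <- order(rss_grid)[seq_len(min(control$n_refine, length(grid)))]
    best_par <- grid[ord[1L]]
    best_rss <- rss_grid[ord[1L]]
    for (j in ord) {
      lo <- grid[max(j - 1L, 1L)]
      hi <- grid[min(j + 1L, length(grid))]
      opt <- stats::optimize(obj, interval = c(lo, hi), tol = control$tol)
      if (opt$objective < best_rss) {
        best_rss <- opt$objective
        best_par <- opt$minimum
      }
    }
    par_val <- best_par
    sol <- ols_profile(z_at(par_val)[idx], y_u)
  }

  floor <- control$rss_floor_rel * max(tss, .Machine$double.eps)
  clamped <- sol$rss <= floor
  rss_b <- max(sol$rss, floor)
  p <- 2L + n_learning_params(model_id)
  structure(list(model = model_id,
                 participant_id = attr(seq, "participant_id") %||% NA_character_,
                 eta = if (model_id == "RW") par_val else NA_real_,
                 k = if (model_id %in% c("HM1", "HM2")) par_val else NA_real_,
                 eta0 = control$eta0,
                 beta0 = sol$beta0, beta1 = sol$beta1,
                 rss = sol$rss, T = Tn, p = p,
                 bic = p * log(Tn) + Tn * log(rss_b / Tn),
                 r2 = if (tss > 0) 1 - sol$rss / tss else NA_real_,
                 rss_clamped = clamped),
            class = "pav_fit")
}

#' @export
print.pav_fit <- function(x, ...) {
  par_str <- if (!is.na(x$eta)) sprintf(", eta = %.3f", x$eta)
             else if (!is.na(x$k)) sprintf(", k = %.3f", x$k) else ""
  cat(sprintf("%s fit (%s): beta1 = %.3f, beta0 = %.3f%s | RSS = %.3f (T = %d), BIC = %.2f, R2 = %.3f\n",
              x$model, x$participant_id, x$beta1, x$beta0, par_str,
              x$rss, x$T, x$bic, x$r2))
  invisible(x)
}

#' Fit the whole model space to one participant
#'
#' @inheritParams fit_model
#' @param models Character vector of model ids (default: all seven).
#' @return A data frame with one row per model: `model`, `eta`, `k`,
#'   `beta0`, `beta1`, `rss`, `T`, `p`, `bic`, `r2`; the participant id in
#'   column `participant`. The full `pav_fit` objects are attached as
#'   attribute `"fits"`.
#' @export
fit_all_models <- function(y, seq, models = model_space(),
                           control = fit_control()) {
  fits <- lapply(models, function(m) fit_model(y, seq, m, control))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(participant = f$participant_id, model = f$model,
               eta = f$eta, k = f$k, beta0 = f$beta0, beta1 = f$beta1,
               rss = f$rss, T = f$T, p = f$p, bic = f$bic, r2 = f$r2)))
  attr(tab, "fits") <- fits
  tab
}

#' Explained variance of a fitted model
#'
#' `R^2 = 1 - RSS / TSS` computed over the non-reinforced trials, the same
#' subset the objective is minimised on. Quantifies fit quality
#' independently of model complexity; can be negative for models worse
#' than the intercept-only fit.
#'
#' @param y,seq As in [fit_model()].
#' @param fit A `pav_fit`.
#' @return Scalar `R^2`, or `NA` with a warning if the amplitudes have zero
#'   variance on the analysed trials.
#' @export
explained_variance <- function(y, seq, fit) {
  idx <- unreinforced_indices(seq)
  y_u <- y[idx]
  tss <- sum((y_u - mean(y_u))^2)
  if (tss <= 0) {
    warning("zero total sum of squares; explained variance undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - fit$rss / tss
}

#' Subtract a fitted habituation null from an amplitude series
#'
#' Removes the fitted predictions of the non-learning habituation model
#' (`UN`) from every trial's amplitude, yielding a residual series to which
#' learning models can be refitted. Used to ask whether a learning signal
#' remains once unspecific habituation is accounted for.
#'
#' @param y Per-trial amplitudes aligned with `seq`.
#' @param seq The participant's `trial_sequence`.
#' @param un_fit A `pav_fit` of model `UN` for the same participant.
#' @return Numeric residual series, one value per trial.
#' @export
residualize <- function(y, seq, un_fit) {
  stopifnot(inherits(un_fit, "pav_fit"))
  if (un_fit$model != "UN")
    stop("`un_fit` must be a fitted UN model", call. = FALSE)
  sid <- attr(seq, "participant_id")
  if (!is.null(sid) && !is.na(un_fit$participant_id) &&
      !identical(sid, un_fit$participant_id))
    stop("participant mismatch between `seq` and `un_fit`", call. = FALSE)
  z <- observation_variable("UN", seq)
  y - (un_fit$beta0 + un_fit$beta1 * z)
}

#' Fit the model space to a long-format dataset
#'
#' Convenience wrapper running [fit_all_models()] for every participant of
#' a tidy long table (`participant`, `trial`, `cs`, `us`, `amplitude`).
#'
#' @param data Long-format data frame; `cs` coded `"CS+"`/`"CS-"`, `us`
#'   0/1, `trial` 1-based within participant.
#' @inheritParams fit_all_models
#' @return Stacked fit table (one row per participant x model).
#' @export
fit_dataset <- function(data, models = model_space(),
                        control = fit_control()) {
  need <- c("participant", "trial", "cs", "us", "amplitude")
  if (!all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  parts <- unique(data$participant)
  do.call(rbind, lapply(parts, function(pid) {
    d <- data[data$participant == pid, , drop = FALSE]
    d <- d[order(d$trial), , drop = FALSE]
    seq <- as_trial_sequence(d, participant_id = as.character(pid))
    fit_all_models(d$amplitude, seq, models, control)
  }))
}

#' Coerce a per-participant data frame to a trial sequence
#'
#' @param df Data frame with columns `trial`, `cs`, `us` (and optionally
#'   `block`), ordered by trial.
#' @param participant_id Label to attach.
#' @return A `trial_sequence`.
#' @export
as_trial_sequence <- function(df, participant_id = "P1") {
  stopifnot(all(c("trial", "cs", "us") %in% names(df)))
  out <- data.frame(trial = as.integer(df$trial),
                    cs = factor(as.character(df$cs), levels = c("CS+", "CS-")),
                    us = as.integer(df$us),
                    block = if ("block" %in% names(df))
                      as.integer(df$block) else 1L)
  if (anyNA(out$cs)) stop("`cs` must be coded \"CS+\"/\"CS-\"", call. = FALSE)
  if (any(out$us == 1L & out$cs == "CS-"))
    stop("US on a CS- trial", call. = FALSE)
  structure(out, participant_id = participant_id,
            class = c("trial_sequence", "data.frame"))
}
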