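#' Build a log-evidence matrix from a fit table
#'
#' Approximates each participant x model log evidence from the BIC as
#' `log p(y|m) ~ -BIC/2` (the default convention; only differences across
#' models matter for group-level selection).
#'
#' @param fit_table Output of [fit_dataset()] (or stacked
#'   [fit_all_models()] tables).
#' @param evidence Function mapping a BIC value to a log evidence
#'   (default `-bic/2`).
#' @return Numeric matrix, participants in rows (named), models in columns
#'   (canonical [model_space()] order restricted to the fitted models).
#' @export
evidence_matrix <- function(fit_table, evidence = function(bic) -bic / 2) {
  models <- intersect(model_space(), unique(fit_table$model))
  parts <- unique(fit_table$participant)
  L <- matrix(NA_real_, length(parts), length(models),
              dimnames = list(parts, models))
  for (i in seq_len(nrow(fit_table)))
    L[as.character(fit_table$participant[i]), fit_table$model[i]] <-
      evidence(fit_table$bic[i])
  if (anyNA(L)) stop("fit table does not cover every participant x model",
                     call. = FALSE)
  L
}

# Variational free energy of the random-effects model (Dirichlet posterior
# `alpha`, responsibilities `g`) given log evidences L and prior alpha0.
rfx_free_energy <- function(L, g, alpha, alpha0) {
  elog <- digamma(alpha) - digamma(sum(alpha))
  gl <- g * log(g)
  gl[g == 0] <- 0
  sum(g * sweep(L, 2L, elog, `+`)) - sum(gl) +
    (lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
       sum((alpha0 - 1) * elog)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog))
}

# Exceedance probabilities of a Dirichlet(alpha) posterior: probability
# that each component's frequency exceeds all others. Closed Beta form for
# K = 2, Monte-Carlo otherwise (fixed seed; ties have measure zero).
dirichlet_xp <- function(alpha, nsamp = 1e6, seed = 20180831) {
  K <- length(alpha)
  if (K == 2L) {
    x1 <- 1 - stats::pbeta(0.5, alpha[1L], alpha[2L])
    return(c(x1, 1 - x1))
  }
  counts <- with_seed(seed, {
    n_left <- as.integer(nsamp)
    acc <- integer(K)
    # draw in blocks to bound memory
    while (n_left > 0L) {
      nb <- min(n_left, 250000L)
      G <- matrix(stats::rgamma(nb * K, shape = rep(alpha, each = nb)), nb, K)
      acc <- acc + tabulate(max.col(G, ties.method = "first"), K)
      n_left <- n_left - nb
    }
    acc
  })
  counts / sum(counts)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants: model
#' frequencies `r` get a Dirichlet prior (uniform, concentration 1 per
#' model) and each participant's model assignment a categorical draw from
#' `r`. The posterior is obtained by the standard variational scheme,
#' iterating participant-wise model responsibilities (softmax of log
#' evidence plus the digamma term of the current Dirichlet) against the
#' Dirichlet counts until convergence.
#'
#' Reported are the posterior concentrations, expected frequencies,
#' exceedance probabilities (probability that a model's frequency exceeds
#' all others), the Bayes omnibus risk `bor` (posterior probability that
#' all frequencies are equal, from the free-energy comparison of the
#' random-effects model against the equal-frequency null), and protected
#' exceedance probabilities `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param L Participants x models matrix of log evidences (e.g.
#'   [evidence_matrix()]; `-BIC/2` convention).
#' @param prior_alpha Per-model prior concentration (default 1).
#' @param tol Convergence tolerance on the concentrations (default 1e-8).
#' @param max_iter Iteration cap (default 1e4).
#' @param xp_samples Monte-Carlo draws for exceedance probabilities when
#'   there are more than two models (default 1e6).
#' @param xp_seed Fixed seed of the Monte-Carlo draw (reproducibility; the
#'   caller's RNG stream is untouched).
#' @return A list of class `bms_result`: `alpha`, `expected_freq`, `xp`,
#'   `bor`, `pxp` (all named by model), `g` (responsibilities),
#'   `free_energy`, `converged`, `n_iter`.
#' @references The variational random-effects scheme and the protected
#'   exceedance probability follow the standard group-study model-selection
#'   literature (Dirichlet-multinomial random effects with Bayes omnibus
#'   risk protection).
#' @export
rfx_bms <- function(L, prior_alpha = 1, tol = 1e-8, max_iter = 1e4,
                    xp_samples = 1e6, xp_seed = 20180831) {
  L <- as.matrix(L)
  if (ncol(L) < 2L) stop("need at least 2 models", call. = FALSE)
  if (nrow(L) < 2L) stop("need at least 2 participants", call. = FALSE)
  if (any(!is.finite(L))) stop("log evidences must be finite", call. = FALSE)
  K <- ncol(L)
  models <- colnames(L) %||% paste0("M", seq_len(K))
  alpha0 <- rep(prior_alpha, K)
  alpha <- alpha0
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lg <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(lg - apply(lg, 1L, max))
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
    if (it >= max_iter) break
  }
  if (!converged)
    warning("random-effects scheme did not converge in ", max_iter,
            " iterations", call. = FALSE)
  # recompute responsibilities at the final alpha
  lg <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
  g <- exp(lg - apply(lg, 1L, max))
  g <- g / rowSums(g)

  xp <- dirichlet_xp(alpha, nsamp = xp_samples, seed = xp_seed)
  f1 <- rfx_free_energy(L, g, alpha, alpha0)
  # null hypothesis: frequencies fixed and equal; exact marginal likelihood
  f0 <- sum(apply(L, 1L, logsumexp)) - nrow(L) * log(K)
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / K
  structure(list(models = models,
                 alpha = stats::setNames(alpha, models),
                 expected_freq = stats::setNames(alpha / sum(alpha), models),
                 xp = stats::setNames(xp, models),
                 bor = bor,
                 pxp = stats::setNames(pxp, models),
                 g = g, free_energy = c(rfx = f1, null = f0),
                 converged = converged, n_iter = it),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, digits = 3, ...) {
  cat("Random-effects Bayesian model selection (", nrow(x$g),
      " participants, ", length(x$models), " models)\n", sep = "")
  tab <- rbind(`E[freq]` = x$expected_freq, xp = x$xp, pxp = x$pxp)
  print(round(tab, digits))
  cat(sprintf("Bayes omnibus risk: %.3g | winner: %s\n", x$bor,
              winner(x)$label))
  invisible(x)
}

#' Family-level random-effects model selection
#'
#' Aggregates each participant's model evidences into family evidences with
#' an equal prior over the models inside a family (log-mean-exp of the
#' member log evidences), so that family size does not bias the comparison,
#' then runs [rfx_bms()] over the families with a uniform Dirichlet prior.
#' With singleton families this reduces exactly to model-level selection.
#'
#' @inheritParams rfx_bms
#' @param partition Named character vector mapping every model (column of
#'   `L`) to a family label; default [model_families()].
#' @return A `bms_result` over families, with the partition attached as
#'   attribute `"partition"`.
#' @export
family_bms <- function(L, partition = model_families(), ...) {
  L <- as.matrix(L)
  if (!all(colnames(L) %in% names(partition)))
    stop("`partition` must cover every model in `L`", call. = FALSE)
  fam <- partition[colnames(L)]
  fams <- unique(unname(fam))
  Lf <- sapply(fams, function(f) {
    cols <- which(fam == f)
    apply(L[, cols, drop = FALSE], 1L, logsumexp) - log(length(cols))
  })
  colnames(Lf) <- fams
  res <- rfx_bms(Lf, ...)
  attr(res, "partition") <- fam
  res
}

#' Winning model of a selection result
#'
#' @param result A `bms_result`.
#' @return List with `label` (argmax of the protected exceedance
#'   probabilities, first label in declared order on a tie at numerical
#'   tolerance), `pxp` (its value) and `tie` (flag).
#' @param tol Probabilities within `tol` of the maximum count as tied.
#' @export
winner <- function(result, tol = 1e-9) {
  stopifnot(inherits(result, "bms_result"))
  mx <- max(result$pxp)
  hits <- which(result$pxp >= mx - tol)
  list(label = result$models[hits[1L]], pxp = mx, tie = length(hits) > 1L)
}
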