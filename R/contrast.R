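#' Linear mixed-effects manipulation check (CS x Trial)
#'
#' Confirms discriminant learning in a dataset of single-trial amplitudes:
#' fits `amplitude ~ CS * Trial` with a random intercept per participant
#' (REML) on the non-reinforced trials and reports F tests for the CS main
#' effect (higher anticipatory responses to CS+ than CS-), the Trial main
#' effect (habituation across the session) and their interaction, with
#' Bonferroni correction across the datasets tested.
#'
#' @param data Long-format data frame with columns `participant`, `trial`,
#'   `cs` (`"CS+"`/`"CS-"`), `us` (0/1) and `amplitude`. Reinforced trials
#'   are dropped before fitting.
#' @param n_datasets Bonferroni correction factor (default 4: the number of
#'   amplitude readouts typically tested together).
#' @param trial_coding `"global"` (default): continuous trial index over
#'   the whole session, shared across CS; `"per_cs"`: continuous index of
#'   that CS's presentations.
#' @param label Optional dataset label carried into the result.
#' @return Data frame of class `contrast_result`, one row per effect
#'   (`CS`, `Trial`, `CS x Trial`): `F`, `df_num`, `df_den`, `p`,
#'   `p_corrected = min(1, p * n_datasets)`.
#' @export
cs_trial_contrast <- function(data, n_datasets = 4L,
                              trial_coding = c("global", "per_cs"),
                              label = NULL) {
  trial_coding <- match.arg(trial_coding)
  need <- c("participant", "trial", "cs", "us", "amplitude")
  if (!all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- data[data$us == 0, , drop = FALSE]
  d$cs <- factor(as.character(d$cs), levels = c("CS+", "CS-"))
  if (nlevels(droplevels(d$cs)) < 2L)
    stop("need both CS levels among non-reinforced trials", call. = FALSE)
  if (length(unique(d$participant)) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  if (trial_coding == "per_cs") {
    d <- d[order(d$participant, d$trial), , drop = FALSE]
    d$trial <- stats::ave(rep(1, nrow(d)),
                          interaction(d$participant, d$cs), FUN = cumsum)
  }
  d$trial <- as.numeric(d$trial)
  effects <- c("CS", "Trial", "CS x Trial")

  if (stats::var(d$amplitude) == 0) {
    # perfectly flat data: every effect's mean square is zero
    out <- data.frame(effect = effects, F = 0, df_num = 1,
                      df_den = nrow(d) - length(unique(d$participant)) - 3,
                      p = 1, p_corrected = 1)
  } else {
    fit <- nlme::lme(amplitude ~ cs * trial, random = ~ 1 | participant,
                     data = d, method = "REML")
    a <- stats::anova(fit)
    rows <- c("cs", "trial", "cs:trial")
    p_raw <- a[rows, "p-value"]
    out <- data.frame(effect = effects,
                      F = a[rows, "F-value"],
                      df_num = a[rows, "numDF"],
                      df_den = a[rows, "denDF"],
                      p = p_raw,
                      p_corrected = pmin(1, p_raw * n_datasets))
  }
  rownames(out) <- NULL
  if (!is.null(label)) out$dataset <- label
  class(out) <- c("contrast_result", "data.frame")
  out
}
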