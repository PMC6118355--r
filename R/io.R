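#' Read / write tidy trial and amplitude tables
#'
#' The package's on-disk interchange format is a tidy CSV with one row per
#' trial: `participant`, `trial` (1-based), `cs` (`"CS+"`/`"CS-"`), `us`
#' (0/1), optionally `block`, and — for amplitude data — `amplitude`.
#'
#' @param x For writing: a `trial_sequence`, a list of them, a long data
#'   frame, or a `synthetic_dataset`.
#' @param path File path.
#' @return `read_*` return a data frame; `write_*` return `path`
#'   invisibly.
#' @name pav_io
NULL

#' @rdname pav_io
#' @export
write_trial_data <- function(x, path) {
  if (inherits(x, "trial_sequence")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(s)
      data.frame(participant = attr(s, "participant_id") %||% "P1",
                 as.data.frame(s))))
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pav_io
#' @export
read_trial_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "cs", "us")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname pav_io
#' @export
write_amplitude_data <- function(x, path) {
  if (inherits(x, "synthetic_dataset")) x <- x$data
  need <- c("participant", "trial", "cs", "us", "amplitude")
  if (!all(need %in% names(x)))
    stop("amplitude table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pav_io
#' @export
read_amplitude_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "cs", "us", "amplitude")
  if (!all(need %in% names(df)))
    stop("amplitude CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$amplitude)))
    stop("amplitudes must be finite", call. = FALSE)
  df
}

#' Write a JSON report of a group-level model selection
#'
#' @param model_res `bms_result` over models.
#' @param family_res Optional `bms_result` over families.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(model_res, family_res = NULL, path) {
  as_report <- function(r) list(
    models = r$models, alpha = unname(r$alpha),
    expected_freq = unname(r$expected_freq), xp = unname(r$xp),
    bor = r$bor, pxp = unname(r$pxp), winner = winner(r)$label)
  rep <- list(model_level = as_report(model_res))
  if (!is.null(family_res)) rep$family_level <- as_report(family_res)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a model-recovery report (confusion CSVs + JSON summary)
#'
#' @param rec A `recovery_result`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_recovery_report <- function(rec, dir) {
  stopifnot(inherits(rec, "recovery_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(rec$cm_model, file.path(dir, "confusion_model.csv"))
  utils::write.csv(rec$cm_family, file.path(dir, "confusion_family.csv"))
  s <- recovery_summary(rec)
  jsonlite::write_json(
    list(family_diag_mean = s$family_diag_mean,
         model_diag_mean = s$model_diag_mean,
         model_diag = as.list(s$model_diag),
         family_diag = as.list(s$family_diag),
         n_experiments = rec$config$n_experiments,
         n_participants = rec$config$n_participants,
         criterion = rec$config$criterion, seed = rec$config$seed),
    file.path(dir, "recovery_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
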