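#' Configuration of a discriminant conditioning design
#'
#' Describes the trial structure of a discriminant threat-conditioning
#' session: two conditioned stimuli (CS+ and CS-), partial reinforcement of
#' the CS+ with an aversive unconditioned stimulus (US), and a block
#' structure in which the first trial of each block is a reinforced CS+.
#' The default corresponds to the standard session used across delay and
#' trace variants of the paradigm: 80 CS+ and 80 CS- trials in two blocks
#' with 50% CS+ reinforcement, so that 40 CS+ trials are reinforced and the
#' analysis set of non-reinforced trials contains 40 CS+ and 80 CS- trials.
#'
#' Blocks are balanced: each block holds `n_per_cs / n_blocks` trials of
#' each CS and `n_per_cs * reinforcement_rate / n_blocks` reinforced CS+
#' trials. Stimulus timing (delay vs trace, CS modality, intertrial
#' intervals) does not enter trial-level modelling and is carried only as a
#' free-form `variant` tag.
#'
#' @param n_per_cs Number of trials per CS (default 80).
#' @param reinforcement_rate Fraction of CS+ trials followed by the US
#'   (default 0.5). `n_per_cs * reinforcement_rate` must be an integer and
#'   divisible by `n_blocks`.
#' @param n_blocks Number of blocks (default 2); must divide `n_per_cs`.
#' @param first_trial_reinforced_csplus If `TRUE` (default) the first trial
#'   of every block is a reinforced CS+ and only the remaining trials are
#'   permuted.
#' @param variant Optional label for the design variant (e.g. `"delay"`,
#'   `"trace"`); metadata only.
#' @return An object of class `design_config` (a list of the above fields).
#' @examples
#' cfg <- design_config()
#' seq <- generate_design(cfg, seed = 1)
#' table(seq$cs, seq$us)
#' @export
design_config <- function(n_per_cs = 80L, reinforcement_rate = 0.5,
                          n_blocks = 2L, first_trial_reinforced_csplus = TRUE,
                          variant = "delay") {
  n_per_cs <- as.integer(n_per_cs)
  n_blocks <- as.integer(n_blocks)
  if (n_per_cs < 1L || n_blocks < 1L)
    stop("n_per_cs and n_blocks must be positive integers", call. = FALSE)
  n_reinf <- n_per_cs * reinforcement_rate
  if (abs(n_reinf - round(n_reinf)) > 1e-9)
    stop("n_per_cs * reinforcement_rate must be an integer", call. = FALSE)
  if (n_per_cs %% n_blocks != 0L)
    stop("n_blocks must divide n_per_cs", call. = FALSE)
  n_reinf <- as.integer(round(n_reinf))
  if (n_reinf %% n_blocks != 0L)
    stop("reinforced CS+ trials cannot be split evenly across blocks",
         call. = FALSE)
  if (first_trial_reinforced_csplus && n_reinf < n_blocks)
    stop("need at least one reinforced CS+ per block for the first-trial rule",
         call. = FALSE)
  structure(list(n_per_cs = n_per_cs,
                 reinforcement_rate = reinforcement_rate,
                 n_reinforced = n_reinf,
                 n_blocks = n_blocks,
                 first_trial_reinforced_csplus =
                   isTRUE(first_trial_reinforced_csplus),
                 variant = variant),
            class = "design_config")
}

#' Generate a randomized trial sequence
#'
#' Builds one participant's trial sequence from a [design_config()]: within
#' each block the configured numbers of reinforced CS+, non-reinforced CS+
#' and CS- trials are placed in uniformly random order, except that (by
#' default) the first trial of each block is a reinforced CS+.
#'
#' @param config A [design_config()].
#' @param seed Integer seed making the permutation reproducible.
#' @param participant_id Label stored with the sequence.
#' @return A `trial_sequence`: a data frame with columns `trial` (1-based,
#'   contiguous), `cs` (factor, `"CS+"`/`"CS-"`), `us` (integer 0/1; 1 only
#'   on CS+ trials) and `block`, plus attributes `participant_id` and
#'   `config`.
#' @seealso [unreinforced_indices()]
#' @export
generate_design <- function(config = design_config(), seed = NULL,
                            participant_id = "P1") {
  stopifnot(inherits(config, "design_config"))
  per_block_cs <- config$n_per_cs %/% config$n_blocks
  per_block_reinf <- config$n_reinforced %/% config$n_blocks
  build <- function() {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      cs <- c(rep("CS+", per_block_cs), rep("CS-", per_block_cs))
      us <- c(rep(1L, per_block_reinf),
              rep(0L, per_block_cs - per_block_reinf),
              rep(0L, per_block_cs))
      if (config$first_trial_reinforced_csplus) {
        ord <- c(1L, 1L + sample.int(length(cs) - 1L))
      } else {
        ord <- sample.int(length(cs))
      }
      data.frame(cs = cs[ord], us = us[ord], block = b)
    })
    do.call(rbind, blocks)
  }
  df <- if (is.null(seed)) build() else with_seed(seed, build())
  df <- data.frame(trial = seq_len(nrow(df)), df)
  df$cs <- factor(df$cs, levels = c("CS+", "CS-"))
  structure(df, participant_id = participant_id, config = config,
            class = c("trial_sequence", "data.frame"))
}

#' Indices of trials without reinforcement
#'
#' Trials on which the US was delivered evoke a response to the US itself;
#' model fitting therefore uses only trials without a US (all CS- trials
#' and the non-reinforced CS+ trials). This returns their 1-based positions
#' in presentation order.
#'
#' @param seq A `trial_sequence` (or any data frame with a 0/1 `us` column).
#' @return Integer vector of trial indices with `us == 0`, in order.
#' @export
unreinforced_indices <- function(seq) {
  if (is.null(seq$us)) stop("`seq` must have a `us` column", call. = FALSE)
  which(seq$us == 0L)
}

#' @export
print.trial_sequence <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Trial sequence '%s': %d trials (%d CS+, %d CS-), %d reinforced\n",
              attr(x, "participant_id"), nrow(x), sum(x$cs == "CS+"),
              sum(x$cs == "CS-"), sum(x$us)))
  if (!is.null(cfg))
    cat(sprintf("  design: %d blocks, %.0f%% CS+ reinforcement (%s)\n",
                cfg$n_blocks, 100 * cfg$reinforcement_rate, cfg$variant))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}
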