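#' Configuration of a simulated saccadic-choice masking experiment
#'
#' Captures the design constants of the emulated experiment: four
#' equiprobable conditions interleaved within blocks, staircase accuracy
#' targets of 0.82 for the high-visibility reference and 0.60 for the
#' three low-visibility conditions, blocks of 96 trials.
#'
#' @param n_observers Number of simulated observers.
#' @param n_blocks Blocks per observer.
#' @param trials_per_block Trials per block; must be divisible by four so
#'   conditions can be exactly balanced within a block.
#' @param target_accuracy Named vector mapping each condition to its
#'   staircase target proportion correct, all in (0.5, 1).
#' @param seed Root integer seed; per-observer random streams are derived
#'   from it deterministically.
#' @param srt_fast_cutoff_ms Anticipation cutoff used downstream (ms).
#' @param bin_width_ms SRT histogram bin width used downstream (ms).
#' @param quest Named list of staircase settings passed to
#'   [quest_init()]: `prior_mean`, `prior_sd`, `slope`, `lapse`,
#'   `grid_n`, `grid_span`, `min_contrast`.
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' cfg <- experiment_config(n_observers = 1, n_blocks = 2, seed = 7)
experiment_config <- function(n_observers = 4, n_blocks = 40,
                              trials_per_block = 96,
                              target_accuracy = c(common_offset = 0.82,
                                                  osm = 0.60,
                                                  backward = 0.60,
                                                  low_contrast = 0.60),
                              seed = 1,
                              srt_fast_cutoff_ms = 70,
                              bin_width_ms = 10,
                              quest = list()) {
  stopifnot(n_observers >= 1, n_blocks >= 1, trials_per_block >= 4)
  if (trials_per_block %% 4L != 0L) {
    stop("trials_per_block must be divisible by 4 for exact condition ",
         "balancing within blocks")
  }
  conds <- saccmask_conditions()
  if (!all(conds %in% names(target_accuracy))) {
    stop("target_accuracy must name all four conditions")
  }
  if (any(target_accuracy <= 0.5) || any(target_accuracy >= 1)) {
    stop("staircase accuracy targets must lie in (0.5, 1)")
  }
  quest_defaults <- list(prior_mean = log10(0.2), prior_sd = 0.5,
                         slope = 3.5, lapse = 0.01, grid_n = 200,
                         grid_span = 4, min_contrast = 1e-4)
  quest <- utils::modifyList(quest_defaults, quest)
  structure(list(n_observers = as.integer(n_observers),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 conditions = conds,
                 target_accuracy = target_accuracy[conds],
                 seed = as.integer(seed),
                 srt_fast_cutoff_ms = srt_fast_cutoff_ms,
                 bin_width_ms = bin_width_ms,
                 quest = quest),
            class = "experiment_config")
}

#' Simulate a full staircase-controlled saccadic-choice experiment
#'
#' Runs each simulated observer through `n_blocks` blocks of
#' `trials_per_block` trials. Within every block the four conditions are
#' exactly balanced (`trials_per_block/4` each) and randomly ordered. One
#' QUEST staircase per observer and condition recommends the contrast of
#' every trial and is updated with its outcome, holding accuracy at the
#' configured targets. Ground-truth generative columns (prefixed `sim_`)
#' are emitted alongside the observables for parameter-recovery tests.
#'
#' Each observer consumes an independent random stream derived
#' deterministically from `config$seed`, so single-observer
#' sub-simulations are reproducible in isolation.
#'
#' @param config An [experiment_config()] object.
#' @param observers A list of [sim_observer()] objects of length
#'   `config$n_observers` (a single object is recycled).
#' @return An object of class `sim_experiment`: a list with
#'   \describe{
#'     \item{trials}{data frame with columns `observer`, `condition`,
#'       `block`, `trial`, `contrast`, `srt_ms`, `correct`, `sim_p`,
#'       `sim_mask_onset_ms`.}
#'     \item{staircases}{nested list `staircases[[observer]][[condition]]`
#'       of final `quest_state` objects (with full histories).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' ex <- simulate_experiment(experiment_config(n_observers = 1, n_blocks = 2,
#'                                             seed = 42))
#' nrow(ex$trials)  # 2 * 96
simulate_experiment <- function(config = experiment_config(),
                                observers = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(observers)) observers <- list(sim_observer())
  if (inherits(observers, "sim_observer")) observers <- list(observers)
  if (length(observers) == 1L) {
    observers <- rep(observers, config$n_observers)
  }
  stopifnot(length(observers) == config$n_observers)
  conds <- config$conditions
  per_block <- config$trials_per_block %/% 4L
  n_per_obs <- config$n_blocks * config$trials_per_block
  out <- vector("list", config$n_observers)
  staircases <- vector("list", config$n_observers)
  names(staircases) <- paste0("obs", seq_len(config$n_observers))
  for (o in seq_len(config$n_observers)) {
    obs <- observers[[o]]
    # deterministic per-observer stream; offsets stay far below 2^31
    set.seed(config$seed + 10007L * o)
    qs <- lapply(conds, function(cond) {
      do.call(quest_init, c(list(target_p = config$target_accuracy[[cond]],
                                 guess = obs$guess), config$quest))
    })
    names(qs) <- conds
    condition <- character(n_per_obs)
    block <- integer(n_per_obs)
    trial <- integer(n_per_obs)
    contrast <- numeric(n_per_obs)
    srt_ms <- numeric(n_per_obs)
    correct <- logical(n_per_obs)
    sim_p <- numeric(n_per_obs)
    i <- 0L
    for (b in seq_len(config$n_blocks)) {
      block_conds <- sample(rep(conds, each = per_block))
      for (t in seq_len(config$trials_per_block)) {
        i <- i + 1L
        cond <- block_conds[t]
        q <- qs[[cond]]
        cntr <- quest_recommend(q)
        srt <- sample_srt(1L, obs)
        p <- generative_p_correct(cond, cntr, srt, obs)
        corr <- stats::runif(1L) < p
        qs[[cond]] <- quest_update(q, cntr, corr)
        condition[i] <- cond
        block[i] <- b
        trial[i] <- t
        contrast[i] <- cntr
        srt_ms[i] <- srt
        correct[i] <- corr
        sim_p[i] <- p
      }
    }
    out[[o]] <- data.frame(observer = paste0("obs", o),
                           condition = condition, block = block,
                           trial = trial, contrast = contrast,
                           srt_ms = srt_ms, correct = correct,
                           sim_p = sim_p,
                           sim_mask_onset_ms = obs$mask_onset_ms)
    staircases[[o]] <- qs
  }
  structure(list(trials = do.call(rbind, out), staircases = staircases,
                 config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "Simulated experiment: %d observers x %d blocks x %d trials = %d trials\n",
    x$config$n_observers, x$config$n_blocks, x$config$trials_per_block,
    nrow(x$trials)))
  acc <- tapply(x$trials$correct, x$trials$condition, mean)
  cat("Overall accuracy by condition:\n")
  print(round(acc, 3))
  invisible(x)
}
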