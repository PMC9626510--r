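#' Build a randomized oddball flash schedule
#'
#' Constructs the timed stimulus schedule of a speller session: `runs` runs,
#' each holding `blocks_per_run` blocks of `trials_per_block` trials; within a
#' trial every one of the `n_stimuli` stimuli flashes exactly once in random
#' order at a fixed stimulus-onset asynchrony (SOA). Each trial is preceded by
#' a preparation interval and a target-lock cue, and followed by `post_ms` so
#' that a full analysis epoch fits after the last flash.
#'
#' The attended (target) stimulus of a block is deterministic: block `b` of any
#' run cues stimulus `((b - 1) %% n_stimuli) + 1`, i.e. blocks sweep the
#' stimuli in fixed order, one target per block.
#'
#' @param runs,blocks_per_run,trials_per_block,n_stimuli Positive counts.
#' @param soa_ms Stimulus-onset asynchrony in ms; must be >= `flash_ms`.
#' @param flash_ms Flash (stimulus on) duration in ms.
#' @param prep_ms,lock_ms Preparation and target-lock intervals preceding the
#'   flash sequence of each trial, in ms.
#' @param post_ms Quiet tail after the last flash of a trial, in ms. Defaults
#'   to 600 so the standard epoch window always fits.
#' @param seed Integer seed; identical seeds yield identical schedules.
#'
#' @return An object of class `stim_schedule`: a list with `events` (a
#'   data.frame with columns `run`, `block`, `trial`, `stimulus`, `onset_ms`,
#'   sorted by onset; indices are 1-based), `target_of_block` (integer vector,
#'   target stimulus of each block position within a run), the timing
#'   parameters, and the protocol counts.
#' @examples
#' sch <- make_schedule(runs = 1, blocks_per_run = 9, trials_per_block = 5)
#' nrow(sch$events)  # 9 blocks x 5 trials x 9 flashes = 405
#' @export
make_schedule <- function(runs = 10L, blocks_per_run = 9L, trials_per_block = 5L,
                          n_stimuli = 9L, soa_ms = 175, flash_ms = 100,
                          prep_ms = 2000, lock_ms = 1500, post_ms = 600,
                          seed = 1L) {
  counts <- c(runs = runs, blocks_per_run = blocks_per_run,
              trials_per_block = trials_per_block, n_stimuli = n_stimuli)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop("all counts (runs, blocks_per_run, trials_per_block, n_stimuli) must be positive integers")
  if (soa_ms < flash_ms) stop("soa_ms must be >= flash_ms")
  if (prep_ms < 0 || lock_ms < 0 || post_ms < 0)
    stop("prep_ms, lock_ms and post_ms must be non-negative")

  runs <- as.integer(runs); blocks_per_run <- as.integer(blocks_per_run)
  trials_per_block <- as.integer(trials_per_block); n_stimuli <- as.integer(n_stimuli)

  n_trials <- runs * blocks_per_run * trials_per_block
  trial_span <- prep_ms + lock_ms + (n_stimuli - 1) * soa_ms + post_ms

  order_mat <- local_seed(seed, {
    matrix(unlist(lapply(seq_len(n_trials), function(i) sample.int(n_stimuli))),
           nrow = n_stimuli)
  })

  idx <- expand.grid(trial = seq_len(trials_per_block),
                     block = seq_len(blocks_per_run),
                     run = seq_len(runs))
  trial_start <- (seq_len(n_trials) - 1) * trial_span
  first_onset <- trial_start + prep_ms + lock_ms

  events <- data.frame(
    run = rep(idx$run, each = n_stimuli),
    block = rep(idx$block, each = n_stimuli),
    trial = rep(idx$trial, each = n_stimuli),
    stimulus = as.vector(order_mat),
    onset_ms = rep(first_onset, each = n_stimuli) +
      rep(seq_len(n_stimuli) - 1, times = n_trials) * soa_ms
  )

  structure(list(
    events = events,
    target_of_block = ((seq_len(blocks_per_run) - 1L) %% n_stimuli) + 1L,
    n_stimuli = n_stimuli, soa_ms = soa_ms, flash_ms = flash_ms,
    prep_ms = prep_ms, lock_ms = lock_ms, post_ms = post_ms,
    runs = runs, blocks_per_run = blocks_per_run,
    trials_per_block = trials_per_block, seed = as.integer(seed)
  ), class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %d run(s) x %d block(s) x %d trial(s) x %d stimuli = %d flashes\n",
    x$runs, x$blocks_per_run, x$trials_per_block, x$n_stimuli, nrow(x$events)))
  cat(sprintf("  SOA %g ms (flash %g ms), prep %g ms, lock %g ms, post %g ms\n",
              x$soa_ms, x$flash_ms, x$prep_ms, x$lock_ms, x$post_ms))
  invisible(x)
}

#' Target stimulus of each event
#'
#' @param schedule A `stim_schedule`.
#' @return Integer vector, one entry per event: the cued target of the block
#'   the event belongs to.
#' @keywords internal
schedule_targets <- function(schedule) {
  schedule$target_of_block[schedule$events$block]
}

#' Export a schedule's event table as CSV
#'
#' @param schedule A `stim_schedule`.
#' @param path Output file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stim_schedule"))
  ev <- schedule$events
  ev$is_target <- as.integer(ev$stimulus == schedule_targets(schedule))
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministically derive a sub-seed from a master seed for a named stage.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
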