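#' Task schedule specification
#'
#' Defaults reproduce the study design this package targets: a 2-min baseline,
#' then 4 blocks of 30 trials separated by 30-s breaks. Each 17-s trial is
#' 5 s rest, 2 s (imagined) tapping, 8 s rest and 2 s feedback. In session 1
#' each block is split into two sub-blocks of 13 imagined ("covert") trials
#' followed by 2 executed ("overt") trials, giving 104 covert + 16 overt
#' trials; sessions 2-3 are fully covert (120 trials).
#'
#' @param n_blocks,trials_per_block block structure.
#' @param rest_pre,task,rest_post,feedback trial phase durations (s).
#' @param baseline,break_between_blocks durations (s).
#' @param session1_covert_per_subblock,session1_overt_per_subblock session-1
#'   sub-block composition (two sub-blocks per block).
#' @return a validated list.
#' @export
scheduleSpec <- function(n_blocks = 4, trials_per_block = 30,
                         rest_pre = 5, task = 2, rest_post = 8, feedback = 2,
                         baseline = 120, break_between_blocks = 30,
                         session1_covert_per_subblock = 13,
                         session1_overt_per_subblock = 2) {
  spec <- list(
    n_blocks = n_blocks, trials_per_block = trials_per_block,
    rest_pre = rest_pre, task = task, rest_post = rest_post,
    feedback = feedback, baseline = baseline,
    break_between_blocks = break_between_blocks,
    session1_covert_per_subblock = session1_covert_per_subblock,
    session1_overt_per_subblock = session1_overt_per_subblock
  )
  spec$trial_duration <- rest_pre + task + rest_post + feedback
  if (trials_per_block %% 2 != 0) {
    stop("trials_per_block must be even for balanced left/right labels")
  }
  spec
}

#' Generate a session marker schedule
#'
#' Produces the marker table of one session: baseline span, block spans, and
#' one marker per trial placed at the tapping onset (i.e. `rest_pre` seconds
#' into the trial), labeled left/right (covert) or overt_left/overt_right
#' (executed, session 1 only). Left/right counts are equal within every block
#' (and within the covert/overt subsets separately), with order
#' pseudo-randomized by `seed`.
#'
#' @param spec a [scheduleSpec()].
#' @param session_number 1..3; session 1 interleaves overt sub-blocks.
#' @param seed integer seed; schedules are deterministic given the seed.
#' @return data.frame with columns time (s), label, block (NA outside
#'   blocks), trial (NA for non-trial markers).
#' @export
generateSchedule <- function(spec = scheduleSpec(), session_number = 1, seed = 1) {
  withSeed(subSeed(seed, "schedule", session_number), {
    rows <- list(
      data.frame(time = 0, label = "baseline_start", block = NA, trial = NA),
      data.frame(time = spec$baseline, label = "baseline_end", block = NA, trial = NA)
    )
    t <- spec$baseline
    trialNo <- 0L
    for (b in seq_len(spec$n_blocks)) {
      if (b > 1) t <- t + spec$break_between_blocks
      rows[[length(rows) + 1]] <- data.frame(
        time = t, label = "block_start", block = b, trial = NA)
      labs <- blockLabels(spec, session_number)
      for (i in seq_along(labs)) {
        trialNo <- trialNo + 1L
        onset <- t + (i - 1) * spec$trial_duration + spec$rest_pre
        rows[[length(rows) + 1]] <- data.frame(
          time = onset, label = labs[i], block = b, trial = trialNo)
      }
      t <- t + length(labs) * spec$trial_duration
      rows[[length(rows) + 1]] <- data.frame(
        time = t, label = "block_end", block = b, trial = NA)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Balanced, pseudo-randomized trial labels of one block.
blockLabels <- function(spec, session_number) {
  balanced <- function(n, labels) {
    if (n == 0) return(character(0))
    stopIfNot(n %% 2 == 0, "sub-block trial count must be even")
    sample(rep(labels, each = n / 2))
  }
  if (session_number == 1) {
    nc <- spec$session1_covert_per_subblock
    no <- spec$session1_overt_per_subblock
    stopIfNot(2 * (nc + no) == spec$trials_per_block,
              "session-1 sub-blocks do not sum to trials_per_block")
    # left/right balance holds across the two sub-blocks of the block
    cov <- balanced(2 * nc, c("left", "right"))
    ove <- balanced(2 * no, c("overt_left", "overt_right"))
    c(cov[seq_len(nc)], ove[seq_len(no)],
      cov[nc + seq_len(nc)], ove[no + seq_len(no)])
  } else {
    balanced(spec$trials_per_block, c("left", "right"))
  }
}

#' Total session duration implied by a schedule spec (s)
#' @param spec a [scheduleSpec()].
#' @export
scheduleDuration <- function(spec = scheduleSpec()) {
  spec$baseline + spec$n_blocks * spec$trials_per_block * spec$trial_duration +
    (spec$n_blocks - 1) * spec$break_between_blocks
}
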