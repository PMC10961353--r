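# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

fullMontage <- function() cached("full", buildDefaultMontage())
midMontage <- function() {
  cached("mid", buildDefaultMontage(defaultGeometryConfig(tilesPerHemisphere = 4)))
}
decodeMontage <- function() cached("decode", reducedMontage())

# One-row factor tables for a mild-hair (MVQ-profile) and severe-hair
# (PQ-profile) subject.
mvqFactors <- function(id = "s1") {
  data.frame(subject_id = id, age = 25, sex = "female", ethnicity = "white",
             hair_length = "short", hair_color = "blond", hair_density = "low",
             hair_length_ord = 1L, hair_color_ord = 1L, hair_density_ord = 0L,
             alertness = 7L)
}
pqFactors <- function(id = "s2") {
  data.frame(subject_id = id, age = 25, sex = "male", ethnicity = "black",
             hair_length = "long", hair_color = "black", hair_density = "high",
             hair_length_ord = 3L, hair_color_ord = 5L, hair_density_ord = 2L,
             alertness = 5L)
}

shortSchedule <- function(n_blocks = 1, trials_per_block = 10) {
  # reduced schedules keep session 1 fully covert (no overt sub-blocks)
  scheduleSpec(n_blocks = n_blocks, trials_per_block = trials_per_block,
               session1_covert_per_subblock = trials_per_block / 2,
               session1_overt_per_subblock = 0)
}

# A small low-noise session on the 8-tile montage with a planted response
# (physiological oscillations retained so TDDR has a healthy noise floor).
lowNoiseSpec <- function() {
  noiseSpec(drift_sd = 0, white_od_sd = 3e-4, additive_sd = 0,
            spike_rate = 0, shift_rate = 0)
}

midSession <- function(seed = 1, n_blocks = 2, trials_per_block = 10,
                       hemo = hemodynamicSpec(superficial_amp = 0),
                       noise = lowNoiseSpec(), coupling = 1,
                       session_number = 2) {
  sched <- generateSchedule(shortSchedule(n_blocks, trials_per_block),
                            session_number, seed)
  simulateSession(midMontage(), sched, hemo, noise, coupling, seed = seed)
}

# Mild-hair demographics used for MVQ-style cohorts.
mvqDemographics <- function() {
  d <- demographicsConfig()
  d$hair_length <- c(1, 1, 0, 0)
  d$hair_color <- c(1, 1, 1, 1, 0, 0)
  d$hair_density <- c(1, 1, 0)
  d
}

# Severe-hair demographics: everybody lands in the PQ coupling-floor regime.
pqDemographics <- function() {
  d <- demographicsConfig()
  d$hair_length <- c(0, 0, 0, 1)
  d$hair_color <- c(0, 0, 0, 0, 0, 1)
  d$hair_density <- c(0, 0, 1)
  d
}
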