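# Synthetic cohort generator.
#
# Emulates the statistical structure a sensor-to-severity analysis assumes:
# repeated examinations per patient, imbalanced ordinal symptom labels,
# 50 Hz 30 s tri-axial recordings in which each symptom leaves a
# characteristic, severity-monotone signature (4-6 Hz tremor oscillation,
# slowed pronation-supination under bradykinesia, irregular 1-3 Hz motion
# under dyskinesia, multiplicatively reduced motion variance under
# stiffness), and a -4..+4 treatment-response state derived from the four
# symptom scores.

# probability of an examination label deviating from the patient's latent
# trait severity by -1 / 0 / +1 (before clipping to 0..4)
EXAM_JITTER_P <- c(0.15, 0.70, 0.15)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the cohort the pipeline is calibrated against: around
#' three examinations per patient, ages near 62 +/- 11 years, 10.5 +/- 6
#' years since diagnosis, a 4-6 Hz tremor band, and per-symptom class
#' weights that are imbalanced towards low severities with severity-4
#' dyskinesia nearly absent.
#'
#' @param n_patients number of patients.
#' @param exam_lambda Poisson rate for the number of examinations per
#'   patient beyond the first (count is `1 + rpois(exam_lambda)`).
#' @param severity_weights named list of length-5 nonnegative weight vectors
#'   (classes 0..4, each summing to 1) for tremor, bradykinesia, stiffness
#'   and dyskinesia latent trait severities.
#' @param tremor_band two-element Hz interval the per-recording tremor
#'   frequency is drawn from.
#' @param noise_sd standard deviation of additive measurement noise
#'   (channel units).
#' @param missing_block_probability probability that any one
#'   device/sensor/hand/exercise recording block is absent from an
#'   examination.
#' @param blocks data frame with columns device, sensor, hand, exercise
#'   listing the recording blocks collected per examination; defaults to
#'   the full 2 devices x 2 sensors x 2 hands x 3 exercises grid.
#' @param trs_noise_sd observer noise on the treatment-response state.
#' @param groups vocabulary of patient group labels.
#' @param seed integer seed; fully determines the generated cohort.
#' @return a `pd_synth_config` list.
#' @export
synthetic_config <- function(n_patients = 50,
                             exam_lambda = 2.07,
                             severity_weights = default_severity_weights(),
                             tremor_band = c(4, 6),
                             noise_sd = 0.05,
                             missing_block_probability = 0,
                             blocks = default_blocks(),
                             trs_noise_sd = 0.5,
                             groups = c("oral-medication", "dbs", "infusion"),
                             seed = 1L) {
  stopifnot(length(tremor_band) == 2, tremor_band[1] < tremor_band[2],
            n_patients >= 0, missing_block_probability >= 0,
            missing_block_probability <= 1)
  if (!all(SYMPTOMS %in% names(severity_weights)))
    stop("severity_weights must name all of: ", paste(SYMPTOMS, collapse = ", "))
  for (s in SYMPTOMS) {
    w <- severity_weights[[s]]
    if (length(w) != 5 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop("severity weights for ", s,
           " must be 5 nonnegative values summing to 1")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    exam_lambda = exam_lambda,
    severity_weights = severity_weights,
    tremor_band = tremor_band,
    noise_sd = noise_sd,
    missing_block_probability = missing_block_probability,
    blocks = blocks,
    trs_noise_sd = trs_noise_sd,
    groups = groups,
    seed = as.integer(seed)
  ), class = "pd_synth_config")
}

#' @rdname synthetic_config
#' @export
default_severity_weights <- function() {
  list(
    tremor       = c(0.28, 0.30, 0.22, 0.13, 0.07),
    bradykinesia = c(0.18, 0.34, 0.26, 0.16, 0.06),
    stiffness    = c(0.15, 0.36, 0.27, 0.16, 0.06),
    dyskinesia   = c(0.55, 0.25, 0.12, 0.06, 0.02)
  )
}

#' @rdname synthetic_config
#' @export
default_blocks <- function() {
  expand.grid(device = c("phone", "myo"),
              sensor = c("accelerometer", "gyroscope"),
              hand = c("left", "right"),
              exercise = 1:3,
              stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

# deterministic sub-stream seed derivation; keeps values within 32-bit range
sub_seed <- function(seed, a, b = 0) {
  as.integer((as.numeric(seed) * 48271 + a * 69621 + b * 16807) %% 2147483563)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate one synthetic patient profile
#'
#' Deterministic given `(config$seed, index)`: metadata categories are drawn
#' from fixed vocabularies and latent trait severities from the configured
#' per-symptom class weights.
#'
#' @param config a [synthetic_config()].
#' @param index patient index in `1..n_patients`.
#' @return list with patient_id, affected_side, handedness, group,
#'   age_at_baseline, years_since_diagnosis and trait severities.
#' @export
generate_patient <- function(config, index) {
  stopifnot(inherits(config, "pd_synth_config"), index >= 1,
            index <= config$n_patients)
  set.seed(sub_seed(config$seed, 1, index))
  traits <- vapply(SYMPTOMS, function(s)
    sample(0:4, 1, prob = config$severity_weights[[s]]), numeric(1))
  age <- clip(rnorm(1, 62.0, 11.1), 35, 90)
  ysd <- clip(rnorm(1, 10.5, 6.1), 0.5, age - 25)
  list(
    patient_id = sprintf("P%04d", index),
    affected_side = sample(c("left", "right", "both"), 1,
                           prob = c(0.40, 0.45, 0.15)),
    handedness = sample(c("left", "right"), 1, prob = c(0.12, 0.88)),
    group = sample(config$groups, 1),
    age_at_baseline = age,
    years_since_diagnosis = ysd,
    trait_severities = traits
  )
}

# Rodrigues rotation matrix about a random axis, angle <= max_deg
random_small_rotation <- function(max_deg = 15) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_unit3 <- function() { u <- rnorm(3); u / sqrt(sum(u^2)) }

# smooth irregular process band-limited to 1-3 Hz, unit variance
irregular_process <- function(n, fs) {
  bf <- signal::butter(2, c(1, 3) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, rnorm(n + 200))[101:(n + 100)]
  s <- sd(z)
  if (s == 0) rep(0, n) else z / s
}

#' Simulate one 30 s tri-axial exercise recording
#'
#' Builds a 1500-sample signal as baseline noise plus a gravity DC offset
#' (accelerometer only) and additive severity-encoded components: a tremor
#' sinusoid at a frequency drawn from the configured tremor band with
#' amplitude monotone in the tremor label (strongest at rest, attenuated in
#' the postural task, amplitude-modulated during pronation-supination); a
#' voluntary pronation-supination oscillation (exercise 3) whose rate and
#' amplitude decrease with the bradykinesia label; an irregular smooth 1-3 Hz
#' process scaled by the dyskinesia label; and a multiplicative shrinkage of
#' all motion components as the stiffness label grows. Device axes receive a
#' small random rotation (<= 15 degrees) per recording, emulating variable
#' sensor orientation.
#'
#' @param profile patient profile (used for identity only).
#' @param labels list/row with tremor, bradykinesia, stiffness, dyskinesia
#'   in 0..4.
#' @param device "phone" or "myo".
#' @param sensor "accelerometer" or "gyroscope".
#' @param hand "left" or "right".
#' @param exercise 1 (rest), 2 (postural) or 3 (pronation-supination).
#' @param seed integer seed for this recording.
#' @param config a [synthetic_config()] (tremor band, noise level).
#' @return list with device, sensor, hand, exercise, sampling_rate and
#'   channels x, y, z (length 1500).
#' @export
simulate_exercise_signal <- function(profile, labels, device, sensor, hand,
                                     exercise, seed,
                                     config = synthetic_config()) {
  stopifnot(device %in% c("phone", "myo"),
            sensor %in% c("accelerometer", "gyroscope"),
            hand %in% c("left", "right"), exercise %in% 1:3)
  lab <- lapply(labels[SYMPTOMS], as.numeric)
  if (any(unlist(lab) < 0 | unlist(lab) > 4)) stop("labels must lie in [0, 4]")
  fs <- 50; n <- 30 * fs
  t <- seq_len(n) / fs
  set.seed(as.integer(seed))

  f_tremor <- runif(1, config$tremor_band[1], config$tremor_band[2])
  ph <- runif(3, 0, 2 * pi)
  u_tr <- random_unit3(); u_vol <- random_unit3(); u_dysk <- random_unit3()
  rot <- random_small_rotation(15)
  # per-recording physiological variability (mean-one lognormal), drawn
  # unconditionally so a fixed seed compares labels on identical draws:
  # no severity is a deterministic function of any single signal property
  jit_tr <- exp(rnorm(1, -0.031, 0.25))   # tremor amplitude
  jit_fv <- exp(rnorm(1, -0.0032, 0.08))  # voluntary movement rate
  jit_av <- exp(rnorm(1, -0.011, 0.15))   # voluntary movement amplitude

  # exercise-dependent tremor expression: rest > postural > kinetic
  ex_gain <- c(1.0, 0.7, 0.5)[exercise]
  a_tr <- 0.18 * lab$tremor^1.3 * ex_gain * jit_tr
  tremor <- a_tr * sin(2 * pi * f_tremor * t + ph[1])

  vol <- rep(0, n); sway <- rep(0, n)
  if (exercise == 3) {
    f_vol <- 2.0 * (1 - 0.18 * lab$bradykinesia) * jit_fv
    a_vol <- 1.6 * (1 - 0.15 * lab$bradykinesia) * jit_av
    vol <- a_vol * sin(2 * pi * f_vol * t + ph[2])
    # kinetic tremor rides on the voluntary movement
    tremor <- tremor * (1 + 0.3 * sin(2 * pi * f_vol * t + ph[2]))
  } else if (exercise == 2) {
    sway <- 0.25 * sin(2 * pi * 0.8 * t + ph[3])
  }

  # Dyskinesia expression fluctuates with the medication cycle, so its
  # per-recording amplitude carries mean-one lognormal variability on top
  # of the label-monotone base amplitude; this makes it the least
  # cleanly-encoded symptom, as involuntary overflow movements are in
  # practice.
  dysk <- if (lab$dyskinesia > 0)
    0.20 * lab$dyskinesia * exp(rnorm(1, -0.18, 0.6)) *
      irregular_process(n, fs) else rep(0, n)

  kappa <- 1 - 0.16 * lab$stiffness # variance shrinkage with rigidity
  gain <- (if (device == "phone") 1.0 else 0.85) *
          (if (sensor == "accelerometer") 1.0 else 0.7)

  xyz <- kappa * gain *
    (outer(tremor, u_tr) + outer(vol + sway, u_vol) + outer(dysk, u_dysk))
  if (sensor == "accelerometer")
    xyz <- sweep(xyz, 2, c(0, 0, 9.81), "+")
  xyz <- xyz %*% t(rot)
  if (config$noise_sd > 0)
    xyz <- xyz + matrix(rnorm(3 * n, 0, config$noise_sd), n, 3)

  list(device = device, sensor = sensor, hand = hand,
       exercise = as.integer(exercise), sampling_rate = fs,
       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

round_half <- function(x) round(x * 2) / 2

#' Derive clinician and patient treatment-response state labels
#'
#' The latent state is the dyskinesia score minus the equal-weight mean of
#' the three parkinsonian symptom scores, so -4 marks severe parkinsonian
#' symptoms, +4 severe dyskinesia and 0 the optimal state. Clinician and
#' patient values share the latent state but carry independent observer
#' noise; both are clipped to [-4, 4] and reported on a 0.5 grid.
#'
#' @param labels list/row with tremor, bradykinesia, stiffness, dyskinesia.
#' @param noise_sd observer noise standard deviation.
#' @param seed integer seed.
#' @return named numeric vector `c(clinician =, patient =)`.
#' @export
derive_trs_label <- function(labels, noise_sd = 0.5, seed = 1L) {
  latent <- as.numeric(labels$dyskinesia) -
    mean(c(labels$tremor, labels$bradykinesia, labels$stiffness))
  set.seed(as.integer(seed))
  eps <- if (noise_sd > 0) rnorm(2, 0, noise_sd) else c(0, 0)
  out <- clip(round_half(latent + eps), -4, 4)
  c(clinician = out[1], patient = out[2])
}

draw_exam_labels <- function(traits) {
  jit <- sample(c(-1, 0, 1), length(SYMPTOMS), replace = TRUE,
                prob = EXAM_JITTER_P)
  clip(traits + jit, 0, 4)
}

#' Generate a full labeled synthetic cohort
#'
#' Per patient, a random number of examinations (1 plus a Poisson count);
#' per examination, integer symptom labels jittered around the patient's
#' latent traits, derived treatment-response states, and one recording per
#' configured block, each independently dropped with
#' `missing_block_probability`. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a `pd_cohort` list with elements `patients` (data frame),
#'   `examinations` (data frame with labels), `recordings` (list keyed by
#'   exam id of named recording blocks) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "pd_synth_config"))
  patients <- list(); exams <- list(); recordings <- list()
  for (i in seq_len(config$n_patients)) {
    prof <- generate_patient(config, i)
    set.seed(sub_seed(config$seed, 5, i))
    n_exams <- 1 + rpois(1, config$exam_lambda)
    exam_offsets <- sort(runif(n_exams, 0, 2))
    patients[[i]] <- data.frame(
      patient_id = prof$patient_id, affected_side = prof$affected_side,
      handedness = prof$handedness, group = prof$group,
      age_at_baseline = prof$age_at_baseline,
      years_since_diagnosis = prof$years_since_diagnosis,
      t(prof$trait_severities))
    for (e in seq_len(n_exams)) {
      key <- i * 1000 + e
      set.seed(sub_seed(config$seed, 2, key))
      lab <- draw_exam_labels(prof$trait_severities)
      lab <- setNames(as.list(lab), SYMPTOMS)
      trs <- derive_trs_label(lab, config$trs_noise_sd,
                              sub_seed(config$seed, 3, key))
      exam_id <- sprintf("%s_E%02d", prof$patient_id, e)
      exams[[length(exams) + 1]] <- data.frame(
        exam_id = exam_id, patient_id = prof$patient_id,
        exam_offset_years = exam_offsets[e],
        age_at_exam = prof$age_at_baseline + exam_offsets[e],
        years_since_diagnosis_at_exam =
          prof$years_since_diagnosis + exam_offsets[e],
        tremor = lab$tremor, bradykinesia = lab$bradykinesia,
        stiffness = lab$stiffness, dyskinesia = lab$dyskinesia,
        trs_clinician = trs[["clinician"]], trs_patient = trs[["patient"]])
      blocks <- list()
      for (b in seq_len(nrow(config$blocks))) {
        bs <- sub_seed(config$seed, 7, key * 100 + b)
        set.seed(bs)
        if (runif(1) < config$missing_block_probability) next
        row <- config$blocks[b, ]
        rec <- simulate_exercise_signal(prof, lab, row$device, row$sensor,
                                        row$hand, row$exercise,
                                        seed = bs + 1, config = config)
        blocks[[block_key(row$device, row$sensor, row$hand, row$exercise)]] <- rec
      }
      recordings[[exam_id]] <- blocks
    }
  }
  structure(list(
    patients = do.call(rbind, patients),
    examinations = if (length(exams)) do.call(rbind, exams) else
      data.frame(),
    recordings = recordings,
    config = config
  ), class = "pd_cohort")
}

block_key <- function(device, sensor, hand, exercise) {
  sprintf("%s_%s_%s_%d",
          device,
          ifelse(sensor == "accelerometer", "acc", "gyro"),
          hand, as.integer(exercise))
}

#' Serialize / load a cohort as plain-text files
#'
#' Layout: one CSV per recording (`t,x,y,z`) under
#' `dir/<patient>/<exam>/<device>_<sensor>_<hand>_<exercise>.csv`, a JSON
#' manifest with patients, examinations and labels, and the configuration
#' as YAML.
#'
#' @param cohort a `pd_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  cfg$blocks <- as.list(cfg$blocks)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(patients = cohort$patients, examinations = cohort$examinations),
    file.path(dir, "manifest.json"), dataframe = "rows", digits = NA)
  for (exam_id in names(cohort$recordings)) {
    pid <- cohort$examinations$patient_id[
      cohort$examinations$exam_id == exam_id]
    ed <- file.path(dir, pid, exam_id)
    dir.create(ed, recursive = TRUE, showWarnings = FALSE)
    for (bk in names(cohort$recordings[[exam_id]])) {
      rec <- cohort$recordings[[exam_id]][[bk]]
      df <- data.frame(t = seq_along(rec$x) / rec$sampling_rate,
                       x = rec$x, y = rec$y, z = rec$z)
      write.csv(df, file.path(ed, paste0(bk, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$blocks <- as.data.frame(cfg$blocks, stringsAsFactors = FALSE)
  class(cfg) <- "pd_synth_config"
  recordings <- list()
  for (k in seq_len(nrow(man$examinations))) {
    exam_id <- man$examinations$exam_id[k]
    pid <- man$examinations$patient_id[k]
    ed <- file.path(dir, pid, exam_id)
    blocks <- list()
    for (f in list.files(ed, pattern = "\\.csv$")) {
      df <- read.csv(file.path(ed, f))
      parts <- strsplit(sub("\\.csv$", "", f), "_")[[1]]
      blocks[[sub("\\.csv$", "", f)]] <- list(
        device = parts[1],
        sensor = ifelse(parts[2] == "acc", "accelerometer", "gyroscope"),
        hand = parts[3], exercise = as.integer(parts[4]),
        sampling_rate = 50, x = df$x, y = df$y, z = df$z)
    }
    recordings[[exam_id]] <- blocks
  }
  structure(list(patients = man$patients, examinations = man$examinations,
                 recordings = recordings, config = cfg),
            class = "pd_cohort")
}
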