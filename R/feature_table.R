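# Metadata features and assembly of the examinations x features table.

#' Metadata features for one examination
#'
#' One-hot indicators over fixed vocabularies for affected side, handedness
#' and patient group, plus age and years since diagnosis at examination
#' time. Unknown categories yield an all-zero block.
#'
#' @param patient one-row data frame / list with `affected_side`,
#'   `handedness`, `group`.
#' @param exam one-row data frame / list with `age_at_exam` and
#'   `years_since_diagnosis_at_exam`.
#' @param groups group vocabulary.
#' @return named numeric vector.
#' @export
metadata_features <- function(patient, exam,
                              groups = c("oral-medication", "dbs", "infusion")) {
  onehot <- function(value, vocab, field) {
    setNames(as.numeric(vocab == value),
             paste0("meta/", field, "=", vocab))
  }
  c(onehot(patient$affected_side, c("left", "right", "both"), "affected_side"),
    onehot(patient$handedness, c("left", "right"), "handedness"),
    onehot(patient$group, groups, "group"),
    "meta/years_since_diagnosis" = as.numeric(exam$years_since_diagnosis_at_exam),
    "meta/age" = as.numeric(exam$age_at_exam))
}

#' Assemble the examinations x features table
#'
#' Computes the full sensor feature bank for every requested recording
#' block of every examination, prefixed
#' `"<Device>-<Sensor>-#<exercise>/<hand>/"`, and appends metadata
#' features. Examinations missing any requested block are excluded
#' (complete-case policy) and reported in `$excluded`. Features are left
#' unnormalized here; z-scoring is fold-aware and happens inside
#' [cross_validate()].
#'
#' @param cohort a `pd_cohort`.
#' @param blocks data frame of device/sensor/hand/exercise rows to use;
#'   defaults to the cohort's configured blocks.
#' @param time_entropy passed to [extract_recording_features()].
#' @param verbose print progress every 50 examinations.
#' @return a `pd_feature_table` list with `features` (numeric matrix),
#'   `labels` (data frame with symptom and state targets), `patient_id`,
#'   `feature_info` (per-column provenance) and `excluded`.
#' @export
assemble_feature_table <- function(cohort, blocks = NULL,
                                   time_entropy = "all", verbose = FALSE) {
  stopifnot(inherits(cohort, "pd_cohort"))
  if (is.null(blocks)) blocks <- cohort$config$blocks
  exams <- cohort$examinations
  keys <- vapply(seq_len(nrow(blocks)), function(b)
    block_key(blocks$device[b], blocks$sensor[b], blocks$hand[b],
              blocks$exercise[b]), character(1))
  prefixes <- vapply(seq_len(nrow(blocks)), function(b)
    paste0(block_label(blocks$device[b], blocks$sensor[b],
                       blocks$exercise[b]), "/",
           capitalize1(blocks$hand[b]), "/"), character(1))

  rows <- list(); kept <- character(0); excluded <- character(0)
  for (k in seq_len(nrow(exams))) {
    exam_id <- exams$exam_id[k]
    recs <- cohort$recordings[[exam_id]]
    if (!all(keys %in% names(recs))) {
      excluded <- c(excluded, exam_id)
      next
    }
    v <- numeric(0)
    for (b in seq_along(keys)) {
      fv <- extract_recording_features(recs[[keys[b]]],
                                       time_entropy = time_entropy)
      names(fv) <- paste0(prefixes[b], names(fv))
      v <- c(v, fv)
    }
    pat <- cohort$patients[cohort$patients$patient_id == exams$patient_id[k], ]
    v <- c(v, metadata_features(pat, exams[k, ],
                                groups = cohort$config$groups))
    rows[[length(rows) + 1]] <- v
    kept <- c(kept, exam_id)
    if (verbose && length(rows) %% 50 == 0)
      message("  features for ", length(rows), " examinations")
  }
  if (length(rows) == 0) stop("no examination has all requested blocks")
  features <- do.call(rbind, rows)
  rownames(features) <- kept
  sel <- match(kept, exams$exam_id)
  info <- parse_feature_names(colnames(features))
  structure(list(
    features = features,
    labels = exams[sel, c("exam_id", "patient_id", SYMPTOMS, TRS_TARGETS)],
    patient_id = exams$patient_id[sel],
    feature_info = info,
    excluded = excluded
  ), class = "pd_feature_table")
}

capitalize1 <- function(s) paste0(toupper(substr(s, 1, 1)), substring(s, 2))

# Recover provenance (device, sensor, exercise, hand, kind) from the
# "Phone-ACC-#1/Left/Z/..." naming convention; metadata columns get
# kind = "meta".
parse_feature_names <- function(nms) {
  info <- data.frame(name = nms, device = NA_character_,
                     sensor = NA_character_, exercise = NA_integer_,
                     hand = NA_character_, kind = "sensor",
                     stringsAsFactors = FALSE)
  meta <- startsWith(nms, "meta/")
  info$kind[meta] <- "meta"
  parts <- strsplit(nms[!meta], "/", fixed = TRUE)
  blk <- vapply(parts, `[`, character(1), 1)
  m <- regmatches(blk, regexec("^(Phone|MYO)-(ACC|GYRO)-#([123])$", blk))
  info$device[!meta] <- ifelse(vapply(m, `[`, character(1), 2) == "Phone",
                               "phone", "myo")
  info$sensor[!meta] <- ifelse(vapply(m, `[`, character(1), 3) == "ACC",
                               "accelerometer", "gyroscope")
  info$exercise[!meta] <- as.integer(vapply(m, `[`, character(1), 4))
  info$hand[!meta] <- tolower(vapply(parts, `[`, character(1), 2))
  info
}

#' Write a feature table as CSV with a JSON provenance sidecar
#'
#' @param ft a `pd_feature_table`.
#' @param path CSV path; the sidecar is written next to it with suffix
#'   `.info.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(exam_id = rownames(ft$features), ft$features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_info = ft$feature_info, labels = ft$labels,
         excluded = ft$excluded),
    sub("\\.csv$", ".info.json", path), dataframe = "rows", digits = NA)
  invisible(path)
}

# Fold-aware z-scoring helpers: fit on training rows only. Constant
# columns get scale 1 so test rows stay finite.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}
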