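#' Map a stertor grade to a BOAS grade
#'
#' Under the respiratory functional grading scheme the stertor grade maps
#' one-to-one onto the overall BOAS grade on the same 0-3 scale (moderate
#' stertor implies moderate BOAS), so the mapping is the identity.
#'
#' @param g Integer grade(s) in 0..3.
#' @return The same grade(s).
#' @export
map_stertor_to_boas <- function(g) {
  if (any(!g %in% 0:3)) stop("grade must be in 0..3")
  g
}

#' Combine per-recording predictions into an encounter prediction
#'
#' An encounter typically has pre- and post-exercise recordings. The
#' encounter severity is the mean (default) or maximum of the recordings'
#' continuous severity scores; the hard grade is decoded from the
#' per-position mean of the output vectors (mean mode) or taken from the
#' max-severity recording (max mode). Averaging continuous outputs (rather
#' than decoded integer grades) keeps the encounter score continuous for
#' ROC analysis; mean combination regularises against single spurious
#' recordings.
#'
#' @param preds List of `recording_prediction` objects (>= 1), as returned
#'   by [forward()].
#' @param method `"mean"` (default) or `"max"`.
#' @param threshold Decoding threshold for the hard grade.
#' @param average_decoded If `TRUE`, the hard grade in mean mode is instead
#'   the rounded mean of decoded grades (default `FALSE`).
#' @return List with `severity`, `grade`, `boas_grade`, `method`,
#'   `n_recordings`.
#' @export
combine_encounter <- function(preds, method = c("mean", "max"),
                              threshold = 0.5, average_decoded = FALSE) {
  method <- match.arg(method)
  if (length(preds) == 0L) stop("no recording predictions to combine")
  sev <- vapply(preds, `[[`, numeric(1), "severity")
  outs <- do.call(rbind, lapply(preds, `[[`, "outputs"))
  if (method == "mean") {
    severity <- mean(sev)
    grade <- if (average_decoded) {
      as.integer(round(mean(vapply(preds, `[[`, numeric(1), "decoded_grade"))))
    } else {
      decode_outputs(colMeans(outs), threshold)
    }
  } else {
    i <- which.max(sev)
    severity <- sev[i]
    grade <- preds[[i]]$decoded_grade
  }
  list(severity = severity, grade = grade,
       boas_grade = map_stertor_to_boas(grade),
       method = method, n_recordings = length(preds))
}

#' Binarise a grade or a continuous severity
#'
#' Grades 0/1 (none/mild) are "negative", grades 2/3 (moderate/severe) are
#' "positive" — the clinically significant boundary at which intervention
#' is considered. A continuous severity is binarised against a threshold
#' `t` (`severity >= t` is positive); sweeping `t` traces the ROC curve.
#'
#' @param x Integer grade(s) in 0..3 (`rule = "grade"`) or numeric
#'   severities in `[0, 3]` (`rule = "severity"`).
#' @param rule `"grade"` or `"severity"`.
#' @param threshold Severity cut-point for `rule = "severity"`.
#' @return Factor with levels `negative`, `positive`.
#' @export
binarise <- function(x, rule = c("grade", "severity"), threshold = 1.5) {
  rule <- match.arg(rule)
  pos <- if (rule == "grade") {
    if (any(!x %in% 0:3)) stop("grade must be in 0..3")
    x >= 2
  } else {
    x >= threshold
  }
  factor(ifelse(pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Per-encounter prediction table
#'
#' Groups a per-recording prediction data frame by encounter and applies
#' [combine_encounter()] to each group.
#'
#' @param pred_df Data frame with columns `encounter_id`, `outputs` columns
#'   `o0`..`o3`, and optionally `post_op`, `boas_grade` (truth).
#' @param method,threshold Passed to [combine_encounter()].
#' @return Data frame with one row per encounter: `encounter_id`,
#'   `severity`, `grade`, `binary_call`, plus carried-through metadata.
#' @export
aggregate_encounters <- function(pred_df, method = "mean", threshold = 0.5) {
  stopifnot(all(c("encounter_id", "o0", "o1", "o2", "o3") %in% names(pred_df)))
  ids <- unique(pred_df$encounter_id)
  rows <- lapply(ids, function(eid) {
    sub <- pred_df[pred_df$encounter_id == eid, , drop = FALSE]
    preds <- lapply(seq_len(nrow(sub)), function(i) {
      o <- as.numeric(sub[i, c("o0", "o1", "o2", "o3")])
      structure(list(outputs = o,
                     decoded_grade = decode_outputs(o, threshold),
                     severity = severity_score(o),
                     attention_weights = NULL),
                class = "recording_prediction")
    })
    comb <- combine_encounter(preds, method = method, threshold = threshold)
    out <- data.frame(encounter_id = eid, severity = comb$severity,
                      grade = comb$grade,
                      binary_call = as.character(binarise(comb$grade)))
    for (col in intersect(c("dog_id", "post_op", "boas_grade"), names(sub))) {
      out[[col]] <- sub[[col]][1L]
    }
    out
  })
  do.call(rbind, rows)
}
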