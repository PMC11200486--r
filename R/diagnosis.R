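# Rule-based ocular myasthenia gravis (OMG) screening.
#
# An eye that cannot fully adduct/abduct leaves residual exposed sclera
# on the gaze side; the decision rule thresholds the gaze-side scleral
# proportion at 3% of the eye area.  Clock grade and eyelid distance
# are reported as supporting evidence but do not enter the decision.

#' Per-eye OMG decision from an indicator set
#'
#' Strictly-greater threshold rule on the gaze-side scleral proportion:
#' a proportion above `threshold` (default 0.03) indicates impaired eye
#' movement and is called OMG; at or below the threshold the eye is
#' called normal (equality is resolved conservatively to normal).
#'
#' @param ind an `"indicator_set"` from [compute_indicators()].
#' @param eye `"left"` or `"right"`.
#' @param threshold decision threshold in (0, 1); default 0.03.
#' @return object of class `"eye_diagnosis"`: list with `eye`,
#'   `indicators`, `decision` (`"normal"` or `"OMG"`) and `threshold`.
#' @export
diagnose_eye <- function(ind, eye = c("left", "right"), threshold = 0.03) {
  eye <- match.arg(eye)
  if (!inherits(ind, "indicator_set"))
    stop("`ind` must be an indicator_set from compute_indicators()")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  structure(list(eye = eye, indicators = ind,
                 decision = if (ind$sclera_proportion > threshold) "OMG" else "normal",
                 threshold = threshold),
            class = "eye_diagnosis")
}

#' Combined two-eye subject report
#'
#' Combines the per-eye decisions by OR: the subject is called OMG when
#' at least one eye is OMG.  A missing eye flags single-eye mode and the
#' overall call comes from the present eye.
#'
#' @param left,right `"eye_diagnosis"` objects (either may be `NULL`).
#' @return object of class `"subject_report"`: list with `left`,
#'   `right`, `overall`, `single_eye` flag and a `narrative` character
#'   vector.
#' @export
diagnose_subject <- function(left = NULL, right = NULL) {
  eyes <- Filter(Negate(is.null), list(left = left, right = right))
  if (length(eyes) == 0L) stop("at least one eye diagnosis is required")
  for (e in eyes)
    if (!inherits(e, "eye_diagnosis")) stop("eyes must be eye_diagnosis objects")
  overall <- if (any(vapply(eyes, function(e) e$decision == "OMG", logical(1))))
    "OMG" else "normal"
  narrative <- c(
    vapply(eyes, function(e) {
      i <- e$indicators
      sprintf(paste0("%s eye: gaze-side scleral proportion %.4f (threshold %.2f)",
                     " -> %s; clock point %s (grade %d); eyelid distance %d px"),
              e$eye, i$sclera_proportion, e$threshold, e$decision,
              i$clock_point, i$clock_grade, i$eyelid_distance_px)
    }, character(1)),
    if (length(eyes) == 1L) "single-eye mode: only one eye supplied",
    sprintf("overall: %s", overall))
  structure(list(left = left, right = right, overall = overall,
                 single_eye = length(eyes) == 1L,
                 narrative = unname(narrative)),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat("OMG screening report\n")
  cat(paste0("  ", x$narrative, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a subject report to JSON
#'
#' @param report a `"subject_report"`.
#' @return single JSON string (deterministic for identical inputs).
#' @export
report_json <- function(report) {
  if (!inherits(report, "subject_report")) stop("`report` must be a subject_report")
  eye_rec <- function(e) if (is.null(e)) NULL else list(
    eye = e$eye, decision = e$decision, threshold = e$threshold,
    indicators = unclass(e$indicators))
  jsonlite::toJSON(list(left = eye_rec(report$left), right = eye_rec(report$right),
                        overall = report$overall, single_eye = report$single_eye,
                        narrative = report$narrative),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' End-to-end screening pipeline on two mask images
#'
#' Runs [compute_indicators()] on each eye's mask, applies the per-eye
#' threshold rule, and combines into a subject report.  Deterministic:
#' identical inputs give byte-identical reports.
#'
#' @param left_mask,right_mask integer five-class label matrices (or
#'   paths to palette PNGs).
#' @param gaze gaze direction of the capture: `"left"`, `"right"` or
#'   `"front"`.
#' @param threshold per-eye decision threshold (default 0.03).
#' @return a `"subject_report"`.
#' @export
full_pipeline <- function(left_mask, right_mask, gaze = "front",
                          threshold = 0.03) {
  load1 <- function(x) if (is.character(x)) read_mask_png(x) else x
  li <- compute_indicators(load1(left_mask), gaze = gaze)
  ri <- compute_indicators(load1(right_mask), gaze = gaze)
  diagnose_subject(diagnose_eye(li, "left", threshold),
                   diagnose_eye(ri, "right", threshold))
}
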