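#' Accuracy of a single measurement against a reference value
#'
#' Agreement between one measured value (MV) and the reference value (RV),
#' as a percentage. The default mode uses the absolute relative deviation,
#' `100 - |MV - RV| / RV * 100`, floored at 0, so 100 means exact agreement
#' and values never exceed 100. The literal mode is the signed form
#' `100 - (MV - RV) / RV * 100`, which exceeds 100 when the instrument
#' underestimates; it is kept for reproducing protocols that define
#' accuracy that way.
#'
#' @param measured Measured value(s).
#' @param reference Reference (true) value(s); must be non-zero.
#' @param mode `"absolute"` (default) or `"literal"`.
#' @return Accuracy percentage(s), vectorised.
#' @examples
#' accuracy_single(105, 100) # 95
#' accuracy_single(95, 100) # 95
#' accuracy_single(95, 100, mode = "literal") # 105
#' @export
accuracy_single <- function(measured, reference,
                            mode = c("absolute", "literal")) {
  mode <- match.arg(mode)
  if (any(reference == 0)) {
    stop("accuracy undefined for zero reference value", call. = FALSE)
  }
  if (mode == "literal") {
    100 - (measured - reference) / reference * 100
  } else {
    pmax(0, 100 - abs(measured - reference) / abs(reference) * 100)
  }
}

#' Population accuracy of a measurement platform
#'
#' Mean of the per-object single-measurement accuracies over a sample of
#' measured objects.
#'
#' @param sessions Data frame of measurement sessions with columns
#'   `measured` and `reference` (one measurement per object).
#' @param mode Passed to [accuracy_single()].
#' @return The average accuracy percentage.
#' @export
accuracy_population <- function(sessions, mode = "absolute") {
  if (nrow(sessions) == 0) stop("no sessions", call. = FALSE)
  if (any(is.na(sessions$reference))) {
    stop("every session needs a reference value", call. = FALSE)
  }
  mean(accuracy_single(sessions$measured, sessions$reference, mode = mode))
}

#' Trueness of a measurement platform
#'
#' Agreement between the average of repeated measurements of each object
#' and its reference value: per object, the accuracy of the replicate mean;
#' averaged over objects. Because averaging shrinks random error, trueness
#' is at least as high as single-measurement accuracy in expectation for an
#' unbiased instrument.
#'
#' @param sessions Data frame with columns `object_id`, `measured`,
#'   `reference` (the reference constant within object), several replicate
#'   rows per object.
#' @param mode Passed to [accuracy_single()].
#' @return The average trueness percentage.
#' @export
trueness <- function(sessions, mode = "absolute") {
  if (nrow(sessions) == 0) stop("no sessions", call. = FALSE)
  reps <- table(sessions$object_id)
  if (length(unique(reps)) > 1) {
    warning("unequal replicate counts across objects; using available ",
            "replicates", call. = FALSE)
  }
  per_obj <- vapply(split(sessions, sessions$object_id), function(d) {
    accuracy_single(mean(d$measured), d$reference[1], mode = mode)
  }, numeric(1))
  mean(per_obj)
}

#' CV-based repeatability metrics
#'
#' The shared computation behind precision, reproducibility, technical
#' repeatability and robustness: group repeated measurements of each object
#' (by replicate, operator x device, fixed-placement repeat or day), compute
#' the coefficient of variation per object, average over objects, and
#' report `100 * (1 - mean CV)` so that zero spread gives 100%. Set
#' `output = "raw_cv"` for the untransformed mean CV. The metric ignores
#' constant bias entirely (a deterministic instrument scores 100 regardless
#' of its offset) and is invariant to rescaling all measurements.
#'
#' @param sessions Data frame with columns `object_id` and `measured`; any
#'   extra grouping columns named in `grouping` further split objects.
#' @param grouping Character vector of column names defining a measurement
#'   group together with `object_id` (empty: all of an object's rows form
#'   one group).
#' @param output `"percent"` (default) or `"raw_cv"`.
#' @return The metric as a percentage (or the mean CV).
#' @examples
#' s <- data.frame(object_id = "a", measured = c(98, 102))
#' cv_based_metric(s) # ~97.17
#' @export
cv_based_metric <- function(sessions, grouping = character(0),
                            output = c("percent", "raw_cv")) {
  output <- match.arg(output)
  keys <- c("object_id", grouping)
  key <- interaction(sessions[keys], drop = TRUE)
  cvs <- vapply(split(sessions$measured, key), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    abs(stats::sd(v) / m)
  }, numeric(1))
  if (any(is.na(cvs))) {
    warning(sum(is.na(cvs)), " group(s) excluded (fewer than 2 values or ",
            "zero mean)", call. = FALSE)
    cvs <- cvs[!is.na(cvs)]
  }
  if (length(cvs) == 0) stop("no usable measurement groups", call. = FALSE)
  mean_cv <- mean(cvs)
  if (output == "raw_cv") mean_cv else 100 * (1 - mean_cv)
}

#' Full static-characteristics report
#'
#' Computes the six measurement-quality metrics from a session log, where
#' each protocol is identified by the `protocol` column: `accuracy` (one
#' measurement per object with reference), `trueness` (replicates with
#' reference), `precision` (replicates, same operator/device),
#' `reproducibility` (operator x device grid), `repeatability`
#' (fixed-placement repeats) and `robustness` (one measurement per day).
#' Protocols absent from the log are reported as `NA`.
#'
#' @param sessions Data frame with columns `protocol`, `object_id`,
#'   `operator_id`, `device_id`, `replicate`, `day`, `measured`,
#'   `reference`.
#' @return A one-row-per-metric data frame (`metric`, `value`).
#' @export
static_characteristics <- function(sessions) {
  get <- function(p) sessions[sessions$protocol == p, , drop = FALSE]
  val <- c(
    accuracy = if (nrow(get("accuracy"))) accuracy_population(get("accuracy"))
      else NA_real_,
    trueness = if (nrow(get("trueness"))) trueness(get("trueness"))
      else NA_real_,
    precision = if (nrow(get("precision"))) cv_based_metric(get("precision"))
      else NA_real_,
    reproducibility = if (nrow(get("reproducibility")))
      cv_based_metric(get("reproducibility")) else NA_real_,
    technical_repeatability = if (nrow(get("repeatability")))
      cv_based_metric(get("repeatability")) else NA_real_,
    robustness = if (nrow(get("robustness")))
      cv_based_metric(get("robustness")) else NA_real_
  )
  data.frame(metric = names(val), value = unname(val),
             stringsAsFactors = FALSE)
}
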