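#' Construct a pressure matrix
#'
#' A `pressure_matrix` is the central data object of the package: a 2D grid
#' of contact pressures (kPa) recorded by a body-pressure mat, together with
#' the sensor pitch and the contact threshold below which a cell is treated
#' as "no contact". Row index increases from the neck edge toward the
#' parietal (crown) edge; cell (1,1) is the top-left of the stored matrix.
#'
#' @param values numeric matrix of pressures in kPa; all finite and >= 0,
#'   at least 2 rows and 2 columns.
#' @param pitch_cm center-to-center sensor spacing in cm (> 0).
#' @param contact_threshold_kpa pressure below which a cell counts as
#'   off-body (default 0.1 kPa).
#' @return an object of class `pressure_matrix`.
#' @export
pressure_matrix <- function(values, pitch_cm = 0.6, contact_threshold_kpa = 0.1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("pressure matrix needs at least 2 rows and 2 columns", call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0))
    stop("all pressures must be finite and >= 0", call. = FALSE)
  if (!is.numeric(pitch_cm) || length(pitch_cm) != 1L || pitch_cm <= 0)
    stop("`pitch_cm` must be a single positive number", call. = FALSE)
  if (contact_threshold_kpa < 0)
    stop("`contact_threshold_kpa` must be >= 0", call. = FALSE)
  structure(
    list(values = unname(values), pitch_cm = pitch_cm,
         contact_threshold_kpa = contact_threshold_kpa),
    class = "pressure_matrix")
}

#' @export
print.pressure_matrix <- function(x, ...) {
  cm <- contact_mask(x)
  cat(sprintf("<pressure_matrix> %d x %d cells, pitch %.2f cm\n",
              nrow(x$values), ncol(x$values), x$pitch_cm))
  cat(sprintf("  contact cells: %d (threshold %.2f kPa), peak %.2f kPa\n",
              sum(cm), x$contact_threshold_kpa, max(x$values)))
  invisible(x)
}

#' @export
dim.pressure_matrix <- function(x) dim(x$values)

is_pressure_matrix <- function(x) inherits(x, "pressure_matrix")

#' Contact mask of a pressure matrix
#'
#' Logical matrix flagging cells at or above the contact threshold; the
#' clustering and partitioning stages operate on these cells only.
#'
#' @param m a [pressure_matrix()].
#' @return logical matrix of the same shape.
#' @export
contact_mask <- function(m) {
  stopifnot(is_pressure_matrix(m))
  m$values >= m$contact_threshold_kpa
}

#' Subjective comfort score
#'
#' Four 1-5 sub-scores (softness, wrapping, support, fit) and their total,
#' as collected on the post-trial evaluation form.
#'
#' @param softness,wrapping,support,fit integer ratings in 1..5.
#' @return an object of class `comfort_score` with a `total` field (4..20).
#' @export
comfort_score <- function(softness, wrapping, support, fit) {
  s <- c(softness = softness, wrapping = wrapping, support = support, fit = fit)
  if (any(s != round(s)) || any(s < 1) || any(s > 5))
    stop("comfort sub-scores must be integers in 1..5", call. = FALSE)
  structure(as.list(c(s, total = sum(s))), class = "comfort_score")
}

#' One body-pressure trial
#'
#' Bundles the pressure recording of one (pillow, subject, posture)
#' combination with its comfort evaluation. `emg_valid` flags whether the
#' surface-EMG check showed the neck muscles at electrical rest; only valid
#' trials should enter downstream analysis.
#'
#' @param pillow_id,subject_id labels.
#' @param posture `"supine"` or `"lateral"`.
#' @param matrix a [pressure_matrix()].
#' @param comfort a [comfort_score()].
#' @param emg_valid logical, default `TRUE`.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(pillow_id, subject_id, posture, matrix, comfort,
                         emg_valid = TRUE) {
  posture <- match.arg(posture, c("supine", "lateral"))
  if (!is_pressure_matrix(matrix)) stop("`matrix` must be a pressure_matrix", call. = FALSE)
  if (!inherits(comfort, "comfort_score")) stop("`comfort` must be a comfort_score", call. = FALSE)
  structure(
    list(pillow_id = as.character(pillow_id),
         subject_id = as.character(subject_id),
         posture = posture, matrix = matrix, comfort = comfort,
         emg_valid = isTRUE(emg_valid),
         trial_id = paste(pillow_id, subject_id, posture, sep = "/")),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s  comfort total %d  emg_valid=%s\n",
              x$trial_id, x$comfort$total, x$emg_valid))
  invisible(x)
}

# keep only trials usable downstream (EMG at rest, requested posture)
valid_trials <- function(trials, posture = NULL) {
  keep <- vapply(trials, function(t) isTRUE(t$emg_valid), logical(1))
  if (!is.null(posture))
    keep <- keep & vapply(trials, function(t) t$posture == posture, logical(1))
  trials[keep]
}
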