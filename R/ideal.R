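# Construction of the approximate ideal pressure-distribution matrix:
# rank trials by subjective comfort, keep the top fraction, align each
# matrix by its center of pressure, and average element-wise.

#' Rank trials by subjective comfort
#'
#' Orders trials of one posture descending by comfort total. Ties are broken
#' by the higher minimum sub-score, then by trial id (lexicographic), so the
#' ordering is deterministic.
#'
#' @param trials list of [trial_record()]s, all `emg_valid` and of the
#'   requested posture.
#' @param posture `"supine"` or `"lateral"`.
#' @return the trials, reordered.
#' @export
rank_trials <- function(trials, posture = c("supine", "lateral")) {
  posture <- match.arg(posture)
  trials <- valid_trials(trials, posture)
  if (length(trials) == 0L)
    stop("no valid trials for posture ", posture, call. = FALSE)
  total <- vapply(trials, function(t) t$comfort$total, numeric(1))
  minsub <- vapply(trials, function(t)
    min(t$comfort$softness, t$comfort$wrapping, t$comfort$support, t$comfort$fit),
    numeric(1))
  id <- vapply(trials, function(t) t$trial_id, character(1))
  trials[order(-total, -minsub, id)]
}

#' Center of pressure of a matrix
#'
#' Pressure-weighted centroid of the contact footprint, in (row, col) cell
#' coordinates.
#'
#' @param m a [pressure_matrix()].
#' @return numeric vector `c(row, col)`.
#' @export
center_of_pressure <- function(m) {
  stopifnot(is_pressure_matrix(m))
  v <- m$values
  w <- sum(v)
  if (w <= 0) stop("no contact: all-zero pressure matrix has no center of pressure", call. = FALSE)
  ri <- row(v); ci <- col(v)
  c(row = sum(ri * v) / w, col = sum(ci * v) / w)
}

# translate the matrix by an integer (dr, dc) cell shift, zero-padding
shift_matrix <- function(v, dr, dc) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- v[src_r[ok_r], src_c[ok_c]]
  out
}

#' Align a pressure matrix to the grid center
#'
#' Translates the matrix by an integer cell shift so its center of pressure
#' lands on the grid center (no interpolation). Used before averaging so
#' anatomically corresponding peaks are not blurred.
#'
#' @param m a [pressure_matrix()].
#' @return list with the aligned `matrix` and the applied `shift` (dr, dc).
#' @export
align_to_center <- function(m) {
  cop <- center_of_pressure(m)
  target <- (dim(m$values) + 1) / 2
  dr <- round(target[1] - cop[1]); dc <- round(target[2] - cop[2])
  out <- m
  out$values <- shift_matrix(m$values, dr, dc)
  list(matrix = out, shift = c(dr = dr, dc = dc))
}

#' Build the approximate ideal pressure-distribution matrix
#'
#' Keeps the top comfort-ranked fraction of the trials (at least `min_keep`),
#' optionally aligns each kept matrix by translating its center of pressure
#' to the grid center, and returns the element-wise mean.
#'
#' @param trials list of [trial_record()]s sharing grid shape and pitch.
#' @param posture `"supine"` or `"lateral"`.
#' @param fraction proportion of top-ranked trials to average (default 0.10).
#' @param min_keep minimum number of trials kept (default 1).
#' @param round_mode how `fraction * n` is rounded to a count: `"floor"`
#'   (default) or `"ceil"`; with `"floor"` a cohort of 42 keeps 4 trials.
#' @param align align matrices by center of pressure before averaging
#'   (default `TRUE`).
#' @return an `ideal_matrix` object: the mean [pressure_matrix()], the
#'   posture, source trial ids, fraction, and the alignment shifts applied.
#' @export
build_ideal_matrix <- function(trials, posture = c("supine", "lateral"),
                               fraction = 0.10, min_keep = 1L,
                               round_mode = c("floor", "ceil"),
                               align = TRUE) {
  posture <- match.arg(posture)
  round_mode <- match.arg(round_mode)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]", call. = FALSE)
  ranked <- rank_trials(trials, posture)
  shapes <- vapply(ranked, function(t) paste(dim(t$matrix$values), collapse = "x"), character(1))
  pitches <- vapply(ranked, function(t) t$matrix$pitch_cm, numeric(1))
  if (length(unique(shapes)) > 1L || length(unique(pitches)) > 1L) {
    bad <- vapply(ranked, function(t) t$trial_id, character(1))[
      shapes != shapes[1] | pitches != pitches[1]]
    stop("trial matrices disagree in shape or pitch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_keep <- if (round_mode == "floor") floor(fraction * length(ranked))
            else ceiling(fraction * length(ranked))
  n_keep <- max(as.integer(n_keep), as.integer(min_keep))
  kept <- ranked[seq_len(min(n_keep, length(ranked)))]
  shifts <- list()
  mats <- lapply(kept, function(t) {
    if (align) {
      a <- align_to_center(t$matrix)
      shifts[[t$trial_id]] <<- a$shift
      a$matrix$values
    } else t$matrix$values
  })
  avg <- Reduce(`+`, mats) / length(mats)
  proto <- kept[[1]]$matrix
  structure(
    list(matrix = pressure_matrix(avg, proto$pitch_cm, proto$contact_threshold_kpa),
         posture = posture,
         source_trial_ids = vapply(kept, function(t) t$trial_id, character(1)),
         fraction = fraction, round_mode = round_mode,
         align = align, shifts = shifts),
    class = "ideal_matrix")
}

#' @export
print.ideal_matrix <- function(x, ...) {
  cat(sprintf("<ideal_matrix> posture %s, mean of %d trials (fraction %.2f)\n",
              x$posture, length(x$source_trial_ids), x$fraction))
  print(x$matrix)
  invisible(x)
}

#' Cosine similarity between two pressure matrices
#'
#' Flattens both matrices and computes `sum(A*B) / (||A|| ||B||)`. For
#' non-negative pressure fields the value lies in \[0, 1\]; 1 means the two
#' matrices are positive scalar multiples of each other, and values closer
#' to 1 indicate closer support patterns.
#'
#' @param A,B [pressure_matrix()]s (or `ideal_matrix` objects) of one shape.
#' @return similarity value in \[0, 1\] for non-negative inputs.
#' @export
cosine_similarity <- function(A, B) {
  a <- if (inherits(A, "ideal_matrix")) A$matrix$values else A$values
  b <- if (inherits(B, "ideal_matrix")) B$matrix$values else B$values
  if (!identical(dim(a), dim(b)))
    stop("matrices must share the same shape", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero-norm input matrix", call. = FALSE)
  sum(a * b) / (na * nb)
}
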