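# Body-pressure-distribution indices: average pressure Pv, peak pressure Pm,
# and the maximum / mean pressure gradient Gm / Gv.
#
# Two gradient conventions are supported.  The "literal" mode forms, for each
# sensor row i >= 2, the column-summed signed difference
#   G_i = sum_j [p(x_i, y_j) - p(x_{i-1}, y_j)] / l
# (l = sensor pitch in cm), and aggregates |G_i|.  The "pointwise" mode
# computes a per-cell central-difference magnitude sqrt(gx^2 + gy^2) / l and
# aggregates over contact cells.  The literal row-wise form matches the
# published index definition verbatim (including its unusual units); the
# pointwise form is the conventional image-gradient reading.  The mode used
# is recorded in every result.

#' Average pressure Pv (kPa)
#'
#' Arithmetic mean of the pressure field. By default only contact cells
#' (at or above the contact threshold) are averaged, so that off-body sensor
#' cells do not dilute the index; set `contact_only = FALSE` for the plain
#' mean over every cell.
#'
#' @param m a [pressure_matrix()].
#' @param contact_only average over contact cells only (default `TRUE`).
#' @return mean pressure in kPa.
#' @export
average_pressure <- function(m, contact_only = TRUE) {
  stopifnot(is_pressure_matrix(m))
  if (contact_only) {
    cm <- contact_mask(m)
    if (!any(cm)) stop("no contact: no cell reaches the contact threshold", call. = FALSE)
    mean(m$values[cm])
  } else {
    mean(m$values)
  }
}

#' Peak pressure Pm (kPa)
#'
#' Maximum pressure over all measuring points.
#'
#' @param m a [pressure_matrix()].
#' @return peak pressure in kPa.
#' @export
peak_pressure <- function(m) {
  stopifnot(is_pressure_matrix(m))
  max(m$values)
}

#' Per-row pressure-gradient profile (literal mode)
#'
#' For each row i >= 2, the column-summed signed difference to the previous
#' row, divided by the sensor pitch. Returns `nrow - 1` values. With
#' `mode = "pointwise"` returns instead the per-cell central-difference
#' gradient magnitude as a matrix (kPa/cm).
#'
#' @param m a [pressure_matrix()].
#' @param mode `"literal"` (default) or `"pointwise"`.
#' @return numeric vector of length `nrow - 1` (literal) or a matrix of
#'   per-cell gradient magnitudes (pointwise).
#' @export
row_gradient_profile <- function(m, mode = c("literal", "pointwise")) {
  stopifnot(is_pressure_matrix(m))
  mode <- match.arg(mode)
  v <- m$values
  if (nrow(v) < 2L) stop("gradient needs at least two sensor rows", call. = FALSE)
  if (mode == "literal") {
    rowSums(v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]) / m$pitch_cm
  } else {
    pointwise_gradient(v, m$pitch_cm)
  }
}

# per-cell gradient magnitude sqrt(gx^2+gy^2)/l; central differences in the
# interior, one-sided at the borders; NA cells (outside a partition mask)
# simply drop out of the stencil
pointwise_gradient <- function(v, pitch_cm) {
  nr <- nrow(v); nc <- ncol(v)
  gr <- matrix(NA_real_, nr, nc)
  gc <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      up   <- if (i > 1L  && !is.na(v[i - 1L, j])) v[i - 1L, j] else NA_real_
      down <- if (i < nr  && !is.na(v[i + 1L, j])) v[i + 1L, j] else NA_real_
      lef  <- if (j > 1L  && !is.na(v[i, j - 1L])) v[i, j - 1L] else NA_real_
      rig  <- if (j < nc  && !is.na(v[i, j + 1L])) v[i, j + 1L] else NA_real_
      gr[i, j] <-
        if (!is.na(up) && !is.na(down)) (down - up) / 2 else
        if (!is.na(down)) down - v[i, j] else
        if (!is.na(up)) v[i, j] - up else 0
      gc[i, j] <-
        if (!is.na(lef) && !is.na(rig)) (rig - lef) / 2 else
        if (!is.na(rig)) rig - v[i, j] else
        if (!is.na(lef)) v[i, j] - lef else 0
    }
  }
  sqrt(gr^2 + gc^2) / pitch_cm
}

#' Maximum and mean pressure gradient Gm, Gv (kPa/cm^2)
#'
#' `max_gradient` and `mean_gradient` aggregate the gradient values of the
#' active mode: in literal mode the magnitudes of the per-row profile, in
#' pointwise mode the per-cell gradient magnitudes over contact cells.
#' The unit label kPa/cm^2 is the one conventionally printed for these
#' indices, although the literal row-sum form strictly yields kPa/cm summed
#' over columns; the label is carried unchanged and documented rather than
#' altered.
#'
#' @param m a [pressure_matrix()].
#' @param mode `"literal"` (default) or `"pointwise"`.
#' @return a single gradient value.
#' @export
max_gradient <- function(m, mode = c("literal", "pointwise")) {
  mode <- match.arg(mode)
  g <- gradient_values(m, mode)
  if (length(g) == 0L) return(NA_real_)
  max(g)
}

#' @rdname max_gradient
#' @export
mean_gradient <- function(m, mode = c("literal", "pointwise")) {
  mode <- match.arg(mode)
  g <- gradient_values(m, mode)
  if (length(g) == 0L) return(NA_real_)
  mean(g)
}

gradient_values <- function(m, mode) {
  if (mode == "literal") {
    abs(row_gradient_profile(m, "literal"))
  } else {
    # the mean is taken over all test points of the mat, as in the index
    # definition; off-body cells carry (near-)zero gradient
    g <- row_gradient_profile(m, "pointwise")
    g[!is.na(g)]
  }
}

#' All four body-pressure indices of a matrix
#'
#' @param m a [pressure_matrix()].
#' @param mode gradient mode, `"literal"` or `"pointwise"`.
#' @param contact_only average Pv over contact cells only (default `TRUE`).
#' @return a `pressure_indices` object: list with `Pv`, `Pm`, `Gm`, `Gv`
#'   and the gradient `mode` used.
#' @export
pressure_indices <- function(m, mode = c("literal", "pointwise"),
                             contact_only = TRUE) {
  mode <- match.arg(mode)
  structure(
    list(Pv = average_pressure(m, contact_only = contact_only),
         Pm = peak_pressure(m),
         Gm = max_gradient(m, mode),
         Gv = mean_gradient(m, mode),
         mode = mode),
    class = "pressure_indices")
}

#' @export
print.pressure_indices <- function(x, ...) {
  cat(sprintf("Pv %.3f kPa  Pm %.3f kPa  Gm %.3f  Gv %.3f kPa/cm^2  [%s]\n",
              x$Pv, x$Pm, x$Gm, x$Gv, x$mode))
  invisible(x)
}

#' Per-partition body-pressure indices
#'
#' Computes the four indices over the cells of each labeled partition only.
#' Gradients are restricted to within-partition cell pairs: in literal mode
#' a row's contribution sums only column positions whose cell and upper
#' neighbour both lie in the partition; in pointwise mode the difference
#' stencil uses in-partition neighbours only. Partitions whose cells include
#' no valid gradient pair report `Gm = Gv = NA`.
#'
#' @param m a [pressure_matrix()].
#' @param pm a [partition_map()] aligned to `m` (same grid shape).
#' @param mode gradient mode.
#' @return named list of `pressure_indices`, one per partition label
#'   (background label 0 is skipped).
#' @export
partition_indices <- function(m, pm, mode = c("literal", "pointwise")) {
  stopifnot(is_pressure_matrix(m), inherits(pm, "partition_map"))
  mode <- match.arg(mode)
  if (!identical(dim(m$values), dim(pm$labels)))
    stop("partition map and pressure matrix have different grid shapes", call. = FALSE)
  labs <- sort(setdiff(unique(as.vector(pm$labels)), 0L))
  out <- list()
  for (lab in labs) {
    sel <- pm$labels == lab
    if (!any(sel))
      stop(sprintf("no contact: partition %s is empty", partition_name(pm, lab)), call. = FALSE)
    vals <- m$values[sel]
    masked <- m$values
    masked[!sel] <- NA_real_
    if (mode == "literal") {
      d <- masked[-1L, , drop = FALSE] - masked[-nrow(masked), , drop = FALSE]
      gi <- apply(d, 1L, function(r) if (all(is.na(r))) NA_real_ else sum(r, na.rm = TRUE))
      gi <- abs(gi[!is.na(gi)]) / m$pitch_cm
    } else {
      g <- pointwise_gradient(masked, m$pitch_cm)
      gi <- g[sel & !is.na(g)]
    }
    out[[partition_name(pm, lab)]] <- structure(
      list(Pv = mean(vals), Pm = max(vals),
           Gm = if (length(gi)) max(gi) else NA_real_,
           Gv = if (length(gi)) mean(gi) else NA_real_,
           mode = mode),
      class = "pressure_indices")
  }
  out
}
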