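# Material design: translate per-partition support requirements into an
# equivalent-stiffness specification and a staggered pore-array layout for
# perforated memory foam.
#
# Unit system: pressures kPa, cell areas cm^2, forces N, lengths mm, with
# 1 kPa * 1 cm^2 = 0.1 N.  The equivalent elastic coefficient k is treated
# as N/mm (force per unit compression under a disc indenter).

KPA_CM2_TO_N <- 0.1

#' Pore-diameter / stiffness calibration of perforated foam
#'
#' Holds (pore diameter d, equivalent elastic coefficient k) calibration
#' pairs for a foam slab, fits the power law `d = a * k^b` by log-log least
#' squares on construction, and records the validity range within which
#' diameter predictions are clamped.
#'
#' @param diameter_mm pore diameters (mm), increasing.
#' @param k measured equivalent elastic coefficients (N/mm), decreasing in d.
#' @param valid_d_range_mm diameter validity range (default c(6, 21) mm).
#' @param foam_height_mm slab thickness (default 110 mm).
#' @param pitch_mm staggered hole pitch (default 30 mm).
#' @return an `elastic_calibration` with `fitted_a`, `fitted_b`, `r_squared`.
#' @export
elastic_calibration <- function(diameter_mm, k, valid_d_range_mm = c(6, 21),
                                foam_height_mm = 110, pitch_mm = 30) {
  if (length(diameter_mm) != length(k) || length(k) < 3L)
    stop("need >= 3 (diameter, k) pairs", call. = FALSE)
  if (any(diameter_mm <= 0) || any(k <= 0))
    stop("diameters and coefficients must be positive", call. = FALSE)
  ord <- order(diameter_mm)
  d <- diameter_mm[ord]; kk <- k[ord]
  if (any(diff(kk) >= 0))
    stop("k must strictly decrease as pore diameter increases", call. = FALSE)
  fit <- fit_power_law(d, kk)
  structure(
    list(pairs = data.frame(diameter_mm = d, k = kk),
         fitted_a = fit[["a"]], fitted_b = fit[["b"]],
         r_squared = attr(fit, "r_squared"),
         valid_d_range_mm = valid_d_range_mm,
         foam_height_mm = foam_height_mm, pitch_mm = pitch_mm),
    class = "elastic_calibration")
}

#' @export
print.elastic_calibration <- function(x, ...) {
  cat(sprintf("<elastic_calibration> %d pairs, d = %.3f k^%.3f (R^2 %.3f), valid d [%g, %g] mm\n",
              nrow(x$pairs), x$fitted_a, x$fitted_b, x$r_squared,
              x$valid_d_range_mm[1], x$valid_d_range_mm[2]))
  invisible(x)
}

#' Fit the pore-diameter power law d = a * k^b
#'
#' Ordinary least squares of `log(d)` on `log(k)`; `a` is the
#' back-transformed intercept, `b` the slope.
#'
#' @param d pore diameters (positive).
#' @param k equivalent elastic coefficients (positive).
#' @return named vector `c(a, b)` with an `r_squared` attribute.
#' @export
fit_power_law <- function(d, k) {
  if (length(d) < 3L) stop("need at least 3 pairs to fit", call. = FALSE)
  if (any(d <= 0) || any(k <= 0)) stop("all values must be positive", call. = FALSE)
  fit <- stats::lm(log(d) ~ log(k))
  out <- c(a = unname(exp(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
  tss <- sum((log(d) - mean(log(d)))^2)
  attr(out, "r_squared") <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  out
}

#' Pore diameter required for a target stiffness
#'
#' Evaluates the fitted power law `d = a * k^b` and clamps the result into
#' the calibration's validity range (the fit is printed with that domain
#' restriction; outside it the foam response is uncharacterized, so the
#' package clamps rather than extrapolates).
#'
#' @param k target equivalent elastic coefficient(s), > 0.
#' @param calibration an [elastic_calibration()].
#' @return numeric vector of diameters (mm) with a logical `clamped`
#'   attribute flagging values that hit the range limits.
#' @export
pore_diameter <- function(k, calibration) {
  stopifnot(inherits(calibration, "elastic_calibration"))
  if (any(k <= 0)) stop("stiffness k must be > 0", call. = FALSE)
  d_raw <- calibration$fitted_a * k^calibration$fitted_b
  lo <- calibration$valid_d_range_mm[1]; hi <- calibration$valid_d_range_mm[2]
  d <- pmin(pmax(d_raw, lo), hi)
  attr(d, "clamped") <- d_raw < lo | d_raw > hi
  d
}

#' Required equivalent stiffness of a partition
#'
#' `k = dF / dH`: the total supported force divided by the compression depth.
#'
#' @param total_force_N total force on the partition (N).
#' @param height_change_mm compression depth (mm), > 0.
#' @return stiffness in N/mm.
#' @export
required_stiffness <- function(total_force_N, height_change_mm) {
  if (any(height_change_mm <= 0))
    stop("height change must be > 0 (no compression, no stiffness requirement)",
         call. = FALSE)
  total_force_N / height_change_mm
}

#' Total force carried by each partition
#'
#' Sums pressure x cell area over the cells of each partition and converts
#' kPa cm^2 to N. Includes a `background` entry for label-0 cells when any
#' exist, so that the partition forces always conserve the whole-grid force.
#'
#' @param m a [pressure_matrix()] (or `ideal_matrix`).
#' @param pm a [partition_map()] on the same grid.
#' @return named numeric vector of forces in N.
#' @export
partition_force <- function(m, pm) {
  if (inherits(m, "ideal_matrix")) m <- m$matrix
  stopifnot(is_pressure_matrix(m), inherits(pm, "partition_map"))
  if (!identical(dim(m$values), dim(pm$labels)))
    stop("partition map and pressure matrix have different grid shapes", call. = FALSE)
  area_cm2 <- m$pitch_cm^2
  labs <- partition_labels(pm)
  out <- vapply(labs, function(l) {
    sel <- pm$labels == l
    if (!any(sel)) { warning("empty partition ", partition_name(pm, l)); return(0) }
    sum(m$values[sel]) * area_cm2 * KPA_CM2_TO_N
  }, numeric(1))
  names(out) <- vapply(labs, function(l) partition_name(pm, l), character(1))
  if (any(pm$labels == 0L))
    out <- c(out, background = sum(m$values[pm$labels == 0L]) * area_cm2 * KPA_CM2_TO_N)
  out
}

#' Contour nodes of an anthropometric group
#'
#' One key ergonomic node per partition: its anatomical role, its position
#' along the pillow length, and the compression depth the group's head/neck
#' contour dictates at that node.
#'
#' @param group `"MS"`, `"ML"`, `"FS"` or `"FL"` (male/female,
#'   small/large physique).
#' @param depth_mm named numeric vector of node depths (mm) per partition.
#' @param x_mm optional named vector of node positions along the pillow (mm).
#' @param foam_height_mm slab thickness bound for depths (default 110).
#' @return an object of class `contour_nodes`.
#' @export
contour_nodes <- function(group, depth_mm, x_mm = NULL, foam_height_mm = 110) {
  group <- match.arg(group, c("MS", "ML", "FS", "FL"))
  if (is.null(names(depth_mm))) stop("depths must be named by partition", call. = FALSE)
  if (any(depth_mm < 0) || any(depth_mm > foam_height_mm))
    stop("node depths must lie in [0, foam height]", call. = FALSE)
  roles <- partition_node_roles()
  roles <- roles[match(names(depth_mm), roles$partition), ]
  structure(list(group = group, depth_mm = depth_mm, x_mm = x_mm,
                 node = stats::setNames(roles$node, names(depth_mm)),
                 foam_height_mm = foam_height_mm),
            class = "contour_nodes")
}

#' @export
print.contour_nodes <- function(x, ...) {
  cat(sprintf("<contour_nodes> group %s\n", x$group))
  print(round(x$depth_mm, 1))
  invisible(x)
}

#' Compressed geometry and stiffness requirement per partition
#'
#' Combines the group's contour-node depths with the partition forces of the
#' ideal pressure-distribution matrix: per partition, the compression depth
#' dH is the node depth, the compressed height is `foam_height - dH`, the
#' force dF comes from [partition_force()] on the ideal matrix, and the
#' required stiffness is `k = dF / dH`.
#'
#' @param nodes a [contour_nodes()] covering the map's partitions.
#' @param ideal an `ideal_matrix` (or plain [pressure_matrix()]).
#' @param pm the named [partition_map()].
#' @param foam_height_mm slab thickness (default from `nodes`).
#' @return a `partition_geometry` data.frame: one row per partition with
#'   `total_force_N`, `height_change_mm`, `compressed_height_mm`,
#'   `required_k`.
#' @export
compressed_geometry <- function(nodes, ideal, pm, foam_height_mm = NULL) {
  stopifnot(inherits(nodes, "contour_nodes"), inherits(pm, "partition_map"))
  if (is.null(foam_height_mm)) foam_height_mm <- nodes$foam_height_mm
  labs <- vapply(partition_labels(pm), function(l) partition_name(pm, l), character(1))
  missing <- setdiff(labs, names(nodes$depth_mm))
  if (length(missing))
    stop("contour nodes missing for partitions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dH <- nodes$depth_mm[labs]
  if (any(dH <= 0)) stop("zero node depth: partition is not compressed", call. = FALSE)
  if (any(dH >= foam_height_mm))
    stop("node depth reaches the foam height: slab would bottom out", call. = FALSE)
  f <- partition_force(ideal, pm)
  f <- f[labs]
  out <- data.frame(partition = labs,
                    total_force_N = unname(f),
                    height_change_mm = unname(dH),
                    compressed_height_mm = foam_height_mm - unname(dH),
                    required_k = unname(required_stiffness(f, dH)),
                    stringsAsFactors = FALSE)
  class(out) <- c("partition_geometry", "data.frame")
  out
}

#' Staggered pore-array layout
#'
#' Lays a staggered (hex-offset) lattice of drill holes at the calibration's
#' pitch across the pillow footprint, maps each lattice point to the
#' partition underneath it (the partition map is scaled onto the footprint),
#' and assigns every hole the pore diameter realizing its partition's
#' required stiffness. Lattice points over background get no hole.
#'
#' @param geometry a `partition_geometry` from [compressed_geometry()].
#' @param pm the named [partition_map()].
#' @param calibration an [elastic_calibration()].
#' @param bounds_mm footprint `c(width, height)` in mm that the partition
#'   map is scaled to (default c(500, 350), a standard pillow).
#' @return a `pore_layout`: data.frame of holes `(x_mm, y_mm, diameter_mm,
#'   partition)` plus `pitch_mm` and `bounds_mm` attributes.
#' @export
pore_layout <- function(geometry, pm, calibration, bounds_mm = c(500, 350)) {
  stopifnot(inherits(geometry, "partition_geometry"),
            inherits(pm, "partition_map"),
            inherits(calibration, "elastic_calibration"))
  pitch <- calibration$pitch_mm
  d_for <- stats::setNames(pore_diameter(geometry$required_k, calibration),
                           geometry$partition)
  if (any(d_for >= pitch))
    stop("required pore diameter reaches the hole pitch: holes would overlap",
         call. = FALSE)
  w <- bounds_mm[1]; h <- bounds_mm[2]
  row_step <- pitch * sqrt(3) / 2
  ys <- seq(pitch / 2, h - pitch / 2, by = row_step)
  holes <- list()
  for (r in seq_along(ys)) {
    offset <- if (r %% 2 == 0) pitch / 2 else 0
    xs <- seq(pitch / 2 + offset, w - pitch / 2, by = pitch)
    for (x in xs) {
      # map footprint mm -> partition grid cell (x along columns, y along rows)
      i <- pmin(pmax(ceiling(ys[r] / h * nrow(pm$labels)), 1L), nrow(pm$labels))
      j <- pmin(pmax(ceiling(x / w * ncol(pm$labels)), 1L), ncol(pm$labels))
      lab <- pm$labels[i, j]
      if (lab == 0L) next
      pname <- partition_name(pm, lab)
      if (!pname %in% names(d_for)) next
      holes[[length(holes) + 1L]] <- data.frame(
        x_mm = x, y_mm = ys[r], diameter_mm = unname(d_for[[pname]]),
        partition = pname, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(holes)) do.call(rbind, holes)
         else data.frame(x_mm = numeric(0), y_mm = numeric(0),
                         diameter_mm = numeric(0), partition = character(0))
  attr(out, "pitch_mm") <- pitch
  attr(out, "bounds_mm") <- bounds_mm
  attr(out, "clamped_partitions") <- geometry$partition[attr(d_for, "clamped") %in% TRUE]
  class(out) <- c("pore_layout", "data.frame")
  out
}

#' @export
print.pore_layout <- function(x, ...) {
  cat(sprintf("<pore_layout> %d holes, pitch %g mm, footprint %g x %g mm\n",
              nrow(x), attr(x, "pitch_mm"), attr(x, "bounds_mm")[1],
              attr(x, "bounds_mm")[2]))
  print(table(x$partition))
  invisible(x)
}
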