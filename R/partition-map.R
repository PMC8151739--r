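# Spatial partitions of the support surface.  Clusters of pressure values
# (from fcm) are mapped back onto the grid, split into 4-connected
# components, and small fragments are merged into the neighbouring region
# with the longest shared boundary.  This is how c = 3 pressure levels can
# yield four spatial regions in the lateral posture: two spatially separate
# areas can share a pressure level.

#' Construct a partition map
#'
#' @param labels integer matrix of region labels; 0 = background/no contact,
#'   1..K = regions.
#' @param names named character vector mapping label (as character) to an
#'   anatomical region name; may be `NULL` before [name_partitions()] runs.
#' @param posture `"supine"` or `"lateral"`.
#' @return an object of class `partition_map`.
#' @export
partition_map <- function(labels, names = NULL, posture = c("supine", "lateral")) {
  posture <- match.arg(posture)
  if (!is.matrix(labels)) stop("`labels` must be an integer matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  k <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(k) < 1L) stop("partition map has no labeled region", call. = FALSE)
  if (!is.null(names)) {
    missing <- setdiff(as.character(k), base::names(names))
    if (length(missing))
      stop("names missing for labels: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = unname(labels), names = names, posture = posture),
            class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  k <- sort(setdiff(unique(as.vector(x$labels)), 0L))
  nm <- vapply(k, function(l) partition_name(x, l), character(1))
  sz <- vapply(k, function(l) sum(x$labels == l), integer(1))
  cat(sprintf("<partition_map> posture %s, %d regions\n", x$posture, length(k)))
  cat(paste(sprintf("  %s: %d cells", nm, sz), collapse = "\n"), "\n")
  invisible(x)
}

partition_name <- function(pm, label) {
  if (is.null(pm$names)) as.character(label)
  else unname(pm$names[as.character(label)])
}

#' Labels present in a partition map
#' @param pm a [partition_map()].
#' @return integer vector of region labels (background excluded).
#' @export
partition_labels <- function(pm) sort(setdiff(unique(as.vector(pm$labels)), 0L))

# 4-connected component labeling of a logical mask; returns integer matrix
# with components numbered 1..k in first-encounter (column-major) order
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                   if (j > 1L) cur - nr, if (j < nc) cur + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# count of 4-adjacent cell pairs between region `a` cells and each other label
boundary_lengths <- function(lab, a) {
  nr <- nrow(lab); nc <- ncol(lab)
  counts <- integer(0)
  cells <- which(lab == a)
  for (cur in cells) {
    i <- ((cur - 1L) %% nr) + 1L
    j <- ((cur - 1L) %/% nr) + 1L
    for (nb in c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                 if (j > 1L) cur - nr, if (j < nc) cur + nr)) {
      l <- lab[nb]
      if (l != 0L && l != a) {
        key <- as.character(l)
        counts[key] <- if (key %in% names(counts)) counts[[key]] + 1L else 1L
      }
    }
  }
  counts
}

#' Spatial region map from a fuzzy clustering
#'
#' Assigns each contact cell of `m` to its argmax-membership cluster, splits
#' every cluster into 4-connected spatial components, and merges components
#' smaller than `min_region_cells` into the neighbouring region with the
#' longest shared boundary (ties to the lower label). Non-contact cells form
#' the background (label 0). Regions are relabeled 1..K in order of their
#' mean-pressure cluster, then position.
#'
#' @param f an [fcm()] result computed from the contact cells of `m`.
#' @param m the [pressure_matrix()] that was clustered.
#' @param posture posture tag carried into the map.
#' @param min_region_cells components smaller than this are merged away;
#'   default 1% of the contact cells (at least 1).
#' @return an unnamed [partition_map()]; follow with [name_partitions()].
#' @export
label_map <- function(f, m, posture = c("supine", "lateral"),
                      min_region_cells = NULL) {
  stopifnot(inherits(f, "fcm_result"), is_pressure_matrix(m))
  posture <- match.arg(posture)
  cm <- contact_mask(m)
  if (!any(cm)) stop("all cells are background: nothing to partition", call. = FALSE)
  if (sum(cm) != nrow(f$memberships))
    stop("fcm result does not match the matrix's contact cells", call. = FALSE)
  if (is.null(min_region_cells))
    min_region_cells <- max(1L, floor(0.01 * sum(cm)))

  cluster_of <- max.col(f$memberships, ties.method = "first")
  cl <- matrix(0L, nrow(m$values), ncol(m$values))
  cl[cm] <- cluster_of

  # split clusters into 4-connected components
  lab <- matrix(0L, nrow(cl), ncol(cl))
  nxt <- 0L
  for (k in seq_len(f$c)) {
    comp <- label_components(cl == k)
    sel <- comp > 0L
    lab[sel] <- comp[sel] + nxt
    nxt <- nxt + max(comp)
  }

  # absorb small fragments, smallest first
  repeat {
    sizes <- table(lab[lab > 0L])
    small <- as.integer(names(sizes)[sizes < min_region_cells])
    if (!length(small)) break
    small <- small[order(sizes[as.character(small)], small)]
    a <- small[1L]
    bl <- boundary_lengths(lab, a)
    if (!length(bl)) {
      # isolated fragment with no labeled neighbour: demote to background
      lab[lab == a] <- 0L
    } else {
      best <- as.integer(names(bl)[order(-bl, as.integer(names(bl)))][1L])
      lab[lab == a] <- best
    }
  }
  if (!any(lab > 0L)) stop("all regions were below min_region_cells", call. = FALSE)

  # stable relabeling: by mean pressure of the region, then centroid position
  ids <- sort(unique(lab[lab > 0L]))
  meanp <- vapply(ids, function(l) mean(m$values[lab == l]), numeric(1))
  crow <- vapply(ids, function(l) mean(row(lab)[lab == l]), numeric(1))
  ord <- ids[order(meanp, crow)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  partition_map(out, names = NULL, posture = posture)
}

#' Assign anatomical names to partitions
#'
#' Supine maps (3 regions expected) are named by pressure-weighted centroid
#' row from the neck edge toward the crown: posterior neck area (A1),
#' occipital area (A2), posterior parietal area (A3). Lateral maps
#' (4 regions expected) are named: cervical area (B1) = neck-edge region,
#' lateral parietal area (B4) = parietal-edge region, temporal bone area
#' (B3) = the higher-mean-pressure central region, jaw area (B2) = the
#' remaining anterior region.
#'
#' @param pm an unnamed [partition_map()].
#' @param m the [pressure_matrix()] the map was derived from (used for
#'   pressure-weighted centroids and mean pressures).
#' @param strict error if the region count differs from the posture's
#'   expected count (3 supine, 4 lateral); with `strict = FALSE` surplus
#'   regions get deterministic suffixed names (e.g. B4a, B4b).
#' @return the [partition_map()] with its `names` table filled.
#' @export
name_partitions <- function(pm, m, strict = TRUE) {
  stopifnot(inherits(pm, "partition_map"), is_pressure_matrix(m))
  ids <- partition_labels(pm)
  expected <- if (pm$posture == "supine") 3L else 4L
  if (strict && length(ids) != expected)
    stop(sprintf("expected %d %s regions, found %d (use strict = FALSE to name anyway)",
                 expected, pm$posture, length(ids)), call. = FALSE)
  crow <- vapply(ids, function(l) {
    sel <- pm$labels == l
    sum(row(pm$labels)[sel] * m$values[sel]) / max(sum(m$values[sel]), .Machine$double.eps)
  }, numeric(1))
  meanp <- vapply(ids, function(l) mean(m$values[pm$labels == l]), numeric(1))

  base <- if (pm$posture == "supine") "A" else "B"
  n_main <- min(length(ids), expected)
  nm <- character(length(ids))
  if (pm$posture == "supine") {
    ord <- order(crow, ids)
    main <- ord[seq_len(n_main)]
    nm[main] <- paste0(base, seq_len(n_main))
  } else {
    remaining <- seq_along(ids)
    b1 <- remaining[which.min(crow[remaining])]
    remaining <- setdiff(remaining, b1)
    b4 <- remaining[which.max(crow[remaining])]
    remaining <- setdiff(remaining, b4)
    b3 <- if (length(remaining)) remaining[which.max(meanp[remaining])] else integer(0)
    remaining <- setdiff(remaining, b3)
    b2 <- if (length(remaining)) remaining[1L] else integer(0)
    remaining <- setdiff(remaining, b2)
    nm[b1] <- "B1"
    if (length(b2)) nm[b2] <- "B2"
    if (length(b3)) nm[b3] <- "B3"
    nm[b4] <- "B4"
  }
  # surplus regions: deterministic suffixes on the last main name,
  # ordered by centroid row then label
  extra <- which(nm == "")
  if (length(extra)) {
    extra <- extra[order(crow[extra], ids[extra])]
    nm[extra] <- paste0(base, expected, letters[seq_along(extra)])
  }
  names(nm) <- as.character(ids)
  pm$names <- nm
  pm
}
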