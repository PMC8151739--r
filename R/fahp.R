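# Fuzzy analytic hierarchy process (FAHP) for per-partition pressure
# sensitivity weights.  Experts compare partitions pairwise on a nine-level
# strength scale; scores are converted to a fuzzy complementary judgment
# matrix (V_ij + V_ji = 1, V_ii = 0.5); weights come from the row-sum
# formula
#   W_i = (sum_j V_ij + n/2 - 1) / (n (n - 1)),
# which sums to 1 for any complementary matrix.  A compatibility index
# against the additively consistent matrix implied by the weights provides
# the consistency test, and a hierarchy layer (posture) combines with the
# partition layer multiplicatively.

#' Construct a judgment matrix
#'
#' @param entries square numeric matrix of pairwise comparisons.
#' @param scale `"complementary"` (entries in \[0,1\], `V_ij + V_ji = 1`,
#'   diagonal 0.5) or `"nine_level"` (strength scores in \[1,9\] both ways,
#'   diagonal neutral).
#' @param labels optional partition labels for rows/columns.
#' @param expert_id optional label of the scoring expert.
#' @return an object of class `judgment_matrix`.
#' @export
judgment_matrix <- function(entries, scale = c("complementary", "nine_level"),
                            labels = NULL, expert_id = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(entries) || nrow(entries) != ncol(entries) || nrow(entries) < 2L)
    stop("`entries` must be a square matrix with n >= 2", call. = FALSE)
  n <- nrow(entries)
  if (is.null(labels)) labels <- rownames(entries)
  if (is.null(labels)) labels <- paste0("P", seq_len(n))
  if (scale == "complementary") {
    check_complementary(entries)
  } else {
    off <- entries[row(entries) != col(entries)]
    if (any(off < 1 | off > 9))
      stop("nine-level scores must lie in [1, 9]", call. = FALSE)
  }
  dimnames(entries) <- list(labels, labels)
  structure(list(entries = entries, scale = scale, labels = labels,
                 expert_id = expert_id),
            class = "judgment_matrix")
}

check_complementary <- function(v, tol = 1e-8) {
  n <- nrow(v)
  if (any(abs(diag(v) - 0.5) > tol))
    stop("complementary matrix must have 0.5 on the diagonal", call. = FALSE)
  bad <- which(abs(v + t(v) - 1) > tol, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad))
    stop(sprintf("V[%d,%d] + V[%d,%d] != 1: matrix is not complementary",
                 bad[1, 1], bad[1, 2], bad[1, 2], bad[1, 1]), call. = FALSE)
  if (any(v < 0 | v > 1))
    stop("complementary entries must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Convert nine-level scores to a complementary matrix
#'
#' Bridges the nine-level expert scale to the additive complementary form:
#' `V'_ij = a_ij / (a_ij + a_ji)`, where `a_ij` is the scored strength of
#' partition i over partition j. The conversion preserves ordering, maps
#' indifference to 0.5, and is reciprocal-consistent
#' (`V'_ij + V'_ji = 1` by construction).
#'
#' @param nine_level a [judgment_matrix()] with `scale = "nine_level"`.
#' @return a [judgment_matrix()] with `scale = "complementary"`.
#' @export
to_complementary <- function(nine_level) {
  stopifnot(inherits(nine_level, "judgment_matrix"))
  if (nine_level$scale != "nine_level")
    stop("input must be a nine_level judgment matrix", call. = FALSE)
  a <- nine_level$entries
  v <- a / (a + t(a))
  diag(v) <- 0.5
  judgment_matrix(v, "complementary", labels = nine_level$labels,
                  expert_id = nine_level$expert_id)
}

#' Construct a weight vector
#'
#' @param weights named numeric vector of positive weights summing to 1.
#' @param level hierarchy level: `"B"` (middle), `"C"` (bottom) or `"final"`.
#' @return an object of class `weight_vector`.
#' @export
weight_vector <- function(weights, level = c("C", "B", "final")) {
  level <- match.arg(level)
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  if (any(weights <= 0)) stop("all weights must be > 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  structure(list(weights = weights, level = level), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> level %s\n", x$level))
  print(round(x$weights, 4))
  invisible(x)
}

#' FAHP weights from a complementary judgment matrix
#'
#' Row-sum weighting `W_i = (sum_j V_ij + n/2 - 1) / (n (n - 1))`. For any
#' complementary matrix the weights sum to exactly 1 (algebraic identity,
#' asserted).
#'
#' @param Mc a complementary [judgment_matrix()].
#' @param level hierarchy level tag for the result.
#' @return a [weight_vector()].
#' @export
fahp_weights <- function(Mc, level = "C") {
  stopifnot(inherits(Mc, "judgment_matrix"))
  if (Mc$scale != "complementary")
    stop("fahp_weights needs a complementary matrix; see to_complementary()", call. = FALSE)
  v <- Mc$entries
  n <- nrow(v)
  w <- (rowSums(v) + n / 2 - 1) / (n * (n - 1))
  stopifnot(abs(sum(w) - 1) < 1e-9)
  names(w) <- Mc$labels
  weight_vector(w, level)
}

#' Consistency check of a complementary judgment matrix
#'
#' An additively consistent complementary matrix satisfies
#' `V_ij = 0.5 + (n - 1) (W_i - W_j)` for the row-sum weights `W`. The
#' compatibility index averages the absolute deviation from that relation
#' over the strict upper triangle,
#' `CI = 2 / (n (n - 1)) * sum_{i<j} |V_ij - 0.5 - (n - 1)(W_i - W_j)|`,
#' and the matrix passes when `CI <= threshold`.
#'
#' @param Mc a complementary [judgment_matrix()].
#' @param W optionally, the [weight_vector()] computed from `Mc`; recomputed
#'   when missing.
#' @param threshold pass/fail cutoff (default 0.1).
#' @return list with `ci`, `pass`, and the `threshold` used.
#' @export
consistency_check <- function(Mc, W = NULL, threshold = 0.1) {
  stopifnot(inherits(Mc, "judgment_matrix"), Mc$scale == "complementary")
  if (is.null(W)) W <- fahp_weights(Mc)
  v <- Mc$entries
  n <- nrow(v)
  w <- W$weights
  dev <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dev <- dev + abs(v[i, j] - 0.5 - (n - 1) * (w[[i]] - w[[j]]))
    }
  }
  ci <- 2 * dev / (n * (n - 1))
  list(ci = ci, pass = ci <= threshold, threshold = threshold)
}

#' Combine hierarchy levels into final weights
#'
#' Final weight of partition i in group g is `WB_g * WC_{g,i}`. When the
#' inputs are normalized the final vector sums to 1.
#'
#' @param WB middle-layer [weight_vector()] over groups.
#' @param WC_groups named list of bottom-layer [weight_vector()]s, one per
#'   element of `WB` (names must match).
#' @return a `"final"` [weight_vector()] over all partitions.
#' @export
combine_hierarchy <- function(WB, WC_groups) {
  stopifnot(inherits(WB, "weight_vector"))
  gs <- names(WB$weights)
  if (!setequal(gs, names(WC_groups)))
    stop("WC_groups must supply one weight vector per B-level element",
         call. = FALSE)
  out <- numeric(0)
  for (g in gs) {
    wc <- WC_groups[[g]]
    stopifnot(inherits(wc, "weight_vector"))
    out <- c(out, WB$weights[[g]] * wc$weights)
  }
  weight_vector(out, "final")
}

#' Average weight vectors across experts
#'
#' Arithmetic mean per partition, renormalized to sum 1.
#'
#' @param per_expert list of [weight_vector()]s over one common partition set.
#' @return the aggregated [weight_vector()].
#' @export
aggregate_experts <- function(per_expert) {
  stopifnot(length(per_expert) >= 1L)
  labs <- names(per_expert[[1]]$weights)
  mat <- vapply(per_expert, function(w) {
    if (!setequal(names(w$weights), labs))
      stop("experts scored different partition sets", call. = FALSE)
    w$weights[labs]
  }, numeric(length(labs)))
  mat <- matrix(mat, nrow = length(labs))
  w <- rowMeans(mat)
  w <- w / sum(w)
  names(w) <- labs
  weight_vector(w, per_expert[[1]]$level)
}
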