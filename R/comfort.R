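# Weighted comfort scoring and the prototype evaluation battery:
# per-partition index comparison against ideal targets, similarity to the
# ideal matrix, and similarity-vs-subjective consistency.

#' Weighted comprehensive comfort score
#'
#' `Comfort = sum_i x_i * w_i`, where `x_i` is the comfort rating of
#' partition i and `w_i` its normalized sensitivity weight. The score is a
#' convex combination, so it always lies within the range of the ratings.
#'
#' @param x named numeric vector of per-partition comfort ratings.
#' @param w a [weight_vector()] over the same partition labels.
#' @return the weighted comfort score.
#' @export
weighted_comfort <- function(x, w) {
  stopifnot(inherits(w, "weight_vector"))
  if (!setequal(names(x), names(w$weights)))
    stop("partition labels of ratings and weights do not match", call. = FALSE)
  sum(x[names(w$weights)] * w$weights)
}

#' Evaluate candidate pillows against the ideal support model
#'
#' For each trial: computes the per-partition body-pressure indices and
#' their deltas (measured minus ideal) against the ideal targets, the cosine
#' similarity of the trial matrix to the ideal matrix, and -- when
#' per-partition subjective ratings are supplied -- the weighted comfort
#' score. Trials are ordered by descending similarity in the report.
#'
#' @param trials list of [trial_record()]s sharing the ideal matrix's grid.
#' @param ideal an `ideal_matrix` from [build_ideal_matrix()].
#' @param pm the named [partition_map()] of the ideal matrix.
#' @param w optional final [weight_vector()] over `pm`'s partitions.
#' @param ideal_targets optional named list of `pressure_indices` per
#'   partition (defaults to the packaged reference targets for the posture,
#'   see [ideal_partition_targets()]).
#' @param partition_scores optional named list: per trial id, a named vector
#'   of per-partition subjective ratings; when absent the weighted comfort
#'   column is `NA` rather than imputed.
#' @param mode gradient mode passed to [partition_indices()].
#' @param align align each trial to the grid center before the similarity
#'   computation, matching how the ideal matrix was built (default follows
#'   the ideal's own setting).
#' @return an `evaluation_report`: a data.frame with one row per
#'   trial x partition (indices, targets, deltas) in `$partitions`, and one
#'   row per trial (similarity, weighted comfort, subjective total) in
#'   `$trials`, ordered by descending similarity.
#' @export
evaluate_prototype <- function(trials, ideal, pm, w = NULL,
                               ideal_targets = NULL, partition_scores = NULL,
                               mode = c("literal", "pointwise"),
                               align = NULL) {
  stopifnot(inherits(ideal, "ideal_matrix"), inherits(pm, "partition_map"))
  mode <- match.arg(mode)
  if (is.null(align)) align <- isTRUE(ideal$align)
  if (is.null(ideal_targets))
    ideal_targets <- ideal_partition_targets(ideal$posture)
  ref <- if (align) align_to_center(ideal$matrix)$matrix else ideal$matrix

  per_trial <- list(); per_part <- list()
  for (t in trials) {
    mt <- if (align) align_to_center(t$matrix)$matrix else t$matrix
    sim <- cosine_similarity(mt, ref)
    pidx <- partition_indices(mt, pm, mode = mode)
    for (lab in names(pidx)) {
      tgt <- ideal_targets[[lab]]
      per_part[[length(per_part) + 1L]] <- data.frame(
        trial_id = t$trial_id, partition = lab,
        Pv = pidx[[lab]]$Pv, Pm = pidx[[lab]]$Pm,
        Gm = pidx[[lab]]$Gm, Gv = pidx[[lab]]$Gv,
        Pv_ideal = if (is.null(tgt)) NA_real_ else tgt$Pv,
        Pm_ideal = if (is.null(tgt)) NA_real_ else tgt$Pm,
        Gm_ideal = if (is.null(tgt)) NA_real_ else tgt$Gm,
        Gv_ideal = if (is.null(tgt)) NA_real_ else tgt$Gv,
        stringsAsFactors = FALSE)
    }
    wc <- NA_real_
    if (!is.null(w) && !is.null(partition_scores[[t$trial_id]]))
      wc <- weighted_comfort(partition_scores[[t$trial_id]], w)
    per_trial[[length(per_trial) + 1L]] <- data.frame(
      trial_id = t$trial_id, similarity = sim,
      weighted_comfort = wc, subjective_total = t$comfort$total,
      stringsAsFactors = FALSE)
  }
  trials_df <- do.call(rbind, per_trial)
  trials_df <- trials_df[order(-trials_df$similarity), , drop = FALSE]
  rownames(trials_df) <- NULL
  parts_df <- do.call(rbind, per_part)
  for (v in c("Pv", "Pm", "Gm", "Gv"))
    parts_df[[paste0(v, "_delta")]] <- parts_df[[v]] - parts_df[[paste0(v, "_ideal")]]
  structure(list(trials = trials_df, partitions = parts_df,
                 posture = ideal$posture, mode = mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> posture %s, %d trials, gradient mode %s\n",
              x$posture, nrow(x$trials), x$mode))
  print(utils::head(x$trials, 5))
  invisible(x)
}

#' Rank agreement between matrix similarity and subjective comfort
#'
#' Spearman rank correlation between each trial's cosine similarity to the
#' ideal matrix and its subjective comfort total. A strongly positive value
#' means closeness to the ideal support pattern tracks perceived comfort.
#'
#' @param trials list of [trial_record()]s.
#' @param ideal an `ideal_matrix`.
#' @param align align matrices to the grid center before comparing
#'   (default `TRUE`).
#' @return Spearman's rho.
#' @export
similarity_comfort_correlation <- function(trials, ideal, align = TRUE) {
  ref <- if (align) align_to_center(ideal$matrix)$matrix else ideal$matrix
  sims <- vapply(trials, function(t) {
    mt <- if (align) align_to_center(t$matrix)$matrix else t$matrix
    cosine_similarity(mt, ref)
  }, numeric(1))
  totals <- vapply(trials, function(t) t$comfort$total, numeric(1))
  stats::cor(sims, totals, method = "spearman")
}
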