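# End-to-end orchestration: simulate -> ideal -> partition -> weights ->
# design -> evaluate, with every artifact written to a run directory and
# all randomness derived from the single run seed.

#' Pipeline configuration
#'
#' Collects every tunable of the full workflow. The resolved configuration
#' is written next to the run outputs so any run can be reproduced.
#'
#' @param seed master seed; each stochastic stage consumes a sub-seed
#'   derived from it.
#' @param generator a [generator_config()].
#' @param fraction,round_mode top-fraction settings of
#'   [build_ideal_matrix()].
#' @param fcm_c,fcm_m,fcm_tol,fcm_max_iter fuzzy c-means settings.
#' @param gradient_mode `"literal"` or `"pointwise"`; used for reported
#'   index tables.
#' @param consistency_threshold FAHP compatibility-index cutoff.
#' @param n_experts,expert_noise synthetic expert panel settings.
#' @param groups physique groups to design for.
#' @param bounds_mm pillow footprint for the pore layouts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, generator = generator_config(),
                            fraction = 0.10, round_mode = "floor",
                            fcm_c = 3L, fcm_m = 2, fcm_tol = 1e-6,
                            fcm_max_iter = 300L,
                            gradient_mode = "pointwise",
                            consistency_threshold = 0.1,
                            n_experts = 10L, expert_noise = 0.5,
                            groups = c("MS", "ML", "FS", "FL"),
                            bounds_mm = c(500, 350)) {
  structure(list(seed = as.integer(seed), generator = generator,
                 fraction = fraction, round_mode = round_mode,
                 fcm_c = as.integer(fcm_c), fcm_m = fcm_m, fcm_tol = fcm_tol,
                 fcm_max_iter = as.integer(fcm_max_iter),
                 gradient_mode = gradient_mode,
                 consistency_threshold = consistency_threshold,
                 n_experts = as.integer(n_experts), expert_noise = expert_noise,
                 groups = groups, bounds_mm = bounds_mm),
            class = "pipeline_config")
}

# sub-seed derivation: stable, readable offsets per stage
stage_seed <- function(config, offset) (config$seed * 101L + offset) %% 1000003L

#' Run the full partitioned-support pipeline
#'
#' Simulates a trial cohort per posture, builds the ideal
#' pressure-distribution matrices, partitions and names them, derives
#' partition sensitivity weights from a synthetic expert panel (posture
#' layer weighted by each posture's share of the reference weights),
#' computes the per-partition ideal index tables, designs a pore layout per
#' physique group, and evaluates every trial against the ideal model. All
#' artifacts are written under `out_dir`; the run is idempotent for a given
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param cohorts optional named list (`supine`, `lateral`) of pre-existing
#'   trial cohorts; when `NULL` they are simulated.
#' @return invisibly, a list with the key in-memory results: ideal matrices,
#'   partition maps, final weights, geometry tables, and evaluation reports.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, cohorts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  warnings <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
  postures <- c("supine", "lateral")

  # -- simulate ------------------------------------------------------------
  if (is.null(cohorts)) {
    cohorts <- list()
    for (i in seq_along(postures)) {
      p <- postures[i]
      cohorts[[p]] <- generate_trial_cohort(config$generator, p,
                                            seed = stage_seed(config, i))
      say("simulated %d %s trials", length(cohorts[[p]]), p)
    }
  } else if (!all(postures %in% names(cohorts))) {
    stop("cohorts must be a named list with supine and lateral entries",
         call. = FALSE)
  }
  for (p in postures)
    write_trial_cohort(cohorts[[p]], file.path(out_dir, paste0("cohort_", p)))

  # -- ideal matrices + partitions ----------------------------------------
  ideals <- list(); maps <- list(); index_tables <- list()
  for (i in seq_along(postures)) {
    p <- postures[i]
    ideals[[p]] <- build_ideal_matrix(cohorts[[p]], p,
                                      fraction = config$fraction,
                                      round_mode = config$round_mode)
    write_pressure_matrix(ideals[[p]],
                          file.path(out_dir, paste0("ideal_", p, ".csv")))
    m <- ideals[[p]]$matrix
    f <- fcm(m$values[contact_mask(m)], c = config$fcm_c,
             m_fuzz = config$fcm_m, tol = config$fcm_tol,
             max_iter = config$fcm_max_iter, seed = stage_seed(config, 10L + i))
    if (!f$converged) warnings <- c(warnings, paste("fcm did not converge:", p))
    pm <- label_map(f, m, posture = p)
    pm <- name_partitions(pm, m, strict = FALSE)
    if (length(partition_labels(pm)) != if (p == "supine") 3L else 4L)
      warnings <- c(warnings, sprintf("unexpected region count (%d) for %s",
                                      length(partition_labels(pm)), p))
    maps[[p]] <- pm
    write_partition_map(pm, file.path(out_dir, paste0("partitions_", p, ".csv")))
    say("%s: %d regions (%s)", p, length(partition_labels(pm)),
        paste(pm$names, collapse = ", "))

    pidx <- partition_indices(m, pm, mode = config$gradient_mode)
    index_tables[[p]] <- data.frame(
      partition = names(pidx),
      Pv = vapply(pidx, `[[`, numeric(1), "Pv"),
      Pm = vapply(pidx, `[[`, numeric(1), "Pm"),
      Gm = vapply(pidx, `[[`, numeric(1), "Gm"),
      Gv = vapply(pidx, `[[`, numeric(1), "Gv"),
      row.names = NULL)
  }
  idx_all <- do.call(rbind, index_tables)
  utils::write.csv(idx_all, file.path(out_dir, "ideal_partition_indices.csv"),
                   row.names = FALSE)

  # -- sensitivity weights -------------------------------------------------
  ref_w <- reference_partition_weights()$weights
  partitions_by_posture <- lapply(maps, function(pm)
    unname(pm$names[as.character(partition_labels(pm))]))
  per_expert_final <- list()
  panel_seed <- stage_seed(config, 20L)
  panels <- lapply(postures, function(p) {
    labs <- partitions_by_posture[[p]]
    s <- ref_w[intersect(names(ref_w), labs)]
    if (length(s) != length(labs))  # fall back to uniform for unnamed extras
      s <- stats::setNames(rep(1 / length(labs), length(labs)), labs)
    generate_expert_panel(config$n_experts, s, noise = config$expert_noise,
                          seed = panel_seed + match(p, postures))
  })
  names(panels) <- postures
  # posture (B) layer: each posture's share of total sensitivity
  wb_raw <- vapply(postures, function(p)
    sum(ref_w[intersect(names(ref_w), partitions_by_posture[[p]])]), numeric(1))
  if (any(wb_raw == 0)) wb_raw[] <- 1
  WB <- weight_vector(wb_raw / sum(wb_raw), "B")
  n_cons_fail <- 0L
  for (e in seq_len(config$n_experts)) {
    WC <- list()
    for (p in postures) {
      mc <- to_complementary(panels[[p]][[e]])
      wv <- fahp_weights(mc)
      cc <- consistency_check(mc, wv, threshold = config$consistency_threshold)
      if (!cc$pass) n_cons_fail <- n_cons_fail + 1L
      WC[[p]] <- wv
    }
    per_expert_final[[e]] <- combine_hierarchy(WB, WC)
  }
  if (n_cons_fail > 0)
    warnings <- c(warnings, sprintf("%d expert matrices failed the consistency test",
                                    n_cons_fail))
  final_w <- aggregate_experts(per_expert_final)
  write_weight_vector(final_w, file.path(out_dir, "partition_weights.csv"))
  say("final weights: %s",
      paste(sprintf("%s=%.3f", names(final_w$weights), final_w$weights),
            collapse = " "))

  # -- material design per group ------------------------------------------
  calibration <- reference_elastic_calibration()
  write_calibration(calibration, file.path(out_dir, "elastic_calibration.csv"))
  designs <- list()
  for (g in config$groups) {
    nodes <- generate_contour_nodes(g, seed = stage_seed(config, 30L))
    geos <- list()
    for (p in postures) {
      geo <- compressed_geometry(nodes, ideals[[p]], maps[[p]])
      layout <- pore_layout(geo, maps[[p]], calibration,
                            bounds_mm = config$bounds_mm)
      if (length(attr(layout, "clamped_partitions")))
        warnings <- c(warnings,
                      sprintf("group %s %s: pore diameter clamped in %s", g, p,
                              paste(attr(layout, "clamped_partitions"), collapse = ",")))
      write_pore_layout(layout,
                        file.path(out_dir, sprintf("pore_layout_%s_%s.csv", g, p)))
      geos[[p]] <- geo
    }
    geo_all <- do.call(rbind, geos)
    utils::write.csv(geo_all,
                     file.path(out_dir, sprintf("partition_geometry_%s.csv", g)),
                     row.names = FALSE)
    designs[[g]] <- geo_all
    say("designed group %s (%d partitions)", g, nrow(geo_all))
  }

  # -- evaluation ----------------------------------------------------------
  reports <- list()
  for (p in postures) {
    rep <- evaluate_prototype(cohorts[[p]], ideals[[p]], maps[[p]],
                              w = NULL, ideal_targets = ideal_partition_targets(p),
                              mode = config$gradient_mode)
    utils::write.csv(rep$trials,
                     file.path(out_dir, sprintf("evaluation_trials_%s.csv", p)),
                     row.names = FALSE)
    utils::write.csv(rep$partitions,
                     file.path(out_dir, sprintf("evaluation_partitions_%s.csv", p)),
                     row.names = FALSE)
    rho <- similarity_comfort_correlation(cohorts[[p]], ideals[[p]])
    say("%s similarity/comfort Spearman rho = %.3f", p, rho)
    reports[[p]] <- list(report = rep, spearman = rho)
  }

  # -- run metadata --------------------------------------------------------
  meta <- list(
    config = unclass(config)[setdiff(names(unclass(config)), "generator")],
    generator = unclass(config$generator),
    partitions = lapply(maps, function(pm) unname(pm$names)),
    total_partitions = sum(vapply(maps, function(pm)
      length(partition_labels(pm)), integer(1))),
    final_weights = as.list(final_w$weights),
    warnings = warnings)
  jsonlite::write_json(meta, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(cohorts = cohorts, ideals = ideals, maps = maps,
                 weights = final_w, designs = designs, reports = reports,
                 warnings = warnings))
}
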