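# File formats.  Pressure matrices travel as delimited text (one sensor row
# per line, kPa) with a `# key=value` header carrying pitch and contact
# threshold; cohorts add a JSON trial manifest; judgment matrices, weight
# vectors, calibrations and pore layouts are small CSV tables.

matrix_header <- function(m) {
  sprintf("# pitch_cm=%.6g contact_threshold_kpa=%.6g", m$pitch_cm,
          m$contact_threshold_kpa)
}

parse_header <- function(line) {
  kv <- regmatches(line, gregexpr("[a-z_]+=[-0-9.eE+]+", line))[[1]]
  vals <- as.numeric(sub(".*=", "", kv))
  stats::setNames(vals, sub("=.*", "", kv))
}

#' Write / read a pressure matrix file
#'
#' Comma-delimited text, one sensor row per line, values in kPa, preceded by
#' a comment header recording the sensor pitch and contact threshold.
#'
#' @param m a [pressure_matrix()] (or `ideal_matrix`, whose mean matrix is
#'   written).
#' @param path file path.
#' @return `read_pressure_matrix` returns a [pressure_matrix()].
#' @export
write_pressure_matrix <- function(m, path) {
  if (inherits(m, "ideal_matrix")) m <- m$matrix
  stopifnot(is_pressure_matrix(m))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(matrix_header(m), con)
  utils::write.table(m$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_matrix
#' @export
read_pressure_matrix <- function(path) {
  if (!file.exists(path)) stop("no such matrix file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  meta <- c(pitch_cm = 0.6, contact_threshold_kpa = 0.1)
  skip <- 0L
  if (startsWith(first, "#")) {
    got <- parse_header(first)
    meta[names(got)] <- got
    skip <- 1L
  }
  sep <- if (grepl("\t", readLines(path, n = skip + 1L)[skip + 1L])) "\t" else ","
  vals <- as.matrix(utils::read.table(path, sep = sep, skip = skip,
                                      header = FALSE))
  pressure_matrix(vals, meta[["pitch_cm"]], meta[["contact_threshold_kpa"]])
}

#' Write / read a trial cohort directory
#'
#' Writes each trial's pressure matrix as a delimited file plus a JSON
#' manifest (`manifest.json`) holding, per trial: matrix file, pillow and
#' subject ids, posture, pitch, the four comfort sub-scores, and the EMG
#' validity flag.
#'
#' @param trials list of [trial_record()]s.
#' @param dir cohort directory (created if needed).
#' @return `read_trial_cohort` returns the list of [trial_record()]s.
#' @export
write_trial_cohort <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(trials), function(i) {
    t <- trials[[i]]
    fn <- sprintf("trial_%03d.csv", i)
    write_pressure_matrix(t$matrix, file.path(dir, fn))
    list(matrix_file = fn, pillow_id = t$pillow_id, subject_id = t$subject_id,
         posture = t$posture, pitch_cm = t$matrix$pitch_cm,
         comfort = list(softness = t$comfort$softness,
                        wrapping = t$comfort$wrapping,
                        support = t$comfort$support, fit = t$comfort$fit),
         emg_valid = t$emg_valid)
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial_cohort
#' @export
read_trial_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing trial manifest: ", mf, call. = FALSE)
  entries <- jsonlite::read_json(mf)
  lapply(entries, function(e) {
    m <- read_pressure_matrix(file.path(dir, e$matrix_file))
    trial_record(e$pillow_id, e$subject_id, e$posture, m,
                 comfort_score(e$comfort$softness, e$comfort$wrapping,
                               e$comfort$support, e$comfort$fit),
                 emg_valid = isTRUE(e$emg_valid))
  })
}

#' Write a partition map
#'
#' The label grid goes to `path` as delimited text; the name table (label,
#' anatomical name, posture) goes to a `_names.csv` side-car.
#'
#' @param pm a [partition_map()].
#' @param path path of the label-grid file.
#' @return invisibly, the paths written.
#' @export
write_partition_map <- function(pm, path) {
  stopifnot(inherits(pm, "partition_map"))
  utils::write.table(pm$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  labs <- partition_labels(pm)
  names_path <- sub("\\.csv$", "", path)
  names_path <- paste0(names_path, "_names.csv")
  utils::write.csv(data.frame(label = labs,
                              name = vapply(labs, function(l) partition_name(pm, l),
                                            character(1)),
                              posture = pm$posture),
                   names_path, row.names = FALSE)
  invisible(c(path, names_path))
}

#' Read a judgment matrix from a delimited table
#'
#' The file may start with a `# scale=... expert=...` comment; otherwise the
#' scale is inferred (complementary if all entries lie in \[0, 1\]).
#'
#' @param path CSV path of the square comparison table (with header row of
#'   partition labels).
#' @return a [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L; scale <- NULL; expert <- NULL
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("scale=(\\w+)", first))[[1]]
    if (length(m) == 2L) scale <- m[2]
    m <- regmatches(first, regexec("expert=([\\w-]+)", first))[[1]]
    if (length(m) == 2L) expert <- m[2]
  }
  tab <- utils::read.csv(path, skip = skip, check.names = FALSE)
  ent <- as.matrix(tab)
  if (is.null(scale)) scale <- if (all(ent >= 0 & ent <= 1)) "complementary" else "nine_level"
  judgment_matrix(ent, scale, labels = colnames(tab), expert_id = expert)
}

#' Write a judgment matrix
#' @param jm a [judgment_matrix()].
#' @param path CSV path.
#' @export
write_judgment_matrix <- function(jm, path) {
  stopifnot(inherits(jm, "judgment_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# scale=%s%s", jm$scale,
                     if (is.null(jm$expert_id)) "" else paste0(" expert=", jm$expert_id)),
             con)
  utils::write.csv(as.data.frame(jm$entries), con, row.names = FALSE)
  invisible(path)
}

#' Write / read a weight vector as a label,weight table
#' @param w a [weight_vector()].
#' @param path CSV path.
#' @export
write_weight_vector <- function(w, path) {
  stopifnot(inherits(w, "weight_vector"))
  utils::write.csv(data.frame(partition = names(w$weights),
                              weight = unname(w$weights), level = w$level),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_vector
#' @export
read_weight_vector <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  weight_vector(stats::setNames(tab$weight, tab$partition),
                level = tab$level[1])
}

#' Write / read an elastic calibration as a 2-column table
#' @param cal an [elastic_calibration()].
#' @param path CSV path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "elastic_calibration"))
  utils::write.csv(cal$pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  tab <- utils::read.csv(path)
  elastic_calibration(tab[[1]], tab[[2]])
}

#' Export a pore layout
#'
#' Writes the hole table as CSV (`x_mm, y_mm, diameter_mm, partition`) and,
#' optionally, a plain-text point list (one `x y d` line per hole) for CAD
#' import.
#'
#' @param layout a `pore_layout`.
#' @param path CSV path.
#' @param point_list optional path of the plain-text point list.
#' @export
write_pore_layout <- function(layout, path, point_list = NULL) {
  stopifnot(inherits(layout, "pore_layout"))
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  if (!is.null(point_list))
    writeLines(sprintf("%.2f %.2f %.2f", layout$x_mm, layout$y_mm,
                       layout$diameter_mm), point_list)
  invisible(path)
}
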