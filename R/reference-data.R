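# Packaged reference tables: the ideal per-partition index targets, the
# per-partition sensitivity weights, the measured pore-diameter/stiffness
# calibration of the 60 D memory foam, the anatomical node roles per
# partition, and the per-partition stiffness verification values for the
# small-physique male group.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "pillowpart")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p)) stop("reference table not found: ", file, call. = FALSE)
  p
}

#' Ideal per-partition body-pressure targets
#'
#' Reference values of the four indices (Pv, Pm kPa; Gm, Gv kPa/cm^2) for
#' each of the seven support partitions of the ideal pressure-distribution
#' matrix.
#'
#' @param posture `"supine"` (A1-A3), `"lateral"` (B1-B4) or `"both"`.
#' @return named list of `pressure_indices` objects, one per partition.
#' @export
ideal_partition_targets <- function(posture = c("both", "supine", "lateral")) {
  posture <- match.arg(posture)
  tab <- utils::read.csv(ref_path("ideal_partition_indices.csv"),
                         stringsAsFactors = FALSE)
  if (posture == "supine") tab <- tab[startsWith(tab$partition, "A"), ]
  if (posture == "lateral") tab <- tab[startsWith(tab$partition, "B"), ]
  out <- lapply(seq_len(nrow(tab)), function(i)
    structure(list(Pv = tab$Pv[i], Pm = tab$Pm[i], Gm = tab$Gm[i],
                   Gv = tab$Gv[i], mode = "reference"),
              class = "pressure_indices"))
  names(out) <- tab$partition
  out
}

#' Reference partition sensitivity weights
#'
#' The expert-panel final pressure-sensitivity weights of the seven
#' partitions (supine A1-A3 and lateral B1-B4; they sum to 1 across both
#' postures, with blocks 0.320 supine / 0.680 lateral). The temporal bone
#' area B3 carries the largest weight, the posterior parietal area A3 the
#' smallest.
#'
#' @return a `"final"` [weight_vector()] over the seven partitions.
#' @export
reference_partition_weights <- function() {
  tab <- utils::read.csv(ref_path("partition_sensitivity_weights.csv"),
                         stringsAsFactors = FALSE)
  w <- tab$weight / sum(tab$weight)
  names(w) <- tab$partition
  weight_vector(w, "final")
}

#' Reference pore-diameter / stiffness calibration
#'
#' Measured equivalent elastic coefficients of 110 mm, 60 D memory foam
#' drilled with a staggered 30 mm-pitch pore array, for pore diameters 6-21
#' mm, fitted with the package's power law (see [fit_power_law()]).
#'
#' @return an [elastic_calibration()].
#' @export
reference_elastic_calibration <- function() {
  tab <- utils::read.csv(ref_path("pore_elasticity_calibration.csv"),
                         stringsAsFactors = FALSE)
  elastic_calibration(tab$diameter_mm, tab$k)
}

#' Anatomical node role of each partition
#'
#' @return data.frame with columns `partition`, `region`, `node`.
#' @export
partition_node_roles <- function() {
  utils::read.csv(ref_path("partition_nodes.csv"), stringsAsFactors = FALSE)
}

#' Reference per-partition stiffness (small-physique male group)
#'
#' Calculated and actually measured equivalent elastic coefficients per
#' partition for the MS group prototype, with their printed relative errors.
#'
#' @return data.frame with columns `partition`, `k_calculated`, `k_actual`,
#'   `error_pct`.
#' @export
reference_partition_stiffness <- function() {
  utils::read.csv(ref_path("ms_partition_stiffness.csv"), stringsAsFactors = FALSE)
}
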