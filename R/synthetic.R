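# Seeded synthetic-data generators emulating the study inputs: smooth
# multi-bump supine/lateral pressure fields with realistic index magnitudes,
# pillow cohorts whose comfort responses favour closeness to the posture
# template, nine-level expert panels, anthropometric contour nodes for four
# physique groups, and pore/stiffness calibrations.
#
# All generators are pure functions of (config, seed).  The templates are
# phenomenological: plateau-like support zones joined by saddles, with a
# single dominant peak (occipital apex when supine, temporal bone when
# lateral), not a biomechanical contact simulation.

# super-Gaussian profile: flat top, controllable edge sharpness
sg_profile <- function(z, center, width, power = 4) {
  exp(-(abs(z - center) / width)^power)
}

# one separable 1-2-1 binomial smoothing pass (edge-replicated); applied to
# the deterministic template so zone transitions stay mat-resolution smooth
smooth_field <- function(m) {
  k <- c(0.25, 0.5, 0.25)
  for (pass in 1:2) {
    pad <- rbind(m[1, ], m, m[nrow(m), ])
    m <- k[1] * pad[seq_len(nrow(m)), ] + k[2] * pad[seq_len(nrow(m)) + 1L, ] +
         k[3] * pad[seq_len(nrow(m)) + 2L, ]
    m <- t(m)
  }
  m
}

#' Synthetic-data generator configuration
#'
#' Defaults encode the emulated study conditions: a 32 x 32 sensor grid at
#' 0.6 cm pitch (a desk-scale stand-in for a 1200-point pressure mat), 7
#' pillows x 6 subjects per posture, spatially correlated measurement noise,
#' and a comfort response whose mean decreases with cosine distance to the
#' posture template, with deviation of the mean pressure gradient from 0.3
#' kPa/cm^2, and with peak-pressure excess.
#'
#' @param grid c(rows, cols) of the sensor grid.
#' @param pitch_cm sensor pitch in cm.
#' @param contact_threshold_kpa contact threshold in kPa.
#' @param noise_sd_kpa standard deviation of the correlated measurement
#'   noise, kPa.
#' @param n_pillows,n_subjects cohort design (default 7 x 6 = 42 trials per
#'   posture).
#' @param max_severity distortion magnitude of the worst pillow; pillow p
#'   gets severity `(p-1)/(n_pillows-1) * max_severity`, so pillow 1 matches
#'   the template.
#' @param comfort list of comfort-response coefficients: `intercept`,
#'   `sim_slope` (penalty per unit of 1 - similarity), `gv_coef`,
#'   `gv_target`, `pm_coef`, `pm_cap`, `noise_sd`.
#' @return a `generator_config` list.
#' @export
generator_config <- function(grid = c(32L, 32L), pitch_cm = 0.6,
                             contact_threshold_kpa = 0.1,
                             noise_sd_kpa = 0.10,
                             n_pillows = 7L, n_subjects = 6L,
                             max_severity = 1,
                             comfort = list(intercept = 5.05, sim_slope = 34,
                                            gv_coef = 2.0, gv_target = 0.30,
                                            pm_coef = 0.5, pm_cap = 9.21,
                                            noise_sd = 0.35)) {
  stopifnot(length(grid) == 2L, all(grid >= 8L), pitch_cm > 0)
  structure(list(grid = as.integer(grid), pitch_cm = pitch_cm,
                 contact_threshold_kpa = contact_threshold_kpa,
                 noise_sd_kpa = noise_sd_kpa,
                 n_pillows = as.integer(n_pillows),
                 n_subjects = as.integer(n_subjects),
                 max_severity = max_severity, comfort = comfort),
            class = "generator_config")
}

# component parameter sets for the posture templates; amplitudes in kPa,
# positions/widths in cell units of the reference 32 x 32 grid (scaled for
# other grid sizes)
template_components <- function(posture) {
  if (posture == "supine") {
    list(
      bands = list(
        # posterior neck support zone
        list(amp = 2.35, r0 = 6.0, rw = 3.2, rp = 4),
        # saddle joining the neck zone to the occipital zone
        list(amp = 1.55, r0 = 10.8, rw = 2.0, rp = 2),
        # occipital support zone (carries the apex dome)
        list(amp = 3.60, r0 = 15.8, rw = 3.8, rp = 4),
        # posterior parietal zone (light support)
        list(amp = 1.10, r0 = 25.5, rw = 3.0, rp = 4)),
      colw = list(c0 = 16.5, cw = 10.0, cp = 6),
      dome = list(amp = 5.60, r0 = 15.8, c0 = 16.5, sigma = 2.4))
  } else {
    list(
      bands = list(
        # cervical strip along the neck edge
        list(amp = 2.45, r0 = 5.5, rw = 2.8, rp = 4,
             c0 = 17.0, cw = 7.5, cp = 6),
        # saddle joining the cervical strip to the temporal zone
        list(amp = 2.05, r0 = 10.3, rw = 2.4, rp = 2,
             c0 = 17.0, cw = 5.0, cp = 4),
        # temporal bone zone: the main support area, carries the peak
        list(amp = 3.55, r0 = 17.0, rw = 4.2, rp = 4,
             c0 = 18.0, cw = 6.5, cp = 6),
        # jaw island on the anterior side, separated by a low moat
        list(amp = 2.30, r0 = 16.0, rw = 4.0, rp = 4,
             c0 = 5.0, cw = 2.6, cp = 4),
        # lateral parietal zone (light support)
        list(amp = 1.10, r0 = 27.5, rw = 2.6, rp = 4,
             c0 = 17.0, cw = 7.0, cp = 6),
        # faint moat floor keeping the jaw island on the contact footprint
        list(amp = 0.45, r0 = 16.0, rw = 4.5, rp = 4,
             c0 = 8.5, cw = 2.0, cp = 2),
        # low bridge keeping the parietal zone on the contact footprint
        list(amp = 0.50, r0 = 22.5, rw = 2.2, rp = 2,
             c0 = 17.0, cw = 5.0, cp = 4)),
      colw = NULL,
      dome = list(amp = 5.50, r0 = 17.0, c0 = 17.5, sigma = 2.4))
  }
}

# evaluate the (optionally perturbed) template on the grid; `extent` scales
# the contact footprint about the grid center (widths and positions alike)
eval_template <- function(posture, grid, perturb = NULL, extent = 0.73) {
  comps <- template_components(posture)
  sr <- grid[1] / 32; sc <- grid[2] / 32
  pr <- function(z) 16.5 + (z - 16.5) * extent  # reference-frame position

  rr <- matrix(seq_len(grid[1]), grid[1], grid[2])
  cc <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  p <- matrix(0, grid[1], grid[2])
  amp_scale <- if (is.null(perturb)) 1 else perturb$amp_scale
  for (i in seq_along(comps$bands)) {
    b <- comps$bands[[i]]
    dr <- 0; dc <- 0; ws <- 1; as_ <- 1
    if (!is.null(perturb)) {
      dr <- perturb$dr[i]; dc <- perturb$dc[i]
      ws <- perturb$width_scale[i]; as_ <- perturb$amp_jitter[i]
    }
    prof <- sg_profile(rr, pr(b$r0 + dr) * sr, b$rw * ws * extent * sr, b$rp)
    if (!is.null(b$c0)) {
      prof <- prof * sg_profile(cc, pr(b$c0 + dc) * sc, b$cw * ws * extent * sc, b$cp)
    }
    p <- p + b$amp * as_ * prof
  }
  if (!is.null(comps$colw)) {
    cwp <- comps$colw
    p <- p * sg_profile(cc, pr(cwp$c0) * sc, cwp$cw * extent * sc, cwp$cp)
  }
  d <- comps$dome
  dda <- 1; ddr <- 0; ddc <- 0
  if (!is.null(perturb)) { dda <- perturb$dome_scale; ddr <- perturb$dome_dr; ddc <- perturb$dome_dc }
  p <- p + d$amp * dda *
    exp(-(((rr - pr(d$r0 + ddr) * sr)^2 + (cc - pr(d$c0 + ddc) * sc)^2)) /
          (2 * (d$sigma * extent * sr)^2))
  smooth_field(p) * amp_scale
}

# spatially correlated noise: white noise smoothed with a 3x3 kernel twice,
# rescaled to the requested sd
correlated_noise <- function(grid, sd) {
  z <- matrix(stats::rnorm(prod(grid)), grid[1], grid[2])
  k <- c(0.25, 0.5, 0.25)
  smooth1 <- function(m) {
    sm <- m
    for (pass in 1:2) {
      pad <- rbind(sm[1, ], sm, sm[nrow(sm), ])
      sm <- k[1] * pad[seq_len(nrow(sm)), ] + k[2] * pad[seq_len(nrow(sm)) + 1L, ] +
            k[3] * pad[seq_len(nrow(sm)) + 2L, ]
      sm <- t(sm)
    }
    sm
  }
  z <- smooth1(z)
  z / stats::sd(z) * sd
}

# deterministic per-trial perturbation; severity 0 = exact template
draw_perturb <- function(n_components, severity) {
  list(amp_scale = 1 + severity * stats::rnorm(1, 0, 0.15),
       amp_jitter = 1 + severity * stats::rnorm(n_components, 0, 0.25),
       dr = severity * stats::rnorm(n_components, 0, 1.8),
       dc = severity * stats::rnorm(n_components, 0, 1.8),
       width_scale = pmax(0.4, 1 + severity * stats::rnorm(n_components, 0, 0.2)),
       dome_scale = 1 + severity * stats::rnorm(1, 0, 0.25),
       dome_dr = severity * stats::rnorm(1, 0, 1.5),
       dome_dc = severity * stats::rnorm(1, 0, 1.5))
}

#' Generate one synthetic pressure matrix
#'
#' Evaluates the posture template (sum of plateau-like support zones plus
#' the apex dome), optionally distorted, adds spatially correlated noise
#' within the contact footprint, and thresholds: cells below the contact
#' threshold are set to 0.
#'
#' @param posture `"supine"` or `"lateral"`.
#' @param config a [generator_config()].
#' @param seed integer seed; the same seed gives a bit-identical matrix.
#' @param severity distortion magnitude in \[0, 1\]; 0 (default) returns the
#'   noisy template.
#' @param noise_sd_kpa override of the config noise level (set 0 for the
#'   exact template).
#' @return a [pressure_matrix()].
#' @export
generate_pressure_matrix <- function(posture = c("supine", "lateral"),
                                     config = generator_config(), seed = 1L,
                                     severity = 0, noise_sd_kpa = NULL) {
  posture <- match.arg(posture)
  if (is.null(noise_sd_kpa)) noise_sd_kpa <- config$noise_sd_kpa
  grid <- config$grid
  ncomp <- length(template_components(posture)$bands)
  with_seed(seed, {
    perturb <- if (severity > 0) draw_perturb(ncomp, severity) else NULL
    p <- eval_template(posture, grid, perturb)
    if (noise_sd_kpa > 0) {
      nz <- correlated_noise(grid, noise_sd_kpa)
      p <- p + nz * (p > 0.05)  # keep off-body cells quiet
    }
    p[p < config$contact_threshold_kpa] <- 0
    pressure_matrix(p, config$pitch_cm, config$contact_threshold_kpa)
  })
}

#' Generate a synthetic trial cohort
#'
#' Emulates the 7-pillow x 6-subject design for one posture. Pillow p
#' distorts the template with severity `(p-1)/(n_pillows-1) * max_severity`
#' (pillow 1 reproduces it), each subject adds a small idiosyncratic
#' distortion, and the four comfort sub-scores are drawn from an ordered
#' response whose mean decreases with cosine distance to the template, with
#' `|Gv - 0.3|`, and with peak-pressure excess. All trials are `emg_valid`.
#'
#' @param config a [generator_config()].
#' @param posture `"supine"` or `"lateral"`.
#' @param seed integer seed.
#' @return list of `n_pillows * n_subjects` [trial_record()]s.
#' @export
generate_trial_cohort <- function(config = generator_config(),
                                  posture = c("supine", "lateral"),
                                  seed = 1L) {
  posture <- match.arg(posture)
  template <- generate_pressure_matrix(posture, config, seed = 0L,
                                       noise_sd_kpa = 0)
  cf <- config$comfort
  ncomp <- length(template_components(posture)$bands)
  trials <- list()
  with_seed(seed, {
    for (p in seq_len(config$n_pillows)) {
      sev_p <- (p - 1) / max(config$n_pillows - 1, 1) * config$max_severity
      for (s in seq_len(config$n_subjects)) {
        sev <- sev_p + 0.04  # small idiosyncratic subject distortion
        perturb <- draw_perturb(ncomp, sev)
        m <- eval_template(posture, config$grid, perturb)
        m <- m + correlated_noise(config$grid, config$noise_sd_kpa) * (m > 0.05)
        m[m < config$contact_threshold_kpa] <- 0
        pmat <- pressure_matrix(m, config$pitch_cm, config$contact_threshold_kpa)
        sim <- cosine_similarity(pmat, template)
        gv <- mean_gradient(pmat, "pointwise")
        pmx <- peak_pressure(pmat)
        latent <- cf$intercept - cf$sim_slope * (1 - sim) -
          cf$gv_coef * abs(gv - cf$gv_target) -
          cf$pm_coef * max(0, pmx - cf$pm_cap)
        sub <- pmin(5L, pmax(1L, round(latent + stats::rnorm(4, 0, cf$noise_sd))))
        trials[[length(trials) + 1L]] <- trial_record(
          pillow_id = sprintf("P%d", p), subject_id = sprintf("S%d", s),
          posture = posture, matrix = pmat,
          comfort = comfort_score(sub[1], sub[2], sub[3], sub[4]))
      }
    }
  })
  trials
}

#' Synthetic ideal matrix for one posture
#'
#' Convenience wrapper running the front half of the pipeline on synthetic
#' data: generates a cohort, ranks it by comfort, and averages the top
#' fraction into the approximate ideal pressure-distribution matrix.
#'
#' @inheritParams generate_trial_cohort
#' @param fraction,round_mode passed to [build_ideal_matrix()].
#' @return an `ideal_matrix`.
#' @export
synthetic_ideal_matrix <- function(posture = c("supine", "lateral"),
                                   config = generator_config(), seed = 1L,
                                   fraction = 0.10, round_mode = "floor") {
  posture <- match.arg(posture)
  cohort <- generate_trial_cohort(config, posture, seed)
  build_ideal_matrix(cohort, posture, fraction = fraction,
                     round_mode = round_mode)
}

#' Generate a synthetic expert panel
#'
#' Each expert scores every partition pair on a continuous nine-level
#' strength scale derived from the true sensitivities: the noise-free score
#' is `a_ij = 10 * clamp(0.5 + (n-1)(s_i - s_j), 0.1, 0.9)` with
#' `a_ji = 10 - a_ij`, which the FAHP row-sum weighting inverts (up to
#' scale saturation) back to the sensitivities. Expert-specific noise is
#' added on the score scale.
#'
#' @param n_experts panel size (default 10).
#' @param true_sensitivities named positive vector; defaults to the packaged
#'   reference partition weights.
#' @param noise sd of the additive score noise (default 0.5).
#' @param seed integer seed.
#' @return list of nine-level [judgment_matrix()]s, one per expert.
#' @export
generate_expert_panel <- function(n_experts = 10L, true_sensitivities = NULL,
                                  noise = 0.5, seed = 1L) {
  if (is.null(true_sensitivities))
    true_sensitivities <- reference_partition_weights()$weights
  s <- true_sensitivities / sum(true_sensitivities)
  if (any(s <= 0)) stop("sensitivities must be positive", call. = FALSE)
  n <- length(s)
  base <- outer(s, s, function(a, b) pmin(pmax(0.5 + (n - 1) * (a - b), 0.1), 0.9)) * 10
  with_seed(seed, {
    lapply(seq_len(n_experts), function(e) {
      a <- base
      if (noise > 0) {
        eps <- matrix(stats::rnorm(n * n, 0, noise), n, n)
        eps[lower.tri(eps, diag = TRUE)] <- 0
        a <- a + eps - t(eps)  # keep a_ij + a_ji = 10
        a <- pmin(pmax(a, 1), 9)
        # re-impose a_ij + a_ji = 10 where truncation broke it
        a[lower.tri(a)] <- (10 - t(a))[lower.tri(a)]
      }
      diag(a) <- 5
      judgment_matrix(a, "nine_level", labels = names(s),
                      expert_id = sprintf("E%d", e))
    })
  })
}

# physique scale factors relative to the small-male group (stature ratios)
GROUP_SCALE <- c(MS = 1.000, ML = 1.081, FS = 0.912, FL = 1.028)

# base compression depths (mm) of the small-male group at each partition
# node, calibrated so the noiseless posture templates' partition forces and
# these depths reproduce published-magnitude equivalent stiffnesses
MS_BASE_DEPTH <- c(A1 = 74, A2 = 62, A3 = 33, B1 = 22, B2 = 3.4, B3 = 48, B4 = 30)

#' Generate contour nodes for a physique group
#'
#' Node depths are the small-male base depths scaled by the group's stature
#' ratio, plus a small node-wise irregularity that is shared across groups
#' for a given seed (so larger physiques are deeper at every node).
#'
#' @param group `"MS"`, `"ML"`, `"FS"` or `"FL"`.
#' @param seed integer seed for the shared node irregularity.
#' @param jitter_sd relative sd of the node irregularity (default 0.02).
#' @return a [contour_nodes()].
#' @export
generate_contour_nodes <- function(group = c("MS", "ML", "FS", "FL"),
                                   seed = 1L, jitter_sd = 0.02) {
  group <- match.arg(group)
  jit <- with_seed(seed, stats::rnorm(length(MS_BASE_DEPTH), 0, jitter_sd))
  depth <- pmax(MS_BASE_DEPTH * (1 + jit), 1) * GROUP_SCALE[[group]]
  x <- stats::setNames(seq(60, 440, length.out = length(depth)), names(depth))
  contour_nodes(group, depth, x_mm = x)
}

#' Generate a stiffness calibration table
#'
#' Inverts the power law `d = a * k^b` on a diameter grid and adds optional
#' relative noise; a noiseless table round-trips through [fit_power_law()]
#' exactly.
#'
#' @param a,b power-law coefficients (defaults match the packaged reference
#'   calibration fit).
#' @param d_grid pore diameters in mm.
#' @param noise relative sd of multiplicative noise on k (default 0).
#' @param seed integer seed, used when `noise > 0`.
#' @return an [elastic_calibration()].
#' @export
generate_calibration <- function(a = 3.613, b = -0.769,
                                 d_grid = seq(6, 21, by = 3), noise = 0,
                                 seed = 1L) {
  k <- (d_grid / a)^(1 / b)
  if (noise > 0)
    k <- with_seed(seed, k * exp(stats::rnorm(length(k), 0, noise)))
  elastic_calibration(d_grid, k)
}
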