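#' Ground-truth LEM to mMKM dose relation of the synthetic generator
#'
#' The generator links the two RBE languages through a single quadratic map
#' `D_MKM = a*D_LEM^2 + b*D_LEM + c`.  Its coefficients are the least-squares
#' quadratic through the four published (translated D_LEM, nominal D_MKM)
#' constraint pairs (42.9, 28.8), (57.7, 46.4), (68.2, 60.0), (72.0, 66.0)
#' Gy(RBE), computed once from the normal equations and frozen here.  The map
#' is increasing on the clinical dose range and maps every LEM dose in
#' [10, 80] Gy(RBE) to a strictly smaller mMKM dose, reproducing the LEM
#' over-estimation of RBE-weighted dose in organs at risk.
#'
#' @return named numeric vector `c(a = ..., b = ..., c = ...)`.
#' @export
default_truth_relation <- function() {
  c(a = 0.00651188379688, b = 0.52173026963, c = -5.53576864653)
}

#' Synthetic cohort configuration
#'
#' Describes the simulated patient population: three groups on a 16-fraction
#' schedule (22 prostate adenocarcinoma at 66.4 Gy(RBE), 28 low-dose sacral
#' chordoma at 70.4, 13 high-dose sacral chordoma at 73.6), rectum volumes
#' from truncated normal distributions (prostate 59 +/- 15 cc, sacrum
#' 91 +/- 39 cc, truncated at 10 cc), a parametric LEM DVH family and the
#' quadratic LEM-to-mMKM truth map plus noise.
#'
#' The LEM cumulative DVH of each patient is a two-component logistic
#' mixture in dose: a bulk falloff (most of the rectum at low dose) plus a
#' small hot-spot plateau near the prescription where the rectum abuts the
#' target.  Group-level shape parameters are chosen so mMKM EUDs land near
#' the clinically reported neighbourhoods (prostate around 50-55 Gy(RBE),
#' sacrum around 35-45): the sacral groups are planned to stricter PRV
#' limits, hence the lower hot-spot fractions of prescription.  The mMKM
#' curve is the LEM curve with its dose axis mapped through the truth
#' relation plus a per-patient offset and a smooth heteroscedastic noise
#' field whose SD grows linearly with dose (scatter widens at high dose).
#'
#' @param group_sizes named integer vector, patients per group.
#' @param prescriptions named numeric vector, total prescription dose
#'   Gy(RBE) per group.
#' @param n_fractions fractions per course.
#' @param volume_mean,volume_sd,volume_min rectum-volume distribution (cc):
#'   per-tumour-site truncated normals.
#' @param dvh_shape per-group DVH family parameters; see Details.  Each
#'   group needs `f_low`/`f_low_sd` (bulk falloff midpoint as a fraction of
#'   prescription), `w_low` (bulk width fraction), `f_high`/`f_high_sd`
#'   (hot-spot midpoint fraction), `w_high` (hot-spot width fraction) and
#'   `hot_frac`/`hot_frac_sd` (volume fraction in the hot-spot component).
#' @param truth_relation numeric `(a, b, c)` of the LEM to mMKM map.
#' @param noise_slope residual SD per Gy(RBE) of mMKM dose noise
#'   (heteroscedastic, `sd(d) = noise_slope * d`), default 0.03.
#' @param patient_effect_sd SD of the per-patient additive offset, Gy(RBE).
#' @param bin_width DVH bin width, Gy(RBE).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c(prostate = 22L, l_sac = 28L, h_sac = 13L),
    prescriptions = c(prostate = 66.4, l_sac = 70.4, h_sac = 73.6),
    n_fractions = 16L,
    volume_mean = c(prostate = 59, sacrum = 91),
    volume_sd = c(prostate = 15, sacrum = 39),
    volume_min = 10,
    dvh_shape = default_dvh_shape(),
    truth_relation = default_truth_relation(),
    noise_slope = 0.03,
    patient_effect_sd = 0.5,
    bin_width = 0.1) {
  if (length(group_sizes) == 0L || any(group_sizes < 1))
    stop("group sizes must be >= 1")
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("`group_sizes` must be a named vector")
  if (!all(names(group_sizes) %in% names(prescriptions)))
    stop("every group needs a prescription")
  if (any(prescriptions <= 0)) stop("prescriptions must be > 0")
  if (any(c(volume_sd, volume_min) < 0) || any(volume_mean <= 0))
    stop("invalid volume distribution")
  if (noise_slope < 0 || patient_effect_sd < 0) stop("SDs must be >= 0")
  if (length(truth_relation) != 3L) stop("truth_relation must be (a, b, c)")
  structure(
    list(group_sizes = group_sizes, prescriptions = prescriptions,
         n_fractions = as.integer(n_fractions), volume_mean = volume_mean,
         volume_sd = volume_sd, volume_min = volume_min,
         dvh_shape = dvh_shape, truth_relation = truth_relation,
         noise_slope = noise_slope, patient_effect_sd = patient_effect_sd,
         bin_width = bin_width),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_dvh_shape <- function() {
  list(
    prostate = list(f_low = 0.25, f_low_sd = 0.04, w_low = 0.10,
                    f_high = 0.95, f_high_sd = 0.015, w_high = 0.02,
                    hot_frac = 0.08, hot_frac_sd = 0.02),
    l_sac = list(f_low = 0.22, f_low_sd = 0.05, w_low = 0.10,
                 f_high = 0.68, f_high_sd = 0.05, w_high = 0.025,
                 hot_frac = 0.05, hot_frac_sd = 0.02),
    h_sac = list(f_low = 0.22, f_low_sd = 0.06, w_low = 0.10,
                 f_high = 0.66, f_high_sd = 0.08, w_high = 0.025,
                 hot_frac = 0.05, hot_frac_sd = 0.02)
  )
}

# truncated-normal draw by rejection (uses the current RNG stream)
rtruncnorm1 <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}

# volume-distribution site for a group
volume_site <- function(group) if (group == "prostate") "prostate" else "sacrum"

#' Generate one synthetic patient (paired LEM/mMKM rectum DVHs)
#'
#' Draws a rectum volume from the group distribution, a LEM DVH from the
#' parametric family scaled to the group prescription (hot-spot D_1% below
#' prescription), and derives the mMKM DVH by mapping the LEM dose axis
#' through the truth relation plus patient offset and smooth heteroscedastic
#' noise, re-binned onto a regular grid with monotonicity preserved.
#' Consumes the current RNG stream; seed upstream (e.g. via
#' [generate_cohort()]) for reproducibility.
#'
#' @param config a [cohort_config()].
#' @param group group name, one of `names(config$group_sizes)`.
#' @param patient_id identifier stamped on both DVHs.
#' @return list with `patient_id`, `group`, `prescription`, `n_fractions`,
#'   `volume_cc`, `dvh_lem`, `dvh_mkm`.
#' @export
generate_patient <- function(config, group, patient_id = "p001") {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$group_sizes))
    stop(sprintf("unknown group '%s'", group))
  P <- config$prescriptions[[group]]
  sh <- config$dvh_shape[[group]]
  site <- volume_site(group)
  vol <- rtruncnorm1(config$volume_mean[[site]], config$volume_sd[[site]],
                     config$volume_min)

  # patient-level DVH shape draws; midpoints kept inside sane fractions
  f_low <- min(max(stats::rnorm(1, sh$f_low, sh$f_low_sd), 0.10), 0.60)
  f_high <- min(max(stats::rnorm(1, sh$f_high, sh$f_high_sd), f_low + 0.15),
                0.955)
  h <- min(max(stats::rnorm(1, sh$hot_frac, sh$hot_frac_sd), 0.01), 0.25)

  bw <- config$bin_width
  # hard maximum dose five hot-spot widths above the hot-spot midpoint
  # (capped near prescription): physical plans have a finite D_max, and the
  # n = 0.035 power mean is sensitive to arbitrarily thin logistic tails
  d_max <- min(f_high + 5 * sh$w_high, 1.02) * P
  edges <- seq(0, by = bw, length.out = ceiling(d_max / bw) + 2L)
  fam <- function(d)
    (1 - h) * stats::plogis((f_low * P - d) / (sh$w_low * P)) +
    h * stats::plogis((f_high * P - d) / (sh$w_high * P))
  raw <- pmax(fam(edges) - fam(d_max), 0)
  cum <- raw / raw[1]
  cum[1] <- 1; cum[length(cum)] <- 0
  cum <- rev(cummax(rev(cum)))  # guard against numeric wiggle
  dvh_lem <- new_dvh(edges, cum, vol, rbe_model = "LEM",
                     structure = "rectum", patient_id = patient_id)

  # mMKM dose axis: truth map + patient offset + smooth noise field
  tr <- config$truth_relation
  u <- stats::rnorm(1, 0, config$patient_effect_sd)
  m <- tr[1] * edges^2 + tr[2] * edges + tr[3] + u
  if (config$noise_slope > 0) {
    # smooth noise field with a correlation length (4 Gy(RBE)) well below
    # the spacing of the extracted v-level doses, so per-point residuals are
    # close to independent while the dose axis stays locally monotone
    n_knots <- max(3L, ceiling(max(edges) / 4) + 1L)
    knots <- seq(0, max(edges), length.out = n_knots)
    z <- stats::rnorm(n_knots)
    zfun <- stats::approxfun(knots, z, rule = 2)
    m <- m + config$noise_slope * edges * zfun(edges)
  }
  m <- pmax(cummax(m), 0)
  # strictly increasing support for interpolation
  m <- m + seq_along(m) * 1e-9
  edges2 <- seq(0, by = bw, length.out = ceiling(max(m) / bw) + 2L)
  cum2 <- stats::approx(m, cum, xout = edges2, yleft = 1, yright = 0,
                        ties = "ordered")$y
  cum2 <- pmin(pmax(rev(cummax(rev(cum2))), 0), 1)
  cum2[1] <- 1; cum2[length(cum2)] <- 0
  dvh_mkm <- new_dvh(edges2, cum2, vol, rbe_model = "MKM",
                     structure = "rectum", patient_id = patient_id)

  list(patient_id = patient_id, group = group, prescription = P,
       n_fractions = config$n_fractions, volume_cc = vol,
       dvh_lem = dvh_lem, dvh_mkm = dvh_mkm)
}

#' Generate a full synthetic cohort
#'
#' Draws all patients group by group from a single seeded RNG stream and
#' optionally writes per-patient DVH CSV files plus a manifest.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param dir optional output directory; when given, DVHs are written as
#'   `<patient_id>_{lem,mkm}.csv` and the manifest as `manifest.csv`.
#' @return list with `manifest` (data frame `patient_id, group,
#'   prescription_gy_rbe, n_fractions, rectum_volume_cc, dvh_lem_path,
#'   dvh_mkm_path`) and `patients` (list from [generate_patient()]).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  patients <- list()
  k <- 0L
  for (g in names(config$group_sizes)) {
    for (i in seq_len(config$group_sizes[[g]])) {
      k <- k + 1L
      pid <- sprintf("%s_%02d", g, i)
      patients[[k]] <- generate_patient(config, g, pid)
    }
  }
  lem_path <- rep(NA_character_, k); mkm_path <- rep(NA_character_, k)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(k)) {
      p <- patients[[i]]
      lem_path[i] <- file.path(dir, paste0(p$patient_id, "_lem.csv"))
      mkm_path[i] <- file.path(dir, paste0(p$patient_id, "_mkm.csv"))
      write_dvh(p$dvh_lem, lem_path[i])
      write_dvh(p$dvh_mkm, mkm_path[i])
    }
  }
  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    group = vapply(patients, `[[`, "", "group"),
    prescription_gy_rbe = vapply(patients, `[[`, 0, "prescription"),
    n_fractions = vapply(patients, `[[`, 0L, "n_fractions"),
    rectum_volume_cc = vapply(patients, `[[`, 0, "volume_cc"),
    dvh_lem_path = lem_path, dvh_mkm_path = mkm_path,
    stringsAsFactors = FALSE)
  if (!is.null(dir))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, patients = patients)
}

#' Extract paired dose-volume points from a cohort
#'
#' For each patient and volume level, reads `D_LEM|v` and `D_MKM|v` off the
#' paired DVHs — the long-format input of [fit_quadratic()].
#'
#' @param cohort result of [generate_cohort()] (or any list with a
#'   `patients` element of the same shape).
#' @param v_levels numeric vector of volume percentages (default
#'   `c(1, 5, 10, 20)`).
#' @return data frame `patient_id, group, v_kind, v_amount, d_lem, d_mkm`.
#' @export
extract_paired_points <- function(cohort, v_levels = c(1, 5, 10, 20)) {
  if (any(v_levels <= 0 | v_levels > 100)) stop("v_levels must be in (0, 100]")
  rows <- lapply(cohort$patients, function(p) {
    data.frame(
      patient_id = p$patient_id, group = p$group,
      v_kind = "percent", v_amount = v_levels,
      d_lem = vapply(v_levels, function(v)
        dose_at_volume(p$dvh_lem, "percent", v), numeric(1)),
      d_mkm = vapply(v_levels, function(v)
        dose_at_volume(p$dvh_mkm, "percent", v), numeric(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
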