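#' Cumulative dose-volume histogram (DVH)
#'
#' Container for a cumulative DVH: `cum_volume_fraction[i]` is the fraction of
#' the structure volume receiving at least `dose_edges[i]` Gy(RBE).  The curve
#' starts at 1, ends at 0 and is monotone non-increasing; dose edges are
#' strictly increasing.  Doses are totals for the full treatment course.
#'
#' @param dose_edges strictly increasing dose bin edges, Gy(RBE).
#' @param cum_volume_fraction fractions in `[0, 1]`, same length as
#'   `dose_edges`, monotone non-increasing, first value 1, last value 0.
#' @param total_volume_cc structure volume in cc (> 0).
#' @param rbe_model `"LEM"` or `"MKM"`.
#' @param structure structure name.
#' @param patient_id optional patient identifier.
#' @return An object of class `dvh`.
#' @export
new_dvh <- function(dose_edges, cum_volume_fraction, total_volume_cc,
                    rbe_model = c("LEM", "MKM"), structure = "structure",
                    patient_id = NA_character_) {
  rbe_model <- match.arg(rbe_model)
  dose_edges <- as.numeric(dose_edges)
  cum <- as.numeric(cum_volume_fraction)
  if (length(dose_edges) < 2L || length(cum) != length(dose_edges))
    stop("dose_edges and cum_volume_fraction must have equal length >= 2")
  if (any(!is.finite(dose_edges)) || any(!is.finite(cum)))
    stop("DVH values must be finite")
  if (any(diff(dose_edges) <= 0))
    stop("dose_edges must be strictly increasing")
  tol <- 1e-9
  if (any(cum < -tol) || any(cum > 1 + tol))
    stop("cum_volume_fraction must lie in [0, 1]")
  if (any(diff(cum) > tol))
    stop("cum_volume_fraction must be monotone non-increasing")
  if (abs(cum[1] - 1) > tol)
    stop("cum_volume_fraction must start at 1")
  if (abs(cum[length(cum)]) > tol)
    stop("cum_volume_fraction must end at 0")
  if (!is.finite(total_volume_cc) || total_volume_cc <= 0)
    stop("total_volume_cc must be > 0")
  cum <- pmin(pmax(cum, 0), 1)
  structure(
    list(dose_edges = dose_edges, cum_volume_fraction = cum,
         total_volume_cc = total_volume_cc, rbe_model = rbe_model,
         structure = structure, patient_id = patient_id),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> %s [%s]%s  volume %.2f cc, dose 0-%.1f Gy(RBE), %d bins\n",
    x$structure, x$rbe_model,
    if (is.na(x$patient_id)) "" else paste0(" patient ", x$patient_id),
    x$total_volume_cc, max(x$dose_edges), length(x$dose_edges)))
  invisible(x)
}

#' Compute a cumulative DVH from a dose grid and structure mask
#'
#' Bins the masked voxel doses onto edges `0, bin_width, 2*bin_width, ...`
#' extending one bin beyond the maximum dose, so the curve reaches 0.  At each
#' edge `d` the value is the fraction of masked voxels with dose `>= d`.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] congruent with `grid`.
#' @param bin_width dose bin width in Gy(RBE), default 0.1 (sub-clinical
#'   reporting precision).
#' @return a [new_dvh()] object.
#' @export
compute_dvh <- function(grid, mask, bin_width = 0.1) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!identical(dim(grid$values), dim(mask$mask)))
    stop("mask shape does not match dose grid shape")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0")
  doses <- grid$values[mask$mask]
  if (length(doses) == 0L) stop("empty structure")
  dmax <- max(doses)
  n_edge <- max(2L, ceiling(dmax / bin_width) + 2L)
  edges <- seq(0, by = bin_width, length.out = n_edge)
  sorted <- sort(doses)
  n <- length(sorted)
  # count of doses >= edge; the tiny offset makes `>=` inclusive despite
  # floating-point edge placement
  cum <- (n - findInterval(edges - bin_width * 1e-9, sorted)) / n
  cum[1] <- 1
  cum[n_edge] <- 0
  new_dvh(edges, cum, mask_volume_cc(mask, grid),
          rbe_model = grid$rbe_model, structure = mask$name)
}

# resolve a volume spec to a fraction of the structure volume
resolve_volume_fraction <- function(dvh, kind, amount) {
  kind <- match.arg(kind, c("percent", "cc"))
  if (!is.finite(amount) || amount <= 0) stop("volume amount must be > 0")
  if (kind == "percent") {
    if (amount > 100) stop("percent volume spec must lie in (0, 100]")
    amount / 100
  } else {
    if (amount > dvh$total_volume_cc + 1e-9)
      stop(sprintf("cc volume spec (%.3g) exceeds structure volume (%.3g cc)",
                   amount, dvh$total_volume_cc))
    amount / dvh$total_volume_cc
  }
}

#' Dose to the hottest v% or v cc of a structure (D_v)
#'
#' Smallest dose `d` with interpolated cumulative volume fraction `<= v`,
#' i.e. the minimum dose received by the hottest `v` of the volume.  cc
#' specifications are converted through the structure volume
#' (`fraction = cc / total_volume_cc`).
#'
#' @param dvh a [new_dvh()] object.
#' @param kind `"percent"` or `"cc"`.
#' @param amount volume amount: in `(0, 100]` for percent, in
#'   `(0, total_volume_cc]` for cc.
#' @return dose in Gy(RBE).
#' @export
dose_at_volume <- function(dvh, kind = c("percent", "cc"), amount) {
  stopifnot(inherits(dvh, "dvh"))
  f <- resolve_volume_fraction(dvh, match.arg(kind), amount)
  d <- dvh$dose_edges; cum <- dvh$cum_volume_fraction
  if (f >= cum[1]) return(d[1])
  i <- which(cum <= f)[1]  # exists: cum ends at 0
  if (i == 1L) return(d[1])
  if (cum[i] == cum[i - 1L]) return(d[i - 1L])
  d[i - 1L] + (cum[i - 1L] - f) / (cum[i - 1L] - cum[i]) * (d[i] - d[i - 1L])
}

#' Volume fraction receiving at least a given dose
#'
#' Linear interpolation of the cumulative curve; returns 0 beyond the maximum
#' dose and the first curve value (1) below the first edge.
#'
#' @param dvh a [new_dvh()] object.
#' @param dose dose in Gy(RBE), `>= 0`; may be a vector.
#' @return volume fraction(s) in `[0, 1]`.
#' @export
volume_at_dose <- function(dvh, dose) {
  stopifnot(inherits(dvh, "dvh"))
  if (any(dose < 0)) stop("`dose` must be >= 0")
  stats::approx(dvh$dose_edges, dvh$cum_volume_fraction, xout = dose,
                yleft = dvh$cum_volume_fraction[1], yright = 0,
                ties = "ordered")$y
}

#' Generalised equivalent uniform dose (gEUD)
#'
#' Power-mean of the differential dose distribution,
#' `EUD = (sum_i v_i d_i^(1/n))^n`, with volume fractions `v_i` obtained by
#' differencing the cumulative curve and bin-midpoint doses `d_i`.  Small `n`
#' weights the hot spot (serial organ); `n = 1` gives the mean dose.
#' Evaluated in log space so that extreme exponents (e.g. `n = 1e-4`) do not
#' overflow.
#'
#' @param dvh a [new_dvh()] object.
#' @param n volume-effect parameter, > 0.  Default 0.035 (late rectal
#'   toxicity, serial behaviour).
#' @return gEUD in Gy(RBE).
#' @export
geud <- function(dvh, n = 0.035) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.finite(n) || n <= 0) stop("`n` must be > 0")
  w <- -diff(dvh$cum_volume_fraction)
  mid <- (dvh$dose_edges[-1] + dvh$dose_edges[-length(dvh$dose_edges)]) / 2
  keep <- w > 0 & mid > 0
  if (!any(keep)) return(0)
  a <- 1 / n
  lx <- log(w[keep]) + a * log(mid[keep])  # log(v_i * d_i^a)
  mx <- max(lx)
  exp(n * (mx + log(sum(exp(lx - mx)))))
}

#' Cohort-averaged DVH with per-bin standard deviation
#'
#' Re-bins every DVH onto a shared edge set (0 to the cohort maximum dose in
#' steps of `bin_width`) by linear interpolation, then returns the per-bin
#' mean and standard deviation of the cumulative volume fraction.  This is
#' the "mean curve with +/- 1 SD band" display used for cohort DVH
#' summaries.  The SD is the population SD (divisor `n`), describing the
#' spread of the curves at hand rather than estimating a sampling variance.
#'
#' @param dvhs list of at least two [new_dvh()] objects.
#' @param bin_width shared bin width, Gy(RBE).
#' @return list with `dose_edges`, `mean` (monotone non-increasing), `sd`,
#'   and `n` (number of DVHs).
#' @export
average_dvh <- function(dvhs, bin_width = 0.1) {
  if (length(dvhs) < 2L) stop("need at least 2 DVHs to average")
  stopifnot(all(vapply(dvhs, inherits, logical(1), "dvh")))
  dmax <- max(vapply(dvhs, function(d) max(d$dose_edges), numeric(1)))
  edges <- seq(0, by = bin_width,
               length.out = max(2L, ceiling(dmax / bin_width) + 2L))
  mat <- vapply(dvhs, volume_at_dose, numeric(length(edges)), dose = edges)
  mu <- rowMeans(mat)
  list(dose_edges = edges,
       mean = mu,
       sd = sqrt(rowMeans((mat - mu)^2)),
       n = length(dvhs))
}
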