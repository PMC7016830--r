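#' Quadratic regression between paired LEM and mMKM dose-volume points
#'
#' Fits, by ordinary least squares, the relation
#' `D_MKM|v = a * D_LEM|v^2 + b * D_LEM|v + c`
#' to paired dose-volume points extracted from the two RBE-weighted dose
#' representations of the same treatment plans.  The fit carries the
#' coefficient covariance so mean-response confidence bands (and their
#' inversion into translated constraints) can be derived from it.
#'
#' @param pairs data frame with numeric columns `d_lem` and `d_mkm`
#'   (one row per patient per volume level), e.g. from
#'   [extract_paired_points()].  Rows of all volume levels may be pooled or
#'   the frame may be pre-filtered to a single level; the default pipeline
#'   fits one model per level.
#' @return An object of class `quadfit`: coefficients `a`, `b`, `c`,
#'   `coef_covariance` (3x3, order a, b, c), `residual_variance`,
#'   `n_points`, `df`, `r_squared`, `domain` (range of observed `d_lem`)
#'   and `mkm_range` (range of observed `d_mkm`).
#' @export
fit_quadratic <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("d_lem", "d_mkm") %in% names(pairs)))
    stop("`pairs` must be a data frame with columns d_lem and d_mkm")
  x <- as.numeric(pairs$d_lem); y <- as.numeric(pairs$d_mkm)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 paired points to fit")
  if (any(x < 0) || any(y < 0)) stop("doses must be >= 0")
  if (length(unique(x)) < 3L) stop("degenerate design")
  X <- cbind(x2 = x^2, x = x, ic = 1)
  qx <- qr(X)
  if (qx$rank < 3L) stop("degenerate design")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- length(x) - 3L
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - sum(res^2) / tss)) else 1
  structure(
    list(a = unname(beta["x2"]), b = unname(beta["x"]), c = unname(beta["ic"]),
         coef_covariance = s2 * XtXinv,
         residual_variance = s2, n_points = length(x), df = df,
         r_squared = r2, domain = range(x), mkm_range = range(y)),
    class = "quadfit"
  )
}

#' @export
print.quadfit <- function(x, ...) {
  cat(sprintf(
    "<quadfit> D_MKM = %.5g*D_LEM^2 + %.5g*D_LEM + %.5g  (n=%d, R2=%.4f)\n",
    x$a, x$b, x$c, x$n_points, x$r_squared))
  invisible(x)
}

#' Forward evaluation of a fitted LEM to mMKM dose map
#'
#' Evaluates `a*x^2 + b*x + c`, floored at 0 Gy(RBE).
#'
#' @param fit a [fit_quadratic()] object.
#' @param d_lem LEM dose(s), Gy(RBE).
#' @return predicted mMKM dose(s), Gy(RBE).
#' @export
translate_dvh_point <- function(fit, d_lem) {
  stopifnot(inherits(fit, "quadfit"))
  pmax(0, fit$a * d_lem^2 + fit$b * d_lem + fit$c)
}

#' Confidence band for the mean response of a quadratic fit
#'
#' Classical linear-model band for the mean response at `x`:
#' `f(x) +/- t_{df} * sqrt((x^2, x, 1) V (x^2, x, 1)')` with `V` the
#' coefficient covariance and `df = n_points - 3`.  The band widens away from
#' the bulk of the data, which is what drives the conservative translated
#' constraints.
#'
#' @param fit a [fit_quadratic()] object.
#' @param x LEM dose(s) at which to evaluate the band.
#' @param level confidence level, default 0.95.
#' @return data frame with columns `x`, `fit`, `lower`, `upper`, `se`.
#' @export
confidence_band <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "quadfit"))
  if (fit$df < 1L) stop("confidence band requires n_points > 3")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  X0 <- cbind(x^2, x, 1)
  se <- sqrt(pmax(0, rowSums((X0 %*% fit$coef_covariance) * X0)))
  pred <- fit$a * x^2 + fit$b * x + fit$c
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  data.frame(x = x, fit = pred, lower = pred - tq * se,
             upper = pred + tq * se, se = se)
}

# increasing-branch search interval for inverting the quadratic map:
# observed domain extended by `extend` of its width on each side, clipped to
# the branch where the derivative 2a*x + b is positive (dose maps are
# physically increasing)
branch_interval <- function(fit, extend = 0.25) {
  w <- diff(fit$domain)
  lo <- max(0, fit$domain[1] - extend * w)
  hi <- fit$domain[2] + extend * w
  if (fit$a > 0) lo <- max(lo, -fit$b / (2 * fit$a))
  if (fit$a < 0) hi <- min(hi, -fit$b / (2 * fit$a))
  if (lo >= hi) stop("no increasing branch inside the model domain")
  c(lo, hi)
}

# root of a*x^2 + b*x + (c - y) = 0 on the increasing branch within [lo, hi];
# closed form, tie-broken toward the observed domain
quad_root_increasing <- function(a, b, c, y, lo, hi, tol = 1e-8) {
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) stop("target outside model range")
    r <- (y - c) / b
    if (r < lo - tol || r > hi + tol) stop("target outside model range")
    return(r)
  }
  disc <- b^2 - 4 * a * (c - y)
  if (disc < 0) stop("target outside model range")
  s <- sqrt(disc)
  roots <- c((-b + s) / (2 * a), (-b - s) / (2 * a))
  incr <- roots[2 * a * roots + b > 0]
  incr <- incr[incr >= lo - tol & incr <= hi + tol]
  if (length(incr) == 0L) stop("target outside model range")
  incr[1]
}

# root of band(x) = y for the (lower/upper) confidence band by bracketed
# bisection via uniroot; falls back to the interval end nearest the crossing
# when the band never reaches y inside the search interval
band_root <- function(fit, y, level, side, lo, hi) {
  g <- function(x) {
    cb <- confidence_band(fit, x, level)
    (if (side == "upper") cb$upper else cb$lower) - y
  }
  xs <- seq(lo, hi, length.out = 201L)
  gv <- g(xs)
  idx <- which(gv[-1] * gv[-length(gv)] <= 0)
  if (length(idx) == 0L) {
    # no crossing: band entirely above (or below) the target in-interval
    return(if (gv[1] > 0) lo else hi)
  }
  i <- idx[1]
  if (gv[i] == 0) return(xs[i])
  stats::uniroot(g, lower = xs[i], upper = xs[i + 1], tol = 1e-10)$root
}

#' Translate an mMKM dose-volume constraint into LEM language
#'
#' Inverts the fitted quadratic map at a target mMKM dose: the point estimate
#' is the root of `a*x^2 + b*x + c = target` on the increasing branch; the
#' 95% interval on the LEM dose is obtained by inverting the two
#' mean-response band curves at the same target.  The upper band crosses the
#' target at a smaller LEM dose, so it yields the lower LEM bound — the
#' conservative value adopted as the translated clinical constraint.
#'
#' @param fit a [fit_quadratic()] object.
#' @param d_mkm_target target mMKM dose, Gy(RBE).  A warning is issued when
#'   the target lies outside the observed mMKM range +/- 20%.
#' @param level confidence level, default 0.95.
#' @param v_level optional label for the volume level (e.g. `"D_20%"`).
#' @return An object of class `translated_constraint`: `v_level`,
#'   `d_mkm_target`, `d_lem_point`, `d_lem_lo`, `d_lem_hi`, `level`.
#'   `d_lem_lo` is the conservative clinical value.
#' @export
translate_constraint <- function(fit, d_mkm_target, level = 0.95,
                                 v_level = NA_character_) {
  stopifnot(inherits(fit, "quadfit"))
  if (!is.finite(d_mkm_target) || d_mkm_target < 0)
    stop("`d_mkm_target` must be a non-negative dose")
  rng <- fit$mkm_range
  if (d_mkm_target < rng[1] * 0.8 || d_mkm_target > rng[2] * 1.2)
    warning(sprintf(
      "target %.3g Gy(RBE) lies outside the fitted D_MKM range [%.3g, %.3g] +/- 20%%",
      d_mkm_target, rng[1], rng[2]))
  iv <- branch_interval(fit)
  point <- quad_root_increasing(fit$a, fit$b, fit$c, d_mkm_target,
                                iv[1], iv[2])
  if (fit$residual_variance <= 1e-12 || fit$df < 1L) {
    lo <- hi <- point  # degenerate (noiseless) band
  } else {
    lo <- band_root(fit, d_mkm_target, level, "upper", iv[1], iv[2])
    hi <- band_root(fit, d_mkm_target, level, "lower", iv[1], iv[2])
  }
  structure(
    list(v_level = v_level, d_mkm_target = d_mkm_target,
         d_lem_point = point, d_lem_lo = min(lo, point),
         d_lem_hi = max(hi, point), level = level),
    class = "translated_constraint"
  )
}

#' @export
print.translated_constraint <- function(x, ...) {
  cat(sprintf(
    "<translated_constraint>%s D_MKM %.1f -> D_LEM %.1f (%.0f%% CI %.1f-%.1f) Gy(RBE)\n",
    if (is.na(x$v_level)) "" else paste0(" ", x$v_level),
    x$d_mkm_target, x$d_lem_point, 100 * x$level, x$d_lem_lo, x$d_lem_hi))
  invisible(x)
}

#' Translation table for a set of mMKM targets
#'
#' Convenience wrapper around [translate_constraint()] producing the
#' translation table written by the pipeline.  Values are reported at full
#' precision; round to 0.1 Gy(RBE) for clinical display.
#'
#' @param fits either a single [fit_quadratic()] object used for all targets
#'   (pooled fit) or a named list of fits, one per element of `targets`
#'   (per-volume-level fits).
#' @param targets named numeric vector of mMKM target doses; names label the
#'   volume level (e.g. `c("D_20%" = 28.8, ...)`).
#' @param level confidence level.
#' @return data frame `v_level, d_mkm_target, d_lem_point, d_lem_lo, d_lem_hi`.
#' @export
translation_table <- function(fits, targets, level = 0.95) {
  labs <- names(targets)
  if (is.null(labs)) labs <- sprintf("target_%d", seq_along(targets))
  rows <- lapply(seq_along(targets), function(i) {
    fit <- if (inherits(fits, "quadfit")) fits else fits[[labs[i]]]
    if (is.null(fit)) stop(sprintf("no fit supplied for level '%s'", labs[i]))
    tc <- translate_constraint(fit, targets[[i]], level = level,
                               v_level = labs[i])
    data.frame(v_level = tc$v_level, d_mkm_target = tc$d_mkm_target,
               d_lem_point = tc$d_lem_point, d_lem_lo = tc$d_lem_lo,
               d_lem_hi = tc$d_lem_hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
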