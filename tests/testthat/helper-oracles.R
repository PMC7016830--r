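# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# sort-based empirical D_v oracle: smallest dose whose survival fraction
# (# doses >= d) / n is <= f, evaluated on the exact voxel list
oracle_dose_at_fraction <- function(doses, f) {
  s <- sort(doses)
  n <- length(s)
  first <- match(s, s)            # first index of each value handles ties
  surv <- (n - first + 1) / n     # survival fraction at each sorted dose
  i <- which(surv <= f)[1]
  if (is.na(i)) s[n] else s[i]    # <= f only beyond the maximum dose
}

# normal-equations quadratic OLS oracle
oracle_quadfit <- function(x, y) {
  X <- cbind(x^2, x, 1)
  beta <- solve(crossprod(X), crossprod(X, y))
  list(a = beta[1], b = beta[2], c = beta[3],
       residuals = as.numeric(y - X %*% beta))
}

# closed-form root of a*x^2 + b*x + c = y on the increasing branch
oracle_quad_root <- function(a, b, c, y) {
  if (abs(a) < 1e-12) return((y - c) / b)
  s <- sqrt(b^2 - 4 * a * (c - y))
  roots <- c((-b + s) / (2 * a), (-b - s) / (2 * a))
  roots[2 * a * roots + b > 0][1]
}

# published anchor pairs linking translated LEM and nominal mMKM limits
anchor_pairs <- function() {
  data.frame(d_lem = c(42.9, 57.7, 68.2, 72.0),
             d_mkm = c(28.8, 46.4, 60.0, 66.0))
}

make_uniform_dvh <- function(dose = 50, volume_cc = 80, rbe_model = "MKM") {
  # the vanishing final bin keeps the whole mass at the uniform dose
  new_dvh(c(0, dose, dose + 1e-9), c(1, 1, 0), volume_cc,
          rbe_model = rbe_model)
}

# linear falloff: fraction receiving >= d is (dmax - d)/dmax on [0, dmax]
make_linear_dvh <- function(dmax = 100, volume_cc = 80, rbe_model = "MKM") {
  edges <- seq(0, dmax, by = 1)
  new_dvh(edges, (dmax - edges) / dmax, volume_cc, rbe_model = rbe_model)
}

# two equal-volume dose bins at d1 < d2
make_two_bin_dvh <- function(d1, d2, volume_cc = 80, rbe_model = "MKM") {
  eps <- 1e-9
  new_dvh(c(0, d1, d1 + eps, d2, d2 + eps),
          c(1, 1, 0.5, 0.5, 0), volume_cc, rbe_model = rbe_model)
}

make_random_grid <- function(dim = c(20, 20, 20), dmax = 100,
                             voxel = c(2, 2, 2)) {
  vals <- array(stats::runif(prod(dim), 0, dmax), dim = dim)
  list(grid = dose_grid(vals, voxel, rbe_model = "MKM"),
       mask = structure_mask(array(TRUE, dim = dim)),
       doses = as.numeric(vals))
}

noiseless_config <- function() {
  cohort_config(noise_slope = 0, patient_effect_sd = 0)
}
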