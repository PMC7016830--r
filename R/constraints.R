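#' Single dose-volume constraint
#'
#' A dose limit on a D_v metric, expressed either as a volume percentage
#' (`D_v% <= limit`) or an absolute volume (`D_vcc <= limit`), stated in one
#' RBE language.  `hard` constraints must hold; `soft` ones may be
#' compromised to prioritise target coverage — the label never changes
#' pass/fail, only the severity class in reports.
#'
#' @param kind `"percent"` or `"cc"`.
#' @param amount volume amount (> 0; `<= 100` for percent).
#' @param limit dose limit, Gy(RBE), > 0.
#' @param rbe_model `"LEM"` or `"MKM"` — the language the limit is stated in.
#' @param priority `"hard"` or `"soft"`.
#' @return An object of class `dose_constraint`.
#' @export
dose_constraint <- function(kind = c("percent", "cc"), amount, limit,
                            rbe_model = c("LEM", "MKM"),
                            priority = c("hard", "soft")) {
  kind <- match.arg(kind); rbe_model <- match.arg(rbe_model)
  priority <- match.arg(priority)
  if (!is.finite(amount) || amount <= 0) stop("`amount` must be > 0")
  if (kind == "percent" && amount > 100) stop("percent amount must be <= 100")
  if (!is.finite(limit) || limit <= 0) stop("`limit` must be > 0")
  structure(
    list(kind = kind, amount = amount, limit = limit, rbe_model = rbe_model,
         priority = priority,
         label = if (kind == "percent") sprintf("D_%g%%", amount)
                 else sprintf("D_%gcc", amount)),
    class = "dose_constraint"
  )
}

#' Named set of dose-volume constraints
#'
#' @param name set name.
#' @param constraints list of [dose_constraint()] objects with unique
#'   metric specifications.
#' @param provenance free-text origin note.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(name, constraints, provenance = "") {
  stopifnot(all(vapply(constraints, inherits, logical(1), "dose_constraint")))
  keys <- vapply(constraints, function(cn) paste(cn$kind, cn$amount), "")
  if (anyDuplicated(keys)) stop("duplicate metric specs in constraint set")
  structure(list(name = name, constraints = constraints,
                 provenance = provenance),
            class = "constraint_set")
}

#' Built-in rectum constraint sets
#'
#' The four constraint systems used throughout the analysis, for 16-fraction
#' pelvic carbon-ion treatments:
#' \describe{
#'   \item{OLD_MKM}{original NIRS-derived mMKM limits: D_20% <= 28.8 (soft),
#'     D_10% <= 46.4 (soft), D_5% <= 60, D_1% <= 66 Gy(RBE).}
#'   \item{SACRUM_PRV}{mMKM limits applied to a 5 mm planning risk volume
#'     around the rectum (expansion is applied upstream on the mask):
#'     D_5% <= 56, D_1% <= 61 Gy(RBE).}
#'   \item{TRANSLATED_LEM}{LEM limits translated through the quadratic fit
#'     (lower 95% CI bounds): D_20% <= 38.7 (soft), D_10% <= 54.7 (soft),
#'     D_5% <= 65.1, D_1% <= 69.3 Gy(RBE).}
#'   \item{NEW_CC}{updated absolute-volume LEM limits robust to rectum-size
#'     variation: D_1cc <= 66, D_5cc <= 61, D_10cc <= 54 (soft) Gy(RBE).}
#' }
#'
#' @param name one of `"OLD_MKM"`, `"SACRUM_PRV"`, `"TRANSLATED_LEM"`,
#'   `"NEW_CC"`; omit to get the full named list.
#' @return a [constraint_set()] (or a named list of all four).
#' @export
builtin_constraint_set <- function(name) {
  sets <- list(
    OLD_MKM = constraint_set("OLD_MKM", list(
      dose_constraint("percent", 20, 28.8, "MKM", "soft"),
      dose_constraint("percent", 10, 46.4, "MKM", "soft"),
      dose_constraint("percent", 5, 60, "MKM", "hard"),
      dose_constraint("percent", 1, 66, "MKM", "hard")
    ), provenance = "original NIRS-derived mMKM rectum limits, 16 fx"),
    SACRUM_PRV = constraint_set("SACRUM_PRV", list(
      dose_constraint("percent", 5, 56, "MKM", "hard"),
      dose_constraint("percent", 1, 61, "MKM", "hard")
    ), provenance = "mMKM limits on the 5 mm rectum PRV (sacral chordoma)"),
    TRANSLATED_LEM = constraint_set("TRANSLATED_LEM", list(
      dose_constraint("percent", 20, 38.7, "LEM", "soft"),
      dose_constraint("percent", 10, 54.7, "LEM", "soft"),
      dose_constraint("percent", 5, 65.1, "LEM", "hard"),
      dose_constraint("percent", 1, 69.3, "LEM", "hard")
    ), provenance = "lower 95% CI bounds of the quadratic LEM translation"),
    NEW_CC = constraint_set("NEW_CC", list(
      dose_constraint("cc", 1, 66, "LEM", "hard"),
      dose_constraint("cc", 5, 61, "LEM", "hard"),
      dose_constraint("cc", 10, 54, "LEM", "soft")
    ), provenance = "updated absolute-volume LEM rectum limits, 16 fx")
  )
  if (missing(name)) return(sets)
  if (!name %in% names(sets))
    stop(sprintf("unknown constraint set '%s' (have: %s)", name,
                 paste(names(sets), collapse = ", ")))
  sets[[name]]
}

#' Evaluate a DVH against a constraint set
#'
#' One row per constraint with the observed [dose_at_volume()] value.  A
#' constraint passes when `observed <= limit + tol`; boundary equality is
#' compliant, and `tol` (default 0.05 Gy(RBE)) absorbs clinical reporting
#' rounding.  Evaluating a DVH in one RBE language against limits stated in
#' the other is the central pitfall this package exists to avoid, so it is a
#' hard error.
#'
#' @param dvh a [new_dvh()] object.
#' @param cset a [constraint_set()].
#' @param tol pass tolerance, Gy(RBE).
#' @return data frame: `patient_id, constraint_set, constraint, kind, amount,
#'   rbe_model, priority, limit, observed, margin, pass`.
#' @export
evaluate_constraints <- function(dvh, cset, tol = 0.05) {
  stopifnot(inherits(dvh, "dvh"), inherits(cset, "constraint_set"))
  models <- unique(vapply(cset$constraints, `[[`, "", "rbe_model"))
  if (!all(models == dvh$rbe_model))
    stop(sprintf("RBE-language mismatch: DVH is %s, constraint set '%s' is %s",
                 dvh$rbe_model, cset$name, paste(models, collapse = "/")))
  rows <- lapply(cset$constraints, function(cn) {
    obs <- dose_at_volume(dvh, cn$kind, cn$amount)
    data.frame(patient_id = dvh$patient_id, constraint_set = cset$name,
               constraint = cn$label, kind = cn$kind, amount = cn$amount,
               rbe_model = cn$rbe_model, priority = cn$priority,
               limit = cn$limit, observed = obs, margin = cn$limit - obs,
               pass = obs <= cn$limit + tol, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-constraint exceedance fractions over a cohort
#'
#' @param reports data frame of stacked [evaluate_constraints()] rows (one or
#'   more patients).
#' @return data frame per constraint: `constraint_set, constraint, priority,
#'   limit, n, n_fail, exceedance_fraction, exceedance_pct` (the percentage
#'   rounded to 0.1).
#' @export
cohort_compliance <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) == 0L)
    stop("`reports` must be a non-empty data frame of evaluation rows")
  key <- interaction(reports$constraint_set, reports$constraint, drop = TRUE)
  rows <- lapply(split(reports, key), function(df) {
    data.frame(constraint_set = df$constraint_set[1],
               constraint = df$constraint[1], priority = df$priority[1],
               limit = df$limit[1], n = nrow(df), n_fail = sum(!df$pass),
               exceedance_fraction = mean(!df$pass),
               exceedance_pct = round(100 * mean(!df$pass), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$constraint_set, out$constraint), , drop = FALSE]
}
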