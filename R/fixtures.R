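#' Published re-optimized plan metrics
#'
#' Rectum D_v values, in both RBE languages, for the five treatment plans
#' that were re-optimized with the translated LEM constraints and
#' recalculated to verify that the original mMKM limits were still
#' respected (two prostate, two low-dose and one high-dose sacral chordoma
#' plans).  Shipped as a plain-text fixture under `inst/extdata`.
#'
#' @return data frame with one row per plan: `patient_id`, `group`,
#'   `rectum_volume_cc` and `d_lem_v` / `d_mkm_v` for v in 20, 10, 5, 1 (%).
#' @export
reoptimized_plans <- function() {
  path <- system.file("extdata", "reoptimized_plans.csv", package = "rbedvh")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Evaluate pre-tabulated D_v metrics against a constraint set
#'
#' Like [evaluate_constraints()] but for plans where only the dose-volume
#' metric values are available (no full DVH), e.g. published plan tables.
#'
#' @param metrics data frame with columns `kind`, `amount`, `observed`
#'   (one row per available metric, doses in Gy(RBE)).
#' @param cset a [constraint_set()].
#' @param rbe_model RBE language of the observed values.
#' @param patient_id identifier for the report rows.
#' @param tol pass tolerance, Gy(RBE).
#' @return data frame in the [evaluate_constraints()] row format; constraints
#'   without a matching metric are dropped.
#' @export
evaluate_metric_table <- function(metrics, cset, rbe_model,
                                  patient_id = NA_character_, tol = 0.05) {
  stopifnot(inherits(cset, "constraint_set"))
  models <- unique(vapply(cset$constraints, `[[`, "", "rbe_model"))
  if (!all(models == rbe_model))
    stop(sprintf("RBE-language mismatch: metrics are %s, constraint set '%s' is %s",
                 rbe_model, cset$name, paste(models, collapse = "/")))
  rows <- lapply(cset$constraints, function(cn) {
    hit <- metrics$kind == cn$kind & metrics$amount == cn$amount
    if (!any(hit)) return(NULL)
    obs <- metrics$observed[which(hit)[1]]
    data.frame(patient_id = patient_id, constraint_set = cset$name,
               constraint = cn$label, kind = cn$kind, amount = cn$amount,
               rbe_model = cn$rbe_model, priority = cn$priority,
               limit = cn$limit, observed = obs, margin = cn$limit - obs,
               pass = obs <= cn$limit + tol, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
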