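#' Write a DVH to CSV
#'
#' Format: commented metadata lines (`# structure=`, `# volume_cc=`,
#' `# rbe_model=`, `# patient_id=`) followed by the header
#' `dose_gy_rbe,cum_volume_fraction` and the curve.  Doses are serialised
#' with 10 significant digits so a read/write round trip reproduces the
#' curve to well below 1e-9 relative error.
#'
#' @param dvh a [new_dvh()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# structure=%s", dvh$structure),
    sprintf("# volume_cc=%s", format(dvh$total_volume_cc, digits = 10)),
    sprintf("# rbe_model=%s", dvh$rbe_model),
    sprintf("# patient_id=%s", dvh$patient_id),
    "dose_gy_rbe,cum_volume_fraction",
    paste(format(dvh$dose_edges, digits = 10, trim = TRUE, scientific = FALSE),
          format(dvh$cum_volume_fraction, digits = 10, trim = TRUE),
          sep = ",")
  ), con)
  invisible(path)
}

#' Read a DVH from CSV
#'
#' Inverse of [write_dvh()].  Malformed or missing metadata and malformed
#' data rows raise errors naming the offending line.
#'
#' @param path file path.
#' @return a [new_dvh()] object.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such DVH file: %s", path))
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (i in meta_idx) {
    mm <- regmatches(lines[i], regexec("^#\\s*([a-z_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(mm) != 3L)
      stop(sprintf("%s: malformed metadata at line %d", path, i))
    meta[[mm[2]]] <- trimws(mm[3])
  }
  for (key in c("structure", "volume_cc", "rbe_model"))
    if (is.null(meta[[key]]))
      stop(sprintf("%s: missing '# %s=' metadata", path, key))
  if (!meta$rbe_model %in% c("LEM", "MKM"))
    stop(sprintf("%s: rbe_model must be LEM or MKM, got '%s'",
                 path, meta$rbe_model))
  body <- lines[-meta_idx]
  hdr_at <- which(body == "dose_gy_rbe,cum_volume_fraction")[1]
  if (is.na(hdr_at))
    stop(sprintf("%s: missing 'dose_gy_rbe,cum_volume_fraction' header", path))
  dat <- utils::read.csv(textConnection(body[hdr_at:length(body)]))
  if (anyNA(dat$dose_gy_rbe) || anyNA(dat$cum_volume_fraction))
    stop(sprintf("%s: non-numeric DVH rows", path))
  pid <- meta$patient_id
  if (is.null(pid) || pid == "NA") pid <- NA_character_
  new_dvh(dat$dose_gy_rbe, dat$cum_volume_fraction,
          as.numeric(meta$volume_cc), rbe_model = meta$rbe_model,
          structure = meta$structure, patient_id = pid)
}

#' Write / read a cohort manifest
#'
#' Plain CSV with columns `patient_id, group, prescription_gy_rbe,
#' n_fractions, rectum_volume_cc, dvh_lem_path, dvh_mkm_path`.
#'
#' @param manifest manifest data frame.
#' @param path file path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the data
#'   frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such manifest: %s", path))
  need <- c("patient_id", "group", "prescription_gy_rbe", "n_fractions",
            "rectum_volume_cc", "dvh_lem_path", "dvh_mkm_path")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("%s: manifest missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  df
}

#' Load a cohort from a manifest
#'
#' Reads every referenced LEM/mMKM DVH pair (paths resolved relative to the
#' manifest location when not absolute) into the in-memory cohort structure
#' used by [extract_paired_points()] and the pipeline.
#'
#' @param path manifest CSV path.
#' @return list with `manifest` and `patients`.
#' @export
read_cohort <- function(path) {
  manifest <- read_manifest(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    list(patient_id = row$patient_id, group = row$group,
         prescription = row$prescription_gy_rbe,
         n_fractions = row$n_fractions,
         volume_cc = row$rectum_volume_cc,
         dvh_lem = read_dvh(resolve(row$dvh_lem_path)),
         dvh_mkm = read_dvh(resolve(row$dvh_mkm_path)))
  })
  list(manifest = manifest, patients = patients)
}

#' Read / write constraint sets as JSON
#'
#' A constraint-set file holds one object
#' `{"name": ..., "provenance": ..., "constraints": [{"kind": "percent",
#' "amount": 20, "limit": 28.8, "rbe_model": "MKM", "priority": "soft"},
#' ...]}` or a list of such objects.
#'
#' @param path JSON file path.
#' @return a [constraint_set()] or named list of them.
#' @export
read_constraint_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such constraint file: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  parse_one <- function(obj) {
    if (is.null(obj$name) || is.null(obj$constraints))
      stop(sprintf("%s: constraint set needs 'name' and 'constraints'", path))
    cons <- lapply(obj$constraints, function(cn)
      dose_constraint(cn$kind, cn$amount, cn$limit, cn$rbe_model,
                      if (is.null(cn$priority)) "hard" else cn$priority))
    constraint_set(obj$name, cons,
                   if (is.null(obj$provenance)) "" else obj$provenance)
  }
  if (!is.null(raw$name)) return(parse_one(raw))
  sets <- lapply(raw, parse_one)
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname read_constraint_set
#' @param cset a [constraint_set()] to serialise.
#' @export
write_constraint_set <- function(cset, path) {
  stopifnot(inherits(cset, "constraint_set"))
  obj <- list(name = cset$name, provenance = cset$provenance,
              constraints = lapply(cset$constraints, function(cn)
                cn[c("kind", "amount", "limit", "rbe_model", "priority")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
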