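#' Patient record
#'
#' One causal perturbation with its clinical outcomes: a site, an anxiety
#' and a depression score (changes for stimulation, severities for lesions),
#' and any further named covariates (baseline severity, lesion size, trait /
#' state measures, diagnoses). Lesion records automatically carry
#' `lesion_size = site$size_voxels`.
#'
#' @param id patient identifier.
#' @param site a `stimulation_site`.
#' @param anxiety,depression finite scalars.
#' @param conn_map optional `connectivity_map` for the site.
#' @param extra_covariates named list/vector of finite scalars.
#' @export
patient_record <- function(id, site, anxiety, depression, conn_map = NULL,
                           extra_covariates = list()) {
  stopifnot(is.finite(anxiety), is.finite(depression))
  extra_covariates <- as.list(extra_covariates)
  if (site$kind == "lesion" && is.null(extra_covariates$lesion_size))
    extra_covariates$lesion_size <- site$size_voxels
  structure(list(id = as.character(id), site = site, conn_map = conn_map,
                 anxiety = as.numeric(anxiety),
                 depression = as.numeric(depression),
                 extra_covariates = extra_covariates),
            class = "patient_record")
}

#' Cohort dataset
#'
#' A named set of patient records from one study, all on one grid.
#' Records with missing (non-finite) outcome or covariate data never enter
#' a cohort; `n` counts complete records and is the dataset weight used when
#' circuit maps are combined.
#'
#' @param name dataset name.
#' @param modality one of "tms_scalp", "tms_individualized", "lesion", "dbs".
#' @param records list of [patient_record()]s.
#' @export
cohort_dataset <- function(name, modality, records) {
  modality <- match.arg(modality,
                        c("tms_scalp", "tms_individualized", "lesion", "dbs"))
  stopifnot(length(records) >= 1L)
  g <- site_grid(records[[1]])
  for (r in records) stop_if_grid_mismatch(site_grid(r), g, "cohort records")
  structure(list(name = name, modality = modality, records = records,
                 n = length(records)),
            class = "cohort_dataset")
}

site_grid <- function(record) record$site$weights$grid

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset", shQuote(x$name), "-", x$modality, "- n =", x$n, "\n")
  invisible(x)
}

#' Default nuisance covariates per modality
#'
#' Stimulation cohorts control for depression change and baseline severity;
#' lesion cohorts for depression severity and lesion size; DBS cohorts for
#' depression change plus baseline anxiety and depression.
#'
#' @param modality cohort modality string.
#' @export
default_covariates <- function(modality) {
  switch(modality,
         lesion = c("depression", "lesion_size"),
         tms_scalp = ,
         tms_individualized = c("depression", "baseline"),
         dbs = c("depression", "baseline", "baseline_depression"),
         stop("unknown modality: ", modality))
}

# pull one named field from a record: anxiety/depression directly, anything
# else from extra_covariates
record_field <- function(record, field) {
  v <- switch(field,
              anxiety = record$anxiety,
              depression = record$depression,
              record$extra_covariates[[field]])
  if (is.null(v)) stop(sprintf("covariate %s missing for patient %s",
                               field, record$id))
  as.numeric(v)
}

# design pieces for one cohort: outcome vector y, covariate matrix C
# (n x k, may have 0 columns), and the stacked Fisher-z matrix Z (n x V)
# over the analysis mask
cohort_design <- function(dataset, outcome_field = "anxiety",
                          covariate_fields = NULL, mask = NULL) {
  if (is.null(covariate_fields))
    covariate_fields <- default_covariates(dataset$modality)
  covariate_fields <- setdiff(covariate_fields, outcome_field)
  recs <- dataset$records
  y <- vapply(recs, record_field, numeric(1), field = outcome_field)
  C <- if (length(covariate_fields) == 0L) {
    matrix(numeric(0), length(recs), 0L)
  } else {
    vapply(recs, function(r)
      vapply(covariate_fields, record_field, numeric(1), record = r),
      numeric(length(covariate_fields)))
  }
  C <- matrix(C, nrow = length(recs), byrow = TRUE,
              dimnames = list(NULL, covariate_fields))
  cm <- recs[[1]]$conn_map
  if (is.null(cm)) stop(sprintf("dataset %s: records carry no connectivity maps",
                                dataset$name))
  grid <- cm$zmap$grid
  m <- cm$zmap$brain_mask
  if (!is.null(mask)) m <- m & resolve_mask(mask, grid)
  Z <- t(vapply(recs, function(r) {
    if (is.null(r$conn_map)) stop(sprintf("patient %s has no connectivity map", r$id))
    stop_if_grid_mismatch(r$conn_map$zmap$grid, grid, "connectivity maps")
    r$conn_map$zmap$data[m]
  }, numeric(sum(m))))
  list(y = y, C = C, Z = Z, grid = grid, mask = m,
       ids = vapply(recs, `[[`, character(1), "id"))
}

#' Write / read a cohort's tabular data as CSV
#'
#' The table holds id, anxiety, depression and all extra covariates; sites
#' and connectivity maps live in NIfTI files referenced by the analysis, not
#' in the table.
#'
#' @param dataset a [cohort_dataset()].
#' @param path CSV path.
#' @export
cohort_table <- function(dataset) {
  rows <- lapply(dataset$records, function(r) {
    base <- data.frame(id = r$id, anxiety = r$anxiety,
                       depression = r$depression,
                       stringsAsFactors = FALSE)
    if (length(r$extra_covariates))
      base <- cbind(base, as.data.frame(r$extra_covariates))
    base
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  })
  do.call(rbind, rows)
}

#' @rdname cohort_table
#' @export
write_cohort_csv <- function(dataset, path) {
  utils::write.csv(cohort_table(dataset), path, row.names = FALSE)
  invisible(path)
}
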