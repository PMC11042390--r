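#' Score a stimulation site's connectivity against a circuit
#'
#' The spatial correlation between a site's whole-brain connectivity map
#' and a circuit map, used as the estimate of "site connectivity to the
#' circuit" for TMS and lesion patients.
#'
#' @param conn_map a `connectivity_map`.
#' @param circuit a `circuit_map` (or [brain_volume()]).
#' @param mask optional analysis mask.
#' @param patient_id optional id recorded on the score.
#' @return A `site_score` with `method = "spatial_corr"`, score in [-1, 1].
#' @export
site_connectivity_score <- function(conn_map, circuit, mask = NULL,
                                    patient_id = NA_character_) {
  s <- spatial_correlation(conn_map, circuit, mask)
  new_site_score(patient_id, s, "spatial_corr", circuit_provenance(circuit))
}

#' DBS field overlap with a circuit
#'
#' The mean circuit voxel value under the left stimulation field plus the
#' mean under the right field (hemifields scored separately, then added).
#' An empty hemifield, or one lying wholly outside the mask, contributes 0;
#' it is an error if both do.
#'
#' @param site a `stimulation_site` of kind "dbs_pair".
#' @param circuit a `circuit_map` (or [brain_volume()]).
#' @param mask optional analysis mask.
#' @param patient_id optional id recorded on the score.
#' @return A `site_score` with `method = "overlap"`.
#' @export
dbs_overlap_score <- function(site, circuit, mask = NULL,
                              patient_id = NA_character_) {
  if (site$kind != "dbs_pair") stop("overlap scoring requires a DBS pair")
  vol <- as_value_volume(circuit)
  m <- vol$brain_mask
  if (!is.null(mask)) m <- m & resolve_mask(mask, vol$grid)
  hemi_mean <- function(field) {
    stop_if_grid_mismatch(field$grid, vol$grid, "DBS field and circuit")
    sel <- m & field$brain_mask & field$data > 0
    if (!any(sel)) return(NA_real_)
    mean(vol$data[sel])
  }
  l <- hemi_mean(site$weights)
  r <- hemi_mean(site$weights_right)
  if (is.na(l) && is.na(r))
    stop("both DBS hemifields are empty or outside the mask")
  score <- (if (is.na(l)) 0 else l) + (if (is.na(r)) 0 else r)
  new_site_score(patient_id, score, "overlap", circuit_provenance(circuit))
}

circuit_provenance <- function(circuit) {
  if (inherits(circuit, "circuit_map")) circuit$provenance else character(0)
}

new_site_score <- function(patient_id, score, method, provenance) {
  structure(list(patient_id = as.character(patient_id),
                 score = as.numeric(score), method = method,
                 circuit_provenance = provenance),
            class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("site_score[%s] %s = %.4f\n", x$patient_id, x$method, x$score))
  invisible(x)
}

#' Score every patient of a cohort against a circuit
#'
#' DBS cohorts are scored by field overlap, all others by connectivity-map
#' spatial correlation.
#'
#' @param dataset a [cohort_dataset()].
#' @param circuit a `circuit_map`.
#' @param mask optional analysis mask.
#' @return list of `site_score`s aligned with `dataset$records`.
#' @export
score_cohort <- function(dataset, circuit, mask = NULL) {
  lapply(dataset$records, function(r) {
    if (dataset$modality == "dbs")
      dbs_overlap_score(r$site, circuit, mask, patient_id = r$id)
    else
      site_connectivity_score(r$conn_map, circuit, mask, patient_id = r$id)
  })
}

#' Predict outcome change from site scores
#'
#' Partial correlation between per-patient circuit scores and the outcome,
#' controlling for the modality's nuisance covariates, with a parametric
#' two-sided p-value from the t-transform of the partial r
#' (t = r * sqrt(df / (1 - r^2)), df = n - k - 2).
#'
#' @param scores list of `site_score`s (or numeric vector), aligned 1:1
#'   with `dataset$records`.
#' @param dataset a [cohort_dataset()].
#' @param outcome_field outcome name (default "anxiety").
#' @param covariate_fields covariate names; NULL = modality defaults.
#' @return list(r, p, n).
#' @export
predict_outcome_change <- function(scores, dataset, outcome_field = "anxiety",
                                   covariate_fields = NULL) {
  s <- if (is.numeric(scores)) scores
       else vapply(scores, `[[`, numeric(1), "score")
  if (length(s) != dataset$n)
    stop("scores do not align 1:1 with the cohort records")
  if (is.null(covariate_fields))
    covariate_fields <- default_covariates(dataset$modality)
  covariate_fields <- setdiff(covariate_fields, outcome_field)
  y <- vapply(dataset$records, record_field, numeric(1), field = outcome_field)
  C <- if (length(covariate_fields) == 0L) NULL else
    matrix(vapply(dataset$records, function(r)
      vapply(covariate_fields, record_field, numeric(1), record = r),
      numeric(length(covariate_fields))),
      nrow = dataset$n, byrow = TRUE)
  r <- partial_correlation(s, y, C)
  k <- if (is.null(C)) 0L else ncol(C)
  df <- dataset$n - k - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = dataset$n)
}

#' Benchmark a circuit against a library of comparator ROIs
#'
#' Scores each ROI exactly as the circuit is scored (spatial correlation of
#' patient connectivity maps with the ROI for TMS/lesion cohorts, field
#' overlap for DBS), then measures how well those scores predict the
#' outcome. Binary ROI masks are z-scored within the analysis mask before
#' correlation scoring so one scoring path serves all comparators. The
#' `circuit` row for each dataset uses a leave-one-dataset-out circuit
#' rebuilt without that dataset (pass `datasets` containing the training
#' cohorts; held-out cohorts absent from `datasets` are scored against the
#' full combination).
#'
#' @param roi_masks named list of [brain_volume()]s (binary or weighted).
#' @param eval_datasets list of [cohort_dataset()]s to predict.
#' @param train_datasets named list of [cohort_dataset()]s used to build
#'   the circuit rows (leave-one-out when the evaluated dataset is inside).
#' @param mask optional analysis mask.
#' @param outcome_field,covariate_fields forwarded to scoring/prediction.
#' @return data.frame with columns roi, dataset, r, p, n.
#' @export
roi_benchmark <- function(roi_masks, eval_datasets, train_datasets,
                          mask = NULL, outcome_field = "anxiety",
                          covariate_fields = NULL) {
  stopifnot(length(roi_masks) >= 1L)
  train_names <- vapply(train_datasets, `[[`, character(1), "name")
  rows <- list()
  for (ds in eval_datasets) {
    circ <- if (ds$name %in% train_names)
      leave_one_dataset_out(train_datasets, ds$name,
                            outcome_field = outcome_field, mask = mask)
    else weighted_mean_map(lapply(train_datasets, circuit_map,
                                  outcome_field = outcome_field, mask = mask))
    maps <- c(list(circuit = circ), lapply(roi_masks, roi_as_map, circ = circ))
    for (nm in names(maps)) {
      sc <- score_cohort(ds, maps[[nm]], mask)
      pr <- predict_outcome_change(sc, ds, outcome_field, covariate_fields)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = nm, dataset = ds$name, r = pr$r, p = pr$p, n = pr$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# an ROI volume cast as a scoring map on the circuit's mask: binary masks
# are z-scored within the analysis mask so correlation scoring treats them
# on the same footing as continuous maps
roi_as_map <- function(roi, circ) {
  m <- circ$rmap$brain_mask & roi$brain_mask
  v <- roi$data[m]
  if (all(v == 0)) stop("ROI is empty within the analysis mask")
  if (all(v %in% c(0, 1))) v <- as.numeric(scale(v))
  new_circuit_map(volume_from_mask(circ$rmap$grid, m, v),
                  weight = circ$weight, provenance = "roi")
}

#' Behavioural specificity profile of a circuit score
#'
#' Fits the multi-predictor linear model of the per-patient site measure on
#' the primary behavioural measure plus all control measures (and optional
#' covariates), and computes each measure's partial correlation with the
#' site measure controlling for all other measures. The primary measure's
#' rank among all measures by |partial r| quantifies specificity.
#'
#' @param site_measure numeric vector, one score per record.
#' @param dataset a [cohort_dataset()] whose records carry the measures.
#' @param primary name of the measure of interest (e.g. trait anxiety).
#' @param controls names of control measures.
#' @param covariate_fields additional nuisance covariates (never ranked).
#' @return A `specificity_profile`: `measures` (data.frame measure, r, p,
#'   n), `model` (lm fit), `primary_measure`, `rank_of_primary`.
#' @export
specificity_profile <- function(site_measure, dataset, primary, controls,
                                covariate_fields = character(0)) {
  all_meas <- c(primary, controls)
  stopifnot(length(site_measure) == dataset$n)
  M <- vapply(dataset$records, function(r)
    vapply(all_meas, record_field, numeric(1), record = r),
    numeric(length(all_meas)))
  M <- matrix(M, nrow = dataset$n, byrow = TRUE,
              dimnames = list(NULL, all_meas))
  Cov <- if (length(covariate_fields) == 0L) NULL else
    matrix(vapply(dataset$records, function(r)
      vapply(covariate_fields, record_field, numeric(1), record = r),
      numeric(length(covariate_fields))), nrow = dataset$n, byrow = TRUE)
  X <- cbind(M, Cov)
  if (dataset$n < ncol(X) + 3L) stop("too few records for the predictor set")
  if (kappa(cbind(1, scale(X))) > 1e8) stop("collinear predictors")
  fit <- stats::lm(site_measure ~ X)
  rows <- lapply(all_meas, function(nm) {
    others <- X[, setdiff(colnames(X), nm), drop = FALSE]
    r <- partial_correlation(site_measure, M[, nm], others)
    k <- ncol(others)
    df <- dataset$n - k - 2L
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(measure = nm, r = r, p = 2 * stats::pt(-abs(tstat), df),
               n = dataset$n)
  })
  tab <- do.call(rbind, rows)
  rank_primary <- match(primary, tab$measure[order(-abs(tab$r))])
  structure(list(measures = tab, model = fit, primary_measure = primary,
                 rank_of_primary = rank_primary),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("specificity_profile: primary =", x$primary_measure,
      "(rank", x$rank_of_primary, "of", nrow(x$measures), "by |partial r|)\n")
  print(x$measures, digits = 3)
  invisible(x)
}

#' Subgroup prediction with leave-one-dataset-out circuits
#'
#' Splits each dataset by a binary grouping field (e.g. baseline anxiety
#' disorder), predicts the outcome within each group from circuit scores
#' computed against a leave-one-dataset-out circuit, and pools per-group
#' correlations across datasets by group-size-weighted mean.
#'
#' @param datasets named list of [cohort_dataset()]s.
#' @param grouping_field name of a binary (0/1) record field.
#' @param mask optional analysis mask.
#' @param outcome_field,covariate_fields forwarded to prediction.
#' @return data.frame with one row per group: group, pooled_r, n.
#' @export
subgroup_prediction <- function(datasets, grouping_field, mask = NULL,
                                outcome_field = "anxiety",
                                covariate_fields = NULL) {
  per <- list()
  for (ds in datasets) {
    circ <- if (length(datasets) > 1L)
      leave_one_dataset_out(datasets, ds$name,
                            outcome_field = outcome_field, mask = mask)
    else circuit_map(ds, outcome_field = outcome_field, mask = mask)
    grp <- vapply(ds$records, record_field, numeric(1), field = grouping_field)
    if (!all(grp %in% c(0, 1))) stop("grouping field must be binary 0/1")
    for (gv in unique(grp)) {
      recs <- ds$records[grp == gv]
      if (length(recs) < 5L) next
      sub <- cohort_dataset(paste0(ds$name, "_g", gv), ds$modality, recs)
      sc <- score_cohort(sub, circ, mask)
      pr <- predict_outcome_change(sc, sub, outcome_field, covariate_fields)
      per[[length(per) + 1L]] <- data.frame(group = gv, r = pr$r, n = pr$n)
    }
  }
  if (length(per) == 0L) stop("no group large enough in any dataset")
  tab <- do.call(rbind, per)
  out <- do.call(rbind, lapply(split(tab, tab$group), function(d)
    data.frame(group = d$group[1], pooled_r = sum(d$r * d$n) / sum(d$n),
               n = sum(d$n))))
  rownames(out) <- NULL
  out
}
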