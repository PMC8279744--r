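#' Aggregate log-ratio per participant over clusters of interest
#'
#' Averages the trial-level log-ratio over each cluster's bin extent and
#' the trials of the cluster's own condition cell, per participant. Clusters
#' whose `flip` flag is set have their aggregates multiplied by -1 (so
#' clusters expressing a male-character preference can be compared on a
#' common scale with female-preference clusters).
#'
#' @param lr [log_ratio_series()] table.
#' @param clusters_of_interest data.table with one row per cluster:
#'   cluster (a label), action, occupation (the cell), start_bin, end_bin,
#'   flip (logical).
#' @return data.table participant, cluster, value, flipped. Participants
#'   with no valid trials in a cluster's cell are absent from that
#'   cluster's rows.
#' @export
aggregate_cluster_logratio <- function(lr, clusters_of_interest) {
  ci <- data.table::as.data.table(clusters_of_interest)
  out <- lapply(seq_len(nrow(ci)), function(i) {
    cl <- ci[i]
    sub <- lr[action_stereotype == cl$action &
                occupation_stereotype == cl$occupation &
                bin >= cl$start_bin & bin <= cl$end_bin]
    agg <- sub[, .(value = mean(logratio)), by = participant]
    agg[, `:=`(cluster = cl$cluster, flipped = isTRUE(cl$flip))]
    if (isTRUE(cl$flip)) agg[, value := -value]
    agg
  })
  out <- data.table::rbindlist(out)
  data.table::setcolorder(out, c("participant", "cluster", "value",
                                 "flipped"))
  out[]
}

#' Cluster-level OLS regression of gaze preference on attitude scores
#'
#' Ordinary least squares of the per-participant cluster aggregates on the
#' three z-standardized attitude scores, a treatment-coded cluster factor
#' at the given reference level, and all scale-by-cluster interactions.
#' With all predictors at 0 the intercept is the reference cluster's mean
#' aggregate, and each scale's main effect is its slope within the
#' reference cluster; refitting with a rotated reference changes the
#' coefficients but not the fitted values.
#'
#' @param aggregates [aggregate_cluster_logratio()] output (or compatible
#'   data.table with participant, cluster, value).
#' @param scales data.table with participant and columns `ngro`, `asi_bs`,
#'   `asi_hs` (z-standardized; set `standardize = TRUE` to standardize
#'   here).
#' @param reference_cluster Cluster label used as the factor reference.
#' @param standardize If TRUE, z-standardize the scale columns first.
#' @return List of class `attitude_model`: `model` (the lm fit) and
#'   `coefficients` (data.table term, estimate, se, t, p), plus
#'   `reference`.
#' @export
fit_attitude_model <- function(aggregates, scales, reference_cluster,
                               standardize = FALSE) {
  dat <- merge(data.table::as.data.table(aggregates),
               data.table::as.data.table(scales), by = "participant")
  if (length(unique(dat$cluster)) < 2)
    stop("need at least 2 clusters of interest")
  if (anyNA(dat[, .(value, ngro, asi_bs, asi_hs)]))
    stop("missing predictor or response values in retained rows")
  if (standardize)
    for (v in c("ngro", "asi_bs", "asi_hs"))
      dat[, (v) := zscore(get(v))]
  dat[, cluster := stats::relevel(factor(cluster), ref = reference_cluster)]
  fit <- stats::lm(value ~ (ngro + asi_bs + asi_hs) * cluster, data = dat)
  a <- stats::alias(fit)
  if (!is.null(a$Complete))
    stop("rank-deficient attitude model; aliased terms: ",
         paste(rownames(a$Complete), collapse = ", "))
  co <- summary(fit)$coefficients
  structure(list(
    model = fit,
    coefficients = data.table::data.table(
      term = rownames(co), estimate = co[, 1], se = co[, 2],
      t = co[, 3], p = co[, 4]),
    reference = reference_cluster,
    df_residual = fit$df.residual), class = "attitude_model")
}

#' @export
print.attitude_model <- function(x, ...) {
  cat("attitude_model (reference cluster:", x$reference, ")\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fit the attitude model once per reference cluster
#'
#' Refits [fit_attitude_model()] with each cluster as the reference level
#' (identical predictors, rotated treatment coding), the standard way to
#' read each scale's within-cluster slope directly off the coefficient
#' table. Fitted values are identical across rotations.
#'
#' @inheritParams fit_attitude_model
#' @return Named list of `attitude_model`s, one per cluster.
#' @export
fit_attitude_models <- function(aggregates, scales, standardize = FALSE) {
  refs <- sort(unique(as.character(aggregates$cluster)))
  stats::setNames(lapply(refs, function(r)
    fit_attitude_model(aggregates, scales, r, standardize = standardize)),
    refs)
}
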