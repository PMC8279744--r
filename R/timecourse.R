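#' Empirical log-ratio (logit) gaze preference
#'
#' `ln((female + s) / (male + s))` on per-bin sample counts, with additive
#' smoothing `s` so the value stays finite at zero counts (empirical-logit
#' convention). Positive values indicate preference for the female
#' character, negative for the male character; the function is antisymmetric
#' under swapping its arguments.
#'
#' @param female_samples,male_samples Per-bin sample counts, each within
#'   `[0, bin_size]`.
#' @param bin_size Bin width in samples (ms).
#' @param smoothing Additive smoothing constant.
#' @return Numeric vector of log-ratios.
#' @examples
#' log_ratio(40, 40)    # 0
#' log_ratio(100, 0)    # log(100.5/0.5) ~ 5.303
#' @export
log_ratio <- function(female_samples, male_samples, bin_size = 100,
                      smoothing = 0.5) {
  if (any(female_samples < 0) || any(male_samples < 0))
    stop("sample counts must be non-negative")
  if (any(female_samples > bin_size + 1e-8) ||
      any(male_samples > bin_size + 1e-8))
    stop("sample counts cannot exceed bin_size")
  log((female_samples + smoothing) / (male_samples + smoothing))
}

#' Per-trial log-ratio series from binned data
#'
#' Adds the female-vs-male log-ratio to a [bin_experiment()] table, one
#' value per participant x trial x bin.
#'
#' @param bins [bin_experiment()] output.
#' @param smoothing Additive smoothing constant, see [log_ratio()].
#' @return The table with an added `logratio` column.
#' @export
log_ratio_series <- function(bins, smoothing = 0.5) {
  out <- data.table::as.data.table(bins)
  out <- data.table::copy(out)
  out[, logratio := log_ratio(female, male, bin_end - bin_start, smoothing)]
  out[]
}

#' Within-subject adjusted confidence-interval half-widths
#'
#' Cousineau normalization (subtract each participant's mean across
#' conditions, add back the grand mean) followed by a per-condition t-based
#' CI of the normalized values, scaled by the Morey correction factor
#' `sqrt(C / (C - 1))`.
#'
#' @param mat Numeric matrix, participants x conditions; participants with
#'   missing cells are dropped with a warning.
#' @param level Confidence level.
#' @return Named vector of CI half-widths, one per condition.
#' @export
within_subject_ci <- function(mat, level = 0.95) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 conditions")
  complete <- stats::complete.cases(mat)
  if (!all(complete)) {
    warning(sum(!complete), " participant(s) with missing cells dropped ",
            "from the within-subject CI")
    mat <- mat[complete, , drop = FALSE]
  }
  n <- nrow(mat); C <- ncol(mat)
  if (n < 2) stop("need at least 2 complete participants")
  norm <- mat - rowMeans(mat) + mean(mat)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  hw <- tcrit * apply(norm, 2, stats::sd) / sqrt(n) * sqrt(C / (C - 1))
  stats::setNames(hw, colnames(mat))
}

#' Condition-mean fixation-proportion time courses
#'
#' Two-stage aggregation of binned fixation proportions: trials to
#' participant means within each condition cell x bin x AOI, then
#' participant means to condition means, with within-subject adjusted 95%
#' CIs computed per bin x AOI across the condition cells.
#'
#' @param bins [bin_experiment()] output.
#' @param aois AOI columns to summarise.
#' @param level Confidence level for the adjusted CIs.
#' @return data.table per occupation x action x bin x AOI: mean proportion,
#'   ci_halfwidth, n participants.
#' @export
condition_timecourse <- function(bins, aois = c("female", "male",
                                                "object1", "object2"),
                                 level = 0.95) {
  dt <- data.table::as.data.table(bins)
  if (length(unique(dt$participant)) < 2)
    stop("need at least 2 participants")
  bin_ms <- dt$bin_end[1] - dt$bin_start[1]
  long <- data.table::melt(
    dt, id.vars = c("participant", "occupation_stereotype",
                    "action_stereotype", "bin", "bin_start"),
    measure.vars = aois, variable.name = "aoi", value.name = "count",
    variable.factor = FALSE)
  # stage 1: trials -> participant
  p1 <- long[, .(prop = mean(count) / bin_ms),
             by = .(participant, occupation_stereotype, action_stereotype,
                    bin, bin_start, aoi)]
  # stage 2: participants -> condition
  out <- p1[, .(mean = mean(prop), n = .N),
            by = .(occupation_stereotype, action_stereotype, bin,
                   bin_start, aoi)]
  # adjusted CI per bin x AOI across the condition cells
  ci <- p1[, {
    w <- data.table::dcast(.SD, participant ~ occupation_stereotype +
                             action_stereotype, value.var = "prop")
    m <- as.matrix(w[, -1])
    if (ncol(m) >= 2 && sum(stats::complete.cases(m)) >= 2) {
      hw <- suppressWarnings(within_subject_ci(m, level))
      cond <- data.table::tstrsplit(names(hw), "_")
      data.table::data.table(occupation_stereotype = cond[[1]],
                             action_stereotype = cond[[2]],
                             ci_halfwidth = unname(hw))
    } else data.table::data.table(occupation_stereotype = character(0),
                                  action_stereotype = character(0),
                                  ci_halfwidth = numeric(0))
  }, by = .(bin, bin_start, aoi)]
  out <- merge(out, ci,
               by = c("occupation_stereotype", "action_stereotype",
                      "bin", "bin_start", "aoi"), all.x = TRUE)
  data.table::setorder(out, action_stereotype, occupation_stereotype,
                       bin, aoi)
  out[]
}

#' Log-ratio preference time courses
#'
#' Mean log-ratio per occupation condition x bin within each action
#' condition, with within-subject adjusted CIs computed across the two
#' occupation conditions (the quantity plotted in preference time-course
#' figures).
#'
#' @param lr [log_ratio_series()] output.
#' @param level Confidence level.
#' @return data.table per action x occupation x bin: mean, ci_halfwidth, n.
#' @export
logratio_timecourse <- function(lr, level = 0.95) {
  p1 <- lr[, .(value = mean(logratio)),
           by = .(participant, occupation_stereotype, action_stereotype,
                  bin, bin_start)]
  out <- p1[, .(mean = mean(value), n = .N),
            by = .(action_stereotype, occupation_stereotype, bin, bin_start)]
  ci <- p1[, {
    w <- data.table::dcast(.SD, participant ~ occupation_stereotype,
                           value.var = "value")
    m <- as.matrix(w[, -1])
    if (ncol(m) >= 2 && sum(stats::complete.cases(m)) >= 2) {
      hw <- suppressWarnings(within_subject_ci(m, level))
      data.table::data.table(occupation_stereotype = names(hw),
                             ci_halfwidth = unname(hw))
    } else data.table::data.table(occupation_stereotype = character(0),
                                  ci_halfwidth = numeric(0))
  }, by = .(action_stereotype, bin, bin_start)]
  out <- merge(out, ci, by = c("action_stereotype", "occupation_stereotype",
                               "bin", "bin_start"), all.x = TRUE)
  data.table::setorder(out, action_stereotype, occupation_stereotype, bin)
  out[]
}

#' Engagement accuracy on filler questions
#'
#' Mean of binary correct/incorrect filler responses per participant, with
#' an overall summary (grand mean and range) attached as attribute
#' `summary`.
#'
#' @param filler_responses data.table with columns participant and correct
#'   (0/1).
#' @return data.table participant, accuracy, n.
#' @export
score_accuracy <- function(filler_responses) {
  dt <- data.table::as.data.table(filler_responses)
  if (!all(dt$correct %in% c(0, 1)))
    stop("filler responses must be binary 0/1")
  out <- dt[, .(accuracy = mean(correct), n = .N), by = participant]
  data.table::setattr(out, "summary",
                      list(mean = mean(out$accuracy),
                           range = range(out$accuracy)))
  out[]
}
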