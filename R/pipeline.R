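#' Default pipeline configuration
#'
#' All study parameters at their canonical values: 14 occupations x 3
#' displays, 28 fillers, 51 participants, analysis window (-2000, +1000) ms
#' in 100-ms bins, bin-level alpha 0.05, two-tailed cluster criterion
#' 0.025, 2000 permutation iterations.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    n_occupations = 14L, displays_per_occupation = 3L, n_fillers = 28L,
    window = c(-2000, 1000), bin_ms = 100,
    alpha_bin = 0.05, criterion = 0.025, n_iterations = 2000L,
    min_cluster_length = 1L,
    design_seed = 1L, sim_seed = 1L, perm_seed = 1L, likert_seed = 1L,
    generator = generator_params(),
    likert = list(ngro = likert_params(29L, c(1L, 7L), 0.89),
                  asi_bs = likert_params(11L, c(0L, 5L), 0.90),
                  asi_hs = likert_params(11L, c(0L, 5L), 0.89)),
    inputs = NULL,  # list(fixations=, trials=, fillers=) paths to ingest
    out_dir = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for missing entries and checks all invariants, collecting
#' every violation rather than stopping at the first.
#'
#' @param config Partial configuration list (possibly empty).
#' @return The completed configuration, or an error listing all violations.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(length(cfg$window) == 2 && cfg$window[1] < cfg$window[2],
      "window must be c(lo, hi) with lo < hi")
  chk(cfg$bin_ms > 0, "bin_ms must be positive")
  if (cfg$bin_ms > 0)
    chk(all(cfg$window %% cfg$bin_ms == 0),
        "window bounds must be multiples of bin_ms")
  chk(cfg$alpha_bin > 0 && cfg$alpha_bin < 1, "alpha_bin must be in (0,1)")
  chk(cfg$criterion > 0 && cfg$criterion < 1, "criterion must be in (0,1)")
  chk(cfg$n_iterations >= 1, "n_iterations must be >= 1")
  chk(cfg$n_occupations >= 2 && cfg$n_occupations %% 2 == 0,
      "n_occupations must be even and >= 2")
  chk(cfg$generator$n_participants >= 1, "need at least 1 participant")
  chk(inherits(cfg$generator, "generator_params"),
      "generator must be generator_params()")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Run the full analysis pipeline
#'
#' Design construction, gaze simulation (or ingestion of fixation/trial/
#' filler TSVs named in `config$inputs`), binning, time courses,
#' cluster-based randomization inference, attitude scale scoring and the
#' cluster-level attitude regression, as one reproducible run. The result
#' is a pure function of the configuration (including its seeds); when
#' `config$out_dir` is set, all stage tables are written there as TSV plus
#' a JSON run report.
#'
#' @param config Configuration list, completed via [validate_config()].
#' @return List of class `run_report`: config echo, stage row counts,
#'   accuracy summary, timecourses, cluster table, attitude coefficient
#'   tables, scale alphas.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  item_set <- build_item_set(cfg$n_occupations, cfg$displays_per_occupation,
                             cfg$n_fillers)
  lists <- latin_square_lists(item_set)
  if (is.null(cfg$inputs)) {
    sim <- simulate_experiment(lists, item_set, cfg$generator,
                               seed = cfg$sim_seed)
    fixations <- sim$fixations; trials <- sim$trials; fillers <- sim$fillers
    aoi_map <- sim$aoi_map
  } else {
    fixations <- read_fixation_report(cfg$inputs$fixations)
    trials <- data.table::fread(cfg$inputs$trials, sep = "\t")
    fillers <- data.table::fread(cfg$inputs$fillers, sep = "\t")
    aoi_map <- if (!is.null(cfg$inputs$aoi_map))
      data.table::fread(cfg$inputs$aoi_map, sep = "\t")
    else default_aoi_map()
  }
  bins <- bin_experiment(fixations, trials, aoi_map,
                         window = cfg$window, bin_ms = cfg$bin_ms)
  lr <- log_ratio_series(bins)
  acc <- score_accuracy(fillers)
  tc <- condition_timecourse(bins)
  lrtc <- logratio_timecourse(lr)
  ca <- cluster_analysis(lr, n_iterations = cfg$n_iterations,
                         seed = cfg$perm_seed, alpha = cfg$alpha_bin,
                         criterion = cfg$criterion,
                         min_length = cfg$min_cluster_length)
  # attitude stage: pre-noun significant zero-reference clusters of interest
  att <- attitude_stage(lr, ca, cfg)
  report <- structure(list(
    config = cfg,
    counts = list(fixations = nrow(fixations), trials = nrow(trials),
                  fillers = nrow(fillers), bins = nrow(bins),
                  clusters = nrow(ca$clusters),
                  significant_clusters = sum(ca$clusters$significant)),
    accuracy = attr(acc, "summary"),
    accuracy_by_participant = acc,
    timecourse = tc, logratio_timecourse = lrtc,
    clusters = ca$clusters, cluster_analysis = ca,
    attitudes = att), class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# score scales, aggregate pre-noun significant clusters, fit the OLS models
attitude_stage <- function(lr, ca, cfg) {
  n <- cfg$generator$n_participants
  likert <- withr_seed(cfg$likert_seed, list(
    ngro = simulate_likert(n, cfg$likert$ngro),
    asi_bs = simulate_likert(n, cfg$likert$asi_bs),
    asi_hs = simulate_likert(n, cfg$likert$asi_hs)))
  scores <- score_attitudes(likert$ngro, likert$asi_bs, likert$asi_hs)
  # clusters of interest: significant zero-reference clusters beginning
  # before the noun; aggregation is truncated at noun onset so the
  # aggregate reflects the anticipatory portion only
  pre <- ca$clusters[significant == TRUE & start_ms < 0 &
                       contrast != "condition"]
  if (nrow(pre) < 2)
    return(list(scores = scores, alphas = attr(scores, "alpha"),
                clusters_of_interest = pre, models = NULL))
  last_pre_bin <- as.integer((0 - cfg$window[1]) / cfg$bin_ms)
  coi <- pre[, .(
    cluster = paste0(ifelse(contrast == "female-vs-zero", "fem_occ",
                            "male_occ"), "_", action, "_act_", start_ms),
    action,
    occupation = ifelse(contrast == "female-vs-zero", "female", "male"),
    start_bin,
    end_bin = pmin(end_bin, last_pre_bin),
    flip = sum_t < 0)]
  agg <- aggregate_cluster_logratio(lr, coi)
  scl <- scores[, .(participant, ngro = ngro_z, asi_bs = asi_bs_z,
                    asi_hs = asi_hs_z)]
  models <- fit_attitude_models(agg, scl)
  list(scores = scores, alphas = attr(scores, "alpha"),
       clusters_of_interest = coi, aggregates = agg, models = models)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                         sep = "\t")
  w(report$timecourse, "timecourse.tsv")
  w(report$logratio_timecourse, "logratio_timecourse.tsv")
  w(report$clusters, "clusters.tsv")
  w(report$accuracy_by_participant, "accuracy.tsv")
  if (!is.null(report$attitudes$models)) {
    coefs <- data.table::rbindlist(lapply(names(report$attitudes$models),
      function(r) {
        co <- report$attitudes$models[[r]]$coefficients
        co <- data.table::copy(co)
        co[, reference := r]
        co
      }))
    w(coefs, "attitude_coefficients.tsv")
  }
  js <- list(
    counts = report$counts, accuracy = report$accuracy,
    seeds = report$config[c("design_seed", "sim_seed", "perm_seed",
                            "likert_seed")],
    n_iterations = report$config$n_iterations,
    alphas = as.list(report$attitudes$alphas))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  trials: %d, fixations: %d, bins: %d\n",
              x$counts$trials, x$counts$fixations, x$counts$bins))
  cat(sprintf("  filler accuracy: mean %.3f (range %.2f-%.2f)\n",
              x$accuracy$mean, x$accuracy$range[1], x$accuracy$range[2]))
  cat(sprintf("  clusters: %d (%d significant)\n", x$counts$clusters,
              x$counts$significant_clusters))
  invisible(x)
}
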