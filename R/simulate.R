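#' Generator parameters for synthetic visual-world gaze data
#'
#' Bundles the parameters of the renewal-process gaze generator: gamma dwell
#' times, a multinomial choice among the five gaze targets (female character,
#' male character, two objects, elsewhere) at each fixation onset, and
#' condition-specific anticipatory and post-noun referential preference ramps
#' expressed as logistic shifts in log-odds toward a target character.
#'
#' Default anticipation onsets encode the condition-specific pattern the
#' analysis is designed to detect: preference for the stereotype-consistent
#' character from 1200 ms before the critical noun when action and occupation
#' stereotypes are both female, from 800 ms before when a female action is
#' heard in a male-occupation display, from 500 ms before for a male action
#' in a female-occupation display, and no anticipation for male action with
#' male occupation or for neutral actions. The referential ramp toward the
#' named agent starts 200 ms after noun onset (oculomotor delay).
#'
#' @param n_participants Number of participants (default 51).
#' @param dwell_mean,dwell_shape Gamma dwell-time mean (ms) and shape.
#' @param baseline Named probability 5-vector over
#'   `c("female","male","object1","object2","elsewhere")`; must sum to 1.
#' @param anticipation data.table with one row per design cell:
#'   occupation_stereotype, action_stereotype, onset (ms relative to noun
#'   onset, NA = no anticipation), asymptote, slope (1/ms), target character.
#' @param referential_onset,referential_asymptote,referential_slope Post-noun
#'   ramp toward the named agent.
#' @param verb_onset_mean,verb_onset_sd Verb-to-noun lead time distribution
#'   (ms, truncated normal > 0).
#' @param participant_sd,item_sd Random-effect SDs on the log-odds asymptote
#'   of target preference.
#' @param preview_ms Display preview before speech onset.
#' @param pre_verb_ms Speech onset to critical-verb onset.
#' @param post_noun_ms Trial continues this long after noun onset.
#' @param filler_accuracy Bernoulli probability of a correct filler response.
#' @param dropout Probability that a fixation is dropped (track loss),
#'   leaving a gap counted as elsewhere.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_participants = 51,
                             dwell_mean = 220, dwell_shape = 4,
                             baseline = c(female = 0.25, male = 0.25,
                                          object1 = 0.175, object2 = 0.175,
                                          elsewhere = 0.15),
                             anticipation = default_anticipation(),
                             referential_onset = 200,
                             referential_asymptote = 0.85,
                             referential_slope = 0.015,
                             verb_onset_mean = 1719.26,
                             verb_onset_sd = 228.75,
                             participant_sd = 0.3, item_sd = 0.3,
                             preview_ms = 3000, pre_verb_ms = 1000,
                             post_noun_ms = 1500,
                             filler_accuracy = 0.91,
                             dropout = 0) {
  if (abs(sum(baseline) - 1) > 1e-8 || any(baseline < 0))
    stop("baseline probabilities must be non-negative and sum to 1")
  if (!all(aoi_levels() %in% names(baseline)))
    stop("baseline must be named over the five gaze targets")
  if (any(!is.na(anticipation$asymptote) &
          (anticipation$asymptote <= 0 | anticipation$asymptote >= 1)))
    stop("asymptotes must lie in (0, 1)")
  if (dwell_mean <= 0 || dwell_shape <= 0) stop("dwell parameters must be > 0")
  structure(list(
    n_participants = n_participants, dwell_mean = dwell_mean,
    dwell_shape = dwell_shape, baseline = baseline[aoi_levels()],
    anticipation = anticipation, referential_onset = referential_onset,
    referential_asymptote = referential_asymptote,
    referential_slope = referential_slope,
    verb_onset_mean = verb_onset_mean, verb_onset_sd = verb_onset_sd,
    participant_sd = participant_sd, item_sd = item_sd,
    preview_ms = preview_ms, pre_verb_ms = pre_verb_ms,
    post_noun_ms = post_noun_ms, filler_accuracy = filler_accuracy,
    dropout = dropout), class = "generator_params")
}

#' @rdname generator_params
#' @export
default_anticipation <- function() {
  data.table::data.table(
    occupation_stereotype = c("female", "male", "female", "male",
                              "female", "male"),
    action_stereotype = c("female", "female", "male", "male",
                          "neutral", "neutral"),
    onset = c(-1200, -800, -500, NA, NA, NA),
    asymptote = c(0.65, 0.65, 0.65, NA, NA, NA),
    slope = c(0.015, 0.015, 0.015, NA, NA, NA),
    target = c("female", "female", "male", NA, NA, NA)
  )
}

#' Null generator parameters: flat gaze preference everywhere
#'
#' All anticipation profiles disabled and no referential effect; gaze stays
#' at the baseline multinomial for the whole trial. Used for type-I-error
#' calibration of the cluster test.
#'
#' @param ... Overrides passed on to [generator_params()].
#' @export
null_generator_params <- function(...) {
  ant <- default_anticipation()
  ant[, `:=`(onset = NA_real_, asymptote = NA_real_, slope = NA_real_,
             target = NA_character_)]
  generator_params(anticipation = ant, referential_asymptote = NA, ...)
}

aoi_levels <- function() c("female", "male", "object1", "object2", "elsewhere")

logit <- function(p) log(p / (1 - p))

# half-logistic ramp: 0 at onset, -> 1 as t grows; 0 before onset
ramp_weight <- function(t, onset, slope) {
  w <- 2 / (1 + exp(-slope * (t - onset))) - 1
  w[t < onset | is.na(onset)] <- 0
  w
}

#' Instantaneous AOI choice probabilities
#'
#' Probability over the five gaze targets at time `t` (ms relative to noun
#' onset) for one design cell. Before any effect onset the vector equals the
#' baseline; past an onset the target character's log-odds ramp from the
#' baseline value toward the asymptote's log-odds (plus additive participant
#' and item effects) along a logistic-shaped curve, the other targets being
#' renormalized proportionally.
#'
#' @param t Numeric vector of times (ms, relative to noun onset).
#' @param cell List or one-row data.frame with `occupation_stereotype` and
#'   `action_stereotype`.
#' @param params [generator_params()].
#' @param participant_effect,item_effect Additive log-odds shifts of the
#'   preference asymptote.
#' @param agent_gender "female" or "male": the character named by the
#'   sentence (target of the post-noun referential ramp).
#' @return Matrix `length(t)` x 5 of probabilities (rows sum to 1).
#' @export
preference_probabilities <- function(t, cell, params,
                                     participant_effect = 0, item_effect = 0,
                                     agent_gender = NULL) {
  stopifnot(inherits(params, "generator_params"))
  a_tab <- params$anticipation
  i <- which(a_tab$occupation_stereotype == cell$occupation_stereotype &
               a_tab$action_stereotype == cell$action_stereotype)
  if (length(i) != 1)
    stop("unknown design cell: ", cell$occupation_stereotype, "/",
         cell$action_stereotype)
  ant <- list(onset = a_tab$onset[i], asymptote = a_tab$asymptote[i],
              slope = a_tab$slope[i], target = a_tab$target[i])
  base <- params$baseline
  lw <- matrix(log(base), nrow = length(t), ncol = 5, byrow = TRUE)
  colnames(lw) <- names(base)
  re <- participant_effect + item_effect
  if (!is.na(ant$onset)) {
    w <- ramp_weight(t, ant$onset, ant$slope)
    shift <- w * (logit(ant$asymptote) + re - logit(base[[ant$target]]))
    lw[, ant$target] <- lw[, ant$target] + shift
  }
  if (is.null(agent_gender) || is.na(agent_gender)) agent_gender <- NULL
  if (!is.na(params$referential_asymptote) && !is.null(agent_gender)) {
    w <- ramp_weight(t, params$referential_onset, params$referential_slope)
    shift <- w * (logit(params$referential_asymptote) + re -
                    logit(base[[agent_gender]]))
    lw[, agent_gender] <- lw[, agent_gender] + shift
  }
  p <- exp(lw)
  p / rowSums(p)
}

# rowwise categorical draw from a probability matrix
sample_rows <- function(p, u = stats::runif(nrow(p))) {
  cs <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)
  idx <- max.col(cs >= u, ties.method = "first")
  colnames(p)[idx]
}

#' Simulate the fixation sequence of one trial
#'
#' Renewal process: fixation dwell times are gamma distributed; at each
#' fixation onset a gaze target is drawn from
#' [preference_probabilities()] frozen at the onset time. Fixations tile the
#' trial without overlap; dropped fixations (track loss) leave gaps.
#'
#' @param trial List with `noun_onset` (ms, trial clock),
#'   `occupation_stereotype`, `action_stereotype`, `agent_gender`.
#' @param params [generator_params()].
#' @param participant_effect,item_effect Log-odds random effects.
#' @param deterministic If TRUE, dwell is fixed at `dwell_mean` and the
#'   modal gaze target is chosen (no randomness); used for oracle tests.
#' @return data.table with columns start, end (ms, trial clock), aoi.
#' @export
simulate_trial <- function(trial, params, participant_effect = 0,
                           item_effect = 0, deterministic = FALSE) {
  stopifnot(inherits(params, "generator_params"))
  core <- sim_trial_core(trial, params, participant_effect, item_effect,
                         deterministic)
  data.table::data.table(start = core$start, end = core$end,
                         aoi = core$aoi)
}

# fixation sequence as plain vectors (hot path of simulate_experiment)
sim_trial_core <- function(trial, params, participant_effect = 0,
                           item_effect = 0, deterministic = FALSE) {
  t_end <- trial$noun_onset + params$post_noun_ms
  if (deterministic) {
    starts <- seq(0, t_end - 1e-9, by = params$dwell_mean)
    dwells <- rep(params$dwell_mean, length(starts))
  } else {
    starts <- numeric(0); dwells <- numeric(0); cur <- 0
    while (cur < t_end) {
      k <- max(16L, ceiling((t_end - cur) / params$dwell_mean * 1.5))
      d <- stats::rgamma(k, shape = params$dwell_shape,
                         scale = params$dwell_mean / params$dwell_shape)
      s <- cur + cumsum(c(0, d[-k]))
      keep <- s < t_end
      starts <- c(starts, s[keep]); dwells <- c(dwells, d[keep])
      cur <- cur + sum(d)
    }
  }
  p <- preference_probabilities(starts - trial$noun_onset, trial, params,
                                participant_effect, item_effect,
                                agent_gender = trial$agent_gender)
  aoi <- if (deterministic) colnames(p)[max.col(p, ties.method = "first")]
         else sample_rows(p)
  # report times at 1-ms resolution, as fixation reports do; rounding the
  # shared boundaries keeps consecutive fixations abutting, never overlapping
  b <- round(c(starts, starts[length(starts)] + dwells[length(dwells)]))
  s <- b[-length(b)]
  e <- pmin(b[-1], round(t_end))
  keep <- e > s
  if (!deterministic && params$dropout > 0)
    keep <- keep & stats::runif(length(s)) >= params$dropout
  list(start = s[keep], end = e[keep], aoi = aoi[keep])
}

# truncated-normal (> 0) draw of verb-to-noun lead times
#' Draw verb-to-noun lead times
#'
#' Truncated normal (> 0) draws of the interval between critical-verb onset
#' and critical-noun onset.
#' @param n Number of draws.
#' @param mean,sd Distribution parameters in ms.
#' @export
rverb_onset <- function(n, mean = 1719.26, sd = 228.75) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a full visual-world experiment
#'
#' One participant per presentation list in rotation. Gaze is simulated for
#' experimental trials only; filler trials contribute Bernoulli
#' correct/incorrect engagement-check responses. Fixation coordinates are
#' drawn inside the assigned AOI rectangle of `aoi_map` (or outside all
#' rectangles for elsewhere fixations), so the output exercises the same
#' point-in-rectangle AOI assignment as real fixation reports.
#'
#' @param lists Result of [latin_square_lists()].
#' @param item_set The matching [build_item_set()] result.
#' @param params [generator_params()].
#' @param seed Integer seed; the full dataset is a pure function of
#'   (design, params, seed).
#' @param aoi_map AOI rectangle table, default [default_aoi_map()].
#' @return List of class `gaze_experiment` with data.tables `fixations`
#'   (participant, trial, start, end, x, y, aoi), `trials` (participant,
#'   trial, item and condition columns, verb_onset, noun_onset), `fillers`
#'   (participant, filler_id, correct), plus `params` and `aoi_map`.
#' @export
simulate_experiment <- function(lists, item_set, params = generator_params(),
                                seed = 1L, aoi_map = default_aoi_map()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_participants
  if (n < 1) stop("need at least one participant")
  withr_seed(seed, {
    part_seeds <- sample.int(.Machine$integer.max - 1L, n)
    part_eff <- stats::rnorm(n, 0, params$participant_sd)
    item_ids <- item_set$items$item_id
    item_eff <- stats::setNames(stats::rnorm(length(item_ids), 0,
                                             params$item_sd),
                                as.character(item_ids))
    fix_all <- vector("list", n); tri_all <- vector("list", n)
    fil_all <- vector("list", n)
    for (p in seq_len(n)) {
      l <- ((p - 1L) %% length(lists)) + 1L
      ord <- randomize_presentation(lists[[l]], item_set$fillers,
                                    seed = part_seeds[p])
      exp_tr <- ord[trial_type == "experimental"]
      exp_tr[, verb_lead := rverb_onset(.N, params$verb_onset_mean,
                                        params$verb_onset_sd)]
      exp_tr[, verb_onset := params$preview_ms + params$pre_verb_ms]
      # onsets are reported at 1-ms resolution, like the fixation times
      exp_tr[, noun_onset := round(verb_onset + verb_lead)]
      tr_list <- lapply(seq_len(nrow(exp_tr)), function(i) {
        tr <- list(noun_onset = exp_tr$noun_onset[i],
                   occupation_stereotype =
                     exp_tr$occupation_stereotype[i],
                   action_stereotype = exp_tr$action_stereotype[i],
                   agent_gender = exp_tr$agent_gender[i])
        f <- sim_trial_core(tr, params, part_eff[p],
                            item_eff[[as.character(exp_tr$item_id[i])]])
        f$trial <- rep(exp_tr$position[i], length(f$start))
        f
      })
      fx <- data.table::data.table(
        start = unlist(lapply(tr_list, `[[`, "start")),
        end = unlist(lapply(tr_list, `[[`, "end")),
        aoi = unlist(lapply(tr_list, `[[`, "aoi")),
        trial = unlist(lapply(tr_list, `[[`, "trial")))
      fx[, participant := p]
      xy <- aoi_to_xy(fx$aoi, aoi_map)
      fx[, `:=`(x = xy$x, y = xy$y)]
      tri <- exp_tr[, .(participant = p, trial = position, item_id,
                        list_id = l, occupation_stereotype,
                        action_stereotype, agent_gender, cell,
                        verb_onset, noun_onset)]
      fil <- ord[trial_type == "filler",
                 .(participant = p, trial = position, filler_id,
                   correct = as.integer(stats::runif(.N) <
                                          params$filler_accuracy))]
      fix_all[[p]] <- fx; tri_all[[p]] <- tri; fil_all[[p]] <- fil
    }
    structure(list(
      fixations = data.table::rbindlist(fix_all)[
        , .(participant, trial, start, end, x, y, aoi)],
      trials = data.table::rbindlist(tri_all),
      fillers = data.table::rbindlist(fil_all),
      params = params, aoi_map = aoi_map, seed = seed),
      class = "gaze_experiment")
  })
}

#' @export
print.gaze_experiment <- function(x, ...) {
  cat(sprintf(paste0("gaze_experiment: %d participants, %d fixations, ",
                     "%d experimental trials, %d filler responses\n"),
              length(unique(x$trials$participant)), nrow(x$fixations),
              nrow(x$trials), nrow(x$fillers)))
  invisible(x)
}

# place a fixation point inside (or, for elsewhere, outside) the AOI rects
aoi_to_xy <- function(aoi, aoi_map) {
  n <- length(aoi)
  x <- numeric(n); y <- numeric(n)
  u1 <- stats::runif(n, 0.1, 0.9); u2 <- stats::runif(n, 0.1, 0.9)
  for (a in setdiff(unique(aoi), "elsewhere")) {
    r <- aoi_map[aoi == a]
    i <- which(aoi == a)
    x[i] <- r$x0 + u1[i] * (r$x1 - r$x0)
    y[i] <- r$y0 + u2[i] * (r$y1 - r$y0)
  }
  i <- which(aoi == "elsewhere")
  if (length(i)) {
    gap <- elsewhere_point(aoi_map)
    x[i] <- gap[1]; y[i] <- gap[2]
  }
  list(x = x, y = y)
}

# a screen point guaranteed to fall outside every AOI rectangle
elsewhere_point <- function(aoi_map) {
  x <- max(aoi_map$x1) + 10
  y <- max(aoi_map$y1) + 10
  c(x, y)
}

#' Mirror an experiment's gender labels
#'
#' Relabels the dataset under a global female/male swap: fixation AOI labels
#' and coordinates move between the two character rectangles, occupation and
#' action stereotypes swap (neutral actions unchanged), and agent gender
#' swaps. The downstream log-ratio series of the mirrored data is exactly
#' the negation of the original's once cells are matched under the swap.
#'
#' @param experiment A [simulate_experiment()] result.
#' @return A new `gaze_experiment` with mirrored labels.
#' @export
mirror_experiment <- function(experiment) {
  swap <- function(x) data.table::fcase(x == "female", "male",
                                        x == "male", "female",
                                        default = x)
  fx <- data.table::copy(experiment$fixations)
  map <- experiment$aoi_map
  rf <- map[aoi == "female"]; rm_ <- map[aoi == "male"]
  transfer <- function(i, from, to) {
    fx[i, `:=`(x = to$x0 + (x - from$x0) / (from$x1 - from$x0) *
                 (to$x1 - to$x0),
               y = to$y0 + (y - from$y0) / (from$y1 - from$y0) *
                 (to$y1 - to$y0))]
  }
  fem <- which(fx$aoi == "female"); mal <- which(fx$aoi == "male")
  transfer(fem, rf, rm_); transfer(mal, rm_, rf)
  fx[, aoi := swap(aoi)]
  tri <- data.table::copy(experiment$trials)
  tri[, `:=`(occupation_stereotype = swap(occupation_stereotype),
             action_stereotype = swap(action_stereotype),
             agent_gender = swap(agent_gender))]
  out <- experiment
  out$fixations <- fx
  out$trials <- tri
  out
}

#' Likert response generator parameters
#'
#' @param n_items Number of scale items.
#' @param bounds Integer response bounds, `c(min, max)`.
#' @param target_alpha Population Cronbach's alpha of the continuous latent
#'   responses (in `[0, 1)`); the common-factor loading is derived from it.
#' @export
likert_params <- function(n_items = 29, bounds = c(1L, 7L),
                          target_alpha = 0.89) {
  if (target_alpha >= 1 || target_alpha < 0)
    stop("target_alpha must lie in [0, 1)")
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy min < max")
  structure(list(n_items = n_items, bounds = as.integer(bounds),
                 target_alpha = target_alpha), class = "likert_params")
}

#' Simulate Likert item responses with a target reliability
#'
#' One-factor model: item j of respondent i is
#' `lambda * theta_i + sqrt(1 - lambda^2) * eps_ij` with standard-normal
#' trait and noise, so items are standardized with inter-item correlation
#' `r = lambda^2`; `lambda` is chosen so the continuous responses have
#' Cronbach's alpha equal to `target_alpha` (`r = alpha / (k - alpha(k-1))`).
#' The continuous responses are then cut at equal-probability (normal
#' quantile) thresholds into the integer response categories, which
#' attenuates alpha slightly.
#'
#' @param n_respondents Number of respondents (>= 2).
#' @param params [likert_params()].
#' @param seed Optional integer seed.
#' @return Integer matrix respondents x items.
#' @export
simulate_likert <- function(n_respondents, params = likert_params(),
                            seed = NULL) {
  stopifnot(inherits(params, "likert_params"))
  if (n_respondents < 2) stop("need at least 2 respondents")
  k <- params$n_items
  a <- params$target_alpha
  r <- if (a == 0) 0 else a / (k - a * (k - 1))
  lam <- sqrt(r)
  gen <- function() {
    theta <- stats::rnorm(n_respondents)
    eps <- matrix(stats::rnorm(n_respondents * k), n_respondents, k)
    xc <- lam * theta + sqrt(1 - lam^2) * eps
    m <- params$bounds[2] - params$bounds[1] + 1L
    th <- stats::qnorm(seq_len(m - 1) / m)
    matrix(params$bounds[1] + findInterval(xc, th), n_respondents, k,
           dimnames = list(NULL, paste0("item_", seq_len(k))))
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Simulate cluster-level gaze aggregates and attitude scores
#'
#' Generates per-participant mean log-ratio aggregates for a set of
#' pre-noun clusters of interest together with standard-normal attitude
#' scores, with configurable linear slopes of the aggregates on the scores.
#' Used to calibrate the cluster-level attitude regression.
#'
#' @param n_participants Number of participants.
#' @param beta Named numeric vector of slopes per scale
#'   (`ngro`, `asi_bs`, `asi_hs`), per SD of the scale.
#' @param cluster_means Named numeric vector of cluster mean aggregates.
#' @param participant_sd SD of the participant intercept shared across
#'   clusters.
#' @param resid_sd Residual SD of an aggregate.
#' @param seed Optional integer seed.
#' @return List with data.tables `aggregates` (participant, cluster, value)
#'   and `scales` (participant, ngro, asi_bs, asi_hs).
#' @export
simulate_attitude_data <- function(n_participants = 51,
                                   beta = c(ngro = 0, asi_bs = 0,
                                            asi_hs = 0),
                                   cluster_means = c(fem_act_fem_occ = 0.070,
                                                     male_act_fem_occ = 0.062,
                                                     fem_act_male_occ = 0.069),
                                   participant_sd = 0.05, resid_sd = 0.14,
                                   seed = NULL) {
  gen <- function() {
    scales <- data.table::data.table(
      participant = seq_len(n_participants),
      ngro = stats::rnorm(n_participants),
      asi_bs = stats::rnorm(n_participants),
      asi_hs = stats::rnorm(n_participants))
    pint <- stats::rnorm(n_participants, 0, participant_sd)
    agg <- data.table::CJ(participant = seq_len(n_participants),
                          cluster = names(cluster_means), sorted = FALSE)
    agg[, value := cluster_means[cluster] + pint[participant] +
          beta["ngro"] * scales$ngro[participant] +
          beta["asi_bs"] * scales$asi_bs[participant] +
          beta["asi_hs"] * scales$asi_hs[participant] +
          stats::rnorm(.N, 0, resid_sd)]
    list(aggregates = agg, scales = scales)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}
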