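#' Per-bin statistical test of the log-ratio
#'
#' Tests, within one action-condition scope and one 100-ms bin, either the
#' contrast between the two occupation conditions ("condition") or a single
#' occupation condition against zero ("female-vs-zero", "male-vs-zero").
#' Positive t means preference for the female character (condition contrast:
#' female-occupation minus male-occupation).
#'
#' Two routes are available. `method = "lmm"` fits a linear mixed model of
#' the log-ratio on a +-0.5 contrast code with crossed random intercepts for
#' participants and items (zero-reference contrasts are fitted on the
#' [zero_reference()]-augmented table) and returns the fixed-effect t; on
#' failure it falls back to the aggregated route with `converged = FALSE`.
#' `method = "agg"` collapses trials to participant-level means and computes
#' the paired (condition) or one-sample (vs zero) t. Bin-level significance
#' uses the normal approximation (p < 0.05 iff |t| > 1.96); the permutation
#' stage calibrates the final inference, so the bin test only forms
#' clusters.
#'
#' @param lr [log_ratio_series()] table.
#' @param bin Bin index to test.
#' @param contrast One of "condition", "female-vs-zero", "male-vs-zero".
#' @param scope List with `action`: the action condition to test within.
#' @param method "agg" (participant-aggregated t, default) or "lmm".
#' @param contrast_factor "occupation" (default): occupation contrast within
#'   an action-condition scope. "action": the roles swap — female- vs
#'   male-stereotypical action contrast within an occupation-condition
#'   scope (neutral-action trials are excluded), and `scope$action` then
#'   names the occupation condition.
#' @return One-row data.table: bin, contrast, action, t, p, method,
#'   converged.
#' @export
per_bin_test <- function(lr, bin, contrast = c("condition", "female-vs-zero",
                                               "male-vs-zero"),
                         scope = list(action = "female"),
                         method = c("agg", "lmm"),
                         contrast_factor = c("occupation", "action")) {
  contrast <- match.arg(contrast)
  method <- match.arg(method)
  lr <- orient_lr(lr, match.arg(contrast_factor))
  b <- bin
  sub <- lr[action_stereotype == scope$action & bin == b]
  if (nrow(sub) == 0) stop("empty scope: no data for action ", scope$action,
                           " in bin ", bin)
  if (contrast == "condition" &&
      length(unique(sub$occupation_stereotype)) < 2)
    stop("condition contrast needs both occupation levels in scope")
  res <- if (method == "lmm") per_bin_lmm(sub, contrast)
         else per_bin_agg(sub, contrast)
  data.table::data.table(bin = b, contrast = contrast,
                         action = scope$action, t = res$t,
                         p = 2 * stats::pnorm(-abs(res$t)),
                         method = res$method, converged = res$converged)
}

# participant-aggregated paired / one-sample t
per_bin_agg <- function(sub, contrast) {
  if (contrast == "condition") {
    pm <- sub[, .(m = mean(logratio)),
              by = .(participant, occupation_stereotype)]
    w <- data.table::dcast(pm, participant ~ occupation_stereotype,
                           value.var = "m")
    d <- w$female - w$male
    d <- d[!is.na(d)]
  } else {
    occ <- if (contrast == "female-vs-zero") "female" else "male"
    d <- sub[occupation_stereotype == occ,
             .(m = mean(logratio)), by = participant]$m
  }
  list(t = safe_t(d), method = "agg", converged = TRUE)
}

safe_t <- function(d) {
  n <- length(d)
  if (n < 2) return(0)
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) return(0)
  mean(d) / (s / sqrt(n))
}

# mixed model with crossed random intercepts; +-0.5 contrast code
per_bin_lmm <- function(sub, contrast) {
  if (contrast == "condition") {
    dat <- data.table::copy(sub)
    dat[, code := ifelse(occupation_stereotype == "female", 0.5, -0.5)]
    dat[, value := logratio]
  } else {
    occ <- if (contrast == "female-vs-zero") "female" else "male"
    dat <- zero_reference(sub[occupation_stereotype == occ])
    dat[, code := ifelse(label == "real", 0.5, -0.5)]
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ code + (1 | participant) + (1 | item_id),
                 data = dat, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- per_bin_agg(sub, contrast)
    out$converged <- FALSE
    return(out)
  }
  co <- summary(fit)$coefficients
  tv <- if ("code" %in% rownames(co)) co["code", "t value"] else 0
  if (!is.finite(tv)) tv <- 0
  list(t = tv, method = "lmm", converged = TRUE)
}

#' Augment a log-ratio table with a zero reference distribution
#'
#' Adds one pseudo-observation with value 0 (label "zero") mirroring each
#' real observation's participant/item/bin keys, so a real-vs-zero contrast
#' can be run with the same machinery as a two-condition contrast.
#'
#' @param lr Log-ratio table (or subset) with a `logratio` column.
#' @return data.table with 2n rows and columns `value`
#'   (log-ratio or 0) and `label` ("real"/"zero") added.
#' @export
zero_reference <- function(lr) {
  if (nrow(lr) == 0) stop("empty scope")
  real <- data.table::copy(lr)[, `:=`(value = logratio, label = "real")]
  zero <- data.table::copy(lr)[, `:=`(value = 0, label = "zero")]
  rbind(real, zero)
}

#' Find clusters of consecutive significant bins
#'
#' Maximal runs of consecutive bins with p below `alpha` and a common t
#' sign (a sign change splits a cluster), each at least `min_length` bins
#' long, with the summed t recorded.
#'
#' @param bin_results data.table with columns bin, t, p covering a
#'   contiguous bin range (e.g. rows of [per_bin_test()]).
#' @param alpha Bin-level cluster-forming threshold.
#' @param min_length Minimum cluster length in bins.
#' @return data.table: start_bin, end_bin, n_bins, sum_t (possibly empty).
#' @export
find_clusters <- function(bin_results, alpha = 0.05, min_length = 1L) {
  dt <- data.table::as.data.table(bin_results)
  data.table::setorder(dt, bin)
  sig <- dt$p < alpha & dt$t != 0
  if (!any(sig))
    return(data.table::data.table(start_bin = integer(0),
                                  end_bin = integer(0),
                                  n_bins = integer(0), sum_t = numeric(0)))
  # group id changes when significance toggles, bins skip, or sign flips
  brk <- c(TRUE, diff(dt$bin) != 1 | diff(sig) != 0 |
             diff(sign(dt$t)) != 0)
  grp <- cumsum(brk)
  out <- data.table::data.table(bin = dt$bin, t = dt$t, sig = sig,
                                grp = grp)
  cl <- out[sig == TRUE,
            .(start_bin = min(bin), end_bin = max(bin),
              n_bins = .N, sum_t = sum(t)), by = grp][, grp := NULL]
  cl[n_bins >= min_length]
}

# swap the roles of the two design factors: with contrast_factor = "action"
# the tested two-level factor becomes the action stereotype (neutral
# dropped) and scopes are occupation conditions
orient_lr <- function(lr, contrast_factor) {
  if (contrast_factor == "occupation") return(lr)
  out <- data.table::copy(lr[action_stereotype != "neutral"])
  data.table::setnames(out,
                       c("occupation_stereotype", "action_stereotype"),
                       c("action_stereotype", "occupation_stereotype"))
  out
}

# ---- vectorized permutation engine ----------------------------------------
# Series matrix: one row per participant x item trial series, columns bins.
build_series <- function(lr, action) {
  sub <- lr[action_stereotype == action]
  if (nrow(sub) == 0) stop("empty scope: no data for action ", action)
  w <- data.table::dcast(sub, participant + item_id +
                           occupation_stereotype ~ bin,
                         value.var = "logratio")
  bins <- sort(unique(sub$bin))
  X <- as.matrix(w[, as.character(bins), with = FALSE])
  list(X = X, participant = w$participant,
       label = w$occupation_stereotype, bins = bins)
}

# per-bin paired t for the occupation contrast given a label vector;
# participants lacking one label (degenerate subsets) drop out via NaN rows
t_condition <- function(X, participant, label) {
  f <- as.numeric(label == "female")
  fs <- rowsum(X * f, participant)
  fc <- as.vector(rowsum(f, participant))
  ms <- rowsum(X * (1 - f), participant)
  mc <- as.vector(rowsum(1 - f, participant))
  col_t(fs / fc - ms / mc)
}

# per-bin one-sample t of participant means, with optional series signs
t_onesample <- function(X, participant, signs = NULL) {
  if (!is.null(signs)) X <- X * signs
  pm <- rowsum(X, participant) / as.vector(table(participant))
  col_t(pm)
}

col_t <- function(D) {
  D <- D[stats::complete.cases(D), , drop = FALSE]
  n <- nrow(D)
  if (n < 2) return(rep(0, ncol(D)))
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  tt <- ifelse(v > 0, m / sqrt(v / n), 0)
  tt[!is.finite(tt)] <- 0
  tt
}

# largest |summed t| over sign-pure runs of significant consecutive bins;
# pure-vector twin of find_clusters() (equivalence is property-tested)
max_cluster_stat <- function(tvec, bins, alpha, min_length) {
  thr <- stats::qnorm(1 - alpha / 2)
  state <- ifelse(abs(tvec) > thr & tvec != 0,
                  ifelse(tvec > 0, 1L, -1L), 0L)
  # non-consecutive bin indices break runs
  gap <- c(FALSE, diff(bins) != 1)
  if (any(gap)) {
    r <- rle(paste(state, cumsum(gap)))
    vals <- as.integer(sub(" .*", "", r$values))
  } else {
    r <- rle(state)
    vals <- r$values
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- vals != 0L & r$lengths >= min_length
  if (!any(keep)) return(0)
  cs <- c(0, cumsum(tvec))
  max(abs(cs[ends[keep] + 1L] - cs[starts[keep]]))
}

#' Permutation null distribution of the largest cluster mass
#'
#' Builds the null distribution of the largest absolute summed t across
#' clusters under one of three label-scrambling schemes, re-running the
#' per-bin tests over all bins on each of `n_iterations` scrambles.
#' Labels attach to a whole participant x item trial series, preserving
#' within-trial temporal correlation:
#' \describe{
#'   \item{condition-swap}{occupation labels are permuted among each
#'     participant's trial series.}
#'   \item{female-vs-zero-swap / male-vs-zero-swap}{each real trial series
#'     of that occupation condition is swapped with its mirrored all-zero
#'     pseudo-series with probability 1/2, which is algebraically a random
#'     sign flip of the series.}
#' }
#' Iterations with no cluster contribute 0.
#'
#' @param lr [log_ratio_series()] table.
#' @param scheme Permutation scheme (see above).
#' @param scope List with `action`.
#' @param n_iterations Number of permutations.
#' @param seed Integer seed (reproducible).
#' @param alpha Bin-level cluster-forming threshold.
#' @param min_length Minimum cluster length.
#' @param contrast_factor See [per_bin_test()].
#' @return Object of class `permutation_null`: list with `scheme`,
#'   `max_stats` (length `n_iterations`), `n_iterations`, `seed`.
#' @export
permutation_null <- function(lr, scheme = c("condition-swap",
                                            "female-vs-zero-swap",
                                            "male-vs-zero-swap"),
                             scope = list(action = "female"),
                             n_iterations = 2000, seed = 1L,
                             alpha = 0.05, min_length = 1L,
                             contrast_factor = c("occupation", "action")) {
  scheme <- match.arg(scheme)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  lr <- orient_lr(lr, match.arg(contrast_factor))
  ser <- build_series(lr, scope$action)
  if (scheme != "condition-swap") {
    occ <- if (scheme == "female-vs-zero-swap") "female" else "male"
    keep <- ser$label == occ
    ser$X <- ser$X[keep, , drop = FALSE]
    ser$participant <- ser$participant[keep]
  }
  blocks <- split(seq_along(ser$participant), ser$participant)
  max_stats <- withr_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      if (scheme == "condition-swap") {
        lab <- ser$label
        for (ix in blocks)
          if (length(ix) > 1L) lab[ix] <- lab[sample(ix)]
        tv <- t_condition(ser$X, ser$participant, lab)
      } else {
        s <- sample(c(-1, 1), nrow(ser$X), replace = TRUE)
        tv <- t_onesample(ser$X, ser$participant, s)
      }
      max_cluster_stat(tv, ser$bins, alpha, min_length)
    }, numeric(1))
  })
  structure(list(scheme = scheme, scope = scope, max_stats = max_stats,
                 n_iterations = n_iterations, seed = seed, alpha = alpha),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null (%s, action=%s): %d iterations, q97.5=%.2f\n",
              x$scheme, x$scope$action, x$n_iterations,
              stats::quantile(x$max_stats, 0.975)))
  invisible(x)
}

#' Permutation p-value and significance of a cluster
#'
#' Add-one estimator `p = (1 + #\{null >= |sum t|\}) / (1 + n_iterations)`;
#' a cluster is significant under the two-tailed criterion iff
#' `p < criterion` (strict).
#'
#' @param sum_t Observed summed t of the cluster.
#' @param null A [permutation_null()] object.
#' @param criterion Two-tailed percentile criterion (default 0.025).
#' @return List with `p` and `significant`.
#' @export
cluster_pvalue <- function(sum_t, null, criterion = 0.025) {
  stopifnot(inherits(null, "permutation_null"))
  p <- (1 + sum(null$max_stats >= abs(sum_t))) / (1 + null$n_iterations)
  list(p = p, significant = p < criterion)
}

#' Full two-stage cluster-based randomization analysis
#'
#' For every action condition present in the data, runs the occupation
#' condition contrast and the two zero-reference contrasts bin by bin,
#' forms clusters of consecutive significant same-sign bins, builds the
#' matching permutation null distribution of largest absolute cluster
#' masses, and assigns each observed cluster a permutation p-value under
#' the two-tailed percentile criterion.
#'
#' @param lr [log_ratio_series()] table.
#' @param contrasts Contrast families to run.
#' @param n_iterations Permutation iterations per null distribution.
#' @param seed Integer seed (per-scope sub-seeds are derived from it).
#' @param alpha Bin-level cluster-forming threshold.
#' @param criterion Two-tailed cluster significance criterion.
#' @param min_length Minimum cluster length in bins.
#' @param method Per-bin test route for the observed statistics ("agg" or
#'   "lmm"); the permutation stage always uses the aggregated route, so
#'   "agg" (default) keeps observed and null statistics identical.
#' @param contrast_factor See [per_bin_test()]; with "action" the `action`
#'   column of the output holds the occupation-condition scope.
#' @return Object of class `cluster_analysis`: list with `clusters`
#'   (data.table: action, contrast, start_bin, end_bin, start_ms, end_ms,
#'   n_bins, sum_t, p, significant), `per_bin` (all per-bin t), `nulls`.
#' @export
cluster_analysis <- function(lr, contrasts = c("condition",
                                               "female-vs-zero",
                                               "male-vs-zero"),
                             n_iterations = 2000, seed = 1L,
                             alpha = 0.05, criterion = 0.025,
                             min_length = 1L, method = "agg",
                             contrast_factor = c("occupation", "action")) {
  contrast_factor <- match.arg(contrast_factor)
  lr <- orient_lr(lr, contrast_factor)
  actions <- sort(unique(lr$action_stereotype))
  bin_ms <- lr$bin_end[1] - lr$bin_start[1]
  bin0 <- lr[bin == min(bin), bin_start[1]]
  bin_start_of <- function(b) bin0 + (b - min(lr$bin)) * bin_ms
  sub_seeds <- withr_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, length(actions) * 3),
    nrow = length(actions), dimnames = list(actions, NULL)))
  schemes <- c(condition = "condition-swap",
               `female-vs-zero` = "female-vs-zero-swap",
               `male-vs-zero` = "male-vs-zero-swap")
  all_cl <- list(); all_bin <- list(); nulls <- list()
  for (a in actions) {
    ser <- build_series(lr, a)
    for (ci in seq_along(contrasts)) {
      ctr <- contrasts[ci]
      tv <- observed_t(lr, ser, a, ctr, method)
      bin_dt <- data.table::data.table(
        action = a, contrast = ctr, bin = ser$bins, t = tv,
        p = 2 * stats::pnorm(-abs(tv)))
      cl <- find_clusters(bin_dt, alpha = alpha, min_length = min_length)
      nul <- permutation_null(lr, schemes[[ctr]], scope = list(action = a),
                              n_iterations = n_iterations,
                              seed = sub_seeds[a, match(ctr, names(schemes))],
                              alpha = alpha, min_length = min_length)
      if (nrow(cl)) {
        pv <- vapply(cl$sum_t,
                     function(s) cluster_pvalue(s, nul, criterion)$p,
                     numeric(1))
        cl[, `:=`(action = a, contrast = ctr, p = pv,
                  significant = pv < criterion)]
      } else {
        cl[, `:=`(action = character(0), contrast = character(0),
                  p = numeric(0), significant = logical(0))]
      }
      all_cl[[paste(a, ctr)]] <- cl
      all_bin[[paste(a, ctr)]] <- bin_dt
      nulls[[paste(a, ctr)]] <- nul
    }
  }
  clusters <- data.table::rbindlist(all_cl)
  if (nrow(clusters)) {
    clusters[, start_ms := bin_start_of(start_bin)]
    clusters[, end_ms := bin_start_of(end_bin) + bin_ms]
    data.table::setcolorder(clusters, c("action", "contrast", "start_bin",
                                        "end_bin", "start_ms", "end_ms",
                                        "n_bins", "sum_t", "p",
                                        "significant"))
    data.table::setorder(clusters, action, contrast, start_bin)
  }
  structure(list(clusters = clusters,
                 per_bin = data.table::rbindlist(all_bin), nulls = nulls,
                 n_iterations = n_iterations, seed = seed, alpha = alpha,
                 criterion = criterion, method = method,
                 contrast_factor = contrast_factor),
            class = "cluster_analysis")
}

observed_t <- function(lr, ser, action, contrast, method) {
  if (method == "agg") {
    if (contrast == "condition")
      return(t_condition(ser$X, ser$participant, ser$label))
    occ <- if (contrast == "female-vs-zero") "female" else "male"
    keep <- ser$label == occ
    return(t_onesample(ser$X[keep, , drop = FALSE], ser$participant[keep]))
  }
  vapply(ser$bins, function(b)
    per_bin_test(lr, b, contrast, scope = list(action = action),
                 method = "lmm")$t, numeric(1))
}

#' @export
print.cluster_analysis <- function(x, ...) {
  cat(sprintf("cluster_analysis: %d clusters (%d significant), %d ",
              nrow(x$clusters), sum(x$clusters$significant),
              x$n_iterations), "iterations\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
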