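library(data.table)

# Literal 1-ms indicator-vector binning oracle: materialize one sample per
# millisecond of the analysis window, look up the fixation covering it
# (t in [start, end)), and average per 100-ms bin. Deliberately brute force.
oracle_expand_bin <- function(fixations, noun_onset, window = c(-2000, 1000),
                              bin_ms = 100) {
  ts <- seq(window[1], window[2] - 1)               # 1-ms sample times
  abs_t <- ts + noun_onset
  lab <- rep("gap", length(ts))
  covered <- rep(FALSE, length(ts))
  if (nrow(fixations)) {
    for (i in seq_len(nrow(fixations))) {
      inside <- abs_t >= fixations$start[i] & abs_t < fixations$end[i]
      lab[inside] <- fixations$aoi[i]
      covered <- covered | inside
    }
  }
  n_bins <- diff(window) / bin_ms
  bin_of <- rep(seq_len(n_bins), each = bin_ms)
  out <- list(bin = seq_len(n_bins),
              bin_start = window[1] + (seq_len(n_bins) - 1) * bin_ms)
  out$bin_end <- out$bin_start + bin_ms
  for (a in c("female", "male", "object1", "object2"))
    out[[a]] <- as.numeric(tapply(lab == a, bin_of, sum))
  out$elsewhere <- bin_ms - (out$female + out$male + out$object1 +
                               out$object2)
  out$n_valid <- as.numeric(tapply(covered, bin_of, sum))
  as.data.table(out)
}

# random non-overlapping integer-ms fixation sequence for binning tests
random_toy_trial <- function(noun_onset = 2500, t_max = 4000) {
  n <- sample(0:8, 1)
  if (n == 0)
    return(data.table(start = numeric(0), end = numeric(0),
                      aoi = character(0)))
  bounds <- sort(sample(0:t_max, 2 * n))
  starts <- bounds[seq(1, 2 * n, 2)]
  ends <- bounds[seq(2, 2 * n, 2)]
  keep <- ends > starts
  data.table(start = starts[keep], end = ends[keep],
             aoi = sample(c("female", "male", "object1", "object2",
                            "elsewhere"), sum(keep), replace = TRUE))
}

# small ready-made design shared across tests
make_design <- function(n_occupations = 14, displays = 3, n_fillers = 28) {
  item_set <- build_item_set(n_occupations, displays, n_fillers)
  list(item_set = item_set, lists = latin_square_lists(item_set))
}

# simulate + bin + log-ratio in one go, small scale
quick_lr <- function(n_participants = 8, seed = 1, params = NULL,
                     design = NULL) {
  d <- if (is.null(design)) make_design() else design
  if (is.null(params)) params <- generator_params(n_participants =
                                                    n_participants)
  sim <- simulate_experiment(d$lists, d$item_set, params, seed = seed)
  log_ratio_series(bin_experiment(sim$fixations, sim$trials))
}

# naive two-loop condition time course (trials -> participant -> condition)
oracle_condition_mean <- function(bins, aoi, bin_ms = 100) {
  out <- list()
  for (occ in unique(bins$occupation_stereotype))
    for (act in unique(bins$action_stereotype))
      for (b in unique(bins$bin)) {
        sub <- bins[occupation_stereotype == occ & action_stereotype == act &
                      bin == b]
        if (nrow(sub) == 0) next
        pm <- sapply(split(sub[[aoi]], sub$participant), mean) / bin_ms
        out[[length(out) + 1]] <- data.table(
          occupation_stereotype = occ, action_stereotype = act, bin = b,
          mean = mean(pm))
      }
  rbindlist(out)
}
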