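test_that("well-formed fixation reports parse and round-trip", {
  fx <- data.table(participant = c(1, 1, 2), trial = c(1, 1, 1),
                   start = c(0, 120, 10), end = c(100, 300, 500),
                   x = c(200, 800, 200), y = c(200, 200, 700),
                   aoi = c("female", "male", "object1"))
  f <- tempfile(fileext = ".tsv")
  write_fixation_report(fx, f)
  back <- read_fixation_report(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$start, fx$start)
  expect_equal(back$aoi, fx$aoi)
  expect_equal(attr(back, "n_rejected"), 0)
})

test_that("invalid rows are rejected with a message, bad files error", {
  fx <- data.table(participant = 1, trial = c(1, 1, 1),
                   start = c(0, 300, 400), end = c(100, 200, "oops"),
                   x = 1, y = 1)
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(fx, f, sep = "\t")
  expect_message(back <- read_fixation_report(f), "rejected")
  expect_equal(nrow(back), 1)          # end<=start and non-numeric dropped
  expect_equal(attr(back, "n_rejected"), 2)

  f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(fx[, .(participant, trial, start)], f2, sep = "\t")
  expect_error(read_fixation_report(f2), "missing required column 'end'")
  f3 <- tempfile(fileext = ".tsv")
  data.table::fwrite(fx[, .(participant, trial, start, end)], f3,
                     sep = "\t")
  expect_error(read_fixation_report(f3), "coordinate columns")
  expect_error(read_fixation_report(tempfile()), "not found")
})

test_that("simulator fixation output round-trips losslessly", {
  d <- make_design(2, 3, 4)
  sim <- simulate_experiment(d$lists, d$item_set,
                             generator_params(n_participants = 2), seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_fixation_report(sim$fixations, f)
  back <- read_fixation_report(f)
  expect_equal(nrow(back), nrow(sim$fixations))
  expect_equal(back$start, sim$fixations$start)
  expect_equal(back$end, sim$fixations$end)
  expect_equal(back$aoi, sim$fixations$aoi)
})

test_that("AOI assignment is half-open point-in-rectangle", {
  map <- default_aoi_map()
  fem <- map[aoi == "female"]
  center <- assign_aoi((fem$x0 + fem$x1) / 2, (fem$y0 + fem$y1) / 2, map)
  expect_equal(center, "female")
  expect_equal(assign_aoi(5000, 5000, map), "elsewhere")
  # touching rectangles: shared-edge point belongs to exactly one
  touching <- data.table(aoi = c("female", "male"),
                         x0 = c(0, 100), y0 = c(0, 0),
                         x1 = c(100, 200), y1 = c(100, 100))
  expect_equal(assign_aoi(100, 50, touching), "male")
  expect_equal(assign_aoi(99.999, 50, touching), "female")
  # overlapping rectangles: strict mode errors, lenient takes priority
  overlap <- data.table(aoi = c("female", "male"),
                        x0 = c(0, 50), y0 = c(0, 0),
                        x1 = c(100, 150), y1 = c(100, 100))
  expect_error(assign_aoi(75, 50, overlap, strict = TRUE), "ambiguous")
  expect_equal(assign_aoi(75, 50, overlap), "female")
  expect_error(assign_aoi(1, 1, data.table(aoi = "a", x0 = 0, y0 = 0,
                                           x1 = 0, y1 = 10)),
               "positive area")
})

test_that("simple bin coverage cases give the exact proportions", {
  # one 100-ms fixation exactly covering the first bin
  fx <- data.table(start = 500, end = 600, aoi = "female")
  b <- expand_and_bin(fx, noun_onset = 2500, window = c(-2000, 1000))
  expect_equal(nrow(b), 30)
  expect_equal(b[bin == 1, female], 100)
  expect_equal(b[bin == 1, elsewhere], 0)
  expect_equal(b[bin == 2, female], 0)
  # 50-ms fixation inside one bin
  fx2 <- data.table(start = 525, end = 575, aoi = "male")
  b2 <- expand_and_bin(fx2, noun_onset = 2500)
  expect_equal(b2[bin == 1, male], 50)
  expect_equal(b2[bin == 1, elsewhere], 50)
  expect_equal(b2[bin == 1, n_valid], 50)
  # no fixations: all elsewhere, flagged by n_valid = 0
  b0 <- expand_and_bin(fx[0], noun_onset = 2500)
  expect_true(all(b0$elsewhere == 100))
  expect_true(all(b0$n_valid == 0))
  expect_error(expand_and_bin(fx, 2500, window = c(-2000, 950)),
               "multiples")
})

test_that("interval binning equals the 1-ms indicator oracle", {
  set.seed(31)
  for (i in 1:200) {
    fx <- random_toy_trial()
    got <- expand_and_bin(fx, noun_onset = 2500)
    want <- oracle_expand_bin(fx, noun_onset = 2500)
    expect_equal(got$female, want$female)
    expect_equal(got$male, want$male)
    expect_equal(got$object1, want$object1)
    expect_equal(got$object2, want$object2)
    expect_equal(got$elsewhere, want$elsewhere)
    expect_equal(got$n_valid, want$n_valid)
  }
})

test_that("binning conserves samples and shifts with the time lock", {
  set.seed(32)
  fx <- random_toy_trial()
  b <- expand_and_bin(fx, noun_onset = 2500)
  expect_true(all(abs(b[, female + male + object1 + object2 + elsewhere] -
                        100) < 1e-9))
  # an earlier noun onset moves the same absolute samples one bin later
  b2 <- expand_and_bin(fx, noun_onset = 2400)
  expect_equal(b2$female[2:30], b$female[1:29])
  expect_equal(b2$n_valid[2:30], b$n_valid[1:29])
})

test_that("bin_experiment assigns AOIs from coordinates when needed", {
  d <- make_design(2, 3, 4)
  sim <- simulate_experiment(d$lists, d$item_set,
                             generator_params(n_participants = 2), seed = 9)
  bins_lab <- bin_experiment(sim$fixations, sim$trials, sim$aoi_map)
  bins_xy <- bin_experiment(sim$fixations[, .(participant, trial, start,
                                              end, x, y)],
                            sim$trials, sim$aoi_map)
  expect_equal(bins_xy$female, bins_lab$female)
  expect_equal(bins_xy$elsewhere, bins_lab$elsewhere)
  expect_equal(nrow(bins_lab), nrow(sim$trials) * 30)
})

test_that("whole-experiment binning equals per-trial expansion", {
  d <- make_design(2, 3, 4)
  sim <- simulate_experiment(d$lists, d$item_set,
                             generator_params(n_participants = 2),
                             seed = 17)
  bins <- bin_experiment(sim$fixations, sim$trials)
  for (p in 1:2) for (tr in sample(unique(sim$trials$trial), 4)) {
    meta <- sim$trials[participant == p & trial == tr]
    if (nrow(meta) == 0) next
    fx <- sim$fixations[participant == p & trial == tr]
    want <- expand_and_bin(fx, meta$noun_onset)
    got <- bins[participant == p & trial == tr]
    expect_equal(got$female, want$female)
    expect_equal(got$elsewhere, want$elsewhere)
    expect_equal(got$n_valid, want$n_valid)
  }
})
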