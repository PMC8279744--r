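# small synthetic log-ratio table with known structure: participants x
# items x bins, occupation label per series, optional per-bin shift added
# to the female-occupation series
make_lr_table <- function(n_part = 8, n_item = 6, n_bin = 10, shift = 0,
                          noise = 0.3, seed = 1) {
  set.seed(seed)
  dt <- data.table::CJ(participant = 1:n_part, item_id = 1:n_item,
                       bin = 1:n_bin)
  dt[, occupation_stereotype := ifelse(item_id %% 2 == 0, "female", "male")]
  dt[, action_stereotype := "female"]
  dt[, bin_start := (bin - 1) * 100 - 500]
  dt[, bin_end := bin_start + 100]
  sh <- if (length(shift) == 1) rep(shift, n_bin) else shift
  dt[, logratio := rnorm(.N, 0, noise) +
       ifelse(occupation_stereotype == "female", sh[bin], 0)]
  dt[]
}

test_that("per-bin tests are zero on no-signal data and reject bad scope", {
  lr <- make_lr_table(noise = 0)
  res <- per_bin_test(lr, bin = 1, "condition")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(per_bin_test(lr, 1, scope = list(action = "neutral")),
               "empty scope")
  one_level <- lr[occupation_stereotype == "female"]
  expect_error(per_bin_test(one_level, 1, "condition"), "both occupation")
})

test_that("aggregated per-bin t equals a naive by-participant oracle", {
  lr <- make_lr_table(shift = 0.4, seed = 2)
  res <- per_bin_test(lr, bin = 3, "condition")
  # oracle: collapse to participant means per label, classical paired t
  sub <- lr[bin == 3]
  pm_f <- sapply(split(sub[occupation_stereotype == "female", logratio],
                       sub[occupation_stereotype == "female", participant]),
                 mean)
  pm_m <- sapply(split(sub[occupation_stereotype == "male", logratio],
                       sub[occupation_stereotype == "male", participant]),
                 mean)
  want <- unname(t.test(pm_f - pm_m)$statistic)
  expect_equal(res$t, want)
  # one-sample contrast against the zero reference
  res_z <- per_bin_test(lr, bin = 3, "female-vs-zero")
  want_z <- unname(t.test(pm_f)$statistic)
  expect_equal(res_z$t, want_z)
})

test_that("mixed-model route agrees with the aggregated t when random
           variance is degenerate", {
  # balanced design, no participant/item variance: lmer converges to the
  # same fixed-effect contrast as the collapsed t up to df conventions
  lr <- make_lr_table(n_part = 10, shift = 0.6, noise = 0.2, seed = 3)
  agg <- per_bin_test(lr, 5, "condition", method = "agg")
  lmm <- per_bin_test(lr, 5, "condition", method = "lmm")
  expect_equal(sign(lmm$t), sign(agg$t))
  expect_equal(lmm$t, agg$t, tolerance = 0.15)
  expect_true(lmm$method %in% c("lmm", "agg"))
})

test_that("zero_reference mirrors each observation with a zero", {
  lr <- make_lr_table(n_part = 3, n_item = 2, n_bin = 2)
  aug <- zero_reference(lr)
  expect_equal(nrow(aug), 2 * nrow(lr))
  expect_equal(sum(aug$label == "zero"), nrow(lr))
  expect_true(all(aug[label == "zero", value] == 0))
  expect_equal(aug[label == "real", value], lr$logratio)
  expect_error(zero_reference(lr[0]), "empty")
})

test_that("vs-zero t grows monotonically with an injected shift", {
  ts <- sapply(c(0, 0.2, 0.4, 0.8), function(s) {
    lr <- make_lr_table(shift = s, seed = 4)   # same noise realisation
    per_bin_test(lr, 2, "female-vs-zero")$t
  })
  expect_true(all(diff(ts) > 0))
})

test_that("cluster formation follows adjacency, sign purity, min length", {
  mk <- function(t) data.table(bin = seq_along(t), t = t,
                               p = 2 * pnorm(-abs(t)))
  expect_equal(nrow(find_clusters(mk(c(0.5, 1, -0.3)))), 0)
  cl <- find_clusters(mk(c(0, 0, 0, 0, 2, 2, 2, 2, 2, 0)))
  expect_equal(cl$start_bin, 5)
  expect_equal(cl$end_bin, 9)
  expect_equal(cl$sum_t, 10)
  # isolated significant bins form separate clusters
  cl2 <- find_clusters(mk(c(0, 3, 0, -3, 0)))
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$sum_t, c(3, -3))
  # a sign change splits an otherwise contiguous run
  cl3 <- find_clusters(mk(c(3, 3, -3, -3)))
  expect_equal(nrow(cl3), 2)
  expect_equal(cl3$sum_t, c(6, -6))
  # min length filters short runs
  expect_equal(nrow(find_clusters(mk(c(0, 3, 0)), min_length = 2)), 0)
})

test_that("permutation nulls are deterministic given a seed", {
  lr <- make_lr_table(seed = 5)
  a <- permutation_null(lr, "condition-swap", n_iterations = 50, seed = 9)
  b <- permutation_null(lr, "condition-swap", n_iterations = 50, seed = 9)
  c_ <- permutation_null(lr, "condition-swap", n_iterations = 50, seed = 10)
  expect_identical(a$max_stats, b$max_stats)
  expect_false(identical(a$max_stats, c_$max_stats))
  expect_length(a$max_stats, 50)
  expect_true(all(a$max_stats >= 0))
  expect_error(permutation_null(lr, n_iterations = 0), "n_iterations")
})

test_that("constant-zero data gives an all-zero null distribution", {
  lr <- make_lr_table(noise = 0)
  nul <- permutation_null(lr, "female-vs-zero-swap", n_iterations = 20,
                          seed = 1)
  expect_true(all(nul$max_stats == 0))
})

test_that("cluster p-values use the add-one estimator and strict cutoff", {
  nul <- structure(list(max_stats = c(rep(1, 2000)), n_iterations = 2000),
                   class = "permutation_null")
  top <- cluster_pvalue(5, nul)
  expect_equal(top$p, 1 / 2001)
  expect_true(top$significant)
  mid <- cluster_pvalue(1, nul)        # every null >= |sum t|
  expect_equal(mid$p, 1)
  expect_false(mid$significant)
  # boundary: p exactly at the criterion is not significant (strict <)
  nul2 <- structure(list(max_stats = c(rep(10, 49), rep(0, 1950)),
                         n_iterations = 1999), class = "permutation_null")
  expect_equal(cluster_pvalue(10, nul2)$p, 0.025)
  expect_false(cluster_pvalue(10, nul2)$significant)
})

test_that("an injected boxcar effect is recovered as a significant
           cluster with the right extent", {
  shift <- rep(0, 10); shift[4:7] <- 0.8
  lr <- make_lr_table(n_part = 12, shift = shift, noise = 0.25, seed = 6)
  ca <- cluster_analysis(lr, n_iterations = 200, seed = 7)
  sig <- ca$clusters[contrast == "condition" & significant == TRUE]
  expect_equal(nrow(sig), 1)
  expect_lte(abs(sig$start_bin - 4), 1)
  expect_lte(abs(sig$end_bin - 7), 1)
  expect_gt(sig$sum_t, 0)
  # scaling the effect up can only increase the largest cluster mass
  lr2 <- make_lr_table(n_part = 12, shift = shift * 2, noise = 0.25,
                       seed = 6)
  ca2 <- cluster_analysis(lr2, n_iterations = 10, seed = 7)
  expect_gte(max(abs(ca2$clusters[contrast == "condition", sum_t])),
             max(abs(ca$clusters[contrast == "condition", sum_t])))
})

test_that("cluster analysis output is a pure function of data and seed", {
  lr <- make_lr_table(shift = 0.5, seed = 8)
  a <- cluster_analysis(lr, n_iterations = 40, seed = 3)
  b <- cluster_analysis(lr, n_iterations = 40, seed = 3)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$per_bin, b$per_bin)
})

test_that("the factor-role swap runs the action contrast within
           occupations", {
  lr <- make_lr_table(shift = 0.5, seed = 9)
  # under the swapped orientation the two-level factor must be the action
  # stereotype; this table has only one action level, so scoping fails
  expect_error(per_bin_test(lr, 1, "condition",
                            scope = list(action = "female"),
                            contrast_factor = "action"),
               "both occupation|empty scope")
  # with both action levels present it runs
  lr2 <- rbind(lr, data.table::copy(lr)[, action_stereotype := "male"][
    , logratio := rnorm(.N, 0, 0.3)])
  res <- per_bin_test(lr2, 1, "condition", scope = list(action = "female"),
                      contrast_factor = "action")
  expect_true(is.finite(res$t))
})

test_that("the fast permutation statistic equals the cluster-table route", {
  set.seed(13)
  for (i in 1:50) {
    tv <- rnorm(12, 0, 1.6)
    bins <- 1:12
    want_cl <- find_clusters(data.table(bin = bins, t = tv,
                                        p = 2 * pnorm(-abs(tv))))
    want <- if (nrow(want_cl)) max(abs(want_cl$sum_t)) else 0
    got <- gazecluster:::max_cluster_stat(tv, bins, alpha = 0.05,
                                          min_length = 1L)
    expect_equal(got, want)
  }
  # with a bin gap: runs cannot straddle it
  tv <- c(3, 3, 3, 3)
  expect_equal(gazecluster:::max_cluster_stat(tv, c(1, 2, 5, 6), 0.05, 1L),
               6)
})
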