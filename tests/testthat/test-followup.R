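mk_pair_records <- function(n = 23, seed = 70) {
  set.seed(seed)
  data.frame(pair = 1:n, synchrony = rnorm(n), strength_of_relation = rnorm(n),
             variability_of_relation = rnorm(n), time_lag = rexp(n, 0.1),
             switching = rexp(n, 0.1), mutual_information = rexp(n),
             psi = rnorm(n))
}

test_that("23 pairs split 11/11/1 and every pair is labelled once", {
  rec <- mk_pair_records()
  sp <- coordination_split(rec)
  expect_equal(as.integer(table(sp$label)[c("strong", "weak",
                                            "excluded-median")]),
               c(11L, 11L, 1L))
  expect_equal(nrow(sp), 23)
  expect_false(anyNA(sp$label))
  ## invariant to measure column ordering
  rec2 <- rec[, c("pair", "psi", "time_lag", "synchrony", "switching",
                  "mutual_information", "strength_of_relation",
                  "variability_of_relation")]
  sp2 <- coordination_split(rec2)
  expect_equal(sp$label, sp2$label)
  expect_error(coordination_split(rec[1:2, ]), "3 pairs")
})

test_that("more coordinated pairs land in the strong half", {
  ## construct records where pairs 13..23 dominate on every oriented measure
  n <- 23
  good <- c(rep(0, 12), rep(1, 11))
  rec <- data.frame(pair = 1:n,
                    synchrony = good + 0.01 * (1:n),
                    strength_of_relation = good,
                    variability_of_relation = 1 - good,
                    time_lag = 10 * (1 - good),
                    switching = 10 * (1 - good),
                    mutual_information = good,
                    psi = (1 - good) * 0.5)
  sp <- coordination_split(rec)
  expect_true(all(sp$label[13:23] == "strong"))
})

test_that("ties at the median aggregate resolve deterministically by pair
           id", {
  rec <- mk_pair_records(5)
  rec[, -1] <- 0   # all pairs tied on every measure
  sp <- coordination_split(rec)
  expect_equal(sp$label[sp$pair == 3], "excluded-median")
  expect_equal(sp$label[sp$pair %in% 1:2], c("weak", "weak"))
  expect_equal(sp$label[sp$pair %in% 4:5], c("strong", "strong"))
})

test_that("window phases use elapsed interval fraction with interior
           windows only", {
  ev <- c(100, 300, 700)
  ph <- dyadgame:::window_phases(c(50, 100, 200, 300, 500, 800), ev)
  expect_true(is.na(ph[1]))              # before first collection
  expect_equal(ph[2], 0)                 # exactly at a collection
  expect_equal(ph[3], 0.5)
  expect_equal(ph[4], 0)                 # boundary starts next interval
  expect_equal(ph[5], 0.5)
  expect_true(is.na(ph[6]))              # after last collection
  expect_equal(dyadgame:::window_phases(c(1, 2), c(100)), c(NA_real_,
                                                            NA_real_))
})

test_that("target-cycle binning conserves windows and equalises counts", {
  set.seed(71)
  n <- 2000
  w <- data.frame(pair = rep(1:10, each = 200),
                  condition = rep(c("SAME", "DIFF"), n / 2),
                  phase = runif(n), peak_r = runif(n))
  prof <- target_cycle_profile(w, n_bins = 20)
  expect_equal(sort(unique(prof$bin)), 1:20)
  ## equal-count binning: reconstruct bin sizes from the pooled windows
  br <- quantile(w$phase, probs = seq(0, 1, length.out = 21))
  br[1] <- -Inf; br[21] <- Inf
  counts <- table(cut(w$phase, br, labels = FALSE))
  expect_equal(as.integer(counts), rep(100L, 20))
  expect_equal(sum(counts), n)
  ## uniform phases, no condition effect: adjusted p values stay high
  expect_gt(min(prof$p_adj, na.rm = TRUE), 0.05)
})

test_that("segment analysis refuses excluded measures and finds injected
           segment trends", {
  fx <- get_fixture()
  expect_error(segment_analysis(fx$measures$segment,
                                families = list(bad = "psi")),
               "segment resolution")
  ## constructed segment data with a strong rise over segments
  set.seed(72)
  base <- expand.grid(pair = 1:16, segment = 1:3, trial = 1:4)
  seg <- rbind(
    transform(base, mode = "joint", measure = "targets",
              value = rnorm(nrow(base)) + base$segment * 1.0),
    transform(base, mode = "joint", measure = "obstacle_time",
              value = rnorm(nrow(base))),
    transform(base, mode = "joint", measure = "path_length",
              value = rnorm(nrow(base))))
  res <- segment_analysis(seg, families = list(
    behaviour = c("targets", "obstacle_time", "path_length")),
    n_boot = 299, seed = 4)
  expect_lt(res$behaviour$manova$p[1], 0.05)
  expect_lt(res$behaviour$anova$targets$p[1], 0.05)
  expect_gt(res$behaviour$anova$obstacle_time$p[1], 0.05)
  expect_equal(nrow(res$behaviour$posthoc$targets), 3)
  expect_true(all(c("targets", "obstacle_time", "path_length") %in%
                    sub(":.*", "", res$behaviour$fdr$name) |
                    res$behaviour$fdr$group == "behaviour"))
})

test_that("transition analysis contrasts strong and weak pairs over the
           mode shift", {
  set.seed(73)
  n <- 20
  lab <- rep(c("strong", "weak"), each = n / 2)
  split <- data.frame(pair = 1:n, aggregate_rank = 1:n, label = lab)
  ## strong pairs drop at the joint -> individual shift, weak pairs rise
  mk_rows <- function(pair, mode, trial, sess, value)
    data.frame(pair = pair, trial = trial, mode = mode,
               player = NA, condition = "SAME", block = NA,
               session = sess, measure = "targets", value = value)
  rows <- list()
  for (i in 1:n) {
    eff <- if (lab[i] == "strong") c(8, 4) else c(4, 8)
    rows[[length(rows) + 1]] <- mk_rows(i, "joint", 41:50, 2,
                                        rnorm(10, eff[1]))
    rows[[length(rows) + 1]] <- mk_rows(i, "individual", 51:60, NA,
                                        rnorm(10, eff[2]))
  }
  tm <- do.call(rbind, rows)
  ratings <- do.call(rbind, lapply(1:n, function(i)
    data.frame(pair = i, trial = c(5, 10, 55, 60, 44, 47, 50, 55, 60),
               block = c(NA, NA, NA, NA, 10, 11, 12, NA, NA), player = 1,
               construct = c(rep("ball_control", 4),
                             rep("engagement", 5)),
               value = round(runif(9, 30, 70)))))
  res <- transition_analysis(tm, ratings, split, n_boot = 299, seed = 5)
  inter <- res$targets[res$targets$effect == "level:phase_mode", ]
  expect_lt(inter$p, 0.05)
  expect_equal(nrow(res$ball_control), 3)
  expect_equal(nrow(res$engagement), 3)
})

test_that("visibility classes follow the condition structure", {
  fx <- get_fixture()
  w <- fx$measures$windows
  same_cls <- unique(w$nearest_vis[w$condition == "SAME"])
  diff_cls <- unique(w$nearest_vis[w$condition == "DIFF"])
  expect_true(all(same_cls %in% c("both", "none")))
  expect_true(all(diff_cls %in% c("both", "one")))
  ov <- obstacle_visibility_profile(w, n_boot = 299, seed = 6)
  expect_true(all(ov$cell_means$nearest_vis %in%
                    c("both", "one", "none")))
  expect_s3_class(ov$test, "dg_rm_test")
})
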