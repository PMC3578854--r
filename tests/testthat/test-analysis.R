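scriptedTraj <- function(dwells, t0 = 0, rnapIndex = 1L) {
  # one initiation then one incorporation after each dwell
  times <- t0 + cumsum(c(0, dwells))
  kinds <- c("initiation", rep("incorporation", length(dwells)))
  makeTrajectoryFixture(times, kinds, rnapIndex = rnapIndex)
}

simFromTrajs <- function(trajs) {
  # minimal ensemble wrapper around scripted trajectories
  tpl <- paste(rep("ACGT", 20), collapse = "")
  cfg <- runConfig(tpl, stdParams(), nReplicates = length(trajs),
                   seed = 1)
  new("TrafficSim", mode = "sra", config = cfg,
      replicates = lapply(trajs, list))
}

test_that("dwell profile recovers scripted dwell times and matches the
           quantile oracle", {
  sim <- simFromTrajs(list(scriptedTraj(rep(1, 10))))
  prof <- dwellProfile(sim)
  # dwell at position i runs from inclusion i to inclusion i+1
  expect_true(all(abs(prof@tq - 1) < 1e-12))
  expect_equal(prof@tauMin, 1)
  # a 10 s wait before inclusion 3 is charged to position 2
  trs <- lapply(1:4, function(r) scriptedTraj(c(1, 1, 10, 1, 1)))
  prof2 <- dwellProfile(simFromTrajs(trs))
  expect_equal(unname(prof2@tq["2"]), 10)
  # random dwells: third quartile equals the type-7 quantile
  set.seed(5)
  dwl <- lapply(1:9, function(r) runif(20, 0.01, 2))
  prof3 <- dwellProfile(simFromTrajs(lapply(dwl, scriptedTraj)))
  for (i in seq_len(20 - 1)) {
    samp <- vapply(dwl, `[`, numeric(1), i + 1L)
    expect_equal(unname(prof3@tq[as.character(i)]),
                 unname(quantile(samp, 0.75, type = 7)))
  }
  # profiles are invariant under replicate reordering
  prof3b <- dwellProfile(simFromTrajs(lapply(rev(dwl), scriptedTraj)))
  expect_equal(prof3b@tq, prof3@tq)
})

test_that("pause calling applies the quartile threshold rule", {
  mk <- function(tq, tauMin) new("DwellProfile", samples = list(),
    tq = tq, tauMin = tauMin,
    positions = as.integer(names(tq)), missing = integer(0))
  flat <- mk(c(`1` = 0.5, `2` = 0.5, `3` = 0.5), 0.5)
  expect_length(callPauses(flat, alpha = 0.9)@positions, 0)
  prof <- mk(c(`10` = 1.5, `11` = 0.9, `20` = 2.0), 0.1)
  rep <- callPauses(prof, alpha = 0.1)
  expect_equal(rep@threshold, 1.0)
  expect_equal(rep@positions, c(10L, 20L))
  expect_error(callPauses(prof, alpha = 0), "positive")
  # clustering at 3 bp
  prof2 <- mk(c(`10` = 5, `12` = 5, `20` = 5, `21` = 0.1), 0.1)
  rep2 <- callPauses(prof2, alpha = 0.5)
  expect_equal(rep2@clusters, list(c(10L, 12L), 20L))
})

test_that("position clustering chains at the gap distance", {
  expect_equal(clusterPositions(integer(0)), list())
  expect_equal(clusterPositions(c(10, 12, 20)), list(c(10L, 12L), 20L))
  expect_equal(clusterPositions(c(1, 4, 7)), list(c(1L, 4L, 7L)))
  expect_equal(clusterPositions(c(7, 1, 4)), list(c(1L, 4L, 7L)))
  expect_equal(clusterPositions(c(1, 5)), list(1L, 5L))
})

test_that("quality metric counts clusters and matches within 3 bp", {
  q <- qualityMetric(c(10, 50), c(10, 50))
  expect_equal(c(q@tp, q@fp, q@fn), c(2L, 0L, 0L))
  expect_equal(q@q, 1)
  q2 <- qualityMetric(c(11, 80), c(10, 50))
  expect_equal(c(q2@tp, q2@fp, q2@fn), c(1L, 1L, 1L))
  expect_equal(q2@q, 1 / 3)
  q3 <- qualityMetric(c(11, 80), c(10, 50), form = "ratio")
  expect_equal(q3@q, 2)
  expect_error(qualityMetric(c(1, 2), numeric(0)), "undefined")
  # a predicted cluster can detect a truth cluster through any member
  q4 <- qualityMetric(c(10, 11, 12), c(13))
  expect_equal(c(q4@tp, q4@fp, q4@fn), c(1L, 0L, 0L))
})

test_that("bootstrap sd of the quality metric matches an independent
           resampler", {
  calls <- list(s1 = c(10, 40), s2 = c(100))
  truth <- list(s1 = c(11, 80), s2 = c(102, 130))
  q <- qualityMetric(calls, truth, bootstrap = 3000, bootstrapSeed = 2)
  # independent brute-force bootstrap over the two sequences
  cnt <- vapply(1:2, function(i)
    RNAPtraffic:::.matchCounts(calls[[i]], truth[[i]]), numeric(3))
  set.seed(77)
  qs <- replicate(10000, {
    idx <- sample.int(2, 2, replace = TRUE)
    tot <- rowSums(cnt[, idx, drop = FALSE])
    tot[1] / sum(tot)
  })
  expect_equal(q@bootstrapSd, sd(qs), tolerance = 0.05)
})

test_that("alpha tuning minimizes incorrect-to-correct predictions and
           matches a brute-force grid search", {
  mk <- function(tq, tauMin) new("DwellProfile", samples = list(),
    tq = tq, tauMin = tauMin,
    positions = as.integer(names(tq)), missing = integer(0))
  # calls at alpha = 0.2 (threshold 0.5) are exactly the truth
  prof <- mk(c(`10` = 1.0, `30` = 0.8, `50` = 0.3, `70` = 0.05), 0.1)
  truth <- list(c(10, 30))
  grid <- seq(0.05, 1, by = 0.05)
  a <- tuneAlpha(list(prof), truth, grid = grid)
  obj <- attr(a, "objective")
  # brute force: recompute the pooled objective per grid point
  ref <- vapply(grid, function(al) {
    calls <- callPauses(prof, al)@positions
    cnt <- RNAPtraffic:::.matchCounts(calls, truth[[1]])
    if (cnt[1] == 0) Inf else (cnt[2] + cnt[3]) / cnt[1]
  }, numeric(1))
  expect_equal(unname(obj), ref)
  expect_true(all(obj[as.character(a)] <= obj))
  # perfect recovery is attainable on this fixture
  expect_equal(obj[[as.character(a)]], 0)
  # ties resolve to the smallest alpha
  expect_equal(as.numeric(a), grid[which.min(ref)])
  expect_error(tuneAlpha(list(prof), list(c(200))), "undefined|true")
})

test_that("backtrack distances measure maximum excursion depth", {
  tr <- makeTrajectoryFixture(
    c(0, 1, 2, 2.5, 3, 3.5, 4, 5),
    c("initiation", "incorporation", "incorporation", "backtrack_step",
      "backtrack_step", "forward_step", "forward_step", "incorporation")
  )
  expect_equal(backtrackDistances(simFromTrajs(list(tr))), 2)
  expect_length(backtrackDistances(simFromTrajs(list(
    scriptedTraj(rep(1, 5))))), 0)
  # an unfinished excursion still contributes its maximum depth
  tr2 <- makeTrajectoryFixture(
    c(0, 1, 2, 3), c("initiation", "incorporation", "backtrack_step",
                     "backtrack_step"))
  expect_equal(backtrackDistances(simFromTrajs(list(tr2))), 2)
})

test_that("efficiency curve implements the average-time and relative
           efficiency definitions", {
  ec <- efficiencyCurve(list(`1` = 10, `2` = c(10, 6)))
  expect_equal(ec@tAvg, c(10, 8))
  expect_equal(ec@eps, c(1, 1.25))
  # all equal medians: efficiency 1 at every N
  ec2 <- efficiencyCurve(list(`1` = 7, `3` = rep(7, 3)))
  expect_equal(ec2@eps, c(1, 1))
  # random median tables against a hand-rolled computation
  set.seed(9)
  for (rep in 1:20) {
    m1 <- runif(1, 5, 50)
    n2 <- sample(2:6, 1)
    mN <- runif(n2, 5, 50)
    ec3 <- efficiencyCurve(stats::setNames(list(m1, mN), c(1, n2)))
    expect_equal(ec3@tAvg[2], mean(mN))
    expect_equal(ec3@eps[2], m1 / mean(mN))
  }
  expect_error(efficiencyCurve(list(`2` = c(5, 5))), "N = 1")
  expect_error(efficiencyCurve(list(`1` = 5, `3` = c(5, 5))), "missing")
})

test_that("simulated gel counts transcripts per length and conserves
           lane mass", {
  trs <- lapply(1:6, function(r) scriptedTraj(rep(1, 10)))
  sim <- simFromTrajs(trs)
  gel <- simulatedGel(sim, c(3.5, 100))
  # at t = 3.5 every replicate sits at length 3
  expect_equal(gel@counts["3", 1], 6L)
  expect_equal(sum(gel@counts[, 1]), 6L)
  # all replicates finished: a single full-length band
  expect_equal(gel@counts["10", 2], 6L)
  expect_equal(sum(gel@counts[, 2] > 0), 1L)
  # brute-force rescan oracle on a stochastic ensemble
  simR <- cachedSim("gel-sra", function()
    simulateSRA(runConfig(plainTemplate(), stdParams(),
                          nReplicates = 8, seed = 12)))
  tps <- c(2, 5, 10, 50)
  gelR <- simulatedGel(simR, tps)
  for (k in seq_along(tps)) {
    lens <- vapply(simR@replicates, function(r) {
      ev <- r[[1]]@events
      sum(ev$time[ev$kind == "incorporation"] <= tps[k])
    }, numeric(1))
    lens <- lens[lens >= 1]
    expect_equal(sum(gelR@counts[, k]), length(lens))
    for (l in unique(lens))
      expect_equal(gelR@counts[as.character(l), k],
                   sum(lens == l))
  }
})

test_that("completion times group by binding order", {
  t1 <- scriptedTraj(rep(1, 5))
  t2 <- makeTrajectoryFixture(c(2, 3, 4), c("initiation",
                                            "incorporation",
                                            "termination"),
                              rnapIndex = 2L)
  tpl <- paste(rep("ACGT", 20), collapse = "")
  cfg <- runConfig(tpl, stdParams(), nReplicates = 1, seed = 1)
  sim <- new("TrafficSim", mode = "mra", config = cfg,
             replicates = list(list(t1, t2)))
  ct <- completionTimes(sim)
  expect_equal(ct$time[ct$rnapIndex == 1], 5)
  expect_equal(ct$time[ct$rnapIndex == 2], 2)
  expect_equal(unname(medianCompletionByIndex(sim)), c(5, 2))
})
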