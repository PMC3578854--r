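test_that("first-reaction waiting times follow the exponential law", {
  set.seed(101)
  draws <- replicate(1e4, gillespieStep(c(a = 4))$dt)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / 4), 3 * se)
  # two equal channels split evenly
  ch <- replicate(1e4, gillespieStep(c(x = 2, y = 2))$channel)
  expect_lt(abs(mean(ch == "x") - 0.5), 3 * 0.005)
  # zero-rate channels never fire; all-zero is a stalled state
  ch0 <- replicate(200, gillespieStep(c(a = 0, b = 1))$channel)
  expect_true(all(ch0 == "b"))
  expect_error(gillespieStep(c(a = 0, b = 0)), "stalled")
})

test_that("collision time solves the linear contact equation", {
  expect_equal(collisionTime(10, 2, 30, 1), 20)
  expect_true(is.na(collisionTime(10, 1, 30, 1)))   # parallel
  expect_true(is.na(collisionTime(10, 1, 30, 2)))   # separating
  expect_true(is.na(collisionTime(10, 2, 30, 1, tEnd = 5)))
  expect_equal(collisionTime(0, 1, 40, 0, d1 = 17, d2 = 17), 6)
  expect_error(collisionTime(10, 1, 12, 1, d1 = 17, d2 = 17),
               "exclusion")
})

test_that("collision solver agrees with a fine-grained scan", {
  set.seed(33)
  for (rep in 1:200) {
    xT <- runif(1, 0, 50)
    gap <- runif(1, 0, 5)
    D <- 34
    xL <- xT + D + gap
    vT <- runif(1, -3, 8); vL <- runif(1, -3, 8)
    tEnd <- 5
    tc <- collisionTime(xT, vT, xL, vL, tStart = 0, tEnd = tEnd,
                        d1 = 17, d2 = 17)
    ref <- bruteCollisionScan(xT, vT, xL, vL, tEnd, D)
    if (is.na(ref)) {
      # the scan grid may just miss a graze at the window edge
      expect_true(is.na(tc) || tc > tEnd - 1e-3)
    } else {
      expect_false(is.na(tc))
      expect_lt(abs(tc - ref), 1e-3)
    }
  }
})

test_that("single-round runs are reproducible and respect the
           stochastic mean on a flat template", {
  tpl <- paste(rep("A", 150), collapse = "")
  # suppress backtracking to isolate the incorporation clock
  p <- kineticParams(ntpConc = 250, k0 = 1e-12)
  cfg <- runConfig(tpl, p, nReplicates = 30, seed = 42)
  sim <- simulateSRA(cfg)
  sim2 <- simulateSRA(cfg)
  expect_identical(sim@replicates, sim2@replicates)
  # expected completion time: sum of exponential means with rates from
  # the package's own (separately tested) rate functions
  nStop <- 150 - 17
  rates <- vapply(0:(nStop - 1), function(n) {
    b <- if (n == 0) 0 else
      translocationBias(tecState(n = n), tpl, force = 0,
                        temperature = p@temperature)
    incorporationRate("A", p, b)
  }, numeric(1))
  expT <- sum(1 / rates)
  sdT <- sqrt(sum(1 / rates^2))
  times <- completionTimes(sim)$time
  se <- sqrt(sdT^2 / length(times))
  expect_lt(abs(mean(times) - expT), 4 * se)
})

test_that("raising all NTP concentrations never slows transcription", {
  tpl <- plainTemplate()
  lo <- runConfig(tpl, kineticParams(ntpConc = 50), nReplicates = 30,
                  seed = 9)
  hi <- runConfig(tpl, kineticParams(ntpConc = 500), nReplicates = 30,
                  seed = 9)
  tLo <- median(completionTimes(simulateSRA(lo))$time)
  tHi <- median(completionTimes(simulateSRA(hi))$time)
  expect_lte(tHi, tLo)
})

test_that("the multi-molecule engine with one molecule reproduces the
           single-round run bit-exactly", {
  cfg <- runConfig(plainTemplate(), stdParams(), nRnapMax = 1L,
                   nReplicates = 3, seed = 17)
  expect_identical(simulateSRA(cfg)@replicates,
                   simulateMRA(cfg)@replicates)
})

test_that("multi-molecule runs are seed-reproducible and respect
           hard-core exclusion and binding order", {
  cfg <- runConfig(pauseTemplate(), stdParams(), nRnapMax = 4L,
                   nReplicates = 8, seed = 23)
  sim <- simulateMRA(cfg)
  expect_identical(sim@replicates, simulateMRA(cfg)@replicates)
  for (rep in sim@replicates) {
    expect_gte(minPairGap(rep), -1e-6)
    for (tr in rep) {
      expect_false(is.unsorted(tr@events$time))
      validateTrajectory(tr)
    }
    # binding order equals spatial order at the end of the record
    fin <- vapply(rep, function(tr) tr@finalLength, numeric(1))
    tEnds <- vapply(rep, function(tr) tr@tEnd, numeric(1))
    # earlier molecules terminate no later than later ones
    expect_true(all(diff(tEnds) >= -1e-9))
  }
})

test_that("collision resolution transmits force in contact and
           exchanges intents elastically", {
  p <- stdParams()
  tr <- list(mode = "elongating", n = 40, offset = 0, x = 40.2,
             pendDir = 1L, pendTime = 1.05)
  ld <- list(mode = "elongating", n = 74, offset = 0, x = 74.2,
             pendDir = 1L, pendTime = 1.30)
  res <- resolveCollision("TN.LN", tr, ld, tc = 1.0, params = p)
  expect_true(res$contact)
  expect_equal(res$forceLeading, 25)
  expect_equal(res$forceTrailing, -25)
  expect_true(res$redrawTrailing && res$redrawLeading)
  # both backtracked: elastic exchange of step intentions
  trB <- list(mode = "backtracked", n = 45, offset = 3, x = 42.1,
              pendDir = 1L, pendTime = 1.4)
  ldB <- list(mode = "backtracked", n = 80, offset = 4, x = 76.1,
              pendDir = -1L, pendTime = 1.2)
  resE <- resolveCollision("TBf.LBb", trB, ldB, tc = 1.0, params = p)
  expect_false(resE$contact)
  expect_equal(resE$trailing$pendDir, -1L)
  expect_equal(resE$leading$pendDir, 1L)
  # remaining flight times are exchanged along with directions
  expect_equal(resE$trailing$pendTime - 1.0, ldB$pendTime - 1.0)
  expect_equal(resE$leading$pendTime - 1.0, trB$pendTime - 1.0)
  # the sum of intended displacements is conserved by the exchange
  expect_equal(resE$trailing$pendDir + resE$leading$pendDir,
               trB$pendDir + ldB$pendDir)
  expect_error(resolveCollision("XX.YY", trB, ldB, 1, p), "unreachable")
})

test_that("contact-scoped forces accelerate a paused leader", {
  # leader paused at a planted site: trailing collisions shorten its
  # dwell there (paired-seed comparison, pooled dwell at the site)
  tpl <- pauseTemplate()
  p <- stdParams()
  s1 <- cachedSim("sra-pause", function()
    simulateSRA(runConfig(tpl, p, nReplicates = 25, seed = 31)))
  s2 <- cachedSim("mra-pause", function()
    simulateMRA(runConfig(tpl, p, nRnapMax = 4L, nReplicates = 25,
                          seed = 31)))
  tqS <- dwellProfile(s1)@tq["120"]
  tqM <- dwellProfile(s2)@tq["120"]
  expect_lt(tqM, tqS)
})

test_that("trajectories hitting the time cap are flagged", {
  cfg <- runConfig(plainTemplate(), stdParams(), nReplicates = 2,
                   seed = 3, tMax = 0.5)
  sim <- simulateSRA(cfg)
  expect_true(all(vapply(sim@replicates,
                         function(r) r[[1]]@truncated, logical(1))))
  ct <- completionTimes(sim)
  expect_equal(nrow(ct), 0L)
  expect_equal(attr(ct, "nTruncated"), 2L)
})
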