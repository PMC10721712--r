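test_that("observed mean jump length matches the Rayleigh closed form", {
  # E[r] = sqrt(pi (D dt + sigma^2)); checked at a static and a fast state
  for (D in c(0, 0.512)) {
    cfg <- simulationConfig(D = D, occupancy = 1, nTrajectories = 1500,
                            meanTrackLength = 9)
    sim <- simulateSwitchingDiffusion(cfg, seed = 100 + round(D * 100))
    r <- computeJumpTable(sim$trajectories)@jumps$r
    se <- stats::sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - expectedMeanJump(D, 0.05, 0.02)), 3 * se)
  }
})

test_that("identity transition matrix yields single-state trajectories", {
  cfg <- simulationConfig(D = c(0.01, 0.5), occupancy = c(0.4, 0.6),
                          A = diag(2), nTrajectories = 200)
  sim <- simulateSwitchingDiffusion(cfg, seed = 3)
  states <- split(sim$truth@jumps$state, sim$truth@jumps$trajectory_id)
  expect_true(all(vapply(states, function(s) length(unique(s)) == 1L,
                         logical(1))))
})

test_that("state dwell times are geometric with the self-transition rate", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  cfg <- simulationConfig(D = c(0.01, 0.5), occupancy = c(0.5, 0.5),
                          A = A, nTrajectories = 400,
                          meanTrackLength = 60)
  sim <- simulateSwitchingDiffusion(cfg, seed = 4)
  # interior dwell runs (not touching track ends) of state 1
  runs <- unlist(lapply(split(sim$truth@jumps$state,
                              sim$truth@jumps$trajectory_id),
                        function(s) {
    r <- rle(s)
    if (length(r$lengths) > 2L)
      r$lengths[-c(1L, length(r$lengths))][r$values[-c(1L,
        length(r$values))] == 1L]
    else integer(0)
  }))
  expect_gt(length(runs), 200)
  # chi-squared against Geometric(p = 0.1) with a pooled tail
  br <- c(1:15, Inf)
  obs <- table(cut(runs, c(0, br)))
  pr <- diff(c(0, stats::pgeom(br - 1, 0.1)))
  expect_gt(stats::chisq.test(as.numeric(obs), p = pr)$p.value, 0.05)
})

test_that("an infinite detection slab reproduces the 2D generator exactly", {
  cfgI <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 50,
                           defocalDepth = Inf)
  cfg0 <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 50,
                           defocalDepth = 0)
  s1 <- simulateSwitchingDiffusion(cfgI, seed = 5)
  s2 <- simulateSwitchingDiffusion(cfg0, seed = 5)
  expect_identical(localizations(s1$trajectories),
                   localizations(s2$trajectories))
})

test_that("defocalization removes fast jumps but mode states stay closer", {
  cfg <- presetConfig("notch_off", nTrajectories = 3000, defocalDepth = 1)
  sim <- simulateSwitchingDiffusion(cfg, seed = 31)
  jumpFrac <- mean(sim$truth@jumps$state == 4L)
  modeFrac <- mean(sim$truth@trajectories$mode_state == 4L)
  expect_lt(jumpFrac, 0.481 - 0.05)        # strong per-jump bias
  expect_gt(modeFrac, jumpFrac)            # whole-trajectory summary closer
})

test_that("homogeneous point patterns follow the transformed-gamma kNN law", {
  pat <- simulateBoundPattern(0, nClusters = 0, clusterRadius = 0.1,
                              window = c(20, 20), nPoints = 2000,
                              seed = 6)
  k <- 11L
  d <- knnDistances(pat$points, k = k)
  lambda <- 2000 / 400
  # interior points are free of window-edge truncation; neighbouring
  # points share neighbourhoods so their kNN distances are positively
  # correlated -- the mean tolerance is widened accordingly
  inner <- which(pat$points[, 1] > 2 & pat$points[, 1] < 18 &
                   pat$points[, 2] > 2 & pat$points[, 2] < 18)
  expect_lt(abs(mean(d[inner]^2) - k / (lambda * pi)),
            5 * stats::sd(d[inner]^2) / sqrt(length(inner)))
  # distributional check on genuinely iid draws: one kNN distance per
  # independent pattern, measured from a fixed query point at the centre
  # (for a Poisson process the added-point view leaves the law unchanged)
  lam2 <- 600 / 144
  d2 <- vapply(seq_len(80), function(rep) {
    p2 <- simulateBoundPattern(0, 0, 0.1, c(12, 12), 600,
                               seed = 9000 + rep)$points
    sort((p2[, 1] - 6)^2 + (p2[, 2] - 6)^2, partial = k)[k]
  }, numeric(1))
  ks <- stats::ks.test(d2, stats::pgamma, shape = k, rate = lam2 * pi)
  expect_gt(ks$p.value, 0.05)
})

test_that("fully clustered patterns stay inside their discs", {
  pat <- simulateBoundPattern(1, nClusters = 1, clusterRadius = 0.5,
                              window = c(10, 10), nPoints = 200, seed = 7)
  dc <- sqrt(colSums((t(pat$points) - pat$centres[1, ])^2))
  expect_true(all(dc <= 0.5 + 1e-12))
  expect_true(all(pat$clustered))
  expect_error(simulateBoundPattern(0.5, 1, clusterRadius = 6,
                                    window = c(10, 10), nPoints = 100),
               "do not fit")
})

test_that("a no-escape trap confines molecules to its radius", {
  tr <- list(list(centre = c(5, 5), radius = 0.125, escapeProb = 0))
  cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 60,
                          meanTrackLength = 20, nucleus = c(10, 10),
                          traps = tr, trapFraction = 1)
  sim <- simulateTrappedMotion(cfg, seed = 8)
  df <- localizations(sim$trajectories)
  tj <- sim$truth@jumps
  trappedIds <- unique(tj$trajectory_id[tj$in_trap])
  dfT <- df[df$trajectory_id %in% trappedIds, ]
  d <- sqrt((dfT$x - 5)^2 + (dfT$y - 5)^2)
  expect_lt(max(d), 0.125 + 5 * 0.02)       # radius + localization noise
})

test_that("free diffusion is isotropic: R near zero and f(180/0) near 1", {
  cfg <- simulationConfig(D = 0.2, occupancy = 1, nTrajectories = 2000,
                          meanTrackLength = 12)
  sim <- simulateSwitchingDiffusion(cfg, seed = 9)
  th <- computeJumpTable(sim$trajectories)@angles$theta
  expect_gt(length(th), 1e4)
  expect_lt(circularSummary(th)$R, 0.02)
  expect_lt(abs(foldAnisotropy(th) - 1), 0.1)
})

test_that("rendered frames place emitter mass at the right pixel", {
  ts <- pathTS(cbind(rep(1.13, 4), rep(0.8, 4)))
  fr <- renderFrames(ts, psfSigma = 0.110, intensity = 1000,
                     background = 2, poissonNoise = FALSE,
                     imgDim = c(20, 20))
  am <- which(fr[, , 1] == max(fr[, , 1]), arr.ind = TRUE)
  expect_equal(as.integer(am[1, "col"]), floor(1.13 / 0.110) + 1L)
  expect_equal(as.integer(am[1, "row"]), floor(0.8 / 0.110) + 1L)
  # zero intensity leaves pure background
  fr0 <- renderFrames(ts, intensity = 0, background = 3,
                      poissonNoise = FALSE, imgDim = c(20, 20))
  expect_true(all(fr0 == 3))
})
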