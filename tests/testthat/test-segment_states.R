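test_that("EM log-likelihood is non-decreasing at every iteration", {
  cfg <- simulationConfig(D = c(0.02, 0.3), occupancy = c(0.5, 0.5),
                          nTrajectories = 300)
  sim <- simulateSwitchingDiffusion(cfg, seed = 41)
  jm <- TrackStates:::jumpMatrix(sim$trajectories)
  fit <- TrackStates:::runEM(jm$R2, jm$nJumps, D = c(0.005, 0.1),
                             A = stickyTransitionMatrix(c(.5, .5), .5),
                             pi0 = c(.5, .5), sigmaLoc = 0.02, dt = 0.05,
                             tol = 1e-6, maxIter = 200)
  expect_true(all(diff(fit$trace) > -1e-7))
})

test_that("single-state fits agree with the closed-form estimator", {
  cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 800)
  sim <- simulateSwitchingDiffusion(cfg, seed = 42)
  hmm <- fitHMM(sim$trajectories, K = 1, seed = 1)
  # independent oracle: D = (mean r^2 / 4 - sigma^2) / dt
  r2 <- TrackStates:::jumpMatrix(sim$trajectories)$R2
  r2 <- r2[!is.na(r2)]
  oracle <- (mean(r2) / 4 - 0.02^2) / 0.05
  expect_equal(diffusionCoefficients(hmm), oracle, tolerance = 1e-4)
  se <- (stats::sd(r2) / sqrt(length(r2))) / (4 * 0.05)
  expect_lt(abs(diffusionCoefficients(hmm) - 0.1), 3 * se)
})

test_that("two-state parameters and labels are recovered from the truth", {
  cfg <- simulationConfig(D = c(0.01, 0.5), occupancy = c(0.5, 0.5),
                          stickiness = 0.9, nTrajectories = 2000)
  sim <- simulateSwitchingDiffusion(cfg, seed = 43)
  hmm <- fitHMM(sim$trajectories, K = 2, seed = 2)
  D <- diffusionCoefficients(hmm)
  expect_lt(abs(D[1] - 0.01) / 0.01, 0.10)
  expect_lt(abs(D[2] - 0.5) / 0.5, 0.10)
  expect_true(all(abs(transitionMatrix(hmm) - cfg$A) < 0.05))
  # per-jump label accuracy against the generator truth
  asg <- decodeStates(hmm, sim$trajectories)
  key <- paste(asg@jumps$trajectory_id, asg@jumps$jump_index)
  tkey <- paste(sim$truth@jumps$trajectory_id, sim$truth@jumps$jump_index)
  acc <- mean(asg@jumps$state == sim$truth@jumps$state[match(key, tkey)])
  expect_gt(acc, 0.90)
})

test_that("model selection picks one state for single-state data", {
  cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 400)
  sim <- simulateSwitchingDiffusion(cfg, seed = 44)
  sel <- suppressWarnings(
    selectModel(sim$trajectories, KMax = 3, seed = 3, nRestarts = 2))
  expect_equal(sel$K, 1L)
  expect_equal(nrow(sel$scores), 3L)
})

test_that("identity-transition data decode to single-labelled trajectories", {
  cfg <- simulationConfig(D = c(0.01, 0.5), occupancy = c(0.5, 0.5),
                          A = diag(2), nTrajectories = 300)
  sim <- simulateSwitchingDiffusion(cfg, seed = 45)
  hmm <- fitHMM(sim$trajectories, K = 2, seed = 4)
  asg <- decodeStates(hmm, sim$trajectories)
  perTraj <- split(asg@jumps$state, asg@jumps$trajectory_id)
  uniq <- vapply(perTraj, function(s) length(unique(s)) == 1L, logical(1))
  expect_gt(mean(uniq), 0.95)
  md <- modeStates(asg)
  one <- names(perTraj)[uniq]
  expect_equal(md$mode_state[match(one, md$trajectory_id)],
               unname(vapply(perTraj[one], `[`, integer(1), 1L)))
  expect_equal(sum(stateProportions(asg)), 1)
  expect_equal(sum(stateProportions(asg, perJump = TRUE)), 1)
})

test_that("mode-state ties break toward the slower state", {
  hmm <- new("DiffusionHMM", K = 2L, D = c(0.01, 0.5),
             A = matrix(0.5, 2, 2), pi = c(0.5, 0.5), sigmaLoc = 0.02,
             frameInterval = 0.05, logLik = 0, nIter = 1L,
             converged = TRUE)
  # two clearly slow and two clearly fast jumps: a 2-2 mode tie
  xy <- cbind(c(0, 0.005, 0.30, 0.305, 0.60), rep(0, 5))
  asg <- decodeStates(hmm, pathTS(xy))
  expect_equal(sort(unique(asg@jumps$state)), c(1L, 2L))
  expect_equal(modeStates(asg)$mode_state, 1L)
})

test_that("degenerate and undersized inputs are rejected", {
  xy <- cbind(cumsum(rep(0.1, 8)), rep(0, 8))
  expect_error(fitHMM(pathTS(xy), K = 1), "at least 100 jumps")
  df <- do.call(rbind, lapply(1:40, function(i)
    data.frame(trajectory_id = sprintf("t%02d", i), frame = 0:4,
               x = (0:4) * 0.25, y = 0)))   # exactly representable steps
  expect_error(fitHMM(trajectorySet(df, 0.05), K = 1), "degenerate")
})

test_that("population summaries aggregate across nuclei", {
  cfg <- simulationConfig(D = c(0.01, 0.5), occupancy = c(0.3, 0.7),
                          nTrajectories = 300)
  asgs <- lapply(1:3, function(i) {
    sim <- simulateSwitchingDiffusion(cfg, seed = 50 + i)
    hmm <- fitHMM(sim$trajectories, K = 2, seed = i, nRestarts = 2)
    decodeStates(hmm, sim$trajectories)
  })
  ps <- populationSummary(asgs)
  expect_equal(nrow(ps), 2L)
  expect_equal(sum(ps$mean_proportion), 1)
  expect_true(all(ps$sd_proportion >= 0))
  # an all-in-one-state nucleus has proportions (0, 1)
  allfast <- asgs[[1]]
  allfast@trajectories$mode_state <- 2L
  allfast@proportions <- c(0, 1)
  expect_equal(stateProportions(allfast), c(0, 1))
})
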