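test_that("spot detection finds isolated emitters and nothing on flat frames", {
  expect_equal(nrow(detectSpots(matrix(5, 40, 40))), 0L)
  ts <- pathTS(cbind(rep(2.2, 4), rep(1.7, 4)))
  fr <- renderFrames(ts, intensity = 2000, background = 5,
                     poissonNoise = TRUE, imgDim = c(40, 40), seed = 1)
  cand <- detectSpots(fr[, , 1])
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$px - (2.2 / 0.110 + 0.5)), 2)
  expect_lt(abs(cand$py - (1.7 / 0.110 + 0.5)), 2)
  # two emitters ten pixels apart give two candidates
  ts2 <- trajectorySet(
    data.frame(trajectory_id = rep(c("a", "b"), each = 4),
               frame = rep(0:3, 2),
               x = rep(c(1.1, 1.1 + 10 * 0.110), each = 4),
               y = rep(1.1, 8)), 0.05)
  fr2 <- renderFrames(ts2, intensity = 2000, background = 5,
                      imgDim = c(40, 40), seed = 2)
  expect_equal(nrow(detectSpots(fr2[, , 1])), 2L)
})

test_that("Gaussian fitting reaches deep sub-pixel accuracy without noise", {
  pos <- c(10.30, 20.70) * 0.110            # emitter at (10.30, 20.70) px
  ts <- pathTS(cbind(rep(pos[1], 4), rep(pos[2], 4)))
  fr <- renderFrames(ts, intensity = 5000, background = 2,
                     poissonNoise = FALSE, imgDim = c(40, 40))
  cand <- detectSpots(fr[, , 1])
  fit <- fitGaussianSpot(fr[, , 1], cand[1, ])
  expect_lt(abs(fit$x - pos[1]) / 0.110, 0.01)
  expect_lt(abs(fit$y - pos[2]) / 0.110, 0.01)
  # border candidates are discarded
  expect_null(fitGaussianSpot(fr[, , 1], data.frame(px = 2, py = 20,
                                                    value = 1)))
})

test_that("fit uncertainty shrinks as the emitter gets brighter", {
  errs <- vapply(c(150, 600, 4000), function(A) {
    e <- vapply(1:25, function(i) {
      ts <- pathTS(cbind(rep(2.17, 4), rep(2.03, 4)))
      fr <- renderFrames(ts, intensity = A, background = 10,
                         imgDim = c(40, 40), seed = 100 + i)
      cand <- detectSpots(fr[, , 1], thresholdSd = 3)
      if (!nrow(cand)) return(NA_real_)
      ft <- fitGaussianSpot(fr[, , 1], cand[1, ])
      if (is.null(ft)) NA_real_ else ft$fitError
    }, numeric(1))
    mean(e, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("linking joins single molecules and separates distant ones", {
  df <- data.frame(frame = 0:4, x = c(0, .05, .09, .15, .18), y = 0.5)
  ts <- linkTrajectories(df, maxDisp = 0.3, frameInterval = 0.05)
  expect_equal(nTrajectories(ts), 1L)
  expect_equal(nrow(localizations(ts)), 5L)
  two <- rbind(transform(df, y = 0.5), transform(df, y = 5))
  ts2 <- linkTrajectories(two, maxDisp = 0.3, frameInterval = 0.05)
  expect_equal(nTrajectories(ts2), 2L)
  tab <- table(localizations(ts2)$trajectory_id,
               localizations(ts2)$y > 2)
  expect_true(all(rowSums(tab > 0) == 1))   # no switches between molecules
})

test_that("linking audits correctly against simulated ground truth", {
  cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 60,
                          meanTrackLength = 12, nucleus = c(25, 25))
  sim <- simulateSwitchingDiffusion(cfg, seed = 101)
  df <- localizations(sim$trajectories)
  maxDisp <- 3 * sqrt(4 * 0.1 * 0.05)
  ts <- linkTrajectories(df[, c("frame", "x", "y")], maxDisp = maxDisp,
                         frameInterval = 0.05)
  # audit: a link is correct when consecutive points it joins carry the
  # same original trajectory id
  lk <- localizations(ts)
  key <- paste(df$frame, round(df$x, 9), round(df$y, 9))
  lk$orig <- df$trajectory_id[match(paste(lk$frame, round(lk$x, 9),
                                          round(lk$y, 9)), key)]
  ok <- unlist(lapply(split(lk$orig, lk$trajectory_id),
                      function(o) o[-1] == o[-length(o)]))
  expect_gt(mean(ok), 0.95)
})

test_that("linking is invariant to within-frame point order", {
  set.seed(102)
  cfg <- simulationConfig(D = 0.05, occupancy = 1, nTrajectories = 30,
                          meanTrackLength = 10, nucleus = c(15, 15))
  sim <- simulateSwitchingDiffusion(cfg, seed = 103)
  df <- localizations(sim$trajectories)[, c("frame", "x", "y")]
  perm <- df[sample(nrow(df)), ]
  pairsOf <- function(ts) {
    d <- TrackStates:::orderLocs(localizations(ts))
    first <- !duplicated(d$trajectory_id)
    sort(paste(round(d$x[-nrow(d)], 9), round(d$y[-nrow(d)], 9),
               round(d$x[-1], 9), round(d$y[-1], 9))[
      !first[-1]])
  }
  t1 <- linkTrajectories(df, 0.5, 0.05)
  t2 <- linkTrajectories(perm, 0.5, 0.05)
  expect_equal(pairsOf(t2), pairsOf(t1))
})

test_that("simulate -> render -> localize -> link recovers the input D", {
  cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 25,
                          meanTrackLength = 12, nucleus = c(8, 8),
                          sigmaLoc = 1e-4)
  sim <- simulateSwitchingDiffusion(cfg, seed = 104)
  stack <- renderFrames(sim$trajectories, psfSigma = 0.110,
                        intensity = 3000, background = 5,
                        imgDim = c(80, 80), seed = 105)
  locs <- localizeStack(stack, thresholdSd = 4)
  ts <- linkTrajectories(locs, maxDisp = 3 * sqrt(4 * 0.1 * 0.05),
                         frameInterval = 0.05)
  jm <- TrackStates:::jumpMatrix(ts)
  r2 <- jm$R2[!is.na(jm$R2)]
  prec <- mean(localizations(ts)$precision)
  Dhat <- (mean(r2) / 4 - prec^2) / 0.05
  expect_gt(length(r2), 100)
  expect_lt(abs(Dhat - 0.1) / 0.1, 0.10)
})
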