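test_that("barycentres are per-trajectory means of bound trajectories", {
  df <- rbind(
    data.frame(trajectory_id = "a", frame = 0:3,
               x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    data.frame(trajectory_id = "b", frame = 0:3, x = 5, y = 7))
  ts <- trajectorySet(df, 0.05)
  asg <- new("StateAssignment",
             jumps = data.frame(trajectory_id = rep(c("a", "b"), each = 3),
                                jump_index = rep(1:3, 2),
                                state = rep(c(1L, 2L), each = 3)),
             trajectories = data.frame(trajectory_id = c("a", "b"),
                                       mode_state = c(1L, 2L),
                                       n_jumps = c(3L, 3L)),
             proportions = c(.5, .5), jumpProportions = c(.5, .5), K = 2L)
  b <- trajectoryBarycentres(ts, asg, boundStates = c(1L, 2L))
  expect_equal(nrow(b), 2L)                      # count conservation
  expect_equal(unname(b["a", ]), c(0.5, 0.5))    # square centroid
  expect_equal(unname(b["b", ]), c(5, 7))        # repeated point
  b1 <- trajectoryBarycentres(ts, asg, boundStates = 1L)
  expect_equal(rownames(b1), "a")
  expect_error(trajectoryBarycentres(ts, asg, boundStates = 4L),
               "no bound")
})

test_that("kNN distances are exact on a unit-spaced line", {
  pts <- cbind(0:11, 0)
  d <- knnDistances(pts, k = 11)
  expect_equal(d[1], 11)   # end point: 11th neighbour is the far end
  expect_equal(d[7], 6)    # interior point: 11th neighbour six steps away
  expect_error(knnDistances(pts[1:10, ], k = 11), "at least")
  # duplicated points: distances remain finite, no NaN
  d2 <- knnDistances(rbind(pts, pts), k = 11)
  expect_true(all(is.finite(d2)))
})

test_that("the mixture EM separates clusters from clutter", {
  pat <- simulateBoundPattern(0.5, nClusters = 15, clusterRadius = 0.25,
                              window = c(20, 20), nPoints = 1000,
                              seed = 91)
  expect_gt(pat$lambda1 / pat$lambda2, 50)
  d <- knnDistances(pat$points, k = 11)
  cm <- fitKnnMixtureEM(d, k = 11, points = pat$points)
  expect_false(cm@degenerate)
  expect_lt(abs(cm@p - 0.5), 0.05)
  expect_gt(mean(clusteredFlags(cm) == pat$clustered), 0.95)
  expect_gt(cm@lambda[1], cm@lambda[2])
  # intensity recovery within 10% needs dense discs (near a disc edge the
  # neighbourhood is truncated, biasing lambda1 down); averaged over
  # seeds to damp the disc-placement variability of few-cluster patterns
  rel <- vapply(1:4, function(s) {
    pat2 <- simulateBoundPattern(0.5, nClusters = 3, clusterRadius = 0.7,
                                 window = c(20, 20), nPoints = 4000,
                                 seed = 95 + s)
    cm2 <- fitKnnMixtureEM(knnDistances(pat2$points, 11), k = 11)
    c((cm2@lambda[1] - pat2$lambda1) / pat2$lambda1,
      (cm2@lambda[2] - pat2$lambda2) / pat2$lambda2)
  }, numeric(2))
  expect_lt(abs(mean(rel[1, ])), 0.10)
  expect_lt(abs(mean(rel[2, ])), 0.10)
})

test_that("homogeneous input is flagged degenerate and one component wins", {
  pat <- simulateBoundPattern(0, 0, 0.1, c(20, 20), 800, seed = 92)
  k <- 11L
  d <- knnDistances(pat$points, k)
  cm <- fitKnnMixtureEM(d, k = k)
  expect_true(cm@degenerate)
  # BIC comparison on exact draws from the one-component kNN law (window
  # edges distort pattern-derived distances away from the pure law)
  set.seed(97)
  lam0 <- 2
  dg <- sqrt(stats::rgamma(800, shape = k, rate = lam0 * pi))
  cmg <- fitKnnMixtureEM(dg, k = k)
  lam <- k * length(dg) / (pi * sum(dg^2))   # closed-form MLE
  ll1 <- sum(TrackStates:::logKnnDensity(dg, k, lam))
  bic1 <- -2 * ll1 + 1 * log(length(dg))
  bic2 <- -2 * cmg@logLik + 3 * log(length(dg))
  expect_lt(bic1, bic2)
  expect_true(cmg@degenerate)
})

test_that("near-cluster jump flags and anisotropic proportions", {
  cl <- rbind(c(5, 5), c(8, 8))
  starts <- rbind(c(5, 5.1), c(5, 5.54), c(5, 5.56), c(1, 1))
  near <- nearClusterJumps(starts, cl, radius = 0.55)
  expect_equal(near, c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(n0 <- nearClusterJumps(starts, NULL), "no clustered")
  expect_false(any(n0))
  set.seed(93)
  th <- runif(3e4, 0, 360)
  nearU <- runif(3e4) < 0.3
  ap <- anisotropicProportion(flagAnisotropicJumps(th), nearU)
  expect_lt(abs(ap$near - 1 / 6), 0.02)
  expect_lt(abs(ap$away - 1 / 6), 0.02)
  expect_lt(abs(ap$nearShare - 0.3), 0.02)
  sent <- anisotropicProportion(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.nan(sent$near))
})

test_that("a forced zero translation reproduces the real near proportion", {
  set.seed(94)
  starts <- cbind(runif(2000, 0, 10), runif(2000, 0, 10))
  anis <- runif(2000) < 1 / 6
  cl <- cbind(runif(20, 3, 7), runif(20, 3, 7))
  real <- anisotropicProportion(anis, nearClusterJumps(starts, cl, 0.55))
  ctl <- shiftedClusterControl(cl, starts, anis, radius = 0.55,
                               shifts = matrix(0, 1, 2))
  expect_equal(ctl$mean, real$near)
  expect_equal(ctl$nAccepted, 1L)
})

test_that("control acceptance falls as clusters spread toward the ROI size", {
  set.seed(95)
  starts <- cbind(runif(3000, 0, 10), runif(3000, 0, 10))
  anis <- runif(3000) < 1 / 6
  tight <- cbind(runif(25, 4.5, 5.5), runif(25, 4.5, 5.5))
  wide <- cbind(runif(25, 0.2, 9.8), runif(25, 0.2, 9.8))
  cT <- shiftedClusterControl(tight, starts, anis, nControl = 100,
                              seed = 1)
  cW <- shiftedClusterControl(wide, starts, anis, nControl = 100,
                              seed = 1)
  expect_gt(cT$nAccepted, cW$nAccepted)
  # null geometry: the control stays near the global anisotropy level
  expect_lt(abs(cT$mean - 1 / 6), 0.05)
})
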