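test_that("stage 1 recovers planted time courses from a noiseless construction", {
  set.seed(20)
  dims <- c(10, 10, 10); nv <- prod(dims); nt <- 80; K <- 3
  # orthogonalized spatial maps
  M <- qr.Q(qr(matrix(rnorm(nv * K), nv, K)))
  tc <- matrix(rnorm(nt * K), nt, K)
  bold <- makeVol(array(t(tc %*% t(M)), c(dims, nt)))
  dec <- new("ICADecomposition", maps = array(M, c(dims, K)),
             mixing = matrix(0, 1, K), mask = fullMask(dims),
             varianceRetained = 1,
             convergence = list(iterations = 0L, tolerance = 0,
                                restarts = 0L), seed = 0)
  est <- stage1Timecourses(bold, dec)
  for (k in seq_len(K)) expect_gt(abs(cor(est[, k], tc[, k])), 0.999)
  # pure-noise volume: no association with the planted courses
  noise <- makeVol(array(rnorm(nv * 200), c(dims, 200)))
  estN <- stage1Timecourses(noise, dec)
  tc200 <- matrix(rnorm(200 * K), 200, K)
  for (k in seq_len(K)) expect_lt(abs(cor(estN[, k], tc200[, k])), 0.2)
  # constant volume: all non-intercept weights vanish
  flat <- makeVol(array(5, c(dims, 20)))
  estF <- stage1Timecourses(flat, dec, normalize = FALSE)
  expect_lt(max(abs(estF)), 1e-10)
})

test_that("stage 2 is a joint regression matching the least-squares oracle", {
  set.seed(21)
  dims <- c(6, 6, 6); nv <- prod(dims); nt <- 60
  tc1 <- rnorm(nt)
  tc2 <- 0.7 * tc1 + sqrt(1 - 0.49) * rnorm(nt)   # deliberately correlated
  tc <- cbind(tc1, tc2)
  B <- matrix(rnorm(nv * 2), nv, 2)
  Y <- tc %*% t(B) + matrix(rnorm(nt * nv, sd = 0.3), nt)
  bold <- makeVol(array(t(Y), c(dims, nt)))
  thal <- fullMask(dims); brain <- fullMask(dims)
  sub <- stage2Subdivisions(bold, tc, thal, brain)
  est <- thalamicBetas(sub)
  # oracle: per-voxel lm on both regressors jointly
  for (v in c(1, 50, 200)) {
    fit <- coef(lm(Y[, v] ~ tc1 + tc2))
    expect_equal(est[1, v], unname(fit[2]), tolerance = 1e-8)
    expect_equal(est[2, v], unname(fit[3]), tolerance = 1e-8)
  }
  # marginal (simple) betas differ when courses are correlated
  marg <- coef(lm(Y[, 1] ~ tc1))[2]
  expect_gt(abs(est[1, 1] - marg), 1e-3)
  # collinear courses are refused with the worst pair named
  expect_error(stage2Subdivisions(bold, cbind(tc1, tc1 * (1 + 1e-12)),
                                  thal, brain),
               "collinear")
})

test_that("noiseless subjects yield exact thalamic weight recovery per component", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 3, noiseSd = 0,
                        nTimepoints = 80, seed = 5)
  s <- simulateSubject(gt, "control", seed = 11)
  dec <- gtDecomposition(gt)
  dr <- dualRegression(s$bold, dec, gt@thalamus, gt@brain)
  tb <- thalamicBetas(dr$subdivisions)
  w <- gtThalWeightMatrix(gt)
  for (k in 1:3) expect_gt(cor(tb[k, ], w[, k]), 0.999)
})

test_that("a component with no thalamic weight gets a near-zero thalamic beta map", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 2, noiseSd = 0.2,
                        thalBaseline = 0, nTimepoints = 120, seed = 8,
                        groupEffect = data.frame(component = integer(0),
                                                 factor = numeric(0)))
  # kill component 2's thalamic weights entirely
  gt@thalWeights[, , , 2] <- 0
  gt@thalWeights[, , , 2][which(gt@thalamus@data)[1]] <- 1e-9
  s <- simulateSubject(gt, "control", seed = 3)
  dec <- gtDecomposition(gt)
  dr <- dualRegression(s$bold, dec, gt@thalamus, gt@brain)
  tb <- thalamicBetas(dr$subdivisions)
  expect_lt(mean(abs(tb[2, ])), 0.25 * mean(abs(tb[1, ])))
})

test_that("patients with a reduced factor show lower thalamic betas on the affected component", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 2, noiseSd = 1,
                        nTimepoints = 100, seed = 4,
                        groupEffect = data.frame(component = 1L,
                                                 factor = 0.5))
  dec <- gtDecomposition(gt)
  w <- gtThalWeightMatrix(gt)
  support <- w[, 1] > 0.5 * max(w[, 1])
  mc <- mp <- numeric(50)
  for (i in 1:50) {
    sc <- simulateSubject(gt, "control", seed = 500 + i)
    sp <- simulateSubject(gt, "patient", seed = 500 + i)
    mc[i] <- mean(thalamicBetas(dualRegression(sc$bold, dec, gt@thalamus,
                                               gt@brain)$subdivisions)[1, support])
    mp[i] <- mean(thalamicBetas(dualRegression(sp$bold, dec, gt@thalamus,
                                               gt@brain)$subdivisions)[1, support])
  }
  expect_gt(mean(mc), mean(mp))
  expect_gt(mean(mc > mp), 0.7)   # consistently, not just on average
})

test_that("group-averaged subdivision maps recover the planted support (Dice)", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 3, noiseSd = 0.5,
                        nTimepoints = 100, seed = 6)
  dec <- gtDecomposition(gt)
  w <- gtThalWeightMatrix(gt)
  n <- 8
  acc <- 0
  for (i in seq_len(n)) {
    s <- simulateSubject(gt, "control", seed = 900 + i)
    acc <- acc + thalamicBetas(dualRegression(s$bold, dec, gt@thalamus,
                                              gt@brain)$subdivisions)
  }
  acc <- acc / n
  for (k in 1:3) {
    truth <- w[, k] > 0.5 * max(w[, k])
    est <- rank(-acc[k, ]) <= sum(truth)   # matched-size threshold
    dice <- 2 * sum(truth & est) / (sum(truth) + sum(est))
    expect_gt(dice, 0.7)
  }
})
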