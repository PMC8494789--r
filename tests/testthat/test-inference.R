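test_that("GLM t map matches the classic pooled two-sample t", {
  mask <- fullMask(c(1, 1, 1))
  Y <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1)
  des <- groupDesign(rep(c("g1", "g2"), each = 3),
                     contrast = c(-1, 0))       # mean(g1) - mean(g2)
  tm <- glmTMap(Y, des, mask)
  expect_equal(tm@stat[1, 1, 1], -3.674, tolerance = 5e-4)
  expect_equal(tm@df, 4)
  # against the base oracle
  tt <- t.test(Y[1:3], Y[4:6], var.equal = TRUE)
  expect_equal(tm@stat[1, 1, 1], unname(tt$statistic), tolerance = 1e-10)
  # identical groups give t = 0
  Y0 <- matrix(rep(c(1, 2, 3), 2), 6, 1)
  expect_equal(glmTMap(Y0, des, mask)@stat[1, 1, 1], 0)
})

test_that("a covariate orthogonal to group and data leaves t unchanged", {
  set.seed(30)
  mask <- fullMask(c(2, 2, 2))
  n <- 60   # large enough that the 1-df change is negligible
  Y <- matrix(rnorm(n * 8), n, 8)
  g <- rep(c("a", "b"), each = n / 2)
  des0 <- groupDesign(g)
  gnum <- as.numeric(g == "b")
  raw <- rnorm(n)
  cov1 <- residuals(lm(raw ~ gnum + Y))  # orthogonal to group and all voxels
  des1 <- groupDesign(g, covariates = data.frame(c1 = cov1),
                      contrast = c(1, 0, 0))
  t0 <- glmTMap(Y, des0, mask)@stat
  t1 <- glmTMap(Y, des1, mask)@stat
  expect_equal(t1, t0, tolerance = 0.02)
})

test_that("TFCE matches its integral oracle and the extent-ratio law", {
  z <- array(0, c(5, 5, 5))
  expect_equal(tfce(z), z)
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 2
  v <- tfce(a, E = 0.5, H = 2, dh = 0.01)
  expect_equal(v[3, 3, 3], 8 / 3, tolerance = 0.01)   # int_0^2 h^2 dh
  # a 2-voxel cluster beats a 1-voxel cluster by exactly 2^E
  b <- array(0, c(9, 9, 9))
  b[2, 2, 2] <- 1.5
  b[7, 7, 7] <- 1.5; b[7, 8, 7] <- 1.5
  vb <- tfce(b, E = 0.5, H = 2, dh = 0.01)
  expect_equal(vb[7, 7, 7] / vb[2, 2, 2], 2^0.5, tolerance = 1e-10)
  # negative tail mirrors the positive tail
  vn <- tfce(-a, E = 0.5, H = 2, dh = 0.01)
  expect_equal(vn[3, 3, 3], -v[3, 3, 3])
  # sub-threshold background below dh does not change the enhancement
  a2 <- a; a2[a2 == 0] <- 0.005
  v2 <- tfce(a2, E = 0.5, H = 2, dh = 0.01)
  expect_equal(v2[3, 3, 3], v[3, 3, 3], tolerance = 1e-10)
})

test_that("connected-component labelling respects the connectivity scheme", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE   # diagonal neighbours in-plane
  lab26 <- labelClusters(m, 26)
  lab6 <- labelClusters(m, 6)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE  # full 3D diagonal
  expect_equal(max(labelClusters(m2, 18)), 2L)
  expect_equal(max(labelClusters(m2, 26)), 1L)
})

test_that("Freedman-Lane with no covariates equals simple label permutation", {
  set.seed(31)
  n <- 10; nv <- 27
  mask <- fullMask(c(3, 3, 3))
  Y <- matrix(rnorm(n * nv), n, nv)
  g <- rep(c("a", "b"), each = 5)
  des <- groupDesign(g)
  nPerm <- 200
  suppressWarnings(
    pr <- permutationTest(Y, des, mask, enhancement = "voxel",
                          nPerm = nPerm, seed = 99))
  # oracle: permute raw rows of Y with the same RNG stream
  X <- des@X
  set.seed(99)
  oracle <- numeric(nPerm)
  for (j in seq_len(nPerm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    tp <- numeric(nv)
    for (v in seq_len(nv))
      tp[v] <- unname(t.test(Yp[1:5, v], Yp[6:10, v],
                             var.equal = TRUE)$statistic)
    oracle[j] <- max(abs(tp))
  }
  expect_equal(pr@nullMax, oracle, tolerance = 1e-8)
})

test_that("corrected p is monotone nonincreasing in the enhanced statistic", {
  set.seed(32)
  mask <- fullMask(c(4, 4, 4))
  Y <- matrix(rnorm(12 * 64), 12, 64)
  Y[7:12, 1:5] <- Y[7:12, 1:5] + 2
  des <- groupDesign(rep(c("a", "b"), each = 6))
  suppressWarnings(
    pr <- permutationTest(Y, des, mask, enhancement = "tfce",
                          nPerm = 300, seed = 1))
  e <- pr@enhanced[mask@data]
  p <- pr@pMap[mask@data]
  o <- order(e)
  expect_true(all(diff(p[o]) <= 1e-12))
  expect_true(all(p >= 1 / 301 - 1e-12 & p <= 1))
})

test_that("exhaustive sign-flip enumeration reproduces the brute-force p exactly", {
  set.seed(33)
  n <- 4; nv <- 8
  mask <- fullMask(c(2, 2, 2))
  Y <- matrix(rnorm(n * nv, mean = 1.2), n, nv)
  des <- oneSampleDesign(n)
  suppressWarnings(
    pr <- permutationTest(Y, des, mask, enhancement = "voxel",
                          nPerm = 500, seed = 1, alternative = "greater"))
  expect_equal(pr@nPerm, 16)
  # brute-force enumeration oracle
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tmax <- apply(signs, 1, function(s) {
    ts <- apply(Y * s, 2, function(y) mean(y) / (sd(y) / sqrt(n)))
    max(ts)
  })
  tobs <- apply(Y, 2, function(y) mean(y) / (sd(y) / sqrt(n)))
  pOracle <- vapply(tobs, function(t0) mean(tmax >= t0 - 1e-12), numeric(1))
  expect_equal(pr@pMap[mask@data], pOracle, tolerance = 1e-10)
  # sampled run at larger n agrees with its own resolution floor
  Yb <- matrix(rnorm(12 * nv, mean = 3), 12, nv)
  suppressWarnings(
    prb <- permutationTest(Yb, oneSampleDesign(12), mask,
                           enhancement = "voxel", nPerm = 500, seed = 1,
                           alternative = "greater"))
  expect_equal(min(prb@pMap[mask@data]), 1 / 501)
})

test_that("sign flipping refuses a varying interest regressor", {
  mask <- fullMask(c(2, 2, 2))
  Y <- matrix(rnorm(48), 6, 8)
  des <- groupDesign(rep(c("a", "b"), each = 3))
  des@scheme <- "sign_flip"
  expect_error(suppressWarnings(
    permutationTest(Y, des, mask, enhancement = "voxel", nPerm = 100)),
    "sign_flip")
})

test_that("cluster-extent correction finds a planted cluster and stays quiet otherwise", {
  set.seed(34)
  dims <- c(10, 10, 10)
  mask <- fullMask(dims)
  n <- 12; nv <- prod(dims)
  Y <- matrix(rnorm(n * nv), n, nv)
  # plant a 30-voxel block effect in group b
  block <- array(FALSE, dims); block[4:6, 4:6, 4:7] <- TRUE
  idx <- which(block[mask@data])[1:30]
  Y[7:12, idx] <- Y[7:12, idx] + 2.5
  des <- groupDesign(rep(c("a", "b"), each = 6))
  suppressWarnings(
    res <- clusterExtentCorrect(Y, des, mask, formingT = 2.3, nPerm = 500,
                                seed = 5))
  ct <- clusterTable(res)
  expect_gt(nrow(ct), 0)
  expect_lt(ct$p[1], 0.05)
  expect_gte(ct$size[1], 20)
  # no suprathreshold voxels: empty table, no error
  Y0 <- matrix(rnorm(n * nv, sd = 0.01), n, nv)
  suppressWarnings(
    res0 <- clusterExtentCorrect(Y0, des, mask, formingT = 50, nPerm = 100,
                                 seed = 5))
  expect_equal(nrow(clusterTable(res0)), 0)
})

test_that("significant clusters are annotated with nucleus names from a label atlas", {
  set.seed(36)
  dims <- c(8, 8, 8)
  mask <- fullMask(dims)
  n <- 12; nv <- prod(dims)
  Y <- matrix(rnorm(n * nv, sd = 0.5), n, nv)
  block <- array(FALSE, dims); block[3:5, 3:5, 3:5] <- TRUE
  idx <- which(block[mask@data])
  Y[7:12, idx] <- Y[7:12, idx] + 2
  des <- groupDesign(rep(c("a", "b"), each = 6))
  suppressWarnings(
    res <- permutationTest(Y, des, mask, enhancement = "tfce", nPerm = 300,
                           seed = 2))
  expect_gt(nrow(clusterTable(res)), 0)
  tab <- readLabelTable(system.file("extdata",
                                    "synthetic_thalamic_nuclei.tsv",
                                    package = "thalnet"))
  expect_equal(tab$name[1], "mediodorsal")
  labArr <- array(0L, dims)
  labArr[block] <- 2L                    # the planted block is "ventrolateral"
  lv <- new("LabelVolume", data = labArr, labelTable = tab,
            voxelSize = c(3, 3, 3), affine = idAffine())
  ann <- annotateClusters(res, lv)
  expect_true("label" %in% names(ann))
  expect_equal(ann$label[1], "ventrolateral")
})
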