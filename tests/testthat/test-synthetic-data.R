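test_that("ground truth is reproducible and its networks are spatially distinct", {
  gt1 <- makeGroundTruth(dims = c(18, 22, 18), K = 3, seed = 9)
  gt2 <- makeGroundTruth(dims = c(18, 22, 18), K = 3, seed = 9)
  expect_identical(gt1@networkMaps, gt2@networkMaps)
  expect_identical(gt1@thalWeights, gt2@thalWeights)
  b <- gt1@brain@data
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(cor(gt1@networkMaps[, , , i][b],
                      gt1@networkMaps[, , , j][b])), 0.2)
  # total thalamic weight positive on every thalamic voxel
  wsum <- apply(gt1@thalWeights, 1:3, sum)
  expect_true(all(wsum[gt1@thalamus@data] > 0))
  expect_error(makeGroundTruth(dims = c(8, 8, 8)), "at least 12")
})

test_that("noiseless single-component voxels are exact scalar multiples of the time course", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 2, noiseSd = 0,
                        thalBaseline = 0, nTimepoints = 60, seed = 3,
                        groupEffect = data.frame(component = integer(0),
                                                 factor = numeric(0)))
  s <- simulateSubject(gt, "control", seed = 8)
  net1 <- gt@networkMaps[, , , 1]
  idx <- which(net1 > 0.5 * max(net1), arr.ind = TRUE)
  ref <- s$bold@data[idx[1, 1], idx[1, 2], idx[1, 3], ]
  for (i in 2:nrow(idx)) {
    v <- s$bold@data[idx[i, 1], idx[i, 2], idx[i, 3], ]
    ratio <- v / ref
    expect_lt(diff(range(ratio)), 1e-10)   # constant ratio: scalar multiple
  }
})

test_that("simulation is deterministic given the seed", {
  gt <- tinyGroundTruth(nTimepoints = 40)
  a <- simulateSubject(gt, "patient", seed = 5)
  b <- simulateSubject(gt, "patient", seed = 5)
  expect_identical(a$bold@data, b$bold@data)
  expect_identical(a$confounds, b$confounds)
})

test_that("near-noiseless thalamo-cortical correlation within a component approaches 1", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 2, noiseSd = 0.1,
                        thalBaseline = 0, nTimepoints = 200, seed = 6,
                        groupEffect = data.frame(component = integer(0),
                                                 factor = numeric(0)))
  s <- simulateSubject(gt, "control", seed = 2)
  for (k in 1:2) {
    w <- gt@thalWeights[, , , k]
    net <- gt@networkMaps[, , , k]
    tpk <- which(w == max(w), arr.ind = TRUE)[1, ]
    cpk <- which(net == max(net), arr.ind = TRUE)[1, ]
    r <- cor(s$bold@data[tpk[1], tpk[2], tpk[3], ],
             s$bold@data[cpk[1], cpk[2], cpk[3], ])
    expect_gt(r, 0.95)
  }
})

test_that("a patient connectivity factor below 1 lowers thalamo-cortical correlation", {
  gt <- makeGroundTruth(dims = c(14, 16, 14), K = 2, noiseSd = 1,
                        nTimepoints = 100, seed = 4,
                        groupEffect = data.frame(component = 1L,
                                                 factor = 0.5))
  w <- gt@thalWeights[, , , 1]
  net <- gt@networkMaps[, , , 1]
  tpk <- which(w == max(w), arr.ind = TRUE)[1, ]
  cpk <- which(net == max(net), arr.ind = TRUE)[1, ]
  rc <- rp <- numeric(50)
  for (i in 1:50) {
    sc <- simulateSubject(gt, "control", seed = 1000 + i)
    sp <- simulateSubject(gt, "patient", seed = 1000 + i)
    rc[i] <- cor(sc$bold@data[tpk[1], tpk[2], tpk[3], ],
                 sc$bold@data[cpk[1], cpk[2], cpk[3], ])
    rp[i] <- cor(sp$bold@data[tpk[1], tpk[2], tpk[3], ],
                 sp$bold@data[cpk[1], cpk[2], cpk[3], ])
  }
  expect_gt(mean(rc), mean(rp))
})

test_that("cohort simulation writes a complete, reproducible dataset", {
  gt <- tinyGroundTruth(nTimepoints = 30)
  spec <- cohortSpec(3, seed = 77)
  d1 <- withr::local_tempdir()
  res <- simulateCohort(gt, spec, d1)
  expect_equal(nrow(res$design), 6L)
  expect_equal(as.vector(table(res$design$group)), c(3L, 3L))
  expect_length(list.files(file.path(d1, "data"), pattern = "_bold"), 6L)
  expect_length(list.files(file.path(d1, "data"), pattern = "_confounds"), 6L)
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  # rebuild in a second directory: identical data arrays
  d2 <- withr::local_tempdir()
  simulateCohort(gt, spec, d2)
  v1 <- readVolume(file.path(d1, "data", "sub-01_bold.nii.gz"))
  v2 <- readVolume(file.path(d2, "data", "sub-01_bold.nii.gz"))
  expect_identical(v1@data, v2@data)
  # manifest seeds regenerate the same subject
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  s <- simulateSubject(gt, res$design$group[2], man$subjects[["sub-02"]])
  v <- readVolume(file.path(d1, "data", "sub-02_bold.nii.gz"))
  expect_equal(v@data, s$bold@data, tolerance = 1e-6)
})
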