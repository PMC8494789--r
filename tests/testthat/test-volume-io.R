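test_that("write/read round-trips data to storage precision and the affine exactly", {
  set.seed(1)
  aff <- rbind(cbind(diag(c(3, 3, 3)), c(-6, -9, -6)), c(0, 0, 0, 1))
  vol <- makeVol(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_equal(back@data, vol@data, tolerance = 1e-6)  # float32 storage
  expect_equal(affineMatrix(back), unname(affineMatrix(vol)))
  expect_equal(voxelSize(back), c(3, 3, 3))
})

test_that("3D images are promoted to single-frame volumes and masks round-trip", {
  m <- fullMask(c(5, 6, 4))
  m@data[1, , ] <- FALSE
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, f)
  vol <- readVolume(f)
  expect_equal(dim(vol)[4], 1L)
  back <- readMask(f)
  expect_identical(back@data, m@data)
  expect_equal(nVoxels(back), nVoxels(m))
})

test_that("non-finite voxels are refused with the offending count", {
  a <- array(0, c(3, 3, 3))
  a[1:2] <- NaN
  img <- RNifti::asNifti(a)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), "2 non-finite")
  expect_error(readVolume(withr::local_tempfile(fileext = ".nii")),
               "not found")
})

test_that("identity resample reproduces the mask and is idempotent", {
  gt <- tinyGroundTruth()
  m <- gt@thalamus
  r1 <- resampleMask(m, m)
  expect_identical(r1@data, m@data)
  # idempotence on its own output grid
  tgt <- list(dims = c(7, 8, 7), voxelSize = c(6, 6, 6),
              affine = rbind(cbind(diag(c(6, 6, 6)), c(-21, -24, -21)),
                             c(0, 0, 0, 1)))
  r2 <- resampleMask(gt@brain, tgt)
  r3 <- resampleMask(r2, r2)
  expect_identical(r3@data, r2@data)
})

test_that("a 6-voxel 1mm cube resamples to a 2x2x2 block on a 3mm grid", {
  affS <- rbind(cbind(diag(c(1, 1, 1)), 0), c(0, 0, 0, 1))
  src <- new("BrainMask", data = array(TRUE, c(6, 6, 6)),
             voxelSize = c(1, 1, 1), affine = affS)
  affT <- rbind(cbind(diag(c(3, 3, 3)), 1), c(0, 0, 0, 1))
  tgt <- list(dims = c(2, 2, 2), voxelSize = c(3, 3, 3), affine = affT)
  out <- resampleMask(src, tgt)
  # brute-force oracle: map every target voxel centre into the source grid
  oracle <- array(FALSE, c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    w <- affT %*% c(i, j, k, 1)
    s <- round(solve(affS, w)[1:3]) + 1
    oracle[i + 1, j + 1, k + 1] <-
      all(s >= 1 & s <= 6) && src@data[s[1], s[2], s[3]]
  }
  expect_identical(out@data, oracle)
  expect_true(all(out@data))
  expect_equal(nVoxels(out), 8L)
})

test_that("resampling to a non-overlapping grid errors rather than silently emptying", {
  affS <- idAffine(c(1, 1, 1))
  src <- new("BrainMask", data = array(TRUE, c(4, 4, 4)),
             voxelSize = c(1, 1, 1), affine = affS)
  far <- rbind(cbind(diag(c(1, 1, 1)), 100), c(0, 0, 0, 1))
  expect_error(resampleMask(src, list(dims = c(4, 4, 4),
                                      voxelSize = c(1, 1, 1), affine = far)),
               "empty")
})

test_that("label lookup tallies, orders and validates", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:3, 1, 1] <- 1L
  lab[1:2, 2, 1] <- 2L
  lv <- new("LabelVolume", data = lab,
            labelTable = data.frame(value = c(1L, 2L),
                                    name = c("mediodorsal", "pulvinar")),
            voxelSize = c(3, 3, 3), affine = idAffine())
  co <- rbind(cbind(1:3, 1L, 1L), cbind(1:2, 2L, 1L))
  res <- lookupLabels(co, lv)
  expect_equal(res$name, c("mediodorsal", "pulvinar"))
  expect_equal(res$count, c(3L, 2L))
  one <- lookupLabels(cbind(1:3, 1L, 1L), lv)
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 3L)
  expect_equal(lookupLabels(cbind(6L, 6L, 6L), lv)$name, "unlabeled")
  expect_error(lookupLabels(cbind(7L, 1L, 1L), lv), "outside")
  lv@data[4, 4, 4] <- 9L
  expect_error(lookupLabels(cbind(4L, 4L, 4L), lv), "absent")
})

test_that("label volumes round-trip through NIfTI with their TSV table", {
  lab <- array(0L, c(4, 4, 4))
  lab[2, 2, 2] <- 3L
  lv <- new("LabelVolume", data = lab,
            labelTable = data.frame(value = 3L, name = "ventrolateral"),
            voxelSize = c(3, 3, 3), affine = idAffine())
  f <- withr::local_tempfile(fileext = ".nii.gz")
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeVolume(lv, f)
  write.table(lv@labelTable, ft, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  back <- readLabelVolume(f, ft)
  expect_identical(back@data, lv@data)
  expect_equal(back@labelTable$name, "ventrolateral")
})
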