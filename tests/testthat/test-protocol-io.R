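test_that("DWI save/load round trip preserves signals and gradients", {
  dwi <- makeTensorDWI(ndir = 4, nb0 = 3, dims = c(4L, 4L, 4L))
  td <- withr::local_tempdir()
  saveDWI(dwi, file.path(td, "d.nii"), file.path(td, "d.bval"),
          file.path(td, "d.bvec"))
  back <- loadDWI(file.path(td, "d.nii"), file.path(td, "d.bval"),
                  file.path(td, "d.bvec"))
  expect_equal(dim(back@signal), dim(dwi@signal))
  # signals stored as 32-bit float on disk
  expect_lt(max(abs(back@signal - dwi@signal) / max(dwi@signal)), 1e-6)
  expect_equal(bValues(back), bValues(dwi))
  expect_equal(bVectors(back), bVectors(dwi), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gradient count mismatch raises a protocol error naming counts", {
  sig <- array(1, c(2, 2, 2, 7))
  gt <- gradientTable(rep(c(0, 1000), c(3, 3)),
                      cbind(matrix(0, 3, 3), diag(3)))
  expect_error(new("DWIVolume", signal = sig, affine = diag(4),
                   gradients = gt), "7.*6|protocol")
  expect_error(gradientTable(rep(0, 7), matrix(0, 3, 6)), "7.*6")
})

test_that("bvec columns are renormalized to unit length, idempotently", {
  gt <- gradientTable(c(0, 1000), matrix(c(0, 0, 0, 2, 0, 0), 3))
  expect_equal(bVectors(gt)[, 2], c(1, 0, 0))
  expect_equal(bVectors(gt)[, 1], c(0, 0, 0))  # b0 left unconstrained
  gt2 <- gradientTable(bValues(gt), bVectors(gt))
  expect_identical(bVectors(gt2), bVectors(gt))
})

test_that("shell grouping partitions volumes with nominal b rounded to 10", {
  gt <- gradientTable(c(0, 5, 995, 1005, 2000),
                      cbind(0, 0, c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  g <- groupShells(gt)
  expect_equal(g@b0Indices, c(1L, 2L))
  expect_equal(length(g@shells), 2L)
  expect_equal(g@shells[[1]]$b, 1000)
  expect_equal(sort(g@shells[[1]]$indices), c(3L, 4L))
  expect_equal(g@shells[[2]]$b, 2000)
  expect_equal(g@shells[[2]]$indices, 5L)
  # partition property: all indices exactly once
  all_idx <- c(g@b0Indices, unlist(lapply(g@shells, `[[`, "indices")))
  expect_setequal(all_idx, 1:5)
  expect_equal(anyDuplicated(all_idx), 0L)
})

test_that("all-b0 tables give one b0 group; empty tables are an error", {
  gt <- gradientTable(c(0, 0, 0), matrix(0, 3, 3))
  g <- groupShells(gt)
  expect_equal(g@b0Indices, 1:3)
  expect_length(g@shells, 0L)
  expect_error(groupShells(gradientTable(numeric(), matrix(0, 3, 0))),
               "empty")
})

test_that("an outlying b-value seeds a new shell rather than erroring", {
  gt <- gradientTable(c(0, 1000, 1500), cbind(0, c(1, 0, 0), c(0, 1, 0)))
  g <- groupShells(gt)
  expect_length(g@shells, 2L)
})

test_that("the synthetic protocol yields three 90-direction shells", {
  ph <- makePhantom(defaultPhantomSpec(snr = Inf, seed = 2,
                                       gridDim = c(4L, 4L, 4L))$spec)
  g <- groupShells(ph$dwi)
  expect_length(g@b0Indices, 18L)
  expect_equal(vapply(g@shells, `[[`, 0, "b"), c(1000, 2000, 3000))
  expect_equal(vapply(g@shells, function(s) length(s$indices), 0L),
               rep(90L, 3))
})

test_that("scalar map round trip preserves values and rejects non-finite", {
  td <- withr::local_tempdir()
  m <- new("ScalarMap", values = array(0.5, c(3, 3, 3)), affine = diag(4),
           meaning = "FA")
  saveScalarMap(m, file.path(td, "m.nii"))
  back <- loadScalarMap(file.path(td, "m.nii"), "FA")
  expect_equal(mapValues(back), mapValues(m), tolerance = 1e-7)

  bad <- new("ScalarMap", values = array(c(Inf, rep(0, 26)), c(3, 3, 3)),
             affine = diag(4), meaning = "other")
  expect_error(saveScalarMap(bad, file.path(td, "bad.nii")),
               "validation error.*1 non-finite")
  # NaN (masked-out voxels) round-trips fine
  withNaN <- new("ScalarMap", values = array(c(NaN, rep(0.2, 26)),
                                             c(3, 3, 3)),
                 affine = diag(4), meaning = "INVF")
  saveScalarMap(withNaN, file.path(td, "nan.nii"))
  expect_true(is.nan(mapValues(loadScalarMap(file.path(td, "nan.nii")))[1]))
})

test_that("FA map mean survives a disk round trip", {
  ph <- makePhantom(defaultPhantomSpec(snr = Inf, seed = 3,
                                       gridDim = c(6L, 6L, 4L))$spec)
  tf <- fitTensor(ph$dwi)
  maps <- faMD(tensorEigensystem(tf))
  td <- withr::local_tempdir()
  saveScalarMap(maps$FA, file.path(td, "fa.nii"))
  back <- loadScalarMap(file.path(td, "fa.nii"), "FA")
  expect_equal(mean(mapValues(back), na.rm = TRUE),
               mean(mapValues(maps$FA), na.rm = TRUE), tolerance = 1e-6)
})

test_that("gross affine obliquity is rejected on load", {
  dwi <- makeTensorDWI(ndir = 6, dims = c(2L, 2L, 2L))
  th <- 30 * pi / 180  # 30-degree in-plane rotation
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dwi@affine <- rot
  td <- withr::local_tempdir()
  saveDWI(dwi, file.path(td, "o.nii"), file.path(td, "o.bval"),
          file.path(td, "o.bvec"))
  expect_error(loadDWI(file.path(td, "o.nii"), file.path(td, "o.bval"),
                       file.path(td, "o.bvec")), "deviates")
  expect_s4_class(loadDWI(file.path(td, "o.nii"), file.path(td, "o.bval"),
                          file.path(td, "o.bvec"), maxObliquity = Inf),
                  "DWIVolume")
})
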