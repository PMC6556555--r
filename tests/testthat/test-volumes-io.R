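test_that("gradient schemes validate lengths, norms and the b=0 convention", {
  dirs <- fix_dirs30()
  sch <- gradient_scheme(c(0, rep(1200, 30)), rbind(0, dirs))
  expect_length(sch$bvals, 31)
  expect_equal(sum(is_b0(sch)), 1)
  # b=0 rows may be zero vectors; b>0 rows must be unit
  expect_error(gradient_scheme(rep(1200, 3), matrix(c(1, 0, 0, 0, 0, 0,
                                                      0, 1, 0), 3,
                                                    byrow = TRUE)),
               "non-unit")
  expect_error(gradient_scheme(c(0, 1200), matrix(0, 3, 3)), "mismatch")
  expect_error(gradient_scheme(-5, matrix(c(1, 0, 0), 1)), "non-negative")
})

test_that("read_dwi round-trips data, affine and gradient table through NIfTI", {
  st <- fix_tensor_stack(dim3 = c(4, 3, 2))
  st$affine[1:3, 4] <- c(-4.8, -3.6, -2.4)
  td <- withr::local_tempdir()
  img <- file.path(td, "dwi.nii.gz")
  write_dwi(st, img, file.path(td, "dwi.bval"), file.path(td, "dwi.bvec"))
  st2 <- read_dwi(img, file.path(td, "dwi.bval"), file.path(td, "dwi.bvec"))
  expect_equal(st2$data, st$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st2$affine, st$affine, tolerance = 1e-6)
  expect_equal(st2$scheme$bvals, st$scheme$bvals)
  expect_equal(st2$scheme$bvecs, st$scheme$bvecs, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("read_dwi rejects image/gradient-table length mismatch", {
  st <- fix_tensor_stack(dim3 = c(2, 2, 2))
  td <- withr::local_tempdir()
  img <- file.path(td, "dwi.nii.gz")
  write_dwi(st, img, file.path(td, "dwi.bval"), file.path(td, "dwi.bvec"))
  short <- gradient_scheme(st$scheme$bvals[-1],
                           st$scheme$bvecs[-1, , drop = FALSE])
  write_gradient_table(short, file.path(td, "s.bval"), file.path(td, "s.bvec"))
  expect_error(read_dwi(img, file.path(td, "s.bval"), file.path(td, "s.bvec")),
               "30")
})

test_that("gradient tables load in both FSL and transposed layouts", {
  sch <- fix_scheme31()
  td <- withr::local_tempdir()
  write_gradient_table(sch, file.path(td, "a.bval"), file.path(td, "a.bvec"))
  s1 <- read_gradient_table(file.path(td, "a.bval"), file.path(td, "a.bvec"))
  expect_equal(s1$bvecs, sch$bvecs, tolerance = 1e-12, ignore_attr = TRUE)
  # transposed (N x 3) dialect
  write.table(sch$bvecs, file.path(td, "t.bvec"), row.names = FALSE,
              col.names = FALSE)
  s2 <- read_gradient_table(file.path(td, "a.bval"), file.path(td, "t.bvec"),
                            transposed = TRUE)
  expect_equal(s2$bvecs, sch$bvecs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("select_shell keeps the requested shell, preserves order, errors when empty", {
  dirs60 <- hemisphere_dirs(60, seed = 9)
  sch <- gradient_scheme(c(0, rep(1200, 30), rep(3000, 30)),
                         rbind(0, dirs60))
  arr <- array(seq_len(2 * 61), dim = c(2, 1, 1, 61))
  st <- dwi_stack(arr, sch, c(2, 2, 2))
  sub <- select_shell(st, 1200, tol = 100)
  expect_equal(dim(sub$data)[4], 31) # 30 DWI + 1 b0
  expect_equal(sum(!is_b0(sub$scheme)), 30)
  # exhaustive-scan oracle for the selected count
  expect_equal(sum(abs(sch$bvals - 1200) <= 100 & sch$bvals >= 50), 30)
  # order preserved and tol=0 equivalent for exact b-values
  sub0 <- select_shell(st, 1200, tol = 0)
  expect_identical(sub0$data, sub$data)
  expect_error(select_shell(st, 5000, tol = 100), "no volumes")
  no_b0 <- select_shell(st, 3000, include_b0 = FALSE)
  expect_equal(sum(is_b0(no_b0$scheme)), 0)
})

test_that("mean_b0 averages exactly the b=0 volumes", {
  dirs <- fix_dirs30()[1:6, ]
  sch <- gradient_scheme(c(0, 0, rep(1200, 6)), rbind(0, 0, dirs))
  arr <- array(0, dim = c(2, 2, 1, 8))
  arr[, , , 1] <- 100
  arr[, , , 2] <- 102
  for (k in 3:8) arr[, , , k] <- k
  st <- dwi_stack(arr, sch, c(2, 2, 2))
  expect_equal(unname(mean_b0(st)[1, 1, 1]), 101)
  # k-volume brute-force elementwise oracle
  set.seed(4)
  arr2 <- array(runif(2 * 2 * 1 * 8, 50, 150), dim = c(2, 2, 1, 8))
  st2 <- dwi_stack(arr2, sch, c(2, 2, 2))
  oracle <- array((arr2[, , , 1, drop = FALSE] +
                     arr2[, , , 2, drop = FALSE]) / 2, dim = c(2, 2, 1))
  expect_equal(mean_b0(st2), oracle, tolerance = 1e-14)
  # single b0 volume: identity
  sch1 <- gradient_scheme(c(0, rep(1200, 6)), rbind(0, dirs))
  st1 <- dwi_stack(arr[, , , -2, drop = FALSE], sch1, c(2, 2, 2))
  expect_equal(mean_b0(st1), array(arr[, , , 1, drop = FALSE], c(2, 2, 1)),
               tolerance = 1e-14)
  # no b0 -> error
  schn <- gradient_scheme(rep(1200, 6), dirs)
  stn <- dwi_stack(arr[, , , 3:8, drop = FALSE], schn, c(2, 2, 2))
  expect_error(mean_b0(stn), "no b = 0")
})
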