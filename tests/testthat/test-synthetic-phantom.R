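test_that("subject anatomy is deterministic, normalised and tissue-consistent", {
  a1 <- make_subject(7)
  a2 <- make_subject(7)
  expect_identical(a1, a2)
  inside <- a1$mask > 0
  sums <- (a1$f1 + a1$f2 + a1$fiso)[inside]
  expect_lt(max(abs(sums - 1)), 1e-12)
  # CSF diffusivity above WM in the noise-free construction
  expect_gt(mean(a1$d_iso[a1$labels == 1]), mean(a1$d_iso[a1$labels %in% 2:5]))
  # different seeds give different anatomies
  expect_false(isTRUE(all.equal(make_subject(8)$s0, a1$s0)))
  # crossing, single-fibre and isotropic regions all present
  expect_true(all(c(1:9) %in% unique(as.vector(a1$labels))))
})

test_that("rendered protocols agree at shared conditions under a null transform", {
  anat <- make_subject(5)
  p1 <- scanner_protocol("a", n_directions = 30, voxel_size = 2.4,
                         snr = Inf, dir_seed = 11)
  p2 <- scanner_protocol("b", n_directions = 30, voxel_size = 2.4,
                         snr = Inf, dir_seed = 11)
  s1 <- render_acquisition(anat, p1)
  s2 <- render_acquisition(anat, p2)
  expect_equal(s1$data, s2$data, tolerance = 1e-12)
  # different direction seeds change the scheme but not the b0 volumes
  p3 <- scanner_protocol("c", n_directions = 30, voxel_size = 2.4,
                         snr = Inf, dir_seed = 12)
  s3 <- render_acquisition(anat, p3)
  expect_false(isTRUE(all.equal(s1$scheme$bvecs, s3$scheme$bvecs)))
  expect_equal(s1$data[, , , 1], s3$data[, , , 1], tolerance = 1e-12)
})

test_that("suppressing order 2 renders an angularly isotropic signal", {
  anat <- make_subject(5)
  p <- scanner_protocol("iso", snr = Inf, order_atten = c(1, 0, 0),
                        dir_seed = 3)
  acq <- render_acquisition(anat, p)
  rm_ <- rish_maps(acq, attr(acq, "mask"))
  expect_lt(max(rm_$R2[attr(acq, "mask") > 0], na.rm = TRUE), 1e-10)
})

test_that("measured b0 noise level matches the configured SNR", {
  anat <- make_subject(6, dim3 = c(12, 12, 12), voxel_size = 2.4)
  proto <- scanner_protocol("n", snr = 30, n_b0 = 1, dir_seed = 21)
  # repeated independent renders give independent b0 noise draws
  b0s <- vapply(1:30, function(k) {
    acq <- render_acquisition(anat, proto, seed = 1000 + k)
    m <- attr(acq, "mask") > 0
    acq$data[, , , 1][m][1:150]
  }, numeric(150))
  s0_ref <- mean(anat$s0[anat$mask > 0]) * proto$gain
  sigma_expected <- s0_ref / proto$snr
  sigma_measured <- mean(apply(b0s, 1, sd))
  expect_lt(abs(sigma_measured - sigma_expected) / sigma_expected, 0.1)
})

test_that("oracle inverse of the scanner effect recovers the unit-effect signal", {
  anat <- make_subject(9)
  protos <- default_protocols()
  src <- protos$source_st; src$snr <- Inf
  tgt <- protos$target_st; tgt$snr <- Inf
  tgt$dir_seed <- src$dir_seed # shared directions isolate the effect
  clean <- render_acquisition(anat, src)
  affected <- render_acquisition(anat, tgt)
  recovered <- invert_scanner_effect(affected, tgt,
                                     mask = attr(affected, "mask"))
  m <- attr(affected, "mask") > 0
  for (k in c(1, 10)) {
    a <- clean$data[, , , k][m]; b <- recovered$data[, , , k][m]
    expect_lt(stats::median(abs(a - b) / pmax(a, 1)), 0.02)
  }
})

test_that("higher SNR strictly lowers scan-rescan MSE", {
  anat <- make_subject(4)
  mse_at <- function(snr) {
    p <- scanner_protocol("x", snr = snr, dir_seed = 31)
    a <- render_acquisition(anat, p, seed = 1)
    b <- render_acquisition(anat, p, seed = 2)
    m <- attr(a, "mask") > 0
    mean((a$data[, , , 2][m] - b$data[, , , 2][m])^2)
  }
  mses <- vapply(c(10, 30, 90), mse_at, 0)
  expect_true(all(diff(mses) < 0))
})

test_that("benchmark datasets round-trip through their manifest", {
  td <- withr::local_tempdir()
  bench <- make_benchmark(n_train = 2, n_test = 1, seed = 3,
                          dim3 = c(12, 12, 12),
                          protocols = default_protocols()[c("source_st",
                                                            "target_st")],
                          dir = td)
  expect_length(bench$subjects, 3)
  expect_equal(bench$split$train, 1:2)
  expect_true(file.exists(file.path(td, "manifest.json")))
  expect_true(file.exists(file.path(td, "sub-01", "source_st.nii.gz")))
  bench2 <- benchmark_from_manifest(file.path(td, "manifest.json"))
  expect_equal(bench2$subjects[[1]]$stacks$source_st$data,
               bench$subjects[[1]]$stacks$source_st$data,
               tolerance = 1e-12)
  expect_identical(bench2$manifest$subject_seeds,
                   bench$manifest$subject_seeds)
})
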