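fa_closed_form <- function(ev) {
  sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
}

test_that("noise-free isotropic tensor is recovered exactly", {
  D <- diag(c(0.7, 0.7, 0.7)) * 1e-3
  st <- fix_tensor_stack(D)
  tf <- fit_wlls(st)
  expect_lt(max(abs(tf$tensors[, 1:3] - 0.7e-3)), 1e-12)
  expect_lt(max(abs(tf$tensors[, 4:6])), 1e-12)
  expect_equal(unname(fa_map(tf)[2, 2, 2]), 0, tolerance = 1e-10)
  expect_equal(unname(md_map(tf)[2, 2, 2]), 0.7e-3, tolerance = 1e-12)
})

test_that("anisotropic FA matches the eigenvalue closed form; WLLS = OLS noise-free", {
  ev <- c(1.7, 0.2, 0.2) * 1e-3
  st <- fix_tensor_stack(diag(ev))
  tf1 <- fit_wlls(st, n_reweight = 1L)
  tf0 <- fit_wlls(st, n_reweight = 0L) # plain OLS
  expect_equal(tf1$tensors, tf0$tensors, tolerance = 1e-10)
  expect_equal(unname(fa_map(tf1)[1, 1, 1]), fa_closed_form(ev),
               tolerance = 1e-10)
  # stick limit: FA -> 1
  expect_equal(fa_closed_form(c(1, 0, 0)), 1)
})

test_that("random SPD tensors recover FA/MD against the eigen-decomposition oracle", {
  set.seed(42)
  sch <- fix_scheme31()
  n <- 50
  tensors <- replicate(n, fix_random_spd(), simplify = FALSE)
  sig <- t(vapply(tensors, function(D) {
    vapply(seq_along(sch$bvals), function(i) {
      if (is_b0(sch)[i]) 1000
      else 1000 * exp(-sch$bvals[i] *
                        drop(sch$bvecs[i, ] %*% D %*% sch$bvecs[i, ]))
    }, 0)
  }, numeric(31)))
  arr <- array(sig, dim = c(n, 1, 1, 31))
  st <- dwi_stack(arr, sch, c(2, 2, 2))
  tf <- fit_wlls(st)
  fa <- fa_map(tf); md <- md_map(tf)
  for (i in seq_len(n)) {
    ev <- sort(eigen(tensors[[i]], symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(unname(fa[i, 1, 1]), fa_closed_form(ev), tolerance = 1e-8)
    expect_equal(unname(md[i, 1, 1]), mean(ev), tolerance = 1e-8)
  }
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("FA and MD are invariant under joint rotation of tensor and scheme", {
  set.seed(5)
  D <- diag(c(1.5, 0.4, 0.25)) * 1e-3
  st <- fix_tensor_stack(D, dim3 = c(1, 1, 1))
  f0 <- unname(fa_map(fit_wlls(st))[1, 1, 1])
  m0 <- unname(md_map(fit_wlls(st))[1, 1, 1])
  for (k in 1:5) {
    R <- fix_random_rotation()
    Dr <- R %*% D %*% t(R)
    sch_r <- gradient_scheme(st$scheme$bvals,
                             st$scheme$bvecs %*% t(R))
    str <- fix_tensor_stack(Dr, dim3 = c(1, 1, 1), scheme = sch_r)
    tf <- fit_wlls(str)
    expect_equal(unname(fa_map(tf)[1, 1, 1]), f0, tolerance = 1e-10)
    expect_equal(unname(md_map(tf)[1, 1, 1]), m0, tolerance = 1e-10)
  }
})

test_that("MD is scale-equivariant in the b-value", {
  D <- diag(c(1.0, 0.5, 0.3)) * 1e-3
  st1 <- fix_tensor_stack(D, dim3 = c(1, 1, 1))
  k <- 2.5
  sch_k <- gradient_scheme(st1$scheme$bvals * k, st1$scheme$bvecs)
  # same signals arise from tensor D/k at b-values k*b
  st2 <- dwi_stack(st1$data, sch_k, st1$voxel_size, st1$affine)
  md1 <- unname(md_map(fit_wlls(st1))[1, 1, 1])
  md2 <- unname(md_map(fit_wlls(st2))[1, 1, 1])
  expect_equal(md2, md1 / k, tolerance = 1e-10)
})

test_that("degenerate inputs are guarded", {
  st <- fix_tensor_stack(dim3 = c(2, 2, 2))
  expect_error(fit_wlls(st, mask = array(0L, c(2, 2, 2))), "empty")
  few <- dwi_stack(st$data[, , , 1:6, drop = FALSE],
                   gradient_scheme(st$scheme$bvals[1:6],
                                   st$scheme$bvecs[1:6, ]),
                   st$voxel_size)
  expect_error(fit_wlls(few), "at least 7")
  # non-positive signals are clamped, not fatal
  stc <- st
  stc$data[1, 1, 1, 5] <- 0
  tf <- fit_wlls(stc)
  expect_gt(tf$n_clamped, 0)
  expect_true(all(is.finite(tf$tensors)))
})
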