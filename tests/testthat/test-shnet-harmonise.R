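test_that("the network is the fixed BatchNorm/fully-connected stack", {
  net <- dwiharm:::shnet_init(15L, 150L, seed = 1)
  types <- vapply(net$layers, `[[`, "", "type")
  expect_equal(types, rep(c("bn", "fc"), 4))
  dims <- lapply(net$layers[c(2, 4, 6, 8)], function(ly) dim(ly$W))
  expect_equal(dims, list(c(15L, 150L), c(150L, 150L), c(150L, 150L),
                          c(150L, 15L)))
  relus <- vapply(net$layers[c(2, 4, 6, 8)], `[[`, TRUE, "relu")
  expect_equal(relus, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("backpropagation matches numerical gradients", {
  net <- dwiharm:::shnet_init(4L, 6L, seed = 2)
  set.seed(1)
  X <- matrix(rnorm(10 * 4), 10); Tt <- matrix(rnorm(10 * 4), 10)
  fw <- dwiharm:::.shnet_forward(net, X, training = TRUE)
  gr <- dwiharm:::.shnet_backward(net, fw$cache,
                                  2 * (fw$out - Tt) / length(Tt))
  loss_of <- function(n2) {
    mean((dwiharm:::.shnet_forward(n2, X, training = TRUE)$out - Tt)^2)
  }
  eps <- 1e-6
  for (i in c(1, 4, 8)) {
    for (p in dwiharm:::.shnet_params(net$layers[[i]])) {
      n2 <- net
      n2$layers[[i]][[p]][1] <- n2$layers[[i]][[p]][1] + eps
      num <- (loss_of(n2) - loss_of(net)) / eps
      expect_equal(gr[[i]][[p]][1], num, tolerance = 1e-4)
    }
  }
})

test_that("a zeroed readout makes the standardised net a constant predictor", {
  net <- dwiharm:::shnet_init(5L, 8L, seed = 3)
  net$layers[[8]]$W[] <- 0
  net$layers[[8]]$b[] <- 0
  set.seed(2)
  X <- matrix(rnorm(64 * 5), 64)
  out <- dwiharm:::.shnet_forward(net, X, training = TRUE)$out
  expect_equal(out, matrix(0, 64, 5), ignore_attr = TRUE)
  # in standardised target space the constant-zero predictor's loss is the
  # target variance
  Tt <- scale(matrix(rnorm(64 * 5), 64))
  expect_equal(mean((out - Tt)^2),
               mean(apply(Tt, 2, function(v) mean(v^2))),
               tolerance = 1e-12)
})

test_that("training is deterministic and the learning rate never increases after the switch", {
  d <- fix_acquisition()
  pv <- preprocess_voxels(d$acq, d$mask)
  X <- unclass(pv$coefs)
  ids <- rep(1:4, length.out = nrow(X))
  cfg <- shnet_config(epochs = 8, seed = 12)
  m1 <- shnet_train(X, X, ids, cfg)
  m2 <- shnet_train(X, X, ids, cfg)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$history, m2$history)
  lrs <- m1$history$lr[m1$history$phase == "sgd"]
  expect_true(all(diff(lrs) <= 1e-15))
  expect_equal(m1$history$phase[1:5], rep("adam", 5))
  expect_equal(m1$history$phase[6], "sgd")
  expect_error(shnet_train(X, X, rep(1, nrow(X)), cfg), "2 subjects")
})

test_that("preprocessing yields 15-vectors consistent with the shared SH fit", {
  d <- fix_acquisition()
  pv <- preprocess_voxels(d$acq, d$mask)
  expect_equal(ncol(pv$coefs), 15)
  ns <- normalised_signals(d$acq, d$mask)
  cf <- sh_fit(ns$signals, ns$dirs, 4, 0.006)
  expect_equal(unclass(pv$coefs), unclass(cf), tolerance = 1e-12)
  # isotropic voxel: only the order-0 entry is nonzero
  iso <- fix_tensor_stack(diag(c(1, 1, 1)) * 0.7e-3, dim3 = c(1, 1, 1))
  pvi <- preprocess_voxels(iso)
  expect_lt(max(abs(unclass(pvi$coefs)[-1])), 1e-10)
})

test_that("matched prediction is voxel-wise and permutation-consistent", {
  d <- fix_acquisition()
  pv <- preprocess_voxels(d$acq, d$mask)
  X <- unclass(pv$coefs)
  ids <- rep(1:4, length.out = nrow(X))
  m <- shnet_train(X, X, ids, shnet_config(epochs = 6, seed = 5))
  set.seed(31)
  perm <- sample(50)
  Y1 <- shnet_apply(m, X[1:50, ])
  Y2 <- shnet_apply(m, X[1:50, ][perm, ])
  expect_equal(Y2, Y1[perm, ], tolerance = 1e-12)
  expect_equal(shnet_apply(m, X[c(3, 1), ]),
               shnet_apply(m, X[c(1, 3), ])[c(2, 1), ],
               tolerance = 1e-12)
  pred <- shnet_harmonise_matched(d$acq, m, mask = d$mask)
  expect_equal(dim(pred$data), dim(d$acq$data))
  expect_true(all(pred$data >= 0))
})

test_that("the superres path interpolates cubically and keeps constants constant", {
  d <- fix_acquisition()
  pv <- preprocess_voxels(d$acq, d$mask)
  X <- unclass(pv$coefs)
  ids <- rep(1:4, length.out = nrow(X))
  m <- shnet_train(X, X, ids, shnet_config(epochs = 6, seed = 5))
  st <- d$acq
  st$data[] <- 0
  st$data[, , , 1] <- 300
  for (k in 2:31) st$data[, , , k] <- 150
  g2 <- upsample_grid(grid_geometry(st), 2)
  pred <- shnet_harmonise_superres(st, m, g2, st$scheme,
                                   mask = array(1L, spatial_dim(st)))
  expect_equal(dim(pred$data)[1:3], g2$dim)
  inner <- pred$data[5:20, 5:20, 5:20, 2]
  expect_lt(stats::sd(inner) / mean(inner), 0.05)
})
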