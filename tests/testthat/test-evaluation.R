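test_that("error maps follow the analytic ME/MNE/MSE definitions", {
  acq <- array(runif(27, 0.5, 1), dim = c(3, 3, 3))
  em0 <- error_maps(acq, acq)
  expect_true(all(em0$me == 0) && all(em0$mse == 0) && all(em0$mne == 0))
  cst <- 0.2
  em1 <- error_maps(acq + cst, acq)
  expect_equal(em1$me, array(cst, dim = dim(acq)), tolerance = 1e-12)
  expect_equal(em1$mse, array(cst^2, dim = dim(acq)), tolerance = 1e-12)
  expect_equal(em1$mne, cst / acq, tolerance = 1e-12)
  em2 <- error_maps(1.1 * acq, acq)
  expect_equal(em2$mne, array(0.1, dim = dim(acq)), tolerance = 1e-12)
  expect_error(error_maps(acq, array(0, c(2, 2, 2))), "grid mismatch")
  # near-zero denominators are excluded and counted
  acq2 <- acq; acq2[1, 1, 1] <- 0
  em3 <- error_maps(acq2 + cst, acq2)
  expect_true(is.na(em3$mne[1, 1, 1]))
  expect_equal(em3$n_zero_denominator, 1L)
})

test_that("global error is the brute-force mean and order-invariant", {
  pred <- array(c(2, 4, rep(1, 6)), dim = c(2, 2, 2))
  acq <- array(1, dim = c(2, 2, 2))
  mask <- array(0L, c(2, 2, 2)); mask[1:2, 1, 1] <- 1L
  g <- global_error(error_maps(pred, acq, mask))
  expect_equal(g$value[g$error_type == "me"], 2) # mean of {1, 3}
  # brute-force enumeration oracle on a random field
  set.seed(8)
  p2 <- array(rnorm(27), c(3, 3, 3)); a2 <- array(rnorm(27, 1), c(3, 3, 3))
  g2 <- global_error(error_maps(p2, a2))
  expect_equal(g2$value[g2$error_type == "mse"], mean((p2 - a2)^2),
               tolerance = 1e-12)
  expect_error(global_error(error_maps(p2, a2, array(0L, c(3, 3, 3)))))
})

test_that("regional medians across subjects match hand enumeration", {
  lab <- array(0L, c(3, 1, 1)); lab[1:3] <- c(1L, 1L, 2L)
  mk <- function(vals) {
    error_maps(array(vals, c(3, 1, 1)), array(0, c(3, 1, 1)))
  }
  # subject ROI-1 means: 1, 2, 9 -> median 2
  maps <- list(mk(c(1, 1, 5)), mk(c(2, 2, 7)), mk(c(9, 9, 4)))
  labs <- list(lab, lab, lab)
  tab <- regional_error(maps, labs)
  expect_equal(tab$value[tab$label == 1 & tab$error_type == "me"], 2)
  expect_equal(tab$value[tab$label == 2 & tab$error_type == "me"], 5)
  expect_equal(unique(tab$n_subjects), 3L)
  # single subject: median equals that subject's ROI mean
  tab1 <- regional_error(maps[1], labs[1])
  expect_equal(tab1$value[tab1$label == 1 & tab1$error_type == "me"], 1)
  # label missing in one subject is dropped from its median
  lab2 <- lab; lab2[3] <- 0L
  tab2 <- regional_error(maps, list(lab, lab2, lab))
  expect_equal(tab2$n_subjects[tab2$label == 2][1], 2L)
  # brute-force group-by oracle on a printed 3-ROI toy map
  lab3 <- array(c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L), c(2, 2, 2))
  err3 <- array(c(4, 8, 1, 6, 2, 5, 2, 6), c(2, 2, 2))
  t3 <- regional_error(list(error_maps(err3, array(0, c(2, 2, 2)))),
                       list(lab3))
  agg <- tapply(as.vector(err3), as.vector(lab3), mean)
  expect_equal(t3$value[t3$error_type == "me"], as.numeric(agg),
               tolerance = 1e-12)
})

test_that("local sliding-window means match the 27-voxel oracle", {
  set.seed(10)
  pred <- array(rnorm(125), c(5, 5, 5)); acq <- array(0, c(5, 5, 5))
  maps <- error_maps(pred, acq)
  le <- local_error(maps, window = 3)
  me_vals <- le$value[le$error_type == "me"]
  expect_length(me_vals, 27) # (5-2)^3 windows
  oracle <- numeric(0)
  for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    oracle <- c(oracle, mean(pred[i:(i + 2), j:(j + 2), k:(k + 2)]))
  }
  expect_equal(sort(me_vals), sort(oracle), tolerance = 1e-12)
  # window = 1 reduces to the voxel map
  le1 <- local_error(maps, window = 1)
  expect_equal(sort(le1$value[le1$error_type == "me"]),
               sort(as.vector(pred)), tolerance = 1e-12)
  # constant error field gives constant local means
  mapsC <- error_maps(acq + 0.3, acq)
  leC <- local_error(mapsC, window = 3)
  expect_equal(unique(round(leC$value[leC$error_type == "me"], 12)), 0.3)
  expect_error(local_error(maps, window = 2), "odd")
  tiny <- error_maps(array(1, c(2, 2, 2)), array(0, c(2, 2, 2)))
  expect_error(local_error(tiny, window = 3), "smaller")
})

test_that("local summaries use linear-interpolation quantiles", {
  s <- summarise_local(1:100)
  expect_equal(unname(s["median"]), 50.5)
  expect_equal(unname(s["p95"]), 95.05)
  s1 <- summarise_local(7)
  expect_equal(unname(s1["median"]), 7)
  expect_equal(unname(s1["p95"]), 7)
  set.seed(2)
  v <- rnorm(333)
  s2 <- summarise_local(v)
  sv <- sort(v)
  expect_equal(unname(s2["median"]), median(sv), tolerance = 1e-12)
  expect_equal(unname(s2["p95"]), unname(quantile(sv, 0.95)),
               tolerance = 1e-12)
})

test_that("poor-region flagging follows the 90th-percentile / >=3-algorithm rule", {
  mk_tbl <- function(values_by_alg) {
    dplyr::bind_rows(lapply(names(values_by_alg), function(a) {
      tibble::tibble(algorithm = a, feature = "fa",
                     label = seq_along(values_by_alg[[a]]),
                     value = values_by_alg[[a]])
    }))
  }
  tissue <- tibble::tibble(label = 1:10,
                           class = rep(c("WM", "GM"), each = 5))
  # ROI 5 (WM) worst for every algorithm -> flagged
  base <- c(1, 1, 1, 1, 10, 2, 2, 2, 2, 2)
  tbl <- mk_tbl(list(a1 = base, a2 = base + 0.1, a3 = base + 0.2))
  expect_equal(flag_poor_regions(tbl, tissue), 5L)
  # identical ROIs: degenerate tie, nothing flagged
  flat <- rep(1, 10)
  tbl2 <- mk_tbl(list(a1 = flat, a2 = flat, a3 = flat))
  expect_length(flag_poor_regions(tbl2, tissue), 0)
  # worst for only 2 of 3 algorithms -> not flagged
  tbl3 <- mk_tbl(list(a1 = base, a2 = base,
                      a3 = c(10, 1, 1, 1, 1, 2, 2, 2, 2, 2)))
  expect_length(flag_poor_regions(tbl3, tissue), 0)
  # brute-force rule evaluation on a random 10-ROI table
  set.seed(6)
  rnd <- lapply(1:4, function(i) runif(10))
  names(rnd) <- paste0("a", 1:4)
  tbl4 <- mk_tbl(rnd)
  got <- flag_poor_regions(tbl4, tissue)
  counts <- integer(10)
  for (a in names(rnd)) {
    for (cls in c("WM", "GM")) {
      rois <- tissue$label[tissue$class == cls]
      thr <- quantile(rnd[[a]][rois], 0.9, type = 7)
      counts[rois] <- counts[rois] + (rnd[[a]][rois] > thr)
    }
  }
  expect_equal(got, sort(which(counts >= 3)))
  expect_error(flag_poor_regions(tbl4[tbl4$algorithm %in% c("a1", "a2"), ],
                                 tissue), ">= 3")
  expect_error(flag_poor_regions(tbl4, tissue[1:5, ]), "tissue-class")
})

test_that("MSE >= ME^2 over any mask (Jensen) and erosion shrinks masks", {
  set.seed(3)
  for (k in 1:5) {
    pred <- array(rnorm(64), c(4, 4, 4)); acq <- array(rnorm(64), c(4, 4, 4))
    g <- global_error(error_maps(pred, acq))
    expect_gte(g$value[g$error_type == "mse"],
               g$value[g$error_type == "me"]^2 - 1e-12)
  }
  mask <- array(1L, c(4, 4, 4))
  er <- erode_mask(mask, 1)
  expect_equal(sum(er), 8) # only the 2^3 interior survives
  expect_true(all(er <= mask))
})

test_that("end-to-end evaluation report accounts for every excluded voxel", {
  fx <- fix_acquisition()
  pred <- fx$acq
  pred$data <- pred$data * 1.05
  rep_ <- evaluate_harmonisation(pred, fx$acq, fx$mask,
                                 labels = fx$labels,
                                 algorithm = "toy")
  expect_s3_class(rep_$global, "tbl_df")
  expect_equal(sort(unique(rep_$global$feature)), c("fa", "md", "r0", "r2"))
  ex <- rep_$exclusions
  expect_true(all(ex$n_evaluated + ex$n_edge_excluded + ex$n_nonfinite +
                    ex$n_class_excluded + ex$n_flagged_excluded ==
                    ex$n_mask_full))
  # tidy/glance interfaces
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_true("mse_md" %in% names(glance(rep_)))
  # regional table covers every in-mask label once per feature/error type
  reg <- rep_$regional
  labs_present <- sort(unique(fx$labels[fx$labels > 0]))
  expect_setequal(unique(reg$label), labs_present)
})
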