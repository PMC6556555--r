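#' Scanner/protocol description for the phantom simulator
#'
#' Captures both the acquisition (b-value, direction count, voxel size,
#' SNR) and a parametric scanner effect: a global gain plus per-SH-order
#' attenuation factors (a0, a2, a4) applied to the normalised signal in SH
#' space — the minimal family that shifts FA, MD, R0 and R2 between
#' scanners — and an optional isotropic Gaussian blur.
#'
#' @param name Protocol identifier.
#' @param bval Shell b-value (s/mm^2), default 1200.
#' @param n_directions Gradient directions on the shell (>= the SH
#'   coefficient count of the rendering order for matched protocols).
#' @param voxel_size Isotropic voxel edge (mm).
#' @param snr Signal-to-noise ratio at b = 0 (> 0; `Inf` = noise-free).
#' @param gain Global multiplicative gain.
#' @param order_atten Named or positional length-3 factors (a0, a2, a4).
#' @param blur_fwhm Spatial blur FWHM in mm (0 = none).
#' @param n_b0 Number of b = 0 volumes.
#' @param dir_seed Seed for this protocol's direction set, so different
#'   protocols have genuinely different schemes.
#' @return List of class `scanner_protocol`.
#' @export
scanner_protocol <- function(name, bval = 1200, n_directions = 30,
                             voxel_size = 2.4, snr = 30, gain = 1,
                             order_atten = c(1, 1, 1), blur_fwhm = 0,
                             n_b0 = 1, dir_seed = 1L) {
  stopifnot(snr > 0, n_directions >= sh_ncoef(4))
  structure(list(name = name, bval = bval,
                 n_directions = as.integer(n_directions),
                 voxel_size = voxel_size, snr = snr, gain = gain,
                 order_atten = unname(as.numeric(order_atten)),
                 blur_fwhm = blur_fwhm, n_b0 = as.integer(n_b0),
                 dir_seed = as.integer(dir_seed)),
            class = "scanner_protocol")
}

#' The study's default protocol set
#'
#' A source "standard" protocol (unit scanner effect; the frame every
#' other protocol is mapped from), a matched-resolution target with a
#' non-trivial order-wise scanner effect, and a high-resolution
#' high-angular target with the same effect. All at b = 1200 s/mm^2,
#' SNR 30.
#'
#' @return Named list of [scanner_protocol()]s: `source_st`, `target_st`,
#'   `target_sa`.
#' @export
default_protocols <- function() {
  eff <- list(gain = 1.05, atten = c(0.95, 0.80, 0.70))
  list(
    source_st = scanner_protocol("source_st", n_directions = 30,
                                 voxel_size = 2.4, dir_seed = 101L),
    target_st = scanner_protocol("target_st", n_directions = 30,
                                 voxel_size = 2.4, gain = eff$gain,
                                 order_atten = eff$atten, dir_seed = 202L),
    target_sa = scanner_protocol("target_sa", n_directions = 60,
                                 voxel_size = 1.2, gain = eff$gain,
                                 order_atten = eff$atten, dir_seed = 303L))
}

# anisotropic tensor with principal direction u and eigenvalues ev (mm^2/s)
.fiber_tensor <- function(u, ev) {
  u <- u / sqrt(sum(u^2))
  # complete an orthonormal frame
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  ev[1] * tcrossprod(u) + ev[2] * tcrossprod(v) + ev[3] * tcrossprod(w)
}

#' Generate a synthetic subject anatomy
#'
#' A spherical "brain" on a high-resolution grid with a CSF core
#' (isotropic, fast diffusion), a white-matter shell containing
#' single-fibre sectors (fibres along x or y) and crossing-fibre sectors
#' where both populations mix, and a gray-matter rim (nearly isotropic,
#' slow). Each voxel carries mixture fractions (two fibre compartments +
#' isotropic) summing to one, compartment tensors, an ROI label map and a
#' WM/GM/CSF tissue table. The seed jitters radii, eigenvalues and
#' fractions so subjects differ.
#'
#' @param seed Integer subject seed.
#' @param dim3 Grid shape (default 24^3 at 1.2 mm: a 28.8 mm field of
#'   view, a desk-scale stand-in, not a realistic head).
#' @param voxel_size High-resolution voxel edge (mm).
#' @return Object of class `subject_anatomy`: arrays `f1`, `f2`, `fiso`
#'   (fractions), `dir1`, `dir2` (x,y,z,3 fibre directions), `ev_fiber`,
#'   `d_iso` per voxel, `s0`, `mask`, `labels`, `tissue` table, `seed`.
#' @export
make_subject <- function(seed, dim3 = c(24, 24, 24), voxel_size = 1.2) {
  rng <- .seeded_rng(seed)
  jit <- function(scale) (rng$unif(1) - 0.5) * 2 * scale
  d <- as.integer(dim3)
  ctr <- (d + 1) / 2 + c(jit(0.5), jit(0.5), jit(0.5))
  r_brain <- min(d) / 2 - 1.5 + jit(0.4)
  r_csf <- 3 + jit(0.4)
  r_wm <- r_brain - 3 + jit(0.3)
  lam_par <- 1.7e-3 * (1 + jit(0.05))
  lam_perp <- 0.3e-3 * (1 + jit(0.05))
  d_csf <- 3.0e-3 * (1 + jit(0.03))
  d_gm <- 0.8e-3 * (1 + jit(0.03))
  f_wm <- 0.85 + jit(0.03)
  idx <- .grid_indices(d) + 1
  x <- idx[, 1] - ctr[1]; y <- idx[, 2] - ctr[2]; z <- idx[, 3] - ctr[3]
  r <- sqrt(x^2 + y^2 + z^2)
  nvox <- nrow(idx)
  f1 <- f2 <- numeric(nvox); fiso <- numeric(nvox)
  d_iso <- rep(d_gm, nvox)
  labels <- integer(nvox)
  mask <- r <= r_brain
  csf <- mask & r <= r_csf
  wm <- mask & r > r_csf & r <= r_wm
  gm <- mask & r > r_wm
  # WM sectors: fibre along x where |x| dominates, along y where |y|
  # dominates, crossing in the wedge where they are comparable
  ratio <- abs(x) / pmax(abs(y), 1e-9)
  crossing <- wm & ratio > 0.6 & ratio < 1.6667
  along_x <- wm & !crossing & abs(x) >= abs(y)
  along_y <- wm & !crossing & abs(x) < abs(y)
  f1[along_x] <- f_wm; fiso[along_x] <- 1 - f_wm
  f1[along_y] <- f_wm; fiso[along_y] <- 1 - f_wm
  f1[crossing] <- f_wm / 2; f2[crossing] <- f_wm / 2
  fiso[crossing] <- 1 - f_wm
  f1[gm] <- 0.1; fiso[gm] <- 0.9
  fiso[csf] <- 1
  d_iso[csf] <- d_csf
  d_iso[wm] <- 1.0e-3
  # labels: 1 CSF; WM 2..5 (x+, x-, y-fibre, crossing); GM 6..9 (quadrants)
  labels[csf] <- 1L
  labels[along_x & x >= 0] <- 2L
  labels[along_x & x < 0] <- 3L
  labels[along_y] <- 4L
  labels[crossing] <- 5L
  labels[gm & x >= 0 & y >= 0] <- 6L
  labels[gm & x < 0 & y >= 0] <- 7L
  labels[gm & x < 0 & y < 0] <- 8L
  labels[gm & x >= 0 & y < 0] <- 9L
  dir1 <- matrix(0, nvox, 3); dir2 <- matrix(0, nvox, 3)
  dir1[along_x | crossing, 1] <- 1
  dir1[along_y, 2] <- 1
  dir1[gm, 1] <- 1
  dir2[crossing, 2] <- 1
  s0 <- 800 * (f1 + f2) + 900 * fiso
  s0[csf] <- 1400
  s0[!mask] <- 0
  shp <- function(v) array(v, dim = d)
  tissue <- tibble::tibble(label = 1:9,
                           class = c("CSF", rep("WM", 4), rep("GM", 4)))
  structure(list(f1 = shp(f1), f2 = shp(f2), fiso = shp(fiso),
                 dir1 = array(dir1, dim = c(d, 3)),
                 dir2 = array(dir2, dim = c(d, 3)),
                 ev_fiber = c(lam_par, lam_perp, lam_perp),
                 d_iso = shp(d_iso), s0 = shp(s0),
                 mask = shp(as.integer(mask)),
                 labels = shp(labels), tissue = tissue,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "subject_anatomy")
}

# noise-free normalised multi-tensor signal of all in-mask voxels at dirs
.anatomy_signal <- function(anat, dirs, bval) {
  dirs <- .as_dir_matrix(dirs)
  vox <- which(anat$mask > 0, arr.ind = TRUE)
  n <- nrow(vox); nd <- nrow(dirs)
  Dfib <- .fiber_tensor(c(1, 0, 0), anat$ev_fiber) # placeholder, per-dir below
  sig <- matrix(0, n, nd)
  lin <- vox[, 1] + (vox[, 2] - 1) * dim(anat$mask)[1] +
    (vox[, 3] - 1) * dim(anat$mask)[1] * dim(anat$mask)[2]
  f1 <- anat$f1[lin]; f2 <- anat$f2[lin]; fiso <- anat$fiso[lin]
  diso <- anat$d_iso[lin]
  d1 <- matrix(anat$dir1, ncol = 3)[lin, , drop = FALSE]
  d2 <- matrix(anat$dir2, ncol = 3)[lin, , drop = FALSE]
  ev <- anat$ev_fiber
  # exp(-b g' D g) for axially symmetric D: depends on (g . u)^2
  gd1 <- tcrossprod(d1, dirs)^2 # n x nd
  gd2 <- tcrossprod(d2, dirs)^2
  att1 <- exp(-bval * (ev[2] + (ev[1] - ev[2]) * gd1))
  att2 <- exp(-bval * (ev[2] + (ev[1] - ev[2]) * gd2))
  sig <- f1 * att1 + f2 * att2 + fiso * exp(-bval * diso)
  list(signal = sig, voxels = vox, lin = lin)
}

# apply order-wise attenuation to SH coefficients (orders 0,2,4)
.apply_order_atten <- function(coefs, atten) {
  L <- attr(coefs, "order")
  tab <- sh_index_table(L)
  fac <- atten[tab$l / 2 + 1]
  out <- sweep(unclass(coefs), 2, fac, "*")
  attr(out, "order") <- L
  class(out) <- c("sh_coefs", class(out))
  out
}

# block-average a 3D array by integer factor per axis
.block_average <- function(vol, factor) {
  d <- dim(vol)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  out <- array(0, dim = dn)
  for (ox in 0:(factor - 1)) for (oy in 0:(factor - 1))
    for (oz in 0:(factor - 1)) {
      out <- out + vol[seq(1 + ox, d[1], by = factor),
                       seq(1 + oy, d[2], by = factor),
                       seq(1 + oz, d[3], by = factor)]
    }
  out / factor^3
}

# separable Gaussian blur, sigma in voxels
.gauss_blur <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(vol)
  for (ax in 1:3) {
    out <- array(0, dim = d)
    for (o in (-rad):rad) {
      src <- pmin(pmax(seq_len(d[ax]) + o, 1), d[ax])
      sl <- switch(ax, vol[src, , , drop = FALSE],
                   vol[, src, , drop = FALSE], vol[, , src, drop = FALSE])
      out <- out + k[o + rad + 1] * sl
    }
    vol <- out
  }
  vol
}

#' Render an acquisition of a subject under a scanner protocol
#'
#' Per voxel, the noise-free multi-tensor signal S = S0 sum_i f_i
#' exp(-b g' D_i g) is computed; the scanner effect is applied in SH
#' space (order-wise multiplication by a0/a2/a4 of the normalised signal,
#' then global gain, then optional blur); the result is sampled at the
#' protocol's direction set, block-averaged to the protocol grid, and
#' Rician noise is added at the configured SNR: each measurement becomes
#' |(S + n1, n2)| with independent zero-mean Gaussians of sigma =
#' S0_ref / SNR (S0_ref = mean in-mask noise-free b = 0 signal).
#'
#' @param anat A [make_subject()] anatomy.
#' @param proto A [scanner_protocol()]; its voxel size must be an integer
#'   multiple of the anatomy's (or equal).
#' @param seed Noise seed.
#' @param render_order SH order used to apply the effect (default 4).
#' @return A [dwi_stack()]; attributes `mask` and `labels` carry the
#'   protocol-grid mask and label map.
#' @export
render_acquisition <- function(anat, proto, seed = 1L, render_order = 4) {
  dirs <- hemisphere_dirs(proto$n_directions, seed = proto$dir_seed)
  sig <- .anatomy_signal(anat, dirs, proto$bval)
  # scanner effect in SH space on the normalised signal
  coefs <- sh_fit(sig$signal, dirs, L = render_order, lambda = 0)
  coefs <- .apply_order_atten(coefs, proto$order_atten)
  s_eff <- sh_resample(coefs, dirs)
  d_hi <- dim(anat$mask)
  s0_eff <- anat$s0 * proto$gain
  # assemble high-res 4D stack: n_b0 b=0 volumes then DWIs
  nvol <- proto$n_b0 + proto$n_directions
  hi <- array(0, dim = c(d_hi, nvol))
  for (j in seq_len(proto$n_b0)) hi[, , , j] <- s0_eff
  for (k in seq_len(proto$n_directions)) {
    vol <- array(0, dim = d_hi)
    vol[sig$voxels] <- s_eff[, k] * s0_eff[sig$voxels]
    hi[, , , proto$n_b0 + k] <- vol
  }
  if (proto$blur_fwhm > 0) {
    sigma <- proto$blur_fwhm / (2 * sqrt(2 * log(2))) / anat$voxel_size
    for (j in seq_len(nvol)) hi[, , , j] <- .gauss_blur(hi[, , , j], sigma)
  }
  # spatial resampling to the protocol grid by block averaging
  factor <- as.integer(round(proto$voxel_size / anat$voxel_size))
  if (abs(proto$voxel_size - factor * anat$voxel_size) > 1e-9) {
    stop("protocol voxel size must be an integer multiple of the ",
         "anatomy voxel size")
  }
  if (factor > 1) {
    d_lo <- d_hi %/% factor
    lo <- array(0, dim = c(d_lo, nvol))
    for (j in seq_len(nvol)) lo[, , , j] <- .block_average(hi[, , , j],
                                                           factor)
    mask_lo <- (.block_average(anat$mask + 0, factor) >= 0.5) * 1L
    labels_lo <- .downsample_labels(anat$labels, factor)
  } else {
    lo <- hi
    mask_lo <- anat$mask
    labels_lo <- anat$labels
  }
  # Rician noise
  s0_ref <- mean(anat$s0[anat$mask > 0]) * proto$gain
  if (is.finite(proto$snr)) {
    rng <- .seeded_rng(seed + 1000L * proto$dir_seed)
    nval <- length(lo)
    n1 <- rng$norm(nval) * s0_ref / proto$snr
    n2 <- rng$norm(nval) * s0_ref / proto$snr
    lo <- sqrt((lo + array(n1, dim = dim(lo)))^2 +
                 array(n2, dim = dim(lo))^2)
  }
  scheme <- gradient_scheme(
    c(rep(0, proto$n_b0), rep(proto$bval, proto$n_directions)),
    rbind(matrix(0, proto$n_b0, 3), dirs))
  aff <- diag(c(rep(proto$voxel_size, 3), 1))
  stack <- dwi_stack(lo, scheme, voxel_size = rep(proto$voxel_size, 3),
                     affine = aff)
  attr(stack, "mask") <- mask_lo
  attr(stack, "labels") <- labels_lo
  stack
}

# majority label within each block
.downsample_labels <- function(labels, factor) {
  d <- dim(labels)
  dn <- d %/% factor
  out <- array(0L, dim = dn)
  for (i in seq_len(dn[1])) for (j in seq_len(dn[2]))
    for (k in seq_len(dn[3])) {
      block <- labels[((i - 1) * factor + 1):(i * factor),
                      ((j - 1) * factor + 1):(j * factor),
                      ((k - 1) * factor + 1):(k * factor)]
      tab <- tabulate(block + 1L)
      out[i, j, k] <- which.max(tab) - 1L
    }
  out
}

#' Invert a protocol's scanner effect on a stack (oracle harmonisation)
#'
#' Divides out the global gain and the per-order SH attenuation recorded
#' in the protocol — the ground-truth inverse transform available only in
#' simulation. On noise-free data this recovers the unit-effect
#' acquisition up to SH truncation error, so its residual error
#' lower-bounds any learned harmoniser.
#'
#' @param stack A rendered [dwi_stack()].
#' @param proto The [scanner_protocol()] it was rendered with.
#' @param mask Optional 3D mask.
#' @param order SH order (default 4).
#' @param lambda Laplace-Beltrami weight of the SH step (default 0.006).
#' @return A [dwi_stack()] with the effect removed.
#' @export
invert_scanner_effect <- function(stack, proto, mask = NULL, order = 4,
                                  lambda = 0.006) {
  ns <- normalised_signals(stack, mask)
  coefs <- sh_fit(ns$signals, ns$dirs, L = order, lambda = lambda)
  coefs <- .apply_order_atten(coefs, 1 / proto$order_atten)
  .stack_from_coefs(coefs, ns$voxels, ns$b0 / proto$gain, stack,
                    stack$scheme, grid_geometry(stack))
}

#' Generate a travelling-subject benchmark dataset
#'
#' Renders every subject under every protocol, with a recorded train/test
#' split (10 training, 4 test subjects by default) and a manifest holding
#' every seed and scanner-effect parameter — the ground-truth transform.
#' With `dir` set, writes a dataset tree (NIfTI + bval/bvec + mask/labels
#' + `manifest.json`); regenerating from the manifest is bit-identical.
#'
#' @param n_train,n_test Subject counts (default 10 / 4).
#' @param protocols Named list of [scanner_protocol()]s; first is the
#'   source by convention.
#' @param seed Master seed; subject seeds are `seed * 100 + subject`.
#' @param dim3,voxel_size Anatomy grid settings.
#' @param dir Optional output directory.
#' @return List of class `dwi_benchmark`: `subjects` (per subject: list of
#'   rendered stacks by protocol, `anatomy`), `split` (train/test
#'   indices), `protocols`, `manifest`.
#' @export
make_benchmark <- function(n_train = 10, n_test = 4,
                           protocols = default_protocols(), seed = 1L,
                           dim3 = c(24, 24, 24), voxel_size = 1.2,
                           dir = NULL) {
  seed <- as.integer(seed)
  n_sub <- n_train + n_test
  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub_seed <- seed * 100L + s
    anat <- make_subject(sub_seed, dim3 = dim3, voxel_size = voxel_size)
    stacks <- lapply(protocols, function(pr)
      render_acquisition(anat, pr, seed = sub_seed))
    subjects[[s]] <- list(anatomy = anat, stacks = stacks)
  }
  manifest <- list(
    seed = seed, n_train = n_train, n_test = n_test,
    dim3 = dim3, voxel_size = voxel_size,
    subject_seeds = seed * 100L + seq_len(n_sub),
    protocols = lapply(protocols, unclass))
  bench <- structure(list(subjects = subjects,
                          split = list(train = seq_len(n_train),
                                       test = n_train + seq_len(n_test)),
                          protocols = protocols, manifest = manifest),
                     class = "dwi_benchmark")
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

#' Write a benchmark dataset tree to disk
#'
#' @param bench A [make_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(bench$subjects)) {
    sub <- bench$subjects[[s]]
    sdir <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    for (pn in names(sub$stacks)) {
      st <- sub$stacks[[pn]]
      write_dwi(st, file.path(sdir, paste0(pn, ".nii.gz")),
                file.path(sdir, paste0(pn, ".bval")),
                file.path(sdir, paste0(pn, ".bvec")))
      write_volume(attr(st, "mask"), file.path(sdir, paste0(pn, "_mask.nii.gz")),
                   st$affine)
      write_volume(attr(st, "labels"),
                   file.path(sdir, paste0(pn, "_labels.nii.gz")), st$affine)
    }
    utils::write.csv(sub$anatomy$tissue,
                     file.path(sdir, "tissue_classes.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Regenerate a benchmark from its manifest
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A [make_benchmark()] result, bit-identical to the original.
#' @export
benchmark_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  protocols <- lapply(m$protocols, function(p)
    scanner_protocol(p$name, bval = p$bval, n_directions = p$n_directions,
                     voxel_size = p$voxel_size, snr = p$snr, gain = p$gain,
                     order_atten = p$order_atten, blur_fwhm = p$blur_fwhm,
                     n_b0 = p$n_b0, dir_seed = p$dir_seed))
  make_benchmark(n_train = m$n_train, n_test = m$n_test,
                 protocols = protocols, seed = m$seed,
                 dim3 = m$dim3, voxel_size = m$voxel_size)
}
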