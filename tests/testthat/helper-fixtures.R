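# Shared in-code fixtures: small schemes, stacks and a cached mini-phantom.

fix_dirs30 <- function() hemisphere_dirs(30, seed = 3)

fix_scheme31 <- function() {
  gradient_scheme(c(0, rep(1200, 30)), rbind(0, fix_dirs30()))
}

# constant-tensor stack on a small grid; defaults to a prolate WM-like tensor
fix_tensor_stack <- function(D = diag(c(1.7, 0.2, 0.2)) * 1e-3,
                             dim3 = c(3, 3, 3), s0 = 1000,
                             scheme = fix_scheme31()) {
  dirs <- scheme$bvecs
  sig <- vapply(seq_along(scheme$bvals), function(i) {
    if (is_b0(scheme)[i]) s0
    else s0 * exp(-scheme$bvals[i] * drop(dirs[i, ] %*% D %*% dirs[i, ]))
  }, 0)
  arr <- array(rep(sig, each = prod(dim3)), dim = c(dim3, length(sig)))
  dwi_stack(arr, scheme, voxel_size = c(2.4, 2.4, 2.4))
}

# memoised small rendered acquisition (shared across tests in a file)
local({
  cache <- new.env(parent = emptyenv())
  fix_acquisition <<- function(subject_seed = 101, proto_name = "source_st",
                               noise_seed = 5) {
    key <- paste(subject_seed, proto_name, noise_seed, sep = "_")
    if (is.null(cache[[key]])) {
      anat <- make_subject(subject_seed)
      acq <- render_acquisition(anat, default_protocols()[[proto_name]],
                                seed = noise_seed)
      cache[[key]] <- list(anat = anat, acq = acq,
                           mask = attr(acq, "mask"),
                           labels = attr(acq, "labels"))
    }
    cache[[key]]
  }
})

# random SPD diffusion tensor (mm^2/s scale)
fix_random_spd <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  S / max(eigen(S, only.values = TRUE)$values) * 2e-3
}

# random 3D rotation matrix
fix_random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
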