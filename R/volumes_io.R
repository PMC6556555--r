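#' Gradient scheme for a diffusion acquisition
#'
#' Stores per-volume b-values (s/mm^2) and unit gradient directions.
#' Directions for b > 0 volumes must be unit vectors (norm within 1e-3 of
#' 1); b = 0 volumes conventionally carry zero vectors. Volumes with
#' b-value below `b0_thresh` are treated as b = 0 throughout the package
#' (the threshold exists because "b = 0" acquisitions often carry a small
#' nominal b-value).
#'
#' @param bvals Numeric vector of non-negative b-values.
#' @param bvecs n x 3 matrix of direction cosines.
#' @param b0_thresh b-values strictly below this (s/mm^2) count as b = 0.
#' @return An object of class `gradient_scheme`: list with `bvals`,
#'   `bvecs`, `b0_thresh`.
#' @export
gradient_scheme <- function(bvals, bvecs, b0_thresh = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- .as_dir_matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop("gradient table mismatch: ", length(bvals), " b-values but ",
         nrow(bvecs), " directions")
  }
  if (any(bvals < 0)) stop("b-values must be non-negative")
  dwi <- bvals >= b0_thresh
  norms <- sqrt(rowSums(bvecs^2))
  bad <- dwi & abs(norms - 1) > 1e-3
  if (any(bad)) {
    stop("non-unit gradient direction(s) for b > 0 at volume(s) ",
         paste(which(bad), collapse = ", "))
  }
  structure(list(bvals = bvals, bvecs = bvecs, b0_thresh = b0_thresh),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(round(x$bvals[!is_b0(x)], -1)))
  cat("<gradient_scheme> ", length(x$bvals), " volumes; ",
      sum(is_b0(x)), " b=0; shells: ",
      paste(shells, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Which volumes of a scheme are b = 0?
#' @param scheme A [gradient_scheme()].
#' @return Logical vector over volumes.
#' @export
is_b0 <- function(scheme) scheme$bvals < scheme$b0_thresh

#' Read FSL-style bval/bvec text files
#'
#' The FSL dialect stores b-values as one whitespace-separated row and
#' directions as 3 rows of N columns. `transposed = TRUE` accepts the
#' N-row, 3-column layout instead.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @param transposed Accept N x 3 bvec layout.
#' @param b0_thresh Passed to [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, transposed = FALSE,
                                b0_thresh = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  raw <- as.matrix(utils::read.table(bvec_path))
  bvecs <- if (transposed) raw else t(raw)
  if (ncol(bvecs) != 3) {
    stop("bvec file does not have 3 ", if (transposed) "columns" else "rows")
  }
  gradient_scheme(bvals, bvecs, b0_thresh = b0_thresh)
}

#' Write a gradient scheme as FSL bval/bvec files
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  m <- t(scheme$bvecs)
  writeLines(apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(scheme)
}

#' A 4D diffusion-weighted image stack
#'
#' The universal image container: a non-negative 4D array (x, y, z, volume)
#' with voxel geometry and its gradient scheme. The 4th dimension must
#' match the scheme length. Voxel indices are 0-based in world-coordinate
#' computations; world coordinates come from the stored affine.
#'
#' @param data 4D numeric array.
#' @param scheme A [gradient_scheme()] with one entry per volume.
#' @param voxel_size Length-3 positive voxel edge lengths (mm).
#' @param affine 4 x 4 voxel-to-world matrix; default scales by
#'   `voxel_size`.
#' @return Object of class `dwi_stack`.
#' @export
dwi_stack <- function(data, scheme, voxel_size,
                      affine = diag(c(voxel_size, 1))) {
  data <- as.array(data)
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4) stop("data must be a 4D array")
  if (dim(data)[4] != length(scheme$bvals)) {
    stop("image has ", dim(data)[4], " volumes but the gradient table has ",
         length(scheme$bvals), " entries")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 strictly positive lengths (mm)")
  }
  structure(list(data = data, scheme = scheme, voxel_size = voxel_size,
                 affine = unname(as.matrix(affine))),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_stack> ", paste(d[1:3], collapse = " x "), " voxels (",
      paste(signif(x$voxel_size, 3), collapse = " x "), " mm), ",
      d[4], " volumes\n", sep = "")
  print(x$scheme)
  invisible(x)
}

#' Spatial dimensions of a stack
#' @param stack A [dwi_stack()].
#' @return Integer length-3 vector.
#' @export
spatial_dim <- function(stack) dim(stack$data)[1:3]

#' Read a DWI stack from NIfTI + bval/bvec
#'
#' @param image_path NIfTI (.nii / .nii.gz) 4D image.
#' @param bval_path,bvec_path FSL gradient table files.
#' @param transposed,b0_thresh Passed to [read_gradient_table()].
#' @return A validated [dwi_stack()]; errors if the image 4th dimension and
#'   gradient table lengths disagree.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, transposed = FALSE,
                     b0_thresh = 50) {
  img <- RNifti::readNifti(image_path)
  scheme <- read_gradient_table(bval_path, bvec_path,
                                transposed = transposed,
                                b0_thresh = b0_thresh)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  nvol <- dim(arr)[4]
  if (nvol != length(scheme$bvals)) {
    stop("image '", basename(image_path), "' has ", nvol,
         " volumes but the gradient table has ", length(scheme$bvals))
  }
  vs <- RNifti::pixdim(img)[1:3]
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  dwi_stack(arr, scheme, voxel_size = vs, affine = aff)
}

#' Write a DWI stack as NIfTI + bval/bvec
#' @param stack A [dwi_stack()].
#' @param image_path Output NIfTI path.
#' @param bval_path,bvec_path Optional gradient table outputs.
#' @export
write_dwi <- function(stack, image_path, bval_path = NULL,
                      bvec_path = NULL) {
  write_volume(stack$data, image_path, stack$affine)
  if (!is.null(bval_path)) {
    write_gradient_table(stack$scheme, bval_path, bvec_path)
  }
  invisible(stack)
}

#' Write a 3D/4D array as NIfTI with a given affine
#' @param arr Numeric array.
#' @param path Output path.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @export
write_volume <- function(arr, path, affine = diag(4)) {
  arr <- as.array(arr)
  nd <- length(dim(arr))
  dimfield <- rep(1L, 8)
  dimfield[1] <- nd
  dimfield[seq_len(nd) + 1L] <- dim(arr)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- c(1, vs, rep(1, 4))
  hdr <- RNifti::niftiHeader(list(
    dim = dimfield, pixdim = pd,
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
    sform_code = 2, qform_code = 0, datatype = 64))
  RNifti::writeNifti(RNifti::asNifti(arr, reference = hdr), path)
  invisible(path)
}

#' Read a binary mask or integer label map
#'
#' @param path NIfTI path.
#' @param spatial_shape Optional expected grid shape for validation.
#' @return 3D integer array; masks are 0/1.
#' @export
read_labels <- function(path, spatial_shape = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3) stop("mask/label map must be 3D")
  if (!is.null(spatial_shape) && !all(dim(arr) == spatial_shape)) {
    stop("mask/label grid ", paste(dim(arr), collapse = "x"),
         " does not match image grid ",
         paste(spatial_shape, collapse = "x"))
  }
  if (any(arr < 0)) stop("labels must be non-negative")
  storage.mode(arr) <- "integer"
  arr
}

#' Select a shell (plus optionally the b = 0 volumes) from a stack
#'
#' Keeps volumes with |bval - b_target| <= tol, preserving acquisition
#' order, and by default also keeps all b = 0 volumes.
#'
#' @param stack A [dwi_stack()].
#' @param b_target Shell b-value (s/mm^2).
#' @param tol Non-negative tolerance (s/mm^2).
#' @param include_b0 Also keep b = 0 volumes.
#' @return A [dwi_stack()] restricted to the selection; errors if no DWI
#'   volume matches.
#' @export
select_shell <- function(stack, b_target, tol = 100, include_b0 = TRUE) {
  stopifnot(tol >= 0)
  sch <- stack$scheme
  in_shell <- abs(sch$bvals - b_target) <= tol & !is_b0(sch)
  if (!any(in_shell)) {
    stop("no volumes within ", tol, " s/mm^2 of b = ", b_target,
         " (shells present: ",
         paste(sort(unique(round(sch$bvals))), collapse = ", "), ")")
  }
  keep <- in_shell | (include_b0 & is_b0(sch))
  sub_scheme <- gradient_scheme(sch$bvals[keep],
                                sch$bvecs[keep, , drop = FALSE],
                                b0_thresh = sch$b0_thresh)
  dwi_stack(stack$data[, , , keep, drop = FALSE], sub_scheme,
            stack$voxel_size, stack$affine)
}

#' Voxel-wise mean of the b = 0 volumes
#'
#' @param stack A [dwi_stack()] with at least one b = 0 volume.
#' @return 3D array of per-voxel mean b = 0 signal.
#' @export
mean_b0 <- function(stack) {
  idx <- which(is_b0(stack$scheme))
  if (length(idx) == 0) stop("stack has no b = 0 volume (threshold ",
                             stack$scheme$b0_thresh, " s/mm^2)")
  sd3 <- spatial_dim(stack)
  out <- array(0, dim = sd3)
  for (i in idx) {
    out <- out + array(stack$data[, , , i, drop = FALSE], dim = sd3)
  }
  out / length(idx)
}

#' b0-normalised DWI signals for in-mask voxels
#'
#' Divides each in-mask voxel's b > 0 signals by its mean b = 0 signal.
#' Voxels with mean b0 below `eps` are dropped (reported in the result).
#'
#' @param stack A [dwi_stack()].
#' @param mask 3D 0/1 array; default all voxels.
#' @param eps Minimum usable mean b0 signal.
#' @return List: `signals` (n_vox x n_dwi matrix), `dirs` (n_dwi x 3),
#'   `bvals`, `voxels` (n_vox x 3 integer voxel indices, 1-based), `b0`
#'   (per-voxel mean b0), `n_excluded_b0`.
#' @export
normalised_signals <- function(stack, mask = NULL, eps = 1e-8) {
  sd3 <- spatial_dim(stack)
  if (is.null(mask)) mask <- array(1L, dim = sd3)
  stopifnot(all(dim(mask) == sd3))
  b0 <- mean_b0(stack)
  vox <- which(mask > 0 & b0 > eps, arr.ind = TRUE)
  n_excl <- sum(mask > 0) - nrow(vox)
  dwi_idx <- which(!is_b0(stack$scheme))
  nvox <- nrow(vox)
  flat <- matrix(stack$data, ncol = dim(stack$data)[4])
  lin <- vox[, 1] + (vox[, 2] - 1L) * sd3[1] +
    (vox[, 3] - 1L) * sd3[1] * sd3[2]
  sig <- flat[lin, dwi_idx, drop = FALSE] / b0[lin]
  list(signals = sig,
       dirs = stack$scheme$bvecs[dwi_idx, , drop = FALSE],
       bvals = stack$scheme$bvals[dwi_idx],
       voxels = vox, b0 = b0[lin], n_excluded_b0 = n_excl)
}

# scatter per-voxel values back into a 3D map (NA outside)
.scatter_map <- function(values, voxels, sd3, fill = NA_real_) {
  out <- array(fill, dim = sd3)
  out[voxels] <- values
  out
}
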