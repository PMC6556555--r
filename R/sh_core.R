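#' Number of real even-order spherical-harmonic coefficients
#'
#' For a real, antipodally symmetric SH basis truncated at even order `L`,
#' the number of basis functions (and hence coefficients per voxel) is
#' `(L + 1) * (L + 2) / 2`: 1 for order 0, 5 for order 2, 9 for order 4, ...
#'
#' @param L Even, non-negative maximum SH order.
#' @return Integer coefficient count, e.g. 15 for `L = 4`, 28 for `L = 6`,
#'   45 for `L = 8`.
#' @export
#' @examples
#' sh_ncoef(4) # 15
#' sh_ncoef(6) + 1 # 29 channels when a b=0 channel is appended
sh_ncoef <- function(L) {
  stopifnot(length(L) == 1, is.numeric(L))
  if (L < 0 || L %% 2 != 0) {
    stop("SH order L must be even and non-negative, got ", L)
  }
  as.integer((L + 1) * (L + 2) / 2)
}

#' Index table of the SH basis ordering
#'
#' The basis is ordered by increasing even order l, and within each order by
#' m = -l, ..., 0, ..., l. This ordering is fixed throughout the package and
#' recorded in serialised coefficient files.
#'
#' @param L Even maximum order.
#' @return A tibble with columns `j` (1-based column index), `l`, `m`.
#' @export
sh_index_table <- function(L) {
  ncoef <- sh_ncoef(L)
  l <- integer(0); m <- integer(0)
  for (ll in seq(0, L, by = 2)) {
    l <- c(l, rep.int(ll, 2 * ll + 1))
    m <- c(m, seq.int(-ll, ll))
  }
  tibble::tibble(j = seq_len(ncoef), l = l, m = m)
}

# Associated Legendre values P_l^m(x) for m = 0..l, as an (l+1) x length(x)
# matrix, MATLAB/pracma convention (includes the Condon-Shortley phase).
.assoc_legendre <- function(l, x) {
  if (l == 0) {
    matrix(1, nrow = 1, ncol = length(x))
  } else {
    pracma::legendre(l, x)
  }
}

#' Evaluate the real symmetric SH basis at unit directions
#'
#' Real, antipodally symmetric basis built from even orders only
#' (Descoteaux-style): for m < 0 the sqrt(2)-scaled cosine harmonic, for
#' m = 0 the zonal harmonic, for m > 0 the sqrt(2)-scaled sine harmonic.
#' Y_{0,0} = 1 / (2 sqrt(pi)), so a constant signal s has c_{0,0} = 2
#' sqrt(pi) s.
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param L Even maximum order.
#' @return n x `sh_ncoef(L)` basis matrix, with attributes `order` and
#'   `index` (the `sh_index_table()`).
#' @export
sh_basis <- function(dirs, L) {
  dirs <- .as_dir_matrix(dirs)
  ncoef <- sh_ncoef(L)
  n <- nrow(dirs)
  theta_cos <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  B <- matrix(0, nrow = n, ncol = ncoef)
  j <- 1L
  for (l in seq(0, L, by = 2)) {
    P <- .assoc_legendre(l, theta_cos) # (l+1) x n, rows m = 0..l
    for (m in seq.int(-l, l)) {
      am <- abs(m)
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      val <- norm * P[am + 1L, ]
      if (m < 0) {
        B[, j] <- sqrt(2) * val * cos(am * phi)
      } else if (m == 0) {
        B[, j] <- val
      } else {
        B[, j] <- sqrt(2) * val * sin(am * phi)
      }
      j <- j + 1L
    }
  }
  attr(B, "order") <- L
  attr(B, "index") <- sh_index_table(L)
  B
}

.as_dir_matrix <- function(dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3) stop("directions must be an n x 3 matrix")
  storage.mode(dirs) <- "double"
  dirs
}

#' Laplace-Beltrami penalty diagonal for an SH basis
#'
#' The Laplace-Beltrami operator acts on Y_{l,m} with eigenvalue -l(l+1);
#' the standard smoothness penalty is therefore diag(l^2 (l+1)^2), which is
#' zero for every order-0 coefficient.
#'
#' @param L Even maximum order.
#' @return Numeric vector of length `sh_ncoef(L)` with entries l^2 (l+1)^2.
#' @export
sh_lb_penalty <- function(L) {
  tab <- sh_index_table(L)
  (tab$l * (tab$l + 1))^2
}

#' Fit regularised SH coefficients to spherical signals
#'
#' Per voxel (row of `signals`) solves the Laplace-Beltrami-damped least
#' squares problem min_c ||B c - s||^2 + lambda c' Lp c, i.e.
#' c = (B'B + lambda Lp)^{-1} B' s, with Lp = diag(l^2 (l+1)^2). The signal
#' is expected to be b0-normalised by the caller; the even-order basis makes
#' antipodal symmetry implicit.
#'
#' @param signals Numeric vector (one voxel) or n_vox x n_dir matrix of
#'   signal values sampled at `dirs`.
#' @param dirs n_dir x 3 unit directions.
#' @param L Even maximum order.
#' @param lambda Laplace-Beltrami regularisation weight (unitless, >= 0).
#'   The harmonisers in this package default to 0.006.
#' @return n_vox x `sh_ncoef(L)` coefficient matrix of class `sh_coefs`,
#'   with attributes `order` and `lambda`.
#' @export
sh_fit <- function(signals, dirs, L, lambda = 0) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  signals <- as.matrix(signals)
  dirs <- .as_dir_matrix(dirs)
  if (ncol(signals) != nrow(dirs)) {
    stop("signals have ", ncol(signals), " samples but ", nrow(dirs),
         " directions were given")
  }
  if (lambda < 0) stop("lambda must be >= 0")
  B <- sh_basis(dirs, L)
  A <- crossprod(B) + lambda * diag(sh_lb_penalty(L), ncol(B))
  if (lambda == 0 && rcond(A) < 1e-12) {
    stop("SH normal matrix is singular: order ", L, " needs at least ",
         sh_ncoef(L), " well-spread directions (got ", nrow(dirs),
         "); use lambda > 0 (e.g. 0.006)")
  }
  coefs <- t(solve(A, crossprod(B, t(signals))))
  attr(coefs, "order") <- L
  attr(coefs, "lambda") <- lambda
  class(coefs) <- c("sh_coefs", class(coefs))
  coefs
}

#' Resample SH coefficients at new directions
#'
#' Evaluates s(g) = sum_j c_j Y_j(g). Antipodal directions give identical
#' values because only even orders are present.
#'
#' @param coefs n_vox x n_coef coefficient matrix (e.g. from [sh_fit()]).
#' @param dirs m x 3 unit directions.
#' @param L Even order; defaults to the `order` attribute of `coefs`.
#' @return n_vox x m matrix of signal values.
#' @export
sh_resample <- function(coefs, dirs, L = attr(coefs, "order")) {
  if (is.null(L)) stop("SH order not given and not stored on `coefs`")
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1)
  coefs <- unclass(coefs)
  if (ncol(coefs) != sh_ncoef(L)) {
    stop("coefficient count ", ncol(coefs), " does not match order ", L)
  }
  B <- sh_basis(.as_dir_matrix(dirs), L)
  coefs %*% t(B)
}

#' Approximately uniform unit directions on a hemisphere
#'
#' Generates `n` directions by electrostatic-repulsion descent on the full
#' sphere with antipodal charge pairs (each point repels every other point
#' and its antipode), started from a seeded random configuration, then
#' collapsed to the z >= 0 hemisphere. Deterministic given `seed`.
#'
#' @param n Number of directions (>= 3).
#' @param seed Integer seed for the random start.
#' @param iterations Descent iterations.
#' @return n x 3 matrix of unit vectors with non-negative z.
#' @export
hemisphere_dirs <- function(n, seed = 1L, iterations = 200L) {
  stopifnot(n >= 3)
  rng <- .seeded_rng(seed)
  X <- matrix(rng$norm(3L * n), ncol = 3)
  X <- X / sqrt(rowSums(X^2))
  step <- 0.1
  energy <- function(X) {
    D1 <- as.matrix(stats::dist(X))
    D2 <- sqrt(outer(rowSums(X^2), rowSums(X^2), "+") + 2 * tcrossprod(X))
    diag(D1) <- Inf
    diag(D2) <- pmax(diag(D2), 1e-9) # self-antipode distance is 2
    sum(1 / D1[upper.tri(D1)]) + sum(1 / D2[upper.tri(D2, diag = TRUE)])
  }
  e_old <- energy(X)
  for (it in seq_len(iterations)) {
    G <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      diff1 <- sweep(X[-i, , drop = FALSE], 2, X[i, ], "-")
      diff2 <- sweep(-X[-i, , drop = FALSE], 2, X[i, ], "-")
      d1 <- pmax(sqrt(rowSums(diff1^2)), 1e-6)
      d2 <- pmax(sqrt(rowSums(diff2^2)), 1e-6)
      # force = -grad(1/d) pushes points apart
      G[i, ] <- -colSums(diff1 / d1^3) - colSums(diff2 / d2^3)
    }
    Xn <- X + step * G
    Xn <- Xn / sqrt(rowSums(Xn^2))
    e_new <- energy(Xn)
    if (e_new < e_old) {
      X <- Xn; e_old <- e_new; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  flip <- X[, 3] < 0
  X[flip, ] <- -X[flip, , drop = FALSE]
  unname(X)
}

# Small self-contained xorshift-based RNG so direction generation and other
# seeded utilities never disturb R's global .Random.seed.
.seeded_rng <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483562L) + 1L)
  nextu <- function() {
    # Lehmer / Park-Miller minimal standard generator
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(
    unif = function(k) vapply(seq_len(k), function(i) nextu(), 0),
    norm = function(k) {
      m <- ceiling(k / 2)
      u1 <- pmax(vapply(seq_len(m), function(i) nextu(), 0), 1e-12)
      u2 <- vapply(seq_len(m), function(i) nextu(), 0)
      z <- c(sqrt(-2 * log(u1)) * cos(2 * pi * u2),
             sqrt(-2 * log(u1)) * sin(2 * pi * u2))
      z[seq_len(k)]
    }
  )
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are computed modulo antipodal symmetry (directions g and -g are
#' the same measurement axis).
#'
#' @param dirs n x 3 unit directions.
#' @return Minimum pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(dirs) {
  dirs <- .as_dir_matrix(dirs)
  C <- abs(tcrossprod(dirs))
  diag(C) <- -Inf
  acos(pmin(1, max(C))) * 180 / pi
}
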