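#' Apply the multicoil Cartesian encoding operator
#'
#' Per frame \eqn{(i,j)} and coil \eqn{c}, computes
#' \eqn{M_{i,j} \, F(S_c \odot m_{i,j})} where \eqn{F} is the orthonormal 3D
#' DFT, \eqn{S_c} the coil sensitivity and \eqn{M_{i,j}} the frame sampling
#' mask.  Output is zero at unsampled k-space locations.  With normalized
#' coils (\eqn{\sum_c |S_c|^2 \le 1}) the operator norm satisfies
#' \eqn{\|E\| \le 1}.
#'
#' @param m an \code{\link{image_series5d}}.
#' @param coils a \code{\link{coil_set}}.
#' @param mask 0/1 array \code{(Nx, Ny, Nz, Nc, Nr)} of per-frame sampling
#'   masks.
#' @return A \code{\link{kspace5d}} object.
#' @export
apply_encoding <- function(m, coils, mask) {
  check_consistent(m = m, coils = coils)
  d <- series_dims(m)
  if (!is.array(mask) || !all(dim(mask) == d[c(1, 2, 3, 4, 5)]))
    stopf("mask dimensions must be (Nx, Ny, Nz, Nc, Nr) = (%s)",
          paste(d, collapse = ", "))
  ncoils <- dim(coils$maps)[4]
  out <- array(0i, c(d[1:3], ncoils, d[4], d[5]))
  for (i in seq_len(d[5])) for (j in seq_len(d[4])) {
    fr <- m$data[, , , j, i]
    msk <- mask[, , , j, i]
    for (c in seq_len(ncoils)) {
      out[, , , c, j, i] <- msk * fft3o(coils$maps[, , , c] * fr)
    }
  }
  storage.mode(mask) <- "double"
  new_kspace5d(out, mask)
}

#' Apply the adjoint of the encoding operator
#'
#' Per frame: \eqn{\sum_c \bar S_c \odot F^{-1}(M_{i,j} \, y_{i,j,c})}.
#' Applied to raw data this is the zero-filled reconstruction \eqn{E^H y},
#' the solver's initialization and quality baseline.
#'
#' @param y a \code{\link{kspace5d}}.
#' @param coils a \code{\link{coil_set}}.
#' @return An \code{\link{image_series5d}}.
#' @export
apply_encoding_adjoint <- function(y, coils) {
  check_consistent(y = y, coils = coils)
  d <- kspace_dims(y)
  if (dim(coils$maps)[4] != d[4])
    stopf("coil count mismatch: k-space has %d coils, maps have %d",
          d[4], dim(coils$maps)[4])
  out <- array(0i, c(d[1:3], d[5], d[6]))
  conj_maps <- Conj(coils$maps)
  for (i in seq_len(d[6])) for (j in seq_len(d[5])) {
    msk <- y$mask[, , , j, i]
    acc <- array(0i, d[1:3])
    for (c in seq_len(d[4])) {
      acc <- acc + conj_maps[, , , c] * ifft3o(msk * y$data[, , , c, j, i])
    }
    out[, , , j, i] <- acc
  }
  new_image_series5d(out)
}

#' Temporal total-variation transform (forward differences)
#'
#' Non-circular forward differences of the frame sequence along the cardiac
#' and respiratory phase axes:
#' \eqn{d^c_{i,j} = w_c (m_{i,j+1} - m_{i,j})} for \eqn{j = 1..Nc-1} and
#' \eqn{d^r_{i,j} = w_r (m_{i+1,j} - m_{i,j})} for \eqn{i = 1..Nr-1}.
#' There is no wrap-around from the last phase to the first.
#'
#' @param m an \code{\link{image_series5d}} (or its bare 5D array).
#' @param weights length-2 nonnegative weights \code{c(cardiac, respiratory)}.
#' @return An object of class \code{ttv_diffs}: a list with complex arrays
#'   \code{cardiac} \code{(Nx,Ny,Nz,Nc-1,Nr)} and \code{respiratory}
#'   \code{(Nx,Ny,Nz,Nc,Nr-1)} (zero-extent when \code{Nr = 1}).
#' @export
ttv_forward <- function(m, weights = c(1, 1)) {
  a <- if (inherits(m, "image_series5d")) m$data else m
  d <- dim(a)
  if (length(d) != 5L) stopf("expected a 5D array or image_series5d")
  if (d[4] < 2L) stopf("temporal TV requires Nc >= 2 cardiac phases")
  Nc <- d[4]; Nr <- d[5]
  card <- weights[1] * (a[, , , 2:Nc, , drop = FALSE] -
                        a[, , , 1:(Nc - 1), , drop = FALSE])
  if (Nr >= 2L) {
    resp <- weights[2] * (a[, , , , 2:Nr, drop = FALSE] -
                          a[, , , , 1:(Nr - 1), drop = FALSE])
  } else {
    resp <- array(0i, c(d[1:3], Nc, 0L))
  }
  structure(list(cardiac = card, respiratory = resp, weights = weights),
            class = "ttv_diffs")
}

#' Adjoint of the temporal total-variation transform
#'
#' Negative temporal divergence: frame \eqn{(i,j)} receives
#' \eqn{w_c (p^c_{i,j-1} - p^c_{i,j}) + w_r (p^r_{i-1,j} - p^r_{i,j})}, with
#' out-of-range terms zero.
#'
#' @param p a \code{ttv_diffs} object (see \code{\link{ttv_forward}}).
#' @return An \code{\link{image_series5d}} whose data array has the original
#'   frame dimensions.
#' @export
ttv_adjoint <- function(p) {
  if (!inherits(p, "ttv_diffs")) stopf("p must be a ttv_diffs object")
  dc <- dim(p$cardiac); dr <- dim(p$respiratory)
  Nc <- dc[4] + 1L
  Nr <- dc[5]
  if (dr[4] != Nc || (dr[5] != 0L && dr[5] != Nr - 1L))
    stopf("cardiac (%s) and respiratory (%s) diff shapes are inconsistent",
          paste(dc, collapse = "x"), paste(dr, collapse = "x"))
  w <- p$weights
  out <- array(0i, c(dc[1:3], Nc, Nr))
  # cardiac contributions
  out[, , , 1:(Nc - 1), ] <- out[, , , 1:(Nc - 1), , drop = FALSE] -
    w[1] * p$cardiac
  out[, , , 2:Nc, ] <- out[, , , 2:Nc, , drop = FALSE] + w[1] * p$cardiac
  if (dr[5] > 0L) {
    out[, , , , 1:(Nr - 1)] <- out[, , , , 1:(Nr - 1), drop = FALSE] -
      w[2] * p$respiratory
    out[, , , , 2:Nr] <- out[, , , , 2:Nr, drop = FALSE] + w[2] * p$respiratory
  }
  new_image_series5d(out)
}

#' Huber (smoothed absolute value) function and its gradient
#'
#' The smoothed l1 surrogate used by NESTA:
#' \deqn{h_\mu(z) = |z|^2 / (2\mu) \textrm{ for } |z| \le \mu, \quad
#'       |z| - \mu/2 \textrm{ otherwise,}}
#' summed over all entries of \code{u}.  Its gradient is
#' \eqn{z/\mu} on the quadratic branch and \eqn{z/|z|} outside, so gradient
#' magnitudes never exceed 1.  As \eqn{\mu \to 0}, \eqn{h_\mu \to |\cdot|},
#' and \eqn{h_\mu(u) \le \|u\|_1} always.
#'
#' @param u complex (or numeric) array.
#' @param mu positive smoothing width \eqn{\mu}.
#' @return \code{huber_value}: a nonnegative scalar. \code{huber_grad}: an
#'   array like \code{u}.
#' @export
huber_value <- function(u, mu) {
  if (!is_scalar_num(mu) || mu <= 0) stopf("mu must be a positive number")
  a <- Mod(u)
  quad <- a <= mu
  sum(a[quad]^2) / (2 * mu) + sum(a[!quad]) - mu / 2 * sum(!quad)
}

#' @rdname huber_value
#' @export
huber_grad <- function(u, mu) {
  if (!is_scalar_num(mu) || mu <= 0) stopf("mu must be a positive number")
  a <- Mod(u)
  # z / max(|z|, mu): quadratic branch z/mu, linear branch z/|z|
  g <- u / pmax(a, mu)
  if (is.array(u)) dim(g) <- dim(u)
  g
}

# Huber value of the temporal TV of a series.
huber_ttv_value <- function(p, mu) {
  huber_value(p$cardiac, mu) +
    (if (length(p$respiratory) > 0) huber_value(p$respiratory, mu) else 0)
}

#' Objective and gradient of the smoothed reconstruction problem
#'
#' The smoothed objective evaluated at iterate \eqn{m^k}:
#' \deqn{f(m^k) = \tfrac12 \|E m^k - y\|_2^2 + \lambda f_\mu(\Phi m^k)}
#' with the l2 norm over sampled k-space entries, and its gradient
#' \deqn{\nabla f(m^k) = E^H (E m^k - y) +
#'       \lambda \, \Phi^H f_\mu'(\Phi m^k),}
#' whose regularization part \eqn{\Lambda} at frame \eqn{(i,j)} depends only
#' on the immediately adjacent phases \eqn{(i, j\pm1)} and \eqn{(i\pm1, j)}
#' — the locality that makes ghost-frame exchange sufficient under
#' partitioning.
#'
#' @param m an \code{\link{image_series5d}} iterate.
#' @param y the acquired \code{\link{kspace5d}}.
#' @param coils a \code{\link{coil_set}}.
#' @param lambda_reg nonnegative regularization weight \eqn{\lambda}.
#' @param mu positive Huber smoothing width.
#' @param ttv_weights length-2 weights for the cardiac/respiratory axes.
#' @return \code{objective_value}: a nonnegative scalar;
#'   \code{objective_gradient}: an \code{\link{image_series5d}}.
#' @export
objective_value <- function(m, y, coils, lambda_reg, mu,
                            ttv_weights = c(1, 1)) {
  if (lambda_reg < 0) stopf("lambda_reg must be nonnegative")
  check_consistent(m = m, y = y, coils = coils)
  em <- apply_encoding(m, coils, y$mask)
  fid <- 0.5 * sum(Mod(em$data - y$data)^2)
  reg <- if (lambda_reg > 0)
    lambda_reg * huber_ttv_value(ttv_forward(m, ttv_weights), mu)
  else 0
  fid + reg
}

#' @rdname objective_value
#' @export
objective_gradient <- function(m, y, coils, lambda_reg, mu,
                               ttv_weights = c(1, 1)) {
  if (lambda_reg < 0) stopf("lambda_reg must be nonnegative")
  check_consistent(m = m, y = y, coils = coils)
  em <- apply_encoding(m, coils, y$mask)
  res <- new_kspace5d(em$data - y$data, y$mask)
  g <- apply_encoding_adjoint(res, coils)
  if (lambda_reg > 0) {
    p <- ttv_forward(m, ttv_weights)
    p$cardiac <- huber_grad(p$cardiac, mu)
    if (length(p$respiratory) > 0) p$respiratory <- huber_grad(p$respiratory, mu)
    lam <- ttv_adjoint(p)
    g$data <- g$data + lambda_reg * lam$data
  }
  g
}

# Fused objective/gradient evaluation over a (possibly partitioned) frame
# range: frame-local data fidelity plus the temporal regularization term,
# whose boundary cardiac differences use the ghost frames ghL/ghR (NULL for
# an unpartitioned run or at the global ends).  Sharing the encoded residual
# between f and g halves the dominant FFT cost per solver iteration.
# x: (Nx,Ny,Nz,nloc,Nr); y_data: (Nx,Ny,Nz,Ncoils,nloc,Nr);
# ghL/ghR: (Nx,Ny,Nz,Nr) or NULL.
device_fg <- function(x, y_data, y_mask, maps, ghL, ghR, lambda, mu, w,
                      want_grad = TRUE) {
  d <- dim(x); nloc <- d[4]; Nr <- d[5]
  ncoils <- dim(maps)[4]
  f <- 0
  g <- if (want_grad) array(0i, d) else NULL
  conj_maps <- Conj(maps)
  for (i in seq_len(Nr)) for (j in seq_len(nloc)) {
    msk <- y_mask[, , , j, i]
    fr <- x[, , , j, i]
    if (want_grad) acc <- array(0i, d[1:3])
    for (c in seq_len(ncoils)) {
      # residual is supported on the mask: y_data is zero off-mask
      res <- msk * fft3o(maps[, , , c] * fr) - y_data[, , , c, j, i]
      f <- f + 0.5 * sum(Mod(res)^2)
      if (want_grad) acc <- acc + conj_maps[, , , c] * ifft3o(res)
    }
    if (want_grad) g[, , , j, i] <- acc
  }
  if (lambda > 0) {
    ext <- extend_cardiac(x, ghL, ghR)
    ne <- dim(ext)[4]
    gl <- if (is.null(ghL)) 0L else 1L
    pc <- w[1] * (ext[, , , 2:ne, , drop = FALSE] -
                  ext[, , , 1:(ne - 1), , drop = FALSE])
    f <- f + lambda * huber_value(pc, mu)
    pr <- if (Nr >= 2L)
      w[2] * (x[, , , , 2:Nr, drop = FALSE] - x[, , , , 1:(Nr - 1), drop = FALSE])
    else NULL
    if (!is.null(pr)) f <- f + lambda * huber_value(pr, mu)
    if (want_grad) {
      hc <- huber_grad(pc, mu)
      lam_ext <- array(0i, dim(ext))
      lam_ext[, , , 1:(ne - 1), ] <- -w[1] * hc
      lam_ext[, , , 2:ne, ] <- lam_ext[, , , 2:ne, , drop = FALSE] + w[1] * hc
      lam <- lam_ext[, , , (gl + 1L):(gl + nloc), , drop = FALSE]
      if (!is.null(pr)) {
        hr <- huber_grad(pr, mu)
        lam[, , , , 1:(Nr - 1)] <- lam[, , , , 1:(Nr - 1), drop = FALSE] -
          w[2] * hr
        lam[, , , , 2:Nr] <- lam[, , , , 2:Nr, drop = FALSE] + w[2] * hr
      }
      g <- g + lambda * lam
    }
  }
  list(f = f, g = g)
}

# Power iteration estimate of the largest eigenvalue of A^H A for a linear
# operator given as forward/adjoint closures on arrays; used to verify the
# operator-norm bounds ||E||^2 <= 1 and ||Phi||^2 <= 8.
power_iteration_norm2 <- function(forward, adjoint, x0, n_iter = 50) {
  x <- x0 / sqrt(sum(Mod(x0)^2))
  ev <- 0
  for (k in seq_len(n_iter)) {
    z <- adjoint(forward(x))
    ev <- sqrt(sum(Mod(z)^2))
    if (ev == 0) return(0)
    x <- z / ev
  }
  ev
}
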