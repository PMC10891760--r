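#' Construct a 5D image series
#'
#' The unknown \eqn{m} of the reconstruction problem: one complex 3D volume
#' \eqn{m_{i,j}} per respiratory phase \eqn{i = 1..Nr} and cardiac phase
#' \eqn{j = 1..Nc}.  Internally the data are held as a complex array with
#' dimensions \code{(Nx, Ny, Nz, Nc, Nr)}: the respiratory index is the
#' slowest-varying axis, the cardiac index the next-slowest.  Public messages
#' and indices are 1-based, matching the \eqn{m_{i,j}} notation.
#'
#' @param data complex (or numeric) 5D array, dimensions
#'   \code{(Nx, Ny, Nz, Nc, Nr)}.
#' @param voxel_size_mm length-3 numeric, voxel size in millimetres
#'   (metadata only).
#' @return An object of class \code{image_series5d} with elements
#'   \code{data} and \code{voxel_size_mm}.
#' @examples
#' m <- image_series5d(array(0i, c(4, 4, 4, 2, 1)))
#' dim(m$data)
#' @export
image_series5d <- function(data, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stopf("image series data must be a 5D array (Nx, Ny, Nz, Nc, Nr); got %s dims",
          length(dim(data)))
  d <- dim(data)
  if (d[4] < 2L)
    stopf("at least 2 cardiac phases are required (temporal TV needs Nc >= 2); got Nc = %d", d[4])
  if (d[5] < 1L) stopf("at least 1 respiratory phase is required")
  storage.mode(data) <- "complex"
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive numbers")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "image_series5d")
}

#' @export
print.image_series5d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series5d> %dx%dx%d voxels, Nc = %d cardiac, Nr = %d respiratory phases\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Construct a 5D multicoil k-space object
#'
#' The acquired data \eqn{y}: per frame \eqn{(i,j)} and coil \eqn{c}, a
#' complex Cartesian k-space volume, together with the per-frame binary
#' sampling masks.  The data must be zero wherever the frame mask is zero
#' (the sampling matrix is part of the encoding operator, so unsampled
#' entries carry no information).
#'
#' @param data complex 6D array, dimensions \code{(Nx, Ny, Nz, Ncoils, Nc, Nr)}.
#' @param mask 0/1 5D array, dimensions \code{(Nx, Ny, Nz, Nc, Nr)}.
#' @return An object of class \code{kspace5d}.
#' @export
kspace5d <- function(data, mask) {
  if (!is.array(data) || length(dim(data)) != 6L)
    stopf("k-space data must be a 6D array (Nx, Ny, Nz, Ncoils, Nc, Nr)")
  if (!is.array(mask) || length(dim(mask)) != 5L)
    stopf("k-space mask must be a 5D array (Nx, Ny, Nz, Nc, Nr)")
  d <- dim(data); dm <- dim(mask)
  if (!all(dm == d[-4]))
    stopf("mask dimensions (%s) do not match k-space frame dimensions (%s)",
          paste(dm, collapse = "x"), paste(d[-4], collapse = "x"))
  if (!all(mask %in% c(0, 1)))
    stopf("mask must be binary (0/1)")
  storage.mode(data) <- "complex"
  storage.mode(mask) <- "double"
  # broadcast mask across the coil axis and verify data support
  nc <- d[4]
  bad <- FALSE
  for (c in seq_len(nc)) {
    slab <- data[, , , c, , , drop = FALSE]
    dim(slab) <- dm
    if (any(slab[mask == 0] != 0)) { bad <- TRUE; break }
  }
  if (bad)
    stopf("k-space data has nonzero values at masked-out locations (coil %d)", c)
  structure(list(data = data, mask = mask), class = "kspace5d")
}

#' @export
print.kspace5d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace5d> %dx%dx%d k-grid, %d coils, Nc = %d, Nr = %d; sampled fraction %.3f\n",
              d[1], d[2], d[3], d[4], d[5], d[6], mean(x$mask)))
  invisible(x)
}

#' Construct a coil sensitivity set
#'
#' Complex sensitivity maps \eqn{S_c} on the image grid.  Maps are expected
#' already normalized: \eqn{\sum_c |S_c|^2 \le 1} at every voxel (the
#' generator normalizes; the constructor only validates).  This convention
#' makes the encoding-operator norm bound \eqn{\|E\| \le 1} hold by
#' construction.
#'
#' @param maps complex 4D array, dimensions \code{(Nx, Ny, Nz, Ncoils)}.
#' @return An object of class \code{coil_set}.
#' @export
coil_set <- function(maps) {
  if (!is.array(maps) || length(dim(maps)) != 4L)
    stopf("coil maps must be a 4D array (Nx, Ny, Nz, Ncoils)")
  storage.mode(maps) <- "complex"
  sos <- apply(Mod(maps)^2, c(1, 2, 3), sum)
  if (max(sos) > 1 + 1e-6)
    stopf("coil maps are not normalized: max sum-of-squares = %.8f > 1 + 1e-6", max(sos))
  structure(list(maps = maps), class = "coil_set")
}

#' @export
print.coil_set <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<coil_set> %d coils on a %dx%dx%d grid\n", d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Reconstruction configuration
#'
#' Collects every tunable of the staged NESTA solver and of the multi-device
#' decomposition.
#'
#' @param lambda_reg nonnegative regularization weight \eqn{\lambda}, or
#'   \code{NULL} to use the data-scaled default
#'   \code{0.01 * max(Mod(E^H y))} at run time.
#' @param n_stages number of continuation stages (default 4).
#' @param max_iter_per_stage iteration cap per stage (default 100).
#' @param tau minimum iterations before the stopping rule activates
#'   (default 7).
#' @param tol stopping tolerance on the progress quotient (default 1e-5).
#' @param mu_final final Huber smoothing width, or \code{NULL} for
#'   \code{mu0 * 1e-3} (decade steps over 4 stages).
#' @param mu_decay_mode only \code{"geometric"} is supported.
#' @param seed integer seed for any stochastic execution mode.
#' @param n_devices number of simulated devices \eqn{d}.
#' @param device_capacities positive weights, one per device (defaults to
#'   equal weights).
#' @param exec_mode one of \code{"single"}, \code{"lockstep"},
#'   \code{"concurrent"}.
#' @param ttv_weights length-2 positive weights for the cardiac and
#'   respiratory temporal-difference axes (default \code{c(1, 1)}).
#' @param local_stopping logical; when \code{FALSE}, per-device stopping is
#'   disabled and every device runs exactly \code{max_iter_per_stage}
#'   iterations per stage (used for equivalence testing against the global
#'   solver).
#' @param split optional manual cardiac split: integer vector of per-device
#'   phase counts summing to \code{Nc}, overriding the capacity-based
#'   partitioner.
#' @return An object of class \code{recon_config}.
#' @export
recon_config <- function(lambda_reg = NULL,
                         n_stages = 4L,
                         max_iter_per_stage = 100L,
                         tau = 7L,
                         tol = 1e-5,
                         mu_final = NULL,
                         mu_decay_mode = "geometric",
                         seed = 1L,
                         n_devices = 1L,
                         device_capacities = NULL,
                         exec_mode = c("single", "lockstep", "concurrent"),
                         ttv_weights = c(1, 1),
                         local_stopping = TRUE,
                         split = NULL) {
  exec_mode <- match.arg(exec_mode)
  if (!is.null(lambda_reg) &&
      (!is_scalar_num(lambda_reg) || lambda_reg < 0))
    stopf("lambda_reg must be a nonnegative number or NULL")
  if (!is_count(n_stages)) stopf("n_stages must be a count >= 1")
  if (!is_count(tau)) stopf("tau must be a count >= 1")
  if (!is_count(max_iter_per_stage, min = tau))
    stopf("max_iter_per_stage must be a count >= tau (= %d)", tau)
  if (!is_scalar_num(tol) || tol < 0) stopf("tol must be nonnegative")
  if (!is.null(mu_final) && (!is_scalar_num(mu_final) || mu_final <= 0))
    stopf("mu_final must be positive or NULL")
  if (!identical(mu_decay_mode, "geometric"))
    stopf("only the geometric mu decay mode is supported")
  if (!is_count(n_devices)) stopf("n_devices must be a count >= 1")
  if (is.null(device_capacities)) device_capacities <- rep(1, n_devices)
  if (length(device_capacities) != n_devices ||
      any(!is.finite(device_capacities)) || any(device_capacities <= 0))
    stopf("device_capacities must be %d positive numbers", n_devices)
  if (length(ttv_weights) != 2L || any(ttv_weights < 0))
    stopf("ttv_weights must be 2 nonnegative numbers (cardiac, respiratory)")
  if (!is.null(split)) {
    if (any(split != round(split)) || any(split < 1))
      stopf("split must be positive integer phase counts")
    if (length(split) != n_devices)
      stopf("split must have one entry per device")
  }
  structure(list(lambda_reg = lambda_reg, n_stages = as.integer(n_stages),
                 max_iter_per_stage = as.integer(max_iter_per_stage),
                 tau = as.integer(tau), tol = tol, mu_final = mu_final,
                 mu_decay_mode = mu_decay_mode, seed = as.integer(seed),
                 n_devices = as.integer(n_devices),
                 device_capacities = as.numeric(device_capacities),
                 exec_mode = exec_mode, ttv_weights = as.numeric(ttv_weights),
                 local_stopping = isTRUE(local_stopping),
                 split = if (is.null(split)) NULL else as.integer(split)),
            class = "recon_config")
}

# Fast internal constructors for data already known to satisfy the
# invariants (operator outputs); skip the O(N) validation passes.
new_image_series5d <- function(data, voxel_size_mm = c(1, 1, 1)) {
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "image_series5d")
}

new_kspace5d <- function(data, mask) {
  structure(list(data = data, mask = mask), class = "kspace5d")
}

# dimension helpers ---------------------------------------------------------

series_dims <- function(m) dim(m$data)          # (Nx,Ny,Nz,Nc,Nr)
kspace_dims <- function(y) dim(y$data)          # (Nx,Ny,Nz,Ncoils,Nc,Nr)

check_consistent <- function(m = NULL, y = NULL, coils = NULL) {
  grid <- NULL; src <- NULL
  take <- function(g, what) {
    if (is.null(grid)) { grid <<- g; src <<- what }
    else if (!all(grid == g))
      stopf("spatial grid of %s (%s) does not match %s (%s)", what,
            paste(g, collapse = "x"), src, paste(grid, collapse = "x"))
  }
  if (!is.null(m)) take(dim(m$data)[1:3], "image series")
  if (!is.null(y)) take(dim(y$data)[1:3], "k-space")
  if (!is.null(coils)) take(dim(coils$maps)[1:3], "coil maps")
  if (!is.null(m) && !is.null(y)) {
    dm <- dim(m$data); dy <- dim(y$data)
    if (dm[4] != dy[5] || dm[5] != dy[6])
      stopf("phase counts differ: image has Nc = %d, Nr = %d; k-space has Nc = %d, Nr = %d",
            dm[4], dm[5], dy[5], dy[6])
  }
  invisible(TRUE)
}
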