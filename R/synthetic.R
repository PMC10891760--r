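# Synthetic 5D acquisition: an analytic beating/breathing phantom, smooth
# complex coil maps, variable-density Cartesian undersampling and complex
# Gaussian noise.  Emulates a numerically simulated free-breathing bSSFP
# cardiac study (20 cardiac x 4 respiratory phases, multicoil, AF 4/8/10)
# at desk scale, so the whole reconstruction pipeline is testable offline.

#' Phantom specification
#'
#' @param nx,ny,nz spatial grid (each >= 4).
#' @param Nc cardiac phases (default 20, the study's phase count).
#' @param Nr respiratory phases (default 4).
#' @param ncoils coil count (default 16, reducible for small runs).
#' @param cardiac_contraction_fraction peak fractional reduction of the
#'   heart radii over the cardiac cycle, in (0, 1).
#' @param respiratory_shift_voxels peak heart translation along z over the
#'   respiratory cycle, in voxels.
#' @param voxel_size_mm voxel size metadata.
#' @param seed integer seed recorded with the data (the phantom itself is a
#'   deterministic analytic function; the seed drives masks and noise).
#' @return A list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(nx = 32, ny = 32, nz = 8, Nc = 20, Nr = 4,
                         ncoils = 4, cardiac_contraction_fraction = 0.3,
                         respiratory_shift_voxels = 1.5,
                         voxel_size_mm = c(2, 2, 2), seed = 1L) {
  if (any(c(nx, ny, nz) < 4)) stopf("grid dimensions must each be >= 4")
  if (!is_count(Nc, 2)) stopf("Nc must be >= 2")
  if (!is_count(Nr, 1)) stopf("Nr must be >= 1")
  if (!is_count(ncoils, 1)) stopf("ncoils must be >= 1")
  if (cardiac_contraction_fraction <= 0 || cardiac_contraction_fraction >= 1)
    stopf("cardiac_contraction_fraction must lie in (0, 1)")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 Nc = as.integer(Nc), Nr = as.integer(Nr),
                 ncoils = as.integer(ncoils),
                 cardiac_contraction_fraction = cardiac_contraction_fraction,
                 respiratory_shift_voxels = respiratory_shift_voxels,
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth edge profile: 1 inside, 0 outside, smoothstep over `soft` units of
# the normalized ellipsoid radius (keeps k-space energy concentrated).
soft_ellipsoid <- function(X, Y, Z, cx, cy, cz, rx, ry, rz, soft = 0.25) {
  r <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2)
  t <- pmin(pmax((1 + soft - r) / soft, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate the dynamic 5D ground-truth phantom
#'
#' A torso ellipse containing a "heart" ellipsoid whose radii oscillate
#' sinusoidally over the cardiac cycle (peak contraction at mid-cycle) and
#' whose centre translates sinusoidally along z over the respiratory cycle,
#' plus two static reference ellipsoids.  A smooth complex phase ramp is
#' applied so the object is genuinely complex.  The output is a
#' deterministic function of the spec.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return Ground-truth \code{\link{image_series5d}}.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  X <- array(rep(seq_len(nx), times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  torso <- 0.4 * soft_ellipsoid(X, Y, Z, cx, cy, cz,
                                0.45 * nx, 0.42 * ny, 0.60 * nz)
  liver <- 0.25 * soft_ellipsoid(X, Y, Z, cx - 0.25 * nx, cy + 0.2 * ny, cz,
                                 0.12 * nx, 0.12 * ny, 0.35 * nz)
  spine <- 0.6 * soft_ellipsoid(X, Y, Z, cx + 0.3 * nx, cy - 0.25 * ny, cz,
                                0.06 * nx, 0.06 * ny, 0.45 * nz)
  phase_ramp <- exp(1i * (0.12 * pi * (X - cx) / nx +
                          0.08 * pi * (Y - cy) / ny +
                          0.05 * pi * (Z - cz) / nz))
  data <- array(0i, c(nx, ny, nz, spec$Nc, spec$Nr))
  ccf <- spec$cardiac_contraction_fraction
  for (i in seq_len(spec$Nr)) {
    dz <- spec$respiratory_shift_voxels * sin(2 * pi * (i - 1) / spec$Nr)
    for (j in seq_len(spec$Nc)) {
      contraction <- 1 - ccf * sin(pi * (j - 1) / spec$Nc)^2
      heart <- 1.0 * soft_ellipsoid(X, Y, Z, cx + 0.05 * nx, cy - 0.05 * ny,
                                    cz + dz,
                                    contraction * 0.18 * nx,
                                    contraction * 0.18 * ny,
                                    contraction * 0.30 * nz)
      frame <- (torso + liver + spine + heart) * phase_ramp
      data[, , , j, i] <- frame
    }
  }
  image_series5d(data, voxel_size_mm = spec$voxel_size_mm)
}

#' Generate smooth normalized coil sensitivity maps
#'
#' Gaussian-profile sensitivities centred at points distributed around the
#' field of view, each with a smooth linear phase, then normalized so
#' \eqn{\sum_c |S_c|^2 = 1} at every voxel.
#'
#' @param spec a \code{\link{phantom_spec}} (grid and coil count are used).
#' @return A \code{\link{coil_set}}.
#' @export
generate_coils <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz; nc <- spec$ncoils
  X <- array(rep(seq_len(nx), times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  maps <- array(0i, c(nx, ny, nz, nc))
  if (nc == 1L) {
    maps[, , , 1] <- 1 + 0i
  } else {
    sigma <- 0.8 * max(nx, ny)
    for (c in seq_len(nc)) {
      ang <- 2 * pi * (c - 1) / nc
      px <- (nx + 1) / 2 + 0.6 * nx * cos(ang) / 2
      py <- (ny + 1) / 2 + 0.6 * ny * sin(ang) / 2
      pz <- (nz + 1) / 2 + 0.3 * nz * sin(2 * ang) / 2
      mag <- exp(-(((X - px)^2 + (Y - py)^2) / (2 * sigma^2) +
                   (Z - pz)^2 / (2 * (2 * sigma)^2)))
      ph <- 0.3 * pi * ((X / nx) * cos(ang) + (Y / ny) * sin(ang))
      maps[, , , c] <- mag * exp(1i * ph)
    }
    sos <- sqrt(apply(Mod(maps)^2, c(1, 2, 3), sum))
    for (c in seq_len(nc)) maps[, , , c] <- maps[, , , c] / sos
  }
  coil_set(maps)
}

#' Generate variable-density Cartesian undersampling masks
#'
#' The readout axis (kx, the first array axis) is fully sampled.  In the
#' (ky, kz) phase-encode plane, a fully sampled elliptical centre covering
#' \code{center_fraction} of the plane is kept, and the remaining samples
#' are drawn without replacement with probability decaying with k-space
#' radius, so that the total sampled fraction of every frame equals
#' \code{1/af} up to rounding.  Each frame gets a different pattern; the
#' whole set is a deterministic function of \code{seed}.
#'
#' @param grid integer triple \code{c(nx, ny, nz)}.
#' @param Nc,Nr phase counts.
#' @param af acceleration factor (>= 1; 4, 8 and 10 are the study presets).
#' @param center_fraction fully sampled central fraction of the (ky, kz)
#'   plane, in [0, 1).
#' @param seed integer seed.
#' @param decay exponent of the radial density decay (larger = more centre-
#'   weighted).
#' @return 0/1 array \code{(nx, ny, nz, Nc, Nr)}.
#' @export
generate_masks <- function(grid, Nc, Nr, af, center_fraction = 0.04,
                           seed = 1L, decay = 2) {
  if (length(grid) != 3L) stopf("grid must be c(nx, ny, nz)")
  if (!is_scalar_num(af) || af < 1) stopf("af must be >= 1")
  if (center_fraction < 0 || center_fraction >= 1)
    stopf("center_fraction must lie in [0, 1)")
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  masks <- array(0, c(nx, ny, nz, Nc, Nr))
  if (af == 1) { masks[] <- 1; return(masks) }
  # (ky, kz) geometry, DC at the centre of the plane
  ky <- seq_len(ny) - (ny + 1) / 2
  kz <- seq_len(nz) - (nz + 1) / 2
  RY <- outer(ky / max(abs(ky)), rep(1, nz))
  RZ <- outer(rep(1, ny), kz / max(abs(kz)))
  r <- sqrt(RY^2 + RZ^2) / sqrt(2)          # normalized radius in [0, 1]
  center <- (RY^2 + RZ^2) <= center_fraction * 4 / pi  # ellipse of that area
  n_plane <- ny * nz
  n_target <- max(round(n_plane / af), sum(center))
  n_random <- n_target - sum(center)
  weight <- (1 - 0.95 * r)^decay
  weight[center] <- 0
  with_seed(seed, {
    for (i in seq_len(Nr)) for (j in seq_len(Nc)) {
      plane <- matrix(0, ny, nz)
      plane[center] <- 1
      if (n_random > 0) {
        pick <- sample.int(n_plane, n_random, prob = as.vector(weight))
        plane[pick] <- 1
      }
      masks[, , , j, i] <- rep(as.vector(plane), each = nx)
    }
  })
  masks
}

#' Simulate the undersampled multicoil acquisition
#'
#' Applies the encoding operator to the ground truth and, for finite
#' \code{snr_db}, adds i.i.d. complex Gaussian noise on the sampled entries
#' scaled so that \eqn{10 \log_{10}(\mathrm{signal\ power}/\mathrm{noise\
#' power})} equals \code{snr_db}, with signal power measured as the mean
#' squared magnitude over sampled entries.
#'
#' @param truth ground-truth \code{\link{image_series5d}}.
#' @param coils \code{\link{coil_set}}.
#' @param masks 0/1 array \code{(nx, ny, nz, Nc, Nr)}.
#' @param snr_db signal-to-noise ratio in dB, or \code{Inf} for noiseless.
#' @param seed integer seed for the noise.
#' @param ref_power reference signal power to use when the encoded truth is
#'   identically zero (otherwise an error for finite \code{snr_db}).
#' @return A \code{\link{kspace5d}}.
#' @export
simulate_acquisition <- function(truth, coils, masks, snr_db = Inf,
                                 seed = 1L, ref_power = NULL) {
  y <- apply_encoding(truth, coils, masks)
  if (!is.finite(snr_db)) return(y)
  sampled <- which(replicate_mask(y$mask, dim(y$data)))
  p_signal <- mean(Mod(y$data[sampled])^2)
  if (p_signal == 0) {
    if (is.null(ref_power))
      stopf("encoded signal is identically zero; supply ref_power to set the noise scale")
    p_signal <- ref_power
  }
  p_noise <- p_signal * 10^(-snr_db / 10)
  sd_comp <- sqrt(p_noise / 2)
  with_seed(seed, {
    n <- length(sampled)
    noise <- complex(real = stats::rnorm(n, sd = sd_comp),
                     imaginary = stats::rnorm(n, sd = sd_comp))
    y$data[sampled] <- y$data[sampled] + noise
  })
  y
}

# expand a frame mask (Nx,Ny,Nz,Nc,Nr) to k-space data dims by replicating
# across the coil axis (axis 4 of the data array); returns a logical vector
# aligned with the data layout.
replicate_mask <- function(mask, kdims) {
  nsp <- kdims[1] * kdims[2] * kdims[3]
  ncoils <- kdims[4]
  nframes <- kdims[5] * kdims[6]
  m <- array(as.vector(mask != 0), c(nsp, nframes))
  full <- array(FALSE, c(nsp, ncoils, nframes))
  for (c in seq_len(ncoils)) full[, c, ] <- m
  as.vector(full)
}

#' Simulate and write a complete synthetic dataset container
#'
#' Runs the full generator pipeline (phantom, coils, masks, acquisition)
#' and writes the HDF5 container including the ground-truth reference and
#' the \code{af}, \code{seed} and \code{snr_db} attributes.  The container
#' bytes are a deterministic function of the spec and arguments.
#'
#' @param path output container path.
#' @param spec a \code{\link{phantom_spec}}.
#' @param af acceleration factor.
#' @param snr_db SNR in dB (\code{Inf} = noiseless).
#' @param center_fraction passed to \code{\link{generate_masks}}.
#' @return Invisibly, the path.
#' @export
simulate_dataset <- function(path, spec = phantom_spec(), af = 4,
                             snr_db = Inf, center_fraction = 0.04) {
  truth <- generate_phantom(spec)
  coils <- generate_coils(spec)
  masks <- generate_masks(c(spec$nx, spec$ny, spec$nz), spec$Nc, spec$Nr,
                          af = af, center_fraction = center_fraction,
                          seed = spec$seed)
  y <- simulate_acquisition(truth, coils, masks, snr_db = snr_db,
                            seed = spec$seed + 1L)
  write_container(path, y, coils, reference = truth,
                  attrs = list(af = af, seed = spec$seed,
                               snr_db = if (is.finite(snr_db)) snr_db else -1))
  invisible(path)
}
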