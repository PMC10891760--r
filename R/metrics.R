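# Image-quality metrics for comparing reconstructions.  Complex images are
# compared by magnitude, the standard convention for MRI quality reporting.

# separable 3D Gaussian filtering with a 'valid' window (no padding): the
# output keeps only voxels whose window lies fully inside the volume.
gauss_kernel <- function(width, sigma) {
  h <- (width - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  g / sum(g)
}

filter_axis_valid <- function(a, g, axis) {
  d <- dim(a)
  w <- length(g)
  n_out <- d[axis] - w + 1L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- matrix(0, n_out, ncol(m))
  for (t in seq_len(w)) out <- out + g[t] * m[t:(t + n_out - 1L), , drop = FALSE]
  dim(out) <- c(n_out, d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

gauss_filter3_valid <- function(a, g) {
  a <- filter_axis_valid(a, g, 1L)
  a <- filter_axis_valid(a, g, 2L)
  filter_axis_valid(a, g, 3L)
}

# SSIM of two real 3D volumes with a Gaussian window.
ssim_volume <- function(a, b, data_range, width = 11L, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03) {
  d <- dim(a)
  w <- min(width, min(d))
  if (w %% 2 == 0) w <- w - 1L
  g <- gauss_kernel(w, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_a <- gauss_filter3_valid(a, g)
  mu_b <- gauss_filter3_valid(b, g)
  saa <- gauss_filter3_valid(a * a, g) - mu_a^2
  sbb <- gauss_filter3_valid(b * b, g) - mu_b^2
  sab <- gauss_filter3_valid(a * b, g) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * sab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2)
  mean(num / den)
}

#' Structural similarity of two 5D image series
#'
#' Mean over frames of the 3D windowed SSIM of the magnitude volumes
#' (Gaussian window, sigma = 1.5, 11-voxel support truncated to the volume;
#' constants K1 = 0.01, K2 = 0.03).  The data range is taken from the
#' reference \code{b} (max minus min magnitude over the whole series).
#'
#' @param a image series under test (\code{\link{image_series5d}}).
#' @param b reference image series.
#' @return A scalar in [-1, 1]; 1 for identical inputs.
#' @seealso \code{\link{quality_report}} for a per-frame breakdown.
#' @export
ssim_series <- function(a, b) {
  mean(ssim_frames(a, b))
}

ssim_frames <- function(a, b) {
  da <- series_dims(a); db <- series_dims(b)
  if (!all(da == db))
    stopf("image series shapes differ: (%s) vs (%s)",
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  magb <- Mod(b$data)
  maga <- Mod(a$data)
  dr <- max(magb) - min(magb)
  if (dr == 0) dr <- 1
  vals <- numeric(0)
  for (i in seq_len(da[5])) for (j in seq_len(da[4])) {
    vals <- c(vals, ssim_volume(maga[, , , j, i], magb[, , , j, i], dr))
  }
  vals
}

#' Peak signal-to-noise ratio of two 5D image series
#'
#' \eqn{10 \log_{10}(\mathrm{peak}^2 / \mathrm{MSE})} over magnitudes, with
#' peak the maximum magnitude of the reference \code{b}.  Identical inputs
#' give \code{Inf}.
#'
#' @param a image series under test.
#' @param b reference image series.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr_series <- function(a, b) {
  da <- series_dims(a); db <- series_dims(b)
  if (!all(da == db))
    stopf("image series shapes differ: (%s) vs (%s)",
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  mse <- mean((Mod(a$data) - Mod(b$data))^2)
  peak <- max(Mod(b$data))
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Quality report comparing two image series
#'
#' @param a image series under test.
#' @param b reference series.
#' @return A list of class \code{quality_report} with \code{ssim},
#'   \code{psnr_db} and a per-frame data frame \code{frames} (respiratory
#'   index, cardiac index, frame SSIM).
#' @export
quality_report <- function(a, b) {
  vals <- ssim_frames(a, b)
  d <- series_dims(a)
  frames <- data.frame(respiratory = rep(seq_len(d[5]), each = d[4]),
                       cardiac = rep(seq_len(d[4]), times = d[5]),
                       ssim = vals)
  structure(list(ssim = mean(vals), psnr_db = psnr_series(a, b),
                 frames = frames),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> SSIM = %.4f, PSNR = %s dB (%d frames)\n",
              x$ssim,
              if (is.finite(x$psnr_db)) sprintf("%.2f", x$psnr_db) else "Inf",
              nrow(x$frames)))
  invisible(x)
}

#' Serialize a quality report as JSON
#'
#' @param report a \code{quality_report}.
#' @param path optional output file.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(ssim = report$ssim,
              psnr_db = if (is.finite(report$psnr_db)) report$psnr_db else "Inf",
              frames = report$frames)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
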