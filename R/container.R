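#' Read and write the 5D acquisition container
#'
#' The package stores an acquisition (k-space, masks, coil maps, and
#' optionally a ground-truth reference and a reconstruction) in a single
#' HDF5 file.  HDF5 has no portable complex type in this toolchain, so every
#' complex dataset is stored as a pair of float64 datasets
#' \code{<name>_real} / \code{<name>_imag}:
#'
#' \preformatted{
#'   /kspace/data_real, /kspace/data_imag   (Nx, Ny, Nz, Ncoils, Nc, Nr)
#'   /kspace/mask                 uint8     (Nx, Ny, Nz, Nc, Nr)
#'   /coils/maps_real, /coils/maps_imag     (Nx, Ny, Nz, Ncoils)
#'   /reference/data_real, _imag  [optional](Nx, Ny, Nz, Nc, Nr)
#'   /recon/data_real, _imag      [optional](Nx, Ny, Nz, Nc, Nr)
#'   root attributes: af, voxel_size_mm, seed, snr_db (optional metadata)
#' }
#'
#' Dimensions above are in R (column-major) order with the respiratory phase
#' slowest; on disk the dataset shapes appear reversed, as usual for HDF5
#' written from column-major arrays.  Writing is deterministic: no
#' timestamps or environment information are stored, so identical objects
#' produce identical dataset contents.
#'
#' @param path file path of the container.
#' @param kspace a \code{\link{kspace5d}} object.
#' @param coils a \code{\link{coil_set}} object.
#' @param reference optional ground-truth \code{\link{image_series5d}}.
#' @param recon optional reconstructed \code{\link{image_series5d}}.
#' @param attrs named list of scalar metadata attributes (e.g. \code{af},
#'   \code{seed}, \code{snr_db}).
#' @return \code{write_container} returns \code{path} invisibly;
#'   \code{read_container} returns a list with elements \code{kspace},
#'   \code{coils}, \code{reference} (or \code{NULL}), \code{recon} (or
#'   \code{NULL}) and \code{attrs}.
#' @export
write_container <- function(path, kspace, coils, reference = NULL,
                            recon = NULL, attrs = list()) {
  if (!inherits(kspace, "kspace5d")) stopf("kspace must be a kspace5d object")
  if (!inherits(coils, "coil_set")) stopf("coils must be a coil_set object")
  check_consistent(y = kspace, coils = coils)
  vox <- c(1, 1, 1)
  for (obj in list(reference, recon)) {
    if (!is.null(obj)) {
      if (!inherits(obj, "image_series5d"))
        stopf("reference/recon must be image_series5d objects")
      check_consistent(m = obj, y = kspace)
      vox <- obj$voxel_size_mm
    }
  }
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stopf("cannot create HDF5 file at '%s'", path)
  on.exit(rhdf5::H5close(), add = TRUE)

  write_cplx <- function(group, name, arr) {
    rhdf5::h5write(Re(arr), path, paste0(group, "/", name, "_real"),
                   level = 0)
    rhdf5::h5write(Im(arr), path, paste0(group, "/", name, "_imag"),
                   level = 0)
  }
  rhdf5::h5createGroup(path, "kspace")
  write_cplx("/kspace", "data", kspace$data)
  msk <- kspace$mask
  storage.mode(msk) <- "integer"
  rhdf5::h5write(msk, path, "/kspace/mask", level = 0)
  rhdf5::h5createGroup(path, "coils")
  write_cplx("/coils", "maps", coils$maps)
  if (!is.null(reference)) {
    rhdf5::h5createGroup(path, "reference")
    write_cplx("/reference", "data", reference$data)
  }
  if (!is.null(recon)) {
    rhdf5::h5createGroup(path, "recon")
    write_cplx("/recon", "data", recon$data)
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.numeric(vox), fid, "voxel_size_mm")
  for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], fid, nm)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stopf("container file '%s' does not exist", path)
  on.exit(rhdf5::H5close(), add = TRUE)
  index <- rhdf5::h5ls(path)
  present <- paste0(index$group, "/", index$name)
  present <- sub("^//", "/", present)
  need <- c("/kspace/data_real", "/kspace/data_imag", "/kspace/mask",
            "/coils/maps_real", "/coils/maps_imag")
  for (ds in need)
    if (!ds %in% present)
      stopf("container '%s' is missing required dataset %s", path, ds)

  read_cplx <- function(name) {
    re <- rhdf5::h5read(path, paste0(name, "_real"))
    im <- rhdf5::h5read(path, paste0(name, "_imag"))
    if (!identical(dim(re), dim(im)))
      stopf("datasets %s_real and %s_imag have mismatched shapes", name, name)
    complex(real = re, imaginary = im, length.out = length(re)) |>
      array(dim = dim(re))
  }
  kdata <- read_cplx("/kspace/data")
  if (length(dim(kdata)) != 6L)
    stopf("dataset /kspace/data has %d dimensions; expected 6 (Nx, Ny, Nz, Ncoils, Nc, Nr)",
          length(dim(kdata)))
  mask <- rhdf5::h5read(path, "/kspace/mask")
  if (length(dim(mask)) != 5L)
    stopf("dataset /kspace/mask has %d dimensions; expected 5 (Nx, Ny, Nz, Nc, Nr)",
          length(dim(mask)))
  maps <- read_cplx("/coils/maps")
  if (length(dim(maps)) != 4L)
    stopf("dataset /coils/maps has %d dimensions; expected 4 (Nx, Ny, Nz, Ncoils)",
          length(dim(maps)))
  attrs <- rhdf5::h5readAttributes(path, "/")
  attrs <- lapply(attrs, as.vector)
  vox <- if (!is.null(attrs$voxel_size_mm)) attrs$voxel_size_mm else c(1, 1, 1)

  ks <- tryCatch(kspace5d(kdata, mask),
                 error = function(e) stopf("dataset /kspace is invalid: %s",
                                           conditionMessage(e)))
  cs <- tryCatch(coil_set(maps),
                 error = function(e) stopf("dataset /coils/maps is invalid: %s",
                                           conditionMessage(e)))
  check_consistent(y = ks, coils = cs)

  read_opt_series <- function(group) {
    if (!paste0(group, "/data_real") %in% present) return(NULL)
    arr <- read_cplx(paste0(group, "/data"))
    if (length(dim(arr)) != 5L)
      stopf("dataset %s/data has %d dimensions; expected 5", group,
            length(dim(arr)))
    ser <- image_series5d(arr, voxel_size_mm = vox)
    check_consistent(m = ser, y = ks)
    ser
  }
  list(kspace = ks, coils = cs,
       reference = read_opt_series("/reference"),
       recon = read_opt_series("/recon"),
       attrs = attrs)
}

#' Export the magnitude frames of an image series as NIfTI volumes
#'
#' Writes one 3D NIfTI file per frame, named
#' \code{<prefix>_r<i>_c<j>.nii.gz}.  Requires the \pkg{RNifti} package.
#'
#' @param series an \code{\link{image_series5d}}.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
export_nifti <- function(series, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("the RNifti package is required for NIfTI export")
  if (!inherits(series, "image_series5d")) stopf("series must be image_series5d")
  d <- series_dims(series)
  paths <- character(0)
  for (i in seq_len(d[5])) for (j in seq_len(d[4])) {
    vol <- Mod(series$data[, , , j, i])
    p <- sprintf("%s_r%02d_c%02d.nii.gz", prefix, i, j)
    img <- RNifti::asNifti(vol, pixdim = series$voxel_size_mm)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
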