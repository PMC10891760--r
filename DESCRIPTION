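Package: cine5d
Title: Partitioned Compressed-Sensing Reconstruction of 5D Cardiac CINE MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Staged NESTA (Nesterov-accelerated, Huber-smoothed l1) solver
    for temporal-total-variation regularized reconstruction of undersampled
    multicoil 5D cardiac CINE MRI: three spatial dimensions plus cardiac and
    respiratory phase dimensions.  The cardiac dimension can be partitioned
    across simulated devices that exchange boundary-frame (ghost)
    dependencies through synchronized per-dependency channels, reproducing
    the behaviour of a multi-device domain decomposition on a single
    machine.  Includes a dynamic beating/breathing numerical phantom,
    smooth coil-map simulation, variable-density Cartesian undersampling,
    an HDF5 container format, and SSIM/PSNR image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: rhdf5, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse, yaml, RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
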