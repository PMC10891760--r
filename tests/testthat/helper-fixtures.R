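# Fixtures are generated programmatically; nothing is read from disk.

rand_cplx <- function(dims) {
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
        dim = dims)
}

# random normalized coil maps (sum-of-squares = 1 everywhere)
rand_coils <- function(nx, ny, nz, ncoils) {
  maps <- rand_cplx(c(nx, ny, nz, ncoils)) + 2  # keep away from zero
  sos <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  for (c in seq_len(ncoils)) maps[, , , c] <- maps[, , , c] / sos
  coil_set(maps)
}

# a random consistent small problem: image, coils, mask and k-space whose
# data respect the mask support
rand_problem <- function(nx = 4, ny = 4, nz = 4, Nc = 3, Nr = 2, ncoils = 2,
                         undersample = 0.5) {
  coils <- rand_coils(nx, ny, nz, ncoils)
  m <- image_series5d(rand_cplx(c(nx, ny, nz, Nc, Nr)))
  mask <- array(rbinom(nx * ny * nz * Nc * Nr, 1, undersample),
                c(nx, ny, nz, Nc, Nr))
  ydat <- rand_cplx(c(nx, ny, nz, ncoils, Nc, Nr))
  for (c in seq_len(ncoils)) {
    sl <- ydat[, , , c, , , drop = FALSE]
    dim(sl) <- dim(mask)
    sl[mask == 0] <- 0
    ydat[, , , c, , ] <- sl
  }
  list(m = m, coils = coils, mask = mask, y = kspace5d(ydat, mask))
}

# small synthetic acquisition of the beating/breathing phantom
phantom_problem <- function(nx = 8, ny = 8, nz = 4, Nc = 6, Nr = 2,
                            ncoils = 2, af = 4, snr_db = Inf, seed = 11) {
  spec <- phantom_spec(nx = nx, ny = ny, nz = nz, Nc = Nc, Nr = Nr,
                       ncoils = ncoils, seed = seed)
  truth <- generate_phantom(spec)
  coils <- generate_coils(spec)
  masks <- generate_masks(c(nx, ny, nz), Nc, Nr, af = af, seed = seed)
  y <- simulate_acquisition(truth, coils, masks, snr_db = snr_db,
                            seed = seed + 1L)
  list(spec = spec, truth = truth, coils = coils, masks = masks, y = y)
}

# independent plain-loop SSIM of two real 3D volumes (brute-force oracle,
# deliberately unrelated to the package's separable-filter implementation)
ssim_bruteforce <- function(a, b, data_range, width = 7L, sigma = 1.5,
                            K1 = 0.01, K2 = 0.03) {
  h <- (width - 1) / 2
  off <- -h:h
  g1 <- exp(-off^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  w3 <- outer(outer(g1, g1), g1)
  d <- dim(a)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  vals <- c()
  for (x in (h + 1):(d[1] - h)) for (y in (h + 1):(d[2] - h))
    for (z in (h + 1):(d[3] - h)) {
      wa <- a[x + off, y + off, z + off]
      wb <- b[x + off, y + off, z + off]
      mua <- sum(w3 * wa); mub <- sum(w3 * wb)
      va <- sum(w3 * wa^2) - mua^2
      vb <- sum(w3 * wb^2) - mub^2
      vab <- sum(w3 * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * vab + C2)) /
                        ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  mean(vals)
}
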