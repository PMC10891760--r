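rel <- cine5d:::rel_diff

new_series <- function(x, pr) {
  m <- pr$m; m$data <- x; m
}

test_that("encoding operator and adjoint satisfy <Ex, y> = <x, E^H y>", {
  set.seed(101)
  for (rep in 1:5) {
    dims <- sample(3:6, 3, replace = TRUE)
    pr <- rand_problem(dims[1], dims[2], dims[3], Nc = sample(2:4, 1),
                       Nr = sample(1:3, 1), ncoils = sample(1:3, 1))
    ex <- apply_encoding(pr$m, pr$coils, pr$mask)
    ehy <- apply_encoding_adjoint(pr$y, pr$coils)
    lhs <- sum(Conj(ex$data) * pr$y$data)
    rhs <- sum(Conj(pr$m$data) * ehy$data)
    expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-12)
  }
})

test_that("encoding degenerates to the orthonormal FFT for a trivial system", {
  set.seed(102)
  m <- image_series5d(rand_cplx(c(4, 4, 4, 2, 1)))
  coils <- coil_set(array(1 + 0i, c(4, 4, 4, 1)))
  mask <- array(1, c(4, 4, 4, 2, 1))
  ex <- apply_encoding(m, coils, mask)
  for (j in 1:2)
    expect_lt(rel(ex$data[, , , 1, j, 1],
                  stats::fft(m$data[, , , j, 1]) / 8), 1e-12)
  # E^H E = identity here (unitary FFT, full mask, flat single coil)
  back <- apply_encoding_adjoint(ex, coils)
  expect_lt(rel(back$data, m$data), 1e-12)
})

test_that("ttv_forward matches hand-computed differences and shapes", {
  a <- array(0i, c(1, 1, 1, 3, 2))
  a[1, 1, 1, , 1] <- c(1, 4, 9)
  a[1, 1, 1, , 2] <- c(2, 2, 2)
  p <- ttv_forward(a)
  expect_identical(dim(p$cardiac), c(1L, 1L, 1L, 2L, 2L))
  expect_identical(dim(p$respiratory), c(1L, 1L, 1L, 3L, 1L))
  expect_equal(as.vector(p$cardiac[1, 1, 1, , 1]), c(3 + 0i, 5 + 0i))
  expect_equal(as.vector(p$cardiac[1, 1, 1, , 2]), c(0i, 0i))
  expect_equal(as.vector(p$respiratory[1, 1, 1, , 1]),
               c(1 + 0i, -2 + 0i, -7 + 0i))
  # no circular wrap: last-to-first difference is never formed
  pw <- ttv_forward(a, weights = c(2, 0.5))
  expect_equal(as.vector(pw$cardiac[1, 1, 1, , 1]), c(6 + 0i, 10 + 0i))
  expect_equal(as.vector(pw$respiratory[1, 1, 1, 1, 1]), 0.5 + 0i)
})

test_that("ttv handles Nr = 1 with a zero-extent respiratory block", {
  a <- array(1i * (1:8), c(2, 2, 1, 2, 1))
  p <- ttv_forward(a)
  expect_identical(dim(p$respiratory), c(2L, 2L, 1L, 2L, 0L))
  back <- ttv_adjoint(p)
  expect_identical(dim(back$data), dim(a))
})

test_that("ttv_adjoint is the exact adjoint of ttv_forward", {
  set.seed(103)
  for (w in list(c(1, 1), c(2, 0.5))) {
    a <- rand_cplx(c(3, 4, 2, 5, 3))
    p <- ttv_forward(a, w)
    q <- ttv_forward(rand_cplx(c(3, 4, 2, 5, 3)), w)  # random codomain element
    lhs <- sum(Conj(p$cardiac) * q$cardiac) +
           sum(Conj(p$respiratory) * q$respiratory)
    rhs <- sum(Conj(a) * ttv_adjoint(q)$data)
    expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-12)
  }
})

test_that("ttv_adjoint places a unit difference on its two endpoint frames", {
  p <- ttv_forward(array(0i, c(1, 1, 1, 3, 1)))
  p$cardiac[1, 1, 1, 1, 1] <- 1 + 0i
  back <- ttv_adjoint(p)
  expect_equal(as.vector(back$data), c(-1 + 0i, 1 + 0i, 0i))
})

test_that("huber value matches hand-computed branch values", {
  expect_equal(huber_value(0i, 1), 0)
  expect_equal(huber_value(3 + 0i, 1), 2.5)           # |z| - mu/2
  expect_equal(huber_value(0.5 + 0i, 1), 0.125)       # |z|^2 / (2 mu)
  expect_equal(huber_value(1 + 0i, 1), 0.5)           # knee: both branches
  expect_equal(huber_value(0 + 4i, 2), 3)
  expect_equal(huber_value(c(3 + 0i, 0.5 + 0i), 1), 2.625)  # sums entries
  expect_error(huber_value(1 + 0i, 0), "positive")
})

test_that("huber gradient is z/max(|z|,mu) with magnitude <= 1", {
  expect_equal(huber_grad(0.5 + 0i, 1), 0.5 + 0i)
  expect_equal(huber_grad(3i, 1), 1i)
  expect_equal(huber_grad(3 + 4i, 1), (3 + 4i) / 5)
  set.seed(104)
  u <- rand_cplx(c(4, 4, 1, 3, 2))
  expect_lte(max(Mod(huber_grad(u, 0.3))), 1 + 1e-12)
  # central-difference check of d/dt huber(t + ci) at points on both branches
  for (t0 in c(0.1, 2.0)) {
    h <- 1e-6
    num <- (huber_value(t0 + h + 0.2i, 0.5) -
            huber_value(t0 - h + 0.2i, 0.5)) / (2 * h)
    expect_equal(Re(huber_grad(t0 + 0.2i, 0.5)), num, tolerance = 1e-6)
  }
})

test_that("huber value lower-bounds the l1 norm and converges to it", {
  set.seed(105)
  u <- rand_cplx(c(5, 5, 1, 2, 1))
  l1 <- sum(Mod(u))
  prev_gap <- Inf
  for (mu in c(1, 1e-3, 1e-6)) {
    h <- huber_value(u, mu)
    expect_lte(h, l1 + 1e-12)
    gap <- l1 - h
    expect_lte(gap, prev_gap)
    prev_gap <- gap
  }
  expect_lt(prev_gap / l1, 1e-5)
})

test_that("objective matches the hand-computed toy case", {
  # one voxel, two cardiac phases, m = 0: f = 0.5 * |y|^2 = 0.5 * 4 = 2
  m <- image_series5d(array(0i, c(1, 1, 1, 2, 1)))
  coils <- coil_set(array(1 + 0i, c(1, 1, 1, 1)))
  mask <- array(1, c(1, 1, 1, 2, 1))
  ydat <- array(0i, c(1, 1, 1, 1, 2, 1))
  ydat[1, 1, 1, 1, 1, 1] <- 2 + 0i
  y <- kspace5d(ydat, mask)
  expect_equal(objective_value(m, y, coils, lambda_reg = 5, mu = 1), 2)
  # and with a nonzero m the regularizer contributes lambda * h_mu(diff)
  m2 <- image_series5d(array(c(0i, 3 + 0i), c(1, 1, 1, 2, 1)))
  f2 <- objective_value(m2, y, coils, lambda_reg = 2, mu = 1)
  expect_equal(f2, 0.5 * (4 + 9) + 2 * 2.5)
})

test_that("gradient matches central differences of the objective", {
  set.seed(106)
  pr <- rand_problem(3, 3, 2, Nc = 3, Nr = 2, ncoils = 2)
  lambda <- 0.3; mu <- 0.4
  g <- objective_gradient(pr$m, pr$y, pr$coils, lambda, mu)
  h <- 1e-5
  idx <- cbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 1), c(1, 2, 3), c(1, 2, 2))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, , drop = FALSE]
    probe <- function(delta) {
      mm <- pr$m
      mm$data[i] <- mm$data[i] + delta
      objective_value(mm, pr$y, pr$coils, lambda, mu)
    }
    # complex gradient convention: df/dRe = Re(g), df/dIm = Im(g)
    dre <- (probe(h) - probe(-h)) / (2 * h)
    dim_ <- (probe(1i * h) - probe(-1i * h)) / (2 * h)
    expect_equal(dre, Re(g$data[i]), tolerance = 1e-5)
    expect_equal(dim_, Im(g$data[i]), tolerance = 1e-5)
  }
})

test_that("gradient vanishes at an exactly consistent, temporally flat image", {
  set.seed(107)
  vol <- rand_cplx(c(4, 4, 2, 1, 1))
  m <- image_series5d(array(rep(vol, 6), c(4, 4, 2, 3, 2)))
  coils <- rand_coils(4, 4, 2, 2)
  mask <- array(1, c(4, 4, 2, 3, 2))
  y <- apply_encoding(m, coils, mask)
  # note: E^H E != I for non-flat coils, but the residual is exactly zero
  g <- objective_gradient(m, y, coils, lambda_reg = 0.5, mu = 0.1)
  expect_lt(max(Mod(g$data)), 1e-12)
})

test_that("regularization gradient is local to adjacent phases", {
  set.seed(108)
  lam_of <- function(a, mu = 0.2) {
    p <- ttv_forward(a)
    p$cardiac <- huber_grad(p$cardiac, mu)
    if (length(p$respiratory) > 0) p$respiratory <- huber_grad(p$respiratory, mu)
    ttv_adjoint(p)$data
  }
  a <- rand_cplx(c(2, 2, 1, 6, 3))
  lam <- lam_of(a)
  # perturbing phase (j=6, i=3) must not change Lambda at (j<=4, any i) or
  # (any j, i=1): only (i, j +/- 1) and (i +/- 1, j) neighbours may react
  b <- a
  b[, , , 6, 3] <- b[, , , 6, 3] + 10
  lam2 <- lam_of(b)
  expect_identical(lam[, , , 1:4, ], lam2[, , , 1:4, ])
  expect_identical(lam[, , , , 1], lam2[, , , , 1])
  expect_false(identical(lam[, , , 5, 3], lam2[, , , 5, 3]))
})

test_that("operator norms respect their analytic bounds", {
  set.seed(109)
  pr <- rand_problem(4, 4, 3, Nc = 4, Nr = 2, ncoils = 2, undersample = 0.6)
  nE <- cine5d:::power_iteration_norm2(
    function(x) apply_encoding(new_series(x, pr), pr$coils, pr$mask)$data,
    function(z) apply_encoding_adjoint(cine5d:::new_kspace5d(z, pr$mask),
                                       pr$coils)$data,
    pr$m$data, n_iter = 30)
  expect_lte(nE, 1 + 1e-9)
  nPhi <- cine5d:::power_iteration_norm2(
    function(x) { p <- ttv_forward(x); c(p$cardiac, p$respiratory) },
    function(v) {
      p <- ttv_forward(array(0i, dim(pr$m$data)))
      nc <- length(p$cardiac)
      p$cardiac[] <- v[seq_len(nc)]
      if (length(p$respiratory) > 0) p$respiratory[] <- v[-seq_len(nc)]
      ttv_adjoint(p)$data
    },
    pr$m$data, n_iter = 30)
  expect_lte(nPhi, 8 + 1e-9)   # ||Phi||^2 <= 4 w_c^2 + 4 w_r^2 = 8
  expect_gt(nPhi, 4)           # and it is not vacuous on this problem
})

test_that("fused device_fg agrees with objective_value/objective_gradient", {
  set.seed(110)
  pr <- rand_problem(3, 4, 2, Nc = 4, Nr = 2, ncoils = 2)
  lambda <- 0.2; mu <- 0.3
  fg <- cine5d:::device_fg(pr$m$data, pr$y$data, pr$y$mask, pr$coils$maps,
                           NULL, NULL, lambda, mu, c(1, 1))
  expect_equal(fg$f, objective_value(pr$m, pr$y, pr$coils, lambda, mu))
  expect_equal(fg$g, objective_gradient(pr$m, pr$y, pr$coils, lambda, mu)$data)
})
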