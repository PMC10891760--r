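# Internal numeric helpers shared by the operator and solver code.

# Orthonormal 3D DFT of a 3D complex array (unitary scaling, so the
# encoding-operator norm bound ||E|| <= 1 holds with normalized coils).
fft3o <- function(a) stats::fft(a) / sqrt(length(a))

ifft3o <- function(a) stats::fft(a, inverse = TRUE) / sqrt(length(a))

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Relative difference of two arrays, guarded for a zero reference.
rel_diff <- function(a, b) {
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(sqrt(sum(Mod(a)^2)))
  sqrt(sum(Mod(a - b)^2)) / nb
}

cplx_inner <- function(a, b) sum(Conj(a) * b)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
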