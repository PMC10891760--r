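#' Build the \eqn{\mu}-continuation schedule
#'
#' One stage per smoothing width: \eqn{\mu_s = \mu_0 \gamma^{s-1}} with
#' \eqn{\gamma = (\mu_{final}/\mu_0)^{1/(n_{stages}-1)}} (geometric
#' interpolation, strictly decreasing).  Each stage also carries the
#' gradient Lipschitz bound
#' \eqn{L_s = \|E\|^2 + \lambda \|\Phi\|^2 / \mu_s}, computable as
#' \eqn{1 + \lambda (4 w_c^2 + 4 w_r^2)/\mu_s} for normalized coils and the
#' orthonormal DFT.
#'
#' @param mu0 initial smoothing width (\eqn{\mu_0 > \mu_{final}}).
#' @param mu_final final smoothing width.
#' @param n_stages number of stages; with \code{n_stages = 1},
#'   \code{mu0} must equal \code{mu_final}.
#' @param lambda_reg regularization weight used for the Lipschitz bounds.
#' @param ttv_weights length-2 cardiac/respiratory difference weights.
#' @return A list of class \code{stage_schedule} with numeric vectors
#'   \code{mus} and \code{lipschitz}.
#' @export
build_schedule <- function(mu0, mu_final, n_stages, lambda_reg,
                           ttv_weights = c(1, 1)) {
  if (!is_scalar_num(mu0) || mu0 <= 0) stopf("mu0 must be positive")
  if (!is_scalar_num(mu_final) || mu_final <= 0)
    stopf("mu_final must be positive")
  if (!is_count(n_stages)) stopf("n_stages must be a count >= 1")
  if (n_stages == 1L) {
    if (mu0 != mu_final)
      stopf("with a single stage, mu0 (%.3g) must equal mu_final (%.3g)",
            mu0, mu_final)
    mus <- mu0
  } else {
    if (mu0 <= mu_final)
      stopf("mu0 (%.3g) must exceed mu_final (%.3g)", mu0, mu_final)
    gamma <- (mu_final / mu0)^(1 / (n_stages - 1))
    mus <- mu0 * gamma^(seq_len(n_stages) - 1)
  }
  phi_norm2 <- 4 * ttv_weights[1]^2 + 4 * ttv_weights[2]^2
  structure(list(mus = mus, lipschitz = 1 + lambda_reg * phi_norm2 / mus),
            class = "stage_schedule")
}

#' Progress quotient stopping statistic
#'
#' The per-stage stopping rule statistic
#' \deqn{q_p^k = (\bar f - f_k) / \bar f}
#' where \eqn{\bar f} is the mean of the objective over the last \eqn{\tau}
#' iterations (including the current one) and \eqn{f_k} the current value.
#' It is only defined once at least \eqn{\tau} iterations have been
#' recorded; a stage halts when \eqn{q_p \le} \code{tol}.
#'
#' @param history numeric vector of per-iteration objective values within
#'   the current stage.
#' @param tau minimum window length (default 7).
#' @return The progress quotient (0 when the recent objective is exactly 0).
#' @export
progress_quotient <- function(history, tau = 7L) {
  if (!is_count(tau)) stopf("tau must be a count >= 1")
  n <- length(history)
  if (n < tau)
    stopf("progress quotient needs at least tau = %d iterations; have %d",
          tau, n)
  fbar <- mean(history[(n - tau + 1L):n])
  if (fbar == 0) return(0)
  (fbar - history[n]) / fbar
}

# One Nesterov update from iterate x at iteration k (0-based):
#   y_k = x_k - g_k / L
#   z_k = x_stage_init - (1/L) sum_{i<=k} alpha_i g_i,  alpha_i = (i+1)/2
#   x_{k+1} = tau_k z_k + (1 - tau_k) y_k,              tau_k = 2/(k+3)
# `acc` carries the running sum of alpha_i g_i.
nesta_step <- function(x, g, x0, acc, L, k) {
  y <- x - g / L
  acc <- acc + ((k + 1) / 2) * g
  z <- x0 - acc / L
  tk <- 2 / (k + 3)
  list(x_next = tk * z + (1 - tk) * y, y = y, acc = acc)
}

#' Run one NESTA stage
#'
#' Nesterov-accelerated descent on the smoothed objective at fixed \eqn{\mu},
#' recording \eqn{f(x_k)} at every iteration and halting when the
#' \code{\link{progress_quotient}} drops to \code{tol} or below (after at
#' least \code{tau} iterations), or at \code{max_iter} iterations.  The
#' stage solution is the final gradient-step iterate \eqn{y_k}.
#'
#' @param x_init complex 5D array, the stage starting point (warm start).
#' @param fg_fn function(x) returning \code{list(f = objective value,
#'   g = gradient array)} at \code{x} (fused evaluation: objective and
#'   gradient share one application of the encoding operator).
#' @param L Lipschitz bound for this stage.
#' @param tau,tol,max_iter stopping parameters (see
#'   \code{\link{recon_config}}).
#' @param stopping logical; \code{FALSE} disables the tolerance test so the
#'   stage always runs \code{max_iter} iterations.
#' @param stage_index stage number, used in diagnostics.
#' @return A list with \code{solution} (the final \eqn{y_k} array),
#'   \code{history} (objective values, one per iteration) and
#'   \code{iterations}.
#' @export
run_stage <- function(x_init, fg_fn, L, tau = 7L, tol = 1e-5,
                      max_iter = 100L, stopping = TRUE, stage_index = 1L) {
  if (max_iter < tau) stopf("max_iter (%d) must be >= tau (%d)", max_iter, tau)
  x <- x_init
  x0 <- x_init
  acc <- array(0i, dim(x_init))
  history <- numeric(0)
  k <- 0L
  repeat {
    fg <- fg_fn(x)
    g <- fg$g
    f <- fg$f
    if (!is.finite(f))
      stopf("objective diverged (non-finite value) at stage %d, iteration %d",
            stage_index, k + 1L)
    history <- c(history, f)
    st <- nesta_step(x, g, x0, acc, L, k)
    n <- length(history)
    if ((stopping && n >= tau && progress_quotient(history, tau) <= tol) ||
        n >= max_iter) {
      return(list(solution = st$y, history = history, iterations = n))
    }
    acc <- st$acc
    x <- st$x_next
    k <- k + 1L
  }
}

# Data-scaled solver constants: initial smoothing width from the dynamic
# range of the temporal differences of the zero-filled image, and the
# default regularization weight from its peak magnitude.
initial_mu0 <- function(m0, ttv_weights) {
  p <- ttv_forward(m0, ttv_weights)
  v <- max(Mod(p$cardiac),
           if (length(p$respiratory) > 0) max(Mod(p$respiratory)) else 0)
  if (v <= 0) 1e-3 else 0.9 * v   # fallback for temporally constant data
}

default_lambda <- function(m0) {
  v <- max(Mod(m0$data))
  if (v <= 0) 0 else 0.01 * v
}

resolve_constants <- function(mu0, config) {
  lambda <- config$lambda_reg          # may be NULL -> caller supplies
  mu_final <- if (is.null(config$mu_final)) {
    if (config$n_stages == 1L) mu0 else mu0 * 1e-3
  } else config$mu_final
  list(mu_final = mu_final, lambda = lambda)
}

#' Single-device staged NESTA reconstruction
#'
#' Initializes with the zero-filled adjoint \eqn{m^0 = E^H y}, sets
#' \eqn{\mu_0 = 0.9 \max |\Phi m^0|_\infty}, then runs \code{n_stages}
#' NESTA stages with geometrically decreasing \eqn{\mu}, each warm-started
#' from the previous stage's solution.
#'
#' @param y acquired \code{\link{kspace5d}}.
#' @param coils \code{\link{coil_set}}.
#' @param config a \code{\link{recon_config}}.
#' @param record optional: \code{"iterates"} or \code{"gradients"} to attach
#'   the per-iteration arrays of the run (used by equivalence audits); by
#'   default nothing is recorded.
#' @return A list of class \code{cine5d_recon} with elements \code{image}
#'   (an \code{\link{image_series5d}}), \code{histories} (list of per-stage
#'   objective-value vectors), \code{schedule}, \code{lambda_reg},
#'   \code{mu0}, and (if requested) \code{recorded}.
#' @export
run_reconstruction <- function(y, coils, config = recon_config(),
                               record = NULL) {
  if (!inherits(y, "kspace5d")) stopf("y must be a kspace5d object")
  if (!inherits(coils, "coil_set")) stopf("coils must be a coil_set object")
  if (!inherits(config, "recon_config")) stopf("config must be a recon_config")
  check_consistent(y = y, coils = coils)
  m0 <- apply_encoding_adjoint(y, coils)
  mu0 <- initial_mu0(m0, config$ttv_weights)
  cst <- resolve_constants(mu0, config)
  lambda <- if (is.null(cst$lambda)) default_lambda(m0) else cst$lambda
  sched <- build_schedule(mu0, cst$mu_final, config$n_stages, lambda,
                          config$ttv_weights)
  w <- config$ttv_weights
  rec_env <- if (!is.null(record)) new.env(parent = emptyenv()) else NULL
  if (!is.null(rec_env)) rec_env$frames <- list()
  fg_fn <- function(x) {
    fg <- device_fg(x, y$data, y$mask, coils$maps, NULL, NULL, lambda,
                    mu_cur, w)
    if (!is.null(rec_env)) {
      rec_env$frames[[length(rec_env$frames) + 1L]] <-
        if (identical(record, "gradients")) fg$g else x
    }
    fg
  }

  x <- m0$data
  histories <- vector("list", config$n_stages)
  for (s in seq_len(config$n_stages)) {
    mu_cur <- sched$mus[s]
    st <- run_stage(x, fg_fn, sched$lipschitz[s],
                    tau = config$tau, tol = config$tol,
                    max_iter = config$max_iter_per_stage,
                    stopping = config$local_stopping, stage_index = s)
    histories[[s]] <- st$history
    x <- st$solution
  }
  out <- list(image = new_image_series5d(x), histories = histories,
              schedule = sched, lambda_reg = lambda, mu0 = mu0)
  if (!is.null(rec_env)) out$recorded <- rec_env$frames
  class(out) <- "cine5d_recon"
  out
}

#' @export
print.cine5d_recon <- function(x, ...) {
  iters <- vapply(x$histories, length, integer(1))
  cat(sprintf("<cine5d_recon> %d stage(s): %s = %d iterations; lambda = %.4g, mu0 = %.4g\n",
              length(iters), paste(iters, collapse = " + "), sum(iters),
              x$lambda_reg, x$mu0))
  invisible(x)
}

#' Export per-stage objective histories as CSV
#'
#' @param histories list of numeric vectors (one per stage), as returned in
#'   a \code{cine5d_recon}.
#' @param path output CSV path (columns: stage, iteration, objective).
#' @return The path, invisibly.
#' @export
export_histories_csv <- function(histories, path) {
  df <- do.call(rbind, lapply(seq_along(histories), function(s) {
    data.frame(stage = s, iteration = seq_along(histories[[s]]),
               objective = histories[[s]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
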