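# Multi-device orchestration: per-device NESTA solvers over a cardiac
# partition, exchanging boundary-frame (ghost) dependencies through
# per-dependency channels.  Devices are simulated as cooperating workers in
# one process; the synchronization protocol (shared constants, stage
# barrier, per-iteration publish/retrieve, final-update notification) is
# reproduced exactly and audited through the trace log.

#' Share per-device constants
#'
#' The stage schedules of all devices must be consistent with the global
#' (unpartitioned) solver, so data-scaled constants (the maximum temporal
#' difference magnitude for \eqn{\mu_0}, the peak zero-filled magnitude for
#' the default \eqn{\lambda}) are computed locally and reduced to their
#' global maximum, delivered identically to every device.
#'
#' @param values one finite numeric value per device.
#' @return The maximum, as a scalar.
#' @export
share_constants <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)))
    stopf("share_constants requires one finite value per device")
  max(values)
}

#' Dependency channels of a partition plan
#'
#' Creates one communication channel per directed ghost-frame dependency
#' (see \code{\link{dependency_pairs}}).  Each channel holds the most
#' recently published payload (all \code{Nr} respiratory phases of one
#' boundary cardiac phase) with a \code{(stage, iteration)} stamp and a
#' flag marking a producer's final in-stage update.  Payload replacement is
#' atomic (last writer wins) and retrieval never blocks: a consumer reuses
#' the latest payload when no new update has been published.
#'
#' @param plan a \code{\link{partition_cardiac}} plan.
#' @return An object of class \code{dependency_channels}.
#' @export
dependency_channels <- function(plan) {
  pairs <- dependency_pairs(plan)
  chans <- new.env(parent = emptyenv())
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      key <- sprintf("%d->%d", pairs$producer[r], pairs$consumer[r])
      ch <- new.env(parent = emptyenv())
      ch$payload <- NULL; ch$stage <- NA_integer_; ch$iter <- NA_integer_
      ch$final <- FALSE; ch$phase <- pairs$phase[r]
      assign(key, ch, envir = chans)
    }
  }
  structure(list(channels = chans, pairs = pairs, plan = plan),
            class = "dependency_channels")
}

#' Publish a device's boundary frames to its outgoing channels
#'
#' Replaces the payload of every channel produced by \code{device} with the
#' given boundary frames, stamped \code{(stage, iteration)}.  A no-op when
#' the device has no outgoing dependencies (single-device plans).
#'
#' @param ch a \code{\link{dependency_channels}} object.
#' @param device producing device index.
#' @param frames named list mapping cardiac phase index (as character) to a
#'   complex array \code{(Nx, Ny, Nz, Nr)} of that phase's respiratory
#'   frames.
#' @param stage,iteration stamp recorded with the payload.
#' @param final logical, marks the producer's last in-stage update.
#' @return Invisibly, the number of channels updated.
#' @export
publish_dependencies <- function(ch, device, frames, stage, iteration,
                                 final = FALSE) {
  pairs <- ch$pairs
  idx <- which(pairs$producer == device)
  for (r in idx) {
    key <- sprintf("%d->%d", pairs$producer[r], pairs$consumer[r])
    chan <- get(key, envir = ch$channels)
    fr <- frames[[as.character(pairs$phase[r])]]
    if (is.null(fr))
      stopf("device %d must publish cardiac phase %d but did not provide it",
            device, pairs$phase[r])
    chan$payload <- fr
    chan$stage <- as.integer(stage)
    chan$iter <- as.integer(iteration)
    chan$final <- isTRUE(final)
  }
  invisible(length(idx))
}

#' Retrieve a device's ghost frames from its incoming channels
#'
#' Returns the latest payloads published for \code{device}, without
#' blocking: if a producer has not published since the consumer's last
#' retrieval the previous payload is returned again (and, after a
#' producer's final in-stage update, that final payload thereafter).
#'
#' @param ch a \code{\link{dependency_channels}} object.
#' @param device consuming device index.
#' @return A list with entries \code{left} and \code{right} (each
#'   \code{NULL} or \code{list(payload, stage, iter, final, phase)}).
#' @export
retrieve_dependencies <- function(ch, device) {
  pairs <- ch$pairs
  idx <- which(pairs$consumer == device)
  out <- list(left = NULL, right = NULL)
  first <- ch$plan$partitions[[device]]$first
  for (r in idx) {
    key <- sprintf("%d->%d", pairs$producer[r], pairs$consumer[r])
    chan <- get(key, envir = ch$channels)
    item <- list(payload = chan$payload, stage = chan$stage, iter = chan$iter,
                 final = chan$final, phase = chan$phase)
    if (pairs$phase[r] < first) out$left <- item else out$right <- item
  }
  out
}

# --- device-local operator evaluations -------------------------------------
# (the fused local objective/gradient evaluation device_fg lives with the
# operators; each local objective is a stopping statistic computed "with the
# data the device works with": assigned frames plus ghosts)

extend_cardiac <- function(x, ghL, ghR) {
  d <- dim(x)
  parts <- list()
  if (!is.null(ghL)) parts <- c(parts, list(array(ghL, c(d[1:3], 1L, d[5]))))
  parts <- c(parts, list(x))
  if (!is.null(ghR)) parts <- c(parts, list(array(ghR, c(d[1:3], 1L, d[5]))))
  if (length(parts) == 1L) return(x)
  ne <- sum(vapply(parts, function(p) dim(p)[4], numeric(1)))
  out <- array(0i, c(d[1:3], ne, d[5]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[4]
    out[, , , (at + 1L):(at + np), ] <- p
    at <- at + np
  }
  out
}

# ghL is (Nx,Ny,Nz,Nr): array() recycling in extend_cardiac relies on exact
# length match (one cardiac slot), which holds by construction.

boundary_frames <- function(x, part, plan) {
  # named list of the device's produced boundary phases, (Nx,Ny,Nz,Nr) each
  out <- list()
  nloc <- part$last - part$first + 1L
  take <- function(j) {
    arr <- x[, , , j, , drop = FALSE]
    dim(arr) <- dim(x)[c(1:3, 5)]
    arr
  }
  if (part$device > 1L) out[[as.character(part$first)]] <- take(1L)
  if (part$device < plan$d) out[[as.character(part$last)]] <- take(nloc)
  out
}

# --- the partitioned run ---------------------------------------------------

#' Partitioned multi-device reconstruction
#'
#' Runs one NESTA solver per simulated device over its cardiac partition.
#' Per stage, devices exchange their boundary frames through the dependency
#' channels immediately before each gradient evaluation, evaluate their
#' local objective and stopping rule on the data they hold (assigned frames
#' plus ghosts), and synchronize at stage boundaries so no payload ever
#' crosses stages.  A device that converges ahead of the others publishes
#' its final boundary frames once more and goes idle; its consumers keep
#' using that final payload.  After the last stage the assigned subsets are
#' concatenated into the full 5D image.
#'
#' In \code{lockstep} mode all devices advance together (publish phase,
#' retrieve phase, compute phase), which is deterministic and makes every
#' retrieved payload stamp equal the consumer's own (stage, iteration).  In
#' \code{concurrent} mode devices advance one iteration per round in a
#' seeded random order, each publishing, retrieving and computing in turn,
#' so early-scheduled devices see neighbours' previous-iteration payloads —
#' a deterministic simulation of asynchronous workers.
#'
#' @param y acquired \code{\link{kspace5d}}.
#' @param coils \code{\link{coil_set}}.
#' @param config \code{\link{recon_config}}; \code{n_devices},
#'   \code{device_capacities}, \code{exec_mode}, \code{local_stopping} and
#'   \code{split} control the decomposition.
#' @param record_gradients logical; record, per synchronized iteration, the
#'   concatenation of the per-device gradients over their assigned frames
#'   (meaningful in lockstep mode with \code{local_stopping = FALSE}, where
#'   all devices stay synchronized for the whole stage).
#' @return A list of class \code{cine5d_partitioned} with elements
#'   \code{image}, \code{device_histories} (per device, per stage objective
#'   vectors), \code{plan}, \code{schedule}, \code{lambda_reg}, \code{mu0},
#'   \code{trace} (event data frame) and optionally \code{recorded_gradients}.
#' @export
run_partitioned <- function(y, coils, config = recon_config(n_devices = 2L,
                                                            exec_mode = "lockstep"),
                            record_gradients = FALSE) {
  if (!inherits(y, "kspace5d")) stopf("y must be a kspace5d object")
  if (!inherits(coils, "coil_set")) stopf("coils must be a coil_set object")
  check_consistent(y = y, coils = coils)
  dk <- kspace_dims(y)
  Nc <- dk[5]; Nr <- dk[6]
  d <- config$n_devices
  if (d > Nc) stopf("n_devices (%d) must not exceed Nc (%d)", d, Nc)
  mode <- config$exec_mode
  if (mode == "single" && d > 1L)
    stopf("exec_mode 'single' requires n_devices = 1")
  plan <- partition_cardiac(Nc, Nr, config$device_capacities,
                            split = config$split)
  ch <- dependency_channels(plan)
  w <- config$ttv_weights
  maps <- coils$maps

  trace <- list()
  note <- function(device, stage, iteration, event, p_stage = NA, p_iter = NA) {
    trace[[length(trace) + 1L]] <<- list(device = device, stage = stage,
                                         iteration = iteration, event = event,
                                         payload_stage = p_stage,
                                         payload_iter = p_iter)
  }

  # device-local data and zero-filled initialization
  devs <- lapply(plan$partitions, function(p) {
    jr <- p$first:p$last
    y_data <- y$data[, , , , jr, , drop = FALSE]
    y_mask <- y$mask[, , , jr, , drop = FALSE]
    dim(y_data) <- c(dk[1:4], length(jr), Nr)
    dim(y_mask) <- c(dk[1:3], length(jr), Nr)
    e <- new.env(parent = emptyenv())
    e$part <- p; e$y_data <- y_data; e$y_mask <- y_mask
    e$x <- apply_encoding_adjoint(new_kspace5d(y_data, y_mask), coils)$data
    e$ghL <- NULL; e$ghR <- NULL
    e$stage_iters <- integer(0)
    e$histories <- list()
    e
  })

  publish_x <- function(e, stage, iter, final = FALSE) {
    fr <- boundary_frames(e$x, e$part, plan)
    publish_dependencies(ch, e$part$device, fr, stage, iter, final = final)
    if (length(fr) > 0) note(e$part$device, stage, iter,
                             if (final) "final_publish" else "publish")
  }
  retrieve_x <- function(e, stage, iter) {
    got <- retrieve_dependencies(ch, e$part$device)
    if (!is.null(got$left)) {
      e$ghL <- got$left$payload
      note(e$part$device, stage, iter, "retrieve", got$left$stage,
           got$left$iter)
    }
    if (!is.null(got$right)) {
      e$ghR <- got$right$payload
      note(e$part$device, stage, iter, "retrieve", got$right$stage,
           got$right$iter)
    }
  }

  # S.0: shared constants, computed from the zero-filled initialization so
  # local stage schedules match the global solver exactly.
  for (e in devs) publish_x(e, 0L, 0L)
  for (e in devs) retrieve_x(e, 0L, 0L)
  local_mu0 <- vapply(devs, function(e) {
    ext <- extend_cardiac(e$x, e$ghL, e$ghR)
    ne <- dim(ext)[4]
    v <- if (ne >= 2L)
      max(Mod(w[1] * (ext[, , , 2:ne, , drop = FALSE] -
                      ext[, , , 1:(ne - 1), , drop = FALSE])))
    else 0
    if (Nr >= 2L)
      v <- max(v, max(Mod(w[2] * (e$x[, , , , 2:Nr, drop = FALSE] -
                                  e$x[, , , , 1:(Nr - 1), drop = FALSE]))))
    v
  }, numeric(1))
  mu0_raw <- share_constants(local_mu0)
  mu0 <- if (mu0_raw <= 0) 1e-3 else 0.9 * mu0_raw
  lambda <- if (is.null(config$lambda_reg)) {
    peak <- share_constants(vapply(devs, function(e) max(Mod(e$x)), numeric(1)))
    if (peak <= 0) 0 else 0.01 * peak
  } else config$lambda_reg
  cst <- resolve_constants(mu0, config)
  sched <- build_schedule(mu0, cst$mu_final, config$n_stages, lambda, w)

  recorded <- if (record_gradients) list() else NULL
  run_seed <- config$seed

  run <- function() {
    for (s in seq_len(config$n_stages)) {
      mu_s <- sched$mus[s]; L_s <- sched$lipschitz[s]
      for (e in devs) {
        e$x0 <- e$x
        e$acc <- array(0i, dim(e$x))
        e$history <- numeric(0)
        e$finished <- FALSE
        e$k <- 0L
      }
      # channels initialized with the stage-initial boundary frames
      for (e in devs) publish_x(e, s, 0L)
      repeat {
        active <- Filter(function(e) !e$finished, devs)
        if (length(active) == 0L) break
        order_idx <- if (mode == "concurrent" && d > 1L)
          sample(seq_along(devs)) else seq_along(devs)
        step_device <- function(e) {
          if (e$finished) return(invisible(NULL))
          k1 <- e$k + 1L
          fg <- device_fg(e$x, e$y_data, e$y_mask, maps, e$ghL, e$ghR,
                          lambda, mu_s, w)
          g <- fg$g
          f <- fg$f
          if (!is.finite(f))
            stopf("device %d diverged (non-finite objective) at stage %d, iteration %d",
                  e$part$device, s, k1)
          e$history <- c(e$history, f)
          e$g_last <- g
          st <- nesta_step(e$x, g, e$x0, e$acc, L_s, e$k)
          n <- length(e$history)
          halt <- (config$local_stopping && n >= config$tau &&
                   progress_quotient(e$history, config$tau) <= config$tol) ||
                  n >= config$max_iter_per_stage
          if (halt) {
            e$x <- st$y
            e$finished <- TRUE
            note(e$part$device, s, k1, "converged")
            publish_x(e, s, k1, final = TRUE)   # S.4 + S.5
          } else {
            e$acc <- st$acc
            e$x <- st$x_next
            e$k <- k1
          }
          invisible(NULL)
        }
        if (mode == "concurrent" && d > 1L) {
          for (qi in order_idx) {
            e <- devs[[qi]]
            if (e$finished) next
            k1 <- e$k + 1L
            publish_x(e, s, k1)
            retrieve_x(e, s, k1)
            step_device(e)
          }
        } else {
          for (qi in order_idx) {           # publish phase (S.2)
            e <- devs[[qi]]
            if (!e$finished) publish_x(e, s, e$k + 1L)
          }
          for (qi in order_idx) {           # retrieve phase (S.3)
            e <- devs[[qi]]
            if (!e$finished) retrieve_x(e, s, e$k + 1L)
          }
          for (qi in order_idx) step_device(devs[[qi]])
          if (record_gradients) {
            gfull <- array(0i, c(dk[1:3], Nc, Nr))
            for (e in devs)
              gfull[, , , e$part$first:e$part$last, ] <- e$g_last
            recorded[[length(recorded) + 1L]] <<- gfull
          }
        }
      }
      for (e in devs) {
        e$histories[[s]] <- e$history
        e$stage_iters <- c(e$stage_iters, length(e$history))
      }
      note(NA_integer_, s, NA_integer_, "barrier")   # S.1 for stage s+1
    }
  }
  if (mode == "concurrent") with_seed(run_seed, run()) else run()

  full <- array(0i, c(dk[1:3], Nc, Nr))
  for (e in devs) full[, , , e$part$first:e$part$last, ] <- e$x
  tr <- do.call(rbind, lapply(trace, function(t)
    data.frame(device = t$device, stage = t$stage, iteration = t$iteration,
               event = t$event, payload_stage = t$payload_stage,
               payload_iter = t$payload_iter)))
  out <- list(image = new_image_series5d(full),
              device_histories = lapply(devs, function(e) e$histories),
              device_iterations = lapply(devs, function(e) e$stage_iters),
              plan = plan, schedule = sched, lambda_reg = lambda, mu0 = mu0,
              trace = tr)
  if (record_gradients) out$recorded_gradients <- recorded
  class(out) <- "cine5d_partitioned"
  out
}

#' @export
print.cine5d_partitioned <- function(x, ...) {
  cat(sprintf("<cine5d_partitioned> %d device(s), Nc = %d, Nr = %d\n",
              x$plan$d, x$plan$Nc, x$plan$Nr))
  for (q in seq_along(x$device_iterations))
    cat(sprintf("  device %d: %s\n", q,
                format_iterations(x$device_iterations[[q]])))
  invisible(x)
}

#' Format per-stage iteration counts
#'
#' Renders counts in the conventional "stage 1 + stage 2 + ... = total"
#' reporting style.
#'
#' @param iters integer vector of per-stage iteration counts.
#' @return A string like \code{"15 + 10 + 9 + 61 = 95"}.
#' @export
format_iterations <- function(iters) {
  sprintf("%s = %d", paste(iters, collapse = " + "), sum(iters))
}

#' Write a trace log as JSON lines
#'
#' One JSON object per synchronization event (publish, retrieve, converged,
#' final_publish, barrier) with device, stage, iteration and payload stamp.
#'
#' @param trace the \code{trace} data frame of a partitioned run.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(trace)))
    writeLines(jsonlite::toJSON(as.list(trace[r, ]), auto_unbox = TRUE,
                                na = "null"), con)
  invisible(path)
}
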