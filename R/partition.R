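#' Partition the cardiac dimension across devices
#'
#' Assigns consecutive, disjoint cardiac-phase ranges covering \code{1..Nc}
#' to \code{d} devices.  With equal capacities every device gets
#' \code{floor(Nc/d)} phases and the remainder goes one phase each to the
#' lowest-indexed devices (so range sizes are non-increasing and differ by
#' at most 1).  With unequal capacities, provisional shares proportional to
#' capacity are rounded by largest remainder and then adjusted so every
#' device keeps at least one phase; devices with larger capacity receive
#' larger ranges.  An explicit \code{split} overrides both rules.
#'
#' Each interior range boundary induces ghost-frame dependencies: a device
#' needs the cardiac phase just outside each end of its range (all \code{Nr}
#' respiratory phases of it) from the neighbouring device, read-only, to
#' evaluate the temporal-difference part of the gradient.
#'
#' @param Nc number of cardiac phases.
#' @param Nr number of respiratory phases.
#' @param capacities positive capacity weights, one per device.
#' @param split optional explicit per-device phase counts (must sum to
#'   \code{Nc}); used e.g. to reproduce vendor-specific allocations that a
#'   proportional rule does not produce.
#' @return An object of class \code{partition_plan}: list with \code{Nc},
#'   \code{Nr}, \code{d} and \code{partitions}, a list of per-device records
#'   \code{list(device, first, last, ghost_left, ghost_right)} (phases
#'   1-based inclusive).
#' @examples
#' plan <- partition_cardiac(20, 4, capacities = c(1, 1))
#' resident_frame_count(plan$partitions[[1]], 4)  # 44 = 10*4 + 1*4
#' @export
partition_cardiac <- function(Nc, Nr, capacities = 1, split = NULL) {
  if (!is_count(Nc, 1)) stopf("Nc must be a positive count")
  if (!is_count(Nr, 1)) stopf("Nr must be a positive count")
  d <- length(capacities)
  if (d < 1L) stopf("at least one device is required")
  if (any(!is.finite(capacities)) || any(capacities <= 0))
    stopf("device capacities must be positive")
  if (d > Nc)
    stopf("cannot partition %d cardiac phases across %d devices (d must be <= Nc)",
          Nc, d)
  if (!is.null(split)) {
    if (length(split) != d)
      stopf("split must give one phase count per device (%d)", d)
    if (any(split != round(split)) || any(split < 1) || sum(split) != Nc)
      stopf("split must be positive integers summing to Nc = %d", Nc)
    sizes <- as.integer(split)
  } else if (length(unique(capacities)) == 1L) {
    base <- Nc %/% d
    rem <- Nc %% d
    sizes <- rep(base, d) + as.integer(seq_len(d) <= rem)
  } else {
    shares <- Nc * capacities / sum(capacities)
    sizes <- floor(shares)
    rem <- Nc - sum(sizes)
    if (rem > 0) {
      frac <- shares - sizes
      # largest remainders first; ties to the lower device index
      ord <- order(-frac, seq_len(d))
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
    while (any(sizes == 0L)) {
      give <- which.max(sizes)
      takei <- which(sizes == 0L)[1L]
      sizes[give] <- sizes[give] - 1L
      sizes[takei] <- 1L
    }
    sizes <- as.integer(sizes)
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  partitions <- lapply(seq_len(d), function(q) {
    list(device = q, first = as.integer(starts[q]), last = as.integer(ends[q]),
         ghost_left = q > 1L, ghost_right = q < d)
  })
  structure(list(Nc = as.integer(Nc), Nr = as.integer(Nr), d = d,
                 partitions = partitions),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> Nc = %d cardiac phases, Nr = %d, %d device(s)\n",
              x$Nc, x$Nr, x$d))
  for (p in x$partitions)
    cat(sprintf("  device %d: phases %d..%d (%d), ghosts L=%s R=%s, resident frames %d\n",
                p$device, p$first, p$last, p$last - p$first + 1L,
                p$ghost_left, p$ghost_right, resident_frame_count(p, x$Nr)))
  invisible(x)
}

#' Resident frame count of a device partition
#'
#' Number of 3D frames a device must hold: assigned frames
#' (\code{|range| * Nr}) plus ghost dependency frames (one cardiac phase per
#' neighbouring device, each with all \code{Nr} respiratory phases).
#'
#' @param p a per-device partition record from a \code{partition_plan}.
#' @param Nr number of respiratory phases.
#' @return Integer frame count.
#' @export
resident_frame_count <- function(p, Nr) {
  (p$last - p$first + 1L) * Nr + (p$ghost_left + p$ghost_right) * Nr
}

#' Directed ghost-frame dependencies of a partition plan
#'
#' For each interior boundary between devices \code{q} and \code{q+1}, two
#' directed dependencies exist: \code{q} produces its last assigned cardiac
#' phase for \code{q+1}, and \code{q+1} produces its first assigned phase
#' for \code{q}.  Total: \code{2(d-1)} pairs.
#'
#' @param plan a \code{partition_plan}.
#' @return A data frame with columns \code{producer}, \code{consumer},
#'   \code{phase} (the produced cardiac phase index); zero rows when
#'   \code{d = 1}.
#' @export
dependency_pairs <- function(plan) {
  if (!inherits(plan, "partition_plan")) stopf("plan must be a partition_plan")
  d <- plan$d
  if (d == 1L)
    return(data.frame(producer = integer(0), consumer = integer(0),
                      phase = integer(0)))
  rows <- lapply(seq_len(d - 1L), function(q) {
    pq <- plan$partitions[[q]]; pn <- plan$partitions[[q + 1L]]
    data.frame(producer = c(q, q + 1L), consumer = c(q + 1L, q),
               phase = c(pq$last, pn$first))
  })
  do.call(rbind, rows)
}

#' Serialize a partition plan as JSON
#'
#' @param plan a \code{partition_plan}.
#' @param path optional file to write; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
plan_to_json <- function(plan, path = NULL) {
  obj <- list(Nc = plan$Nc, Nr = plan$Nr, d = plan$d,
              devices = lapply(plan$partitions, function(p)
                list(device = p$device, first = p$first, last = p$last,
                     ghost_left = p$ghost_left, ghost_right = p$ghost_right,
                     resident_frames = resident_frame_count(p, plan$Nr))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
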