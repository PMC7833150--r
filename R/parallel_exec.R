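## Deterministic tile-based parallel execution: a manager process splits
## the target window into contiguous row-major tiles and hands them to a
## pool of worker processes with dynamic first-in-first-out dispatch; a
## finished worker immediately receives the next queued tile.  Because each
## cell's summation order is fixed inside the kernel and tiles are
## reassembled by position, the map is bit-identical for any worker count.

#' Partition a target area into balanced tiles
#'
#' Tiles are contiguous runs of cells in row-major order; sizes differ by
#' at most one cell.
#'
#' @param area Integer vector \code{c(i0, i1, j0, j1)} or a
#'   \code{shinemap_job}.
#' @param n_tiles Number of tiles (1 .. cell count).
#' @return List of tiles, each \code{list(id, start, end)} with 0-based
#'   inclusive linear cell offsets.
#' @export
partition_target <- function(area, n_tiles) {
  if (inherits(area, "shinemap_job")) area <- area$target
  n_tiles <- as.integer(n_tiles)
  nc <- (area[2L] - area[1L] + 1L) * (area[4L] - area[3L] + 1L)
  if (n_tiles < 1L || n_tiles > nc)
    .stop_cls("shinemap_partition_error",
              "n_tiles must be in 1..", nc, " (got ", n_tiles, ")")
  base <- nc %/% n_tiles
  extra <- nc %% n_tiles
  sizes <- rep(base, n_tiles) + c(rep(1L, extra), rep(0L, n_tiles - extra))
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-n_tiles])
  lapply(seq_len(n_tiles), function(t)
    list(id = t, start = starts[t], end = ends[t] - 1L))
}

.compute_tile <- function(job, tile) {
  cells <- tile$start:tile$end
  list(id = tile$id, start = tile$start, end = tile$end,
       values = .job_compute_cells(job, cells), pid = Sys.getpid())
}

#' Run a dose job with a manager/worker tile queue
#'
#' With \code{n_workers = 1} the tiles are executed in-process; otherwise a
#' PSOCK worker pool is used with dynamic FIFO scheduling.  The assembled
#' map is bit-identical to the serial result for every worker count.
#'
#' @param job A \code{\link{make_job}} object.
#' @param n_workers Number of worker processes (>= 1).
#' @param n_tiles Number of tiles (default \code{4 * n_workers}, capped at
#'   the cell count).
#' @param t_serial Optional externally measured serial elapsed time (s)
#'   used to populate the speed-up metrics; if \code{NA} the metrics carry
#'   only the parallel time.
#' @return List with \code{map} (a \code{dose_map}), \code{metrics}
#'   (a \code{\link{metrics}} object or NULL when no serial time is given)
#'   and \code{ledger}, a data.frame recording each tile exactly once
#'   (id, cell range, worker pid, completion order).
#' @export
run_parallel <- function(job, n_workers = 1L, n_tiles = NULL,
                         t_serial = NA_real_) {
  stopifnot(inherits(job, "shinemap_job"), n_workers >= 1L)
  nc <- length(.job_cells(job))
  if (is.null(n_tiles)) n_tiles <- min(nc, 4L * n_workers)
  tiles <- partition_target(job, n_tiles)
  t0 <- proc.time()[["elapsed"]]
  if (n_workers == 1L) {
    results <- lapply(tiles, function(t) .compute_tile(job, t))
  } else {
    cl <- makeCluster(n_workers)
    on.exit(stopCluster(cl), add = TRUE)
    clusterEvalQ(cl, suppressPackageStartupMessages(library(shinemap)))
    clusterExport(cl, "job", envir = environment())
    results <- clusterApplyLB(cl, tiles, function(t)
      tryCatch(shinemap:::.compute_tile(job, t),
               error = function(e) list(id = t$id, error = conditionMessage(e))))
    failed <- Filter(function(r) !is.null(r$error), results)
    if (length(failed))
      .stop_cls("shinemap_job_error", "worker failure on tiles ",
                paste(vapply(failed, `[[`, 1L, "id"), collapse = ", "),
                ": ", failed[[1L]]$error)
  }
  t_parallel <- proc.time()[["elapsed"]] - t0
  values <- numeric(nc)
  for (r in results) values[(r$start:r$end) + 1L] <- r$values
  ledger <- data.frame(
    tile = vapply(results, `[[`, 1L, "id"),
    start = vapply(results, `[[`, 1L, "start"),
    end = vapply(results, `[[`, 1L, "end"),
    pid = vapply(results, `[[`, 1L, "pid"),
    order = seq_along(results))
  stopifnot(identical(sort(ledger$tile), seq_len(n_tiles)))  # exactly once
  mets <- if (is.finite(t_serial) && t_serial > 0 && t_parallel > 0)
    metrics(t_serial, t_parallel, n_workers) else NULL
  list(map = .job_assemble(job, values), metrics = mets,
       t_parallel = t_parallel, ledger = ledger)
}

#' Parallel speed-up and efficiency
#'
#' Speed-up \eqn{S = T_{serial}/T_{parallel}} and efficiency
#' \eqn{\varepsilon = S/N_{process}}.  Pure arithmetic; rounding happens
#' only at presentation (2 decimals in the print method).  Efficiency above
#' 1 (superlinear) is flagged, not rejected.
#'
#' @param t_serial,t_parallel Elapsed times, s (> 0).
#' @param n_process Number of processing elements (>= 1).
#' @return Object of class \code{parallel_metrics} with fields
#'   \code{t_serial}, \code{t_parallel}, \code{n_process}, \code{speedup},
#'   \code{efficiency}, \code{superlinear}.
#' @export
metrics <- function(t_serial, t_parallel, n_process) {
  if (!(t_serial > 0) || !(t_parallel > 0) || !(n_process >= 1))
    .stop_cls("shinemap_domain_error",
              "times must be > 0 and n_process >= 1")
  s <- t_serial / t_parallel
  e <- s / n_process
  structure(list(t_serial = t_serial, t_parallel = t_parallel,
                 n_process = as.integer(n_process),
                 speedup = s, efficiency = e, superlinear = e > 1),
            class = "parallel_metrics")
}

#' @export
print.parallel_metrics <- function(x, ...) {
  cat(sprintf("S = %.2f, efficiency = %.2f (N = %d)%s\n",
              x$speedup, x$efficiency, x$n_process,
              if (x$superlinear) " [superlinear]" else ""))
  invisible(x)
}

#' Problem-size index of a job
#'
#' \eqn{N_T} is the number of target cells, \eqn{N_R} the horizontal cell
#' count of the resized response function, and \eqn{N_{Sz}} the number of
#' vertical layers carrying source activity (the ground layer counts as one
#' when ground sources exist).  The index is \eqn{N_T N_R N_{Sz}}.
#'
#' @param job A \code{shinemap_job}.
#' @return List with \code{N_T}, \code{N_R}, \code{N_Sz}, \code{index}.
#' @export
problem_size <- function(job) {
  stopifnot(inherits(job, "shinemap_job"))
  N_T <- (job$target[2L] - job$target[1L] + 1L) *
    (job$target[4L] - job$target[3L] + 1L)
  N_R <- (2L * job$rf$half_l + 1L) * (2L * job$rf$half_m + 1L)
  n_sz <- 0L
  if (length(job$groundA) && any(job$groundA > 0)) n_sz <- 1L
  if (length(job$cloudA)) {
    ca <- array(job$cloudA, c(job$spec$nx, job$spec$ny, job$n_layers))
    n_sz <- n_sz + sum(apply(ca, 3L, function(m) any(m > 0)))
  }
  list(N_T = N_T, N_R = N_R, N_Sz = as.integer(n_sz),
       index = as.numeric(N_T) * as.numeric(N_R) * as.numeric(n_sz))
}

#' @rdname problem_size
#' @export
problem_size_index <- function(job) problem_size(job)$index
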