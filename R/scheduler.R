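# Batch partitioning, deterministic worker assignment and the associative
# reduction/broadcast contract. Workers are emulated in-process: the contract
# under test is that batching and worker count change memory layout and
# summation order only, never the reconstruction.

#' Partition scan indices into contiguous batches
#'
#' Splits `0..N-1` into `ceil(N/B)` contiguous, ordered, disjoint batches of
#' size `B`; only the last batch may be smaller.
#'
#' @param n_total Number of measurements N (>= 1).
#' @param batch_size Batch size B (>= 1).
#' @return Object of class `batch_plan` with fields `batches` (list of
#'   1-based integer index vectors), `batch_size`, `n_total`.
#' @examples
#' lengths(partition_batches(400, 128)$batches)  # 128 128 128 16
#' @export
partition_batches <- function(n_total, batch_size) {
  if (!is.numeric(n_total) || n_total < 1 || !is.numeric(batch_size) || batch_size < 1)
    stop_ptychor("n_total and batch_size must be >= 1",
                 class = "ptychor_invalid_input")
  n_total <- as.integer(n_total); batch_size <- as.integer(batch_size)
  starts <- seq.int(1L, n_total, by = batch_size)
  batches <- lapply(starts, function(s) seq.int(s, min(s + batch_size - 1L, n_total)))
  structure(list(batches = batches, batch_size = batch_size, n_total = n_total),
            class = "batch_plan")
}

#' Assign batches to workers
#'
#' Deterministic availability-queue simulation with unit cost per batch: each
#' batch goes to the earliest-available worker (lowest id on ties), which for
#' unit costs reduces to round-robin `batch k -> worker ((k-1) mod W) + 1`.
#'
#' @param plan A [partition_batches()] plan.
#' @param n_workers Number of emulated workers W (>= 1).
#' @return The plan with `assignments` (worker id per batch), `n_workers` and
#'   `worker_loads` added.
#' @export
schedule_batches <- function(plan, n_workers) {
  stopifnot(inherits(plan, "batch_plan"))
  if (!is.numeric(n_workers) || n_workers < 1)
    stop_ptychor("n_workers must be >= 1", class = "ptychor_invalid_input")
  n_workers <- as.integer(n_workers)
  avail <- numeric(n_workers)        # next-free time per worker
  assignments <- integer(length(plan$batches))
  for (k in seq_along(plan$batches)) {
    w <- which.min(avail)            # earliest available, lowest id on ties
    assignments[k] <- w
    avail[w] <- avail[w] + 1         # unit cost
  }
  plan$assignments <- assignments
  plan$n_workers <- n_workers
  plan$worker_loads <- tabulate(assignments, nbins = n_workers)
  plan
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("Batch plan: %d measurements in %d batch(es) of size <= %d\n",
              x$n_total, length(x$batches), x$batch_size))
  if (!is.null(x$assignments))
    cat("  worker loads:", paste(x$worker_loads, collapse = " "), "\n")
  invisible(x)
}

# Elementwise addition of two accumulators (or any congruent nested lists of
# numeric/complex arrays).
acc_add <- function(a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- a
    for (i in seq_along(a)) out[[i]] <- acc_add(a[[i]], b[[i]])
    return(out)
  }
  a + b
}

#' Binary-tree reduction of partial accumulators
#'
#' Combines partial sums pairwise in `ceil(log2(n))` rounds. Because the
#' combine operation is elementwise addition, the result equals the serial
#' left-fold up to float rounding, and is invariant to the order of the
#' partials at the same tolerance.
#'
#' @param partials Nonempty list of congruent partials (e.g.
#'   [new_accumulator()] objects).
#' @param combine Binary combine function; defaults to elementwise addition.
#' @return The total, with attribute `rounds` (number of combine rounds).
#' @export
tree_reduce <- function(partials, combine = acc_add) {
  if (!is.list(partials) || length(partials) < 1L)
    stop_ptychor("need at least one partial", class = "ptychor_invalid_input")
  rounds <- 0L
  while (length(partials) > 1L) {
    nxt <- vector("list", ceiling(length(partials) / 2))
    for (i in seq_along(nxt)) {
      a <- partials[[2 * i - 1]]
      nxt[[i]] <- if (2 * i <= length(partials))
        combine(a, partials[[2 * i]]) else a
    }
    partials <- nxt
    rounds <- rounds + 1L
  }
  out <- partials[[1]]
  attr(out, "rounds") <- rounds
  out
}

#' Broadcast the updated model to all workers
#'
#' In-process emulation of the post-reduction broadcast: every worker
#' receives (a handle to) the identical object/probe pair for the next
#' iteration. The value-equality contract is verified before returning.
#'
#' @param model List with the updated `object` and `probe`.
#' @param n_workers Number of workers.
#' @return List of `n_workers` identical model handles.
#' @export
broadcast_model <- function(model, n_workers) {
  handles <- rep(list(model), n_workers)
  for (h in handles) stopifnot(identical(h, model))
  handles
}
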