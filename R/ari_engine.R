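# High-throughput ARI execution engine.
#
# Every (partition of x) x (partition of y) combination across all requested
# feature pairs becomes one task with a unique global index. Tasks are laid
# out contiguously per pair, split into memory-budgeted batches, evaluated by
# a backend (a compiled kernel or a pure-R reference loop, with bit-identical
# results), and reduced per pair to the maximum ARI with first-encountered
# argmax. The output is invariant to the worker count and the batch budget.

#' Engine configuration
#'
#' @param budget_bytes Working-memory budget per batch, in bytes. Controls how
#'   many ARI tasks are planned per batch (default 4 GiB).
#' @param workers Number of parallel workers used within a batch (forked via
#'   [parallel::mclapply()]; results are order-preserving, so the output does
#'   not depend on `workers`).
#' @param backend `"vectorized"` (compiled kernel) or `"reference"` (pure-R
#'   loop). Both produce bit-identical results; the reference backend exists
#'   as an independently auditable implementation of the same contract.
#' @return An object of class `ccc_engine_config`.
#' @export
engine_config <- function(budget_bytes = 4 * 1024^3, workers = 1L,
                          backend = c("vectorized", "reference")) {
  backend <- match.arg(backend)
  budget_bytes <- as.numeric(budget_bytes)
  workers <- as.integer(workers)
  if (is.na(budget_bytes) || budget_bytes < 1) stop("budget_bytes must be >= 1")
  if (is.na(workers) || workers < 1L) stop("workers must be >= 1")
  structure(list(budget_bytes = budget_bytes, workers = workers,
                 backend = backend),
            class = "ccc_engine_config")
}

#' Cross-tabulate two partitions
#'
#' Builds the contingency table feeding the ARI formula: `counts[i, j]` is the
#' number of samples with label `i` in `p` and `j` in `q`, with row marginals
#' `a`, column marginals `b`, and total `n`.
#'
#' @param p,q `ccc_partition` objects over the same samples. Degenerate
#'   (single-cluster) partitions are accepted; the engine itself never emits
#'   them, but the ARI remains well-defined on their tables.
#' @return A `ccc_contingency`: `counts`, `a`, `b`, `n`.
#' @export
contingency_table <- function(p, q) {
  if (length(p$labels) != length(q$labels))
    stop("contingency_table: partitions have different sample counts")
  counts <- matrix(tabulate(p$labels * q$k + q$labels + 1L,
                            nbins = p$k * q$k),
                   nrow = p$k, ncol = q$k, byrow = TRUE)
  structure(list(counts = counts, a = rowSums(counts), b = colSums(counts),
                 n = length(p$labels)),
            class = "ccc_contingency")
}

comb2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand Index from a contingency table
#'
#' Hubert-Arabie chance-corrected form:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}
#'                  {\tfrac12[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}] - E},
#'       \quad E = \frac{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2}}{\binom{n}{2}}.}
#' Equals 1 for identical partitions and has expectation 0 under independent
#' random partitions with the same cluster sizes; never exceeds 1. When
#' numerator and denominator are both exactly 0 (both partitions trivially
#' identical) the value is defined as 1.
#'
#' @param t A `ccc_contingency` from [contingency_table()].
#' @return The ARI, a real number `<= 1`.
#' @export
ari_from_table <- function(t) {
  if (t$n < 2L) stop("ari_from_table: need at least 2 samples")
  sij <- sum(comb2(t$counts))
  sa <- sum(comb2(t$a))
  sb <- sum(comb2(t$b))
  e <- sa * sb / comb2(t$n)
  num <- sij - e
  den <- 0.5 * (sa + sb) - e
  if (num == 0 && den == 0) return(1)
  num / den
}

#' Brute-force pair-counting ARI oracle
#'
#' Independent check of [ari_from_table()]: enumerates all `choose(n, 2)`
#' sample pairs into the pair-confusion counts N11 (together in both
#' partitions), N10, N01, N00 and evaluates
#' `2 (N11 N00 - N10 N01) / ((N11+N10)(N10+N00) + (N11+N01)(N01+N00))`.
#' Intended for testing only; quadratic in the sample count.
#'
#' @param p,q Partitions over the same samples (`n >= 2`).
#' @return The ARI.
#' @export
ari_pair_oracle <- function(p, q) {
  lp <- p$labels
  lq <- q$labels
  n <- length(lp)
  if (length(lq) != n) stop("ari_pair_oracle: different sample counts")
  if (n < 2L) stop("ari_pair_oracle: need at least 2 samples")
  ij <- utils::combn(n, 2L)
  same_p <- lp[ij[1L, ]] == lp[ij[2L, ]]
  same_q <- lq[ij[1L, ]] == lq[ij[2L, ]]
  n11 <- sum(same_p & same_q)
  n10 <- sum(same_p & !same_q)
  n01 <- sum(!same_p & same_q)
  n00 <- sum(!same_p & !same_q)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

#' Plan memory-budgeted batches over a task stream
#'
#' Splits `[0, n_tasks)` into contiguous half-open intervals of at most
#' `max(1, floor(budget_bytes / per_task_bytes))` tasks each; the last batch
#' may be smaller. A budget below one task's footprint degrades to batches of
#' size 1 rather than failing.
#'
#' @param n_tasks Total number of tasks (0 yields an empty plan).
#' @param per_task_bytes Declared working-memory footprint of one task.
#' @param budget_bytes Total working-memory budget per batch.
#' @return A `ccc_batch_plan`: `boundaries` (2-column matrix of half-open
#'   `[start, end)` task intervals, 0-based), `per_task_bytes`, `budget_bytes`.
#' @export
plan_batches <- function(n_tasks, per_task_bytes, budget_bytes) {
  n_tasks <- as.numeric(n_tasks)
  if (per_task_bytes < 1 || budget_bytes < 1)
    stop("plan_batches: byte arguments must be >= 1")
  if (n_tasks < 0) stop("plan_batches: n_tasks must be >= 0")
  batch_size <- max(1, floor(budget_bytes / per_task_bytes))
  if (n_tasks == 0) {
    boundaries <- matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  } else {
    starts <- seq(0, n_tasks - 1, by = batch_size)
    ends <- pmin(starts + batch_size, n_tasks)
    boundaries <- cbind(start = starts, end = ends)
  }
  structure(list(boundaries = boundaries,
                 per_task_bytes = per_task_bytes,
                 budget_bytes = budget_bytes),
            class = "ccc_batch_plan")
}

# Pure-R reference backend: same task semantics as the compiled kernel.
# P: n x n_partitions integer matrix of 0-based labels; ks: clusters per
# column; task_x/task_y: 0-based column indices per task.
ari_batch_reference <- function(P, ks, task_x, task_y) {
  n <- nrow(P)
  cn2 <- comb2(n)
  vapply(seq_along(task_x), function(t) {
    cx <- task_x[t] + 1L
    cy <- task_y[t] + 1L
    kx <- ks[cx]
    ky <- ks[cy]
    tab <- tabulate(P[, cx] * ky + P[, cy] + 1L, nbins = kx * ky)
    m <- matrix(tab, nrow = kx, ncol = ky, byrow = TRUE)
    sij <- sum(comb2(m))
    sa <- sum(comb2(rowSums(m)))
    sb <- sum(comb2(colSums(m)))
    e <- sa * sb / cn2
    num <- sij - e
    den <- 0.5 * (sa + sb) - e
    if (num == 0 && den == 0) 1 else num / den
  }, numeric(1))
}

run_backend <- function(P, ks, task_x, task_y, config) {
  f <- switch(config$backend,
    vectorized = function(tx, ty) cpp_ari_batch(P, ks, tx, ty),
    reference  = function(tx, ty) ari_batch_reference(P, ks, tx, ty)
  )
  nt <- length(task_x)
  if (config$workers > 1L && nt > 1L &&
      .Platform$OS.type == "unix") {
    # contiguous worker chunks, reassembled in order: output is identical to
    # the single-worker result
    w <- min(config$workers, nt)
    chunk <- ceiling(nt / w)
    starts <- seq(1L, nt, by = chunk)
    pieces <- parallel::mclapply(starts, function(s) {
      e <- min(s + chunk - 1L, nt)
      f(task_x[s:e], task_y[s:e])
    }, mc.cores = w)
    unlist(pieces, use.names = FALSE)
  } else {
    f(task_x, task_y)
  }
}

#' Execute the ARI task stream for a set of feature pairs
#'
#' For each requested pair `(i, j)` of features, evaluates the ARI of every
#' combination of the two features' partitions and reduces to the raw maximum
#' (no clamping; the coefficient layer clamps) with the first-encountered
#' argmax in global-index order. Tasks are enumerated contiguously per pair
#' (`global_index = offset(pair) + px * m_y + py`), planned into
#' memory-budgeted batches, and evaluated with reusable working buffers.
#' The result is bit-identical for any `workers`, `backend`, or
#' `budget_bytes`.
#'
#' Pairs referencing an empty partition set (constant features) are reported
#' degenerate with `max_ari = NA`.
#'
#' @param partition_sets List of `ccc_partition_set`, all over the same
#'   samples.
#' @param pairs 2-column integer matrix of feature indices into
#'   `partition_sets`.
#' @param config An [engine_config()].
#' @return A list: `max_ari`, `argmax_x`, `argmax_y` (1-based partition
#'   indices within each feature's set, NA for degenerate pairs),
#'   `degenerate`, and the `plan` used.
#' @export
execute_tasks <- function(partition_sets, pairs, config = engine_config()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n_pairs <- nrow(pairs)
  m <- vapply(partition_sets, function(s) length(s$partitions), integer(1))
  ns <- unique(vapply(partition_sets[m > 0L],
                      function(s) s$n_effective, integer(1)))
  if (length(ns) > 1L)
    stop("execute_tasks: partition sets cover different sample counts")

  degenerate <- m[pairs[, 1L]] == 0L | m[pairs[, 2L]] == 0L
  out <- list(max_ari = rep(NA_real_, n_pairs),
              argmax_x = rep(NA_integer_, n_pairs),
              argmax_y = rep(NA_integer_, n_pairs),
              degenerate = degenerate)
  live <- which(!degenerate)
  if (length(live) == 0L) {
    out$plan <- plan_batches(0, 1, config$budget_bytes)
    return(out)
  }

  # flatten all partitions into one label matrix
  n <- ns[1L]
  all_parts <- unlist(lapply(partition_sets, function(s) s$partitions),
                      recursive = FALSE)
  offsets <- c(0L, cumsum(m))  # column offset of feature f's partitions
  P <- vapply(all_parts, function(p) p$labels, integer(n))
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  ks <- vapply(all_parts, function(p) p$k, integer(1))

  # global task stream, contiguous per pair, inner layout px * m_y + py
  mx <- m[pairs[live, 1L]]
  my <- m[pairs[live, 2L]]
  seg_len <- mx * my
  seg_start <- c(0L, cumsum(seg_len))[seq_along(live)]
  task_x <- integer(sum(seg_len))
  task_y <- integer(sum(seg_len))
  pos <- 1L
  for (r in seq_along(live)) {
    i <- pairs[live[r], 1L]
    j <- pairs[live[r], 2L]
    grid <- expand.grid(py = seq_len(my[r]) - 1L, px = seq_len(mx[r]) - 1L)
    len <- seg_len[r]
    task_x[pos:(pos + len - 1L)] <- offsets[i] + grid$px
    task_y[pos:(pos + len - 1L)] <- offsets[j] + grid$py
    pos <- pos + len
  }

  kmax <- max(ks)
  per_task_bytes <- 8 * kmax^2 + 2 * 8 * kmax + 64
  plan <- plan_batches(length(task_x), per_task_bytes, config$budget_bytes)

  aris <- numeric(length(task_x))
  for (b in seq_len(nrow(plan$boundaries))) {
    s <- plan$boundaries[b, "start"] + 1
    e <- plan$boundaries[b, "end"]
    idx <- s:e
    aris[idx] <- run_backend(P, ks, task_x[idx], task_y[idx], config)
  }

  red <- cpp_segment_max(aris, as.integer(seg_start), as.integer(seg_len))
  within <- red$argmax - seg_start          # 0-based offset within segment
  out$max_ari[live] <- red$max
  out$argmax_x[live] <- within %/% my + 1L  # 1-based partition index
  out$argmax_y[live] <- within %% my + 1L
  out$plan <- plan
  out
}
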