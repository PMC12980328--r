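# Shared test helpers: hand-built partitions and exhaustive enumeration of
# set partitions (as restricted growth strings) for oracle comparisons.

make_partition <- function(labels) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  structure(list(labels = labels, k = k, source_k = k, degenerate = k < 2L),
            class = "ccc_partition")
}

# All set partitions of n items into at most kmax blocks, as 0-based label
# vectors in restricted growth form (first occurrence of each block id is in
# increasing order), enumerated recursively.
enumerate_set_partitions <- function(n, kmax) {
  out <- list()
  recurse <- function(labels, used) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (b in seq_len(min(used + 1L, kmax)) - 1L) {
      recurse(c(labels, b), max(used, b + 1L))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Random numerical feature pair with a fixed seed, for property loops.
random_pair <- function(n, seed) {
  set.seed(seed)
  list(x = stats::rnorm(n), y = stats::rnorm(n))
}

no_pvalue_config <- function(...) ccc_config(n_perm = 0L, ...)
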