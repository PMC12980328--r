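# The Clustermatch Correlation Coefficient: clamped maximum ARI over all
# combinations of the two features' internal clusterings, with optional
# permutation p-values.

#' CCC configuration
#'
#' @param k_range Cluster counts swept when partitioning numerical features
#'   (default `2:10`).
#' @param n_perm Number of permutations for the p-value (default 1000;
#'   0 disables p-values).
#' @param seed Integer seed; the permutation stream of each pair is derived
#'   deterministically from `(seed, pair index)`, so p-values are reproducible
#'   and independent of parallelism.
#' @param min_samples Minimum pairwise-complete sample count below which a
#'   pair is reported degenerate (default 10).
#' @param engine An [engine_config()].
#' @return An object of class `ccc_config`.
#' @export
ccc_config <- function(k_range = 2:10, n_perm = 1000L, seed = 1L,
                       min_samples = 10L, engine = engine_config()) {
  n_perm <- as.integer(n_perm)
  min_samples <- as.integer(min_samples)
  if (is.na(n_perm) || n_perm < 0L) stop("n_perm must be >= 0")
  if (is.na(min_samples) || min_samples < 2L) stop("min_samples must be >= 2")
  if (length(k_range) < 1L || any(k_range < 2L))
    stop("k_range must be non-empty with entries >= 2")
  structure(list(k_range = as.integer(k_range), n_perm = n_perm,
                 seed = as.integer(seed), min_samples = min_samples,
                 engine = engine),
            class = "ccc_config")
}

# Deterministic per-pair seed derivation; kept below 2^31 - 1.
perm_seed <- function(seed, pair_index) {
  as.integer((abs(as.numeric(seed)) * 69621 +
                as.numeric(pair_index) * 10007 + 1) %% 2147483647)
}

part_matrix <- function(pset) {
  n <- pset$n_effective
  P <- vapply(pset$partitions, function(p) p$labels, integer(n))
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  P
}

# Permutation p-value with the add-one estimator. Runs on a private RNG
# stream seeded from (config seed, pair index); the caller's RNG state is
# left untouched.
perm_pvalue <- function(obs, Px, kx, Py, ky, backend, n_perm, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- nrow(Py)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm <- pair_max_ari(Px, kx, Py[idx, , drop = FALSE], ky, backend)
    if (max(0, perm$max) >= obs) count <- count + 1L
  }
  (1 + count) / (1 + n_perm)
}

# Max ARI over the cross product of two partition families, tasks in
# global-index order (px * m_y + py), ties to the lowest index.
pair_max_ari <- function(Px, kx, Py, ky, backend = "vectorized") {
  mx <- ncol(Px)
  my <- ncol(Py)
  grid <- expand.grid(py = seq_len(my) - 1L, px = seq_len(mx) - 1L)
  P <- cbind(Px, Py)
  ks <- c(kx, ky)
  tx <- grid$px
  ty <- mx + grid$py
  aris <- if (backend == "reference") {
    ari_batch_reference(P, ks, tx, ty)
  } else {
    cpp_ari_batch(P, as.integer(ks), as.integer(tx), as.integer(ty))
  }
  best <- which.max(aris)  # first max = lowest global index
  list(max = aris[best], ix = grid$px[best] + 1L, iy = grid$py[best] + 1L)
}

degenerate_result <- function(x, y, n_used) {
  data.frame(feature_i = x$id, feature_j = y$id, ccc = 0,
             best_kx = NA_integer_, best_ky = NA_integer_,
             pvalue = NA_real_, n_used = n_used, degenerate = TRUE,
             stringsAsFactors = FALSE)
}

#' Clustermatch Correlation Coefficient of one feature pair
#'
#' Restricts to samples non-missing in both features, builds each feature's
#' partition family ([build_partition_set()]), and returns
#' `ccc = max(0, max ARI over all partition combinations)` together with the
#' cluster counts (`best_kx`, `best_ky`) of the maximizing combination. Pairs
#' with fewer than `min_samples` usable samples, or where either feature is
#' constant, are reported degenerate with `ccc = 0`.
#'
#' With `n_perm > 0`, a permutation p-value is attached: the null is generated
#' by uniform random permutations of the second feature's values (first held
#' fixed) and estimated with the add-one rule
#' `p = (1 + #\{CCC_perm >= CCC_obs\}) / (1 + n_perm)`, so `p >= 1/(1+n_perm)`
#' and never 0.
#'
#' @param x,y Feature vectors ([feature_vector()]) or plain numeric/character
#'   vectors of the same length; either may be numerical or categorical.
#' @param config A [ccc_config()].
#' @return One-row data frame: `feature_i`, `feature_j`, `ccc`, `best_kx`,
#'   `best_ky`, `pvalue`, `n_used`, `degenerate`.
#' @examples
#' x <- 1:20
#' ccc_pair(x, 2 * x + 1, ccc_config(n_perm = 0))$ccc  # 1
#' @export
ccc_pair <- function(x, y, config = ccc_config()) {
  x <- as_feature_vector(x, "x")
  y <- as_feature_vector(y, "y")
  if (length(x$values) != length(y$values))
    stop("ccc_pair: features have different sample counts")
  ccc_pair_impl(x, y, config, pair_index = 0L)
}

ccc_pair_impl <- function(x, y, config, pair_index) {
  keep <- !x$missing & !y$missing
  n_used <- sum(keep)
  if (n_used < config$min_samples) return(degenerate_result(x, y, n_used))
  psx <- build_partition_set(subset_feature(x, keep), config$k_range)
  psy <- build_partition_set(subset_feature(y, keep), config$k_range)
  if (length(psx$partitions) == 0L || length(psy$partitions) == 0L)
    return(degenerate_result(x, y, n_used))

  Px <- part_matrix(psx)
  Py <- part_matrix(psy)
  kx <- vapply(psx$partitions, function(p) p$k, integer(1))
  ky <- vapply(psy$partitions, function(p) p$k, integer(1))
  backend <- config$engine$backend
  res <- pair_max_ari(Px, kx, Py, ky, backend)
  ccc <- max(0, res$max)

  pvalue <- NA_real_
  if (config$n_perm > 0L) {
    pvalue <- perm_pvalue(ccc, Px, kx, Py, ky, backend,
                          config$n_perm, perm_seed(config$seed, pair_index))
  }

  data.frame(feature_i = x$id, feature_j = y$id, ccc = ccc,
             best_kx = psx$partitions[[res$ix]]$source_k,
             best_ky = psy$partitions[[res$iy]]$source_k,
             pvalue = pvalue, n_used = n_used, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Pairwise CCC over a feature set
#'
#' Computes [ccc_pair()] for every unordered feature pair `(i < j)`. When the
#' data have no missing values, each feature is partitioned once and all
#' pairs are evaluated through the batched engine ([execute_tasks()]); the
#' result is identical to independent `ccc_pair()` calls and invariant to the
#' engine's `workers` and `budget_bytes`.
#'
#' @param data A numeric matrix (features in rows, samples in columns; row
#'   names are feature ids) or a list of [feature_vector()]s with equal
#'   sample counts.
#' @param config A [ccc_config()].
#' @return Data frame with one row per unordered pair, ordered by `(i, j)`
#'   in input feature order: columns as in [ccc_pair()].
#' @export
ccc_matrix <- function(data, config = ccc_config()) {
  features <- as_feature_list(data)
  nf <- length(features)
  if (nf < 2L) stop("ccc_matrix: need at least 2 features")
  lens <- vapply(features, function(f) length(f$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("ccc_matrix: features have different sample counts")

  pairs <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]

  any_missing <- any(vapply(features, function(f) any(f$missing), logical(1)))
  if (any_missing) {
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
      ccc_pair_impl(features[[pairs[r, 1L]]], features[[pairs[r, 2L]]],
                    config, pair_index = r - 1L)
    })
    return(do.call(rbind, rows))
  }

  psets <- lapply(features, build_partition_set, k_range = config$k_range)
  eng <- execute_tasks(psets, pairs, config$engine)

  n <- lens[1L]
  ids <- vapply(features, function(f) f$id, character(1))
  res <- data.frame(feature_i = ids[pairs[, 1L]],
                    feature_j = ids[pairs[, 2L]],
                    ccc = pmax(0, eng$max_ari),
                    best_kx = NA_integer_, best_ky = NA_integer_,
                    pvalue = NA_real_, n_used = n,
                    degenerate = eng$degenerate,
                    stringsAsFactors = FALSE)
  res$ccc[eng$degenerate] <- 0
  live <- which(!eng$degenerate)
  res$best_kx[live] <- vapply(live, function(r) {
    psets[[pairs[r, 1L]]]$partitions[[eng$argmax_x[r]]]$source_k
  }, integer(1))
  res$best_ky[live] <- vapply(live, function(r) {
    psets[[pairs[r, 2L]]]$partitions[[eng$argmax_y[r]]]$source_k
  }, integer(1))

  if (config$n_perm > 0L) {
    backend <- config$engine$backend
    for (r in live) {
      i <- pairs[r, 1L]
      j <- pairs[r, 2L]
      Px <- part_matrix(psets[[i]])
      Py <- part_matrix(psets[[j]])
      kx <- vapply(psets[[i]]$partitions, function(p) p$k, integer(1))
      ky <- vapply(psets[[j]]$partitions, function(p) p$k, integer(1))
      res$pvalue[r] <- perm_pvalue(res$ccc[r], Px, kx, Py, ky, backend,
                                   config$n_perm,
                                   perm_seed(config$seed, r - 1L))
    }
  }
  rownames(res) <- NULL
  res
}

as_feature_list <- function(data) {
  if (is.matrix(data)) {
    ids <- rownames(data)
    if (is.null(ids)) ids <- paste0("f", seq_len(nrow(data)))
    lapply(seq_len(nrow(data)), function(i) {
      feature_vector(data[i, ], id = ids[i])
    })
  } else if (is.list(data) && all(vapply(data, is_feature_vector, logical(1)))) {
    data
  } else {
    stop("ccc_matrix: data must be a numeric matrix or a list of feature vectors")
  }
}
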