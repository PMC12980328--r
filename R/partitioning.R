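# Internal clusterings of single features: quantile partitions for numerical
# features over a sweep of cluster counts, category-defined partitions for
# categorical features. These per-feature partition families are what the ARI
# engine crosses to compute the coefficient.

#' Construct a feature vector
#'
#' A feature vector is one gene's (or one metadata variable's) values across
#' samples, together with its type and a missing mask. Numerical features are
#' partitioned by empirical quantiles; categorical features contribute a single
#' partition defined by their categories.
#'
#' @param values Numeric vector (numerical feature) or character/factor vector
#'   (categorical feature). `NA` marks missing samples.
#' @param id Feature identifier.
#' @param kind `"numerical"` or `"categorical"`. Defaults to the type of
#'   `values`.
#' @return An object of class `ccc_feature` with fields `id`, `kind`,
#'   `values` (numeric values, or 0-based integer category codes in
#'   first-occurrence order), and `missing` (logical mask).
#' @examples
#' feature_vector(c(1.2, 3.4, NA, 5.6), id = "geneA")
#' feature_vector(c("M", "F", "F"), id = "sex")
#' @export
feature_vector <- function(values, id = "feature",
                           kind = c("auto", "numerical", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (is.numeric(values)) "numerical" else "categorical"
  }
  if (length(values) < 1L) stop("feature '", id, "': empty values")
  if (kind == "numerical") {
    vals <- as.numeric(values)
    missing <- is.na(vals)
  } else {
    raw <- as.character(values)
    missing <- is.na(raw)
    vals <- rep(NA_integer_, length(raw))
    if (any(!missing)) {
      lev <- unique(raw[!missing])       # first-occurrence order
      vals[!missing] <- match(raw[!missing], lev) - 1L
    }
  }
  structure(list(id = as.character(id), kind = kind,
                 values = vals, missing = missing),
            class = "ccc_feature")
}

is_feature_vector <- function(x) inherits(x, "ccc_feature")

as_feature_vector <- function(x, id = "feature") {
  if (is_feature_vector(x)) x else feature_vector(x, id = id)
}

# Restrict a feature to a logical subset of samples (drops the mask).
subset_feature <- function(feature, keep) {
  structure(list(id = feature$id, kind = feature$kind,
                 values = feature$values[keep],
                 missing = feature$missing[keep]),
            class = "ccc_feature")
}

new_partition <- function(labels, k, source_k) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 source_k = as.integer(source_k),
                 degenerate = k < 2L),
            class = "ccc_partition")
}

#' Quantile partition of a numerical feature
#'
#' Splits `values` into (at most) `k` clusters at the empirical quantiles
#' `i/k`, `i = 1..k-1`, estimated by linear interpolation of the order
#' statistics with plotting positions `(j-1)/(n-1)` (the usual type-7
#' convention, as in [stats::quantile()]). A sample's label is the number of
#' cut points strictly below its value, so a value equal to a cut point joins
#' the lower cluster. Labels are compacted so every cluster is non-empty;
#' if fewer than 2 non-empty clusters remain (e.g. constant input) the
#' partition is flagged degenerate.
#'
#' Because type-7 quantiles interpolate between order statistics, the labels
#' depend only on the ranks of `values`: any strictly increasing transform of
#' the data yields the identical partition.
#'
#' @param values Numeric vector without missing entries.
#' @param k Requested number of clusters, at least 2.
#' @return A `ccc_partition`: `labels` (0-based integers), `k` (non-empty
#'   cluster count), `source_k` (the requested `k`), `degenerate`.
#' @examples
#' quantile_partition(c(10, 20, 30, 40), k = 2)$labels  # 0 0 1 1
#' @export
quantile_partition <- function(values, k) {
  if (length(values) < 1L) stop("quantile_partition: empty input")
  if (anyNA(values)) stop("quantile_partition: values contain missing entries")
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("quantile_partition: k must be >= 2")
  cuts <- stats::quantile(values, probs = seq_len(k - 1L) / k,
                          type = 7, names = FALSE)
  # label = number of cut points strictly below the value
  raw <- findInterval(values, cuts, left.open = TRUE)
  compact_partition(raw, source_k = k)
}

# Renumber labels to 0..(k-1) over non-empty clusters, preserving cluster
# value order.
compact_partition <- function(raw, source_k) {
  u <- sort(unique(raw))
  labels <- match(raw, u) - 1L
  new_partition(labels, k = length(u), source_k = source_k)
}

#' Category-defined partition of a categorical feature
#'
#' One cluster per distinct category; label order follows first occurrence in
#' the input. Degenerate when fewer than 2 categories are present.
#'
#' @param values Character vector, factor, or a `ccc_feature` of categorical
#'   kind, without missing entries.
#' @return A `ccc_partition`.
#' @examples
#' encode_categorical(c("M", "F", "M", "F"))$labels  # 0 1 0 1
#' @export
encode_categorical <- function(values) {
  if (is_feature_vector(values)) {
    if (values$kind != "categorical")
      stop("encode_categorical: feature is not categorical")
    if (any(values$missing)) stop("encode_categorical: missing entries present")
    codes <- values$values
  } else {
    if (length(values) < 1L) stop("encode_categorical: empty input")
    raw <- as.character(values)
    if (anyNA(raw)) stop("encode_categorical: missing entries present")
    codes <- match(raw, unique(raw)) - 1L
  }
  if (length(codes) < 1L) stop("encode_categorical: empty input")
  new_partition(codes, k = length(unique(codes)),
                source_k = length(unique(codes)))
}

#' Build the partition family of one feature
#'
#' For a numerical feature, computes [quantile_partition()] at every cluster
#' count in `k_range` and keeps the non-degenerate ones (duplicate label
#' vectors arising at different `k` are retained; the downstream max-reduction
#' is unaffected). For a categorical feature, the single
#' [encode_categorical()] partition is used and `k_range` is ignored.
#' Samples flagged missing are excluded before partitioning.
#'
#' @param feature A `ccc_feature` (or a plain vector, coerced).
#' @param k_range Integer vector of requested cluster counts, all `>= 2`.
#' @return A `ccc_partition_set`: `feature_id`, `partitions` (list, possibly
#'   empty for constant features), `n_effective` (samples used).
#' @export
build_partition_set <- function(feature, k_range = 2:10) {
  feature <- as_feature_vector(feature)
  if (length(k_range) < 1L || any(k_range < 2L))
    stop("build_partition_set: k_range must be non-empty with entries >= 2")
  keep <- !feature$missing
  vals <- feature$values[keep]
  parts <- list()
  if (length(vals) >= 1L) {
    if (feature$kind == "categorical") {
      # re-densify codes in first-occurrence order: dropping missing samples
      # may have removed whole categories
      codes <- match(vals, unique(vals)) - 1L
      p <- new_partition(codes, k = length(unique(codes)),
                         source_k = length(unique(codes)))
      if (!p$degenerate) parts <- list(p)
    } else {
      for (k in as.integer(k_range)) {
        p <- quantile_partition(vals, k)
        if (!p$degenerate) parts[[length(parts) + 1L]] <- p
      }
    }
  }
  structure(list(feature_id = feature$id, partitions = parts,
                 n_effective = length(vals)),
            class = "ccc_partition_set")
}
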