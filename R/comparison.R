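# Coefficient-agreement analysis: Pearson/Spearman baselines, percentile
# tiers (high / low / neither), UpSet-style intersection categories, candidate
# selection, and gene-metadata association.

TIERS <- c("high", "low", "neither")

#' Pearson or Spearman baseline over all feature pairs
#'
#' Standard product-moment or rank correlation for every unordered pair, with
#' pairwise-complete observations, in the same `(i < j)` row order as
#' [ccc_matrix()].
#'
#' @param data Numeric matrix (features in rows) or list of numerical
#'   [feature_vector()]s.
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame `feature_i`, `feature_j`, `value`.
#' @export
baseline_coefficients <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  features <- as_feature_list(data)
  if (any(vapply(features, function(f) f$kind != "numerical", logical(1))))
    stop("baseline_coefficients: categorical features are not supported")
  nf <- length(features)
  if (nf < 2L) stop("baseline_coefficients: need at least 2 features")
  vals <- vapply(features, function(f) {
    v <- f$values
    v[f$missing] <- NA
    v
  }, numeric(length(features[[1L]]$values)))
  cm <- suppressWarnings(
    stats::cor(vals, method = method, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  ids <- vapply(features, function(f) f$id, character(1))
  data.frame(feature_i = ids[pairs[, 1L]], feature_j = ids[pairs[, 2L]],
             value = cm[pairs], stringsAsFactors = FALSE)
}

#' Percentile tiers of a coefficient vector
#'
#' Labels the `ceiling(q_high * N)` largest values "high", the
#' `ceiling(q_low * N)` smallest "low", and the remainder "neither", where `N`
#' counts the finite values. Signed coefficients (Pearson, Spearman) are
#' ranked by absolute value via `magnitude = TRUE`; CCC is ranked by the value
#' itself. Ties are broken by stable input order; non-finite values are
#' labelled "neither". High labels are assigned before low ones, so with
#' `q_high + q_low <= 1` the two never collide.
#'
#' @param values Numeric coefficient per pair.
#' @param q_high,q_low Tier fractions (defaults 0.30 each).
#' @param magnitude Rank by `abs(values)`?
#' @return Character vector of tiers, same length as `values`.
#' @export
classify_tiers <- function(values, q_high = 0.30, q_low = 0.30,
                           magnitude = FALSE) {
  if (q_high < 0 || q_low < 0 || q_high + q_low > 1)
    stop("classify_tiers: need q_high, q_low >= 0 with q_high + q_low <= 1")
  v <- if (magnitude) abs(values) else values
  fin <- which(is.finite(v))
  if (length(fin) == 0L) stop("classify_tiers: no finite values")
  n_high <- ceiling(q_high * length(fin))
  n_low <- ceiling(q_low * length(fin))
  tier <- rep("neither", length(v))
  ord_desc <- fin[order(-v[fin], fin)]
  high_idx <- utils::head(ord_desc, n_high)
  tier[high_idx] <- "high"
  ord_asc <- fin[order(v[fin], fin)]
  low_idx <- utils::head(setdiff(ord_asc, high_idx), n_low)
  tier[low_idx] <- "low"
  tier
}

category_class <- function(ccc_tier, pearson_tier, spearman_tier) {
  triple <- cbind(ccc_tier, pearson_tier, spearman_tier)
  apply(triple, 1L, function(tr) {
    if (all(tr == tr[1L]) && tr[1L] %in% c("high", "low")) "agreement"
    else if (any(tr == "high") && any(tr == "low")) "disagreement"
    else "other"
  })
}

#' Intersection categories of per-coefficient tiers
#'
#' Combines the three tier vectors into a per-pair category (a tier triple)
#' and classifies each as "agreement" (all three identically high or low),
#' "disagreement" (at least one high and one low among the three), or
#' "other".
#'
#' @param ccc_tier,pearson_tier,spearman_tier Tier vectors from
#'   [classify_tiers()], aligned on the same pair ordering.
#' @return A list: `pairs` (data frame with the three tiers, `category`
#'   label `"ccc/pearson/spearman"`, and `class`) and `counts` (data frame
#'   `ccc_tier`, `pearson_tier`, `spearman_tier`, `class`, `n_pairs` for the
#'   occupied categories).
#' @export
intersect_categories <- function(ccc_tier, pearson_tier, spearman_tier) {
  nlen <- length(ccc_tier)
  if (length(pearson_tier) != nlen || length(spearman_tier) != nlen)
    stop("intersect_categories: tier tables are misaligned")
  ok <- function(x) all(x %in% TIERS)
  if (!ok(ccc_tier) || !ok(pearson_tier) || !ok(spearman_tier))
    stop("intersect_categories: tiers must be high/low/neither")
  pairs <- data.frame(ccc_tier = ccc_tier, pearson_tier = pearson_tier,
                      spearman_tier = spearman_tier,
                      stringsAsFactors = FALSE)
  pairs$category <- paste(ccc_tier, pearson_tier, spearman_tier, sep = "/")
  pairs$class <- category_class(ccc_tier, pearson_tier, spearman_tier)
  agg <- stats::aggregate(list(n_pairs = seq_len(nlen)),
                          pairs[c("ccc_tier", "pearson_tier",
                                  "spearman_tier", "class")],
                          FUN = length)
  agg <- agg[order(-agg$n_pairs), , drop = FALSE]
  rownames(agg) <- NULL
  list(pairs = pairs, counts = agg)
}

#' The CCC-high disagreement categories
#'
#' Enumerates the tier triples with CCC "high" and Pearson or Spearman "low":
#' the intersection groups whose members are candidate nonlinear pairs
#' (detected by the clustering-based coefficient but ranked low by at least
#' one linear/monotonic baseline). There are exactly five such categories.
#'
#' @return Character vector of `"high/<pearson>/<spearman>"` category labels.
#' @export
ccc_high_disagreement_categories <- function() {
  grid <- expand.grid(pearson = TIERS, spearman = TIERS,
                      stringsAsFactors = FALSE)
  keep <- grid$pearson == "low" | grid$spearman == "low"
  paste("high", grid$pearson[keep], grid$spearman[keep], sep = "/")
}

#' Select top candidate pairs from chosen intersection groups
#'
#' Filters pairs to the given categories, sorts by CCC descending (ties broken
#' by `(feature_i, feature_j)` input order), and truncates to `top_n`.
#'
#' @param results Pair table with a `ccc` column (as from [ccc_matrix()]).
#' @param categories Per-pair category labels aligned with `results` (the
#'   `pairs$category` column of [intersect_categories()]).
#' @param groups Category labels to keep (default: the five CCC-high
#'   disagreement groups).
#' @param top_n Maximum number of pairs returned.
#' @return Subset of `results` rows, ranked.
#' @export
select_candidate_pairs <- function(results, categories,
                                   groups = ccc_high_disagreement_categories(),
                                   top_n = 100L) {
  if (top_n < 1L) stop("select_candidate_pairs: top_n must be >= 1")
  if (length(categories) != nrow(results))
    stop("select_candidate_pairs: categories misaligned with results")
  eligible <- which(categories %in% groups)
  if (length(eligible) == 0L) return(results[integer(0), , drop = FALSE])
  eligible <- eligible[order(-results$ccc[eligible], eligible)]
  out <- results[utils::head(eligible, top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-metadata associations for candidate pairs
#'
#' For every gene appearing in the selected pairs and every metadata variable,
#' computes the CCC between the gene's expression and the variable
#' (categorical variables enter through their category partition, numerical
#' ones through quantile partitions, exactly like a gene). Output is sorted by
#' CCC descending.
#'
#' @param candidates Data frame with `feature_i`, `feature_j` columns naming
#'   genes present in `expr`.
#' @param expr Numeric expression matrix, genes in rows, sample ids in
#'   columns.
#' @param metadata A metadata table from [read_metadata()], or a data frame
#'   whose first column holds sample ids.
#' @param config A [ccc_config()]; set `n_perm > 0` for permutation p-values.
#' @return Data frame `gene`, `variable`, `kind`, `ccc`, `pvalue`, `n_used`.
#' @export
metadata_associations <- function(candidates, expr, metadata,
                                  config = ccc_config(n_perm = 0L)) {
  meta <- as_metadata_table(metadata)
  samples <- intersect(colnames(expr), meta$sample_id)
  if (length(samples) == 0L)
    stop("metadata_associations: no overlapping samples between expression and metadata")
  if (length(samples) < ncol(expr) || length(samples) < length(meta$sample_id))
    warning("metadata_associations: restricting to ",
            length(samples), " overlapping samples")
  genes <- unique(c(candidates$feature_i, candidates$feature_j))
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0L)
    stop("metadata_associations: genes absent from expression: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  mrows <- match(samples, meta$sample_id)

  out <- list()
  pair_index <- 0L
  for (g in genes) {
    gx <- feature_vector(expr[g, samples], id = g)
    for (v in names(meta$variables)) {
      var <- meta$variables[[v]]
      fy <- feature_vector(var$values[mrows], id = v, kind = var$kind)
      res <- ccc_pair_impl(gx, fy, config, pair_index = pair_index)
      pair_index <- pair_index + 1L
      out[[length(out) + 1L]] <- data.frame(
        gene = g, variable = v, kind = var$kind,
        ccc = res$ccc, pvalue = res$pvalue, n_used = res$n_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$ccc, out$gene, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}
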