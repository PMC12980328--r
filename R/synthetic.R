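# Synthetic expression motifs. Each pattern reproduces one of the canonical
# gene-pair relationships that motivate a clustering-based coefficient:
# plain linear association, a symmetric quadratic (invisible to Pearson),
# two cohorts whose within-group slopes are positive but whose pooled slope
# is negative, a relationship confined to one sample group (the other pinned
# at zero, as for a Y-chromosome gene in females), a relationship masked by
# an unrelated sample subset, and pure independence.

SYNTHETIC_PATTERNS <- c("linear", "quadratic", "cohort_shift",
                        "group_masked", "subset_masked", "null")

#' Pattern specification for a synthetic gene pair
#'
#' @param pattern One of `"linear"`, `"quadratic"`, `"cohort_shift"`,
#'   `"group_masked"`, `"subset_masked"`, `"null"`.
#' @param n_samples Number of samples (default 200, at least 4).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.1).
#' @param group_fraction Fraction of samples in the first group/cohort/subset
#'   for the two-population patterns (default 0.5; membership counts are
#'   exact, order shuffled).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `ccc_pattern_spec`.
#' @export
pattern_spec <- function(pattern, n_samples = 200L, noise_sd = 0.1,
                         group_fraction = 0.5, seed = 1L) {
  pattern <- as.character(pattern)
  if (!pattern %in% SYNTHETIC_PATTERNS)
    stop("unknown pattern '", pattern, "'; choose one of: ",
         paste(SYNTHETIC_PATTERNS, collapse = ", "))
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (group_fraction <= 0 || group_fraction >= 1)
    stop("group_fraction must be in (0, 1)")
  structure(list(pattern = pattern, n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, group_fraction = group_fraction,
                 seed = as.integer(seed)),
            class = "ccc_pattern_spec")
}

# Exact-count shuffled binary membership.
balanced_groups <- function(n, fraction, labels = c("A", "B")) {
  n1 <- round(n * fraction)
  sample(c(rep(labels[1L], n1), rep(labels[2L], n - n1)))
}

#' Generate one synthetic gene pair
#'
#' Draws `(x, y)` realizing the requested motif, deterministic under the
#' spec's seed:
#' \describe{
#'   \item{linear}{`x ~ U(0, 1)`, `y = 2x + noise`.}
#'   \item{quadratic}{`x ~ U(-1, 1)` (symmetric), `y = x^2 + noise`.}
#'   \item{cohort_shift}{two cohorts with within-cohort slope +1 and offsets
#'     of opposite sign (+2 at low `x`, -2 at high `x`), so both cohorts show
#'     a strong positive trend while the pooled least-squares slope is
#'     negative.}
#'   \item{group_masked}{`x = 0` exactly in one group; in the other, `x`
#'     positive and `y = x + noise`; `y` in the zero group is independently
#'     drawn above the active group's range (a partner gene upregulated where
#'     `x` is silenced), so the relationship is invisible to a pooled linear
#'     fit but visible to the cluster cross-tabulation.}
#'   \item{subset_masked}{one subset linear (`y = x + noise`); the other
#'     independent noise overlapping the same `x`/`y` ranges.}
#'   \item{null}{independent standard-normal draws.}
#' }
#'
#' @param spec A [pattern_spec()].
#' @return List: `x`, `y` (numeric vectors), `metadata` (data frame of the
#'   sample labels driving the pattern: `group`, `cohort`, or `subset`
#'   column, or NULL), `spec`.
#' @export
generate_pair_pattern <- function(spec) {
  stopifnot(inherits(spec, "ccc_pattern_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sd <- spec$noise_sd
  noise <- function() stats::rnorm(n, 0, sd)
  metadata <- NULL

  if (spec$pattern == "linear") {
    x <- stats::runif(n, 0, 1)
    y <- 2 * x + 1 + noise()
  } else if (spec$pattern == "quadratic") {
    x <- stats::runif(n, -1, 1)
    y <- x^2 + noise()
  } else if (spec$pattern == "cohort_shift") {
    cohort <- balanced_groups(n, spec$group_fraction,
                              c("postmortem", "organ_donor"))
    a <- cohort == "postmortem"
    x <- numeric(n)
    y <- numeric(n)
    x[a] <- stats::runif(sum(a), 0, 2)
    y[a] <- x[a] + 2
    x[!a] <- stats::runif(sum(!a), 2, 4)
    y[!a] <- x[!a] - 2
    y <- y + noise()
    metadata <- data.frame(cohort = cohort, stringsAsFactors = FALSE)
  } else if (spec$pattern == "group_masked") {
    group <- balanced_groups(n, spec$group_fraction, c("F", "M"))
    m <- group == "M"
    x <- numeric(n)                       # exactly zero in the F group
    x[m] <- stats::runif(sum(m), 1, 3)
    y <- numeric(n)
    y[m] <- x[m] + stats::rnorm(sum(m), 0, sd)
    # partner gene upregulated in the x-silenced group: its top quantiles are
    # pure group-F samples, which the cluster cross-tabulation picks up while
    # the pooled linear fit is diluted
    y[!m] <- stats::runif(sum(!m), 3, 5)
    metadata <- data.frame(group = group, stringsAsFactors = FALSE)
  } else if (spec$pattern == "subset_masked") {
    subset <- balanced_groups(n, spec$group_fraction,
                              c("organ_donor", "postmortem"))
    a <- subset == "organ_donor"
    x <- stats::runif(n, 0, 2)
    y <- numeric(n)
    y[a] <- x[a] + stats::rnorm(sum(a), 0, sd)
    y[!a] <- stats::runif(sum(!a), 0, 2)  # masks the linear subset
    metadata <- data.frame(subset = subset, stringsAsFactors = FALSE)
  } else {  # null
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
  }
  list(x = x, y = y, metadata = metadata, spec = spec)
}

#' Assemble a synthetic expression dataset
#'
#' Builds a feature-by-sample expression matrix containing `n_pairs_per_pattern`
#' engineered pairs of each motif plus `n_null_features` independent null
#' features, a per-sample metadata table (binary group, binary cohort, one
#' numerical covariate), and a truth table recording each engineered pair's
#' generating pattern. Group/cohort patterns use the shared metadata labels,
#' so gene-metadata association can recover them. Fully reproducible from
#' `seed`.
#'
#' @param n_pairs_per_pattern Engineered pairs per motif (default 1).
#' @param n_null_features Additional independent features (default 0).
#' @param n_samples Samples (default 200).
#' @param noise_sd Noise level shared by all motifs (default 0.1).
#' @param seed Integer seed.
#' @return List of class `ccc_synthetic_dataset`: `expression` (matrix,
#'   features x samples), `metadata` (data frame with `sample_id`, `group`,
#'   `cohort`, `age`), `truth` (data frame `pattern`, `feature_x`,
#'   `feature_y`), `params`.
#' @export
generate_dataset <- function(n_pairs_per_pattern = 1L, n_null_features = 0L,
                             n_samples = 200L, noise_sd = 0.1, seed = 1L) {
  if (n_pairs_per_pattern < 0L || n_null_features < 0L)
    stop("generate_dataset: counts must be >= 0")
  n_feat <- 2L * n_pairs_per_pattern * length(SYNTHETIC_PATTERNS) +
    n_null_features
  if (n_feat == 0L) stop("generate_dataset: zero total features")

  set.seed(seed)
  group <- balanced_groups(n_samples, 0.5, c("F", "M"))
  cohort <- balanced_groups(n_samples, 0.5, c("postmortem", "organ_donor"))
  age <- round(stats::runif(n_samples, 20, 70), 1)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  rows <- list()
  truth <- list()
  pair_seed <- 0L
  for (pat in SYNTHETIC_PATTERNS) {
    for (r in seq_len(n_pairs_per_pattern)) {
      pair_seed <- pair_seed + 1L
      spec <- pattern_spec(pat, n_samples = n_samples, noise_sd = noise_sd,
                           group_fraction = 0.5,
                           seed = (seed * 1000L + pair_seed) %% 2147483647L)
      gp <- generate_pair_pattern(spec)
      # overwrite the pair's own labels with the dataset-wide metadata so the
      # truth is recoverable from the shared metadata table
      if (pat == "cohort_shift") {
        gp <- regenerate_with_labels(spec, cohort == "postmortem")
      } else if (pat == "group_masked") {
        gp <- regenerate_with_labels(spec, group == "M")
      } else if (pat == "subset_masked") {
        gp <- regenerate_with_labels(spec, cohort == "organ_donor")
      }
      fx <- sprintf("%s_p%d_x", pat, r)
      fy <- sprintf("%s_p%d_y", pat, r)
      rows[[fx]] <- gp$x
      rows[[fy]] <- gp$y
      truth[[length(truth) + 1L]] <- data.frame(
        pattern = pat, feature_x = fx, feature_y = fy,
        stringsAsFactors = FALSE)
    }
  }
  if (n_null_features > 0L) {
    set.seed((seed * 1000L + 999L) %% 2147483647L)
    for (i in seq_len(n_null_features)) {
      rows[[sprintf("null_f%d", i)]] <- stats::rnorm(n_samples)
    }
  }

  expression <- do.call(rbind, rows)
  colnames(expression) <- sample_ids
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(pattern = character(0), feature_x = character(0),
               feature_y = character(0))
  structure(list(
    expression = expression,
    metadata = data.frame(sample_id = sample_ids, group = group,
                          cohort = cohort, age = age,
                          stringsAsFactors = FALSE),
    truth = truth,
    params = list(n_pairs_per_pattern = n_pairs_per_pattern,
                  n_null_features = n_null_features, n_samples = n_samples,
                  noise_sd = noise_sd, seed = seed)),
    class = "ccc_synthetic_dataset")
}

# Re-draw a two-population pattern conditional on a fixed membership vector
# (TRUE = the "active" population: postmortem / male / organ-donor).
regenerate_with_labels <- function(spec, active) {
  set.seed(spec$seed)
  n <- spec$n_samples
  sd <- spec$noise_sd
  x <- numeric(n)
  y <- numeric(n)
  if (spec$pattern == "cohort_shift") {
    x[active] <- stats::runif(sum(active), 0, 2)
    y[active] <- x[active] + 2
    x[!active] <- stats::runif(sum(!active), 2, 4)
    y[!active] <- x[!active] - 2
    y <- y + stats::rnorm(n, 0, sd)
  } else if (spec$pattern == "group_masked") {
    x[active] <- stats::runif(sum(active), 1, 3)
    y[active] <- x[active] + stats::rnorm(sum(active), 0, sd)
    y[!active] <- stats::runif(sum(!active), 3, 5)
  } else if (spec$pattern == "subset_masked") {
    x <- stats::runif(n, 0, 2)
    y[active] <- x[active] + stats::rnorm(sum(active), 0, sd)
    y[!active] <- stats::runif(sum(!active), 0, 2)
  } else {
    stop("regenerate_with_labels: not a two-population pattern")
  }
  list(x = x, y = y, spec = spec)
}
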