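test_that("pattern specs validate their arguments", {
  expect_error(pattern_spec("spiral"), "unknown pattern")
  expect_error(pattern_spec("linear", n_samples = 3), "n_samples")
  expect_error(pattern_spec("linear", noise_sd = -1), "noise_sd")
  expect_error(pattern_spec("linear", group_fraction = 1), "group_fraction")
})

test_that("pattern generation is deterministic under the spec seed", {
  for (pat in c("linear", "quadratic", "cohort_shift", "group_masked",
                "subset_masked", "null")) {
    a <- generate_pair_pattern(pattern_spec(pat, seed = 42))
    b <- generate_pair_pattern(pattern_spec(pat, seed = 42))
    expect_identical(a$x, b$x)
    expect_identical(a$y, b$y)
    expect_identical(a$metadata, b$metadata)
  }
})

test_that("group_masked puts exactly the masked fraction at zero", {
  gp <- generate_pair_pattern(
    pattern_spec("group_masked", n_samples = 100, group_fraction = 0.5,
                 noise_sd = 0, seed = 3))
  expect_identical(sum(gp$x == 0), 50L)
  expect_true(all(gp$x[gp$metadata$group == "M"] > 0))
  # noiseless: y exactly linear in x within the positive group
  m <- gp$metadata$group == "M"
  expect_equal(gp$y[m], gp$x[m])
})

test_that("cohort_shift has positive within-cohort and negative pooled slopes", {
  gp <- generate_pair_pattern(pattern_spec("cohort_shift", n_samples = 200,
                                           noise_sd = 0.1, seed = 8))
  a <- gp$metadata$cohort == "postmortem"
  expect_lt(stats::cor(gp$x, gp$y), 0)
  expect_gt(stats::cor(gp$x[a], gp$y[a]), 0.9)
  expect_gt(stats::cor(gp$x[!a], gp$y[!a]), 0.9)
  expect_gte(ccc_pair(gp$x, gp$y, no_pvalue_config())$ccc, 0.3)
})

test_that("noiseless linear and group-label contracts give CCC of 1", {
  gp <- generate_pair_pattern(pattern_spec("linear", n_samples = 100,
                                           noise_sd = 0, seed = 5))
  expect_equal(ccc_pair(gp$x, gp$y, no_pvalue_config())$ccc, 1)

  gm <- generate_pair_pattern(pattern_spec("group_masked", n_samples = 100,
                                           group_fraction = 0.5, seed = 6))
  r <- ccc_pair(feature_vector(gm$x),
                feature_vector(gm$metadata$group), no_pvalue_config())
  expect_equal(r$ccc, 1)
})

test_that("null pairs have small CCC on average", {
  cccs <- vapply(1:200, function(s) {
    gp <- generate_pair_pattern(pattern_spec("null", n_samples = 100,
                                             seed = s))
    ccc_pair(gp$x, gp$y, no_pvalue_config())$ccc
  }, numeric(1))
  expect_lt(mean(cccs), 0.2)
})

test_that("generate_dataset assembles features, metadata, and truth reproducibly", {
  ds <- generate_dataset(n_pairs_per_pattern = 1, n_null_features = 0,
                         seed = 4)
  expect_identical(dim(ds$expression), c(12L, 200L))
  expect_identical(nrow(ds$truth), 6L)
  expect_false(anyDuplicated(ds$truth[c("feature_x", "feature_y")]) > 0)
  expect_true(all(c(ds$truth$feature_x, ds$truth$feature_y) %in%
                    rownames(ds$expression)))
  expect_identical(colnames(ds$metadata),
                   c("sample_id", "group", "cohort", "age"))
  expect_identical(sum(ds$metadata$group == "M"), 100L)

  ds2 <- generate_dataset(n_pairs_per_pattern = 1, n_null_features = 0,
                          seed = 4)
  expect_identical(ds$expression, ds2$expression)
  expect_identical(ds$metadata, ds2$metadata)

  ds3 <- generate_dataset(n_pairs_per_pattern = 2, n_null_features = 3,
                          seed = 4)
  expect_identical(dim(ds3$expression), c(27L, 200L))
  expect_error(generate_dataset(0, 0), "zero total features")
})

test_that("dataset motifs are recovered by the coefficients they target", {
  ds <- generate_dataset(seed = 1)
  res <- ccc_matrix(ds$expression, no_pvalue_config())
  key <- paste(res$feature_i, res$feature_j)
  get <- function(tr) res[key == paste(tr$feature_x, tr$feature_y), ]
  pe <- function(tr) stats::cor(ds$expression[tr$feature_x, ],
                                ds$expression[tr$feature_y, ])
  tr <- split(ds$truth, ds$truth$pattern)

  # strong-signal motifs clear the fixture floor with Pearson below CCC
  for (pat in c("quadratic", "cohort_shift", "group_masked")) {
    expect_gte(get(tr[[pat]])$ccc, 0.3)
    expect_lt(abs(pe(tr[[pat]])), get(tr[[pat]])$ccc)
  }
  # the masked-subset motif is detectable but weaker by construction
  expect_gte(get(tr[["subset_masked"]])$ccc, 0.1)
  expect_gte(get(tr[["linear"]])$ccc, 0.5)
  expect_lt(get(tr[["null"]])$ccc, 0.15)

  # gene-group association: the masked gene is fully explained by the group
  gm_x <- tr[["group_masked"]]$feature_x
  r <- ccc_pair(feature_vector(ds$expression[gm_x, ]),
                feature_vector(ds$metadata$group), no_pvalue_config())
  expect_equal(r$ccc, 1)

})

test_that("a structurally Pearson-null quadratic tiers CCC-high and Pearson-low in a mixed suite", {
  # symmetric grid: the quadratic's Pearson is exactly zero by design, the
  # lowest possible magnitude, so its low tier is deterministic
  x <- seq(-1, 1, length.out = 200)
  set.seed(17)
  m <- rbind(qx = x, qy = x^2,
             lx = seq(0, 1, length.out = 200),
             ly = seq(0, 1, length.out = 200) * 2 + stats::rnorm(200, 0, 0.05),
             matrix(stats::rnorm(6 * 200), 6, 200,
                    dimnames = list(paste0("n", 1:6), NULL)))
  res <- ccc_matrix(m, no_pvalue_config())
  pev <- baseline_coefficients(m, "pearson")$value
  tiers_c <- classify_tiers(res$ccc, 0.3, 0.3)
  tiers_p <- classify_tiers(pev, 0.3, 0.3, magnitude = TRUE)
  qidx <- which(res$feature_i == "qx" & res$feature_j == "qy")
  lidx <- which(res$feature_i == "lx" & res$feature_j == "ly")
  expect_identical(tiers_c[qidx], "high")
  expect_identical(tiers_p[qidx], "low")
  # the strong linear pair agrees across all coefficients
  tiers_s <- classify_tiers(baseline_coefficients(m, "spearman")$value,
                            0.3, 0.3, magnitude = TRUE)
  ic <- intersect_categories(tiers_c, tiers_p, tiers_s)
  expect_identical(ic$pairs$class[lidx], "agreement")
  expect_identical(ic$pairs$class[qidx], "disagreement")
})
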