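test_that("Cohen's kappa evaluates the chance-corrected agreement formula", {
  # confusion table [[20, 5], [10, 15]], n = 50
  truth <- rep(c("a", "b"), c(25, 25))
  pred <- rep(c("a", "b", "a", "b"), c(20, 5, 10, 15))
  k <- cohen_kappa(truth, pred)
  expect_equal(k$po, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4)
  # perfect agreement
  expect_equal(cohen_kappa(truth, truth)$kappa, 1)
  # both constant and equal: defined as 1
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5))$kappa, 1)
  # total disagreement on a balanced binary problem
  expect_equal(cohen_kappa(c("a", "b"), c("b", "a"))$kappa, -1)
  expect_error(cohen_kappa(character(0), character(0)), "non-empty")
  expect_error(cohen_kappa(c("a", "b"), "a"), "equal length")
})

test_that("kappa matches an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(51)
  for (i in 1:25) {
    truth <- sample(letters[1:3], 60, replace = TRUE)
    pred <- sample(letters[1:3], 60, replace = TRUE)
    tab <- table(factor(truth, levels = letters[1:3]),
                 factor(pred, levels = letters[1:3]))
    expect_equal(cohen_kappa(truth, pred)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("shuffled predictions give near-zero kappa at large n", {
  set.seed(52)
  truth <- sample(c("a", "b"), 1e4, replace = TRUE, prob = c(0.6, 0.4))
  expect_lt(abs(cohen_kappa(truth, sample(truth))$kappa), 0.05)
})

test_that("bootstrap splits are deterministic, disjoint and class-complete", {
  labels <- rep(c("a", "b"), each = 100)
  sp <- paired_bootstrap_splits(200, labels, n_boot = 30, seed = 3)
  sp2 <- paired_bootstrap_splits(200, labels, n_boot = 30, seed = 3)
  expect_identical(sp, sp2)
  for (b in seq_along(sp)) {
    expect_length(sp[[b]]$train, 100)
    expect_length(sp[[b]]$test, 100)
    expect_length(intersect(sp[[b]]$train, sp[[b]]$test), 0)
    expect_setequal(c(sp[[b]]$train, sp[[b]]$test), 1:200)
    expect_setequal(unique(labels[sp[[b]]$train]), c("a", "b"))
  }
  # minimal case: n = 4 balanced -> one disjoint 2/2 split
  m <- paired_bootstrap_splits(4, c("a", "a", "b", "b"), n_boot = 1, seed = 1)
  expect_length(m[[1]]$train, 2)
  expect_length(m[[1]]$test, 2)
  # different seeds give different splits
  expect_false(identical(paired_bootstrap_splits(200, labels, 5, seed = 1),
                         paired_bootstrap_splits(200, labels, 5, seed = 2)))
  expect_error(paired_bootstrap_splits(3, n_boot = 1), "at least 4")
  expect_error(paired_bootstrap_splits(10, split = 1), "fraction")
  # an impossible class constraint fails loudly after the retry budget
  expect_error(paired_bootstrap_splits(8, c(rep("a", 7), "b"), n_boot = 50,
                                       split = 0.25, max_retry = 3),
               "absent")
})

test_that("group-stratified splits sample within pseudo-subjects", {
  groups <- rep(1:4, each = 10)
  sp <- paired_bootstrap_splits(40, groups = groups, n_boot = 5, seed = 2)
  for (b in seq_along(sp)) {
    expect_length(sp[[b]]$train, 20)
    per_group <- table(groups[sp[[b]]$train])
    expect_true(all(per_group == 5))
  }
})

test_that("baseline classifiers honour the shared fit/predict contract", {
  cfg <- benchmark_config()
  set.seed(53)
  x <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
  y <- rep(c("a", "b"), each = 100)
  xt <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  yt <- rep(c("a", "b"), each = 50)
  # LDA on two well-separated Gaussians
  lda <- baseline_classifier("LDA", cfg)
  acc <- mean(as.character(lda$predict(lda$fit(x, y), xt)) == yt)
  expect_gt(acc, 0.95)
  # 2-NN classifies a duplicate of a training point as that point's class
  knn <- baseline_classifier("2-NN", cfg)
  mk <- knn$fit(x, y)
  expect_equal(as.character(knn$predict(mk, x[5, , drop = FALSE])), "a")
  # MLP: identical seed, identical predictions
  mlp <- baseline_classifier("MLP", cfg)
  p1 <- mlp$predict(mlp$fit(x, y, seed = 11), xt)
  p2 <- mlp$predict(mlp$fit(x, y, seed = 11), xt)
  expect_identical(p1, p2)
  # NLCS wrapper dispatches to the package classifier
  nl <- baseline_classifier("NLCS", cfg)
  expect_s3_class(nl$fit(x, y), "nlcs")
})

test_that("the deterministic 2-NN agrees with class::knn away from ties", {
  skip_if_not_installed("class")
  set.seed(54)
  x <- matrix(rnorm(120), 60, 2)
  y <- factor(rep(c("a", "b"), 30))
  xt <- matrix(rnorm(40), 20, 2)
  ours <- knn_predict(x, y, xt, k = 1)
  ref <- class::knn(x, xt, y, k = 1)
  expect_equal(as.character(ours), as.character(ref))
})

test_that("LDA falls back to shrinkage when within-class variance vanishes", {
  x <- rbind(matrix(1, 10, 3), matrix(2, 10, 3))   # zero within-class spread
  y <- rep(c("a", "b"), each = 10)
  lda <- baseline_classifier("LDA", benchmark_config())
  m <- lda$fit(x, y)
  expect_true(m$shrinkage)
  expect_equal(as.character(lda$predict(m, rbind(rep(1, 3), rep(2, 3)))),
               c("a", "b"))
})

test_that("a one-cell benchmark reduces to a direct fit-predict-kappa call", {
  cfg <- phantom_config(grid = default_grid(5, 5, 5), voxels_per_class = 12,
                        seed = 2)
  ds <- realize_dataset(make_truth_spectra(cfg))
  bc <- benchmark_config(n_boot = 1, seed = 2, methods = "NLCS",
                         representations = "signal")
  rep1 <- run_benchmark(ds, bc)
  sp <- paired_bootstrap_splits(24, ds$labels, n_boot = 1, seed = 2)[[1]]
  m <- nlcs_fit(ds$signal[sp$train, ], ds$labels[sp$train], k = bc$nlcs_k)
  k_direct <- cohen_kappa(ds$labels[sp$test],
                          predict(m, ds$signal[sp$test, ]))$kappa
  expect_equal(as.numeric(rep1$kappa[1, "NLCS", "signal"]), k_direct)
})

test_that("all benchmark cells reach kappa 1 on the separable smoke phantom", {
  cfg <- phantom_config(classes = default_phantom_classes(jitter = 0),
                        grid = default_grid(6, 6, 6), voxels_per_class = 8,
                        noise_model = "none", seed = 4)
  ds <- realize_dataset(make_truth_spectra(cfg))
  rep <- run_benchmark(ds, benchmark_config(n_boot = 3, seed = 4))
  expect_true(all(rep$kappa == 1))
  expect_true(all(rep$failures == 0))
})

test_that("empirical prediction error respects the Fano bound from the exact chain", {
  set.seed(55)
  f <- make_chain_fixture(c(3, 4, 4), seed = 9)
  jxy <- f$px * f$channel_xy
  et <- entropy_terms(discrete_joint(jxy / sum(jxy)))
  fano <- fano_lower(et$H_X_given_Y, 3, clamp = TRUE)
  # draw labelled samples from the chain, learn the empirical MAP rule on
  # one half and score it on the other
  n <- 2e4
  cells <- sample(length(jxy), n, replace = TRUE, prob = as.numeric(jxy))
  x <- (cells - 1) %% 3 + 1
  y <- (cells - 1) %/% 3 + 1
  train <- seq_len(n / 2); test <- setdiff(seq_len(n), train)
  map_rule <- apply(unclass(table(x[train], y[train])), 2, which.max)
  err <- mean(map_rule[y[test]] != x[test])
  expect_gte(err, fano)
  # and it cannot beat the exact Bayes error by more than noise
  expect_gte(err, bayes_error(discrete_joint(jxy / sum(jxy))) - 0.02)
})

test_that("kappa reports are paired, bounded and reproducible", {
  cfg <- phantom_config(grid = default_grid(5, 5, 5), voxels_per_class = 10,
                        seed = 5)
  ds <- realize_dataset(make_truth_spectra(cfg))
  bc <- benchmark_config(n_boot = 4, seed = 5, methods = c("2-NN", "NLCS"),
                         representations = c("signal", "T1-T2"))
  r1 <- run_benchmark(ds, bc)
  r2 <- run_benchmark(ds, bc)
  expect_identical(r1$kappa, r2$kappa)
  expect_identical(r1$splits, r2$splits)
  expect_true(all(r1$kappa >= -1 & r1$kappa <= 1, na.rm = TRUE))
  # pairing: stored splits equal an independent regeneration from the config
  regen <- paired_bootstrap_splits(20, droplevels(ds$labels),
                                   n_boot = 4, seed = 5)
  expect_identical(r1$splits, regen)
  # CSV export round-trip
  dir <- withr::local_tempdir()
  write_kappa_report(r1, dir)
  tab <- read.csv(file.path(dir, "kappa_table.csv"), row.names = 1)
  expect_equal(as.matrix(tab), r1$mean, ignore_attr = TRUE)
  raw <- read.csv(file.path(dir, "kappa_raw.csv"))
  expect_equal(nrow(raw), 4 * 2 * 2)
})
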