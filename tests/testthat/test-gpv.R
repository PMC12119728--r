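make_lesion_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * length(gpv_columns("GpVd")), 5, 2),
                             nrow = n))
  names(df) <- gpv_columns("GpVd")
  df
}

test_that("variant column sets follow the static/dynamic rule", {
  dyn <- c("Ki_std", "Ki_mod", "K1", "k2", "k3", "vb")
  expect_length(intersect(gpv_columns("GpVs"), dyn), 0)
  expect_true(all(dyn %in% gpv_columns("GpVd")))
  expect_true(all(gpv_columns("GpVs") %in% gpv_columns("GpVd")))
})

test_that("feature assembly standardises, refuses gaps, and round-trips", {
  df <- make_lesion_df(8)
  tab <- assemble_features(df, "GpVd")
  expect_equal(unname(colMeans(tab$features)),
               rep(0, ncol(tab$features)), tolerance = 1e-12)
  expect_equal(unname(vapply(tab$features, sd, numeric(1))),
               rep(1, ncol(tab$features)), tolerance = 1e-12)

  # identical lesions produce identical standardised rows
  df2 <- rbind(df, df[3, ])
  tab2 <- assemble_features(df2, "GpVd")
  expect_equal(unlist(tab2$features[3, ]), unlist(tab2$features[9, ]))

  # inverse transform recovers the raw values
  expect_equal(as.matrix(unstandardise_features(tab)), as.matrix(df),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(assemble_features(df[, -2], "GpVd"), "missing required")
  dfna <- df; dfna[2, 4] <- NA
  expect_error(assemble_features(dfna, "GpVd"), "missing values")
  expect_silent(assemble_features(dfna, "GpVd", impute = "median"))
})

test_that("LASSO classifier selects the true support on separable data", {
  st <- simulate_feature_table(n_lesions = 200, n_features = 20,
                               support = 3, effect_size = 5, seed = 42)
  tab <- assemble_features(st$features, "custom",
                           columns = names(st$features))
  m <- fit_lasso_classifier(tab, st$labels, seed = 7)
  truth <- paste0("F", st$support)
  expect_true(all(truth %in% m$selected_features))
  expect_lte(length(setdiff(m$selected_features, truth)), 2L)

  # path sparsity is monotone along the penalty grid
  nz <- m$path_nonzero$nonzero[order(m$path_nonzero$lambda)]
  expect_true(all(diff(nz) <= 0))
  # at the largest penalty everything is shrunk away
  expect_equal(nz[length(nz)], 0)

  # reproducible given the seed (fold assignment fixed)
  m2 <- fit_lasso_classifier(tab, st$labels, seed = 7)
  expect_identical(m$lambda, m2$lambda)
  expect_identical(m$weights, m2$weights)

  expect_error(fit_lasso_classifier(tab, rep(1, 200)), "single class")
})

test_that("scoring is a checked linear predictor, invariant to row order", {
  df <- make_lesion_df(10)
  tab <- assemble_features(df, "GpVd")
  model <- structure(list(selected_features = c("SUVmax", "Ktrans"),
                          weights = c(SUVmax = 1, Ktrans = -0.5),
                          intercept = 0.2, lambda = 0.1, rule = "min",
                          variant = "GpVd",
                          standardisation = list(center = tab$center,
                                                 scale = tab$scale)),
                     class = "gpv_model")
  sc <- compute_gpv(tab, model)
  expect_equal(sc, 0.2 + tab$features$SUVmax - 0.5 * tab$features$Ktrans)

  # zero weights: all scores equal the intercept
  m0 <- model; m0$selected_features <- character(0); m0$weights <- numeric(0)
  expect_equal(compute_gpv(tab, m0), rep(0.2, 10))

  # row permutation permutes scores identically
  perm <- sample(10)
  expect_equal(compute_gpv(tab$features[perm, ], model), sc[perm])

  # raw table through the stored standardisation gives the same scores
  expect_equal(compute_gpv(df, model, standardised = FALSE), sc)
  expect_error(compute_gpv(df[, -1], model, standardised = FALSE),
               "missing required")

  # JSON serialisation round trip preserves scoring exactly
  p <- withr::local_tempfile(fileext = ".json")
  write_gpv_json(model, p)
  back <- read_gpv_json(p)
  expect_equal(compute_gpv(df, back, standardised = FALSE), sc)
})

test_that("ROC evaluation equals the pair-counting (Mann-Whitney) oracle", {
  # perfectly separated scores
  ev <- evaluate_classifier(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 1)

  # 6-point toy list against exhaustive pair counting
  s <- c(0.2, 0.8, 0.4, 0.9, 0.1, 0.7); l <- c(0, 1, 1, 1, 0, 0)
  pos <- s[l == 1]; neg <- s[l == 0]
  oracle <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(evaluate_classifier(s, l)$auc, oracle)

  # random instances, including ties
  set.seed(77)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) l[1] <- 1 - l[1]
    pos <- s[l == 1]; neg <- s[l == 0]
    oracle <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(evaluate_classifier(s, l)$auc, oracle, tolerance = 1e-12)
  }

  # label-independent scores at large n: AUC near one half
  set.seed(78)
  ev2 <- evaluate_classifier(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_equal(ev2$auc, 0.5, tolerance = 0.05)
  expect_error(evaluate_classifier(1:5, rep(1, 5)), "both classes")
})

test_that("trained vector transfers to unseen lesions with high accuracy", {
  tr <- simulate_feature_table(200, 20, 3, 5, seed = 1)
  te <- simulate_feature_table(400, 20, 3, 5, seed = 2)
  tab <- assemble_features(tr$features, "custom", columns = names(tr$features))
  m <- fit_lasso_classifier(tab, tr$labels, seed = 3)
  thr <- evaluate_classifier(compute_gpv(tab, m), tr$labels)$threshold
  ev <- evaluate_classifier(compute_gpv(te$features, m, standardised = FALSE),
                            te$labels, threshold = thr)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auc, 0.99)
})
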