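test_that("cohort comparison reports rank-sum p with exact small-sample tails", {
  # completely separated n = 4/4 against an exhaustive permutation oracle
  df <- data.frame(v = c(1, 2, 3, 4, 11, 12, 13, 14))
  grp <- rep(c("a", "b"), each = 4)
  res <- compare_groups(df, grp)
  combos <- utils::combn(8, 4)
  stat <- apply(combos, 2, function(ix) sum(rank(df$v)[ix]))
  obs <- sum(rank(df$v)[1:4])
  p_oracle <- 2 * mean(stat <= obs)   # two-sided, symmetric null
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$mean_a, 2.5)
  expect_equal(res$sd_b, sd(c(11, 12, 13, 14)))

  # identical groups: maximal p
  di <- data.frame(v = rep(c(5, 6, 7), 2))
  pv <- compare_groups(di, rep(c("a", "b"), each = 3))$p_value
  expect_gte(pv, 0.99)

  expect_error(compare_groups(df, rep("a", 8)), "two groups")
  expect_error(compare_groups(df, c("a", rep("b", 7))), ">= 2")
})

test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  # single subject, event at 5
  k1 <- km_estimate(5, 1)
  expect_equal(k1$curve$surv[k1$curve$time == 5], 0)
  expect_equal(k1$median, 5)

  # all censored: survival stays at 1, median undefined
  k2 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(k2$curve$surv == 1))
  expect_false(k2$median_defined)

  # events at 1 and 3, censored at 2, 4, 5:
  # S(1) = 4/5; S(3) = 4/5 * 2/3 = 8/15
  k3 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))
  expect_equal(k3$curve$surv[k3$curve$time == 1], 4 / 5)
  expect_equal(k3$curve$surv[k3$curve$time == 3], 8 / 15)

  # without censoring the KM curve is the empirical survivor function
  set.seed(61)
  tt <- rexp(300, 0.2)
  k4 <- km_estimate(tt, rep(1, 300))
  emp <- vapply(k4$curve$time, function(x) mean(tt > x), numeric(1))
  expect_equal(k4$curve$surv, emp, tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("marker dichotomisation splits, estimates medians, reports both tests", {
  rec <- data.frame(time_months = c(2, 4, 6, 10, 15, 20),
                    event = rep(1L, 6))
  marker <- c(3, 3, 3, 1, 1, 1)   # high marker = short survival
  sp <- dichotomise_survival(rec, marker, cutoff = 2)
  expect_equal(sp$median_high, 4)
  expect_equal(sp$median_low, 15)
  expect_equal(sp$n_high, 3L)
  expect_true(sp$p_mann_whitney > 0 && sp$p_mann_whitney <= 1)
  expect_true(sp$p_logrank > 0 && sp$p_logrank <= 1)

  # monotone relabelling of the marker leaves the split unchanged
  sp2 <- dichotomise_survival(rec, exp(marker), cutoff = exp(2))
  expect_equal(sp2$median_high, sp$median_high)
  expect_equal(sp2$p_mann_whitney, sp$p_mann_whitney)

  expect_error(dichotomise_survival(rec, marker, cutoff = 99), "empty")
})

test_that("two-group exponential survival recovers the generating medians", {
  sv <- simulate_survival(n = 1000, group_rates = c(low = log(2) / 15,
                                                    high = log(2) / 4),
                          censoring_rate = 0, seed = 9)
  marker <- ifelse(sv$group == "high", 3, 1)
  sp <- dichotomise_survival(sv, marker, 2)
  expect_equal(sp$median_high, 4, tolerance = 0.1)
  expect_equal(sp$median_low, 15, tolerance = 0.1)
  expect_lt(sp$p_mann_whitney, 1e-10)
  expect_lt(sp$p_logrank, 1e-10)
})

test_that("metabolite screen matches hand Welch-Satterthwaite arithmetic", {
  # printed toy pair with unequal variances (already log scale)
  a <- c(1.0, 1.4, 1.8); b <- c(4.9, 5.1, 6.2)
  mat <- rbind(m1 = exp(c(a, b)))
  colnames(mat) <- paste0("s", 1:6)
  res <- metabolite_screen(mat, rep(c("g1", "g2"), each = 3))
  va <- var(a); vb <- var(b)
  t_hand <- (mean(b) - mean(a)) / sqrt(va / 3 + vb / 3)
  df_hand <- (va / 3 + vb / 3)^2 /
    ((va / 3)^2 / 2 + (vb / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df_hand))
  expect_equal(res$fold_change, exp(mean(b) - mean(a)))
  expect_identical(res$category, "sig-up")

  # identical groups: unit fold-change, not significant
  same <- rbind(x = rep(c(2, 3, 4), 2))
  colnames(same) <- paste0("s", 1:6)
  r2 <- metabolite_screen(same, rep(c("g1", "g2"), each = 3))
  expect_equal(r2$fold_change, 1)
  expect_identical(r2$category, "ns")

  # zero variance in both groups is flagged, not crashed
  flat <- rbind(x = rep(5, 6))
  colnames(flat) <- paste0("s", 1:6)
  expect_true(is.na(metabolite_screen(flat,
                                      rep(c("g1", "g2"), each = 3))$p))
})

test_that("screen-wide q-values and shading rules behave as estimators", {
  met <- simulate_metabolomics(n_per_group = c(A = 8, B = 8),
                               n_metabolites = 300, block_size = 20,
                               fold_changes = c(B = 2), seed = 12)
  scr <- metabolite_screen(met$matrix, met$groups)
  expect_true(all(scr$q >= scr$p - 1e-12, na.rm = TRUE))
  expect_true(all(scr$category[!is.na(scr$p) & scr$p <= 0.05] %in%
                    c("sig-up", "sig-down")))
  expect_true(all(scr$category[!is.na(scr$p) & scr$p > 0.05 &
                                 scr$p < 0.10] %in%
                    c("trend-up", "trend-down")))

  # Welch p invariant to a common positive rescaling of the logged data
  # (equivalently, raising the raw abundances to a power)
  scr2 <- metabolite_screen(met$matrix^2, met$groups)
  expect_equal(scr2$p, scr$p, tolerance = 1e-12)
})

test_that("PCA overview reports variance fractions faithfully", {
  # exact 1-D structure
  set.seed(71)
  u <- rnorm(20)
  line <- outer(c(1, 2, 3), u) + 5
  p1 <- pca_overview(exp(line), n_components = 2)
  expect_equal(p1$percent_variance[1], 100, tolerance = 1e-9)

  # 4x3 hand matrix against a direct SVD oracle
  m <- matrix(c(1, 2, 3, 4, 2, 1, 0, 1, 5, 5, 4, 6), nrow = 3,
              byrow = TRUE)
  rownames(m) <- paste0("met", 1:3); colnames(m) <- paste0("s", 1:4)
  po <- pca_overview(exp(m), n_components = 3)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- svd(x)$d^2
  expect_equal(po$percent_variance, 100 * ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(po$percent_variance) <= 1e-12))
  expect_equal(sum(po$percent_variance), 100)

  # isotropic 2-D cloud: two roughly equal components
  set.seed(72)
  iso <- exp(matrix(rnorm(2 * 3000), nrow = 2))
  p2 <- pca_overview(iso, n_components = 2)
  expect_equal(p2$percent_variance[1], 50, tolerance = 3)

  expect_error(pca_overview(matrix(1:3, ncol = 1)), ">= 2")
})
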