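test_that("population AIF starts at zero, stays nonnegative, AUC matches quadrature", {
  sch <- make_schedule28()
  input <- make_input28()
  expect_equal(input$cp[1L], 0)
  expect_true(all(input$cp >= 0))
  expect_equal(input$time[which.max(input$cp)], 1.05, tolerance = 0.3)

  # AUC over 0-60 min vs an independent trapezoid oracle on a 0.2 s grid
  p <- default_aif_params()
  tq <- seq(0, 60, by = 0.2 / 60)
  cq <- (p$A1 * tq - p$A2 - p$A3) * exp(-p$lambda1 * tq) +
    p$A2 * exp(-p$lambda2 * tq) + p$A3 * exp(-p$lambda3 * tq)
  auc_oracle <- sum(diff(tq) * (cq[-1] + cq[-length(cq)]) / 2)
  sel <- input$time <= 60
  auc_pkg <- sum(diff(input$time[sel]) *
                   (input$cp[sel][-1] + input$cp[sel][-sum(sel)]) / 2)
  expect_equal(auc_pkg, auc_oracle, tolerance = 1e-3)

  # washout rates -> 0: curve stops decaying (monotone after the bolus)
  flat <- make_population_aif(params = list(A1 = 30, A2 = 6, A3 = 2,
                                            lambda1 = 1e-9, lambda2 = 1e-9,
                                            lambda3 = 1e-9),
                              schedule = sch)
  late <- flat$cp[flat$time > 2]
  expect_true(all(diff(late) >= -1e-9))
})

test_that("population input scales to a blood TAC by AUC matching", {
  input <- make_input28()
  tb <- seq(0.5, 60, by = 0.5)
  shape_at_tb <- approx(input$time, input$cb, xout = tb)$y
  blood <- time_activity_curve(tb, 2 * shape_at_tb, label = "sagittal-sinus")
  scaled <- scale_population_input(input, blood)
  expect_equal(attr(scaled, "scale_factor"), 2, tolerance = 1e-12)
  expect_equal(scaled$cb, 2 * input$cb)
  expect_identical(scaled$provenance, "population-scaled")

  expect_error(scale_population_input(input, blood, window = c(100, 110)),
               "window")

  # noisy blood curve: recovered scale within 2 percent
  set.seed(31)
  noisy <- time_activity_curve(tb, 3.7 * shape_at_tb *
                                 (1 + rnorm(length(tb), 0, 0.01)))
  s <- attr(scale_population_input(input, noisy), "scale_factor")
  expect_equal(s, 3.7, tolerance = 0.02)
})

test_that("2TCM simulator obeys closed-form limits and matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  sch <- make_schedule28()
  input <- make_input28()

  # K1 = 0: pure blood spillover
  t0 <- simulate_2tcm_tac(input, list(k1 = 0, k2 = 0.1, k3 = 0.01,
                                      vb = 0.05), sch)
  cb_frames <- simulate_2tcm_tac(input, list(k1 = 0, k2 = 0, k3 = 0, vb = 1),
                                 sch)
  expect_equal(t0$value, 0.05 * cb_frames$value)

  # k3 = 0 with a sustained input: late-time distribution-volume plateau
  # C_t/C_p -> K1/k2 (for a decaying input the quasi-equilibrium ratio is
  # K1/(k2 - lambda), so the clean plateau needs a constant tail)
  tconst <- seq(0, 66.5, by = 1 / 60)
  const_inp <- input_function(tconst, rep(3, length(tconst)))
  tp <- simulate_2tcm_tac(const_inp, list(k1 = 0.1, k2 = 0.15, k3 = 0,
                                          vb = 0), sch)
  expect_equal(tail(tp$value, 1) / 3, 0.1 / 0.15, tolerance = 1e-4)

  # frame-averaged curve vs explicit ODE integration (independent oracle)
  tac <- simulate_2tcm_tac(input, lesion_truth(), sch)
  rhs <- function(t, y, p) {
    cp <- approx(input$time, input$cp, xout = t, rule = 2)$y
    list(c(p$k1 * cp - (p$k2 + p$k3) * y[1], p$k3 * y[1]))
  }
  tf <- seq(0, 66.5, by = 0.1 / 60)
  sol <- deSolve::ode(c(0, 0), tf, rhs, lesion_truth(), method = "lsoda")
  ct <- (1 - 0.03) * (sol[, 2] + sol[, 3]) +
    0.03 * approx(input$time, input$cb, xout = tf, rule = 2)$y
  oracle <- vapply(seq_along(sch$frame_start), function(i) {
    s <- sch$frame_start[i] / 60; e <- s + sch$frame_duration[i] / 60
    mean(ct[tf >= s - 1e-9 & tf <= e + 1e-9])
  }, numeric(1))
  expect_lt(max(abs(tac$value[-1] - oracle[-1]) / oracle[-1]), 0.005)

  expect_error(simulate_2tcm_tac(input, list(k1 = -0.1, k2 = 0.1, k3 = 0,
                                             vb = 0), sch), "nonnegative")
})

test_that("simulators are deterministic given (parameters, seed)", {
  sch <- make_schedule28()
  input <- make_input28()
  n <- noise_spec("gaussian", 0.05, seed = 99)
  a <- simulate_2tcm_tac(input, lesion_truth(), sch, noise = n)
  b <- simulate_2tcm_tac(input, lesion_truth(), sch, noise = n)
  expect_identical(a$value, b$value)
  c_ <- simulate_2tcm_tac(input, lesion_truth(), sch,
                          noise = noise_spec("gaussian", 0.05, seed = 100))
  expect_false(identical(a$value, c_$value))

  ft1 <- simulate_feature_table(seed = 5)
  ft2 <- simulate_feature_table(seed = 5)
  expect_identical(ft1$features, ft2$features)

  m1 <- simulate_metabolomics(seed = 8)
  m2 <- simulate_metabolomics(seed = 8)
  expect_identical(m1$matrix, m2$matrix)
})

test_that("frame averaging converges to instantaneous sampling for short frames", {
  input <- make_input28()
  fine_sch <- frame_schedule_from_counts(600, 1)   # 1 s frames, 10 min
  tac <- simulate_2tcm_tac(input, lesion_truth(), fine_sch)
  inst <- approx(input$time,
                 (1 - 0.03) * (0.1 * (0.02 / 0.17) *
                                 petmrquant:::cumtrapz_int(input$time,
                                                           input$cp) +
                                 0.1 * (0.15 / 0.17) *
                                 petmrquant:::exp_conv(input$time, input$cp,
                                                       0.17)) +
                   0.03 * input$cb,
                 xout = tac$time)$y
  expect_equal(tac$value[-(1:5)], inst[-(1:5)], tolerance = 1e-3)
})

test_that("feature-table generator has the stated class structure", {
  # null effect: labels carry no information (AUC near 0.5 over repeats)
  aucs <- vapply(1:10, function(r) {
    ft <- simulate_feature_table(n_lesions = 200, effect_size = 0, seed = r)
    sc <- rowSums(ft$features[, ft$support, drop = FALSE])
    evaluate_classifier(sc, ft$labels)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)

  # strong effect: near-perfect separability on the support score
  ft <- simulate_feature_table(n_lesions = 200, effect_size = 5, seed = 3)
  sc <- rowSums(ft$features[, ft$support, drop = FALSE])
  expect_gt(evaluate_classifier(sc, ft$labels)$auc, 0.99)

  expect_error(simulate_feature_table(n_features = 5, support = 9),
               "support")
})

test_that("survival generator matches exponential closed forms", {
  # true median ln2 / rate; large-sample KM median close to it
  sv <- simulate_survival(n = 4000, rate = log(2) / 4, censoring_rate = 0,
                          seed = 17)
  expect_equal(km_estimate(sv$time_months, sv$event)$median, 4,
               tolerance = 0.1)
  expect_true(all(sv$event == 1L))

  allc <- simulate_survival(n = 50, rate = 0.1, censoring_rate = 1, seed = 2)
  expect_true(all(allc$event == 0L))
  expect_false(km_estimate(allc$time_months, allc$event)$median_defined)

  expect_error(simulate_survival(n = 10, rate = -1), "positive")
  expect_error(simulate_survival(n = 10, group_rates = c(a = 0, b = 1)),
               "positive")
})

test_that("metabolomics generator: null calibration and elevated block", {
  # all fold-changes 1: ~5% of Welch tests significant at 0.05
  null <- simulate_metabolomics(n_per_group = c(A = 10, B = 10),
                                n_metabolites = 2000, block_size = 10,
                                fold_changes = c(B = 1), seed = 4)
  scr <- metabolite_screen(null$matrix, null$groups)
  expect_gte(mean(scr$p <= 0.05, na.rm = TRUE), 0.035)
  expect_lte(mean(scr$p <= 0.05, na.rm = TRUE), 0.065)

  # fold-change 6 block dominates the q-ranked list
  met <- simulate_metabolomics(n_per_group = c(LGG = 10, METS = 10),
                               n_metabolites = 150, block_size = 10,
                               fold_changes = c(METS = 6), seed = 9)
  scr2 <- metabolite_screen(met$matrix, met$groups)
  top10 <- scr2$metabolite[order(scr2$q)][1:10]
  expect_gte(sum(grepl("^carnitine", top10)), 9)

  expect_error(simulate_metabolomics(n_per_group = c(A = 1, B = 5)), ">= 2")
})
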