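test_that("Durbin-Watson matches closed forms and the reference implementation", {
  expect_equal(durbin_watson(rep(2.5, 10)), 0)
  # alternating +1,-1 of length n has d = 4(n-1)/n
  for (n in c(4, 11, 50)) {
    e <- rep(c(1, -1), length.out = n)
    expect_equal(durbin_watson(e), 4 * (n - 1) / n)
  }
  expect_error(durbin_watson(rep(0, 5)), "undefined")
  expect_error(durbin_watson(1), "at least 2")

  # iid standard-normal residuals give d near 2
  set.seed(42)
  dws <- replicate(50, durbin_watson(stats::rnorm(1000)))
  expect_equal(mean(dws), 2, tolerance = 0.15 / 2)

  skip_if_not_installed("lmtest")
  set.seed(7)
  x <- stats::rnorm(40)
  y <- 1 + 2 * x + stats::rnorm(40)
  fit <- stats::lm(y ~ x)
  expect_equal(durbin_watson(stats::residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("Breusch-Pagan equals the n*R2 auxiliary form and lmtest's statistic", {
  panel <- unit_panel()
  spec <- design_spec(panel, internal_rescale = FALSE)
  grid <- default_dose_grid(panel, m = Inf)
  set.seed(3)
  y <- 60 - 5 * grid$a + stats::rnorm(nrow(grid), 0, 4)
  agg <- cbind(grid, endpoint = "viability_pct", context = "x",
               mean_value = y)
  m <- fit_quadratic_surface(agg, spec)
  bp <- breusch_pagan(m)
  expect_gte(bp$statistic, 0)
  expect_true(bp$p_value >= 0 && bp$p_value <= 1)

  # textbook recomputation: n * R2 of e^2 on the design
  X <- build_design_matrix(grid, spec)
  e2 <- m$residuals^2
  aux <- stats::lm.fit(X, e2)
  r2_aux <- 1 - sum(aux$residuals^2) / sum((e2 - mean(e2))^2)
  expect_equal(bp$statistic, nrow(grid) * r2_aux, tolerance = 1e-10)

  skip_if_not_installed("lmtest")
  df <- cbind(data.frame(y = y), as.data.frame(X[, -1]))
  names(df) <- c("y", paste0("t", 1:9))
  fit <- stats::lm(y ~ ., data = df)
  ref <- lmtest::bptest(fit)
  expect_equal(bp$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(bp$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("Breusch-Pagan is calibrated under the null and powered under heteroscedasticity", {
  panel <- unit_panel()
  spec <- design_spec(panel, internal_rescale = FALSE)
  set.seed(10)
  grid <- data.frame(a = stats::runif(100, 0, 1),
                     b = stats::runif(100, 0, 2),
                     c = stats::runif(100, 0, 3))
  # power: variance proportional to a regressor
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 50 - 4 * grid$a + stats::rnorm(100, 0, 1 + 4 * grid$b)
    agg <- cbind(grid, endpoint = "viability_pct", context = "x",
                 mean_value = y)
    breusch_pagan(fit_quadratic_surface(agg, spec))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("Shapiro-Wilk wrapper validates input and detects skew", {
  expect_error(shapiro_wilk(c(1, 2)), "outside supported range")
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
  set.seed(5)
  p_skew <- vapply(1:60, function(s) {
    set.seed(s)
    shapiro_wilk(stats::rexp(100))$p_value
  }, numeric(1))
  expect_gte(mean(p_skew < 0.05), 0.9)
  sw <- shapiro_wilk(stats::rnorm(50))
  expect_true(sw$statistic > 0 && sw$statistic <= 1)
})

test_that("VIF matches the 1/(1-r^2) closed form and flags exact collinearity", {
  # mutually orthogonal columns -> all VIF 1
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)

  # constructed pair with sample correlation 0.8 -> both VIF 1/(1-0.64)
  n <- 200
  set.seed(8)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  z1 <- (z1 - mean(z1)) / stats::sd(z1)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))
  z2 <- z2 / stats::sd(z2)
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  V <- vif(cbind(a = z1, b = x2))
  expect_equal(unname(V), rep(1 / (1 - 0.64), 2), tolerance = 1e-6)

  # duplicated column -> infinite VIF, reported not raised
  Vd <- vif(cbind(a = z1, b = z1, c = stats::rnorm(n)))
  expect_true(is.infinite(Vd[["a"]]) && is.infinite(Vd[["b"]]))
  expect_true(is.finite(Vd[["c"]]))
})

test_that("VIF agrees with car::vif on a fitted linear model", {
  skip_if_not_installed("car")
  set.seed(12)
  d <- data.frame(x1 = stats::rnorm(80), x2 = stats::rnorm(80),
                  x3 = stats::rnorm(80))
  d$x2 <- d$x2 + 0.7 * d$x1
  d$y <- 1 + d$x1 - d$x2 + 0.5 * d$x3 + stats::rnorm(80)
  fit <- stats::lm(y ~ x1 + x2 + x3, data = d)
  Xc <- scale(as.matrix(d[c("x1", "x2", "x3")]), scale = FALSE)
  expect_equal(unname(vif(Xc)), unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("rescaling plus centering conditions the quadratic design", {
  panel <- pmr_panel()
  grid <- default_dose_grid(panel)
  raw <- build_design_matrix(
    grid, design_spec(panel, internal_rescale = FALSE))
  conditioned <- build_design_matrix(
    grid, design_spec(panel, center_for_vif = TRUE))
  v_raw <- suppressWarnings(vif(scale(raw[, -1], scale = FALSE)))
  v_cond <- vif(conditioned[, -1])
  expect_true(all(is.finite(v_cond)))
  expect_lt(max(v_cond), max(v_raw[is.finite(v_raw)], Inf))
  m <- random_unit_model(5)
  vr <- vif_report(m, threshold = 3)
  expect_setequal(names(vr$vif), m$terms[-1])
})

test_that("cross-validated RMSE is deterministic, near zero without noise, near sigma with", {
  panel <- unit_panel()
  spec <- design_spec(panel)
  co <- stats::setNames(c(70, -8, -4, -3, 3, 1, 0.8, 2, -1, 0.6),
                        term_names_for(panel))
  grid <- default_dose_grid(panel, m = Inf)  # 125 points
  tr0 <- surface_truth(co, panel, grid = grid, noise_sd = 0, bio_rep_sd = 0,
                       n_tech = 1, n_bio = 1, seed = 1)
  agg0 <- aggregate_replicates(generate_viability_table(tr0), panel)
  cv0 <- kfold_cv_rmse(agg0, spec, k = 5, seed = 3)
  expect_lt(cv0$cv_rmse, 1e-6)
  expect_identical(cv0$cv_rmse, kfold_cv_rmse(agg0, spec, k = 5, seed = 3)$cv_rmse)
  expect_false(identical(cv0$cv_rmse,
                         kfold_cv_rmse(agg0, spec, k = 5, seed = 4)$cv_rmse))

  rmses <- vapply(1:20, function(s) {
    agg <- agg0
    set.seed(s)
    agg$mean_value <- agg$mean_value + stats::rnorm(nrow(agg), 0, 5)
    kfold_cv_rmse(agg, spec, k = 5, seed = s)$cv_rmse
  }, numeric(1))
  expect_equal(mean(rmses), 5, tolerance = 0.3)
  expect_error(kfold_cv_rmse(agg0[1:3, ], spec, k = 5), "n >= k")
})

test_that("bootstrap CIs are deterministic, contain the estimate, and collapse without noise", {
  panel <- unit_panel()
  spec <- design_spec(panel)
  co <- stats::setNames(c(70, -8, -4, -3, 3, 1, 0.8, 2, -1, 0.6),
                        term_names_for(panel))
  tr <- surface_truth(co, panel, grid = default_dose_grid(panel, m = Inf),
                      noise_sd = 4, bio_rep_sd = 0, n_tech = 1, n_bio = 1,
                      seed = 2)
  agg <- aggregate_replicates(generate_viability_table(tr), panel)
  m <- fit_quadratic_surface(agg, spec)
  b1 <- bootstrap_model(agg, spec, B = 200, seed = 5)
  b2 <- bootstrap_model(agg, spec, B = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[, "lo"] <= m$coefficients_original + 1e-10 &
                  m$coefficients_original <= b1$ci[, "hi"] + 1e-10))

  tr0 <- surface_truth(co, panel, grid = default_dose_grid(panel, m = Inf),
                       noise_sd = 0, bio_rep_sd = 0, n_tech = 1, n_bio = 1,
                       seed = 2)
  agg0 <- aggregate_replicates(generate_viability_table(tr0), panel)
  b0 <- bootstrap_model(agg0, spec, B = 100, seed = 5)
  expect_lt(max(b0$ci[, "hi"] - b0$ci[, "lo"]), 1e-6)
})

test_that("bootstrap coverage of true coefficients is near nominal", {
  panel <- unit_panel()
  spec <- design_spec(panel)
  co <- stats::setNames(c(70, -8, -4, -3, 3, 1, 0.8, 2, -1, 0.6),
                        term_names_for(panel))
  grid <- default_dose_grid(panel, m = 40)
  covered <- vapply(1:100, function(s) {
    tr <- surface_truth(co, panel, grid = grid, noise_sd = 3,
                        bio_rep_sd = 0, n_tech = 1, n_bio = 3, seed = s)
    agg <- aggregate_replicates(generate_viability_table(tr), panel)
    b <- bootstrap_model(agg, spec, B = 200, seed = s)
    b$ci["b", "lo"] <= co["b"] && co["b"] <= b$ci["b", "hi"]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})

test_that("diagnose assembles the full report and never aborts nomination inputs", {
  panel <- pmr_panel()
  tr <- surface_truth(pmr_truth_coef(), panel, noise_sd = 5, bio_rep_sd = 2,
                      seed = 21)
  agg <- aggregate_replicates(generate_viability_table(tr), panel)
  m <- fit_quadratic_surface(agg, design_spec(panel))
  rep <- diagnose(m, agg, k = 5, B = 150, seed = 9)
  expect_s3_class(rep, "diagnostics_report")
  expect_true(rep$dw_stat >= 0 && rep$dw_stat <= 4)
  expect_setequal(names(rep$vif), m$terms[-1])
  expect_true(all(rep$vif >= 1))
  expect_equal(rep$cv_k, 5L)
  expect_equal(rep$bootstrap_B, 150L)
  expect_true(all(rep$bootstrap_ci[, "lo"] <= rep$bootstrap_ci[, "hi"]))
  expect_output(print(rep), "Durbin-Watson")
})
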