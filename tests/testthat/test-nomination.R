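# Lipschitz bound on how much the objective can vary across one grid cell
# of a points-per-axis tensor grid: sum over axes of (max |df/dx_j| over
# the box) times the cell width.
one_cell_tolerance <- function(model, ppa = 51) {
  co <- model$coefficients_original
  up <- vapply(model$spec$panel, `[[`, numeric(1), "upper_bound")
  lo <- vapply(model$spec$panel, `[[`, numeric(1), "lower_bound")
  d <- length(up)
  a_l <- co[2:(1 + d)]; a_q <- co[(2 + d):(1 + 2 * d)]
  a_int <- co[(2 + 2 * d):length(co)]
  bnd <- abs(a_l) + 2 * abs(a_q) * up
  k <- 0
  for (i in seq_len(d - 1)) {
    for (j in seq(i + 1, d)) {
      k <- k + 1
      bnd[i] <- bnd[i] + abs(a_int[k]) * up[j]
      bnd[j] <- bnd[j] + abs(a_int[k]) * up[i]
    }
  }
  sum(bnd * (up - lo) / (ppa - 1))
}

test_that("a monotone decreasing objective is nominated at the upper corner", {
  panel <- unit_panel()
  co <- stats::setNames(c(100, -5, -2, -1, rep(0, 6)),
                        term_names_for(panel))
  tr <- surface_truth(co, panel, noise_sd = 0, bio_rep_sd = 0,
                      n_tech = 1, n_bio = 1, seed = 1)
  m <- fit_quadratic_surface(
    aggregate_replicates(generate_viability_table(tr), panel),
    design_spec(panel))
  r <- nominate(nomination_problem(m, seed = 3))
  expect_true(r$feasible)
  expect_equal(unname(r$dose), c(1, 2, 3), tolerance = 1e-6)
  expect_equal(r$objective_value, 100 - 5 - 4 - 3, tolerance = 1e-6)
})

test_that("optimizer matches the exhaustive grid oracle on random constrained problems", {
  worst_over <- -Inf
  worst_under <- -Inf
  for (s in 1:25) {
    m_obj <- random_unit_model(s)
    m_con <- random_unit_model(s + 500)
    floor_v <- predict(m_con, data.frame(a = 0.5, b = 1, c = 1.5))
    pb <- nomination_problem(m_obj, list(hep = list(model = m_con,
                                                    floor = floor_v)),
                             n_starts = 16, seed = s)
    r <- nominate(pb)
    g <- grid_oracle(pb, 51)
    expect_true(all(r$dose >= 0 - 1e-9))
    expect_true(all(r$dose <= c(1, 2, 3) + 1e-9))
    if (g$feasible) {
      worst_over <- max(worst_over, r$objective_value - g$objective_value)
      worst_under <- max(worst_under,
                         g$objective_value - r$objective_value -
                           one_cell_tolerance(m_obj))
    }
  }
  # the continuous optimizer is never worse than the grid...
  expect_lte(worst_over, 1e-6)
  # ...and never better than one grid cell's objective variation explains
  expect_lte(worst_under, 1e-9)
})

test_that("a floor above the constraint surface's maximum is infeasible, loudly", {
  m_obj <- random_unit_model(11)
  m_con <- random_unit_model(12)
  g_max <- -grid_oracle(
    nomination_problem(local({
      m2 <- m_con; m2$coefficients_original <- -m2$coefficients_original; m2
    }), seed = 1), 51)$objective_value  # box-wide max via negated min
  pb <- nomination_problem(
    m_obj, list(hep = list(model = m_con, floor = g_max + 10)), seed = 2)
  r <- nominate(pb)
  expect_false(r$feasible)
  expect_true(all(r$dose >= 0 & r$dose <= c(1, 2, 3)))
  g <- grid_oracle(pb, 21)
  expect_false(g$feasible)
  expect_output(print(r), "INFEASIBLE")
})

test_that("grid oracle hits on-grid analytic minima exactly and refines consistently", {
  panel <- unit_panel()
  # separable convex bowl with interior minimum at (0.5, 1.0, 1.5), on-grid
  co <- stats::setNames(c(10, -4, -4, -4, 4, 2, 4 / 3, 0, 0, 0),
                        term_names_for(panel))
  tr <- surface_truth(co, panel, noise_sd = 0, bio_rep_sd = 0,
                      n_tech = 1, n_bio = 1, seed = 1)
  m <- fit_quadratic_surface(
    aggregate_replicates(generate_viability_table(tr), panel),
    design_spec(panel))
  pb <- nomination_problem(m, seed = 1)
  g51 <- grid_oracle(pb, 51)
  expect_equal(unname(g51$dose), c(0.5, 1.0, 1.5), tolerance = 1e-9)
  g101 <- grid_oracle(pb, 101)
  expect_lte(abs(g51$objective_value - g101$objective_value),
             one_cell_tolerance(m, 51))
  r <- nominate(pb)
  expect_equal(unname(r$dose), c(0.5, 1.0, 1.5), tolerance = 1e-5)
})

test_that("weighted-sum scalarization reduces, balances, and flips as the weights say", {
  panel <- unit_panel()
  m_obj <- random_unit_model(21)
  m_con <- random_unit_model(22)
  cons <- list(hep = list(model = m_con, floor = -Inf))

  # all weight on the objective: identical to the unconstrained hard run
  r_w <- nominate(nomination_problem(m_obj, cons, seed = 4,
                                     mode = "weighted_sum",
                                     weights = c(1, 0)))
  r_h <- nominate(nomination_problem(m_obj, seed = 4))
  expect_equal(r_w$dose, r_h$dose, tolerance = 1e-5)

  # all weight on the constraint model: nominates that model's maximizer
  r_c <- nominate(nomination_problem(m_obj, cons, seed = 4,
                                     mode = "weighted_sum",
                                     weights = c(0, 1)))
  g_c <- grid_oracle(nomination_problem(m_obj, cons, seed = 4,
                                        mode = "weighted_sum",
                                        weights = c(0, 1)), 51)
  expect_lte(r_c$scalarized_value, g_c$scalarized_value + 1e-6)

  # symmetric two-model toy: equal weights nominate the symmetry point
  co1 <- stats::setNames(c(0, -4, 0, 0, 2, 0, 0, 0, 0, 0),
                         term_names_for(panel))
  co2 <- stats::setNames(c(0, 4, 0, 0, -2, 0, 0, 0, 0, 0),
                         term_names_for(panel))
  mk <- function(co, s) {
    tr <- surface_truth(co, panel, noise_sd = 0, bio_rep_sd = 0,
                        n_tech = 1, n_bio = 1, seed = s)
    fit_quadratic_surface(
      aggregate_replicates(generate_viability_table(tr), panel),
      design_spec(panel))
  }
  m1 <- mk(co1, 1); m2 <- mk(co2, 2)
  # minimize f1 - f2 = -8a + 4a^2: interior minimum at a = 1; b, c flat,
  # tie-broken to zero dose burden
  r_s <- nominate(nomination_problem(m1, list(x = list(model = m2,
                                                       floor = -Inf)),
                                     seed = 9, mode = "weighted_sum",
                                     weights = c(1, 1)))
  expect_equal(unname(r_s$dose), c(1, 0, 0), tolerance = 1e-5)
  expect_error(nomination_problem(m1, list(x = list(model = m2, floor = 0)),
                                  mode = "weighted_sum"), "weights")
})

test_that("tightening the floor never improves the optimal objective", {
  m_obj <- random_unit_model(31)
  m_con <- random_unit_model(32)
  base <- predict(m_con, data.frame(a = 0.5, b = 1, c = 1.5))
  vals <- vapply(c(-20, -10, 0, 5, 10), function(delta) {
    pb <- nomination_problem(
      m_obj, list(hep = list(model = m_con, floor = base + delta)),
      n_starts = 16, seed = 7)
    r <- nominate(pb)
    if (r$feasible) r$objective_value else Inf
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-6))
})

test_that("nomination is deterministic under a fixed seed", {
  m_obj <- random_unit_model(41)
  m_con <- random_unit_model(42)
  fl <- predict(m_con, data.frame(a = 0.5, b = 1, c = 1.5))
  pb <- nomination_problem(m_obj, list(hep = list(model = m_con,
                                                  floor = fl)),
                           n_starts = 12, seed = 13)
  r1 <- nominate(pb)
  r2 <- nominate(pb)
  expect_identical(r1$dose, r2$dose)
  expect_identical(r1$objective_value, r2$objective_value)
})

test_that("per-context nomination diverges exactly as a constructed shift dictates", {
  panel <- unit_panel()
  spec <- design_spec(panel)
  # objective falls with every agent; constraint penalizes agent a
  # strongly in the shifted context and agent b less
  obj_co <- stats::setNames(c(100, -10, -6, -4, 0, 0, 0, 0, 0, 0),
                            term_names_for(panel))
  con_co <- stats::setNames(c(100, -20, -20, -2, 0, 0, 0, 0, 0, 0),
                            term_names_for(panel))
  tr_obj <- surface_truth(obj_co, panel, noise_sd = 0, bio_rep_sd = 0,
                          n_tech = 1, n_bio = 1, seed = 1)
  tr_con <- surface_truth(con_co, panel, noise_sd = 0, bio_rep_sd = 0,
                          n_tech = 1, n_bio = 1, seed = 2)
  obj_tab <- generate_viability_table(tr_obj)
  # shifted context: agent a hurts the constraint more, agent b less
  con_pair <- generate_fa_shift_pair(tr_con, c(a = -40, b = 10),
                                     shifted_context = "FA")
  agg_obj <- aggregate_replicates(obj_tab, panel)
  data_by_ctx <- list(
    "FA-free" = list(
      objective = transform(agg_obj, context = "FA-free"),
      constraints = list(hep = aggregate_replicates(
        con_pair[con_pair$context == "FA-free", ], panel))),
    "FA" = list(
      objective = transform(agg_obj, context = "FA"),
      constraints = list(hep = aggregate_replicates(
        con_pair[con_pair$context == "FA", ], panel)))
  )
  res <- nominate_context_pair(data_by_ctx, spec, floors = 55, seed = 3)
  d_free <- res[["FA-free"]]$result$dose
  d_fa <- res[["FA"]]$result$dose
  expect_true(res[["FA-free"]]$result$feasible)
  expect_true(res[["FA"]]$result$feasible)
  # the shift makes agent a costlier and agent b cheaper for the
  # constraint: nominated a decreases, b increases
  expect_lt(d_fa[["a"]], d_free[["a"]] - 1e-4)
  expect_gt(d_fa[["b"]], d_free[["b"]] + 1e-4)
  # each context's answer is verified against its own grid oracle
  for (ctx in c("FA-free", "FA")) {
    pb <- nomination_problem(
      res[[ctx]]$objective_model,
      list(hep = list(model = res[[ctx]]$constraint_models$hep, floor = 55)),
      seed = 3)
    g <- grid_oracle(pb, 51)
    expect_lte(res[[ctx]]$result$objective_value,
               g$objective_value + 1e-6)
  }
})

test_that("identical data in both contexts nominate identically; broken contexts are isolated", {
  panel <- unit_panel()
  spec <- design_spec(panel)
  m <- random_unit_model(51)
  agg <- cbind(m$doses, endpoint = "viability_pct", context = "x",
               mean_value = m$observed)
  res <- nominate_context_pair(
    list(c1 = transform(agg, context = "c1"),
         c2 = transform(agg, context = "c2")),
    spec, seed = 5)
  expect_equal(res$c1$result$dose, res$c2$result$dose, tolerance = 1e-9)

  broken <- agg[1:4, ]  # under-determined
  res2 <- nominate_context_pair(
    list(good = transform(agg, context = "good"),
         bad = transform(broken, context = "bad")),
    spec, seed = 5)
  expect_false(is.null(res2$bad$error))
  expect_true(res2$good$result$feasible)
})
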