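#' Define a constrained dose-nomination problem
#'
#' A nomination problem bundles the fitted surface to minimize (for
#' example tumor viability, or the macrophage infiltration ratio), any
#' floor constraints on other fitted surfaces (for example hepatocyte
#' viability must stay at or above a threshold), and the search box — the
#' experimentally tested dose bounds taken from the agent panel. The
#' optimizer never leaves the box: nomination is interpolation within
#' tested dose space, not extrapolation.
#'
#' Two modes are available. `"hard_constraint"` (the default reproduction
#' path) minimizes the objective subject to every constraint surface
#' staying at or above its floor. `"weighted_sum"` minimizes
#' `w[1] * objective - sum(w[-1] * constraint predictions)` over the box,
#' ignoring the floors — a scalarized alternative, labeled as such in the
#' result.
#'
#' @param objective_model `response_surface` whose prediction is minimized.
#' @param constraints List of `list(model = <response_surface>,
#'   floor = <numeric>)`; optionally named (names label the constraints).
#' @param n_starts Number of Latin-hypercube multistart points (the box
#'   corners and center are always added).
#' @param seed Integer seed for the start set.
#' @param mode `"hard_constraint"` or `"weighted_sum"`.
#' @param weights Numeric weights for `"weighted_sum"`; length
#'   `1 + length(constraints)`, nonnegative, not all zero.
#' @return An object of class `nomination_problem`.
#' @export
nomination_problem <- function(objective_model, constraints = list(),
                               n_starts = 32, seed = 1,
                               mode = c("hard_constraint", "weighted_sum"),
                               weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(objective_model, "response_surface"))
  panel <- objective_model$spec$panel
  nms <- panel_names(panel)
  if (length(constraints)) {
    for (ct in constraints) {
      stopifnot(inherits(ct$model, "response_surface"),
                is.numeric(ct$floor))
      if (!identical(panel_names(ct$model$spec$panel), nms)) {
        .stopf("constraint model's agent panel differs from the objective's")
      }
    }
    if (is.null(names(constraints)) || any(names(constraints) == "")) {
      names(constraints) <- paste0("constraint", seq_along(constraints))
    }
  }
  if (mode == "weighted_sum") {
    if (is.null(weights)) .stopf("weighted_sum mode requires weights")
    if (length(weights) != 1 + length(constraints) ||
        any(weights < 0) || all(weights == 0)) {
      .stopf("weights must be %d nonnegative values, not all zero",
             1 + length(constraints))
    }
  }
  structure(
    list(objective_model = objective_model, constraints = constraints,
         panel = panel, lower = panel_lower(panel), upper = panel_upper(panel),
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         mode = mode, weights = weights),
    class = "nomination_problem"
  )
}

# Combined quadratic coefficients for the weighted-sum scalarization:
# a weighted combination of quadratic forms is itself a quadratic form.
.scalarized_coef <- function(problem) {
  co <- problem$weights[1] * problem$objective_model$coefficients_original
  for (i in seq_along(problem$constraints)) {
    co <- co - problem$weights[1 + i] *
      problem$constraints[[i]]$model$coefficients_original
  }
  co
}

# Multistart set in normalized [0,1]^d coordinates: seeded Latin hypercube
# plus all box corners plus the center.
.start_points <- function(problem) {
  d <- length(problem$upper)
  Z <- .with_seed(substream_seed(problem$seed, "starts"),
                  lhs::randomLHS(max(problem$n_starts, 1L), d))
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  rbind(Z, corners, matrix(0.5, 1, d))
}

# Augmented-Lagrangian local solve from one normalized start.
# Works in z = (x - lower) / (upper - lower) in [0,1]^d; box bounds are
# handled natively by L-BFGS-B, inequality constraints g(x) <= 0 by
# multiplier updates. Objective and constraints are quadratic forms with
# analytic gradients.
.local_solve <- function(z0, obj_coef, con_coefs, floors, lower, upper,
                         agent_names, maxit_outer = 20) {
  span <- upper - lower
  to_x <- function(z) lower + z * span
  f <- function(z) .quad_eval(obj_coef, agent_names,
                              matrix(to_x(z), 1,
                                     dimnames = list(NULL, agent_names)))
  gf <- function(z) .quad_grad(obj_coef, agent_names, to_x(z)) * span
  ncon <- length(con_coefs)
  gval <- function(z) {
    x <- matrix(to_x(z), 1, dimnames = list(NULL, agent_names))
    vapply(seq_len(ncon), function(i) {
      floors[i] - .quad_eval(con_coefs[[i]], agent_names, x)
    }, numeric(1))
  }
  if (ncon == 0L) {
    fit <- stats::optim(z0, f, gf, method = "L-BFGS-B",
                        lower = rep(0, length(z0)),
                        upper = rep(1, length(z0)),
                        control = list(maxit = 200, factr = 1e4))
    return(list(z = fit$par, value = fit$value, violation = 0,
                converged = fit$convergence == 0))
  }
  lambda <- rep(0, ncon)
  scale_f <- max(1, abs(f(z0)))
  rho <- scale_f
  z <- z0
  prev_viol <- Inf
  conv <- FALSE
  for (it in seq_len(maxit_outer)) {
    al <- function(zz) {
      g <- gval(zz)
      s <- pmax(0, lambda / rho + g)
      f(zz) + (rho / 2) * sum(s^2) - sum(lambda^2) / (2 * rho)
    }
    gal <- function(zz) {
      x <- to_x(zz)
      g <- gval(zz)
      s <- pmax(0, lambda / rho + g)
      grad <- gf(zz)
      for (i in seq_len(ncon)) {
        if (s[i] > 0) {
          gcon <- -.quad_grad(con_coefs[[i]], agent_names, x) * span
          grad <- grad + rho * s[i] * gcon
        }
      }
      grad
    }
    fit <- stats::optim(z, al, gal, method = "L-BFGS-B",
                        lower = rep(0, length(z)),
                        upper = rep(1, length(z)),
                        control = list(maxit = 500, factr = 1e3))
    z_prev <- z
    z <- fit$par
    g <- gval(z)
    viol <- max(0, max(g))
    lambda <- pmax(0, lambda + rho * g)
    # converge on feasibility AND a settled iterate (multipliers at rest),
    # not on feasibility alone: a live multiplier still biases the point
    # into the interior of the feasible region.
    if (viol < 1e-10 && max(abs(z - z_prev)) < 1e-10) {
      conv <- TRUE
      break
    }
    if (viol > 0.25 * prev_viol) rho <- rho * 10
    prev_viol <- viol
    if (rho > 1e12 * scale_f) break
  }
  g <- gval(z)
  list(z = z, value = f(z), violation = max(0, max(g)),
       converged = conv || max(0, max(g)) < 1e-6)
}

# Tie-break among near-equal objective values: lowest total normalized
# dose burden sum(dose/upper), then lexicographic by agent order.
.tie_break <- function(X, values, upper, tol = 1e-6) {
  best <- min(values)
  cand <- which(values <= best + tol)
  if (length(cand) > 1L) {
    burden <- as.matrix(X[cand, , drop = FALSE]) %*% (1 / upper)
    cand <- cand[burden <= min(burden) + 1e-12]
    if (length(cand) > 1L) {
      ord <- do.call(order, as.data.frame(X[cand, , drop = FALSE]))
      cand <- cand[ord[1]]
    }
  }
  cand[1]
}

.make_result <- function(problem, x, feasible, solver, n_conv = NA_integer_) {
  nms <- panel_names(problem$panel)
  x <- stats::setNames(as.numeric(x), nms)
  xd <- as.data.frame(as.list(x))
  pred <- c(objective = unname(.quad_eval(
    problem$objective_model$coefficients_original, nms, xd)))
  active <- character(0)
  for (lab in names(problem$constraints)) {
    ct <- problem$constraints[[lab]]
    pv <- unname(.quad_eval(ct$model$coefficients_original, nms, xd))
    pred[lab] <- pv
    if (pv <= ct$floor + 1e-6) active <- c(active, lab)
  }
  structure(
    list(dose = x, predicted = pred, feasible = feasible,
         active_constraints = active, solver = solver,
         n_starts_converged = n_conv,
         objective_value = unname(pred["objective"]),
         mode = problem$mode),
    class = "nomination_result"
  )
}

#' @export
print.nomination_result <- function(x, ...) {
  banner <- if (x$feasible) "" else "  ** INFEASIBLE **"
  cat(sprintf("<nomination_result> [%s, %s]%s\n", x$mode, x$solver, banner))
  cat("  dose:     ", paste(sprintf("%s=%g", names(x$dose), x$dose),
                            collapse = ", "), "\n")
  cat("  predicted:", paste(sprintf("%s=%.4g", names(x$predicted),
                                    x$predicted), collapse = ", "), "\n")
  if (length(x$active_constraints)) {
    cat("  active constraints:",
        paste(x$active_constraints, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nominate a dose combination by constrained optimization
#'
#' Minimizes the objective surface over the tested dose box, honoring
#' every floor constraint, by deterministic multistart local optimization:
#' a seeded Latin-hypercube start set (plus the box corners and center) is
#' polished by an augmented-Lagrangian sequential solver with analytic
#' gradients of the quadratic forms. The best feasible local optimum wins;
#' near-ties are broken toward the lowest total normalized dose burden. If
#' no start yields a feasible point and a feasibility pre-scan also fails,
#' the result is flagged `feasible = FALSE` and carries the least-violating
#' dose found — never a silent answer.
#'
#' @param problem A [nomination_problem()].
#' @return A `nomination_result`: nominated `dose`, `predicted` values per
#'   surface, `feasible`, `active_constraints`, `objective_value`,
#'   provenance fields.
#' @export
nominate <- function(problem) {
  stopifnot(inherits(problem, "nomination_problem"))
  nms <- panel_names(problem$panel)
  lower <- problem$lower; upper <- problem$upper
  if (problem$mode == "weighted_sum") {
    obj_coef <- .scalarized_coef(problem)
    con_coefs <- list(); floors <- numeric(0)
  } else {
    obj_coef <- problem$objective_model$coefficients_original
    con_coefs <- lapply(problem$constraints,
                        function(ct) ct$model$coefficients_original)
    floors <- vapply(problem$constraints, `[[`, numeric(1), "floor")
  }
  starts <- .start_points(problem)
  sols <- lapply(seq_len(nrow(starts)), function(i) {
    .local_solve(starts[i, ], obj_coef, con_coefs, floors, lower, upper,
                 nms)
  })
  viol <- vapply(sols, `[[`, numeric(1), "violation")
  vals <- vapply(sols, `[[`, numeric(1), "value")
  n_conv <- sum(vapply(sols, `[[`, logical(1), "converged"))
  X <- t(vapply(sols, function(s) lower + s$z * (upper - lower),
                numeric(length(nms))))
  colnames(X) <- nms
  feas <- viol <= 1e-6
  solver <- "multistart augmented-Lagrangian (SQP-class, L-BFGS-B inner)"
  if (any(feas)) {
    idx <- which(feas)
    pick <- idx[.tie_break(X[idx, , drop = FALSE], vals[idx], upper)]
    res <- .make_result(problem, X[pick, ], TRUE, solver, n_conv)
    if (problem$mode == "weighted_sum") {
      res$objective_value <- vals[pick]
      res$scalarized_value <- vals[pick]
    }
    return(res)
  }
  # Feasibility pre-scan: minimize the smooth sum of squared violations.
  span <- upper - lower
  sq_viol <- function(z) {
    x <- matrix(lower + z * span, 1, dimnames = list(NULL, nms))
    g <- vapply(seq_along(con_coefs), function(i) {
      floors[i] - .quad_eval(con_coefs[[i]], nms, x)
    }, numeric(1))
    sum(pmax(0, g)^2)
  }
  scans <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(starts[i, ], sq_viol, method = "L-BFGS-B",
                 lower = rep(0, length(nms)), upper = rep(1, length(nms)),
                 control = list(maxit = 200))
  })
  sv <- vapply(scans, `[[`, numeric(1), "value")
  best <- which.min(sv)
  if (sv[best] <= 1e-12) {
    # A feasible point exists; polish from it.
    sol <- .local_solve(scans[[best]]$par, obj_coef, con_coefs, floors,
                        lower, upper, nms)
    x <- lower + sol$z * span
    return(.make_result(problem, x, sol$violation <= 1e-6, solver, n_conv))
  }
  x <- lower + scans[[best]]$par * span
  .make_result(problem, x, FALSE, solver, n_conv)
}

#' Exhaustive grid oracle for a nomination problem
#'
#' Evaluates the objective and all constraints on the full tensor-product
#' grid over the box (endpoints included) and returns the exact feasible
#' arg-min among grid points — a deterministic brute-force reference
#' against which the continuous optimizer is verified.
#'
#' @param problem A [nomination_problem()].
#' @param points_per_axis Grid points per agent axis (>= 11; default 51).
#' @return A `nomination_result` with `solver = "grid"`.
#' @export
grid_oracle <- function(problem, points_per_axis = 51) {
  stopifnot(inherits(problem, "nomination_problem"), points_per_axis >= 11)
  nms <- panel_names(problem$panel)
  axes <- lapply(seq_along(nms), function(j) {
    seq(problem$lower[j], problem$upper[j], length.out = points_per_axis)
  })
  G <- as.matrix(expand.grid(axes))
  colnames(G) <- nms
  if (problem$mode == "weighted_sum") {
    vals <- .quad_eval(.scalarized_coef(problem), nms, G)
    feas <- rep(TRUE, nrow(G))
  } else {
    vals <- .quad_eval(problem$objective_model$coefficients_original,
                       nms, G)
    feas <- rep(TRUE, nrow(G))
    for (ct in problem$constraints) {
      pv <- .quad_eval(ct$model$coefficients_original, nms, G)
      feas <- feas & (pv >= ct$floor - 1e-9)
    }
  }
  if (!any(feas)) {
    # report the least-violating grid point, flagged infeasible
    worst <- rep(0, nrow(G))
    for (ct in problem$constraints) {
      pv <- .quad_eval(ct$model$coefficients_original, nms, G)
      worst <- pmax(worst, ct$floor - pv)
    }
    pick <- which.min(worst)
    return(.make_result(problem, G[pick, ], FALSE, "grid"))
  }
  idx <- which(feas)
  pick <- idx[.tie_break(G[idx, , drop = FALSE], vals[idx], problem$upper)]
  res <- .make_result(problem, G[pick, ], TRUE, "grid")
  if (problem$mode == "weighted_sum") {
    res$objective_value <- vals[pick]
    res$scalarized_value <- vals[pick]
  }
  res
}

#' Weighted-sum scalarization of a nomination problem
#'
#' Convenience wrapper: solves the problem in `"weighted_sum"` mode with
#' the supplied weights (see [nomination_problem()]); the hard-constraint
#' path remains the default reproduction route.
#'
#' @param problem A [nomination_problem()].
#' @param weights Nonnegative weights, length `1 + length(constraints)`.
#' @return A `nomination_result` labeled with the scalarized mode.
#' @export
scalarize_weighted <- function(problem, weights = problem$weights) {
  if (is.null(weights)) .stopf("scalarize_weighted: weights are required")
  pb <- nomination_problem(problem$objective_model, problem$constraints,
                           n_starts = problem$n_starts, seed = problem$seed,
                           mode = "weighted_sum", weights = weights)
  nominate(pb)
}

#' Fit and nominate independently per context
#'
#' Fits the objective (and any constraint) surfaces separately within each
#' context — for example fatty-acid-free versus fatty-acid-enriched — and
#' runs the same constrained nomination in each, so that context-dependent
#' reshaping of the response surfaces shows up as a shift of the nominated
#' dose set within the same tested box.
#'
#' @param data_by_context Named list: context -> either an aggregated table
#'   (objective only) or `list(objective = <agg>, constraints =
#'   list(<agg>, ...))`.
#' @param spec A [design_spec()].
#' @param floors Numeric vector of constraint floors (recycled across
#'   constraint tables), or `NULL` for box-only problems.
#' @param n_starts,seed Passed to [nomination_problem()].
#' @return Named list per context: `list(result = <nomination_result>,
#'   objective_model, constraint_models)`. Contexts whose fit fails are
#'   returned as `list(error = <message>)`.
#' @export
nominate_context_pair <- function(data_by_context, spec, floors = NULL,
                                  n_starts = 32, seed = 1) {
  stopifnot(length(data_by_context) >= 1, !is.null(names(data_by_context)))
  out <- list()
  for (ctx in names(data_by_context)) {
    entry <- data_by_context[[ctx]]
    res <- tryCatch({
      if (is.data.frame(entry)) {
        obj_dat <- entry; con_dat <- list()
      } else {
        obj_dat <- entry$objective
        con_dat <- entry$constraints %||% list()
      }
      objm <- fit_quadratic_surface(obj_dat, spec, context = ctx)
      cons <- list()
      if (length(con_dat)) {
        fl <- rep_len(floors, length(con_dat))
        for (i in seq_along(con_dat)) {
          cm <- fit_quadratic_surface(con_dat[[i]], spec, context = ctx)
          cons[[i]] <- list(model = cm, floor = fl[i])
        }
        names(cons) <- names(con_dat) %||%
          paste0("constraint", seq_along(con_dat))
        if (any(names(cons) == "")) {
          names(cons)[names(cons) == ""] <-
            paste0("constraint", which(names(cons) == ""))
        }
      }
      pb <- nomination_problem(objm, cons, n_starts = n_starts,
                               seed = substream_seed(seed, ctx))
      list(result = nominate(pb), objective_model = objm,
           constraint_models = lapply(cons, `[[`, "model"))
    }, error = function(e) list(error = conditionMessage(e)))
    out[[ctx]] <- res
  }
  out
}
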