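#' Specify the quadratic design
#'
#' Fixes how dose combinations are expanded into the quadratic design
#' matrix. Term order is frozen so coefficient reports are comparable
#' across endpoints and contexts: intercept, then one linear term per
#' agent in panel order, then the squared terms, then the pairwise
#' interactions `a:b` with `a` before `b` in panel order — `1 + d + d +
#' d(d-1)/2` columns for `d` agents (10 for 3).
#'
#' Because agents may span wildly different numeric ranges (a fold-dilution
#' around 1e-4 next to a millimolar concentration), `internal_rescale`
#' divides each dose by the agent's upper bound before the quadratic
#' expansion and back-transforms the coefficients to original units for
#' reporting; this is a pure numerical-conditioning device that leaves the
#' fitted surface unchanged in exact arithmetic. `standardize = "zscore"`
#' instead z-scores the linear columns before squaring/multiplying and
#' reports coefficients on the standardized scale — a sensitivity analysis;
#' fitted values and R-squared are identical to the original-units fit.
#'
#' @param panel An [agent_panel()].
#' @param standardize `"original_units"` (default) or `"zscore"`.
#' @param center_for_vif If `TRUE`, mean-center every non-intercept column
#'   after expansion (the design used for collinearity checks).
#' @param internal_rescale Divide doses by per-agent upper bounds before
#'   expansion (default `TRUE`; ignored under `"zscore"`).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(panel, standardize = c("original_units", "zscore"),
                        center_for_vif = FALSE, internal_rescale = TRUE) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(panel, "agent_panel"))
  structure(
    list(panel = panel, standardize = standardize,
         center_for_vif = isTRUE(center_for_vif),
         internal_rescale = isTRUE(internal_rescale)),
    class = "design_spec"
  )
}

# Frozen term names for d agents in panel order.
.term_names <- function(agent_names) {
  d <- length(agent_names)
  inter <- character(0)
  if (d >= 2) {
    for (i in seq_len(d - 1)) {
      for (j in seq(i + 1, d)) {
        inter <- c(inter, paste0(agent_names[i], ":", agent_names[j]))
      }
    }
  }
  unname(c("(Intercept)", agent_names, paste0(agent_names, "^2"), inter))
}

# Expand linear columns (already transformed) into the full quadratic
# design in frozen term order.
.expand_quadratic <- function(L) {
  d <- ncol(L)
  n <- nrow(L)
  sq <- L * L
  inter <- NULL
  if (d >= 2) {
    cols <- list()
    for (i in seq_len(d - 1)) {
      for (j in seq(i + 1, d)) cols[[length(cols) + 1L]] <- L[, i] * L[, j]
    }
    inter <- do.call(cbind, cols)
  }
  cbind(`(Intercept)` = rep(1, n), L, sq, inter)
}

#' Build the quadratic design matrix
#'
#' Expands dose combinations into the frozen-term-order quadratic design
#' under a [design_spec()]. The applied per-agent affine transform
#' (centers, scales) is attached as attribute `"transform"` so that fitted
#' models can reproduce it at prediction time.
#'
#' @param doses Data frame (or matrix) with one column per panel agent.
#' @param spec A [design_spec()].
#' @param transform Optional precomputed transform (as attached by a
#'   previous call) — used when predicting from a fitted model.
#' @return Numeric matrix `n x p` with term-name column names and
#'   attributes `"transform"` and `"terms"`.
#' @export
build_design_matrix <- function(doses, spec, transform = NULL) {
  nms <- panel_names(spec$panel)
  doses <- as.data.frame(doses)[nms]
  X0 <- as.matrix(doses)
  if (nrow(X0) < 1L) .stopf("build_design_matrix: need at least one dose")
  if (is.null(transform)) {
    if (spec$standardize == "zscore") {
      ctr <- colMeans(X0)
      scl <- apply(X0, 2, stats::sd)
      zero <- which(!is.finite(scl) | scl == 0)
      if (length(zero)) {
        .stopf("z-score standardization impossible: zero variance in %s",
               paste(nms[zero], collapse = ", "))
      }
    } else if (spec$internal_rescale) {
      ctr <- rep(0, length(nms))
      scl <- panel_upper(spec$panel)
    } else {
      ctr <- rep(0, length(nms))
      scl <- rep(1, length(nms))
    }
    transform <- list(center = stats::setNames(ctr, nms),
                      scale = stats::setNames(scl, nms))
  }
  L <- sweep(sweep(X0, 2, transform$center, "-"), 2, transform$scale, "/")
  X <- .expand_quadratic(L)
  terms <- .term_names(nms)
  colnames(X) <- terms
  if (spec$center_for_vif) {
    X[, -1] <- sweep(X[, -1, drop = FALSE], 2,
                     colMeans(X[, -1, drop = FALSE]), "-")
  }
  attr(X, "transform") <- transform
  attr(X, "terms") <- terms
  X
}

# Back-transform coefficients fitted on t = (x - c)/s columns to the
# original dose units (full quadratic reparameterization).
.coef_to_original <- function(beta, terms, agent_names, center, scale) {
  d <- length(agent_names)
  b0 <- beta[1]
  bl <- beta[2:(1 + d)]
  bq <- beta[(2 + d):(1 + 2 * d)]
  nint <- d * (d - 1) / 2
  bint <- if (nint > 0) beta[(2 + 2 * d):(1 + 2 * d + nint)] else numeric(0)
  # interaction index pairs in frozen order
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  a_q <- bq / scale^2
  a_int <- numeric(nint)
  a_l <- bl / scale - 2 * bq * center / scale^2
  a_0 <- b0 - sum(bl * center / scale) + sum(bq * center^2 / scale^2)
  if (nint > 0) {
    for (k in seq_len(nint)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      a_int[k] <- bint[k] / (scale[i] * scale[j])
      a_l[i] <- a_l[i] - bint[k] * center[j] / (scale[i] * scale[j])
      a_l[j] <- a_l[j] - bint[k] * center[i] / (scale[i] * scale[j])
      a_0 <- a_0 + bint[k] * center[i] * center[j] / (scale[i] * scale[j])
    }
  }
  stats::setNames(c(a_0, a_l, a_q, a_int), terms)
}

#' Fit the quadratic response surface by ordinary least squares
#'
#' Fits the frozen-order quadratic surface to aggregated per-condition
#' responses (one row per dose x context condition, as produced by
#' [aggregate_replicates()]). The fit is plain OLS; under
#' `internal_rescale` the numerics run on conditioned columns and the
#' coefficients are back-transformed to original dose units for reporting.
#'
#' @param agg Aggregated table from [aggregate_replicates()], or any data
#'   frame with agent columns and a response column.
#' @param spec A [design_spec()].
#' @param context Optional context label to filter on (and record).
#' @param response Name of the response column (default `"mean_value"`).
#' @param per_bio If `TRUE`, fit on per-biological-replicate rows (the
#'   `per_bio` list column is expanded) instead of condition means — a
#'   sensitivity option; the default reproduces the mean-input fit.
#' @return An object of class `response_surface` with elements
#'   `coefficients` (reported scale), `fitted`, `residuals`, `r_squared`,
#'   `n_obs`, `context`, `endpoint`, `spec`, `transform`, plus internals.
#' @export
fit_quadratic_surface <- function(agg, spec, context = NULL,
                                  response = "mean_value",
                                  per_bio = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  nms <- panel_names(spec$panel)
  dat <- as.data.frame(agg)
  if (!is.null(context)) {
    dat <- dat[dat$context == context, , drop = FALSE]
    if (nrow(dat) == 0L) .stopf("no rows for context '%s'", context)
  } else if ("context" %in% names(dat) &&
             length(unique(dat$context)) == 1L) {
    context <- unique(dat$context)
  }
  if (per_bio && "per_bio" %in% names(dat)) {
    reps <- rep(seq_len(nrow(dat)), lengths(dat$per_bio))
    y <- unlist(dat$per_bio)
    dat <- dat[reps, , drop = FALSE]
  } else {
    if (!response %in% names(dat)) {
      .stopf("response column '%s' not found", response)
    }
    y <- dat[[response]]
  }
  endpoint <- if ("endpoint" %in% names(dat) && nrow(dat) > 0) {
    unique(dat$endpoint)[1]
  } else NA_character_

  X <- build_design_matrix(dat[nms], spec)
  terms <- attr(X, "terms")
  p <- ncol(X)
  n <- nrow(X)
  if (n < p) {
    .stopf("under-determined fit: %d observations < %d terms", n, p)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- terms[qrX$pivot[(qrX$rank + 1):p]]
    .stopf("singular design: collinear term(s) %s",
           paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst <= .Machine$double.eps * max(1, sum(y^2))
  r2 <- if (degenerate) 1 else 1 - sse / sst
  if (degenerate) {
    .warnf("degenerate fit: response is constant; R-squared reported as 1")
  }
  tr <- attr(X, "transform")
  reported <- if (spec$standardize == "zscore") {
    stats::setNames(beta, terms)
  } else {
    .coef_to_original(beta, terms, nms, tr$center[nms], tr$scale[nms])
  }
  structure(
    list(coefficients = reported,
         coefficients_internal = stats::setNames(beta, terms),
         coefficients_original = .coef_to_original(
           beta, terms, nms, tr$center[nms], tr$scale[nms]),
         transform = tr, terms = terms,
         fitted = fitted, residuals = resid, observed = y,
         r_squared = r2, degenerate = degenerate,
         n_obs = n, context = context, endpoint = endpoint,
         spec = spec, doses = dat[nms]),
    class = "response_surface"
  )
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> endpoint=%s context=%s n=%d R2=%.4f%s\n",
              x$endpoint, x$context %||% "<all>", x$n_obs, x$r_squared,
              if (x$degenerate) " (degenerate)" else ""))
  print(round(x$coefficients, 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.response_surface <- function(object, ...) object$coefficients

# Evaluate the quadratic form in original units at a dose matrix.
.quad_eval <- function(coef_orig, agent_names, X) {
  X <- as.matrix(as.data.frame(X)[agent_names])
  D <- .expand_quadratic(X)
  unname(drop(D %*% coef_orig))
}

# Analytic gradient of the original-unit quadratic form at one dose x.
.quad_grad <- function(coef_orig, agent_names, x) {
  d <- length(agent_names)
  a_l <- coef_orig[2:(1 + d)]
  a_q <- coef_orig[(2 + d):(1 + 2 * d)]
  g <- a_l + 2 * a_q * x
  nint <- d * (d - 1) / 2
  if (nint > 0) {
    a_int <- coef_orig[(2 + 2 * d):(1 + 2 * d + nint)]
    k <- 0
    for (i in seq_len(d - 1)) {
      for (j in seq(i + 1, d)) {
        k <- k + 1
        g[i] <- g[i] + a_int[k] * x[j]
        g[j] <- g[j] + a_int[k] * x[i]
      }
    }
  }
  unname(g)
}

#' Predict from a fitted response surface
#'
#' Evaluates the fitted quadratic form at new dose combinations, in the
#' endpoint's units and without clipping. Doses outside the panel's tested
#' box are refused unless `extrapolate = TRUE`.
#'
#' @param object A `response_surface`.
#' @param newdata Data frame with one column per agent (or a named
#'   numeric vector for a single dose combination).
#' @param extrapolate Allow prediction outside the tested dose box.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.response_surface <- function(object, newdata,
                                     extrapolate = FALSE, ...) {
  nms <- panel_names(object$spec$panel)
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  newdata <- as.data.frame(newdata)[nms]
  if (!extrapolate) {
    up <- panel_upper(object$spec$panel)
    for (j in seq_along(nms)) {
      v <- newdata[[j]]
      if (any(v < -1e-12 | v > up[j] * (1 + 1e-12))) {
        .stopf(paste0("dose '%s' outside the tested box [0, %g]; ",
                      "set extrapolate = TRUE to override"), nms[j], up[j])
      }
    }
  }
  .quad_eval(object$coefficients_original, nms, newdata)
}

#' Predicted-versus-observed pairs
#'
#' Returns the training-order (observed, predicted) pairs together with the
#' coefficient of determination — the concordance summary behind
#' predicted-vs-actual plots.
#'
#' @param model A `response_surface`.
#' @return Data frame with columns `observed`, `predicted`; attribute
#'   `r_squared`.
#' @export
predicted_vs_observed <- function(model) {
  stopifnot(inherits(model, "response_surface"))
  out <- data.frame(observed = model$observed, predicted = model$fitted)
  attr(out, "r_squared") <- model$r_squared
  out
}
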