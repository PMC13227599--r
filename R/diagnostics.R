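#' Durbin-Watson statistic
#'
#' First-order serial-correlation statistic of residuals taken in
#' acquisition (run) order: `sum(diff(e)^2) / sum(e^2)`, ranging 0..4 with
#' values near 2 indicating no first-order autocorrelation. Reported as a
#' statistic only, without a p-value.
#'
#' @param residuals Numeric residuals ordered by run order (length >= 2).
#' @return The statistic, a number in `[0, 4]`.
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 2L) .stopf("durbin_watson: need at least 2 residuals")
  denom <- sum(e^2)
  if (denom == 0) .stopf("durbin_watson: all residuals are zero; undefined")
  sum(diff(e)^2) / denom
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Lagrange-multiplier test for variance depending on the regressors:
#' squared residuals are regressed on the model's design columns and the
#' statistic is `n * R^2` of that auxiliary regression, compared to a
#' chi-squared distribution with `p - 1` degrees of freedom (the
#' studentized/Koenker form).
#'
#' @param model A fitted `response_surface`.
#' @return List with `statistic` and `p_value`.
#' @export
breusch_pagan <- function(model) {
  stopifnot(inherits(model, "response_surface"))
  n <- model$n_obs
  p <- length(model$terms)
  if (n <= p) .stopf("breusch_pagan: need n_obs > number of terms")
  X <- build_design_matrix(model$doses, model$spec,
                           transform = model$transform)
  u <- model$residuals^2
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) .stopf("breusch_pagan: singular auxiliary design")
  fit <- qr.fitted(qrX, u)
  sse <- sum((u - fit)^2)
  sst <- sum((u - mean(u))^2)
  r2_aux <- if (sst == 0) 0 else 1 - sse / sst
  stat <- n * r2_aux
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = p - 1, lower.tail = FALSE))
}

#' Shapiro-Wilk normality test of residuals
#'
#' Thin, validated wrapper around [stats::shapiro.test()] restricted to the
#' supported sample-size range; identical residuals are refused explicitly
#' rather than returning silently.
#'
#' @param residuals Numeric vector, `3 <= n <= 5000`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(residuals) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 3L || n > 5000L) {
    .stopf("shapiro_wilk: sample size %d outside supported range 3..5000", n)
  }
  if (diff(range(e)) == 0) {
    .stopf("shapiro_wilk: all residuals identical; W undefined")
  }
  ht <- stats::shapiro.test(e)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Variance inflation factors
#'
#' For each column of a mean-centered design (intercept excluded), the VIF
#' is `1 / (1 - R^2_j)` from regressing that column on all the others.
#' Exactly collinear columns are reported as `Inf` rather than raising an
#' error, so the full collinearity pattern is visible at once.
#'
#' @param X Numeric matrix of mean-centered, non-intercept columns
#'   (>= 2 columns).
#' @param terms Optional term names (defaults to `colnames(X)`).
#' @return Named numeric vector of VIFs (>= 1, possibly `Inf`).
#' @export
vif <- function(X, terms = colnames(X)) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) .stopf("vif: need at least 2 columns")
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(X)))
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    Z <- X[, -j, drop = FALSE]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) { out[j] <- Inf; next }
    qz <- qr(cbind(1, Z))
    res <- qr.resid(qz, y)
    r2 <- 1 - sum(res^2) / sst
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, terms)
}

#' VIFs of a fitted surface's centered quadratic design
#'
#' Rebuilds the model's design on the mean-centered scale and reports the
#' VIF of every non-intercept term, flagging those at or above the
#' threshold (default 3, the prespecified severe-multicollinearity cut).
#'
#' @param model A `response_surface`.
#' @param threshold Flagging threshold (default 3).
#' @return List with `vif` (named vector) and `flagged` (character).
#' @export
vif_report <- function(model, threshold = 3) {
  spec_c <- model$spec
  spec_c$center_for_vif <- TRUE
  X <- build_design_matrix(model$doses, spec_c, transform = model$transform)
  v <- vif(X[, -1, drop = FALSE], terms = model$terms[-1])
  list(vif = v, threshold = threshold,
       flagged = names(v)[v >= threshold])
}

#' K-fold cross-validated RMSE
#'
#' Shuffles the aggregated conditions with the given seed, splits them into
#' `k` folds, fits the quadratic surface on each training split and pools
#' the held-out prediction errors into one RMSE. Folds whose training
#' design loses full column rank are skipped with a warning.
#'
#' @param agg Aggregated table (one row per condition).
#' @param spec A [design_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @param response Response column (default `"mean_value"`).
#' @return List with `cv_rmse`, `k`, `n_skipped_folds`, `n_predicted`.
#' @export
kfold_cv_rmse <- function(agg, spec, k = 5, seed = 1,
                          response = "mean_value") {
  dat <- as.data.frame(agg)
  n <- nrow(dat)
  if (n < k || k < 2) .stopf("kfold_cv_rmse: need n >= k >= 2 (n=%d, k=%d)",
                             n, k)
  perm <- .with_seed(substream_seed(seed, "cv"), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  errs <- numeric(0)
  skipped <- 0L
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    m <- tryCatch(
      fit_quadratic_surface(dat[train, , drop = FALSE], spec,
                            response = response),
      error = function(e) NULL)
    if (is.null(m)) {
      skipped <- skipped + 1L
      .warnf("kfold_cv_rmse: fold %d skipped (rank-deficient training set)", f)
      next
    }
    pred <- predict(m, dat[test, panel_names(spec$panel), drop = FALSE],
                    extrapolate = TRUE)
    errs <- c(errs, dat[[response]][test] - pred)
  }
  if (skipped == k) .stopf("kfold_cv_rmse: every fold was rank-deficient")
  list(cv_rmse = sqrt(mean(errs^2)), k = k,
       n_skipped_folds = skipped, n_predicted = length(errs))
}

#' Nonparametric bootstrap of the fitted surface
#'
#' Case bootstrap at the level the model is fit on: aggregated conditions
#' are resampled with replacement, the surface refit per replicate, and
#' percentile confidence intervals formed per coefficient (reported in
#' original dose units). Rank-deficient resamples are redrawn and counted;
#' if more than half of all draws are rank-deficient the bootstrap is
#' declared unstable. When a [nomination_problem()] is supplied, each
#' replicate's refitted objective surface is re-nominated, yielding
#' per-agent percentile intervals for the nominated dose.
#'
#' @param agg Aggregated table (one row per condition).
#' @param spec A [design_spec()].
#' @param B Number of bootstrap replicates (>= 100 recommended;
#'   default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param problem Optional [nomination_problem()] for optimum-location
#'   intervals.
#' @param response Response column (default `"mean_value"`).
#' @return List with `ci` (term x (lo, hi) matrix), `B`, `seed`,
#'   `n_redrawn`, `coef_replicates`, and optionally `dose_ci`.
#' @export
bootstrap_model <- function(agg, spec, B = 1000, seed = 1, level = 0.95,
                            problem = NULL, response = "mean_value") {
  dat <- as.data.frame(agg)
  n <- nrow(dat)
  if (B < 2) .stopf("bootstrap_model: B must be >= 2")
  terms <- .term_names(panel_names(spec$panel))
  coefs <- matrix(NA_real_, B, length(terms),
                  dimnames = list(NULL, terms))
  doses <- if (!is.null(problem)) {
    matrix(NA_real_, B, length(panel_names(spec$panel)),
           dimnames = list(NULL, panel_names(spec$panel)))
  } else NULL
  redrawn <- 0L
  .with_seed(substream_seed(seed, "bootstrap"), {
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > 2L * B && redrawn / attempts > 0.5) {
        .stopf("bootstrap unstable: >50%% of resamples rank-deficient")
      }
      idx <- sample.int(n, n, replace = TRUE)
      m <- tryCatch(
        suppressWarnings(
          fit_quadratic_surface(dat[idx, , drop = FALSE], spec,
                                response = response)),
        error = function(e) NULL)
      if (is.null(m)) { redrawn <- redrawn + 1L; next }
      coefs[b, ] <- m$coefficients_original
      if (!is.null(problem)) {
        pb <- problem
        pb$objective_model <- m
        pb$seed <- substream_seed(seed, "bootstrap-nominate", b)
        res <- tryCatch(nominate(pb), error = function(e) NULL)
        if (!is.null(res)) doses[b, ] <- unlist(res$dose)
      }
      b <- b + 1L
    }
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(coefs, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lo", "hi")
  out <- list(ci = ci, B = B, seed = seed, level = level,
              n_redrawn = redrawn, coef_replicates = coefs)
  if (!is.null(doses)) {
    dci <- t(apply(doses, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                   na.rm = TRUE, names = FALSE))
    colnames(dci) <- c("lo", "hi")
    out$dose_ci <- dci
  }
  out
}

#' Full model-adequacy and robustness report
#'
#' Runs the prespecified diagnostic suite on one fitted surface: residual
#' normality (Shapiro-Wilk), heteroscedasticity (Breusch-Pagan),
#' first-order error independence (Durbin-Watson), collinearity (VIF on
#' the mean-centered design, flag at the threshold), K-fold CV RMSE and a
#' nonparametric bootstrap of the coefficients. Diagnostics warn — they
#' never abort downstream nomination; the surface is retained for
#' interpretability and its robustness is judged by the out-of-sample and
#' bootstrap summaries.
#'
#' @param model A `response_surface`.
#' @param agg The aggregated table the model was fit on (needed for CV and
#'   bootstrap; if omitted those entries are `NULL`).
#' @param k CV folds (default 5).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed for CV shuffling and bootstrap resampling.
#' @param vif_threshold VIF flag threshold (default 3).
#' @param response Response column (default `"mean_value"`).
#' @return An object of class `diagnostics_report`.
#' @export
diagnose <- function(model, agg = NULL, k = 5, B = 1000, seed = 1,
                     vif_threshold = 3, response = "mean_value") {
  stopifnot(inherits(model, "response_surface"))
  sw <- tryCatch(shapiro_wilk(model$residuals),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))
  bp <- tryCatch(breusch_pagan(model),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))
  dw <- tryCatch(durbin_watson(model$residuals),
                 error = function(e) NA_real_)
  vr <- vif_report(model, threshold = vif_threshold)
  cv <- if (!is.null(agg)) {
    tryCatch(kfold_cv_rmse(agg, model$spec, k = k, seed = seed,
                           response = response),
             error = function(e) NULL)
  } else NULL
  bs <- if (!is.null(agg)) {
    tryCatch(bootstrap_model(agg, model$spec, B = B, seed = seed,
                             response = response),
             error = function(e) NULL)
  } else NULL
  structure(
    list(shapiro_w = sw$statistic, shapiro_p = sw$p_value,
         bp_stat = bp$statistic, bp_p = bp$p_value,
         dw_stat = dw,
         vif = vr$vif, vif_flag_threshold = vif_threshold,
         vif_flagged = vr$flagged,
         cv_rmse = if (is.null(cv)) NA_real_ else cv$cv_rmse,
         cv_k = if (is.null(cv)) NA_integer_ else cv$k,
         bootstrap_ci = if (is.null(bs)) NULL else bs$ci,
         bootstrap_B = if (is.null(bs)) NA_integer_ else bs$B,
         seed = seed),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  Shapiro-Wilk   W = %.4f, p = %.4g\n", x$shapiro_w,
              x$shapiro_p))
  cat(sprintf("  Breusch-Pagan  LM = %.4f, p = %.4g\n", x$bp_stat, x$bp_p))
  cat(sprintf("  Durbin-Watson  d = %.4f\n", x$dw_stat))
  cat(sprintf("  CV RMSE (k=%s) = %.4g\n", x$cv_k, x$cv_rmse))
  flagged <- if (length(x$vif_flagged)) paste(x$vif_flagged, collapse = ", ")
             else "none"
  cat(sprintf("  VIF >= %g: %s (max VIF %.3g)\n", x$vif_flag_threshold,
              flagged, max(x$vif)))
  if (!is.null(x$bootstrap_ci)) {
    cat(sprintf("  Bootstrap B = %d, 95%% percentile CIs per term\n",
                x$bootstrap_B))
  }
  invisible(x)
}
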