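#' Assemble a validated pipeline run configuration
#'
#' Gathers every knob of the five-stage workflow — ingest, aggregate, fit,
#' diagnose, nominate — into one serializable object with explicit seeds
#' for every stochastic stage. In `"hard_constraint"` mode with constraint
#' tables present, the viability floor `theta` is required up front: the
#' tested data never pin a universal floor, so it is an explicit analysis
#' choice, not a default.
#'
#' @param panel An [agent_panel()].
#' @param endpoint Endpoint name (default `"viability_pct"`).
#' @param contexts Optional character vector restricting contexts.
#' @param standardize,internal_rescale Design options (see
#'   [design_spec()]).
#' @param cv_k CV folds (default 5).
#' @param bootstrap_B Bootstrap replicates (default 1000).
#' @param vif_threshold VIF flag threshold (default 3).
#' @param mode Nomination mode (see [nomination_problem()]).
#' @param theta Constraint floor(s), endpoint units; required when
#'   `mode = "hard_constraint"` and constraint data are supplied.
#' @param weights Weights for `"weighted_sum"`.
#' @param n_starts Multistart count (default 32).
#' @param seed Root seed for CV, bootstrap and multistart.
#' @param has_constraints Declare whether constraint tables will be
#'   supplied (drives the early theta check; default `FALSE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel, endpoint = "viability_pct", contexts = NULL,
                       standardize = "original_units",
                       internal_rescale = TRUE, cv_k = 5,
                       bootstrap_B = 1000, vif_threshold = 3,
                       mode = c("hard_constraint", "weighted_sum"),
                       theta = NULL, weights = NULL, n_starts = 32,
                       seed = 1, has_constraints = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "agent_panel"))
  if (mode == "hard_constraint" && has_constraints && is.null(theta)) {
    .stopf(paste0("config error: hard_constraint mode with constraint data ",
                  "requires an explicit viability floor theta"))
  }
  if (mode == "weighted_sum" && is.null(weights)) {
    .stopf("config error: weighted_sum mode requires weights")
  }
  structure(
    list(schema_version = "1.0", panel = panel, endpoint = endpoint,
         contexts = contexts, standardize = standardize,
         internal_rescale = internal_rescale, cv_k = cv_k,
         bootstrap_B = bootstrap_B, vif_threshold = vif_threshold,
         mode = mode, theta = theta, weights = weights,
         n_starts = n_starts, seed = as.integer(seed),
         has_constraints = has_constraints),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$panel <- lapply(unname(config$panel), function(a) {
    out <- unclass(a)
    out[!vapply(out, is.null, logical(1))]
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  agents <- lapply(raw$panel, function(a) {
    agent_spec(a$name, a$unit, a$lower_bound, a$upper_bound,
               a$stock_mass_conc)
  })
  run_config(agent_panel(agents), endpoint = raw$endpoint,
             contexts = raw$contexts, standardize = raw$standardize,
             internal_rescale = raw$internal_rescale, cv_k = raw$cv_k,
             bootstrap_B = raw$bootstrap_B,
             vif_threshold = raw$vif_threshold, mode = raw$mode,
             theta = raw$theta, weights = raw$weights,
             n_starts = raw$n_starts, seed = raw$seed,
             has_constraints = isTRUE(raw$has_constraints))
}

#' Run the full modeling-and-nomination pipeline
#'
#' Executes ingest, replicate aggregation, surface fitting, the diagnostic
#' suite and constrained nomination per context, and returns a structured
#' report bundle. Input tables may be passed in memory or as file paths
#' (read with [read_dose_response_table()]). With constraint tables, the
#' objective surface is minimized subject to each constraint surface
#' staying at or above `config$theta`; without them the problem is
#' box-only.
#'
#' @param config A [run_config()].
#' @param objective_data Long-schema data frame or file path (objective
#'   endpoint, all contexts).
#' @param constraint_data Optional named list of long-schema data frames or
#'   paths (constraint endpoints, same contexts).
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `report.json` plus delimited `summary.tsv`.
#' @return A `report_bundle`: per-context coefficients, R-squared,
#'   diagnostics, predicted-vs-observed pairs and nomination results.
#' @export
run_pipeline <- function(config, objective_data,
                         constraint_data = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "hard_constraint" && length(constraint_data) &&
      is.null(config$theta)) {
    .stopf("config error: theta required before any compute")
  }
  load_tab <- function(x, label) {
    tab <- if (is.character(x)) read_dose_response_table(x, config$panel)
           else validate_dose_response_table(x, config$panel, label)
    tab
  }
  obj_tab <- load_tab(objective_data, "objective")
  con_tabs <- lapply(seq_along(constraint_data), function(i) {
    load_tab(constraint_data[[i]], paste0("constraint", i))
  })
  names(con_tabs) <- names(constraint_data) %||%
    (if (length(con_tabs)) paste0("constraint", seq_along(con_tabs)))

  contexts <- config$contexts %||% unique(obj_tab$context)
  spec <- design_spec(config$panel, standardize = config$standardize,
                      internal_rescale = config$internal_rescale)
  exclusion_log <- list()
  per_context <- list()
  for (ctx in contexts) {
    stage <- "aggregate"
    res <- tryCatch({
      agg_obj <- aggregate_replicates(
        obj_tab[obj_tab$context == ctx, , drop = FALSE], config$panel)
      stage <- "fit"
      model <- fit_quadratic_surface(agg_obj, spec, context = ctx)
      stage <- "diagnose"
      diag <- diagnose(model, agg_obj, k = config$cv_k,
                       B = config$bootstrap_B,
                       seed = substream_seed(config$seed, ctx, "diag"),
                       vif_threshold = config$vif_threshold)
      stage <- "nominate"
      cons <- list()
      for (lab in names(con_tabs)) {
        agg_c <- aggregate_replicates(
          con_tabs[[lab]][con_tabs[[lab]]$context == ctx, , drop = FALSE],
          config$panel)
        cm <- fit_quadratic_surface(agg_c, spec, context = ctx)
        cons[[lab]] <- list(model = cm, floor = config$theta)
      }
      pb <- nomination_problem(model, cons, n_starts = config$n_starts,
                               seed = substream_seed(config$seed, ctx,
                                                     "nominate"),
                               mode = config$mode, weights = config$weights)
      nom <- nominate(pb)
      list(context = ctx,
           coefficients = as.list(model$coefficients),
           r_squared = model$r_squared, n_obs = model$n_obs,
           degenerate_fit = model$degenerate,
           diagnostics = diag,
           predicted_vs_observed = predicted_vs_observed(model),
           nomination = nom)
    }, error = function(e) {
      .stopf("pipeline stage '%s' failed for context '%s': %s",
             stage, ctx, conditionMessage(e))
    })
    per_context[[ctx]] <- res
  }
  bundle <- structure(
    list(schema_version = "1.0",
         endpoint = config$endpoint, mode = config$mode,
         theta = config$theta, seed = config$seed,
         contexts = per_context),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.bundle_to_json(bundle),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 9, pretty = TRUE)
    utils::write.table(report_summary(bundle, config$panel),
                       file.path(out_dir, "summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  bundle
}

.bundle_to_json <- function(bundle) {
  ctxs <- lapply(bundle$contexts, function(cx) {
    d <- cx$diagnostics
    list(context = cx$context, coefficients = cx$coefficients,
         r_squared = cx$r_squared, n_obs = cx$n_obs,
         degenerate_fit = cx$degenerate_fit,
         diagnostics = list(
           shapiro_w = d$shapiro_w, shapiro_p = d$shapiro_p,
           bp_stat = d$bp_stat, bp_p = d$bp_p, dw_stat = d$dw_stat,
           vif = as.list(d$vif), vif_flagged = as.list(d$vif_flagged),
           cv_rmse = d$cv_rmse, cv_k = d$cv_k,
           bootstrap_B = d$bootstrap_B,
           bootstrap_ci = if (is.null(d$bootstrap_ci)) NULL else
             apply(d$bootstrap_ci, 1, as.list, simplify = FALSE)),
         predicted_vs_observed = cx$predicted_vs_observed,
         nomination = list(
           dose = as.list(cx$nomination$dose),
           predicted = as.list(cx$nomination$predicted),
           feasible = cx$nomination$feasible,
           active_constraints = as.list(cx$nomination$active_constraints),
           objective_value = cx$nomination$objective_value,
           solver = cx$nomination$solver, mode = cx$nomination$mode))
  })
  list(schema_version = bundle$schema_version, endpoint = bundle$endpoint,
       mode = bundle$mode, theta = bundle$theta, seed = bundle$seed,
       contexts = ctxs)
}

#' Human-readable per-context summary of a report bundle
#'
#' One row per context: nominated doses in original units (with the
#' fold-dilution converted to ug/mL where the agent carries a stock
#' concentration), predicted objective and constraint values (displayed
#' clipped at 0, with a flag when clipping applied), feasibility,
#' R-squared, CV RMSE and flagged VIF terms. Infeasible nominations are
#' rendered with an explicit INFEASIBLE banner.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param panel The [agent_panel()] used in the run.
#' @return A data frame, one row per context, in stable context order.
#' @export
report_summary <- function(bundle, panel) {
  rows <- lapply(bundle$contexts, function(cx) {
    nom <- cx$nomination
    row <- list(context = cx$context)
    for (nm in names(nom$dose)) {
      row[[paste0("dose_", nm)]] <- unname(nom$dose[nm])
      a <- panel[[nm]]
      if (!is.null(a$stock_mass_conc)) {
        row[[paste0("dose_", nm, "_ug_per_mL")]] <-
          dilution_to_mass(unname(nom$dose[nm]), a$stock_mass_conc)
      }
    }
    clipped <- FALSE
    for (nm in names(nom$predicted)) {
      v <- unname(nom$predicted[nm])
      if (v < 0) { v <- 0; clipped <- TRUE }
      row[[paste0("pred_", nm)]] <- v
    }
    row$pred_clipped_at_zero <- clipped
    row$status <- if (nom$feasible) "feasible" else "INFEASIBLE"
    row$r_squared <- cx$r_squared
    row$cv_rmse <- cx$diagnostics$cv_rmse
    row$vif_flagged <- paste(cx$diagnostics$vif_flagged, collapse = ",")
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> endpoint=%s mode=%s contexts=%s\n",
              x$endpoint, x$mode,
              paste(names(x$contexts), collapse = ", ")))
  for (cx in x$contexts) {
    cat(sprintf("-- context %s: R2=%.4f, %s\n", cx$context, cx$r_squared,
                if (cx$nomination$feasible) "feasible nomination"
                else "** INFEASIBLE **"))
  }
  invisible(x)
}
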