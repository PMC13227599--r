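#' Read a long-format dose-response table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) holding one measured endpoint value per row. Required columns are
#' one dose column per panel agent plus `endpoint`, `value`, `context`,
#' `subject`, `bio_rep`, `tech_rep`; `timepoint_dpf` is optional. Doses are
#' validated against the panel bounds; row order is preserved.
#'
#' @param path Path to a CSV/TSV file with one header row.
#' @param panel An [agent_panel()].
#' @return A `data.frame` with validated columns in canonical order.
#' @export
read_dose_response_table <- function(path, panel) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, na.strings = character(0),
                           encoding = "UTF-8")
  validate_dose_response_table(tab, panel, where = path)
}

#' Validate an in-memory dose-response table
#'
#' Applies the same schema, type and range checks as
#' [read_dose_response_table()] to a data frame already in memory.
#'
#' @param tab A data frame in the long schema.
#' @param panel An [agent_panel()].
#' @param where Label used in error messages.
#' @return The validated data frame, columns in canonical order.
#' @export
validate_dose_response_table <- function(tab, panel, where = "table") {
  required <- c(panel_names(panel), "endpoint", "value", "context",
                "subject", "bio_rep", "tech_rep")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    .stopf("%s: missing column(s): %s", where, paste(missing, collapse = ", "))
  }
  numcols <- c(panel_names(panel), "value")
  for (cn in numcols) {
    v <- tab[[cn]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        .stopf("%s: non-numeric value '%s' in column '%s' at row %d",
               where, v[bad[1]], cn, bad[1])
      }
      tab[[cn]] <- num
    }
    if (anyNA(tab[[cn]])) {
      .stopf("%s: missing value in column '%s' at row %d", where, cn,
             which(is.na(tab[[cn]]))[1])
    }
    tab[[cn]] <- as.numeric(tab[[cn]])
  }
  .check_doses(tab[panel_names(panel)], panel, where = where)
  for (cn in c("bio_rep", "tech_rep")) {
    tab[[cn]] <- as.integer(tab[[cn]])
    if (anyNA(tab[[cn]]) || any(tab[[cn]] < 1L)) {
      .stopf("%s: column '%s' must hold integers >= 1", where, cn)
    }
  }
  known <- c("viability_pct", "macrophage_density", "macrophage_ratio")
  bad <- setdiff(unique(tab$endpoint), known)
  if (length(bad)) {
    .stopf("%s: unknown endpoint(s): %s (expected one of %s)", where,
           paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  neg <- which(tab$endpoint != "macrophage_ratio" & tab$value < 0)
  if (length(neg)) {
    .stopf("%s: negative %s value at row %d", where, tab$endpoint[neg[1]],
           neg[1])
  }
  ord <- c(panel_names(panel), "endpoint", "value", "context", "subject",
           "bio_rep", "tech_rep",
           intersect("timepoint_dpf", names(tab)))
  tab[ord]
}

#' Write a dose-response table
#'
#' Writes the long schema as delimited text. Numeric columns are written
#' with up to 15 significant digits so that a write/read round trip is
#' exact for decimal inputs of ordinary precision.
#'
#' @param tab A data frame in the long schema (or aggregated schema).
#' @param path Output path; extension `.tsv` selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_dose_response_table <- function(tab, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- tab
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- formatC(out[[cn]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a wide plate map to the long schema
#'
#' Helper for plate-shaped inputs: takes a data frame with one column per
#' replicate (`rep_cols`) and melts it into the long schema with
#' `tech_rep` numbered by column order.
#'
#' @param wide Data frame with agent columns, metadata and replicate columns.
#' @param rep_cols Character vector of replicate column names.
#' @param endpoint Endpoint name applied to every row.
#' @param bio_rep Biological replicate index applied to every row.
#' @return A long-schema data frame.
#' @export
plate_map_to_long <- function(wide, rep_cols, endpoint = "viability_pct",
                              bio_rep = 1L) {
  keep <- setdiff(names(wide), rep_cols)
  pieces <- lapply(seq_along(rep_cols), function(j) {
    out <- wide[keep]
    out$endpoint <- endpoint
    out$value <- wide[[rep_cols[j]]]
    out$bio_rep <- as.integer(bio_rep)
    out$tech_rep <- j
    out
  })
  do.call(rbind, pieces)
}

#' Normalize a raw viability signal to percent of vehicle
#'
#' Background-corrects a raw plate-reader signal against the blank and
#' scales it so that the vehicle-control mean maps to 100 and the blank to
#' 0. Values above 100 are retained, not clipped: clipping would bias the
#' downstream least-squares surface.
#'
#' @param raw_signal Raw well signal (same scale as blank/vehicle).
#' @param blank Blank (no-cell) signal.
#' @param vehicle_mean Mean vehicle-control signal; must exceed `blank`.
#' @return Viability in percent (vectorized over `raw_signal`).
#' @export
#' @examples
#' normalize_viability(0.40, 0.05, 0.75)  # 50
normalize_viability <- function(raw_signal, blank, vehicle_mean) {
  if (!is.finite(vehicle_mean) || !is.finite(blank) ||
      vehicle_mean <= blank) {
    .stopf("degenerate plate: vehicle_mean (%g) must exceed blank (%g)",
           vehicle_mean, blank)
  }
  100 * (raw_signal - blank) / (vehicle_mean - blank)
}

#' Aggregate replicate measurements to per-condition means
#'
#' Two-stage replicate aggregation: values are first averaged across
#' technical replicates within each (dose, context, biological replicate)
#' cell, then the per-biological-replicate means are averaged across
#' biological replicates. The per-biological-replicate means are retained
#' (`per_bio` list column) so the nonparametric bootstrap can resample at
#' the condition level. Unbalanced technical replicate counts are averaged
#' as-is; a message records any imbalance.
#'
#' @param tab Long-schema data frame sharing one `endpoint`.
#' @param panel An [agent_panel()].
#' @return A data frame with one row per (dose, context): agent columns,
#'   `endpoint`, `context`, `mean_value`, `n_bio`, and list column
#'   `per_bio`.
#' @export
aggregate_replicates <- function(tab, panel) {
  nms <- panel_names(panel)
  if (nrow(tab) == 0L) {
    out <- tab[c(nms, "endpoint", "context")][0, , drop = FALSE]
    out$mean_value <- numeric(0)
    out$n_bio <- integer(0)
    out$per_bio <- list()
    return(out)
  }
  if (length(unique(tab$endpoint)) != 1L) {
    .stopf("aggregate_replicates: records must share one endpoint, got: %s",
           paste(unique(tab$endpoint), collapse = ", "))
  }
  dose_key <- do.call(paste, c(lapply(tab[nms], format, digits = 15),
                               sep = "|"))
  cond_key <- paste(dose_key, tab$context, sep = "||")
  bio_key <- paste(cond_key, tab$bio_rep, sep = "||")

  tech_n <- tapply(tab$value, bio_key, length)
  if (length(unique(tech_n)) > 1L) {
    message(sprintf(
      "aggregate_replicates: unbalanced technical replicates (%s per cell)",
      paste(sort(unique(tech_n)), collapse = "/")))
  }
  bio_mean <- tapply(tab$value, bio_key, mean)
  bio_cond <- sub("\\|\\|[^|]*$", "", names(bio_mean))

  conds <- unique(cond_key)
  first <- match(conds, cond_key)
  out <- tab[first, c(nms, "endpoint", "context"), drop = FALSE]
  rownames(out) <- NULL
  per_bio <- lapply(conds, function(k) unname(bio_mean[bio_cond == k]))
  out$mean_value <- vapply(per_bio, mean, numeric(1))
  out$n_bio <- vapply(per_bio, length, integer(1))
  out$per_bio <- per_bio
  out
}

#' Convert a stock fold-dilution to mass concentration
#'
#' For an extract dosed as a fold-dilution of a weighed stock, converts the
#' dilution to the working mass concentration:
#' `dilution * stock_mass_conc` (mg/mL) expressed in ug/mL. A 1e-4
#' dilution of a 200 mg/mL stock is 20 ug/mL.
#'
#' @param dilution Non-negative fold-dilution (vectorized).
#' @param stock_mass_conc Stock concentration in mg/mL (> 0).
#' @return Working concentration in ug/mL.
#' @export
#' @examples
#' dilution_to_mass(1e-4, 200)    # 20
#' dilution_to_mass(0.3e-4, 200)  # 6
dilution_to_mass <- function(dilution, stock_mass_conc) {
  if (!is.numeric(stock_mass_conc) || stock_mass_conc <= 0) {
    .stopf("stock_mass_conc must be positive (mg/mL)")
  }
  if (any(dilution < 0)) .stopf("dilution must be non-negative")
  dilution * stock_mass_conc * 1000
}
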