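#' Define one agent of a combination panel
#'
#' An agent specification records the dosing unit and the experimentally
#' tested dose bounds of a single drug or extract. The bounds are the
#' extremes actually tested in the experiment and later define the box
#' within which dose nomination is allowed to search; the optimizer never
#' extrapolates beyond them.
#'
#' @param name Agent name, e.g. `"propolis"`.
#' @param unit Dose unit as free text, e.g. `"fold-dilution"`, `"mM"`,
#'   `"uM"`, `"nM"`.
#' @param lower_bound Non-negative lower tested dose (same unit).
#' @param upper_bound Positive upper tested dose (same unit); must exceed
#'   `lower_bound`.
#' @param stock_mass_conc Optional stock mass concentration in mg/mL, used
#'   to convert fold-dilutions to mass concentration (see
#'   [dilution_to_mass()]). Typically supplied for a natural-product
#'   extract dosed as a dilution of a weighed stock.
#' @return An object of class `agent_spec`.
#' @export
#' @examples
#' agent_spec("propolis", "fold-dilution", 0, 1e-4, stock_mass_conc = 200)
#' agent_spec("metformin", "mM", 0, 10)
agent_spec <- function(name, unit, lower_bound = 0, upper_bound,
                       stock_mass_conc = NULL) {
  stopifnot(is.character(name), nchar(name) > 0, is.character(unit))
  if (!is.numeric(lower_bound) || lower_bound < 0) {
    .stopf("agent '%s': lower_bound must be a non-negative number", name)
  }
  if (!is.numeric(upper_bound) || upper_bound <= 0) {
    .stopf("agent '%s': upper_bound must be a positive number", name)
  }
  if (lower_bound >= upper_bound) {
    .stopf("agent '%s': lower_bound (%g) must be < upper_bound (%g)",
           name, lower_bound, upper_bound)
  }
  if (!is.null(stock_mass_conc) && stock_mass_conc <= 0) {
    .stopf("agent '%s': stock_mass_conc must be positive (mg/mL)", name)
  }
  structure(
    list(name = name, unit = unit,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         stock_mass_conc = if (is.null(stock_mass_conc)) NULL
                           else as.numeric(stock_mass_conc)),
    class = "agent_spec"
  )
}

#' Assemble an ordered agent panel
#'
#' The panel fixes the identity, order, units and tested bounds of the
#' agents in a combination study. Agent order is significant: design-matrix
#' terms, coefficient reports and nomination outputs all follow it.
#'
#' @param ... One or more [agent_spec()] objects.
#' @return An object of class `agent_panel` (a named list of `agent_spec`).
#' @export
#' @examples
#' pmr_panel <- agent_panel(
#'   agent_spec("propolis", "fold-dilution", 0, 1e-4, stock_mass_conc = 200),
#'   agent_spec("metformin", "mM", 0, 10),
#'   agent_spec("regorafenib", "uM", 0, 6.5)
#' )
agent_panel <- function(...) {
  agents <- list(...)
  if (length(agents) == 1L && is.list(agents[[1]]) &&
      !inherits(agents[[1]], "agent_spec")) {
    agents <- agents[[1]]
  }
  if (length(agents) < 1L) .stopf("panel needs at least one agent")
  ok <- vapply(agents, inherits, logical(1), "agent_spec")
  if (!all(ok)) .stopf("all panel entries must be agent_spec objects")
  nms <- vapply(agents, `[[`, character(1), "name")
  if (anyDuplicated(nms)) .stopf("duplicate agent names in panel")
  names(agents) <- nms
  structure(agents, class = "agent_panel")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent> %s [%s]: tested %g .. %g%s\n", x$name, x$unit,
              x$lower_bound, x$upper_bound,
              if (is.null(x$stock_mass_conc)) ""
              else sprintf(" (stock %g mg/mL)", x$stock_mass_conc)))
  invisible(x)
}

#' @export
print.agent_panel <- function(x, ...) {
  cat(sprintf("<agent_panel> %d agents\n", length(x)))
  for (a in x) print(a)
  invisible(x)
}

panel_names <- function(panel) vapply(panel, `[[`, character(1), "name")
panel_lower <- function(panel) vapply(panel, `[[`, numeric(1), "lower_bound")
panel_upper <- function(panel) vapply(panel, `[[`, numeric(1), "upper_bound")

# Validate a dose matrix/data.frame against the panel: agent set identity,
# non-negativity and containment in [0, upper_bound].
.check_doses <- function(doses, panel, where = "dose table") {
  nms <- panel_names(panel)
  doses <- as.data.frame(doses)
  missing <- setdiff(nms, names(doses))
  if (length(missing)) {
    .stopf("%s: missing dose column(s): %s", where,
           paste(missing, collapse = ", "))
  }
  doses <- doses[nms]
  up <- panel_upper(panel)
  for (j in seq_along(nms)) {
    v <- doses[[j]]
    if (!is.numeric(v)) .stopf("%s: dose column '%s' is not numeric",
                               where, nms[j])
    bad <- which(v < 0 | v > up[j])
    if (length(bad)) {
      .stopf("%s: dose '%s' outside [0, %g] at row(s) %s", where, nms[j],
             up[j], paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  doses
}
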