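#' Default space-filling dose grid over the tested box
#'
#' Builds a full factorial over per-agent levels `{0, 1/4, 1/2, 3/4, 1} x
#' upper_bound` (lower bound substituted when nonzero) and prunes it to a
#' deterministic space-filling subset by greedy maximin selection in
#' box-normalized coordinates, seeded from the origin and all-upper
#' corners. The default subset size is `max(2 * p, 27)` points for `p`
#' design terms, comfortably above the identifiability minimum of the
#' 10-term quadratic for 3 agents.
#'
#' @param panel An [agent_panel()].
#' @param levels Fractions of the box span per agent (default
#'   `c(0, .25, .5, .75, 1)`).
#' @param m Subset size; `NULL` for the default above; `Inf` keeps the full
#'   factorial.
#' @return Data frame of dose combinations (one column per agent).
#' @export
default_dose_grid <- function(panel, levels = c(0, 0.25, 0.5, 0.75, 1),
                              m = NULL) {
  nms <- panel_names(panel)
  lo <- panel_lower(panel); up <- panel_upper(panel)
  axes <- lapply(seq_along(nms), function(j) lo[j] + levels * (up[j] - lo[j]))
  G <- expand.grid(axes)
  names(G) <- nms
  d <- length(nms)
  p <- 1 + 2 * d + d * (d - 1) / 2
  if (is.null(m)) m <- max(2 * p, 27)
  if (!is.finite(m) || m >= nrow(G)) return(G)
  # greedy maximin in normalized coordinates, deterministic
  Z <- sweep(sweep(as.matrix(G), 2, lo, "-"), 2, up - lo, "/")
  chosen <- c(1L, nrow(G))  # origin-most and upper-most corners
  mind <- pmin(
    sqrt(rowSums(sweep(Z, 2, Z[chosen[1], ], "-")^2)),
    sqrt(rowSums(sweep(Z, 2, Z[chosen[2], ], "-")^2)))
  while (length(chosen) < m) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, sqrt(rowSums(sweep(Z, 2, Z[nxt, ], "-")^2)))
  }
  out <- G[sort(unique(chosen)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define the true surface behind a simulated viability experiment
#'
#' Holds everything that determines a generated plate dataset: the true
#' quadratic coefficients in original dose units, the dose grid, the
#' replication layout (3 technical x 3 biological replicates by default,
#' the layout of a replicated plate experiment run on different days), and
#' the noise model — an additive Gaussian per-well technical error and an
#' additive Gaussian per-biological-replicate offset shared by all wells
#' of that run.
#'
#' @param coefficients Named vector over the frozen quadratic terms of the
#'   panel (missing terms default to 0; `"(Intercept)"` required).
#' @param panel An [agent_panel()].
#' @param grid Data frame of dose combinations (default
#'   [default_dose_grid()]).
#' @param noise_sd Per-well technical noise SD in endpoint units
#'   (default 5).
#' @param bio_rep_sd SD of the shared biological-replicate offset
#'   (default 3).
#' @param n_tech,n_bio Replication (defaults 3 and 3).
#' @param context Context label (default `"FA-free"`).
#' @param endpoint Endpoint name (default `"viability_pct"`).
#' @param seed Integer root seed.
#' @return An object of class `surface_truth`.
#' @export
surface_truth <- function(coefficients, panel, grid = NULL,
                          noise_sd = 5, bio_rep_sd = 3,
                          n_tech = 3, n_bio = 3,
                          context = "FA-free", endpoint = "viability_pct",
                          seed = 1) {
  if (noise_sd < 0 || bio_rep_sd < 0) {
    .stopf("noise_sd and bio_rep_sd must be non-negative")
  }
  if (n_tech < 1 || n_bio < 1) .stopf("replicate counts must be >= 1")
  terms <- .term_names(panel_names(panel))
  co <- stats::setNames(numeric(length(terms)), terms)
  unknown <- setdiff(names(coefficients), terms)
  if (length(unknown)) {
    .stopf("unknown coefficient term(s): %s", paste(unknown, collapse = ", "))
  }
  co[names(coefficients)] <- coefficients
  if (is.null(grid)) grid <- default_dose_grid(panel)
  grid <- .check_doses(grid, panel, "truth grid")
  structure(
    list(coefficients = co, panel = panel, grid = grid,
         noise_sd = noise_sd, bio_rep_sd = bio_rep_sd,
         n_tech = as.integer(n_tech), n_bio = as.integer(n_bio),
         context = context, endpoint = endpoint, seed = as.integer(seed)),
    class = "surface_truth"
  )
}

#' True surface value at dose combinations
#'
#' @param truth A `surface_truth` (or `cohort_truth`).
#' @param doses Data frame of dose combinations.
#' @return Numeric vector of noiseless surface values.
#' @export
true_surface_value <- function(truth, doses) {
  .quad_eval(truth$coefficients, panel_names(truth$panel), doses)
}

#' Generate a replicated viability table from a known surface
#'
#' Simulates the long-schema record table of a replicated plate
#' experiment: for each biological replicate a shared Gaussian offset is
#' drawn, then every (dose, technical replicate) well gets the true
#' quadratic value plus that offset plus independent Gaussian technical
#' noise. Random draws use named substreams per (context, biological
#' replicate), so adding replicates or contexts never changes existing
#' draws; the output is a pure function of (truth, seed).
#'
#' @param truth A [surface_truth()].
#' @return Long-schema data frame of `DoseResponseRecord` rows.
#' @export
generate_viability_table <- function(truth) {
  stopifnot(inherits(truth, "surface_truth"))
  nms <- panel_names(truth$panel)
  mu <- true_surface_value(truth, truth$grid)
  n_dose <- nrow(truth$grid)
  pieces <- vector("list", truth$n_bio)
  for (b in seq_len(truth$n_bio)) {
    s <- substream_seed(truth$seed, truth$context, paste0("bio", b))
    draws <- .with_seed(s, {
      list(offset = stats::rnorm(1, 0, truth$bio_rep_sd),
           tech = stats::rnorm(n_dose * truth$n_tech, 0, truth$noise_sd))
    })
    rows <- truth$grid[rep(seq_len(n_dose), each = truth$n_tech), ,
                       drop = FALSE]
    rows$endpoint <- truth$endpoint
    rows$value <- rep(mu, each = truth$n_tech) + draws$offset + draws$tech
    rows$context <- truth$context
    rows$subject <- "simulated"
    rows$bio_rep <- b
    rows$tech_rep <- rep(seq_len(truth$n_tech), times = n_dose)
    pieces[[b]] <- rows
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Generate a paired two-context table with a coefficient shift
#'
#' Emulates a context (for example fatty-acid enrichment) that reshapes
#' the true response surface: the second context's truth equals the first
#' plus the supplied coefficient deltas. Both contexts share the grid and
#' replication layout; their noise streams are split by context label.
#'
#' @param truth_base A [surface_truth()] for the base context.
#' @param shift Named numeric vector of coefficient deltas (frozen term
#'   names; missing terms shift by 0).
#' @param shifted_context Label for the shifted context (default `"FA"`).
#' @return One long-schema data frame holding both contexts; attribute
#'   `"truth"` carries the two `surface_truth` objects.
#' @export
generate_fa_shift_pair <- function(truth_base, shift,
                                   shifted_context = "FA") {
  stopifnot(inherits(truth_base, "surface_truth"))
  terms <- names(truth_base$coefficients)
  unknown <- setdiff(names(shift), terms)
  if (length(unknown)) {
    .stopf("unknown shift term(s): %s", paste(unknown, collapse = ", "))
  }
  co2 <- truth_base$coefficients
  co2[names(shift)] <- co2[names(shift)] + shift
  truth_fa <- truth_base
  truth_fa$coefficients <- co2
  truth_fa$context <- shifted_context
  tab <- rbind(generate_viability_table(truth_base),
               generate_viability_table(truth_fa))
  attr(tab, "truth") <- stats::setNames(
    list(truth_base, truth_fa), c(truth_base$context, shifted_context))
  tab
}

#' Define the true ratio surface behind a simulated fish cohort
#'
#' Parameters of a zebrafish cohort generator: the true macrophage
#' infiltration-ratio surface (quadratic, original dose units, must be
#' positive over the tested box), a per-fish multiplicative lognormal
#' noise, lognormal baseline-density parameters, a shared per-batch
#' lognormal factor, and the cohort layout (2-3 independent batches of
#' roughly 10-20 fish per dose group).
#'
#' @param coefficients Named vector over the frozen quadratic terms
#'   (the true ratio surface).
#' @param panel An [agent_panel()].
#' @param sigma_log Per-fish lognormal noise SD on the log scale
#'   (default 0.15).
#' @param n_batches Independent batches (default 3).
#' @param fish_per_group Fish per dose group per batch (default 12).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline area-normalized density (defaults `log(5)`, 0.3).
#' @param batch_sd_log SD of the shared per-batch log factor
#'   (default 0.1).
#' @param baseline_dpf Baseline timepoint, 9 or 12 (default 9).
#' @param context Context label (default `"MASLD-HCC"`).
#' @param seed Integer root seed.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(coefficients, panel, sigma_log = 0.15,
                         n_batches = 3, fish_per_group = 12,
                         baseline_meanlog = log(5), baseline_sdlog = 0.3,
                         batch_sd_log = 0.1, baseline_dpf = 9,
                         context = "MASLD-HCC", seed = 1) {
  if (fish_per_group < 1) .stopf("fish_per_group must be >= 1")
  if (n_batches < 1) .stopf("n_batches must be >= 1")
  if (sigma_log < 0 || batch_sd_log < 0) .stopf("noise SDs must be >= 0")
  if (!baseline_dpf %in% c(9, 12)) .stopf("baseline_dpf must be 9 or 12")
  terms <- .term_names(panel_names(panel))
  co <- stats::setNames(numeric(length(terms)), terms)
  unknown <- setdiff(names(coefficients), terms)
  if (length(unknown)) {
    .stopf("unknown coefficient term(s): %s", paste(unknown, collapse = ", "))
  }
  co[names(coefficients)] <- coefficients
  structure(
    list(coefficients = co, panel = panel, sigma_log = sigma_log,
         n_batches = as.integer(n_batches),
         fish_per_group = as.integer(fish_per_group),
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         batch_sd_log = batch_sd_log,
         baseline_dpf = as.integer(baseline_dpf),
         context = context, seed = as.integer(seed)),
    class = "cohort_truth"
  )
}

#' Generate a fish cohort from a known ratio surface
#'
#' Simulates per-fish baseline and endpoint area-normalized densities:
#' baseline drawn lognormal; endpoint = baseline x true ratio(dose) x
#' per-fish lognormal noise x shared batch factor. Generated ratios are
#' strictly positive by construction. Draws use named substreams per
#' batch; the cohort is a pure function of (truth, seed).
#'
#' @param truth A [cohort_truth()].
#' @param dose_groups Data frame of dose combinations (one row per group),
#'   within the panel box.
#' @return Data frame in the cohort schema accepted by
#'   [ratio_table_to_responses()].
#' @export
generate_fish_cohort <- function(truth, dose_groups) {
  stopifnot(inherits(truth, "cohort_truth"))
  nms <- panel_names(truth$panel)
  dose_groups <- .check_doses(dose_groups, truth$panel, "dose_groups")
  ratio_true <- .quad_eval(truth$coefficients, nms, dose_groups)
  if (any(ratio_true <= 0)) {
    .stopf("true ratio surface must be positive at every dose group")
  }
  n_g <- nrow(dose_groups)
  n_f <- truth$fish_per_group
  pieces <- list()
  fish_counter <- 0L
  for (b in seq_len(truth$n_batches)) {
    s <- substream_seed(truth$seed, truth$context, paste0("batch", b))
    draws <- .with_seed(s, {
      list(batch_factor = exp(stats::rnorm(1, 0, truth$batch_sd_log)),
           baseline = stats::rlnorm(n_g * n_f, truth$baseline_meanlog,
                                    truth$baseline_sdlog),
           noise = exp(stats::rnorm(n_g * n_f, 0, truth$sigma_log)))
    })
    rows <- dose_groups[rep(seq_len(n_g), each = n_f), , drop = FALSE]
    baseline <- draws$baseline
    ratio <- rep(ratio_true, each = n_f) * draws$noise * draws$batch_factor
    rows$fish_id <- sprintf("fish%05d", fish_counter + seq_len(n_g * n_f))
    fish_counter <- fish_counter + n_g * n_f
    rows$context <- truth$context
    rows$batch <- b
    rows$baseline_dpf <- truth$baseline_dpf
    rows$density_baseline <- baseline
    rows$density_15dpf <- baseline * ratio
    pieces[[b]] <- rows
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
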