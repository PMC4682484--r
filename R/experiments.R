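# Config-driven reproduction harness: enumerate geometry grids, compare the
# forward model against Monte Carlo, and summarise microstructure recovery.
# Grids default to the study conditions; Monte Carlo budgets are desk-scale.

#' Experiment configuration
#'
#' @param packing_types Regular packing types to enumerate.
#' @param R_tilde Regular grid of abutting EAS radii (um).
#' @param p Regular grid of fractional separations.
#' @param multipliers Radius-distribution multipliers for random packings.
#' @param phi Area fractions for random packings.
#' @param freq_hz Frequency ladder (Hz); NULL picks ~10 points bracketing
#'   each case's transition band from the forward model.
#' @param n_freq Number of auto-chosen frequencies per case.
#' @param freq_decades Half-width (decades) of the auto-chosen ladder around
#'   the transition band.
#' @param D_free Free diffusivity (um^2/ms).
#' @param b Diffusion weighting(s) (ms/um^2).
#' @param n_walkers,n_steps Monte Carlo budget per frequency.
#' @param n_cylinders Cylinders per random tile.
#' @param seed Base seed.
#' @param dist Base [radius_distribution()].
#' @param outdir Output directory for [run_experiment()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(packing_types = c("square", "hexagonal"),
                              R_tilde = c(0.05, 0.1, 0.5, 1, 5),
                              p = c(1.00, 1.03, 1.06, 1.09, 1.12, 1.25, 1.50, 2.00),
                              multipliers = c(1, 2, 3),
                              phi = c(0.73, 0.6, 0.5, 0.4, 0.3),
                              freq_hz = NULL, n_freq = 10, freq_decades = 1.2,
                              D_free = 2, b = 1,
                              n_walkers = 2000, n_steps = 50000,
                              n_cylinders = 500, seed = 1,
                              dist = radius_distribution(),
                              outdir = NULL) {
  structure(list(packing_types = packing_types, R_tilde = R_tilde, p = p,
                 multipliers = multipliers, phi = phi, freq_hz = freq_hz,
                 n_freq = n_freq, freq_decades = freq_decades,
                 D_free = D_free, b = b,
                 n_walkers = n_walkers, n_steps = n_steps,
                 n_cylinders = n_cylinders, seed = seed, dist = dist,
                 outdir = outdir),
            class = "experiment_config")
}

#' Enumerate experiment cases
#'
#' Cross-product of the regular grids (type x R_tilde x p) and the random
#' grid (multiplier x phi), with stable case identifiers and deterministic
#' ordering.
#'
#' @param cfg An [experiment_config()].
#' @return A tibble with `case_id`, `kind`, and case parameters.
#' @examples
#' nrow(dplyr::filter(enumerate_cases(experiment_config()), kind == "random"))
#' @export
enumerate_cases <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  reg <- tidyr::expand_grid(packing_type = cfg$packing_types,
                            R_tilde = cfg$R_tilde, p = cfg$p)
  reg <- dplyr::mutate(reg, kind = "regular",
                       case_id = sprintf("%s_Rt%g_p%g", .data$packing_type,
                                         .data$R_tilde, .data$p))
  rnd <- tidyr::expand_grid(multiplier = cfg$multipliers, phi = cfg$phi)
  rnd <- dplyr::mutate(rnd, kind = "random",
                       case_id = sprintf("random_x%g_phi%g",
                                         .data$multiplier, .data$phi))
  dplyr::bind_rows(reg, rnd)[, c("case_id", "kind", "packing_type",
                                 "R_tilde", "p", "multiplier", "phi")]
}

# frequency ladder bracketing a case's transition band
.case_frequencies <- function(cfg, packing_type, R_tilde, p) {
  if (!is.null(cfg$freq_hz)) return(sort(cfg$freq_hz))
  R <- switch(packing_type,
              square = R_tilde * sqrt(pi / (4 - pi)),
              hexagonal = R_tilde * sqrt(pi / (2 * sqrt(3) - pi)))
  R0 <- R0_from_geometry(packing_type, max(p, 1 + 1e-9), R)
  f_c <- radms_to_hz(2 * cfg$D_free / R0^2)   # transition band centre
  w <- cfg$freq_decades %||% 1.2
  10^seq(log10(f_c) - w, log10(f_c) + w, length.out = cfg$n_freq)
}

#' Forward model vs Monte Carlo residuals for one case
#'
#' Builds the substrate, predicts the spectrum with the forward model, runs
#' the Monte Carlo ground truth at the configured budget, and tabulates the
#' residuals (model minus data) per frequency.
#'
#' @param case One row of [enumerate_cases()] (or a list with the same
#'   fields; `kind` may also be "free" for the control case).
#' @param cfg An [experiment_config()].
#' @return A tibble with per-frequency model, data, SE, residual and z; the
#'   summary `max |residual| / D_free` is attached as attribute
#'   `"max_resid_frac"`.
#' @export
run_comparison <- function(case, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  mc <- mc_config(cfg$n_walkers, cfg$n_steps, seed = cfg$seed,
                  D_free = cfg$D_free,
                  compartment = if (identical(case$kind, "free")) "free" else "eas")
  if (identical(case$kind, "free")) {
    freqs <- if (is.null(cfg$freq_hz)) 10^seq(1, 4, length.out = cfg$n_freq)
             else sort(cfg$freq_hz)
    spec <- simulate_spectrum(NULL, freqs, mc, b_target = cfg$b[1])
    model <- rep(cfg$D_free, length(freqs))
  } else {
    if (!case$packing_type %in% c("square", "hexagonal"))
      stop("run_comparison requires a regular (or free) case; fit random cases instead")
    pk <- switch(case$packing_type,
                 square = make_square_packing(case$R_tilde, case$p),
                 hexagonal = make_hexagonal_packing(case$R_tilde, case$p))
    freqs <- .case_frequencies(cfg, case$packing_type, case$R_tilde, case$p)
    spec <- simulate_spectrum(pk, freqs, mc, b_target = cfg$b[1])
    model <- forward_predict(pk, spec$frequency_hz, cfg$D_free)$D_um2_per_ms
  }
  out <- tibble::tibble(
    frequency_hz = spec$frequency_hz,
    D_model = model,
    D_mc = spec$D_um2_per_ms,
    se_mc = spec$se_um2_per_ms,
    residual = model - spec$D_um2_per_ms,
    z = (model - spec$D_um2_per_ms) / spec$se_um2_per_ms)
  attr(out, "max_resid_frac") <- max(abs(out$residual)) / cfg$D_free
  out
}

#' Microstructure recovery for one case
#'
#' For a regular case: generate the noiseless forward-model spectrum, fit it
#' by NLS, recover (`R_EAS`, `L`, `p`) and compare with the generating
#' geometry. For a deliberately mis-specified `packing_type` the recovery is
#' flagged by its residual rather than failing silently.
#'
#' @param case One row of [enumerate_cases()].
#' @param cfg An [experiment_config()].
#' @param fit_type Packing type assumed in recovery (defaults to the truth;
#'   set to another type as a negative control).
#' @return A tibble with truth, estimate and relative error per quantity.
#' @export
run_recovery <- function(case, cfg, fit_type = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!case$packing_type %in% c("square", "hexagonal"))
    stop("run_recovery operates on regular cases")
  pk <- switch(case$packing_type,
               square = make_square_packing(case$R_tilde, case$p),
               hexagonal = make_hexagonal_packing(case$R_tilde, case$p))
  rcfg <- cfg
  rcfg$n_freq <- max(cfg$n_freq, 9)   # noiseless fits are cheap; keep them well posed
  freqs <- .case_frequencies(rcfg, case$packing_type, case$R_tilde, case$p)
  dat <- forward_predict(pk, freqs, cfg$D_free)
  names(dat)[2] <- "D_um2_per_ms"
  fit <- fit_nls(dat, "single", D_free = cfg$D_free)
  type_used <- if (is.null(fit_type)) case$packing_type else fit_type
  rec <- recover_microstructure(fit$params, type_used)
  tru <- c(pk$p, pk$radii[1], pk$L,
           pore_radius_regular(case$packing_type, pk$p, pk$radii[1]))
  est <- as.numeric(rec[1, ])
  tibble::tibble(
    case_id = case$case_id,
    fit_type = type_used,
    quantity = c("p", "R", "L", "R_EAS"),
    truth = tru,
    estimate = est,
    rel_error = (est - tru) / tru,
    fit_sse = fit$sse)
}

#' Run an experiment grid and write outputs
#'
#' Enumerates the configured cases, runs comparisons (regular cases) and
#' recoveries, and writes per-case CSVs plus a JSON manifest (config, seeds,
#' package version, config hash) sufficient to reproduce the outputs
#' byte-identically.
#'
#' @param cfg An [experiment_config()] with `outdir` set.
#' @param cases Optional subset of [enumerate_cases()] rows.
#' @param what Any of "comparison", "recovery".
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(cfg, cases = NULL, what = c("comparison", "recovery")) {
  stopifnot(inherits(cfg, "experiment_config"), !is.null(cfg$outdir))
  what <- match.arg(what, several.ok = TRUE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cases)) cases <- enumerate_cases(cfg)
  reg <- dplyr::filter(cases, .data$kind == "regular")
  outputs <- character(0)
  for (i in seq_len(nrow(reg))) {
    case <- as.list(reg[i, ])
    if ("comparison" %in% what) {
      cmp <- run_comparison(case, cfg)
      f <- file.path(cfg$outdir, paste0(case$case_id, "_residuals.csv"))
      utils::write.csv(cmp, f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
    if ("recovery" %in% what) {
      rec <- run_recovery(case, cfg)
      f <- file.path(cfg$outdir, paste0(case$case_id, "_recovery.csv"))
      utils::write.csv(rec, f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$dist <- unclass(cfg_plain$dist)
  cfg_plain$outdir <- NULL     # hash the scientific config, not the destination
  manifest <- list(
    package = "easpec",
    version = as.character(utils::packageVersion("easpec")),
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    seed = cfg$seed,
    n_cases = nrow(reg),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read an experiment config from YAML
#'
#' @param path YAML file whose top-level keys match [experiment_config()]
#'   arguments (`dist` given as a list with shape/scale/multiplier).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$dist)) y$dist <- do.call(radius_distribution, y$dist)
  do.call(experiment_config, y)
}
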