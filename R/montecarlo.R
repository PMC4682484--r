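# Monte Carlo ground truth: 2D fixed-step random walks with specular
# reflection in periodic substrates, OGSE phase encoding, and conversion of
# signal attenuation to diffusion-spectrum points. The walk is 2D because the
# cylinders are parallel and gradients are applied perpendicular to their
# axes; the axial coordinate decouples exactly.

#' Monte Carlo configuration
#'
#' @param n_walkers Number of walkers.
#' @param n_steps Step budget per frequency (cap on the number of time steps;
#'   the walk warns when honouring it forces steps longer than a tenth of the
#'   narrowest inter-cylinder gap, which biases D downward).
#' @param seed Integer seed.
#' @param D_free Free diffusivity (um^2/ms).
#' @param compartment "eas", "intracylinder" or "free".
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_walkers = 2000, n_steps = 50000, seed = 1,
                      D_free = 2, compartment = c("eas", "intracylinder", "free")) {
  compartment <- match.arg(compartment)
  stopifnot(n_walkers >= 1, n_steps >= 1, D_free > 0)
  structure(list(n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps),
                 seed = as.integer(seed), D_free = D_free,
                 compartment = compartment),
            class = "mc_config")
}

# initial walker positions by rejection sampling in the stated compartment
.init_walkers <- function(packing, cfg) {
  nw <- cfg$n_walkers
  if (cfg$compartment == "free" || is.null(packing)) {
    return(list(x = rep(0, nw), y = rep(0, nw)))
  }
  W <- packing$tile[1]; H <- packing$tile[2]
  if (cfg$compartment == "intracylinder") {
    R <- packing$radii[1]
    r <- R * sqrt(runif(nw)); th <- runif(nw, 0, 2 * pi)
    return(list(x = r * cos(th), y = r * sin(th)))
  }
  xs <- numeric(0); ys <- numeric(0)
  cx <- packing$centers[, 1]; cy <- packing$centers[, 2]; rr <- packing$radii
  while (length(xs) < nw) {
    m <- 2 * (nw - length(xs)) + 16
    x <- runif(m, 0, W); y <- runif(m, 0, H)
    inside <- rep(FALSE, m)
    for (i in seq_along(rr)) {
      dx <- abs(x - cx[i]); dx <- pmin(dx, W - dx)
      dy <- abs(y - cy[i]); dy <- pmin(dy, H - dy)
      inside <- inside | (dx^2 + dy^2 < rr[i]^2)
    }
    xs <- c(xs, x[!inside]); ys <- c(ys, y[!inside])
  }
  list(x = xs[seq_len(nw)], y = ys[seq_len(nw)])
}

# low-level engine dispatch for a gradient matrix sampled at dt
.run_engine <- function(packing, cfg, gmat, dt, record_every = 0L) {
  step <- sqrt(4 * cfg$D_free * dt)
  if (cfg$compartment == "free" || is.null(packing)) {
    init <- .init_walkers(NULL, cfg)
    res <- .mc_walk_cpp(matrix(numeric(0), 0, 2), numeric(0),
                        1e9, 1e9, TRUE, FALSE, init$x, init$y,
                        step, nrow(gmat), gmat, dt, as.integer(record_every))
  } else if (cfg$compartment == "intracylinder") {
    R <- packing$radii[1]
    box <- 2.5 * R + 10 * step
    init <- .init_walkers(packing, cfg)
    init$x <- init$x + box / 2; init$y <- init$y + box / 2
    centers <- matrix(c(box / 2, box / 2), ncol = 2)
    res <- .mc_walk_cpp(centers, R, box, box, FALSE, TRUE,
                        init$x, init$y,
                        step, nrow(gmat), gmat, dt, as.integer(record_every))
  } else {
    init <- .init_walkers(packing, cfg)
    res <- .mc_walk_cpp(packing$centers, packing$radii,
                        packing$tile[1], packing$tile[2], TRUE, FALSE,
                        init$x, init$y, step, nrow(gmat), gmat, dt,
                        as.integer(record_every))
  }
  res$x0 <- init$x; res$y0 <- init$y
  res
}

#' Run a random walk in a substrate
#'
#' Runs the fixed-step random walk without gradients, returning net
#' displacements and (optionally) periodic position snapshots. Useful for
#' Einstein-relation and confinement checks.
#'
#' @param packing A `cylinder_packing`, or NULL for free diffusion.
#' @param cfg An [mc_config()].
#' @param duration_ms Walk duration.
#' @param dt_ms Time step.
#' @param record_every Record wrapped positions every this many steps (0 = off).
#' @return A list with `disp_x`, `disp_y` (net unwrapped displacements, um),
#'   `duration`, `dt`, and optionally `rec_x`, `rec_y` (walkers x snapshots).
#' @export
run_walk <- function(packing, cfg, duration_ms, dt_ms, record_every = 0) {
  set.seed(cfg$seed)
  nsteps <- max(1L, as.integer(round(duration_ms / dt_ms)))
  gmat <- matrix(0, nsteps, 1)
  res <- .run_engine(packing, cfg, gmat, dt_ms, record_every)
  out <- list(disp_x = res$x_final - res$x0, disp_y = res$y_final - res$y0,
              duration = nsteps * dt_ms, dt = dt_ms, nsteps = nsteps)
  if (record_every > 0) { out$rec_x <- res$rec_x; out$rec_y <- res$rec_y }
  out
}

#' Simulate OGSE signal attenuation in a substrate
#'
#' Runs the random walk under one or more gradient waveforms (which must
#' share duration and time step) and accumulates per-walker phases
#' `phi = sum g(t_i) x(t_i) dt` along the gradient axis. The attenuation is
#' `E = <cos phi>` (the mean phase vanishes by symmetry, and the cosine
#' average is unbiased with lower variance than `|<exp(i phi)>|`).
#'
#' @param packing A `cylinder_packing` (or NULL with compartment "free").
#' @param waveform A `gradient_waveform` or list of them (equal dt/length).
#' @param cfg An [mc_config()].
#' @return A tibble with one row per waveform: `f0_hz`, `b`, `E`, `se_E`,
#'   `D_um2_per_ms`, `se_um2_per_ms`.
#' @export
simulate_signal <- function(packing, waveform, cfg) {
  if (inherits(waveform, "gradient_waveform")) waveform <- list(waveform)
  dts <- vapply(waveform, `[[`, numeric(1), "dt")
  ns <- vapply(waveform, function(w) length(w$samples), integer(1))
  if (length(unique(signif(dts, 12))) != 1 || length(unique(ns)) != 1)
    stop("all waveforms must share time step and duration")
  gmat <- do.call(cbind, lapply(waveform, `[[`, "samples"))
  set.seed(cfg$seed)
  res <- .run_engine(packing, cfg, gmat, dts[1])
  purrr::map_dfr(seq_along(waveform), function(k) {
    cphi <- cos(res$phase[, k])
    E <- mean(cphi); se <- sd(cphi) / sqrt(length(cphi))
    b <- waveform[[k]]$b
    tibble::tibble(f0_hz = waveform[[k]]$f0_hz, b = b, E = E, se_E = se,
                   D_um2_per_ms = -log(E) / b,
                   se_um2_per_ms = se / (E * b))
  })
}

#' Convert signal attenuation to a diffusion-spectrum point
#'
#' `D = -log(E) / b`, with standard error `se_E / (E b)`.
#'
#' @param E Attenuation in (0, 1].
#' @param b Diffusion weighting (ms/um^2), > 0.
#' @param se_E Optional standard error of E.
#' @return A tibble with `D_um2_per_ms` and `se_um2_per_ms` (NA without `se_E`).
#' @export
signal_to_D <- function(E, b, se_E = NULL) {
  if (any(E <= 0) || any(E > 1 + 1e-12)) stop("E must be in (0, 1]")
  if (any(b <= 0)) stop("b must be positive")
  tibble::tibble(D_um2_per_ms = -log(E) / b,
                 se_um2_per_ms = if (is.null(se_E)) NA_real_ else se_E / (E * b))
}

# choose duration/dt for one frequency under the two-regime rule
.plan_frequency <- function(f_hz, cfg, packing, n_periods, f_split_hz,
                            max_duration_low, max_duration_high,
                            gap_fraction, oversample) {
  f0 <- f_hz / 1000
  cap <- if (f_hz < f_split_hz) max_duration_low else max_duration_high
  n_per <- max(1L, floor(min(cap, n_periods / f0) * f0))
  duration <- n_per / f0
  dt_wave <- 1 / (f0 * oversample)
  dt_step <- Inf
  if (!is.null(packing) && cfg$compartment != "free") {
    lim <- if (cfg$compartment == "intracylinder") packing$radii[1]
           else max(min_gap(packing), 1e-3 * min(packing$radii))
    dt_step <- (gap_fraction * lim)^2 / (4 * cfg$D_free)
    # the step must also resolve the high-frequency boundary layer
    # sqrt(D/omega): keep step length below a quarter of it
    dt_step <- min(dt_step, 0.25^2 / (4 * 2 * pi * f0))
  }
  dt <- min(dt_wave, dt_step)
  npp <- 4 * ceiling(1 / (f0 * dt) / 4)
  nsteps <- n_per * npp
  warned <- FALSE
  if (nsteps > cfg$n_steps) {
    npp_max <- max(8L, 4L * floor(cfg$n_steps / n_per / 4))
    while (n_per > 1 && npp_max < oversample) {
      n_per <- ceiling(n_per / 2)
      npp_max <- max(8L, 4L * floor(cfg$n_steps / n_per / 4))
    }
    npp <- npp_max
    nsteps <- n_per * npp
    step_len <- sqrt(4 * cfg$D_free / (f0 * npp))
    if (is.finite(dt_step) && 1 / (f0 * npp) > dt_step) {
      warning(sprintf(
        "step budget forces walker displacement %.3g um above a tenth of the narrowest gap at %g Hz; D may be underestimated",
        step_len, f_hz))
      warned <- TRUE
    }
  }
  duration <- n_per / f0
  list(n_periods = n_per, duration = duration, npp = npp, warned = warned)
}

#' Simulate a diffusion spectrum by Monte Carlo
#'
#' One synthesize -> walk -> signal -> convert pass per frequency. Waveform
#' durations follow a two-regime rule (longer sampling at low frequency,
#' capped at `max_duration_low` ms below `f_split_hz` and at
#' `max_duration_high` ms above), and the time step honours both the waveform
#' resolution and the walker-displacement rule (step length at most
#' `gap_fraction` of the narrowest inter-cylinder gap), within the step
#' budget of `cfg`.
#'
#' @param packing A `cylinder_packing` (or NULL with compartment "free").
#' @param freq_hz Frequencies to sample (Hz).
#' @param cfg An [mc_config()].
#' @param b_target Diffusion weighting (ms/um^2).
#' @param n_periods Target number of gradient periods per waveform.
#' @param f_split_hz Boundary between the long- and short-duration regimes.
#' @param max_duration_low,max_duration_high Duration caps (ms).
#' @param gap_fraction Maximal step length as a fraction of the gap.
#' @param oversample Waveform samples per period.
#' @return A tibble `frequency_hz`, `D_um2_per_ms`, `se_um2_per_ms`, sorted
#'   by frequency, with a `detail` attribute (per-frequency b, duration, dt,
#'   steps, E).
#' @export
simulate_spectrum <- function(packing, freq_hz, cfg, b_target = 1,
                              n_periods = 8, f_split_hz = 10000,
                              max_duration_low = 50, max_duration_high = 2,
                              gap_fraction = 0.1, oversample = 32) {
  freq_hz <- sort(freq_hz)
  set.seed(cfg$seed)
  rows <- vector("list", length(freq_hz))
  for (i in seq_along(freq_hz)) {
    f <- freq_hz[i]
    plan <- .plan_frequency(f, cfg, packing, n_periods, f_split_hz,
                            max_duration_low, max_duration_high,
                            gap_fraction, oversample)
    wf <- synthesize_apodized_cosine(f, plan$duration, b_target,
                                     samples_per_period = plan$npp)
    gmat <- matrix(wf$samples, ncol = 1)
    res <- .run_engine(packing, cfg, gmat, wf$dt)
    cphi <- cos(res$phase[, 1])
    E <- mean(cphi); se <- sd(cphi) / sqrt(length(cphi))
    rows[[i]] <- tibble::tibble(
      frequency_hz = f,
      D_um2_per_ms = -log(E) / wf$b,
      se_um2_per_ms = se / (E * wf$b),
      b = wf$b, duration = wf$duration, dt = wf$dt,
      n_steps = length(wf$samples), E = E, se_E = se)
  }
  detail <- dplyr::bind_rows(rows)
  out <- detail[, c("frequency_hz", "D_um2_per_ms", "se_um2_per_ms")]
  attr(out, "detail") <- detail
  attr(out, "config") <- cfg
  out
}
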