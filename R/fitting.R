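# Estimation of exchange-model parameters from D(omega) samples:
# bounded nonlinear least squares followed by random-walk Metropolis-Hastings
# initialised at the NLS point. D_free is fixed at its known value.

.spectrum_check <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency_hz", "D_um2_per_ms") %in% names(spectrum)))
  if (nrow(spectrum) < 5)
    stop("need at least 5 spectrum points")
  f <- spectrum$frequency_hz
  if (any(diff(order(f)) < 0) || any(f <= 0)) stop("frequencies must be positive")
  if (log10(max(f) / min(f)) < 2)
    warning("spectrum spans less than two decades of frequency; fits may be poorly conditioned")
  spectrum[order(f), ]
}

# model curves parameterised for fitting; theta on the unconstrained-ish
# bounded scale used by nls.lm / MH
.model_curve_single <- function(theta, omega, D_free) {
  # theta = (lambda, R0, rho) with Rinf = rho * R0
  eas_spectrum(eas_params(D_free, theta[1], theta[2],
                          max(1e-12, theta[3]) * theta[2]), omega)
}

.model_curve_dist <- function(theta, omega, D_free, b_ref, n_nodes = 128) {
  # theta = (lambda, R0_mean, cv, Rinf) with R0_sd = cv * R0_mean
  eas_spectrum_dist(eas_params_dist(D_free, theta[1], theta[2],
                                    theta[3] * theta[2],
                                    theta[4], b_ref), omega, n_nodes)
}

.fit_bounds <- function(model) {
  if (model == "single")
    list(lower = c(1, 1e-4, 1e-4), upper = c(50, 100, 1))
  else
    list(lower = c(1, 1e-4, 1e-3, 1e-4), upper = c(50, 100, 2, 100))
}

#' Nonlinear least-squares fit of the exchange model
#'
#' Fits the single-radius model (`lambda`, `R0`, `Rinf`) or the
#' distribution model (`lambda`, `R0` mean and sd, `Rinf`) to a measured
#' diffusion spectrum by bounded Levenberg-Marquardt. The tortuosity is
#' initialised from the lowest-frequency sample as
#' `sqrt(D_free / D(omega_min))`; the radii start from small nominal values
#' (10 nm and 1 nm for the single model; 1 um, 10 nm and 500 nm for the
#' distribution model) plus a data-driven alternative start at the observed
#' transition frequency, keeping whichever converges to the lower residual.
#'
#' @param spectrum Tibble/data frame with `frequency_hz`, `D_um2_per_ms` and
#'   optionally `se_um2_per_ms` (inverse-variance weights).
#' @param model "single" or "distribution".
#' @param D_free Free diffusivity (um^2/ms), fixed during fitting.
#' @param init Optional named list overriding initial values
#'   (`lambda`, `R0`, `Rinf`, `R0_mean`, `R0_sd`).
#' @param b_ref Reference diffusion weighting for the distribution model.
#' @return An object of class `eas_fit_nls`: parameter object (`params`),
#'   `theta`, `sse`, `converged`, `residuals`, `model`, plus fit metadata.
#' @export
fit_nls <- function(spectrum, model = c("single", "distribution"),
                    D_free = 2, init = NULL, b_ref = 1) {
  model <- match.arg(model)
  spectrum <- .spectrum_check(spectrum)
  omega <- hz_to_radms(spectrum$frequency_hz)
  D <- spectrum$D_um2_per_ms
  w <- rep(1, length(D))
  if ("se_um2_per_ms" %in% names(spectrum) &&
      all(is.finite(spectrum$se_um2_per_ms)) &&
      all(spectrum$se_um2_per_ms > 0))
    w <- 1 / spectrum$se_um2_per_ms

  lambda0 <- sqrt(D_free / max(D[1], 1e-6 * D_free))
  lambda0 <- min(max(lambda0, 1 + 1e-6), 49)
  # data-driven radius scale: free displacement at the transition frequency
  Dmid <- (min(D) + max(D)) / 2
  imid <- which.min(abs(D - Dmid))
  R_trans <- sqrt(2 * D_free / max(omega[imid], 1e-9))

  starts <- if (model == "single") {
    c(list(c(lambda0, 0.01, 0.1)),
      lapply(as.list(tidyr::expand_grid(s = c(0.3, 1, 3), r = c(0.2, 0.7)) |>
                       purrr::transpose()),
             function(g) c(lambda0, g$s * R_trans, g$r)))
  } else {
    # seed the distribution model from the (robust) single-radius fit
    single <- tryCatch(fit_nls(spectrum, "single", D_free = D_free),
                       error = function(e) NULL)
    extra <- list()
    if (!is.null(single)) {
      s0 <- single$params
      extra <- lapply(c(0.05, 0.3, 0.6), function(cv)
        c(s0$lambda, s0$R0, cv, min(s0$Rinf, s0$R0)))
    }
    c(extra,
      list(c(lambda0, 1, 0.01, 0.5)),
      lapply(as.list(tidyr::expand_grid(s = c(0.5, 1.5), cv = c(0.1, 0.5)) |>
                       purrr::transpose()),
             function(g) c(lambda0, g$s * R_trans, g$cv, 0.4 * g$s * R_trans)))
  }
  if (!is.null(init)) {
    ov <- function(s) {
      if (!is.null(init$lambda)) s[1] <- init$lambda
      if (model == "single") {
        if (!is.null(init$R0)) s[2] <- init$R0
        if (!is.null(init$Rinf)) s[3] <- init$Rinf / s[2]
      } else {
        if (!is.null(init$R0_mean)) s[2] <- init$R0_mean
        if (!is.null(init$R0_sd)) s[3] <- init$R0_sd / s[2]
        if (!is.null(init$Rinf)) s[4] <- init$Rinf
      }
      s
    }
    starts <- c(list(ov(starts[[1]])), starts)
  }

  bounds <- .fit_bounds(model)
  resid_fn <- function(theta) {
    m <- if (model == "single") .model_curve_single(theta, omega, D_free)
         else .model_curve_dist(theta, omega, D_free, b_ref)
    w * (m - D)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse, start = s)
  }
  if (is.null(best)) stop("nonlinear least squares failed from every start")
  th <- best$fit$par
  converged <- best$fit$info %in% 1:4
  params <- if (model == "single") {
    eas_params(D_free, th[1], th[2], max(1e-12, th[3]) * th[2])
  } else {
    eas_params_dist(D_free, th[1], th[2], th[3] * th[2], th[4], b_ref)
  }
  structure(list(params = params, theta = th, model = model,
                 sse = best$sse, converged = converged,
                 info = best$fit$info, message = best$fit$message,
                 residuals = best$fit$fvec / w,
                 spectrum = spectrum, D_free = D_free, b_ref = b_ref,
                 weights = w),
            class = "eas_fit_nls")
}

#' @export
print.eas_fit_nls <- function(x, ...) {
  cat(sprintf("<eas_fit_nls> %s model, sse = %.4g, converged: %s\n",
              x$model, x$sse, x$converged))
  print(x$params)
  invisible(x)
}

#' Metropolis-Hastings fit of the exchange model
#'
#' Random-walk Metropolis-Hastings over the model parameters with a Gaussian
#' likelihood (per-point standard errors when available, otherwise a pooled
#' residual variance with a small floor) and independent uniform priors on
#' generous positive ranges. Proposal widths adapt toward ~25% acceptance
#' during burn-in and are then frozen. Seeded and reproducible.
#'
#' @inheritParams fit_nls
#' @param nls_init An `eas_fit_nls` from [fit_nls()] (computed if NULL).
#' @param n_burn,n_keep Burn-in and retained draws.
#' @param seed Integer seed.
#' @return An object of class `eas_fit`: `point` (posterior-mean parameter
#'   object), `posterior_mean`, `posterior_sd`, `samples` (draws x params),
#'   `acceptance_rate`, `converged` and a diagnostic message.
#' @export
fit_mh <- function(spectrum, model = c("single", "distribution"),
                   D_free = 2, nls_init = NULL, n_burn = 5000, n_keep = 20000,
                   seed = 1, b_ref = 1) {
  model <- match.arg(model)
  spectrum <- .spectrum_check(spectrum)
  if (is.null(nls_init))
    nls_init <- fit_nls(spectrum, model, D_free = D_free, b_ref = b_ref)
  omega <- hz_to_radms(spectrum$frequency_hz)
  D <- spectrum$D_um2_per_ms
  n <- length(D)
  sigma <- if ("se_um2_per_ms" %in% names(spectrum) &&
               all(is.finite(spectrum$se_um2_per_ms)) &&
               all(spectrum$se_um2_per_ms > 0)) {
    spectrum$se_um2_per_ms
  } else {
    rep(max(sqrt(mean(nls_init$residuals^2)), 1e-6 * D_free), n)
  }
  bounds <- .fit_bounds(model)
  curve <- function(theta) {
    if (model == "single") .model_curve_single(theta, omega, D_free)
    else .model_curve_dist(theta, omega, D_free, b_ref)
  }
  loglik <- function(theta) {
    if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
    -0.5 * sum(((curve(theta) - D) / sigma)^2)
  }

  set.seed(seed)
  theta <- nls_init$theta
  np <- length(theta)
  # curvature-scaled initial proposals: sd ~ Laplace-approximation scale
  J <- matrix(0, n, np)
  f0 <- curve(theta)
  for (k in seq_len(np)) {
    h <- pmax(abs(theta[k]), 1e-4) * 1e-5
    tk <- theta; tk[k] <- tk[k] + h
    J[, k] <- (curve(tk) - f0) / h
  }
  A <- crossprod(J / sigma)
  prop_sd <- tryCatch(2.4 / sqrt(np) * sqrt(diag(solve(A + diag(1e-12, np)))),
                      error = function(e) pmax(abs(theta) * 0.05, 1e-6))
  prop_sd[!is.finite(prop_sd)] <- pmax(abs(theta[!is.finite(prop_sd)]) * 0.05, 1e-6)
  ll <- loglik(theta)
  keep <- matrix(NA_real_, n_keep, np)
  acc_window <- 0L; acc_total <- 0L
  for (i in seq_len(n_burn + n_keep)) {
    cand <- theta + rnorm(np, 0, prop_sd)
    llc <- loglik(cand)
    if (log(runif(1)) < llc - ll) {
      theta <- cand; ll <- llc
      acc_window <- acc_window + 1L
      if (i > n_burn) acc_total <- acc_total + 1L
    }
    if (i <= n_burn && i %% 200 == 0) {
      rate <- acc_window / 200
      # strong correction far from the 25% target, gentle near it
      prop_sd <- prop_sd *
        if (rate < 0.05) 0.3 else if (rate > 0.6) 2.5 else exp(rate - 0.25)
      acc_window <- 0L
    }
    if (i > n_burn) keep[i - n_burn, ] <- theta
  }
  acc_rate <- acc_total / n_keep

  post_mean <- colMeans(keep)
  post_sd <- apply(keep, 2, sd)
  nm <- if (model == "single") c("lambda", "R0", "rho")
        else c("lambda", "R0_mean", "R0_cv", "Rinf")
  colnames(keep) <- nm
  names(post_mean) <- nm; names(post_sd) <- nm
  point <- if (model == "single") {
    eas_params(D_free, post_mean[1], post_mean[2],
               max(1e-12, post_mean[3]) * post_mean[2])
  } else {
    eas_params_dist(D_free, post_mean[1], post_mean[2],
                    post_mean[3] * post_mean[2], post_mean[4], b_ref)
  }
  ok <- acc_rate >= 0.05 && acc_rate <= 0.8
  diag_msg <- if (ok) "acceptance rate within [0.05, 0.8]"
              else sprintf("acceptance rate %.3f outside [0.05, 0.8] after adaptation", acc_rate)
  if (!ok) warning(diag_msg)
  structure(list(point = point, posterior_mean = post_mean,
                 posterior_sd = post_sd, samples = keep,
                 acceptance_rate = acc_rate, converged = ok,
                 diagnostic = diag_msg, model = model,
                 nls_init = nls_init, D_free = D_free, b_ref = b_ref,
                 seed = seed, spectrum = spectrum),
            class = "eas_fit")
}

#' @export
print.eas_fit <- function(x, ...) {
  cat(sprintf("<eas_fit> %s model, %d draws, acceptance %.2f (%s)\n",
              x$model, nrow(x$samples), x$acceptance_rate,
              if (x$converged) "ok" else "check"))
  s <- rbind(mean = x$posterior_mean, sd = x$posterior_sd)
  print(round(s, 6))
  invisible(x)
}

#' Microstructure from fitted model parameters
#'
#' Translates fitted (`lambda`, `R0`, `Rinf`) into geometric descriptors of a
#' regular packing: the fractional separation `p` by numerically inverting
#' the lattice tortuosity, the cylinder radius `R` by weighted least squares
#' on the two linear-in-R radius relations, then the separation `L = 2 R p`
#' and the effective pore radius `R_EAS` at that geometry.
#'
#' @param params An [eas_params()] (or an `eas_fit`/`eas_fit_nls` object).
#' @param packing_type "square" or "hexagonal".
#' @return A tibble with `p`, `R`, `L`, `R_EAS` (um where applicable).
#' @export
recover_microstructure <- function(params, packing_type) {
  if (inherits(params, "eas_fit")) params <- params$point
  if (inherits(params, "eas_fit_nls")) params <- params$params
  stopifnot(inherits(params, "eas_params"))
  packing_type <- match.arg(packing_type, c("square", "hexagonal"))
  p <- p_from_tortuosity(packing_type, params$lambda)
  a <- R0_from_geometry(packing_type, p, 1)
  b <- Rinf_from_geometry(packing_type, p, 1)
  R <- (a * params$R0 + b * params$Rinf) / (a^2 + b^2)
  tibble::tibble(p = p, R = R, L = 2 * R * p,
                 R_EAS = pore_radius_regular(packing_type, p, R))
}

#' Compare a fitted R0 distribution with a pore segmentation
#'
#' Volume-weighted mean and standard deviation of the fitted gamma R0
#' distribution (weighting by pore volume ~ R0^2 turns gamma(k, s) into
#' gamma(k + 2, s)) against the area-weighted R_EAS distribution of a
#' [segment_pores()] result, with difference statistics.
#'
#' @param fit An `eas_fit` or `eas_fit_nls` with `model = "distribution"`,
#'   or an `eas_params_dist`.
#' @param seg A `pore_segmentation`.
#' @return A one-row tibble with fitted and segmented means/sds and their
#'   differences (absolute and relative to the segmented values).
#' @export
compare_r0_distribution <- function(fit, seg) {
  if (inherits(fit, "eas_fit")) fit <- fit$point
  if (inherits(fit, "eas_fit_nls")) fit <- fit$params
  stopifnot(inherits(fit, "eas_params_dist"), inherits(seg, "pore_segmentation"))
  shape <- (fit$R0_mean / fit$R0_sd)^2
  scale <- fit$R0_sd^2 / fit$R0_mean
  fit_mean <- (shape + 2) * scale
  fit_sd <- sqrt(shape + 2) * scale
  seg_mean <- .wmean(seg$pores$R_EAS, seg$pores$weight)
  seg_sd <- sqrt(.wvar(seg$pores$R_EAS, seg$pores$weight))
  tibble::tibble(
    fit_mean = fit_mean, fit_sd = fit_sd,
    seg_mean = seg_mean, seg_sd = seg_sd,
    mean_diff = fit_mean - seg_mean,
    sd_diff = fit_sd - seg_sd,
    mean_rel_diff = (fit_mean - seg_mean) / seg_mean)
}
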