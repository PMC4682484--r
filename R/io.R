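# Plain-text interchange: substrate JSON and spectrum CSV.

#' Write / read a substrate as JSON
#'
#' The substrate file stores the packing type, tile, centres, radii and
#' descriptors (`phi`, `phi_max`, `p`), plus the seed and radius distribution
#' for random packings.
#'
#' @param packing A `cylinder_packing`.
#' @param path Output path.
#' @return `write_substrate()`: the path, invisibly. `read_substrate()`: a
#'   `cylinder_packing`.
#' @export
write_substrate <- function(packing, path) {
  stopifnot(inherits(packing, "cylinder_packing"))
  obj <- list(packing_type = packing$packing_type,
              tile = packing$tile,
              centers = unname(apply(packing$centers, 1, c, simplify = FALSE)),
              radii = packing$radii,
              phi = packing$phi, phi_max = packing$phi_max, p = packing$p,
              L = packing$L, R_tilde = packing$R_tilde,
              seed = packing$seed,
              dist = if (!is.null(packing$dist)) unclass(packing$dist))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_substrate
#' @export
read_substrate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dist <- if (!is.null(obj$dist)) do.call(radius_distribution, as.list(obj$dist))
  centers <- if (is.matrix(obj$centers)) obj$centers
             else matrix(unlist(obj$centers), ncol = 2, byrow = TRUE)
  pk <- new_cylinder_packing(obj$packing_type,
                             centers,
                             obj$radii, obj$tile,
                             L = obj$L %||% NA_real_,
                             R_tilde = obj$R_tilde %||% NA_real_,
                             phi_max = obj$phi_max,
                             seed = obj$seed %||% NA_integer_,
                             dist = dist)
  pk
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read diffusion-spectrum samples as CSV
#'
#' Columns `frequency_hz`, `D_um2_per_ms` and optionally `se_um2_per_ms`;
#' header row mandatory.
#'
#' @param spectrum Tibble with the columns above.
#' @param path File path.
#' @return `write_spectrum()`: the path, invisibly; `read_spectrum()`: a
#'   validated tibble sorted by frequency.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(all(c("frequency_hz", "D_um2_per_ms") %in% names(spectrum)))
  cols <- intersect(c("frequency_hz", "D_um2_per_ms", "se_um2_per_ms"),
                    names(spectrum))
  utils::write.csv(spectrum[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frequency_hz", "D_um2_per_ms") %in% names(df)))
    stop("spectrum CSV must have columns frequency_hz, D_um2_per_ms")
  df <- df[order(df$frequency_hz), ]
  if (any(df$frequency_hz <= 0)) stop("frequencies must be positive")
  if (any(diff(df$frequency_hz) <= 0)) stop("frequencies must be strictly increasing")
  tibble::as_tibble(df)
}
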