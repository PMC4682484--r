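# Segmentation of the extra-cylinder space into pores.
#
# The EAS is rasterised, the distance-to-nearest-wall field is computed
# exactly at pixel centres, and a periodic watershed of that field partitions
# the space into basins separated by ridges running through the throats
# between cylinders. Adjacent basins are merged when the throat between them
# is wide relative to the pores it joins, so a wide opening does not split
# one physical pore in two.

#' Segment the EAS of a substrate into pores
#'
#' Partitions the extra-cylinder space of a periodic substrate into pores and
#' summarises each pore by its area, effective radius `R_EAS` (mean
#' centre-to-wall distance by angular quadrature about the pore's deepest
#' point) and area-proportional volume weight.
#'
#' Pixelised pore areas are rescaled by a common factor so that they sum
#' exactly to the analytic EAS area of the tile. Pores smaller than
#' `min_area_frac` of the EAS are merged into their best-connected neighbour
#' and counted in `n_degenerate_merged`.
#'
#' @param packing A `cylinder_packing` (any type; intended for random).
#' @param resolution Raster size along the longer tile edge.
#' @param merge_ratio Merge two basins when the throat saddle radius is at
#'   least this fraction of the smaller basin's peak radius.
#' @param min_area_frac Degenerate-pore threshold as a fraction of EAS area.
#' @param n_rays Angular quadrature rays for R_EAS.
#' @return An object of class `pore_segmentation`: list with `pores`
#'   (tibble: area, R_EAS, weight), `total_eas_area`, and diagnostics.
#' @export
segment_pores <- function(packing, resolution = 768, merge_ratio = 0.75,
                          min_area_frac = 1e-4, n_rays = 4096) {
  stopifnot(inherits(packing, "cylinder_packing"))
  W <- packing$tile[1]; H <- packing$tile[2]
  nx <- as.integer(round(resolution * W / max(W, H)))
  ny <- as.integer(round(resolution * H / max(W, H)))
  nx <- max(nx, 16L); ny <- max(ny, 16L)
  dist <- .dist_to_walls_cpp(nx, ny, W, H, packing$centers, packing$radii)
  mask <- dist > 0
  ws <- .watershed_cpp(dist, mask, nx, ny)
  label <- ws$label
  nlab <- length(ws$peak)

  # union-find merge of basins across wide throats
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  peaks <- ws$peak
  if (length(ws$ridge_a)) {
    ord <- order(ws$ridge_saddle, decreasing = TRUE)
    for (k in ord) {
      a <- find(ws$ridge_a[k]); b <- find(ws$ridge_b[k])
      if (a == b) next
      if (ws$ridge_saddle[k] >= merge_ratio * min(peaks[a], peaks[b])) {
        parent[b] <- a
        peaks[a] <- max(peaks[a], peaks[b])
      }
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  label[mask] <- root[label[mask]]

  px_area <- (W / nx) * (H / ny)
  counts <- table(factor(label[mask], levels = sort(unique(root))))
  ids <- as.integer(names(counts))
  areas_px <- as.numeric(counts) * px_area
  eas_area <- prod(packing$tile) - sum(pi * packing$radii^2)
  areas <- areas_px * eas_area / sum(areas_px)

  # fold degenerate pores into their strongest-connected neighbour
  n_degenerate <- 0L
  if (length(ids) > 1) {
    repeat {
      small <- which(areas < min_area_frac * eas_area)
      if (!length(small)) break
      k <- small[which.min(areas[small])]
      # neighbour with the highest saddle to pore k
      ra <- root[ws$ridge_a]; rb <- root[ws$ridge_b]
      touch <- which((ra == ids[k] & rb != ids[k]) | (rb == ids[k] & ra != ids[k]))
      if (!length(touch)) break
      j <- touch[which.max(ws$ridge_saddle[touch])]
      other <- if (ra[j] == ids[k]) rb[j] else ra[j]
      oi <- match(other, ids)
      areas[oi] <- areas[oi] + areas[k]
      label[label == ids[k]] <- ids[oi]
      root[root == ids[k]] <- ids[oi]
      ids <- ids[-k]; areas <- areas[-k]
      n_degenerate <- n_degenerate + 1L
    }
  }

  # deepest point (Chebyshev centre) of each pore and its R_EAS, with rays
  # capped where they leave the pore's basin (the straight throat boundaries)
  xs <- ((seq_len(nx)) - 0.5) * W / nx
  ys <- ((seq_len(ny)) - 0.5) * H / ny
  labmat <- label
  r_eas <- numeric(length(ids))
  for (k in seq_along(ids)) {
    sel <- which(label == ids[k] & mask)
    best <- sel[which.max(dist[sel])]
    i <- ((best - 1) %% nx) + 1
    j <- ((best - 1) %/% nx) + 1
    r_eas[k] <- .pore_ray_radius(xs[i], ys[j], packing,
                                 cap = 6 * dist[best] + 3 * max(packing$radii),
                                 n_rays = n_rays, label = labmat,
                                 label_id = ids[k], nx = nx, ny = ny)
  }

  pores <- tibble::tibble(area = areas, R_EAS = r_eas,
                          weight = areas / sum(areas))
  structure(list(pores = pores, total_eas_area = eas_area,
                 resolution = c(nx, ny), merge_ratio = merge_ratio,
                 n_degenerate_merged = n_degenerate,
                 label = matrix(label, nx, ny), packing_type = packing$packing_type),
            class = "pore_segmentation")
}

# mean ray distance from (x0, y0) to the nearest cylinder wall over periodic
# images, with rays capped where they exit the pore's basin (when a label
# matrix is supplied) or at the search radius
.pore_ray_radius <- function(x0, y0, packing, cap, n_rays = 4096,
                             label = NULL, label_id = NULL,
                             nx = NULL, ny = NULL) {
  W <- packing$tile[1]; H <- packing$tile[2]
  th <- (seq_len(n_rays) - 0.5) / n_rays * 2 * pi
  ux <- cos(th); uy <- sin(th)
  d <- rep(cap, n_rays)
  kx <- ceiling((cap + max(packing$radii)) / W)
  ky <- ceiling((cap + max(packing$radii)) / H)
  for (i in seq_len(nrow(packing$centers))) {
    cx0 <- packing$centers[i, 1]; cy0 <- packing$centers[i, 2]; r <- packing$radii[i]
    for (sx in -kx:kx) for (sy in -ky:ky) {
      cx <- cx0 + sx * W - x0; cy <- cy0 + sy * H - y0
      if (cx^2 + cy^2 > (cap + r)^2) next
      d <- pmin(d, .ray_circle_dist(ux, uy, cx, cy, r))
    }
  }
  d <- pmin(d, cap)
  if (!is.null(label)) {
    # march along each ray at half-pixel resolution; stop at the first sample
    # outside this pore's basin (crossing a throat into a neighbour)
    px <- min(W / nx, H / ny) / 2
    smax <- max(d)
    s <- seq(px, smax, by = px)
    if (length(s)) {
      for (b in seq_along(s)) {
        act <- d > s[b] - px    # rays still marching
        if (!any(act)) break
        xw <- (x0 + ux[act] * s[b]) %% W
        yw <- (y0 + uy[act] * s[b]) %% H
        ii <- pmin(pmax(floor(xw / W * nx), 0), nx - 1)
        jj <- pmin(pmax(floor(yw / H * ny), 0), ny - 1)
        lab <- label[jj * nx + ii + 1]
        out <- lab != label_id & lab != 0L
        if (any(out)) {
          idx <- which(act)[out]
          d[idx] <- pmin(d[idx], s[b])
        }
      }
    }
  }
  mean(d)
}

#' @export
print.pore_segmentation <- function(x, ...) {
  cat(sprintf(
    "<pore_segmentation> %d pores, EAS area %.4g um^2 (%d degenerate merged)\n",
    nrow(x$pores), x$total_eas_area, x$n_degenerate_merged))
  cat(sprintf("  volume-weighted R_EAS: mean %.4g um, sd %.4g um\n",
              .wmean(x$pores$R_EAS, x$pores$weight),
              sqrt(.wvar(x$pores$R_EAS, x$pores$weight))))
  invisible(x)
}

.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
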