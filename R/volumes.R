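#' Separable Gaussian blur of a 3-D array
#'
#' Convolves the array with a Gaussian kernel of the given standard deviation
#' in voxel units along each axis (zero padding at the borders), the blur
#' used to soften binary organelle masks into probability maps.
#'
#' @param a 3-D numeric array indexed (z, y, x).
#' @param sigma_vox kernel s.d. in voxels (scalar, applied to all axes).
#' @return blurred array of the same shape.
#' @keywords internal
gaussianBlur3d <- function(a, sigma_vox = 1) {
  if (sigma_vox <= 0) return(a)
  r <- ceiling(3 * sigma_vox)
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  shift <- function(x, j, dim) {
    ## shift along 'dim' by j voxels with zero fill
    d <- dim(x)
    out <- array(0, d)
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[dim]
    if (j >= 0) {
      if (j >= n) return(out)
      idx[[dim]] <- (1 + j):n
      src[[dim]] <- 1:(n - j)
    } else {
      if (-j >= n) return(out)
      idx[[dim]] <- 1:(n + j)
      src[[dim]] <- (1 - j):n
    }
    out[idx[[1]], idx[[2]], idx[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (dm in 1:3) {
    acc <- array(0, dim(a))
    for (j in -r:r) acc <- acc + k[j + r + 1] * shift(a, j, dm)
    a <- acc
  }
  a
}

#' Binarize an organelle probability map
#'
#' Thresholds a probability map at \code{threshold} (values greater than or
#' equal to the threshold are foreground) and labels the foreground into
#' 26-connected 3-D components.
#'
#' @param stack 3-D array (z, y, x) of probabilities in [0, 1].
#' @param threshold binarization threshold (0.5 by default).
#' @param connectivity 3-D connectivity, 26 (default) or 6.
#' @return list with \code{mask} (logical array) and \code{labels} (integer
#'   array; 0 = background).
#' @export
binarizeProbabilityMap <- function(stack, threshold = 0.5,
                                   connectivity = 26) {
  .check(is.array(stack) && length(dim(stack)) == 3,
         "stack must be a 3-D array")
  .check(min(stack) >= 0 && max(stack) <= 1,
         "input error: probability values outside [0, 1]")
  mask <- stack >= threshold
  list(mask = mask, labels = labelComponents3d(mask, connectivity))
}

#' Label 26-connected components of a 3-D mask
#'
#' Builds the voxel adjacency graph over the foreground voxels and labels its
#' connected components.
#'
#' @param mask logical 3-D array.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return integer array of component labels (0 = background).
#' @export
labelComponents3d <- function(mask, connectivity = 26) {
  .check(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  d <- dim(mask)
  fg <- which(mask)
  labels <- array(0L, d)
  if (length(fg) == 0) return(labels)
  coords <- arrayInd(fg, d)
  key <- (coords[, 3] - 1) * (d[1] * d[2]) + (coords[, 2] - 1) * d[1] +
    coords[, 1]
  lut <- seq_along(fg)
  names(lut) <- as.character(key)
  offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  if (connectivity == 6) offsets <- offsets[rowSums(abs(offsets)) == 1, ]
  ## keep one of each +/- pair
  offsets <- offsets[offsets$dz > 0 | (offsets$dz == 0 & offsets$dy > 0) |
                       (offsets$dz == 0 & offsets$dy == 0 & offsets$dx > 0), ]
  edges <- list()
  for (i in seq_len(nrow(offsets))) {
    nz <- coords[, 1] + offsets$dz[i]
    ny <- coords[, 2] + offsets$dy[i]
    nx <- coords[, 3] + offsets$dx[i]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    nkey <- (nx - 1) * (d[1] * d[2]) + (ny - 1) * d[1] + nz
    j <- lut[as.character(nkey)]
    hit <- ok & !is.na(j)
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(hit), j[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Segment cells from a cell-channel stack
#'
#' A simple cell segmenter: z-projection of the cell channel, Otsu threshold,
#' 8-connected 2-D component labelling, and a minimum-area filter.  The
#' default projection is maximum intensity, which yields a near-binary image
#' whose thresholded footprint matches the true cell outline; an
#' average-intensity projection of a rounded cell is chord-graded and its
#' Otsu footprint systematically erodes the outline.  The downstream
#' contract starts from 2-D cell masks, so masks from any external segmenter
#' can be supplied instead.
#'
#' @param cell_stack 3-D array (z, y, x) of cell-channel intensities.
#' @param min_area_px minimum footprint area in pixels.
#' @param projection \code{"max"} (default) or \code{"mean"}.
#' @return integer matrix (y, x) of cell labels (0 = background); zero cells
#'   found yields an all-zero matrix with a warning.
#' @export
segmentCells <- function(cell_stack, min_area_px = 50L,
                         projection = c("max", "mean")) {
  .check(is.array(cell_stack) && length(dim(cell_stack)) == 3,
         "cell_stack must be a 3-D array")
  projection <- match.arg(projection)
  proj <- apply(cell_stack, c(2, 3), projection)
  rng <- range(proj)
  if (diff(rng) == 0) {
    warning("empty cell channel: no cells found")
    return(matrix(0L, nrow(proj), ncol(proj)))
  }
  norm <- (proj - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  maskArr <- array(norm > th, c(1, dim(proj)))   # reuse the 3-D labeller
  lab <- labelComponents3d(maskArr, connectivity = 26)[1, , ]
  counts <- table(lab[lab > 0])
  keepIds <- as.integer(names(counts)[counts >= min_area_px])
  if (length(keepIds) == 0) {
    warning("no cells found above the minimum area")
    return(matrix(0L, nrow(proj), ncol(proj)))
  }
  out <- matrix(0L, nrow(proj), ncol(proj))
  for (i in seq_along(keepIds)) out[lab == keepIds[i]] <- i
  out
}

#' Fit the prolate-ellipsoid cell model to a 2-D cell mask
#'
#' Estimates the cell's semi-axes from the second-order central moments of
#' its footprint (the equivalent-ellipse axes, corrected for the finite pixel
#' size) and returns the prolate-ellipsoid volume
#' \eqn{V = \frac{4}{3}\pi a b^2} with \eqn{a \ge b} (the out-of-plane
#' semi-axis is taken equal to the minor in-plane semi-axis).
#'
#' @param cell_mask_2d logical or 0/1 matrix (y, x) of one cell's footprint.
#' @param pixel_dims c(dy, dx) pixel size in micrometres.
#' @return list with \code{a_um}, \code{b_um}, \code{v_cell_um3}.
#' @export
fitProlateEllipsoid <- function(cell_mask_2d, pixel_dims) {
  .check(length(pixel_dims) == 2 && all(pixel_dims > 0),
         "pixel_dims must be c(dy, dx) > 0")
  pix <- which(cell_mask_2d != 0, arr.ind = TRUE)
  .check(nrow(pix) >= 3, "geometry error: degenerate cell mask")
  yy <- pix[, 1] * pixel_dims[1]
  xx <- pix[, 2] * pixel_dims[2]
  cov <- stats::cov(cbind(yy, xx)) * (nrow(pix) - 1) / nrow(pix)
  ## add the within-pixel variance of the uniform pixel density
  cov <- cov + diag(pixel_dims^2) / 12
  ev <- eigen(cov, symmetric = TRUE)$values
  .check(all(ev > 0), "geometry error: degenerate (line/point) cell mask")
  a <- 2 * sqrt(ev[1])
  b <- 2 * sqrt(ev[2])
  list(a_um = a, b_um = b, v_cell_um3 = prolateEllipsoidVolume(a, b))
}

#' Prolate-ellipsoid volume
#'
#' \eqn{V = \frac{4}{3}\pi a b^2} for semi-major axis \eqn{a} and semi-minor
#' axes \eqn{b = c}, in cubic micrometres.
#'
#' @param a,b semi-axes in micrometres, \code{a >= b > 0}.
#' @return volume in um^3.
#' @examples
#' prolateEllipsoidVolume(5, 5)    # sphere: 523.60
#' prolateEllipsoidVolume(10, 5)   # 1047.20
#' @export
prolateEllipsoidVolume <- function(a, b) {
  .check(all(b > 0) && all(a >= b), "need a >= b > 0")
  4 / 3 * pi * a * b^2
}

#' Organelle volume inside a cell footprint
#'
#' Counts organelle voxels whose (y, x) position falls inside the cell's 2-D
#' footprint, across all z-planes, and converts the count to physical units.
#'
#' @param organelle_mask logical 3-D array (z, y, x).
#' @param cell_mask_2d logical/0-1 matrix (y, x); the cell mask is applied
#'   over all z-planes.
#' @param voxel_dims c(dz, dy, dx) voxel size in micrometres.
#' @return organelle volume in um^3.
#' @export
organelleVolume <- function(organelle_mask, cell_mask_2d, voxel_dims) {
  d <- dim(organelle_mask)
  .check(length(d) == 3, "organelle_mask must be a 3-D array")
  .check(all(d[2:3] == dim(cell_mask_2d)),
         "alignment error: mask shapes differ (%dx%d vs %dx%d)",
         d[2], d[3], nrow(cell_mask_2d), ncol(cell_mask_2d))
  .check(length(voxel_dims) == 3 && all(voxel_dims > 0),
         "voxel_dims must be c(dz, dy, dx) > 0")
  foot <- array(rep(cell_mask_2d != 0, each = d[1]), d)
  sum(organelle_mask & foot) * prod(voxel_dims)
}

#' Organelle volume fraction
#'
#' @param v_org organelle volume (um^3, >= 0).
#' @param v_cell estimated cell volume (um^3, > 0).
#' @return dimensionless fraction \code{v_org / v_cell}.
#' @export
volumeFraction <- function(v_org, v_cell) {
  .check(all(v_cell > 0), "geometry error: cell volume must be positive")
  .check(all(v_org >= 0), "organelle volume must be non-negative")
  v_org / v_cell
}

#' Classify cells as normal against a wild-type reference population
#'
#' A cell is \code{none_detected} if it has no organelle signal (fraction
#' exactly 0); otherwise it is \code{normal} iff its volume fraction lies
#' within \code{k} standard deviations (1.5 by default) of the wild-type
#' mean, and \code{abnormal_low} / \code{abnormal_high} by the sign of the
#' deviation otherwise.
#'
#' @param fractions volume fractions to classify.
#' @param wt_fractions wild-type reference fractions (>= 2 values with
#'   non-zero s.d.).
#' @param k s.d. multiplier of the normality band.
#' @return list with \code{labels} (character vector), \code{percent_normal}
#'   and \code{percent_none} population summaries.
#' @export
classifyNormality <- function(fractions, wt_fractions, k = 1.5) {
  .check(length(wt_fractions) >= 2, "need >= 2 wild-type reference values")
  mu <- mean(wt_fractions)
  sg <- sd(wt_fractions)
  .check(sg > 0, "degenerate-reference error: WT fractions have zero s.d.")
  labels <- ifelse(fractions == 0, "none_detected",
                   ifelse(abs(fractions - mu) <= k * sg, "normal",
                          ifelse(fractions < mu, "abnormal_low",
                                 "abnormal_high")))
  list(labels = labels,
       percent_normal = 100 * mean(labels == "normal"),
       percent_none = 100 * mean(labels == "none_detected"))
}

#' Gaussian kernel density estimate of a fraction population
#'
#' Gaussian-kernel density with Scott's-rule bandwidth by default, evaluated
#' on a stated grid; the curve integrates to 1 over the grid.
#'
#' @param fractions numeric vector (>= 2 finite values).
#' @param bandwidth numeric bandwidth, or \code{"scott"} (default) /
#'   \code{"silverman"} rules.
#' @param n grid size.
#' @return data.frame with columns \code{x} (grid) and \code{density}.
#' @export
kdeDensity <- function(fractions, bandwidth = "scott", n = 512L) {
  .check(length(fractions) >= 2 && all(is.finite(fractions)),
         "need >= 2 finite values")
  if (sd(fractions) == 0) {
    warning("degenerate density: all values identical; returning a ",
            "delta-like spike")
    x0 <- fractions[1]
    eps <- max(abs(x0), 1) * 1e-3
    d <- density(fractions, bw = eps, n = n)
    return(data.frame(x = d$x, density = d$y))
  }
  bw <- if (is.numeric(bandwidth)) bandwidth
        else switch(match.arg(bandwidth, c("scott", "silverman")),
                    scott = bw.nrd(fractions),
                    silverman = bw.nrd0(fractions))
  d <- density(fractions, bw = bw, kernel = "gaussian", n = n)
  data.frame(x = d$x, density = d$y)
}

#' Per-cell volume fractions from cell and organelle stacks
#'
#' The end-to-end imaging pipeline: segments cells from the cell channel,
#' fits the prolate-ellipsoid model to every cell footprint, binarizes the
#' organelle probability map at 0.5, counts organelle voxels within each
#' cell's footprint, and reports per-cell volume fractions.
#'
#' @param cell_stack 3-D cell-channel array (z, y, x).
#' @param organelle_stack 3-D organelle probability map (z, y, x).
#' @param voxel_dims c(dz, dy, dx) in micrometres (dz defaults to 0.2).
#' @param threshold probability-map binarization threshold.
#' @param min_area_px minimum cell footprint area.
#' @return data.frame (one row per cell): \code{cell_id}, \code{a_um},
#'   \code{b_um}, \code{v_cell_um3}, \code{v_org_um3}, \code{volume_fraction}.
#' @export
cellVolumeFractions <- function(cell_stack, organelle_stack,
                                voxel_dims = c(0.2, 0.1, 0.1),
                                threshold = 0.5, min_area_px = 50L) {
  .check(all(dim(cell_stack) == dim(organelle_stack)),
         "alignment error: channel stacks have different shapes")
  cells <- segmentCells(cell_stack, min_area_px = min_area_px)
  seg <- binarizeProbabilityMap(organelle_stack, threshold = threshold)
  ids <- setdiff(sort(unique(as.vector(cells))), 0L)
  rows <- lapply(ids, function(i) {
    m2 <- cells == i
    fit <- fitProlateEllipsoid(m2, voxel_dims[2:3])
    vo <- organelleVolume(seg$mask, m2, voxel_dims)
    data.frame(cell_id = i, a_um = fit$a_um, b_um = fit$b_um,
               v_cell_um3 = fit$v_cell_um3, v_org_um3 = vo,
               volume_fraction = volumeFraction(vo, fit$v_cell_um3))
  })
  do.call(rbind, rows)
}
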