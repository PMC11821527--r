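#' Simulate a confocal z-stack with prolate-ellipsoid cells
#'
#' Rasterizes prolate-ellipsoid cells (semi-axes \code{a >= b = c}, major
#' axis in-plane along x) into a 3-D stack and embeds organelle blobs inside
#' each cell totalling a requested fraction of the analytic cell volume.
#' Blobs are spheres in voxel index space with radius \code{blob_radius_vox}
#' voxels; the "probability map" channel is the binary organelle truth
#' blurred with a Gaussian of s.d. \code{blur_sigma_vox} voxels and clipped
#' to [0, 1].  Cells are placed side by side without overlap.  A configurable
#' share of cells carries no organelle at all (the none-detected class).
#'
#' @param n_cells number of cells.
#' @param a_um,b_um cell semi-axes in micrometres (scalars or one per cell;
#'   \code{a_um >= b_um}).
#' @param organelle_fraction requested organelle volume fraction (scalar or
#'   one per cell; 0 gives a cell without organelle voxels).
#' @param zero_fraction_rate probability that a cell is forced to fraction 0.
#' @param voxel_dims c(dz, dy, dx) in micrometres; dz defaults to the 0.2 um
#'   z-step.
#' @param blob_radius_vox organelle blob radius in voxels.
#' @param blur_sigma_vox probability-map blur s.d. in voxels.
#' @param margin_um empty margin around each cell.
#' @param seed integer RNG seed.
#' @return list with \code{cell_stack} (intensity array), \code{organelle_map}
#'   (probability array), \code{organelle_truth} (logical array),
#'   \code{voxel_dims} and \code{truth} - a data.frame of per-cell planted
#'   geometry: \code{a_um}, \code{b_um}, \code{v_cell_um3} (analytic),
#'   \code{requested_fraction}, \code{true_fraction} (rasterized organelle
#'   volume over analytic cell volume) and \code{v_org_um3}.
#' @export
simulateImageStack <- function(n_cells = 3L, a_um = 9, b_um = 4.5,
                               organelle_fraction = 0.05,
                               zero_fraction_rate = 0,
                               voxel_dims = c(0.2, 0.1, 0.1),
                               blob_radius_vox = 9L, blur_sigma_vox = 1,
                               margin_um = 2, seed = 1L) {
  .check(all(voxel_dims > 0), "voxel dims must be positive")
  a_um <- rep_len(a_um, n_cells)
  b_um <- rep_len(b_um, n_cells)
  organelle_fraction <- rep_len(organelle_fraction, n_cells)
  .check(all(a_um >= b_um & b_um > 0), "need a >= b > 0 for every cell")
  .check(all(organelle_fraction >= 0 & organelle_fraction < 1),
         "fractions must be in [0, 1)")
  dz <- voxel_dims[1]; dy <- voxel_dims[2]; dx <- voxel_dims[3]

  withSeed(seed, {
    zeroed <- runif(n_cells) < zero_fraction_rate
    organelle_fraction[zeroed] <- 0

    ## stack geometry: cells in a row along x
    widths <- 2 * a_um + 2 * margin_um
    nx <- ceiling(sum(widths) / dx)
    ny <- ceiling((2 * max(b_um) + 2 * margin_um) / dy)
    nz <- ceiling((2 * max(b_um) + 2 * margin_um) / dz)
    d <- c(nz, ny, nx)
    cellStack <- array(0, d)
    orgTruth <- array(FALSE, d)
    y0 <- ny / 2 * dy
    z0 <- nz / 2 * dz
    xoff <- c(0, cumsum(widths))[seq_len(n_cells)]

    zc <- (seq_len(nz) - 0.5) * dz
    yc <- (seq_len(ny) - 0.5) * dy

    truthRows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      a <- a_um[i]; b <- b_um[i]
      x0 <- xoff[i] + margin_um + a
      ## rasterize the cell ellipsoid over its bounding box
      xi <- which(abs((seq_len(nx) - 0.5) * dx - x0) <= a)
      yi <- which(abs(yc - y0) <= b)
      zi <- which(abs(zc - z0) <= b)
      xs <- (xi - 0.5) * dx; ys <- (yi - 0.5) * dy; zs <- (zi - 0.5) * dz
      ell <- outer(((zs - z0) / b)^2,
                   outer(((ys - y0) / b)^2, ((xs - x0) / a)^2, `+`), `+`) <= 1
      sub <- cellStack[zi, yi, xi, drop = FALSE]
      cellStack[zi, yi, xi] <- pmax(sub, array(as.numeric(ell), dim(ell)))

      vCell <- prolateEllipsoidVolume(a, b)
      frac <- organelle_fraction[i]
      nOrgVox <- 0L
      if (frac > 0) {
        blobVoxels <- .sphereOffsets(blob_radius_vox)
        targetVox <- round(frac * vCell / prod(voxel_dims))
        ## paint blobs (overlap allowed, as in a merged organelle network)
        ## until the union reaches the target voxel count
        centers <- list()
        tries <- 0L
        while (nOrgVox < targetVox - nrow(blobVoxels) / 2 &&
               tries < 20000L) {
          tries <- tries + 1L
          ctr <- .sampleBlobCenter(a, b, x0, y0, z0, voxel_dims,
                                   blob_radius_vox, d)
          if (is.null(ctr)) next
          ok <- TRUE
          for (prev in centers)
            if (sum((ctr - prev)^2) < blob_radius_vox^2) { ok <- FALSE
              break }
          if (!ok) next
          centers[[length(centers) + 1L]] <- ctr
          vox <- cbind(blobVoxels[, 1] + ctr[1], blobVoxels[, 2] + ctr[2],
                       blobVoxels[, 3] + ctr[3])
          orgTruth[vox] <- TRUE
          nOrgVox <- sum(orgTruth[, , xi])
        }
        if (nOrgVox < targetVox - nrow(blobVoxels))
          warning(sprintf(
            "cell %d: reached %d of %d target organelle voxels", i,
            nOrgVox, targetVox))
      }
      vOrg <- nOrgVox * prod(voxel_dims)
      truthRows[[i]] <- data.frame(cell_id = i, a_um = a, b_um = b,
                                   v_cell_um3 = vCell,
                                   requested_fraction = frac,
                                   v_org_um3 = vOrg,
                                   true_fraction = vOrg / vCell)
    }
    orgMap <- gaussianBlur3d(orgTruth * 1, blur_sigma_vox)
    orgMap <- pmin(pmax(orgMap, 0), 1)
    cellBlur <- gaussianBlur3d(cellStack, blur_sigma_vox)
    list(cell_stack = cellBlur, organelle_map = orgMap,
         organelle_truth = orgTruth, voxel_dims = voxel_dims,
         truth = do.call(rbind, truthRows))
  })
}

## voxel offsets of a sphere of radius r in index space
.sphereOffsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, ]
  as.matrix(g)
}

## sample one blob center (voxel indices) inside a shrunken cell ellipsoid,
## so the blob lies fully inside the cell and the stack; NULL on a miss
.sampleBlobCenter <- function(a, b, x0, y0, z0, voxel_dims, r_vox, d) {
  dz <- voxel_dims[1]; dy <- voxel_dims[2]; dx <- voxel_dims[3]
  rz <- r_vox * dz; rxy <- r_vox * dx
  sa <- max(a - rxy, 0.1 * a)
  sb <- max(b - max(rz, rxy), 0.1 * b)
  u <- runif(3, -1, 1)
  if (sum(u^2) > 1) return(NULL)
  ctr <- c(round((z0 + u[3] * sb) / dz), round((y0 + u[2] * sb) / dy),
           round((x0 + u[1] * sa) / dx))
  if (any(ctr < r_vox + 1) || any(ctr > d - r_vox)) return(NULL)
  ctr
}
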