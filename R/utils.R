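#' @keywords internal
"_PACKAGE"

#' @useDynLib neurophenoclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef vcov pf pt pchisq qnorm rnorm rexp runif rbinom
#'   sd median cutree as.dist dist anova quantile setNames aggregate
#'   binomial complete.cases
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("hr", "label", "ci_low", "ci_high"))

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Voxel-centre coordinates of a mask, in mm
#'
#' @param mask logical or 0/1 3D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return n x 3 matrix of voxel-centre coordinates (mm).
#' @export
voxel_coords <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

#' Boundary voxels of a binary mask
#'
#' A foreground voxel is a boundary voxel when at least one of its six
#' face neighbours is background (voxels on the array edge count as
#' adjacent to background).
#'
#' @param mask logical or 0/1 3D array.
#' @return logical array of the same shape.
#' @export
boundary_voxels <- function(mask) {
  mask <- mask != 0
  n <- dim(mask)
  nb <- array(0L, n)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (d in shifts) {
    sh <- shift_mask(mask, d)
    nb <- nb + sh
  }
  mask & nb < 6L
}

# shift with zero fill (background beyond the array edge)
shift_mask <- function(a, d) {
  n <- dim(a)
  out <- array(FALSE, n)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(n[ax] - d[ax]) + d[ax]
      dst[[ax]] <- seq_len(n[ax] - d[ax])
    } else {
      src[[ax]] <- seq_len(n[ax] + d[ax])
      dst[[ax]] <- seq_len(n[ax] + d[ax]) - d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 3^3 box-mean smoothing with zero padding; used before isosurfacing.
smooth_field3 <- function(mask) {
  a <- array(0, dim(mask))
  a[mask != 0] <- 1
  n <- dim(a)
  out <- array(0, n)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    out <- out + shift_num(a, c(dx, dy, dz))
  }
  out / 27
}

shift_num <- function(a, d) {
  n <- dim(a)
  out <- array(0, n)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(n[ax] - d[ax]) + d[ax]
      dst[[ax]] <- seq_len(n[ax] - d[ax])
    } else {
      src[[ax]] <- seq_len(n[ax] + d[ax])
      dst[[ax]] <- seq_len(n[ax] + d[ax]) - d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

pad_array <- function(a, pad = 1, value = 0) {
  n <- dim(a)
  out <- array(value, n + 2 * pad)
  out[pad + seq_len(n[1]), pad + seq_len(n[2]), pad + seq_len(n[3])] <- a
  out
}

#' Resample a binary mask to an isotropic grid
#'
#' Nearest-neighbour resampling to a cubic voxel whose edge equals the
#' smallest input spacing. Thick-slice acquisitions (e.g. 0.9 x 0.9 x 4 mm)
#' otherwise distort mesh areas and box counts.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing numeric length-3 spacing in mm.
#' @param iso target isotropic spacing in mm; default `min(spacing)`.
#' @return list with elements `mask` (logical array) and `spacing`.
#' @export
resample_isotropic <- function(mask, spacing, iso = min(spacing)) {
  stop_if(any(spacing <= 0), "spacing must be strictly positive")
  if (all(abs(spacing - iso) < 1e-12)) {
    return(list(mask = mask != 0, spacing = rep(iso, 3)))
  }
  n <- dim(mask)
  newn <- pmax(1L, as.integer(round(n * spacing / iso)))
  # sample at new voxel centres, nearest neighbour in the source grid
  src_idx <- function(ax) {
    centres <- (seq_len(newn[ax]) - 0.5) * iso
    pmin(pmax(as.integer(ceiling(centres / spacing[ax])), 1L), n[ax])
  }
  out <- (mask != 0)[src_idx(1), src_idx(2), src_idx(3), drop = FALSE]
  dim(out) <- newn
  list(mask = out, spacing = rep(iso, 3))
}

# deterministic child seeds below 2^31
derive_seed <- function(seed, i) (as.integer(seed) %% 100000L) * 1000L + as.integer(i)
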