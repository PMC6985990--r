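#' Connected lesions of a binary mask
#'
#' Components under 26-connectivity, numbered deterministically by the
#' smallest linear voxel index they contain.
#'
#' @param mask logical/0-1 3D array.
#' @return list with `labels` (integer array, 0 = background) and
#'   `n` (number of components).
#' @export
extract_lesions <- function(mask) {
  stop_if(is.null(dim(mask)) || length(dim(mask)) != 3, "mask must be a 3D array")
  lab <- .label_components_cpp(mask != 0, dim(mask))
  n <- max(lab)
  if (n > 1) {
    first <- vapply(seq_len(n), function(l) which.max(lab == l), integer(1))
    ord <- order(first)
    relab <- integer(n)
    relab[ord] <- seq_len(n)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  list(labels = lab, n = n)
}

#' Classify WMH voxels as periventricular/confluent or deep
#'
#' The Euclidean distance from each WMH voxel to the lateral-ventricle
#' surface is computed in mm on the anisotropic grid; voxels at most
#' `threshold` mm away are periventricular/confluent (CPWMH), the rest deep
#' (DWMH). A connected lesion is assigned a single class: under the default
#' `"any"` rule it is CPWMH when any of its voxels touches the 3 mm zone
#' (confluent lesions reach the ventricle margin); a majority-vote rule is
#' available.
#'
#' @param wmh,ventricles logical/0-1 3D arrays on the same grid.
#' @param spacing voxel spacing in mm.
#' @param threshold distance threshold in mm (default 3, boundary
#'   inclusive).
#' @param rule `"any"` or `"majority"` lesion-level assignment.
#' @return list with `class_map` (integer array: 1 = CPWMH, 2 = DWMH on WMH
#'   voxels, 0 elsewhere), `lesions` (data frame: lesion id, class,
#'   `min_dist`, `n_voxels`), and `labels` (lesion label array).
#' @export
classify_wmh <- function(wmh, ventricles, spacing, threshold = 3,
                         rule = c("any", "majority")) {
  rule <- match.arg(rule)
  stop_if(!identical(dim(wmh), dim(ventricles)), "masks must share one grid")
  les <- extract_lesions(wmh)
  class_map <- array(0L, dim(wmh))
  if (les$n == 0) {
    return(list(class_map = class_map,
                lesions = data.frame(lesion = integer(), class = character(),
                                     min_dist = numeric(), n_voxels = integer()),
                labels = les$labels))
  }
  stop_if(sum(ventricles != 0) == 0, "ventricle mask is empty")
  wmh_mm <- voxel_coords(wmh, spacing)
  vent_surface <- boundary_voxels(ventricles != 0)
  vent_mm <- voxel_coords(vent_surface, spacing)
  d <- .set_distance_cpp(wmh_mm, vent_mm)
  # voxels inside the ventricle mask (shouldn't occur in clean data) are at 0
  lab_at <- les$labels[les$labels > 0]
  per_vox_cp <- d <= threshold
  cls <- character(les$n); mind <- numeric(les$n); nvox <- integer(les$n)
  for (l in seq_len(les$n)) {
    sel <- lab_at == l
    mind[l] <- min(d[sel])
    nvox[l] <- sum(sel)
    cp <- if (rule == "any") any(per_vox_cp[sel]) else mean(per_vox_cp[sel]) >= 0.5
    cls[l] <- if (cp) "CPWMH" else "DWMH"
  }
  for (l in seq_len(les$n)) {
    class_map[les$labels == l] <- if (cls[l] == "CPWMH") 1L else 2L
  }
  list(class_map = class_map,
       lesions = data.frame(lesion = seq_len(les$n), class = cls,
                            min_dist = mind, n_voxels = nvox),
       labels = les$labels)
}

#' Mesh-based volume, surface and convex-hull metrics of a lesion
#'
#' The mask is resampled to an isotropic grid, box-smoothed and isosurfaced
#' with marching tetrahedra at level 0.5; the surface area is the mesh
#' area and the hull area comes from the 3D convex hull of the mesh
#' vertices. Volume is voxel count times voxel volume, and the hull volume
#' is measured the same way — as the volume of the voxelized hull (voxel
#' centres inside the convex hull of the lesion's voxel centres) — so that
#' the volume ratio of a convex voxel set is exactly 1. One-voxel or
#' plane-like lesions whose smoothed field never crosses the iso level fall
#' back to the binary-field mesh (or to voxel-face area) and are flagged
#' `degenerate`.
#'
#' @param mask logical/0-1 3D array (one lesion).
#' @param spacing voxel spacing in mm.
#' @return list: `volume`, `surface_area`, `hull_volume`, `hull_area`
#'   (mm-based), `mesh_vertices` (matrix), `degenerate`, `hull_ok`.
#' @export
mesh_metrics <- function(mask, spacing) {
  stop_if(sum(mask != 0) == 0, "lesion is empty")
  volume <- sum(mask != 0) * prod(spacing)
  iso <- resample_isotropic(mask, spacing)
  m <- pad_array(iso$mask, 2)
  degenerate <- FALSE
  f <- smooth_field3(m)
  if (max(f) < 0.5) {            # too thin for the smoothed field
    f <- array(0, dim(m)); f[m] <- 1
    degenerate <- TRUE
  }
  tri <- .marching_tetra_cpp(as.numeric(f), dim(f), 0.5, iso$spacing)
  if (nrow(tri) == 0) {          # single isolated voxel: voxel-face fallback
    area <- 6 * iso$spacing[1]^2 * sum(m)
    return(list(volume = volume, surface_area = area,
                hull_volume = volume, hull_area = area,
                mesh_vertices = NULL, degenerate = TRUE, hull_ok = FALSE))
  }
  surface_area <- sum(triangle_areas(tri))
  verts <- unique(rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                        tri[, 7:9, drop = FALSE]))
  hull <- .hull3d_cpp(verts)
  hv <- hull_voxel_volume(iso$mask, iso$spacing)
  if (!identical(hull$status, "ok") || is.na(hv)) {
    return(list(volume = volume, surface_area = surface_area,
                hull_volume = NA_real_, hull_area = NA_real_,
                mesh_vertices = verts, degenerate = TRUE, hull_ok = FALSE))
  }
  list(volume = volume, surface_area = surface_area,
       hull_volume = hv, hull_area = hull$area,
       mesh_vertices = verts, degenerate = degenerate, hull_ok = TRUE)
}

#' Volume of the voxelized convex hull of a mask
#'
#' Counts the voxel centres lying inside the convex hull of the mask's
#' voxel centres and multiplies by the voxel volume. For a convex voxel
#' set this equals the mask volume exactly.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing voxel spacing in mm.
#' @return hull volume in mm^3, or `NA` when the point set is degenerate
#'   (fewer than 4 affinely independent voxel centres).
#' @export
hull_voxel_volume <- function(mask, spacing) {
  coords <- voxel_coords(mask, spacing)
  if (nrow(coords) < 4) return(NA_real_)
  hull <- .hull3d_cpp(coords)
  if (!identical(hull$status, "ok")) return(NA_real_)
  planes <- hull$planes
  # candidate voxel centres: the mask's bounding box
  rng <- apply(coords, 2, range)
  grids <- lapply(1:3, function(ax) seq(rng[1, ax], rng[2, ax], by = spacing[ax]))
  cand <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  tol <- 1e-7 * (1 + max(abs(rng)))
  inside <- rep(TRUE, nrow(cand))
  for (r in seq_len(nrow(planes))) {
    inside <- inside &
      (cand %*% planes[r, 1:3] - planes[r, 4] <= tol)
    if (!any(inside)) break
  }
  sum(inside) * prod(spacing)
}

triangle_areas <- function(tri) {
  v1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  v2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Dimensionless lesion shape features
#'
#' Solidity is volume over hull volume; convexity is hull area over surface
#' area (both 1 for a convex body). The concavity index, `2 - convexity -
#' solidity`, is 0 for a convex body and grows with irregularity.
#' Eccentricity is `sqrt(1 - lambda_min / lambda_max)` over the eigenvalues
#' of the second-moment matrix of the voxel coordinates in mm (0 for a
#' sphere, towards 1 for elongated lesions); for plane-like lesions with a
#' degenerate hull it is computed from the top two moments and the hull
#' ratios are flagged `NA`.
#'
#' @param mm output of [mesh_metrics()].
#' @param coords n x 3 voxel-centre coordinates in mm (for the moments).
#' @return list: `solidity`, `convexity`, `concavity_index`, `eccentricity`,
#'   `flagged`.
#' @export
shape_features <- function(mm, coords) {
  if (isTRUE(mm$hull_ok)) {
    solidity <- mm$volume / mm$hull_volume
    convexity <- mm$hull_area / mm$surface_area
    concavity <- 2 - convexity - solidity
    flagged <- isTRUE(mm$degenerate)
  } else {
    solidity <- convexity <- concavity <- NA_real_
    flagged <- TRUE
  }
  ecc <- moment_eccentricity(coords)
  list(solidity = solidity, convexity = convexity, concavity_index = concavity,
       eccentricity = ecc, flagged = flagged)
}

moment_eccentricity <- function(coords) {
  if (nrow(coords) < 2) return(0)
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- sort(eigen(crossprod(cc) / nrow(cc), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  if (ev[1] <= .Machine$double.eps) return(0)
  lmin <- if (ev[3] > 1e-9 * ev[1]) ev[3] else ev[2]  # 2D fallback for coplanar sets
  sqrt(max(0, 1 - lmin / ev[1]))
}

#' Box-counting fractal dimension of a voxel set
#'
#' Counts occupied boxes N(eps) over a ladder of box sizes and returns the
#' least-squares slope of log N against log(1/eps). The default ladder is
#' dyadic (1, 2, 4, 8, 16 voxels) restricted to sizes at most one eighth of
#' the largest extent, so that every scale used lies in the scaling regime;
#' an explicitly supplied ladder is used as-is. Fewer than three usable
#' scales leave the dimension undefined (`NA`, flagged) rather than
#' silently defaulted.
#'
#' @param x logical/0-1 3D array, or an n x 3 matrix of integer voxel
#'   coordinates (isotropic grid assumed; resample first on anisotropic
#'   data).
#' @param sizes optional integer vector of box edge lengths (voxels).
#' @return list: `fd`, `sizes`, `counts`, `flag` (`NA` or
#'   `"insufficient_scales"`).
#' @export
fractal_dimension <- function(x, sizes = NULL) {
  coords <- if (is.matrix(x)) x else which(x != 0, arr.ind = TRUE)
  stop_if(nrow(coords) == 0, "voxel set is empty")
  coords <- coords - rep(apply(coords, 2, min), each = nrow(coords))  # 0-based
  extent <- max(apply(coords, 2, max) + 1)
  explicit <- !is.null(sizes)
  if (!explicit) {
    sizes <- c(1L, 2L, 4L, 8L, 16L)
    sizes <- sizes[sizes <= max(1, extent / 8)]
  }
  sizes <- sort(unique(as.integer(sizes)))
  counts <- vapply(sizes, function(e) nrow(unique(coords %/% e)), integer(1))
  if (length(sizes) < 3) {
    return(list(fd = NA_real_, sizes = sizes, counts = counts,
                flag = "insufficient_scales"))
  }
  fit <- lm(log(counts) ~ log(1 / sizes))
  list(fd = unname(coef(fit)[2]), sizes = sizes, counts = counts, flag = NA)
}

#' Per-lesion shape feature table for one patient
#'
#' Runs lesion extraction, the 3 mm classification and the full shape
#' feature set over a WMH mask.
#'
#' @inheritParams classify_wmh
#' @param min_voxels lesions smaller than this are still measured but their
#'   mesh metrics are typically flagged degenerate.
#' @return data frame with one row per lesion: class, volume, surface and
#'   hull metrics, solidity, convexity, concavity index, eccentricity,
#'   per-lesion fractal dimension and flags.
#' @export
lesion_shape_table <- function(wmh, ventricles, spacing, threshold = 3,
                               rule = "any", min_voxels = 1) {
  cl <- classify_wmh(wmh, ventricles, spacing, threshold, rule)
  n <- nrow(cl$lesions)
  rows <- vector("list", n)
  for (l in seq_len(n)) {
    m <- cl$labels == l
    dim(m) <- dim(wmh)
    mm <- mesh_metrics(m, spacing)
    coords <- voxel_coords(m, spacing)
    sf <- shape_features(mm, coords)
    iso <- resample_isotropic(m, spacing)
    fd <- fractal_dimension(boundary_voxels(iso$mask))
    rows[[l]] <- data.frame(
      lesion = l, class = cl$lesions$class[l], n_voxels = cl$lesions$n_voxels[l],
      min_dist = cl$lesions$min_dist[l], volume = mm$volume,
      surface_area = mm$surface_area, hull_volume = mm$hull_volume,
      hull_area = mm$hull_area, solidity = sf$solidity,
      convexity = sf$convexity, concavity_index = sf$concavity_index,
      eccentricity = sf$eccentricity, fd = fd$fd,
      flagged = sf$flagged, fd_flag = !is.na(fd$flag))
  }
  if (n == 0) {
    return(data.frame(lesion = integer(), class = character(),
                      n_voxels = integer(), min_dist = numeric(),
                      volume = numeric(), surface_area = numeric(),
                      hull_volume = numeric(), hull_area = numeric(),
                      solidity = numeric(), convexity = numeric(),
                      concavity_index = numeric(), eccentricity = numeric(),
                      fd = numeric(), flagged = logical(), fd_flag = logical()))
  }
  do.call(rbind, rows)
}

#' Patient-level WMH shape summary
#'
#' Unweighted means of each shape feature across lesions, separately for
#' the CPWMH and DWMH classes, with lesion counts and missing-class
#' indicators; a class with no lesions yields `NA` means and a set
#' indicator (this is what produces the deep-WMH missingness pattern in
#' cohorts where many patients have no deep lesions). Pooled per-class
#' fractal dimensions (all voxels of a class pooled before box counting)
#' are included alongside the per-lesion means.
#'
#' @param lesions data frame from [lesion_shape_table()].
#' @param pooled_fd optional named list `list(CPWMH = , DWMH = )` of pooled
#'   per-class FD values (see [patient_shape_summary()]).
#' @return one-row data frame per class bound together, plus attributes.
#' @export
aggregate_patient <- function(lesions, pooled_fd = NULL) {
  feats <- c("volume", "surface_area", "solidity", "convexity",
             "concavity_index", "eccentricity", "fd")
  out <- lapply(c("CPWMH", "DWMH"), function(cl) {
    sub <- lesions[lesions$class == cl, , drop = FALSE]
    if (nrow(sub) == 0) {
      row <- as.data.frame(as.list(setNames(rep(NA_real_, length(feats)), feats)))
      row$n_lesions <- 0L
      row$missing <- TRUE
    } else {
      row <- as.data.frame(lapply(sub[feats], function(v) mean(v, na.rm = TRUE)))
      row[vapply(row, is.nan, logical(1))] <- NA_real_
      row$n_lesions <- nrow(sub)
      row$missing <- FALSE
    }
    row$class <- cl
    row$fd_pooled <- if (!is.null(pooled_fd)) pooled_fd[[cl]] %||% NA_real_ else NA_real_
    row
  })
  do.call(rbind, out)
}

#' Full per-patient WMH shape pipeline
#'
#' @inheritParams classify_wmh
#' @return list with `lesions` (per-lesion table) and `summary`
#'   (per-class patient summary including pooled FD).
#' @export
patient_shape_summary <- function(wmh, ventricles, spacing, threshold = 3,
                                  rule = "any") {
  tab <- lesion_shape_table(wmh, ventricles, spacing, threshold, rule)
  cl <- classify_wmh(wmh, ventricles, spacing, threshold, rule)
  pooled <- list(CPWMH = NA_real_, DWMH = NA_real_)
  for (cls in c("CPWMH", "DWMH")) {
    code <- if (cls == "CPWMH") 1L else 2L
    m <- cl$class_map == code
    dim(m) <- dim(wmh)
    if (sum(m) > 0) {
      iso <- resample_isotropic(m, spacing)
      fd <- fractal_dimension(boundary_voxels(iso$mask))
      pooled[[cls]] <- fd$fd
    }
  }
  list(lesions = tab, summary = aggregate_patient(tab, pooled))
}
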