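#' Analytic lesion phantoms with known geometry
#'
#' Builds a voxelized test body together with its analytic truth record, so
#' that shape-feature code can be validated against closed forms: balls and
#' ellipsoids (volume, area, principal moments), a dented ball (non-convex),
#' a one-voxel-thick segment (box-counting dimension 1) and a Menger-sponge
#' level set (box-counting dimension log 20 / log 3).
#'
#' @param kind one of `"ball"`, `"ellipsoid"`, `"dented_ball"`,
#'   `"menger_like"`, `"segment"`.
#' @param params named list of parameters: `r` (mm) for balls, `semiaxes`
#'   (length-3 mm) for ellipsoids, `dent_r` (mm) for the dent, `length`
#'   (voxels) for segments, `level` for the Menger set. `grid_shape`
#'   optionally fixes the array size; the primitive must fit.
#' @param spacing voxel spacing in mm (default isotropic 1 mm).
#' @return object of class `lesion_phantom`: list with `mask` (logical
#'   array), `spacing`, and `truth` (analytic volume, surface area, moment
#'   ratio and box-counting dimension where defined).
#' @examples
#' ph <- make_lesion_phantom("ball", list(r = 5))
#' sum(ph$mask) * prod(ph$spacing) / ph$truth$volume  # ~1
#' @export
make_lesion_phantom <- function(kind = c("ball", "ellipsoid", "dented_ball",
                                         "menger_like", "segment"),
                                params = list(), spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  stop_if(any(spacing <= 0), "spacing must be strictly positive")
  truth <- list(volume = NA_real_, surface_area = NA_real_,
                moment_ratio = NA_real_, fd = NA_real_)

  if (kind == "segment") {
    len <- as.integer(params$length %||% 40L)
    stop_if(len < 1, "segment length must be >= 1 voxel")
    gs <- as.integer(params$grid_shape %||% c(3L, 3L, len + 2L))
    stop_if(gs[3] < len, "segment exceeds grid along axis z")
    mask <- array(FALSE, gs)
    mask[2, 2, seq_len(len) + 1L] <- TRUE
    truth$fd <- 1
    truth$volume <- len * prod(spacing)
    return(new_phantom(kind, mask, spacing, truth, params))
  }

  if (kind == "menger_like") {
    level <- as.integer(params$level %||% 2L)
    stop_if(level < 1, "menger level must be >= 1")
    n <- 3L^level
    idx <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
    ok <- apply(idx, 1, function(r) {
      for (l in seq_len(level)) {
        dig <- (r %/% 3L^(l - 1L)) %% 3L
        if (sum(dig == 1L) >= 2L) return(FALSE)
      }
      TRUE
    })
    mask <- array(FALSE, c(n, n, n))
    mask[idx[ok, , drop = FALSE] + 1L] <- TRUE
    truth$fd <- log(20) / log(3)
    truth$volume <- sum(mask) * prod(spacing)
    return(new_phantom(kind, mask, spacing, truth, params))
  }

  # ellipsoidal bodies
  semi <- switch(kind,
    ball = rep(as.numeric(params$r %||% 10), 3),
    dented_ball = rep(as.numeric(params$r %||% 10), 3),
    ellipsoid = as.numeric(params$semiaxes %||% c(20, 5, 5)))
  stop_if(length(semi) != 3 || any(semi <= 0), "semi-axes/radius must be positive")

  need <- 2 * semi / spacing + 5   # voxels needed per axis
  gs <- as.integer(params$grid_shape %||% ceiling(need))
  for (ax in 1:3) {
    stop_if(gs[ax] < need[ax] - 1,
            sprintf("primitive exceeds grid along axis %s", c("x", "y", "z")[ax]))
  }
  centre <- (gs + 1) / 2
  mask <- ellipsoid_mask(gs, spacing, centre, semi)

  truth$volume <- 4 / 3 * pi * prod(semi)
  truth$surface_area <- ellipsoid_area(semi)
  truth$moment_ratio <- min(semi)^2 / max(semi)^2   # lambda_min / lambda_max
  truth$eccentricity <- sqrt(1 - truth$moment_ratio)

  if (kind == "dented_ball") {
    dent_r <- as.numeric(params$dent_r %||% (semi[1] * 0.6))
    dent_centre <- centre + c(semi[1] / spacing[1], 0, 0)  # on the surface
    dent <- ellipsoid_mask(gs, spacing, dent_centre, rep(dent_r, 3))
    mask <- mask & !dent
    truth$volume <- NA_real_      # no simple closed form; voxel count is used
    truth$surface_area <- NA_real_
    truth$convex <- FALSE
  } else {
    truth$convex <- TRUE
  }
  new_phantom(kind, mask, spacing, truth, params)
}

new_phantom <- function(kind, mask, spacing, truth, params) {
  structure(list(kind = kind, mask = mask, spacing = spacing,
                 truth = truth, params = params),
            class = "lesion_phantom")
}

ellipsoid_mask <- function(grid_shape, spacing, centre_vox, semi_mm) {
  i <- ((seq_len(grid_shape[1]) - centre_vox[1]) * spacing[1] / semi_mm[1])^2
  j <- ((seq_len(grid_shape[2]) - centre_vox[2]) * spacing[2] / semi_mm[2])^2
  k <- ((seq_len(grid_shape[3]) - centre_vox[3]) * spacing[3] / semi_mm[3])^2
  outer(outer(i, j, `+`), k, `+`) <= 1
}

# Thomsen's approximation, accurate to ~1%
ellipsoid_area <- function(s) {
  p <- 1.6075
  4 * pi * ((s[1]^p * s[2]^p + s[1]^p * s[3]^p + s[2]^p * s[3]^p) / 3)^(1 / p)
}

#' Specification for a whole-head segmentation phantom
#'
#' @param grid_shape voxels per axis.
#' @param spacing mm per axis; the study acquisition grid 0.9 x 0.9 x 4 mm
#'   is the default.
#' @param n_wmh number of planted WMH lesions.
#' @param wmh_r_range min/max WMH radius (mm).
#' @param n_infarcts number of planted infarct lesions.
#' @param seed integer; the phantom is a pure function of the spec and seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 28),
                         spacing = c(0.9, 0.9, 4.0),
                         n_wmh = 4, wmh_r_range = c(2, 6),
                         n_infarcts = 1, seed = 1L) {
  stop_if(any(spacing <= 0), "spacing must be strictly positive")
  stop_if(any(grid_shape < 16), "grid too small for a head phantom")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 n_wmh = n_wmh, wmh_r_range = wmh_r_range,
                 n_infarcts = n_infarcts, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Label dictionary used by the head phantom and the volumetric stage
#' @return named integer vector mapping tissue names to label values.
#' @export
head_labels <- function() {
  c(background = 0L, white_matter = 1L, cortical_gm = 2L,
    peripheral_csf = 3L, lateral_ventricles = 4L, wmh = 5L, infarct = 6L)
}

#' Whole-head segmentation phantom
#'
#' Nested-ellipsoid head: an intracranial ellipsoid holding (outside in) a
#' peripheral-CSF shell, a cortical grey-matter shell and a white-matter
#' core; two lateral-ventricle ellipsoids inside the core; WMH balls planted
#' in the white matter near the ventricles and deeper; optional infarcts.
#' A geometric lobe parcellation (frontal / parietal / temporal / occipital
#' by anterior-posterior and superior-inferior position) covers the brain
#' mask. Structures are planted without overlap; a placement that would
#' overlap an existing structure with a different label is an error.
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (integer array), `spacing`, `dict`,
#'   `lobe_map` (integer array: 1 frontal, 2 parietal, 3 temporal,
#'   4 occipital over the brain mask), and `truth` (per-label mm^3 from the
#'   construction).
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape; sp <- spec$spacing
  dict <- head_labels()
  centre <- (gs + 1) / 2
  extent <- gs * sp
  icv_semi <- extent / 2 - 2 * sp          # leave a background margin
  csf_th <- 3; gm_th <- 4                  # shell thickness, mm

  icv <- ellipsoid_mask(gs, sp, centre, icv_semi)
  inner1 <- ellipsoid_mask(gs, sp, centre, icv_semi - csf_th)
  inner2 <- ellipsoid_mask(gs, sp, centre, icv_semi - csf_th - gm_th)

  labels <- array(dict[["background"]], gs)
  labels[icv & !inner1] <- dict[["peripheral_csf"]]
  labels[inner1 & !inner2] <- dict[["cortical_gm"]]
  labels[inner2] <- dict[["white_matter"]]

  # two lateral ventricles, elongated along y, offset in x
  vent_semi <- pmax(icv_semi * c(0.10, 0.30, 0.18), sp * 1.5)
  for (sgn in c(-1, 1)) {
    vc <- centre + sgn * c(icv_semi[1] * 0.18 / sp[1], 0, 0)
    vent <- ellipsoid_mask(gs, sp, vc, vent_semi)
    labels <- plant(labels, vent, dict[["lateral_ventricles"]],
                    allowed = dict[["white_matter"]])
  }

  wm <- labels == dict[["white_matter"]]
  vent_mask <- labels == dict[["lateral_ventricles"]]

  # WMH: alternate periventricular (near the ventricle surface) and deep
  if (spec$n_wmh > 0) {
    wm_idx <- which(wm, arr.ind = TRUE)
    vox_mm <- sweep(wm_idx - 1, 2, sp, `*`)
    vent_mm <- voxel_coords(vent_mask, sp)
    dvent <- .set_distance_cpp(vox_mm, vent_mm)
    for (i in seq_len(spec$n_wmh)) {
      r <- runif(1, spec$wmh_r_range[1], spec$wmh_r_range[2])
      near <- i %% 2 == 1
      cand <- if (near) which(dvent > r & dvent < r + 2) else which(dvent > r + 8)
      stop_if(length(cand) == 0, "no room to plant a WMH lesion")
      c_idx <- wm_idx[sample(cand, 1), ]
      ball <- ellipsoid_mask(gs, sp, c_idx, rep(r, 3))
      labels <- plant(labels, ball, dict[["wmh"]], allowed = dict[["white_matter"]],
                      clip = wm)
    }
  }

  if (spec$n_infarcts > 0) {
    wm_now <- labels == dict[["white_matter"]]
    wm_idx <- which(wm_now, arr.ind = TRUE)
    for (i in seq_len(spec$n_infarcts)) {
      c_idx <- wm_idx[sample(nrow(wm_idx), 1), ]
      ball <- ellipsoid_mask(gs, sp, c_idx, rep(3, 3))
      labels <- plant(labels, ball, dict[["infarct"]],
                      allowed = dict[["white_matter"]], clip = wm_now)
    }
  }

  brain <- labels %in% dict[c("white_matter", "cortical_gm", "wmh", "infarct")]
  dim(brain) <- gs
  lobe_map <- lobe_parcellation(brain, centre)

  voxvol <- prod(sp)
  truth <- vapply(dict, function(l) sum(labels == l) * voxvol, numeric(1))
  list(labels = labels, spacing = sp, dict = dict, lobe_map = lobe_map,
       truth = truth, spec = spec)
}

# overwrite `where` voxels with `label`; voxels outside `allowed` label are an
# error unless clipped away first
plant <- function(labels, where, label, allowed, clip = NULL) {
  if (!is.null(clip)) where <- where & clip
  hit <- labels[where]
  bad <- !(hit %in% allowed)
  stop_if(any(bad), sprintf(
    "structure with label %d overlaps existing labels: %s",
    label, paste(unique(hit[bad]), collapse = ", ")))
  labels[where] <- label
  labels
}

# 1 frontal, 2 parietal, 3 temporal, 4 occipital.
# y is the anterior-posterior axis, z inferior-superior.
lobe_parcellation <- function(brain, centre) {
  gs <- dim(brain)
  lob <- array(0L, gs)
  jj <- rep(seq_len(gs[2]), each = gs[1])
  kk <- rep(seq_len(gs[3]), each = gs[1] * gs[2])
  anterior <- array(rep(jj < centre[2], gs[3]), gs)
  superior <- array(kk >= centre[3], gs)
  lob[brain & anterior & superior] <- 1L    # frontal
  lob[brain & !anterior & superior] <- 2L   # parietal
  lob[brain & anterior & !superior] <- 3L   # temporal
  lob[brain & !anterior & !superior] <- 4L  # occipital
  lob
}

#' @export
lobe_names <- function() c("frontal", "parietal", "temporal", "occipital")
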