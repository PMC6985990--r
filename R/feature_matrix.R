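#' Names of the clustering features
#'
#' The feature set used for phenotype clustering: the five volume
#' fractions, periventricular/confluent and deep WMH fractions per lobe,
#' the five WMH shape means (with separate pooled FD per class), infarct
#' counts overall and per lobe, and normalized cerebral blood flow.
#'
#' @return character vector of column names.
#' @export
clustering_features <- function() {
  lobes <- lobe_names()
  c("bpf", "wm_frac", "gm_frac", "csf_frac", "ventricle_frac",
    paste0("cpwmh_frac_", lobes), paste0("dwmh_frac_", lobes),
    "solidity", "convexity", "concavity_index", "eccentricity",
    "fd_cpwmh", "fd_dwmh",
    "n_lacunes", "n_cortical_infarcts", "n_subcortical_infarcts",
    paste0("cortical_infarct_", lobes), paste0("lacunes_", lobes),
    "cbf_norm")
}

#' Assemble the patient-by-feature table
#'
#' Joins the per-patient outputs of the volumetric, WMH-shape and infarct
#' stages into one row per included patient. Per-lobe WMH fractions are the
#' class-specific WMH volume within the lobe divided by ICV, in percent, so
#' the lobe fractions of a class sum to the class's total WMH fraction.
#'
#' @param fractions data frame: `patient_id`, the five volume fractions.
#' @param wmh_lobe data frame: `patient_id`, `cpwmh_frac_<lobe>` and
#'   `dwmh_frac_<lobe>` columns (percent of ICV).
#' @param shape data frame: `patient_id`, `solidity`, `convexity`,
#'   `concavity_index`, `eccentricity`, `fd_cpwmh`, `fd_dwmh`.
#' @param infarcts data frame: `patient_id`, infarct counts and per-lobe
#'   indicators/counts.
#' @param cbf data frame: `patient_id`, `cbf_norm`.
#' @return data frame with `patient_id` plus [clustering_features()]
#'   columns.
#' @export
assemble_features <- function(fractions, wmh_lobe, shape, infarcts, cbf) {
  sources <- list(fractions = fractions, wmh_lobe = wmh_lobe, shape = shape,
                  infarcts = infarcts, cbf = cbf)
  ids <- fractions$patient_id
  for (nm in names(sources)) {
    stop_if(!"patient_id" %in% names(sources[[nm]]),
            sprintf("source '%s' lacks patient_id", nm))
    missing <- setdiff(ids, sources[[nm]]$patient_id)
    stop_if(length(missing) > 0,
            sprintf("patients missing from source '%s': %s", nm,
                    paste(head(missing, 5), collapse = ", ")))
  }
  out <- fractions
  for (nm in c("wmh_lobe", "shape", "infarcts", "cbf")) {
    out <- merge(out, sources[[nm]], by = "patient_id", sort = FALSE)
  }
  cols <- clustering_features()
  stop_if(!all(cols %in% names(out)),
          paste("assembled table lacks columns:",
                paste(setdiff(cols, names(out)), collapse = ", ")))
  out[, c("patient_id", cols)]
}

#' Per-lobe WMH fractions from the class map and lobe parcellation
#'
#' Class-specific WMH volume within each lobe divided by ICV, in percent,
#' so that a class's lobe fractions sum to its total WMH fraction.
#'
#' @param class_map integer array from [classify_wmh()] (1 = CPWMH,
#'   2 = DWMH).
#' @param lobe_map integer array (1..4 per [lobe_names()]) covering the
#'   brain mask.
#' @param spacing voxel spacing in mm.
#' @param icv intracranial volume in mm^3.
#' @return one-row data frame with `cpwmh_frac_<lobe>` and
#'   `dwmh_frac_<lobe>` columns (percent of ICV).
#' @export
wmh_lobe_fractions <- function(class_map, lobe_map, spacing, icv) {
  stop_if(!identical(dim(class_map), dim(lobe_map)), "maps must share one grid")
  stop_if(icv <= 0, "icv must be positive")
  voxvol <- prod(spacing)
  out <- list()
  for (cls in c(1L, 2L)) {
    prefix <- if (cls == 1L) "cpwmh_frac_" else "dwmh_frac_"
    for (l in seq_along(lobe_names())) {
      v <- sum(class_map == cls & lobe_map == l) * voxvol
      out[[paste0(prefix, lobe_names()[l])]] <- 100 * v / icv
    }
  }
  as.data.frame(out)
}

#' Default per-column normalization methods
#'
#' Which columns are treated as normally distributed (Z-scored) versus
#' scaled to the 0--2 range is declared here rather than decided by a
#' data-dependent test: volume fractions, shape means and normalized CBF
#' are Z-scored; counts, indicators and the zero-inflated per-lobe WMH
#' fractions use the 0--2 min-max scaling.
#'
#' @return named character vector, values `"zscore"` or `"minmax02"`.
#' @export
default_normality <- function() {
  cols <- clustering_features()
  method <- setNames(rep("minmax02", length(cols)), cols)
  zcols <- c("bpf", "wm_frac", "gm_frac", "csf_frac", "ventricle_frac",
             "solidity", "convexity", "concavity_index", "eccentricity",
             "fd_cpwmh", "fd_dwmh", "cbf_norm")
  method[zcols] <- "zscore"
  method
}

#' Normalize the feature table
#'
#' Columns declared normal are Z-scored over their observed values;
#' all other columns are affinely mapped so the observed minimum becomes 0
#' and the maximum 2 (binary indicators land on \{0, 2\}). The scaling
#' record makes the transformation invertible via [denormalize_features()].
#'
#' @param table feature data frame (a `patient_id` column is carried
#'   through).
#' @param methods named character vector per column (`"zscore"` /
#'   `"minmax02"`); defaults to [default_normality()] for known columns and
#'   `"zscore"` otherwise.
#' @return list of class `normalized_matrix`: `x` (numeric matrix, NAs
#'   preserved), `scaling` (data frame of per-column method and
#'   parameters), `patient_id`, `imputed` (empty until
#'   [impute_missing()]).
#' @export
normalize_features <- function(table, methods = NULL) {
  ids <- table$patient_id %||% seq_len(nrow(table))
  num <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  if (is.null(methods)) {
    methods <- default_normality()
  }
  x <- matrix(NA_real_, nrow(num), ncol(num),
              dimnames = list(NULL, names(num)))
  scaling <- data.frame(column = names(num), method = NA_character_,
                        p1 = NA_real_, p2 = NA_real_)
  for (j in seq_along(num)) {
    v <- as.numeric(num[[j]])
    obs <- v[!is.na(v)]
    stop_if(length(unique(obs)) < 2,
            sprintf("column '%s' is constant; normalization undefined", names(num)[j]))
    m <- methods[[names(num)[j]]] %||% "zscore"
    if (m == "zscore") {
      mu <- mean(obs); sdev <- sd(obs)
      x[, j] <- (v - mu) / sdev
      scaling[j, c("method", "p1", "p2")] <- list("zscore", mu, sdev)
    } else {
      lo <- min(obs); hi <- max(obs)
      x[, j] <- 2 * (v - lo) / (hi - lo)
      scaling[j, c("method", "p1", "p2")] <- list("minmax02", lo, hi)
    }
  }
  structure(list(x = x, scaling = scaling, patient_id = ids,
                 imputed = data.frame(column = character(), n = integer())),
            class = "normalized_matrix")
}

#' Invert the normalization using the stored scaling record
#' @param nm a `normalized_matrix`.
#' @return data frame of raw-scale values.
#' @export
denormalize_features <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  out <- nm$x
  for (j in seq_len(ncol(out))) {
    s <- nm$scaling[j, ]
    out[, j] <- if (s$method == "zscore") out[, j] * s$p2 + s$p1
                else out[, j] / 2 * (s$p2 - s$p1) + s$p1
  }
  cbind(data.frame(patient_id = nm$patient_id), as.data.frame(out))
}

#' Fill missing entries of a normalized matrix
#'
#' The default policy sets a missing entry to the column's
#' post-normalization centre: 0 for Z-scored columns (the observed mean)
#' and the observed median for 0--2 scaled columns. This is neutral in the
#' Ward distance. Complete-case analysis is available via
#' `policy = "complete"` (drops patients with any missing value).
#'
#' @param nm a `normalized_matrix`.
#' @param policy `"center"` or `"complete"`.
#' @return a `normalized_matrix` without missing values; the imputation
#'   record lists per-column fill counts.
#' @export
impute_missing <- function(nm, policy = c("center", "complete")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  policy <- match.arg(policy)
  x <- nm$x
  full_missing <- colSums(!is.na(x)) == 0
  stop_if(any(full_missing),
          paste("columns fully missing:",
                paste(colnames(x)[full_missing], collapse = ", ")))
  if (policy == "complete") {
    keep <- complete.cases(x)
    nm$x <- x[keep, , drop = FALSE]
    nm$patient_id <- nm$patient_id[keep]
    nm$imputed <- data.frame(column = "(complete-case)", n = sum(!keep))
    return(nm)
  }
  rec <- list()
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    centre <- if (nm$scaling$method[j] == "zscore") 0 else median(x[!miss, j])
    x[miss, j] <- centre
    rec[[length(rec) + 1]] <- data.frame(column = colnames(x)[j], n = sum(miss))
  }
  nm$x <- x
  nm$imputed <- if (length(rec)) do.call(rbind, rec)
                else data.frame(column = character(), n = integer())
  nm
}
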