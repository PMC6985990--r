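#' Brain tissue volumes
#'
#' Container for the per-patient tissue volumes. Total brain volume is the
#' sum of white matter, grey matter, WMH and infarct volume; intracranial
#' volume (ICV) adds the lateral ventricles and the peripheral CSF.
#'
#' @param wm,gm,wmh,infarct,ventricles,peripheral_csf tissue volumes.
#' @param units `"mm3"` (storage unit) or `"ml"`.
#' @return object of class `brain_volumes` (all fields in mm^3).
#' @examples
#' v <- brain_volumes(450, 550, 8, 2, 25, 265, units = "ml")
#' v$total_brain / 1000  # 1010 ml
#' @export
brain_volumes <- function(wm, gm, wmh, infarct, ventricles, peripheral_csf,
                          units = c("mm3", "ml")) {
  units <- match.arg(units)
  f <- if (units == "ml") 1000 else 1
  vals <- c(wm = wm, gm = gm, wmh = wmh, infarct = infarct,
            ventricles = ventricles, peripheral_csf = peripheral_csf) * f
  stop_if(any(!is.finite(vals)) || any(vals < 0), "volumes must be finite and >= 0")
  out <- as.list(vals)
  out$total_brain <- out$wm + out$gm + out$wmh + out$infarct
  out$icv <- out$total_brain + out$ventricles + out$peripheral_csf
  structure(out, class = "brain_volumes")
}

#' @export
print.brain_volumes <- function(x, ...) {
  ml <- unlist(x) / 1000
  cat("Brain volumes (ml):\n")
  print(round(ml, 1))
  invisible(x)
}

#' Compute tissue volumes from a segmentation label volume
#'
#' Volume per label is voxel count times voxel volume; total brain and ICV
#' follow by summation.
#'
#' @param seg list with `labels` (integer 3D array), `spacing` (mm) and
#'   optionally `dict` (named label dictionary; default [head_labels()]).
#' @return a [brain_volumes()] object with an extra `per_label` attribute
#'   (mm^3 per label).
#' @export
compute_volumes <- function(seg) {
  dict <- seg$dict %||% head_labels()
  labs <- seg$labels
  stop_if(is.null(dim(labs)) || length(dim(labs)) != 3, "labels must be a 3D array")
  present <- sort(unique(as.integer(labs)))
  unknown <- setdiff(present, unname(dict))
  stop_if(length(unknown) > 0,
          sprintf("unknown labels present: %s", paste(unknown, collapse = ", ")))
  voxvol <- prod(seg$spacing)
  per <- vapply(dict, function(l) sum(labs == l) * voxvol, numeric(1))
  v <- brain_volumes(per[["white_matter"]], per[["cortical_gm"]], per[["wmh"]],
                     per[["infarct"]], per[["lateral_ventricles"]],
                     per[["peripheral_csf"]])
  attr(v, "per_label") <- per
  v
}

#' Volume fractions as a percentage of intracranial volume
#'
#' Brain parenchymal fraction (BPF) and the tissue fractions are the
#' respective volumes divided by ICV, expressed in percent. The identity
#' `bpf + csf_frac + ventricle_frac = 100` holds by construction.
#'
#' @param v a [brain_volumes()] object.
#' @return named list of fractions (percent of ICV).
#' @export
compute_fractions <- function(v) {
  stopifnot(inherits(v, "brain_volumes"))
  stop_if(v$icv <= 0, "icv must be positive")
  pct <- function(x) 100 * x / v$icv
  list(bpf = pct(v$total_brain), wm_frac = pct(v$wm), gm_frac = pct(v$gm),
       csf_frac = pct(v$peripheral_csf), ventricle_frac = pct(v$ventricles),
       wmh_frac = pct(v$wmh))
}

#' Normalize total cerebral blood flow by brain volume
#'
#' Expresses total CBF per 100 ml of total brain volume (the field
#' convention for "flow as a fraction of brain volume"); the denominator
#' convention is carried in the result for auditability.
#'
#' @param total_flow total CBF in ml/min.
#' @param v a [brain_volumes()] object.
#' @param per reference brain volume in ml (default 100).
#' @return list with `total_flow` and `normalized_flow`
#'   (ml/min per `per` ml brain).
#' @export
normalize_cbf <- function(total_flow, v, per = 100) {
  stopifnot(inherits(v, "brain_volumes"))
  stop_if(!is.finite(total_flow) || total_flow < 0, "flow must be finite and >= 0")
  stop_if(v$total_brain <= 0, "total brain volume must be positive")
  list(total_flow = total_flow,
       normalized_flow = per * total_flow / (v$total_brain / 1000),
       per_ml = per)
}

#' Study-sample exclusion accounting
#'
#' Applies the exclusion cascade to an enrolment manifest. Categories are
#' mutually exclusive by precedence: no MRI, then missing sequences, then
#' artefacts; a patient flagged for several reasons is counted only once,
#' under the first matching category.
#'
#' @param manifest data frame with one row per enrolled patient: column
#'   `patient_id` plus logical columns `no_mri`, `missing_sequence`,
#'   `artefact`.
#' @return list of class `exclusion_report` with the category counts and
#'   `n_included`.
#' @export
apply_exclusions <- function(manifest) {
  need <- c("patient_id", "no_mri", "missing_sequence", "artefact")
  stop_if(!all(need %in% names(manifest)),
          paste("manifest must have columns:", paste(need, collapse = ", ")))
  stop_if(anyDuplicated(manifest$patient_id) > 0, "duplicate patient identifiers")
  cat1 <- manifest$no_mri
  cat2 <- !cat1 & manifest$missing_sequence
  cat3 <- !cat1 & !cat2 & manifest$artefact
  out <- list(n_enrolled = nrow(manifest),
              n_no_mri = sum(cat1),
              n_missing_sequences = sum(cat2),
              n_artefacts = sum(cat3),
              included_ids = manifest$patient_id[!(cat1 | cat2 | cat3)])
  out$n_included <- out$n_enrolled - out$n_no_mri - out$n_missing_sequences -
    out$n_artefacts
  structure(out, class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Enrolled %d; excluded: %d no MRI, %d missing sequences, %d artefacts; included %d\n",
              x$n_enrolled, x$n_no_mri, x$n_missing_sequences, x$n_artefacts,
              x$n_included))
  invisible(x)
}
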