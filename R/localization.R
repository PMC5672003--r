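#' Deep sucrose-gradient peak test
#'
#' Membrane vesicles penetrate deep into a sucrose velocity gradient while
#' soluble proteins stay in the top fractions.  A protein's dominant
#' reproducible sucrose peak counts as "deep" when its center lies strictly
#' beyond the boundary fraction.
#'
#' @param center Peak center (continuous fraction); `NA` if the protein has
#'   no reproducible sucrose peak.
#' @param boundary_fraction Last fraction still regarded as shallow.
#' @return Logical vector (`NA` in, `NA` out).
#' @export
sucrose_deep_peak <- function(center, boundary_fraction = 8) {
  center > boundary_fraction
}

#' Sucrose evidence category for a protein
#'
#' @param center Dominant reproducible sucrose peak center, or `NA` when no
#'   reproducible peak exists.
#' @param boundary_fraction Passed to [sucrose_deep_peak()].
#' @return Character vector over
#'   `c("sucrose_deep", "sucrose_shallow", "no_sucrose_peak")`.
#' @export
sucrose_evidence <- function(center, boundary_fraction = 8) {
  ifelse(is.na(center), "no_sucrose_peak",
         ifelse(sucrose_deep_peak(center, boundary_fraction),
                "sucrose_deep", "sucrose_shallow"))
}

#' Call true membrane-associated proteins
#'
#' Only proteins detected in the cholate-solubilized microsome profiling are
#' considered.  A protein is membrane-associated when it is not detected in
#' the cytosol at all (evidence `cholate_only`), or when it is detected in
#' both compartments but its sucrose-gradient peak lies beyond the boundary
#' fraction (evidence `sucrose_deep`).  Cholate-detected proteins that are
#' also cytosolic and lack a deep sucrose peak are cytosolic contaminants.
#'
#' @param in_cholate Logical: detected in the cholate-soluble profiling
#'   (must be `TRUE`; other proteins are not candidates).
#' @param in_cytosol Logical: detected in the cytosolic (soluble) dataset.
#' @param sucrose Evidence string from [sucrose_evidence()] (ignored for
#'   proteins absent from the cytosol).
#' @return Data frame with columns `status`
#'   (`"membrane_associated"`/`"cytosolic_contaminant"`) and `evidence`.
#' @export
call_membrane <- function(in_cholate, in_cytosol, sucrose) {
  if (!all(in_cholate))
    stop("membrane calls are defined only for cholate-detected proteins")
  evidence <- ifelse(!in_cytosol, "cholate_only", sucrose)
  bad <- in_cytosol &
    !sucrose %in% c("sucrose_deep", "sucrose_shallow", "no_sucrose_peak")
  if (any(bad)) stop("invalid sucrose evidence: ",
                     paste(unique(sucrose[bad]), collapse = ", "))
  status <- ifelse(evidence %in% c("cholate_only", "sucrose_deep"),
                   "membrane_associated", "cytosolic_contaminant")
  data.frame(status = status, evidence = evidence)
}

#' Flag dual-localized proteins with an oligomerization shift
#'
#' For membrane-associated proteins that also have a cytosolic pool, the
#' ratio of the cytosolic to the membrane apparent mass flags a change of
#' oligomerization state between compartments: shifted when the ratio
#' exceeds 2 or falls below 0.5.  Cytosolic proteins at or above the
#' large-complex cutoff are excluded from the dual-localization comparison
#' (their sucrose mobility cannot distinguish them from membrane vesicles)
#' and carry no shift verdict.
#'
#' @param m_app_cytosol_kda Apparent mass in the soluble dataset (kDa).
#' @param m_app_membrane_kda Apparent mass in the membrane dataset (kDa).
#' @param large_cytosolic_cutoff_kda Exclusion cutoff for very large
#'   cytosolic species (kDa).
#' @param ratio_bounds Shift thresholds `(low, high)` on the mass ratio.
#' @return Data frame with `ratio`, `excluded_large_cytosolic`, `shifted`
#'   (`NA` for excluded proteins).
#' @export
flag_dual_localized <- function(m_app_cytosol_kda, m_app_membrane_kda,
                                large_cytosolic_cutoff_kda = 450,
                                ratio_bounds = c(0.5, 2)) {
  if (any(c(m_app_cytosol_kda, m_app_membrane_kda) <= 0, na.rm = TRUE))
    stop("masses must be positive")
  ratio <- m_app_cytosol_kda / m_app_membrane_kda
  excluded <- m_app_cytosol_kda >= large_cytosolic_cutoff_kda
  shifted <- ifelse(excluded, NA,
                    ratio > ratio_bounds[2] | ratio < ratio_bounds[1])
  data.frame(ratio = ratio, excluded_large_cytosolic = excluded,
             shifted = shifted)
}
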