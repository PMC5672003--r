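#' Apparent oligomerization ratio R_app
#'
#' The ratio of the apparent native mass to the annotated monomer mass.
#' `R_app` near 1 indicates a monomer; values of 2 and above indicate an
#' oligomer or complex; values well below 1 indicate degradation products.
#'
#' @param m_app_kda Apparent mass (kDa), positive.
#' @param m_mono_kda Monomer mass (kDa), positive.
#' @return `m_app_kda / m_mono_kda`, vectorized.
#' @export
compute_rapp <- function(m_app_kda, m_mono_kda) {
  if (any(m_app_kda <= 0, na.rm = TRUE) || any(m_mono_kda <= 0, na.rm = TRUE))
    stop("masses must be positive")
  m_app_kda / m_mono_kda
}

#' Classify oligomerization state from R_app
#'
#' Boundary-inclusive classes: degraded `R_app < 0.5`; monomer
#' `0.5 <= R_app < 2`; small complex `2 <= R_app < 10`; large complex
#' `R_app >= 10`.
#'
#' @param r_app Nonnegative numeric vector.
#' @param boundaries Class boundaries `(degraded/monomer, monomer/small,
#'   small/large)`; each boundary value belongs to the higher class.
#' @return Character vector over
#'   `c("degraded", "monomer", "small_complex", "large_complex")` (`NA` in,
#'   `NA` out).
#' @export
classify_state <- function(r_app, boundaries = c(0.5, 2, 10)) {
  if (any(r_app < 0, na.rm = TRUE)) stop("r_app must be nonnegative")
  ifelse(r_app < boundaries[1], "degraded",
  ifelse(r_app < boundaries[2], "monomer",
  ifelse(r_app < boundaries[3], "small_complex", "large_complex")))
}

#' Complex prediction rule
#'
#' A protein peak is predicted to elute as a complex when it is reproducible
#' across the biological replicates and its `R_app` reaches the threshold in
#' at least one replicate.
#'
#' @param r_app_rep1,r_app_rep2 Per-replicate `R_app` values (`NA` allowed).
#' @param reproducible Logical: does the peak pass the replicate-shift rule?
#' @param threshold Complex-call threshold on `R_app`.
#' @return Logical vector.
#' @export
predict_complex <- function(r_app_rep1, r_app_rep2, reproducible,
                            threshold = 2) {
  reproducible & (pmax(r_app_rep1, r_app_rep2, na.rm = TRUE) >= threshold)
}

#' Oligomerization calls for labelled reproducible peaks
#'
#' Joins labelled peaks (see [assign_labels()]) with monomer masses and
#' produces per-peak `R_app` values (per replicate and on the geometric-mean
#' mass), the oligomer class, and the complex call.  Peaks without a mass
#' (void/unresolved) get state `"unresolved"` and no `R_app`.
#'
#' @param labeled Data frame from [assign_labels()] with an added
#'   `protein_id` column.
#' @param annotations Data frame with `protein_id` and `monomer_mass_kda`.
#' @param threshold Complex-call threshold on `R_app`.
#' @return `labeled` extended with `monomer_mass_kda`, `r_app_rep1`,
#'   `r_app_rep2`, `r_app_mean`, `state`, `is_complex`.
#' @export
call_oligomers <- function(labeled, annotations, threshold = 2) {
  stopifnot(all(c("protein_id", "monomer_mass_kda") %in% names(annotations)))
  m_mono <- annotations$monomer_mass_kda[
    match(labeled$protein_id, annotations$protein_id)]
  if (nrow(labeled) > 0 && any(is.na(m_mono)))
    stop("missing monomer mass annotation for: ",
         paste(unique(labeled$protein_id[is.na(m_mono)]), collapse = ", "))
  out <- labeled
  out$monomer_mass_kda <- m_mono
  out$r_app_rep1 <- ifelse(out$resolved, out$m_app_rep1 / m_mono, NA_real_)
  out$r_app_rep2 <- ifelse(out$resolved, out$m_app_rep2 / m_mono, NA_real_)
  out$r_app_mean <- ifelse(out$resolved, out$m_app_mean / m_mono, NA_real_)
  out$state <- ifelse(out$resolved, classify_state(out$r_app_mean), "unresolved")
  out$is_complex <- ifelse(out$resolved,
                           predict_complex(out$r_app_rep1, out$r_app_rep2,
                                           TRUE, threshold),
                           FALSE)
  out
}
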