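#' Match fitted peaks across two biological replicates
#'
#' A peak is reproducible when the two replicates place it within
#' `max_shift` fractions of each other (inclusive).  Matching is one-to-one
#' and greedy by smallest shift: candidate cross-replicate pairs are ranked
#' by `|center_1 - center_2|` and accepted in order, each peak used at most
#' once; pairs over the threshold are rejected.  Because retained peaks
#' within a replicate are at least 4 fractions apart while the shift
#' tolerance is 2, at most one partner can ever lie within tolerance, and
#' greedy matching coincides with the optimal assignment.  Unmatched peaks
#' are logged and excluded from all downstream results.
#'
#' @param model_rep1,model_rep2 `peakfit` objects for the same protein and
#'   scheme (numeric center vectors are also accepted).
#' @param max_shift Largest accepted center shift, in fractions.
#' @return List with `pairs` (data frame `center_rep1`, `center_rep2`,
#'   `shift`, `amplitude_rep1`, `amplitude_rep2`) and `unmatched` (data
#'   frame `replicate`, `center`).
#' @export
match_peaks <- function(model_rep1, model_rep2, max_shift = 2) {
  p1 <- peak_table(model_rep1)
  p2 <- peak_table(model_rep2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  pairs <- data.frame(center_rep1 = numeric(0), center_rep2 = numeric(0),
                      shift = numeric(0), amplitude_rep1 = numeric(0),
                      amplitude_rep2 = numeric(0))
  used1 <- logical(n1); used2 <- logical(n2)
  if (n1 > 0 && n2 > 0) {
    cand <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    cand$shift <- abs(p1$center[cand$i] - p2$center[cand$j])
    cand <- cand[cand$shift <= max_shift, , drop = FALSE]
    cand <- cand[order(cand$shift, cand$i, cand$j), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used1[i] || used2[j]) next
      used1[i] <- TRUE; used2[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        center_rep1 = p1$center[i], center_rep2 = p2$center[j],
        shift = cand$shift[r],
        amplitude_rep1 = p1$amplitude[i], amplitude_rep2 = p2$amplitude[j]))
    }
  }
  unmatched <- rbind(
    if (any(!used1)) data.frame(replicate = "rep1", center = p1$center[!used1]),
    if (any(!used2)) data.frame(replicate = "rep2", center = p2$center[!used2]))
  if (is.null(unmatched))
    unmatched <- data.frame(replicate = character(0), center = numeric(0))
  pairs <- pairs[order(pairs$center_rep1), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = unmatched)
}

peak_table <- function(x) {
  if (inherits(x, "peakfit")) {
    if (x$n_peaks == 0L)
      data.frame(center = numeric(0), amplitude = numeric(0))
    else x$peaks[, c("center", "amplitude")]
  } else {
    data.frame(center = as.numeric(x), amplitude = rep(NA_real_, length(x)))
  }
}

#' Assign P-labels and apparent masses to reproducible peaks
#'
#' Reproducible peaks of one protein are labelled P1, P2, ... in decreasing
#' apparent mass (equivalently, increasing mean elution fraction).  Apparent
#' masses are computed per replicate via the calibration line for resolved
#' peaks; the per-peak summary mass is the geometric mean of the replicate
#' masses, since masses live on a log scale along the column.  A peak is
#' resolved only when both replicate centers are at least one fraction past
#' the void; void peaks keep their label but carry no mass and are flagged.
#'
#' @param pairs `pairs` data frame from [match_peaks()].
#' @param cal A `sec_calibration` object.
#' @param void_fraction Void fraction index or `NULL`.
#' @return Data frame with columns `label`, `center_rep1`, `center_rep2`,
#'   `shift`, `resolved`, `m_app_rep1`, `m_app_rep2`, `m_app_mean`,
#'   `extrapolated` (masses `NA` for unresolved peaks).
#' @export
assign_labels <- function(pairs, cal, void_fraction = NULL) {
  if (nrow(pairs) == 0L)
    return(cbind(pairs[, 0, drop = FALSE],
                 data.frame(label = character(0), center_rep1 = numeric(0),
                            center_rep2 = numeric(0), shift = numeric(0),
                            resolved = logical(0), m_app_rep1 = numeric(0),
                            m_app_rep2 = numeric(0), m_app_mean = numeric(0),
                            extrapolated = logical(0))))
  resolved <- is_resolved(pairs$center_rep1, void_fraction) &
    is_resolved(pairs$center_rep2, void_fraction)
  m1 <- apparent_mass(cal, pairs$center_rep1)
  m2 <- apparent_mass(cal, pairs$center_rep2)
  m_app_rep1 <- ifelse(resolved, m1$mass_kda, NA_real_)
  m_app_rep2 <- ifelse(resolved, m2$mass_kda, NA_real_)
  m_app_mean <- sqrt(m_app_rep1 * m_app_rep2)
  # earlier elution = larger mass; ordering by mean center is ordering by
  # decreasing mass and also ranks void peaks (no mass) first
  ord <- order((pairs$center_rep1 + pairs$center_rep2) / 2)
  out <- data.frame(
    label = paste0("P", seq_along(ord)),
    center_rep1 = pairs$center_rep1[ord],
    center_rep2 = pairs$center_rep2[ord],
    shift = pairs$shift[ord],
    resolved = resolved[ord],
    m_app_rep1 = m_app_rep1[ord],
    m_app_rep2 = m_app_rep2[ord],
    m_app_mean = m_app_mean[ord],
    extrapolated = ifelse(resolved[ord], m1$extrapolated[ord] | m2$extrapolated[ord], NA))
  rownames(out) <- NULL
  out
}
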