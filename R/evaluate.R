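#' Score pipeline results against simulation ground truth
#'
#' Matches reported reproducible peaks to the true resolved peak positions
#' (greedy, within `tolerance` fractions of the true center) and computes
#' recovery metrics for every stage: peak recall/precision and center RMSE,
#' the oligomer-state confusion matrix, complex-call sensitivity and
#' specificity, and the membrane-call confusion matrix with contaminant
#' recall.
#'
#' @param run A `pcp_run` bundle from [run_pipeline()].
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param tolerance Center tolerance (fractions) for counting a true peak
#'   as recovered.
#' @return List of metrics: `peak_recall`, `peak_precision`, `center_rmse`,
#'   `state_confusion`, `state_accuracy`, `complex_sensitivity`,
#'   `complex_specificity`, `membrane_confusion`, `contaminant_recall`.
#' @export
evaluate_against_truth <- function(run, truth, tolerance = 1) {
  lab <- run$labeled_peaks
  tp <- truth$sec_peaks[!truth$sec_peaks$is_void, , drop = FALSE]
  # only proteins that entered the comparison (detected, id-accepted)
  scored <- intersect(unique(tp$protein_id), truth$proteins$protein_id[
    truth$proteins$accepted_id])
  if (!all(unique(lab$protein_id) %in% truth$proteins$protein_id))
    stop("results contain proteins unknown to the ground truth")

  n_true <- 0L; n_rep <- 0L; n_match <- 0L; sqerr <- numeric(0)
  for (p in scored) {
    true_c <- tp$mu[tp$protein_id == p]
    rep_c <- (lab$center_rep1[lab$protein_id == p] +
                lab$center_rep2[lab$protein_id == p]) / 2
    n_true <- n_true + length(true_c)
    n_rep <- n_rep + length(rep_c)
    if (length(true_c) == 0 || length(rep_c) == 0) next
    m <- match_peaks(true_c, rep_c, max_shift = tolerance)$pairs
    n_match <- n_match + nrow(m)
    sqerr <- c(sqerr, (m$center_rep1 - m$center_rep2)^2)
  }

  # per-protein complex call: any reproducible resolved peak called complex
  calls <- run$oligomer_calls
  pred_complex <- tapply(calls$is_complex, calls$protein_id, any)
  prot <- truth$proteins[truth$proteins$protein_id %in% names(pred_complex), ]
  pc <- pred_complex[prot$protein_id]
  tc <- prot$is_complex
  sens <- if (any(tc)) mean(pc[tc]) else NA_real_
  spec <- if (any(!tc)) mean(!pc[!tc]) else NA_real_

  # dominant-peak state confusion
  dom <- dominant_peaks(calls[calls$resolved, , drop = FALSE])
  st_true <- truth$proteins$state[match(dom$protein_id,
                                        truth$proteins$protein_id)]
  state_conf <- table(truth = st_true, predicted = dom$state)

  membrane_conf <- NULL; cont_recall <- NA_real_
  if (!is.null(run$membrane_calls)) {
    mt <- truth$proteins$membrane_status[
      match(run$membrane_calls$protein_id, truth$proteins$protein_id)]
    membrane_conf <- table(truth = mt, predicted = run$membrane_calls$status)
    is_cont <- mt == "cytosolic_contaminant"
    if (any(is_cont))
      cont_recall <- mean(run$membrane_calls$status[is_cont] ==
                            "cytosolic_contaminant")
  }

  list(peak_recall = if (n_true) n_match / n_true else NA_real_,
       peak_precision = if (n_rep) n_match / n_rep else NA_real_,
       center_rmse = if (length(sqerr)) sqrt(mean(sqerr)) else NA_real_,
       state_confusion = state_conf,
       state_accuracy = if (nrow(dom)) mean(st_true == dom$state) else NA_real_,
       complex_sensitivity = sens,
       complex_specificity = spec,
       membrane_confusion = membrane_conf,
       contaminant_recall = cont_recall)
}
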