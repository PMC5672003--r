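#' Co-immunoprecipitation interactor acceptance rule
#'
#' Presence/absence filter over a 3-replicate antibody vs preimmune-control
#' CoIP-MS design.  A protein is accepted as an interactor when it was
#' identified with at least two peptides and either (a) detected in two of
#' the three antibody replicates with zero intensity in every control, or
#' (b) detected in all three antibody replicates and in at most one control.
#' Intensities themselves are never compared; "identified" means nonzero
#' XIC intensity in that replicate.
#'
#' @param peptide_count Number of identifying peptides.
#' @param antibody_hits Antibody replicates with nonzero intensity (0-3).
#' @param control_hits Control replicates with nonzero intensity (0-3).
#' @param n_replicates Replicates per arm of the design.
#' @return Logical vector.
#' @examples
#' accept_interactor(2, 2, 0)  # TRUE
#' accept_interactor(2, 3, 1)  # TRUE
#' accept_interactor(2, 2, 1)  # FALSE
#' @export
accept_interactor <- function(peptide_count, antibody_hits, control_hits,
                              n_replicates = 3) {
  if (any(antibody_hits < 0 | antibody_hits > n_replicates |
          control_hits < 0 | control_hits > n_replicates))
    stop("replicate hit counts must lie in [0, ", n_replicates, "]")
  peptide_count >= 2 &
    ((antibody_hits >= n_replicates - 1 & control_hits == 0) |
       (antibody_hits == n_replicates & control_hits <= 1))
}

#' Filter a CoIP-MS detection table
#'
#' Applies [accept_interactor()] to a table of per-replicate intensities
#' with columns `protein_id`, `peptides`, `ab1..ab3`, `ctl1..ctl3`.
#'
#' @param table Data frame in the layout above.
#' @return The accepted rows, extended with `antibody_hits` and
#'   `control_hits` counts.
#' @export
filter_interactors <- function(table) {
  ab <- grep("^ab[0-9]+$", names(table), value = TRUE)
  ctl <- grep("^ctl[0-9]+$", names(table), value = TRUE)
  stopifnot(length(ab) == 3L, length(ctl) == 3L,
            all(c("protein_id", "peptides") %in% names(table)))
  table$antibody_hits <- rowSums(table[, ab, drop = FALSE] > 0)
  table$control_hits <- rowSums(table[, ctl, drop = FALSE] > 0)
  keep <- accept_interactor(table$peptides, table$antibody_hits,
                            table$control_hits)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
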