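#' Pipeline thresholds and options
#'
#' Collects every tunable threshold of the workflow with its default value:
#' replicate shift tolerance 2 fractions, complex call at `R_app >= 2`,
#' large complexes at `R_app >= 10`, degraded below 0.5, secondary peaks at
#' 20% relative height, 4-fraction peak separation, sucrose boundary at
#' fraction 8, large-cytosolic exclusion at 450 kDa, at most 4 peaks,
#' single-peptide identifications accepted from score 5.
#'
#' @param max_shift Replicate peak-shift tolerance (fractions, inclusive).
#' @param rapp_complex Complex-call threshold on `R_app`.
#' @param rapp_large Large-complex boundary on `R_app`.
#' @param rapp_degraded Degraded boundary on `R_app`.
#' @param secondary_height Minimum relative height of non-dominant peaks.
#' @param min_separation Minimum peak separation (fractions).
#' @param sucrose_boundary Last shallow sucrose fraction.
#' @param large_cytosolic Dual-localization exclusion cutoff (kDa).
#' @param max_peaks Maximum Gaussian components per profile.
#' @param min_single_peptide_score Identification score threshold for
#'   single-peptide hits.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed feeds any simulated input).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_shift = 2, rapp_complex = 2, rapp_large = 10,
                            rapp_degraded = 0.5, secondary_height = 0.2,
                            min_separation = 4, sucrose_boundary = 8,
                            large_cytosolic = 450, max_peaks = 4,
                            min_single_peptide_score = 5, seed = 1L) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[setdiff(names(cfg), "seed")]) <= 0))
    stop("all thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

# polynomial rolling hash of the deparsed config (stays within 31 bits),
# recorded on every output table
config_fingerprint <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# fit both replicates of every protein and match peaks across replicates
fit_and_match <- function(profiles, protein_ids, cal, void_fraction, cfg) {
  reps <- names(profiles$intensities)
  fits <- list()
  labeled <- list()
  unmatched <- 0L
  for (p in protein_ids) {
    f1 <- fit_elution_peaks(profiles$intensities[[reps[1]]][p, ],
                            max_peaks = cfg$max_peaks,
                            min_separation = cfg$min_separation,
                            min_rel_height = cfg$secondary_height,
                            void_fraction = void_fraction)
    f2 <- fit_elution_peaks(profiles$intensities[[reps[2]]][p, ],
                            max_peaks = cfg$max_peaks,
                            min_separation = cfg$min_separation,
                            min_rel_height = cfg$secondary_height,
                            void_fraction = void_fraction)
    fits[[p]] <- list(f1, f2)
    m <- match_peaks(f1, f2, max_shift = cfg$max_shift)
    unmatched <- unmatched + nrow(m$unmatched)
    if (nrow(m$pairs) > 0) {
      lab <- assign_labels(m$pairs, cal, void_fraction)
      amp <- (m$pairs$amplitude_rep1 + m$pairs$amplitude_rep2) / 2
      lab <- cbind(protein_id = p, lab,
                   amplitude_mean = amp[match(lab$center_rep1,
                                              m$pairs$center_rep1)])
      labeled[[p]] <- lab
    }
  }
  lab <- if (length(labeled)) do.call(rbind, c(labeled, list(make.row.names = FALSE)))
  else data.frame(protein_id = character(0), label = character(0),
                  center_rep1 = numeric(0), center_rep2 = numeric(0),
                  shift = numeric(0), resolved = logical(0),
                  m_app_rep1 = numeric(0), m_app_rep2 = numeric(0),
                  m_app_mean = numeric(0), extrapolated = logical(0),
                  amplitude_mean = numeric(0))
  list(fits = fits, labeled = lab, n_unmatched = unmatched)
}

# dominant (largest mean amplitude) peak per protein from a labelled table
dominant_peaks <- function(labeled) {
  if (nrow(labeled) == 0) return(labeled)
  sp <- split(labeled, labeled$protein_id)
  out <- do.call(rbind, c(lapply(sp, function(x)
    x[which.max(x$amplitude_mean), , drop = FALSE]),
    list(make.row.names = FALSE)))
  out
}

#' Run the co-fractionation analysis end to end
#'
#' Orchestrates every stage on one dataset: identification filtering,
#' replicate pairing, per-profile Gaussian deconvolution, replicate peak
#' matching, apparent-mass and oligomer-state calls, sucrose-gradient
#' membrane filtering, dual-localization flags, optional reference-complex
#' coverage, and the replicate-correlation / clustering analytics.  Record
#' conservation is asserted at each stage and the drop ledger returned.
#'
#' @param data A dataset as returned by [simulate_dataset()], or a list of
#'   file paths with elements `sec`, `sucrose`, `standards`, `annotations`,
#'   `cytosol` (and schemes under `schemes`).
#' @param config A [pipeline_config()].
#' @param complexes,ortholog_map Optional reference complex table and
#'   ortholog map for the coverage stage (see [map_orthologs()]).
#' @return A result bundle (class `pcp_run`): calibration model, labelled
#'   reproducible peaks, oligomer calls, membrane calls, dual-localization
#'   table, analytics, optional coverage tables, the drop ledger, config
#'   and its fingerprint.
#' @export
run_pipeline <- function(data, config = pipeline_config(),
                         complexes = NULL, ortholog_map = NULL) {
  cfg <- config
  if (is.character(data$sec)) {
    schemes <- data$schemes
    sec <- read_quant_table(data$sec, schemes$sec)
    suc <- if (!is.null(data$sucrose))
      read_quant_table(data$sucrose, schemes$sucrose)
    standards <- utils::read.csv(data$standards)
    annotations <- utils::read.csv(data$annotations)
    cytosol <- if (!is.null(data$cytosol)) utils::read.csv(data$cytosol)
  } else {
    schemes <- data$schemes
    sec <- parse_quant_table(data$sec_table, schemes$sec)
    suc <- if (!is.null(data$sucrose_table))
      parse_quant_table(data$sucrose_table, schemes$sucrose)
    standards <- data$standards
    annotations <- data$annotations
    cytosol <- data$cytosol
  }
  drop_log <- list()
  n_in <- nrow(sec$records)

  cal <- fit_sec_calibration(standards)

  kept <- filter_identifications(sec$records,
                                 min_single_peptide_score = cfg$min_single_peptide_score)
  drop_log$identification <- data.frame(
    stage = "identification", n_in = n_in, n_kept = nrow(kept),
    n_dropped = length(attr(kept, "dropped")))
  keep_ids <- kept$protein_id
  for (r in names(sec$profiles$intensities))
    sec$profiles$intensities[[r]] <-
      sec$profiles$intensities[[r]][keep_ids, , drop = FALSE]

  pairing <- pair_replicates(sec$profiles)
  drop_log$replicate_pairing <- data.frame(
    stage = "replicate_pairing", n_in = length(keep_ids),
    n_kept = length(pairing$protein_ids),
    n_dropped = length(keep_ids) - length(pairing$protein_ids))

  void <- schemes$sec$void_fraction
  sec_fm <- fit_and_match(sec$profiles, pairing$protein_ids, cal, void, cfg)
  with_peak <- unique(sec_fm$labeled$protein_id)
  drop_log$reproducible_peaks <- data.frame(
    stage = "reproducible_peaks", n_in = length(pairing$protein_ids),
    n_kept = length(with_peak),
    n_dropped = length(pairing$protein_ids) - length(with_peak))

  calls <- call_oligomers(sec_fm$labeled, annotations,
                          threshold = cfg$rapp_complex)
  calls$state <- ifelse(calls$resolved,
                        classify_state(calls$r_app_mean,
                                       c(cfg$rapp_degraded, cfg$rapp_complex,
                                         cfg$rapp_large)),
                        "unresolved")

  # sucrose stage: dominant reproducible sucrose peak per cholate protein
  membrane <- NULL
  dual <- NULL
  if (!is.null(suc)) {
    sucp <- pair_replicates(suc$profiles)
    suc_fm <- fit_and_match(suc$profiles, sucp$protein_ids, cal,
                            NULL, cfg)
    suc_dom <- dominant_peaks(suc_fm$labeled)
    suc_center <- (suc_dom$center_rep1 + suc_dom$center_rep2) / 2
    names(suc_center) <- suc_dom$protein_id

    cholate_ids <- pairing$protein_ids
    in_cyt <- cholate_ids %in% cytosol$protein_id
    ev <- sucrose_evidence(unname(suc_center[cholate_ids]),
                           boundary_fraction = cfg$sucrose_boundary)
    membrane <- cbind(data.frame(protein_id = cholate_ids),
                      call_membrane(rep(TRUE, length(cholate_ids)),
                                    in_cyt, ev))

    # dual localization: membrane-associated proteins with a cytosolic pool
    sec_dom <- dominant_peaks(calls[calls$resolved, , drop = FALSE])
    cand <- membrane$protein_id[membrane$status == "membrane_associated" &
                                  membrane$protein_id %in% cytosol$protein_id &
                                  membrane$protein_id %in% sec_dom$protein_id]
    if (length(cand) > 0) {
      m_mem <- sec_dom$m_app_mean[match(cand, sec_dom$protein_id)]
      m_cyt <- cytosol$m_app_kda[match(cand, cytosol$protein_id)]
      dual <- cbind(data.frame(protein_id = cand,
                               m_app_cytosol_kda = m_cyt,
                               m_app_membrane_kda = m_mem),
                    flag_dual_localized(m_cyt, m_mem,
                                        large_cytosolic_cutoff_kda = cfg$large_cytosolic))
    }
  }

  coverage <- NULL; mass_comparison <- NULL
  if (!is.null(complexes) && !is.null(ortholog_map)) {
    mapped <- dedupe_complexes(map_orthologs(complexes, ortholog_map))
    coverage <- coverage_table(
      mapped,
      target_masses = annotations[, c("protein_id", "monomer_mass_kda")])
    sec_dom <- dominant_peaks(calls[calls$resolved, , drop = FALSE])
    mass_comparison <- compare_masses(coverage, sec_dom)
  }

  reps <- names(sec$profiles$intensities)
  corr <- fraction_correlation(sec$profiles$intensities[[1]],
                               sec$profiles$intensities[[2]])
  rec <- reconstruct_profiles(lapply(sec_fm$fits[with_peak], `[[`, 1),
                              as.numeric(schemes$sec$fraction_ids))
  clustering <- if (nrow(rec) >= 3) cluster_profiles(rec)

  drops <- do.call(rbind, c(drop_log, list(make.row.names = FALSE)))
  stopifnot(all(drops$n_kept + drops$n_dropped == drops$n_in))

  structure(
    list(calibration = cal, labeled_peaks = sec_fm$labeled,
         oligomer_calls = calls, membrane_calls = membrane,
         dual_localization = dual, coverage = coverage,
         mass_comparison = mass_comparison,
         fraction_correlation = corr, clustering = clustering,
         sec_fits = sec_fm$fits, drop_log = drops,
         config = cfg, config_hash = config_fingerprint(cfg),
         replicates = reps),
    class = "pcp_run")
}

#' @export
print.pcp_run <- function(x, ...) {
  cat("Co-fractionation pipeline run (config ", x$config_hash, ")\n", sep = "")
  print(x$drop_log, row.names = FALSE)
  cat("reproducible peaks:", nrow(x$labeled_peaks),
      "for", length(unique(x$labeled_peaks$protein_id)), "proteins\n")
  if (!is.null(x$membrane_calls))
    cat("membrane-associated:",
        sum(x$membrane_calls$status == "membrane_associated"),
        "/ contaminants:",
        sum(x$membrane_calls$status == "cytosolic_contaminant"), "\n")
  invisible(x)
}

#' Write the result bundle as TSV tables
#'
#' Every table carries the config fingerprint as a leading comment line.
#'
#' @param run A `pcp_run` bundle.
#' @param dir Output directory.
#' @return Named vector of the written paths, invisibly.
#' @export
write_pipeline_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(reproducible_peaks = run$labeled_peaks,
               oligomer_calls = run$oligomer_calls,
               membrane_calls = run$membrane_calls,
               dual_localization = run$dual_localization,
               coverage = run$coverage,
               drop_log = run$drop_log)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(p, "w")
    writeLines(paste0("# config=", run$config_hash), con)
    utils::write.table(tabs[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths[nm] <- p
  }
  if (!is.null(run$clustering))
    paths["dendrogram"] <- write_dendrogram_newick(
      run$clustering, file.path(dir, "profile_dendrogram.nwk"))
  invisible(paths)
}
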