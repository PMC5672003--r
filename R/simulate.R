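#' Configuration for the co-fractionation profile simulator
#'
#' Defines a ground-truth-labelled experiment: two biological replicates of
#' an SEC separation of cholate-solubilized microsomal proteins plus a
#' sucrose velocity gradient of the same proteins, with a noiseless
#' log-linear calibration law spanning the 29-669 kDa sizing standards.
#' Defaults reflect the separation geometry of the emulated experiments: 24
#' SEC fractions with the void at fraction 2, 25 sucrose fractions, 1-4
#' Gaussian elution peaks per protein, log-normal XIC amplitudes,
#' multiplicative intensity noise, replicate-to-replicate peak jitter,
#' per-fraction dropout, a void-trapped subpopulation and a
#' cytosolic-contaminant subpopulation.
#'
#' @param seed Integer seed; the seed fully determines the dataset.
#' @param n_proteins Number of simulated proteins.
#' @param sec_fractions,sec_void SEC fraction count and void fraction.
#' @param sucrose_fractions Sucrose gradient fraction count.
#' @param peak_count_probs Probabilities of 1-4 SEC peaks per protein.
#' @param sigma_range Peak width range (fractions).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal XIC amplitude law.
#' @param secondary_height_range Relative height range of non-dominant
#'   peaks (fraction of the dominant amplitude).
#' @param jitter_sd,jitter_max Replicate peak jitter: normal SD, truncated
#'   at `+/- jitter_max` fractions.
#' @param noise_cv Multiplicative (log-normal) intensity noise CV.
#' @param additive_floor Additive noise scale, relative to the dominant
#'   amplitude.
#' @param detection_floor Intensities below this fraction of the protein's
#'   maximum are reported as 0 (below XIC detection).
#' @param dropout_prob Per-fraction dropout probability.
#' @param void_trapped_rate Fraction of proteins with an extra unresolved
#'   peak at the void.
#' @param contaminant_rate Fraction of proteins that are cytosolic
#'   contaminants (shallow sucrose peaks).
#' @param bleed_prob,bleed_height Probability and relative height of a deep
#'   bleed-through component for contaminants.
#' @param sucrose_detect_rate Probability a protein is detected in the
#'   sucrose experiment at all.
#' @param dual_cytosol_rate Fraction of true membrane proteins that also
#'   have a cytosolic pool.
#' @param dual_shift_rate Among dual-localized membrane proteins, fraction
#'   whose cytosolic pool has a shifted oligomeric state (mass ratio > 2 or
#'   < 0.5).
#' @param large_cytosolic_rate Fraction of cytosolic masses drawn at or
#'   above 450 kDa (excluded from dual-localization calls).
#' @param state_probs Mixture over oligomer states for the dominant peak.
#' @param rapp_targets True `R_app` of the dominant peak per state.
#' @param min_separation Minimum separation between true peak centers.
#' @param single_peptide_rate Fraction of proteins reported with a single
#'   identifying peptide (half of them below the score-5 acceptance line).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 300L,
                              sec_fractions = 24L,
                              sec_void = 2L,
                              sucrose_fractions = 25L,
                              peak_count_probs = c(0.75, 0.20, 0.04, 0.01),
                              sigma_range = c(1, 2.5),
                              amplitude_meanlog = log(1e6),
                              amplitude_sdlog = 1,
                              secondary_height_range = c(0.25, 0.9),
                              jitter_sd = 0.5,
                              jitter_max = 2,
                              noise_cv = 0.2,
                              additive_floor = 0.002,
                              detection_floor = 0.01,
                              dropout_prob = 0.02,
                              void_trapped_rate = 0.05,
                              contaminant_rate = 0.2,
                              bleed_prob = 0.1,
                              bleed_height = 0.25,
                              sucrose_detect_rate = 0.9,
                              dual_cytosol_rate = 0.3,
                              dual_shift_rate = 0.1,
                              large_cytosolic_rate = 0.03,
                              state_probs = c(degraded = 0.25, monomer = 0.25,
                                              small_complex = 0.25,
                                              large_complex = 0.25),
                              rapp_targets = c(degraded = 0.3, monomer = 1,
                                               small_complex = 4,
                                               large_complex = 12),
                              min_separation = 4,
                              single_peptide_rate = 0.1) {
  cfg <- as.list(environment())
  probs <- c(cfg$peak_count_probs, cfg$state_probs, cfg$dropout_prob,
             cfg$void_trapped_rate, cfg$contaminant_rate, cfg$bleed_prob,
             cfg$sucrose_detect_rate, cfg$dual_cytosol_rate,
             cfg$dual_shift_rate, cfg$large_cytosolic_rate,
             cfg$single_peptide_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  usable <- (cfg$sec_fractions - 2) - (cfg$sec_void + 1)
  kmax <- max(which(cfg$peak_count_probs > 0))
  if ((kmax - 1) * cfg$min_separation > usable)
    stop("infeasible config: ", kmax, " peaks separated by >= ",
         cfg$min_separation, " fractions do not fit in ", usable,
         " usable fractions")
  class(cfg) <- "sim_config"
  cfg
}

# calibration law used by the simulator: noiseless log-linear placement of
# the 29-669 kDa standards on the SEC fraction axis
sim_calibration_law <- function() list(slope = -0.105, intercept = 3.2)

truncated_jitter <- function(n, sd, max) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -max), max)
}

# render one replicate profile from true peaks (data frame A, mu, s)
render_profile <- function(peaks, n_frac, cfg) {
  y <- gauss_mix(as.numeric(t(peaks[, c("A", "mu", "s")])), seq_len(n_frac))
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    y <- y * stats::rlnorm(n_frac, -sdlog^2 / 2, sdlog)
  }
  a_ref <- max(peaks$A)
  y <- y + abs(stats::rnorm(n_frac, 0, cfg$additive_floor * a_ref))
  y[stats::runif(n_frac) < cfg$dropout_prob] <- 0
  y[y < cfg$detection_floor * max(y)] <- 0
  y
}

# draw k centers in [lo, hi] pairwise >= min_sep apart, uniformly over the
# feasible region (spacing construction)
draw_centers <- function(k, lo, hi, min_sep) {
  slack <- (hi - lo) - (k - 1) * min_sep
  if (slack < 0)
    stop("cannot place ", k, " separated peak centers in [", lo, ", ", hi, "]")
  sort(stats::runif(k, 0, slack))[seq_len(k)] + lo +
    (seq_len(k) - 1) * min_sep
}

#' Simulate a ground-truth-labelled co-fractionation dataset
#'
#' Generates MaxQuant-style wide quantification tables (SEC and sucrose,
#' two biological replicates each), the SEC calibration standards table,
#' the protein annotation table, a cytosolic apparent-mass table for
#' dual-localization analysis, and the full ground truth.  All outputs are
#' deterministic given the config seed, and the emitted tables are readable
#' by [read_quant_table()] without modification.
#'
#' @param config A [simulation_config()].
#' @return List with elements `sec_table`, `sucrose_table` (wide data
#'   frames), `standards`, `annotations`, `cytosol`, `schemes` (list of
#'   [fraction_scheme()]s), `truth` (list: `proteins`, `sec_peaks`,
#'   `sucrose_peaks`, `law`), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  law <- sim_calibration_law()

  n <- cfg$n_proteins
  ids <- sprintf("SIM%04d", seq_len(n))
  sec_scheme <- fraction_scheme("sec_superdex", cfg$sec_fractions,
                                void_fraction = cfg$sec_void)
  suc_scheme <- fraction_scheme("sucrose", cfg$sucrose_fractions)

  standards <- data.frame(mass_kda = c(669, 443, 200, 150, 66, 29))
  standards$peak_fraction <-
    (log10(standards$mass_kda) - law$intercept) / law$slope

  state <- sample(names(cfg$state_probs), n, replace = TRUE,
                  prob = cfg$state_probs)
  n_peaks <- sample.int(4L, n, replace = TRUE, prob = cfg$peak_count_probs)
  contaminant <- stats::runif(n) < cfg$contaminant_rate
  void_trapped <- stats::runif(n) < cfg$void_trapped_rate
  lo <- cfg$sec_void + 1.5
  hi <- cfg$sec_fractions - 2

  sec_peaks <- vector("list", n)
  sec_rows <- list(bio1 = matrix(0, n, cfg$sec_fractions,
                                 dimnames = list(ids, NULL)),
                   bio2 = matrix(0, n, cfg$sec_fractions,
                                 dimnames = list(ids, NULL)))
  m_mono <- numeric(n)
  for (i in seq_len(n)) {
    k <- n_peaks[i]
    ctr <- draw_centers(k, lo, hi, cfg$min_separation)
    a1 <- stats::rlnorm(1, cfg$amplitude_meanlog, cfg$amplitude_sdlog)
    # dominant peak carries the protein's oligomer-state truth
    dom <- sample.int(k, 1L)
    rel <- numeric(k)
    rel[dom] <- 1
    rel[-dom] <- stats::runif(k - 1, cfg$secondary_height_range[1],
                              cfg$secondary_height_range[2])
    pk <- data.frame(A = a1 * rel, mu = ctr,
                     s = stats::runif(k, cfg$sigma_range[1],
                                      cfg$sigma_range[2]),
                     is_void = FALSE)
    if (void_trapped[i])
      pk <- rbind(pk, data.frame(A = a1 * stats::runif(1, 0.5, 1.5),
                                 mu = cfg$sec_void, s = 1, is_void = TRUE))
    m_app_dom <- 10^(law$intercept + law$slope * ctr[dom])
    m_mono[i] <- m_app_dom / cfg$rapp_targets[[state[i]]]
    pk$m_app_true <- ifelse(pk$is_void, NA,
                            10^(law$intercept + law$slope * pk$mu))
    pk$r_app_true <- pk$m_app_true / m_mono[i]
    pk$dominant <- seq_len(nrow(pk)) == dom
    for (r in c("bio1", "bio2")) {
      jpk <- pk
      jpk$mu <- jpk$mu + truncated_jitter(nrow(jpk), cfg$jitter_sd,
                                          cfg$jitter_max)
      sec_rows[[r]][i, ] <- render_profile(jpk, cfg$sec_fractions, cfg)
      pk[[paste0("mu_", r)]] <- jpk$mu
    }
    pk$protein_id <- ids[i]
    sec_peaks[[i]] <- pk
  }
  sec_peaks <- do.call(rbind, sec_peaks)

  # sucrose gradient: membrane proteins sediment deep, contaminants stay
  # in the top fractions (emulating soluble complexes such as RUBISCO)
  in_sucrose <- stats::runif(n) < cfg$sucrose_detect_rate
  suc_peaks <- vector("list", n)
  suc_rows <- list(bio1 = matrix(0, n, cfg$sucrose_fractions,
                                 dimnames = list(ids, NULL)),
                   bio2 = matrix(0, n, cfg$sucrose_fractions,
                                 dimnames = list(ids, NULL)))
  for (i in seq_len(n)) {
    if (!in_sucrose[i]) next
    a1 <- stats::rlnorm(1, cfg$amplitude_meanlog, cfg$amplitude_sdlog)
    if (contaminant[i]) {
      pk <- data.frame(A = a1, mu = stats::runif(1, 2, 7.5),
                       s = stats::runif(1, cfg$sigma_range[1],
                                        cfg$sigma_range[2]))
      if (stats::runif(1) < cfg$bleed_prob)
        pk <- rbind(pk, data.frame(A = a1 * cfg$bleed_height,
                                   mu = pk$mu[1] + 8,
                                   s = stats::runif(1, 1.5, 3)))
    } else {
      pk <- data.frame(A = a1, mu = stats::runif(1, 10, 23),
                       s = stats::runif(1, cfg$sigma_range[1],
                                        cfg$sigma_range[2]))
    }
    for (r in c("bio1", "bio2")) {
      jpk <- pk
      jpk$mu <- jpk$mu + truncated_jitter(nrow(jpk), cfg$jitter_sd,
                                          cfg$jitter_max)
      suc_rows[[r]][i, ] <- render_profile(jpk, cfg$sucrose_fractions, cfg)
      pk[[paste0("mu_", r)]] <- jpk$mu
    }
    pk$protein_id <- ids[i]
    suc_peaks[[i]] <- pk
  }
  suc_peaks <- do.call(rbind, suc_peaks)

  # cytosolic pools: contaminants always; a share of true membrane proteins
  # is dual-localized, some with a shifted oligomeric state
  in_cytosol <- contaminant | (stats::runif(n) < cfg$dual_cytosol_rate)
  dom_rows <- sec_peaks[sec_peaks$dominant, ]
  m_app_dom <- dom_rows$m_app_true[match(ids, dom_rows$protein_id)]
  cyt_shift <- !contaminant & in_cytosol &
    stats::runif(n) < cfg$dual_shift_rate
  shift_factor <- ifelse(stats::runif(n) < 0.5, stats::runif(n, 2.5, 6),
                         1 / stats::runif(n, 2.5, 6))
  m_cyt <- m_app_dom * stats::rlnorm(n, 0, 0.05)
  m_cyt[cyt_shift] <- m_app_dom[cyt_shift] * shift_factor[cyt_shift]
  large_cyt <- in_cytosol & stats::runif(n) < cfg$large_cytosolic_rate
  m_cyt[large_cyt] <- stats::runif(sum(large_cyt), 450, 2000)
  cytosol <- data.frame(protein_id = ids[in_cytosol],
                        m_app_kda = m_cyt[in_cytosol])

  # identification metadata; a slice of single-peptide ids exercises the
  # score >= 5 acceptance rule (half below, half above)
  peptides <- sample(2:25, n, replace = TRUE)
  single <- stats::runif(n) < cfg$single_peptide_rate
  peptides[single] <- 1L
  score <- stats::runif(n, 10, 300)
  score[single] <- ifelse(stats::runif(sum(single)) < 0.5,
                          stats::runif(sum(single), 0, 4.99),
                          stats::runif(sum(single), 5, 40))
  accepted_id <- peptides >= 2 | score >= 5

  make_table <- function(rows, n_frac) {
    tab <- data.frame(protein_id = ids, Peptides = peptides, Score = score,
                      stringsAsFactors = FALSE)
    for (r in names(rows)) {
      m <- rows[[r]]
      colnames(m) <- sprintf("Intensity.%s.%02d", r, seq_len(n_frac))
      tab <- cbind(tab, as.data.frame(m, check.names = FALSE))
    }
    rownames(tab) <- NULL
    tab
  }
  sec_table <- make_table(sec_rows, cfg$sec_fractions)
  suc_keep <- in_sucrose
  sucrose_table <- make_table(suc_rows, cfg$sucrose_fractions)[suc_keep, ]
  rownames(sucrose_table) <- NULL

  annotations <- data.frame(
    protein_id = ids,
    monomer_mass_kda = m_mono,
    localization_label = ifelse(contaminant, "cytosol", "membrane"),
    tmd_count = ifelse(contaminant, 0L, sample(0:12, n, replace = TRUE)))

  truth_proteins <- data.frame(
    protein_id = ids, state = state, n_peaks = n_peaks,
    monomer_mass_kda = m_mono, m_app_dominant_kda = m_app_dom,
    contaminant = contaminant, void_trapped = void_trapped,
    in_sucrose = in_sucrose, in_cytosol = in_cytosol,
    membrane_status = ifelse(contaminant, "cytosolic_contaminant",
                             "membrane_associated"),
    m_app_cytosol_kda = ifelse(in_cytosol, m_cyt, NA),
    cytosol_shifted = ifelse(in_cytosol & !contaminant & !large_cyt,
                             cyt_shift, NA),
    large_cytosolic = ifelse(in_cytosol, large_cyt, NA),
    is_complex = NA, accepted_id = accepted_id)
  r_by_prot <- split(sec_peaks$r_app_true, sec_peaks$protein_id)
  truth_proteins$is_complex <- vapply(truth_proteins$protein_id, function(p) {
    r <- r_by_prot[[p]]
    any(!is.na(r) & r >= 2)
  }, logical(1))

  list(sec_table = sec_table, sucrose_table = sucrose_table,
       standards = standards, annotations = annotations, cytosol = cytosol,
       schemes = list(sec = sec_scheme, sucrose = suc_scheme),
       truth = list(proteins = truth_proteins, sec_peaks = sec_peaks,
                    sucrose_peaks = suc_peaks, law = law),
       config = cfg)
}

#' Write a simulated dataset to plain-text tables
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sec = file.path(dir, "sec_quant.tsv"),
             sucrose = file.path(dir, "sucrose_quant.tsv"),
             standards = file.path(dir, "calibration_standards.csv"),
             annotations = file.path(dir, "annotations.csv"),
             cytosol = file.path(dir, "cytosol_mass.csv"))
  utils::write.table(dataset$sec_table, paths["sec"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$sucrose_table, paths["sucrose"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(dataset$standards, paths["standards"], row.names = FALSE)
  utils::write.csv(dataset$annotations, paths["annotations"], row.names = FALSE)
  utils::write.csv(dataset$cytosol, paths["cytosol"], row.names = FALSE)
  invisible(paths)
}
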