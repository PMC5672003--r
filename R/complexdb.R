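#' Project reference complexes onto a target species via ortholog maps
#'
#' Joins a reference (metazoan) complex table with one or more ortholog
#' mapping tables.  A subunit counts as matched when any mapping source
#' provides at least one target-species ortholog; one-to-many mappings are
#' all retained and their multiplicity recorded.
#'
#' @param complexes Long-format data frame: `complex_id`, `species`,
#'   `subunit_id` (one row per subunit).
#' @param ortholog_map Data frame `source_id`, `target_id` (a union of
#'   mapping sources may simply be row-bound).
#' @return List of `reference_complex` records: `complex_id`, `species`,
#'   `subunit_ids`, `target_ids` (sorted unique mapped loci), `n_subunits`,
#'   `n_matched`, `multi_mapped` (subunits with >1 ortholog).
#' @export
map_orthologs <- function(complexes, ortholog_map) {
  stopifnot(all(c("complex_id", "species", "subunit_id") %in% names(complexes)),
            all(c("source_id", "target_id") %in% names(ortholog_map)))
  key <- paste(complexes$complex_id, complexes$species, sep = "\r")
  lapply(split(complexes, key), function(cx) {
    subunits <- unique(cx$subunit_id)
    hits <- ortholog_map[ortholog_map$source_id %in% subunits, , drop = FALSE]
    per_subunit <- split(unique(hits[c("source_id", "target_id")])$target_id,
                         unique(hits[c("source_id", "target_id")])$source_id)
    list(complex_id = cx$complex_id[1],
         species = cx$species[1],
         subunit_ids = subunits,
         target_ids = sort(unique(hits$target_id)),
         n_subunits = length(subunits),
         n_matched = sum(subunits %in% hits$source_id),
         multi_mapped = names(per_subunit)[lengths(per_subunit) > 1])
  })
}

#' Collapse cross-species duplicate complexes
#'
#' The same complex curated in several source species projects onto the
#' same target-species subunit set; such records collapse to one, keeping
#' the first species and listing the others as aliases.  Only complexes
#' with a nonempty mapped set are compared (unmapped complexes share the
#' empty set vacuously and are all kept).  Idempotent.
#'
#' @param mapped List from [map_orthologs()].
#' @return The deduplicated list; each kept record gains an `aliases` field.
#' @export
dedupe_complexes <- function(mapped) {
  keys <- vapply(mapped, function(x)
    if (length(x$target_ids) == 0) NA_character_
    else paste(x$target_ids, collapse = "|"), "")
  keep <- !duplicated(keys) | is.na(keys)
  out <- mapped[keep]
  for (i in seq_along(out)) {
    if (is.null(out[[i]]$aliases)) out[[i]]$aliases <- character(0)
    k <- keys[keep][i]
    if (!is.na(k)) {
      dup <- !keep & !is.na(keys) & keys == k
      out[[i]]$aliases <- unique(c(out[[i]]$aliases,
                                   vapply(mapped[dup], function(x)
                                     paste(x$complex_id, x$species), "")))
    }
  }
  out
}

#' Ortholog coverage class of a projected complex
#'
#' High coverage: orthologs for at least 80% of subunits, or the special
#' small-complex cases 3-of-4 and 2-of-3.  Medium: 60% up to (excluding)
#' 80%.  Low: 40% up to (excluding) 60%.  Below 40%: none.
#'
#' @param n_matched Subunits with an identified ortholog.
#' @param n_subunits Total subunits (>= 1).
#' @return Character vector over `c("high", "medium", "low", "none")`.
#' @export
classify_coverage <- function(n_matched, n_subunits) {
  if (any(n_subunits < 1) || any(n_matched < 0) || any(n_matched > n_subunits))
    stop("need 0 <= n_matched <= n_subunits and n_subunits >= 1")
  frac <- n_matched / n_subunits
  ifelse(frac >= 0.8 | (n_matched == 3 & n_subunits == 4) |
           (n_matched == 2 & n_subunits == 3), "high",
  ifelse(frac >= 0.6, "medium",
  ifelse(frac >= 0.4, "low", "none")))
}

#' Calculated mass of a fully assembled complex
#'
#' Sum of subunit monomer masses, assuming unit stoichiometry (each subunit
#' counted once).
#'
#' @param subunit_masses_kda Positive masses in kDa.
#' @return The summed mass in kDa.
#' @export
calc_complex_mass <- function(subunit_masses_kda) {
  if (length(subunit_masses_kda) == 0) stop("no subunit masses given")
  if (any(subunit_masses_kda <= 0)) stop("masses must be positive")
  sum(subunit_masses_kda)
}

#' Build the coverage table for projected reference complexes
#'
#' @param mapped List from [map_orthologs()] (after [dedupe_complexes()]).
#' @param source_masses Optional data frame `subunit_id`,
#'   `monomer_mass_kda` for the source species; `m_calc_source_kda` is the
#'   sum over all subunits (NA when any subunit mass is unknown).
#' @param target_masses Optional data frame `protein_id`,
#'   `monomer_mass_kda` for the target species; `m_calc_target_kda` is
#'   reported only at 100% ortholog coverage.
#' @return Data frame, one row per complex: ids, subunit counts, coverage
#'   class, calculated masses, aliases, mapped target loci.
#' @export
coverage_table <- function(mapped, source_masses = NULL, target_masses = NULL) {
  rows <- lapply(mapped, function(x) {
    m_src <- NA_real_
    if (!is.null(source_masses)) {
      m <- source_masses$monomer_mass_kda[
        match(x$subunit_ids, source_masses$subunit_id)]
      if (!anyNA(m)) m_src <- calc_complex_mass(m)
    }
    m_tgt <- NA_real_
    if (!is.null(target_masses) && x$n_matched == x$n_subunits &&
        x$n_subunits > 0) {
      m <- target_masses$monomer_mass_kda[
        match(x$target_ids, target_masses$protein_id)]
      if (!anyNA(m) && length(m) > 0) m_tgt <- calc_complex_mass(m)
    }
    data.frame(complex_id = x$complex_id, species = x$species,
               n_subunits = x$n_subunits, n_matched = x$n_matched,
               coverage_class = classify_coverage(x$n_matched, x$n_subunits),
               m_calc_source_kda = m_src, m_calc_target_kda = m_tgt,
               aliases = paste(x$aliases, collapse = ";"),
               target_ids = paste(x$target_ids, collapse = ";"))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(complex_id = character(0), species = character(0),
                      n_subunits = integer(0), n_matched = integer(0),
                      coverage_class = character(0),
                      m_calc_source_kda = numeric(0),
                      m_calc_target_kda = numeric(0),
                      aliases = character(0), target_ids = character(0))
  out
}

#' Compare assembled complex masses with measured subunit apparent masses
#'
#' For each projected complex, collects the measured apparent masses of its
#' mapped subunits and the log10 ratio of each measurement to the
#' calculated assembled mass.  The full scatter (one point per measured
#' subunit) and its Pearson correlation on the log10 scale are attached as
#' attributes for global concordance reporting.
#'
#' @param coverage Data frame from [coverage_table()] (needs
#'   `m_calc_target_kda` and `target_ids`).
#' @param calls Data frame with `protein_id` and `m_app_mean` (kDa), e.g.
#'   pooled output of [call_oligomers()].
#' @return Per-complex data frame `complex_id`, `m_calc_kda`,
#'   `n_measured`, `median_m_app_kda`, `median_log10_ratio`; attributes
#'   `scatter` (data frame `complex_id`, `protein_id`, `m_calc_kda`,
#'   `m_app_kda`, `log10_ratio`) and `pearson_r`.
#' @export
compare_masses <- function(coverage, calls) {
  stopifnot(all(c("protein_id", "m_app_mean") %in% names(calls)))
  scatter <- list(); rows <- list()
  for (i in seq_len(nrow(coverage))) {
    m_calc <- coverage$m_calc_target_kda[i]
    tgt <- strsplit(coverage$target_ids[i], ";", fixed = TRUE)[[1]]
    m_app <- calls$m_app_mean[match(tgt, calls$protein_id)]
    meas <- !is.na(m_app)
    rows[[i]] <- data.frame(
      complex_id = coverage$complex_id[i], m_calc_kda = m_calc,
      n_measured = sum(meas),
      median_m_app_kda = if (any(meas)) stats::median(m_app[meas]) else NA_real_,
      median_log10_ratio = if (any(meas) && !is.na(m_calc))
        stats::median(log10(m_app[meas] / m_calc)) else NA_real_)
    if (any(meas) && !is.na(m_calc))
      scatter[[length(scatter) + 1L]] <- data.frame(
        complex_id = coverage$complex_id[i], protein_id = tgt[meas],
        m_calc_kda = m_calc, m_app_kda = m_app[meas],
        log10_ratio = log10(m_app[meas] / m_calc))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  sc <- if (length(scatter)) do.call(rbind, scatter) else
    data.frame(complex_id = character(0), protein_id = character(0),
               m_calc_kda = numeric(0), m_app_kda = numeric(0),
               log10_ratio = numeric(0))
  attr(out, "scatter") <- sc
  attr(out, "pearson_r") <- if (nrow(sc) >= 3)
    stats::cor(log10(sc$m_calc_kda), log10(sc$m_app_kda)) else NA_real_
  out
}
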