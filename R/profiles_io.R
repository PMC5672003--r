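#' Read a wide-format quantification table into elution profiles
#'
#' Parses a MaxQuant-style protein-groups export: one row per protein group,
#' one raw XIC intensity column per fraction and replicate.  Intensity
#' columns are recognised by a configurable prefix pattern; the remainder of
#' the column name must be `<replicate>.<fraction>` (separators `.`, `_` or
#' space), e.g. `Intensity.bio1.07`.  Blank or missing intensity cells become
#' zero: XIC absence means signal below detection, not missing data.
#'
#' @param path Path to a tab- or comma-separated table (the delimiter is
#'   sniffed from the header line).
#' @param scheme A [fraction_scheme()]; every declared fraction must have an
#'   intensity column in each replicate found in the header.
#' @param intensity_pattern Regular expression marking intensity columns.
#' @return A list with components
#'   \describe{
#'     \item{profiles}{class `elution_profiles`: the scheme plus one
#'       proteins-by-fractions intensity matrix per replicate (rownames are
#'       protein ids).}
#'     \item{records}{data frame of per-protein metadata: `protein_id`,
#'       `peptide_count`, `id_score`, plus any further non-intensity columns
#'       present in the file.}
#'   }
#' @export
read_quant_table <- function(path, scheme,
                             intensity_pattern = "^Intensity[._ ]") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  parse_quant_table(tab, scheme, intensity_pattern)
}

# shared body so simulated in-memory tables go through the identical parser
parse_quant_table <- function(tab, scheme,
                              intensity_pattern = "^Intensity[._ ]") {
  stopifnot(inherits(scheme, "fraction_scheme"))
  cols <- names(tab)
  int_cols <- grep(intensity_pattern, cols, value = TRUE)
  if (length(int_cols) == 0L)
    stop("no intensity columns match pattern '", intensity_pattern, "'")

  rest <- sub(intensity_pattern, "", int_cols)
  parts <- strsplit(rest, "[._ ]")
  ok <- vapply(parts, length, 1L) == 2L
  if (!all(ok))
    stop("cannot parse replicate/fraction from column(s): ",
         paste(int_cols[!ok], collapse = ", "))
  rep_id <- vapply(parts, `[`, "", 1L)
  frac <- suppressWarnings(as.integer(sub("^F", "", vapply(parts, `[`, "", 2L))))
  if (anyNA(frac))
    stop("non-numeric fraction token in intensity column names")

  id_col <- intersect(c("protein_id", "Protein IDs", "Protein.IDs", "Majority protein IDs"),
                      cols)[1]
  if (is.na(id_col)) stop("no protein id column found")
  ids <- as.character(tab[[id_col]])

  reps <- unique(rep_id)
  profiles <- list()
  for (r in reps) {
    have <- frac[rep_id == r]
    missing <- setdiff(scheme$fraction_ids, have)
    if (length(missing) > 0L)
      stop("replicate '", r, "' is missing intensity column(s) for fraction(s) ",
           paste(missing, collapse = ", "))
    if (anyDuplicated(ids))
      stop("duplicate protein_id within replicate '", r, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sel <- int_cols[rep_id == r][order(have)]
    m <- vapply(tab[, sel, drop = FALSE], function(v) {
      v <- suppressWarnings(as.numeric(v))
      v[is.na(v)] <- 0
      v
    }, numeric(length(ids)))
    m <- matrix(m, nrow = length(ids),
                ncol = length(scheme$fraction_ids),
                dimnames = list(ids, scheme$fraction_ids))
    if (any(m < 0)) stop("negative intensity encountered in replicate '", r, "'")
    profiles[[r]] <- m
  }

  meta_cols <- setdiff(cols, c(int_cols, id_col))
  records <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (mc in meta_cols) records[[mc]] <- tab[[mc]]
  names(records) <- sub("^Peptides$", "peptide_count", names(records))
  names(records) <- sub("^Score$", "id_score", names(records))

  list(profiles = structure(list(scheme = scheme, intensities = profiles),
                            class = "elution_profiles"),
       records = records)
}

#' @export
print.elution_profiles <- function(x, ...) {
  cat("Elution profiles (", x$scheme$kind, "): ",
      nrow(x$intensities[[1]]), " proteins x ",
      length(x$scheme$fraction_ids), " fractions, replicates: ",
      paste(names(x$intensities), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write elution profiles and protein records back to a quantification table
#'
#' Inverse of [read_quant_table()]; the written file round-trips bit-exactly
#' for finite decimal intensities.
#'
#' @param profiles An `elution_profiles` object.
#' @param records Per-protein metadata data frame (must contain `protein_id`).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(profiles, records, path) {
  stopifnot(inherits(profiles, "elution_profiles"))
  ids <- rownames(profiles$intensities[[1]])
  out <- records[match(ids, records$protein_id), , drop = FALSE]
  names(out) <- sub("^peptide_count$", "Peptides", names(out))
  names(out) <- sub("^id_score$", "Score", names(out))
  for (r in names(profiles$intensities)) {
    m <- profiles$intensities[[r]]
    colnames(m) <- sprintf("Intensity.%s.%02d", r, profiles$scheme$fraction_ids)
    out <- cbind(out, as.data.frame(m, check.names = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the identification acceptance filter
#'
#' Single-peptide identifications are accepted only when the identification
#' score is at least `min_single_peptide_score`; proteins identified by two
#' or more peptides are always kept.  The filter is idempotent.
#'
#' @param records Data frame with `peptide_count` and `id_score` columns.
#' @param min_single_peptide_score Score threshold for single-peptide hits.
#' @return The filtered data frame, with a `dropped` attribute listing the
#'   removed `protein_id`s.
#' @export
filter_identifications <- function(records, min_single_peptide_score = 5) {
  stopifnot(all(c("peptide_count", "id_score") %in% names(records)))
  if (any(records$peptide_count < 1L))
    stop("peptide_count must be >= 1")
  keep <- records$peptide_count >= 2L |
    records$id_score >= min_single_peptide_score
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- records$protein_id[!keep]
  out
}

#' Pair protein profiles across two biological replicates
#'
#' A protein is paired when it is detected (any nonzero intensity) in both
#' replicates; proteins present in only one replicate are reported in the
#' drop log and excluded.
#'
#' @param profiles An `elution_profiles` object holding exactly two
#'   replicates of the same scheme.
#' @return A list with `protein_ids` (paired proteins), `rep_ids` (the two
#'   replicate names), and `drop_log` (data frame `protein_id`,
#'   `present_in`).
#' @export
pair_replicates <- function(profiles) {
  stopifnot(inherits(profiles, "elution_profiles"))
  reps <- names(profiles$intensities)
  if (length(reps) != 2L)
    stop("pair_replicates requires exactly 2 replicates, got ", length(reps))
  det <- lapply(profiles$intensities, function(m) rownames(m)[rowSums(m) > 0])
  shared <- intersect(det[[1]], det[[2]])
  only1 <- setdiff(det[[1]], det[[2]])
  only2 <- setdiff(det[[2]], det[[1]])
  drop_log <- data.frame(
    protein_id = c(only1, only2),
    present_in = rep(reps, c(length(only1), length(only2))),
    stringsAsFactors = FALSE)
  list(protein_ids = shared, rep_ids = reps, drop_log = drop_log)
}
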