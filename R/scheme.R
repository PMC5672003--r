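#' Define a fractionation scheme
#'
#' A fractionation scheme describes one separation: the ordered set of
#' collected fractions and, for size-exclusion columns, the position of the
#' void fraction (species too large for the column's pores elute there,
#' unresolved).  Sucrose velocity gradients have no void.
#'
#' @param kind Separation type, one of `"sec_superdex"`, `"sec_superose"`,
#'   `"sucrose"`.
#' @param n_fractions Number of collected fractions (fractions are numbered
#'   `1:n_fractions` in elution order).
#' @param void_fraction Integer index of the void fraction, or `NULL` for
#'   separations without a void (required `NULL` for sucrose gradients).
#' @return An object of class `fraction_scheme`.
#' @examples
#' fraction_scheme("sec_superdex", 24, void_fraction = 2)
#' fraction_scheme("sucrose", 25)
#' @export
fraction_scheme <- function(kind = c("sec_superdex", "sec_superose", "sucrose"),
                            n_fractions, void_fraction = NULL) {
  kind <- match.arg(kind)
  n_fractions <- as.integer(n_fractions)
  if (n_fractions < 3L)
    stop("a fractionation scheme needs at least 3 fractions")
  if (kind == "sucrose" && !is.null(void_fraction))
    stop("sucrose gradients have no void fraction")
  if (!is.null(void_fraction)) {
    void_fraction <- as.integer(void_fraction)
    if (void_fraction < 1L || void_fraction > n_fractions)
      stop("void_fraction must lie within the collected fractions")
  }
  structure(
    list(kind = kind,
         fraction_ids = seq_len(n_fractions),
         void_fraction = void_fraction),
    class = "fraction_scheme")
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat("Fractionation scheme:", x$kind, "\n")
  cat("  fractions: 1 -", length(x$fraction_ids), "\n")
  if (!is.null(x$void_fraction))
    cat("  void fraction:", x$void_fraction, "\n")
  invisible(x)
}
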