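#' Simulate the isotopologue pattern of a molecular formula
#'
#' Full convolution of the per-element isotope distributions of the packaged
#' table. Isotopologues closer than `merge_tol` are merged into one peak at
#' the abundance-weighted mean mass (centroided Q-ToF envelopes resolve the
#' ~1 Da isotope spacing but not fine structure, hence the 0.05 Da default).
#' Peaks below `prune * max(abundance)` are dropped after normalization, so
#' with `prune = 0` abundances sum to exactly 1 (within 1e-9).
#'
#' A single chlorine gives the diagnostic two-peak envelope
#' (M : M+2 = 0.7577 : 0.2423); bromine gives the near 1:1 doublet
#' (0.5069 : 0.4931) that distinguishes Br from Cl at MS1.
#'
#' @param f `chem_formula` or formula string.
#' @param prune relative abundance threshold in `[0, 1)`.
#' @param merge_tol peak merge tolerance in Da (> 0).
#' @return `isotope_pattern`: data.frame with columns `mass` (Da, strictly
#'   increasing) and `abundance` (fraction of all isotopologues).
#' @export
#' @examples
#' isotope_pattern("Cl", prune = 0)
#' isotope_pattern("C21H23ClO5")
isotope_pattern <- function(f, prune = 1e-4, merge_tol = 0.05) {
  if (prune < 0 || prune >= 1) stop("prune must be in [0, 1)", call. = FALSE)
  if (merge_tol <= 0) stop("merge_tol must be > 0", call. = FALSE)
  f <- .as_formula(f)
  pat <- data.frame(mass = 0, abundance = 1)
  for (el in names(f)) {
    iso <- element_isotopes(el)
    atom <- data.frame(mass = iso$mass, abundance = iso$abundance)
    n <- unclass(f)[[el]]
    # binary exponentiation keeps intermediate peak lists short
    pow <- atom
    while (n > 0L) {
      if (n %% 2L == 1L) pat <- .convolve_patterns(pat, pow, merge_tol)
      n <- n %/% 2L
      if (n > 0L) pow <- .convolve_patterns(pow, pow, merge_tol)
    }
  }
  if (prune > 0) {
    pat <- pat[pat$abundance >= prune * max(pat$abundance), , drop = FALSE]
  }
  rownames(pat) <- NULL
  structure(pat, class = c("isotope_pattern", "data.frame"))
}

.convolve_patterns <- function(a, b, merge_tol) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance, `*`)
  .merge_peaks(data.frame(mass = as.vector(mass), abundance = as.vector(ab)),
               merge_tol)
}

# cluster peaks whose consecutive gaps are < merge_tol; abundance-weighted
# mean mass per cluster
.merge_peaks <- function(pat, merge_tol) {
  o <- order(pat$mass)
  m <- pat$mass[o]
  ab <- pat$abundance[o]
  grp <- cumsum(c(1, diff(m) >= merge_tol))
  tot <- as.vector(tapply(ab, grp, sum))
  wm <- as.vector(tapply(ab * m, grp, sum)) / tot
  data.frame(mass = wm, abundance = tot)
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", nrow(x), " peaks\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
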