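#' Construct an MS/MS spectrum
#'
#' @param mz fragment m/z values (will be sorted ascending).
#' @param intensity matching non-negative intensities.
#' @param precursor_mz precursor ion m/z (> 0).
#' @param rt retention time in seconds (NA allowed; spectra without their
#'   own RT inherit the owning feature's).
#' @param id scan identifier.
#' @return `ms_spectrum` object.
#' @export
ms_spectrum <- function(mz, intensity, precursor_mz, rt = NA_real_,
                        id = "") {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!is.na(precursor_mz) && precursor_mz <= 0) {
    stop("precursor_mz must be > 0", call. = FALSE)
  }
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    # merge exact duplicates rather than fail
    agg <- tapply(intensity, mz, sum)
    mz <- as.numeric(names(agg)); intensity <- as.vector(agg)
  }
  structure(list(mz = mz, intensity = intensity,
                 precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), id = as.character(id)),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s: %d peaks, precursor m/z %.4f, RT %.1f s\n",
              x$id, length(x$mz), x$precursor_mz, x$rt))
  invisible(x)
}

#' @export
length.ms_spectrum <- function(x) length(x$mz)

#' Window filter: keep locally dominant fragment peaks
#'
#' A peak is retained iff it ranks among the `top_k` most intense peaks
#' within the `+/- half_window` Da interval centered on itself (the
#' GNPS-style WINDOW_FILTER; defaults: top 6 peaks in a +/- 50 Da window).
#' Idempotent.
#'
#' @param s `ms_spectrum`.
#' @param top_k peaks to keep per window (>= 1).
#' @param half_window half width of the centered window, Da.
#' @return filtered `ms_spectrum`.
#' @export
window_filter <- function(s, top_k = 6L, half_window = 50) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (half_window <= 0) stop("half_window must be > 0", call. = FALSE)
  n <- length(s$mz)
  if (n <= top_k) return(s)
  keep <- vapply(seq_len(n), function(i) {
    win <- abs(s$mz - s$mz[i]) <= half_window
    rank_i <- sum(s$intensity[win] > s$intensity[i]) + 1L
    rank_i <= top_k
  }, logical(1))
  ms_spectrum(s$mz[keep], s$intensity[keep], s$precursor_mz, s$rt, s$id)
}

#' Remove fragment peaks near the precursor m/z
#'
#' Drops every peak with `|mz - precursor_mz| <= half_range` (default
#' +/- 17 Da), removing residual precursor and neutral-loss artifacts
#' before similarity scoring. Idempotent.
#'
#' @param s `ms_spectrum`.
#' @param half_range half width in Da (> 0).
#' @return filtered `ms_spectrum` (possibly empty).
#' @export
precursor_exclusion <- function(s, half_range = 17) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (half_range <= 0) stop("half_range must be > 0", call. = FALSE)
  keep <- abs(s$mz - s$precursor_mz) > half_range
  ms_spectrum(s$mz[keep], s$intensity[keep], s$precursor_mz, s$rt, s$id)
}

#' Standard spectral preprocessing for networking
#'
#' `window_filter()` followed by `precursor_exclusion()` with the pipeline
#' defaults (top 6 in +/- 50 Da; +/- 17 Da precursor exclusion).
#'
#' @param s `ms_spectrum`.
#' @param top_k,half_window,half_range see the two filters.
#' @return preprocessed `ms_spectrum`.
#' @export
preprocess_spectrum <- function(s, top_k = 6L, half_window = 50,
                                half_range = 17) {
  precursor_exclusion(window_filter(s, top_k, half_window), half_range)
}
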