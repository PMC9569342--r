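#' Packaged reference compound library
#'
#' The main-text compounds of the source study (azaphilones of
#' *Penicillium sclerotiorum*, ilicicolins of *Neonectria discophora*),
#' shipped as a versioned plain-text table. Entries whose molecular formula
#' was never printed are kept name-only (`formula` NA) and excluded from
#' exact-mass matching.
#'
#' @return data.frame with columns `number`, `name`, `formula`, `family`,
#'   `halogens`, `note`, plus computed `mz` (theoretical `[M+H]+`, NA for
#'   name-only entries).
#' @export
reference_library <- function() {
  path <- system.file("extdata", "reference_compounds.tsv",
                      package = "halonet")
  lib <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, na.strings = "NA")
  lib$mz <- vapply(lib$formula, function(f) {
    if (is.na(f)) NA_real_ else adduct_mz(f)
  }, numeric(1))
  lib
}

#' Annotate a feature against the reference library by exact mass
#'
#' Candidates within `ppm_tol` of the feature's `[M+H]+` m/z are returned
#' ranked by absolute ppm error; isobaric candidates are all reported. When
#' both the feature and a library entry carry an MS/MS spectrum, candidates
#' may additionally be ranked/filtered by modified cosine (`min_cosine`);
#' the packaged library is mass-only, so this path applies only to
#' user-supplied libraries with a `spectrum` list column.
#'
#' @param mz feature m/z (or a `feature_table`, in which case every feature
#'   is annotated and the result gains an `id` column).
#' @param lib library data.frame from [reference_library()] (default).
#' @param ppm_tol mass tolerance, ppm.
#' @param min_cosine minimum MS/MS cosine when spectra are available.
#' @param spectrum optional `ms_spectrum` of the query feature.
#' @return data.frame of annotations (`number`, `name`, `formula`,
#'   `family`, `halogens`, `theoretical_mz`, `ppm`, `cosine`).
#' @export
match_library <- function(mz, lib = reference_library(), ppm_tol = 5,
                          min_cosine = 0, spectrum = NULL) {
  if (is.null(lib) || nrow(lib) == 0L) {
    stop("empty reference library", call. = FALSE)
  }
  if (ppm_tol <= 0) stop("ppm_tol must be > 0", call. = FALSE)
  if (inherits(mz, "feature_table")) {
    ft <- mz
    out <- lapply(seq_len(nrow(ft$features)), function(k) {
      ann <- match_library(ft$features$mz[k], lib, ppm_tol, min_cosine,
                           feature_spectrum(ft, ft$features$id[k]))
      if (nrow(ann) > 0L) cbind(id = ft$features$id[k], ann)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(id = character(), number = integer(),
                        name = character(), formula = character(),
                        family = character(), halogens = character(),
                        theoretical_mz = numeric(), ppm = numeric(),
                        cosine = numeric())
    }
    rownames(out) <- NULL
    return(out)
  }
  usable <- !is.na(lib$mz)
  ppm <- rep(NA_real_, nrow(lib))
  ppm[usable] <- ppm_error(mz, lib$mz[usable])
  hit <- usable & abs(ppm) <= ppm_tol
  out <- data.frame(number = lib$number[hit], name = lib$name[hit],
                    formula = lib$formula[hit], family = lib$family[hit],
                    halogens = lib$halogens[hit],
                    theoretical_mz = lib$mz[hit], ppm = ppm[hit],
                    cosine = rep(NA_real_, sum(hit)),
                    stringsAsFactors = FALSE)
  if (!is.null(spectrum) && "spectrum" %in% names(lib) && nrow(out) > 0L) {
    cs <- vapply(which(hit), function(i) {
      ref <- lib$spectrum[[i]]
      if (is.null(ref)) return(NA_real_)
      modified_cosine(spectrum, ref)$score
    }, numeric(1))
    out$cosine <- cs
    out <- out[is.na(out$cosine) | out$cosine >= min_cosine, , drop = FALSE]
  }
  out <- out[order(abs(out$ppm), out$number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
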