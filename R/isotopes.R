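#' @title Element isotope table and physical constants
#' @description The package ships a versioned plain-text isotope table
#'   (CIAAW/IUPAC masses; chlorine abundances pinned to 35Cl 75.77% / 37Cl
#'   24.23%, the values used for all chlorine envelope reasoning here).
#' @name isotopes
NULL

# mass of the electron and of the proton, Da (CODATA)
.electron_mass <- 0.000548579909
.proton_mass <- 1.00782503207 - 0.000548579909

.halonet_env <- new.env(parent = emptyenv())

#' Element isotope table
#'
#' Returns the packaged isotope table: one row per naturally occurring
#' isotope with its exact mass (Da) and fractional abundance. Per-element
#' abundances sum to 1 within 1e-9.
#'
#' @param element optional element symbol; if given, only that element's
#'   isotopes are returned (ordered by increasing mass).
#' @return data.frame with columns `element`, `isotope`, `mass`, `abundance`.
#' @export
#' @examples
#' element_isotopes("Cl")
element_isotopes <- function(element = NULL) {
  tab <- .isotope_table()
  if (!is.null(element)) {
    if (!element %in% tab$element) {
      stop("unsupported element symbol: ", element, call. = FALSE)
    }
    tab <- tab[tab$element == element, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

.isotope_table <- function() {
  if (is.null(.halonet_env$isotab)) {
    path <- system.file("extdata", "isotope_table.tsv", package = "halonet")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    tab <- tab[order(tab$element, tab$mass), ]
    rownames(tab) <- NULL
    # fail fast on a corrupted resource
    sums <- tapply(tab$abundance, tab$element, sum)
    stopifnot(all(abs(sums - 1) < 1e-9))
    .halonet_env$isotab <- tab
  }
  .halonet_env$isotab
}

.supported_elements <- function() unique(.isotope_table()$element)

# lightest-isotope (monoisotopic) mass for one element symbol
.mono_mass <- function(element) {
  tab <- .isotope_table()
  m <- tab$mass[tab$element == element]
  if (length(m) == 0L) stop("unsupported element symbol: ", element,
                            call. = FALSE)
  min(m)
}

#' Physical constants used in ion mass arithmetic
#'
#' @return named list with `electron_mass` and `proton_mass` in Da. The
#'   proton mass (hydrogen atom minus electron) is what protonation adds to
#'   a neutral monoisotopic mass under positive electrospray.
#' @export
atomic_constants <- function() {
  list(electron_mass = .electron_mass, proton_mass = .proton_mass)
}
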