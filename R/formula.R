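#' Parse a Hill-notation molecular formula
#'
#' Accepts formulas such as `"C21H23ClO5"`: element symbols (one upper-case
#' letter optionally followed by one lower-case letter) each followed by an
#' optional positive count. Supported elements are those of the packaged
#' isotope table (C, H, N, O, P, S, Cl, Br, I, Na, K).
#'
#' @param text formula string.
#' @return a `chem_formula`: named integer vector of element counts in Hill
#'   order (C first, then H, then the rest alphabetically).
#' @export
#' @examples
#' parse_formula("C21H23ClO5")
#' format(parse_formula("H2O"))
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text)) {
    stop("cannot parse formula: ", text, call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", toks)
  counts <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(counts), suppressWarnings(as.integer(counts)), 1L)
  bad <- setdiff(elems, .supported_elements())
  if (length(bad) > 0L) {
    stop("unsupported element symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(n)) || any(n <= 0L)) {
    stop("element counts must be positive integers in: ", text,
         call. = FALSE)
  }
  out <- tapply(n, elems, sum)
  chem_formula(stats::setNames(as.integer(out), names(out)))
}

#' Construct a chem_formula from a named count vector
#'
#' @param counts named integer vector, element symbol -> count (> 0).
#' @return `chem_formula` object in Hill order.
#' @export
chem_formula <- function(counts) {
  if (length(counts) == 0L) stop("formula must contain at least one element",
                                 call. = FALSE)
  counts <- counts[counts != 0L]
  if (length(counts) == 0L) stop("formula must contain at least one element",
                                 call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(names(counts), .supported_elements())
  if (length(bad) > 0L) {
    stop("unsupported element symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(counts[.hill_order(names(counts))], class = "chem_formula")
}

.hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  n <- stats::setNames(integer(length(all_el)), all_el)
  n[names(e1)] <- n[names(e1)] + unclass(e1)
  n[names(e2)] <- n[names(e2)] + unclass(e2)
  chem_formula(n)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of count times lightest-isotope mass over all elements.
#'
#' @param f `chem_formula` (or string, parsed on the fly).
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C23H32O4") # 372.2301
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  sum(vapply(names(f), .mono_mass, numeric(1)) * unclass(f))
}

.as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' Adduct specification
#'
#' Only singly protonated positive-mode ions (`"[M+H]+"`) are required by
#' this pipeline; `"[M+Na]+"` and `"[M+K]+"` are provided as conveniences.
#'
#' @param name adduct name.
#' @return list with `name`, `delta_mass` (Da added to the neutral
#'   monoisotopic mass) and `charge`.
#' @export
adduct_spec <- function(name = "[M+H]+") {
  known <- list(
    "[M+H]+"  = list(delta = .proton_mass, charge = 1L),
    "[M+Na]+" = list(delta = 22.98976928 - .electron_mass, charge = 1L),
    "[M+K]+"  = list(delta = 38.9637064864 - .electron_mass, charge = 1L)
  )
  if (!name %in% names(known)) {
    stop("unsupported adduct: ", name, call. = FALSE)
  }
  list(name = name, delta_mass = known[[name]]$delta,
       charge = known[[name]]$charge)
}

#' Theoretical adduct m/z of a neutral formula
#'
#' For `[M+H]+` this is monoisotopic mass plus the proton mass (hydrogen
#' atom minus electron), i.e. the electron correction is applied.
#'
#' @param f `chem_formula` or formula string.
#' @param adduct adduct name or `adduct_spec()` result.
#' @return m/z value (not rounded).
#' @export
#' @examples
#' round(adduct_mz("C23H23BrO5"), 4) # 459.0802
adduct_mz <- function(f, adduct = "[M+H]+") {
  a <- if (is.character(adduct)) adduct_spec(adduct) else adduct
  (monoisotopic_mass(f) + a$delta_mass) / a$charge
}

#' Mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return ppm error (vectorized).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0",
                                  call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}

#' Ring and double bond equivalents
#'
#' RDBE = C + 1 - (H + Cl + Br + I)/2 + N/2, the usual valence-based
#' plausibility filter for candidate formulas.
#'
#' @param f `chem_formula` or string.
#' @return RDBE value (can be half-integer).
#' @export
rdbe <- function(f) {
  f <- .as_formula(f)
  g <- function(el) if (el %in% names(f)) unclass(f)[[el]] else 0L
  g("C") + 1 - (g("H") + g("Cl") + g("Br") + g("I")) / 2 + g("N") / 2
}

#' Mass shift of halogen-for-hydrogen substitution
#'
#' Replacing one H by the halogen adds its lightest-isotope mass minus one
#' hydrogen atom mass: Cl +33.9610, Br +77.9105, I +125.8966 Da. These are
#' the fixed shifts linking the members of an OSMAC substitution series.
#'
#' @param halogen one of "Cl", "Br", "I" (vectorized).
#' @return shift in Da.
#' @export
halogen_shift <- function(halogen) {
  ok <- halogen %in% c("Cl", "Br", "I")
  if (!all(ok)) stop("halogen must be one of Cl, Br, I; got: ",
                     paste(halogen[!ok], collapse = ", "), call. = FALSE)
  vapply(halogen, .mono_mass, numeric(1), USE.NAMES = FALSE) -
    .mono_mass("H")
}

#' Substitute hydrogens by halogens on a base formula
#'
#' Removes `n_cl + n_br + n_i` hydrogens and adds the requested halogens;
#' used to build candidate formulas for envelope classification and for the
#' synthetic generator.
#'
#' @param f base `chem_formula` or string (must contain enough H).
#' @param n_cl,n_br,n_i halogen counts to introduce.
#' @return substituted `chem_formula`.
#' @export
substitute_halogens <- function(f, n_cl = 0L, n_br = 0L, n_i = 0L) {
  f <- .as_formula(f)
  n_sub <- n_cl + n_br + n_i
  h <- if ("H" %in% names(f)) unclass(f)[["H"]] else 0L
  if (h < n_sub) stop("not enough hydrogens to substitute", call. = FALSE)
  counts <- stats::setNames(as.integer(f), names(f))
  counts["H"] <- counts["H"] - as.integer(n_sub)
  add <- c(Cl = as.integer(n_cl), Br = as.integer(n_br), I = as.integer(n_i))
  for (el in names(add)[add > 0L]) {
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + add[[el]]
  }
  chem_formula(counts)
}

#' Enumerate candidate molecular formulas for an observed ion
#'
#' Exhaustive search over element-count bounds for neutral formulas whose
#' adduct m/z falls within `tol_ppm` of the target and whose RDBE lies in
#' `rdbe_range`, sorted by absolute ppm error. Default bounds cover the
#' halogenated azaphilone/ilicicolin chemical space (up to C40, 3 Cl, 2 Br,
#' 2 I).
#'
#' @param target_mz observed m/z.
#' @param adduct adduct name or spec (default `"[M+H]+"`).
#' @param tol_ppm match tolerance in ppm (> 0).
#' @param bounds named list of maximum element counts; elements absent from
#'   the list are excluded. C and H are searched implicitly and default to
#'   40 and 60 if not given.
#' @param rdbe_range length-2 numeric, inclusive RDBE interval.
#' @return data.frame with columns `formula`, `mz`, `ppm`, `rdbe`, ordered
#'   by `abs(ppm)`; zero rows if nothing matches.
#' @export
#' @examples
#' enumerate_formulas(373.2373, tol_ppm = 5,
#'                    bounds = list(C = 30, H = 60, O = 10))
enumerate_formulas <- function(target_mz, adduct = "[M+H]+", tol_ppm = 5,
                               bounds = list(C = 40, H = 60, N = 3, O = 12,
                                             S = 1, Cl = 3, Br = 2, I = 2),
                               rdbe_range = c(0, 25)) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (length(bounds) == 0L) stop("empty bounds", call. = FALSE)
  bad <- setdiff(names(bounds), .supported_elements())
  if (length(bad) > 0L) stop("unsupported element in bounds: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  if (any(unlist(bounds) < 0)) stop("bounds must be non-negative",
                                    call. = FALSE)
  a <- if (is.character(adduct)) adduct_spec(adduct) else adduct
  c_max <- if ("C" %in% names(bounds)) bounds$C else 40L
  h_max <- if ("H" %in% names(bounds)) bounds$H else 60L
  hetero <- setdiff(names(bounds), c("C", "H"))

  neutral_target <- target_mz * a$charge - a$delta_mass
  m_h <- .mono_mass("H")
  tol_da <- target_mz * tol_ppm * 1e-6

  grid_args <- c(list(C = 0:c_max),
                 stats::setNames(lapply(hetero,
                                        function(e) 0:bounds[[e]]), hetero))
  grid <- do.call(expand.grid, c(grid_args, KEEP.OUT.ATTRS = FALSE))
  base_mass <- grid$C * .mono_mass("C")
  for (e in hetero) base_mass <- base_mass + grid[[e]] * .mono_mass(e)

  h_est <- round((neutral_target - base_mass) / m_h)
  keep <- h_est >= 0 & h_est <= h_max
  # H count may be off by one at the tolerance edge; test the neighbours too
  cand <- NULL
  for (dh in -1:1) {
    h <- h_est + dh
    ok <- keep & h >= 0 & h <= h_max
    if (!any(ok)) next
    mass <- base_mass[ok] + h[ok] * m_h
    mz <- (mass + a$delta_mass) / a$charge
    hit <- abs(mz - target_mz) <= tol_da
    if (!any(hit)) next
    sub <- grid[ok, , drop = FALSE][hit, , drop = FALSE]
    sub$H <- h[ok][hit]
    sub$mz <- mz[hit]
    cand <- rbind(cand, sub)
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(formula = character(), mz = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  }
  cand <- unique(cand)
  g <- function(e) if (e %in% names(cand)) cand[[e]] else 0
  cand$rdbe <- cand$C + 1 - (cand$H + g("Cl") + g("Br") + g("I")) / 2 +
    g("N") / 2
  cand <- cand[cand$rdbe >= rdbe_range[1] & cand$rdbe <= rdbe_range[2], ,
               drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(formula = character(), mz = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  }
  elems <- c("C", "H", hetero)
  fml <- apply(cand[, elems, drop = FALSE], 1, function(r) {
    r <- r[r > 0]
    format(chem_formula(stats::setNames(as.integer(r), names(r))))
  })
  out <- data.frame(formula = fml, mz = cand$mz,
                    ppm = ppm_error(target_mz, cand$mz), rdbe = cand$rdbe,
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}
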