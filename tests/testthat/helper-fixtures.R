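# shared fixtures and independent oracles

# random small formula with <= max_poly polyisotopic atoms (for the
# brute-force isotopologue oracle)
random_small_formula <- function(max_poly = 12L) {
  n_c <- sample(0:6, 1)
  n_cl <- sample(0:2, 1)
  n_br <- sample(0:1, 1)
  n_o <- sample(0:3, 1)
  n_s <- sample(0:1, 1)
  while (n_c + n_cl + n_br + n_o + n_s == 0 ||
         n_c + n_cl + n_br + n_o + n_s > max_poly) {
    n_c <- sample(0:6, 1); n_cl <- sample(0:2, 1); n_br <- sample(0:1, 1)
    n_o <- sample(0:3, 1); n_s <- sample(0:1, 1)
  }
  counts <- c(C = n_c, H = sample(0:10, 1), O = n_o, S = n_s,
              Cl = n_cl, Br = n_br)
  chem_formula(counts[counts > 0])
}

# all compositions of n into k non-negative parts (k small)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# independent brute-force isotopologue enumeration: per-element multinomial
# compositions crossed over elements, then merged like the implementation
oracle_isotope_pattern <- function(f, merge_tol = 0.05) {
  f <- if (inherits(f, "chem_formula")) f else parse_formula(f)
  cur <- data.frame(mass = 0, p = 1)
  for (el in names(f)) {
    iso <- element_isotopes(el)
    n <- unclass(f)[[el]]
    comp <- compositions(n, nrow(iso))
    mass <- as.vector(comp %*% iso$mass)
    logp <- apply(comp, 1, function(cc) {
      lgamma(n + 1) - sum(lgamma(cc + 1)) + sum(cc * log(iso$abundance))
    })
    d <- data.frame(mass = mass, p = exp(logp))
    cur <- data.frame(mass = as.vector(outer(cur$mass, d$mass, `+`)),
                      p = as.vector(outer(cur$p, d$p, `*`)))
  }
  o <- order(cur$mass)
  m <- cur$mass[o]; p <- cur$p[o]
  grp <- cumsum(c(1, diff(m) >= merge_tol))
  tot <- as.vector(tapply(p, grp, sum))
  data.frame(mass = as.vector(tapply(p * m, grp, sum)) / tot,
             abundance = tot)
}

# exhaustive maximum-weight one-to-one pairing oracle for modified cosine
oracle_modified_cosine <- function(a, b, frag_tol = 0.02,
                                   weighting = "sqrt") {
  if (length(a$mz) == 0L || length(b$mz) == 0L) return(0)
  wa <- if (weighting == "sqrt") sqrt(a$intensity) else a$intensity
  wb <- if (weighting == "sqrt") sqrt(b$intensity) else b$intensity
  wa <- wa / sqrt(sum(wa^2)); wb <- wb / sqrt(sum(wb^2))
  diff <- outer(a$mz, b$mz, `-`)
  shift <- a$precursor_mz - b$precursor_mz
  cand <- which(abs(diff) <= frag_tol | abs(diff - shift) <= frag_tol,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0)
  prod <- wa[cand[, 1]] * wb[cand[, 2]]
  o <- order(-prod)
  cand <- cand[o, , drop = FALSE]; prod <- prod[o]
  best <- 0
  recurse <- function(k, used_a, used_b, acc) {
    if (k > length(prod)) {
      best <<- max(best, acc)
      return(invisible())
    }
    # bound: even taking every remaining pair cannot beat best
    if (acc + sum(prod[k:length(prod)]) <= best) return(invisible())
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recurse(k + 1L, used_a, used_b, acc + prod[k])
      used_a[i] <- FALSE; used_b[j] <- FALSE
    }
    recurse(k + 1L, used_a, used_b, acc)
  }
  recurse(1L, logical(length(a$mz)), logical(length(b$mz)), 0)
  best
}

# random spectrum with n peaks; grid-ish m/z so conflicts within frag_tol
# do occur
random_spectrum <- function(n, precursor, id = "s", gridded = FALSE) {
  mz <- if (gridded) {
    sample(seq(80, precursor - 20, by = 0.01), n)
  } else {
    runif(n, 80, precursor - 20)
  }
  ms_spectrum(mz, rlnorm(n, log(100), 1), precursor, rt = 100, id = id)
}

# toy azaphilone-like family: shared fragments across analogs + decoys
toy_family_table <- function() {
  base <- parse_formula("C19H24O4")
  frags <- c(91.05, 115.05, 147.04, 173.06, 201.09, 229.12)
  ints <- c(200, 500, 900, 400, 700, 300)
  feats <- list(); spectra <- list()
  add_feat <- function(id, mz, rt, cond, fmz, fint, env = NULL) {
    ref <- paste0(id, "_ms2")
    spectra[[ref]] <<- ms_spectrum(fmz, fint, mz, rt, ref)
    row <- data.frame(id = id, mz = mz, rt = rt, intensity = 1e5,
                      condition = cond, msms_ref = ref,
                      stringsAsFactors = FALSE)
    row$envelope <- list(env)
    feats[[id]] <<- row
  }
  mz_h <- adduct_mz(base)
  add_feat("fam_H", mz_h, 300, "PDA", frags, ints)
  for (x in c("Cl", "Br")) {
    fml <- substitute_halogens(base, n_cl = as.integer(x == "Cl"),
                               n_br = as.integer(x == "Br"))
    mz <- adduct_mz(fml)
    pat <- isotope_pattern(fml, prune = 1e-3)
    env <- cbind(mz = pat$mass + atomic_constants()$proton_mass,
                 intensity = pat$abundance * 1e5)
    # halogen retained on the two largest fragments, lost on the rest
    fmz <- c(frags[1:4], frags[5:6] + halogen_shift(x))
    add_feat(paste0("fam_", x), mz,
             300 + c(Cl = 18, Br = 36)[[x]],
             c(Cl = "NaCl", Br = "KBr")[[x]], fmz, ints, env)
  }
  for (d in 1:4) {
    mz <- 250 + 37 * d
    add_feat(paste0("dec_", d), mz, 100 + 50 * d, "PDA",
             sort(runif(5, 60, mz - 25)), rlnorm(5, log(300), 0.5))
  }
  fdf <- do.call(rbind, feats)
  rownames(fdf) <- NULL
  feature_table(fdf[, c("id", "mz", "rt", "intensity", "condition",
                        "envelope", "msms_ref")], spectra)
}
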