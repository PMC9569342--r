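# noiseless H/Cl/Br/I quartet built from a library scaffold
quartet_table <- function(rt = c(H = 300, Cl = 318, Br = 336, I = 360),
                          conditions = c(H = "PDA", Cl = "NaCl",
                                         Br = "KBr", I = "KI"),
                          with_iodine = TRUE) {
  base <- parse_formula("C19H24O4")
  frags <- c(91.05, 115.05, 147.04, 173.06, 201.09, 229.12)
  ints <- c(200, 500, 900, 400, 700, 300)
  feats <- list(); spectra <- list()
  members <- c("H", "Cl", "Br", if (with_iodine) "I")
  for (x in members) {
    fml <- if (x == "H") base else
      substitute_halogens(base, n_cl = as.integer(x == "Cl"),
                          n_br = as.integer(x == "Br"),
                          n_i = as.integer(x == "I"))
    mz <- adduct_mz(fml)
    pat <- isotope_pattern(fml, prune = 1e-3)
    env <- cbind(mz = pat$mass + atomic_constants()$proton_mass,
                 intensity = pat$abundance * 1e5)
    fmz <- c(frags[1:4],
             frags[5:6] + if (x == "H") 0 else halogen_shift(x))
    id <- paste0("q_", x)
    ref <- paste0(id, "_ms2")
    spectra[[ref]] <- ms_spectrum(fmz, ints, mz, rt[[x]], ref)
    row <- data.frame(id = id, mz = mz, rt = rt[[x]], intensity = 1e5,
                      condition = conditions[[x]], msms_ref = ref,
                      stringsAsFactors = FALSE)
    row$envelope <- list(env)
    feats[[id]] <- row
  }
  fdf <- do.call(rbind, feats)
  rownames(fdf) <- NULL
  feature_table(fdf[, c("id", "mz", "rt", "intensity", "condition",
                        "envelope", "msms_ref")], spectra)
}

test_that("a noiseless quartet forms one RT-ordered 4-member series", {
  ft <- quartet_table()
  ser <- find_series(ft)
  expect_identical(length(ser), 1L)
  s <- ser[[1]]
  expect_identical(names(s$members), c("H", "Cl", "Br", "I"))
  expect_true(s$rt_ordered)
  expect_equal(max(abs(s$evidence$ppm)), 0, tolerance = 1e-6)
  # emitted precursor differences match the halogen shifts
  mzs <- s$evidence$mz
  expect_equal(mzs[2] - mzs[1], halogen_shift("Cl"), tolerance = 1e-6)
  expect_equal(mzs[3] - mzs[1], halogen_shift("Br"), tolerance = 1e-6)
  expect_equal(mzs[4] - mzs[1], halogen_shift("I"), tolerance = 1e-6)
})

test_that("rt_rule strict discards RT violations, warn keeps them flagged", {
  ft <- quartet_table(rt = c(H = 300, Cl = 318, Br = 336, I = 250))
  strict <- find_series(ft, rt_rule = "strict")
  expect_identical(length(strict), 0L)
  warned <- find_series(ft, rt_rule = "warn")
  expect_identical(length(warned), 1L)
  expect_false(warned[[1]]$rt_ordered)
  off <- find_series(ft, rt_rule = "off")
  expect_identical(length(off), 1L)
})

test_that("missing iodine partner yields a 3-member series", {
  ft <- quartet_table(with_iodine = FALSE)
  ser <- find_series(ft)
  expect_identical(length(ser), 1L)
  expect_identical(names(ser[[1]]$members), c("H", "Cl", "Br"))
})

test_that("condition requirement gates Br and I members", {
  ft <- quartet_table(conditions = c(H = "PDA", Cl = "NaCl", Br = "PDA",
                                     I = "PDA"))
  ser <- find_series(ft, require_condition = TRUE)
  expect_identical(length(ser), 1L)
  expect_identical(names(ser[[1]]$members), c("H", "Cl"))
  ser2 <- find_series(ft, require_condition = FALSE)
  expect_identical(names(ser2[[1]]$members), c("H", "Cl", "Br", "I"))
})

test_that("loosening ppm_tol never removes a reported series", {
  sim <- generate_dataset(generator_config(seed = 9, n_series = 6,
                                           n_full = 4, n_decoys = 40))
  calls <- classify_features(sim$features)
  membersets <- function(ser) {
    lapply(ser, function(s) sort(unname(s$members)))
  }
  prev <- list()
  for (tol in c(1, 2, 5, 10)) {
    cur <- membersets(find_series(sim$features, ppm_tol = tol,
                                  halogen_calls = calls))
    # every series reported at the tighter tolerance survives, possibly
    # having gained members
    for (ms in prev) {
      survives <- any(vapply(cur, function(cm) all(ms %in% cm),
                             logical(1)))
      expect_true(survives, info = paste("tol", tol))
    }
    prev <- cur
  }
})

test_that("reported pairwise differences satisfy the propagated tolerance", {
  sim <- generate_dataset(generator_config(seed = 10, n_series = 8,
                                           n_full = 5, n_decoys = 60))
  ppm_tol <- 5
  ser <- find_series(sim$features, ppm_tol = ppm_tol)
  shifts <- c(H = 0, setNames(halogen_shift(c("Cl", "Br", "I")),
                              c("Cl", "Br", "I")))
  for (s in ser) {
    ev <- s$evidence
    for (i in seq_len(nrow(ev))) {
      for (j in seq_len(nrow(ev))) {
        if (i >= j) next
        want <- shifts[[ev$halogen[j]]] - shifts[[ev$halogen[i]]]
        got <- ev$mz[j] - ev$mz[i]
        expect_lte(abs(got - want),
                   ppm_tol * 1e-6 * (ev$mz[i] + ev$mz[j]))
      }
    }
  }
})

test_that("series_report cross-references network components", {
  ft <- quartet_table()
  ser <- find_series(ft)
  net <- build_network(ft, min_score = 0.5)
  rep <- series_report(ser, net)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$component_check, "consistent")
  expect_true(rep$rt_ordered)

  # a mass-matched pair whose spectra are unrelated ends up split
  f <- ft$features
  specs <- ft$spectra
  odd_id <- "odd_Cl"
  mz <- f$mz[f$id == "q_H"] + halogen_shift("Cl")
  # unrelated-but-mass-matched feature: same mz, alien spectrum
  specs[["odd_ms2"]] <- ms_spectrum(c(71.3, 83.9, 96.4), c(5, 5, 5),
                                    mz, 320, "odd_ms2")
  env <- ft$features$envelope[[which(f$id == "q_Cl")]]
  row <- data.frame(id = odd_id, mz = mz, rt = 320, intensity = 1e4,
                    condition = "NaCl", msms_ref = "odd_ms2",
                    stringsAsFactors = FALSE)
  row$envelope <- list(env)
  f2 <- rbind(f, row[, names(f)])
  ft2 <- feature_table(f2, specs)
  # unrelated spectrum fails the cosine gate, so no false merge either
  ser2 <- find_series(ft2)
  tab <- series_table(ser2)
  expect_false(odd_id %in% tab$id)

  # empty series set gives an empty report
  expect_identical(nrow(series_report(list(), net)), 0L)
})
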