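# Core model construction, elemental balance, and serialization.

FIG4_IDS <- c("AGTim", "DABT2D", "DABT4D", "EX_eg_e", "EX_glyclt_e",
              "EX_xyl__D_e", "GAPD", "GLYCDO1p", "GLYCLTt", "GLYCLTDy",
              "GLYCLTDxm", "GLYCLTtm", "GLXtp", "ICLp", "RPE", "T_eg",
              "TPI", "XYLTD_D", "XYLK", "XYLR", "XYLt")

test_that("core model contains the canonical network reaction set", {
  m <- build_core_model(eg_cofactors = c("NAD", "NADP"),
                        xylulose1p_route = FALSE,
                        glyoxylate_secretion = TRUE)
  expect_true(all(FIG4_IDS %in% names(m$reactions)))
  # requested variants present, plus glucose/PPP/TCA/respiration backbone
  expect_true(all(c("EGDH_NAD", "EGDH_NADP", "G6PDH_GND", "ICDHxm",
                    "RESPm", "BIOMASS", "EX_glx_e") %in% names(m$reactions)))
})

test_that("cofactor variant selection and error cases behave", {
  expect_error(build_core_model(eg_cofactors = character(0)),
               "at least one")
  m_nadp <- build_core_model(eg_cofactors = "NADP")
  expect_false("EGDH_NAD" %in% names(m_nadp$reactions))
  expect_true("EGDH_NADP" %in% names(m_nadp$reactions))
})

test_that("the model has exactly two EG->GAH oxidations, differing only in cofactor", {
  m <- build_core_model()
  is_eg_ox <- vapply(m$reactions, function(r) {
    s <- r$stoichiometry
    isTRUE(s["eg_c"] < 0) && isTRUE(s["gah_c"] > 0)
  }, logical(1))
  egdh <- m$reactions[is_eg_ox]
  expect_length(egdh, 2L)
  expect_setequal(vapply(egdh, `[[`, "", "cofactor"), c("NAD", "NADP"))
  # strip the cofactor species: remaining stoichiometry must be identical
  strip <- function(r) {
    s <- r$stoichiometry
    sort_s <- s[!names(s) %in% c("nad_c", "nadh_c", "nadp_c", "nadph_c")]
    sort_s[order(names(sort_s))]
  }
  expect_identical(strip(egdh[[1]]), strip(egdh[[2]]))
})

test_that("EG->GA chain regenerates exactly two reduced cofactor equivalents", {
  m <- build_core_model()
  for (cf in c("NAD", "NADP")) {
    chain <- m$reactions[paste0(c("EGDH_", "GAHDH_"), cf)]
    net <- numeric(0)
    for (r in chain) for (k in names(r$stoichiometry))
      net[k] <- sum(net[k], r$stoichiometry[[k]], na.rm = TRUE)
    red <- if (cf == "NAD") "nadh_c" else "nadph_c"
    per_eg <- net[[red]] / -net[["eg_c"]]
    expect_equal(per_eg, 2, tolerance = 1e-12)
    expect_equal(net[["glyclt_c"]] / -net[["eg_c"]], 1, tolerance = 1e-12)
  }
})

test_that("every internal reaction is elementally balanced", {
  m <- build_core_model(xylulose1p_route = TRUE, glyoxylate_secretion = TRUE)
  mb <- check_mass_balance(m)
  expect_identical(nrow(mb), 0L)
  # the EG oxidation chain balances by direct hand count:
  # C2H6O2 -> C2H4O2 (2 H to the cofactor) -> C2H4O3 (+H2O, 2 H out)
  eg <- m$metabolites$eg_c$formula
  gah <- m$metabolites$gah_c$formula
  ga <- m$metabolites$glyclt_c$formula
  expect_equal(unname(eg[c("C", "H", "O")]), c(2, 6, 2))
  expect_equal(unname(gah[c("C", "H", "O")]), c(2, 4, 2))
  expect_equal(unname(ga[c("C", "H", "O")]), c(2, 3, 3))  # glycolate anion
})

test_that("a perturbed carbon coefficient is flagged for exactly that reaction", {
  m <- build_core_model()
  m$reactions$TPI$stoichiometry[["g3p_c"]] <-
    m$reactions$TPI$stoichiometry[["g3p_c"]] + 1
  mb <- check_mass_balance(m)
  expect_true(nrow(mb) > 0)
  expect_identical(unique(mb$reaction), "TPI")
  expect_true("C" %in% mb$element)
  expect_equal(mb$imbalance[mb$element == "C"], 3, tolerance = 1e-12)
})

test_that("model serialization round-trips bit-for-bit", {
  m <- build_core_model(glyoxylate_secretion = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(names(m$reactions), names(m2$reactions))
  for (id in names(m$reactions)) {
    expect_identical(m$reactions[[id]]$stoichiometry,
                     m2$reactions[[id]]$stoichiometry)
    expect_identical(m$reactions[[id]]$lower_bound,
                     m2$reactions[[id]]$lower_bound)
    expect_identical(m$reactions[[id]]$upper_bound,
                     m2$reactions[[id]]$upper_bound)
  }
  expect_identical(m$biomass_composition, m2$biomass_composition)
  # companion TSV: one row per reaction
  tsv <- sub("\\.json$", ".tsv", path)
  expect_true(file.exists(tsv))
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), length(m$reactions))
  expect_true(all(c("id", "equation", "lb", "ub", "subsystem", "cofactor")
                  %in% names(tab)))
})

test_that("reading a model with a dangling metabolite id names the id", {
  m <- build_core_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  doc <- jsonlite::read_json(path)
  doc$reactions[[20]]$stoichiometry[["ghost_met_c"]] <- "1"
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "ghost_met_c")
})

test_that("schema version mismatch is rejected", {
  m <- build_core_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  doc <- jsonlite::read_json(path)
  doc$schema_version <- "99.0"
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "schema version")
})
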