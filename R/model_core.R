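# Reduced core stoichiometric model of R. toruloides central carbon
# metabolism with the curated ethylene glycol (EG) oxidation pathway.
#
# Compartments: e extracellular, c cytosol, m mitochondrion, p peroxisome.
# Internal reactions are elementally balanced for C,H,O,N (P,S tracked too);
# exchanges and the biomass pseudo-reaction are exempt, except that the
# biomass reaction must be carbon-balanced against the configured biomass
# composition.

MODEL_SCHEMA_VERSION <- "1.0"
DEFAULT_BOUND <- 1000

#' Construct a metabolite
#'
#' @param id Short unique identifier, e.g. `"glc__D_c"`.
#' @param name Human-readable name.
#' @param compartment One of `"e"`, `"c"`, `"m"`, `"p"`.
#' @param formula Named numeric vector of element counts over C,H,O,N,P,S.
#' @return A `metabolite` list.
#' @export
metabolite <- function(id, name, compartment, formula) {
  stopifnot(is.character(id), nchar(id) > 0)
  if (!compartment %in% c("e", "c", "m", "p"))
    stop("unknown compartment '", compartment, "' for metabolite ", id)
  f <- formula[formula != 0]
  bad <- setdiff(names(f), c("C", "H", "O", "N", "P", "S"))
  if (length(bad)) stop("unknown elements in formula of ", id, ": ",
                        paste(bad, collapse = ","))
  if (any(f < 0)) stop("negative element count in formula of ", id)
  structure(list(id = id, name = name, compartment = compartment,
                 formula = f), class = "metabolite")
}

#' Construct a reaction
#'
#' @param id Short unique identifier.
#' @param name Human-readable name.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound Flux bounds in mmol/gCDW/h.
#' @param subsystem Free-text pathway tag.
#' @param cofactor `"NAD"`, `"NADP"` or `"none"`; marks the redox cofactor a
#'   dehydrogenase uses, used when comparing cofactor routes.
#' @return A `reaction` list.
#' @export
reaction <- function(id, name, stoichiometry, lower_bound = -DEFAULT_BOUND,
                     upper_bound = DEFAULT_BOUND, subsystem = "",
                     cofactor = "none") {
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower_bound > upper_bound")
  if (!any(stoichiometry != 0))
    stop("reaction ", id, ": no nonzero coefficients")
  if (!cofactor %in% c("NAD", "NADP", "none"))
    stop("reaction ", id, ": cofactor must be NAD, NADP or none")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry[stoichiometry != 0],
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 subsystem = subsystem, cofactor = cofactor),
            class = "reaction")
}

# --- metabolite formula table ------------------------------------------------

core_formulas <- function() {
  list(
    `glc__D` = c(C = 6, H = 12, O = 6),
    g6p      = c(C = 6, H = 11, O = 9, P = 1),
    f6p      = c(C = 6, H = 11, O = 9, P = 1),
    fdp      = c(C = 6, H = 10, O = 12, P = 2),
    dhap     = c(C = 3, H = 5, O = 6, P = 1),
    g3p      = c(C = 3, H = 5, O = 6, P = 1),
    `13dpg`  = c(C = 3, H = 4, O = 10, P = 2),
    `3pg`    = c(C = 3, H = 4, O = 7, P = 1),
    pep      = c(C = 3, H = 2, O = 6, P = 1),
    pyr      = c(C = 3, H = 3, O = 3),
    `ru5p__D` = c(C = 5, H = 9, O = 8, P = 1),
    `xu5p__D` = c(C = 5, H = 9, O = 8, P = 1),
    r5p      = c(C = 5, H = 9, O = 8, P = 1),
    `xyl__D` = c(C = 5, H = 10, O = 5),
    xylt     = c(C = 5, H = 12, O = 5),
    `xylu__D` = c(C = 5, H = 10, O = 5),
    `abt__D` = c(C = 5, H = 12, O = 5),
    `rbl__D` = c(C = 5, H = 10, O = 5),
    xu1p     = c(C = 5, H = 9, O = 8, P = 1),
    eg       = c(C = 2, H = 6, O = 2),
    gah      = c(C = 2, H = 4, O = 2),
    glyclt   = c(C = 2, H = 3, O = 3),
    glx      = c(C = 2, H = 1, O = 3),
    accoa    = c(C = 23, H = 34, N = 7, O = 17, P = 3, S = 1),
    coa      = c(C = 21, H = 32, N = 7, O = 16, P = 3, S = 1),
    cit      = c(C = 6, H = 5, O = 7),
    icit     = c(C = 6, H = 5, O = 7),
    akg      = c(C = 5, H = 4, O = 5),
    succoa   = c(C = 25, H = 35, N = 7, O = 19, P = 3, S = 1),
    succ     = c(C = 4, H = 4, O = 4),
    fum      = c(C = 4, H = 2, O = 4),
    `mal__L` = c(C = 4, H = 4, O = 5),
    oaa      = c(C = 4, H = 2, O = 5),
    `glu__L` = c(C = 5, H = 8, N = 1, O = 4),
    `ala__L` = c(C = 3, H = 7, N = 1, O = 2),
    gly      = c(C = 2, H = 5, N = 1, O = 2),
    nh4      = c(H = 4, N = 1),
    nad      = c(C = 21, H = 26, N = 7, O = 14, P = 2),
    nadh     = c(C = 21, H = 27, N = 7, O = 14, P = 2),
    nadp     = c(C = 21, H = 25, N = 7, O = 17, P = 3),
    nadph    = c(C = 21, H = 26, N = 7, O = 17, P = 3),
    atp      = c(C = 10, H = 12, N = 5, O = 13, P = 3),
    adp      = c(C = 10, H = 12, N = 5, O = 10, P = 2),
    pi       = c(H = 1, O = 4, P = 1),
    h2o      = c(H = 2, O = 1),
    h        = c(H = 1),
    o2       = c(O = 2),
    co2      = c(C = 1, O = 2),
    h2o2     = c(H = 2, O = 2)
  )
}

met_base <- function(id) sub("_(e|c|m|p)$", "", id)
met_comp <- function(id) sub("^.*_(e|c|m|p)$", "\\1", id)

#' Build the reduced core model
#'
#' Assembles the core network of *R. toruloides* central carbon metabolism:
#' glucose uptake and glycolysis to pyruvate, oxidative and non-oxidative
#' pentose phosphate pathway, the XR-XDH-XK xylose route with its
#' NADPH/NAD cofactor asymmetry plus the D-arabitol dehydrogenase pair,
#' compartmented TCA cycle, peroxisomal isocitrate lyase with glyoxylate
#' export to the cytosol, cytosolic (NADP) and mitochondrial (NAD)
#' glyoxylate reductase, lumped respiration (P/O = 2), a biomass
#' pseudo-reaction with NADPH (lipid) and ATP demands, and the curated EG
#' pathway: EG transport, EG -> glycolaldehyde dehydrogenase in the
#' requested cofactor variant(s), glycolaldehyde -> glycolate dehydrogenase
#' in both cofactor variants, glycolate exchange, and a reductive
#' glycolaldehyde -> EG reaction (GRE2 homolog) closed by default.
#'
#' @param eg_cofactors Character subset of `c("NAD","NADP")`; which EG
#'   dehydrogenase variant(s) to include. Must be non-empty.
#' @param xylulose1p_route Include the optional D-xylulose-1P aldolase route
#'   (D-xylulose -> DHAP + glycolaldehyde)?
#' @param glyoxylate_secretion Include a glyoxylate exchange reaction?
#' @param ga_reoxidation If `FALSE`, close the glycolate -> glyoxylate
#'   direction of both glyoxylate reductases (reflecting the observed 100%
#'   GA yield); default leaves them reversible.
#' @param nadph_per_cmol,atp_per_cmol Biomass NADPH and ATP demands,
#'   mol per Cmol biomass.
#' @return A `stoichiometric_model` list with fields `metabolites`,
#'   `reactions`, `objective_id`, `biomass_composition`.
#' @export
build_core_model <- function(eg_cofactors = c("NAD", "NADP"),
                             xylulose1p_route = FALSE,
                             glyoxylate_secretion = FALSE,
                             ga_reoxidation = TRUE,
                             nadph_per_cmol = 0.45,
                             atp_per_cmol = 2.5) {
  if (length(eg_cofactors) == 0)
    stop("at least one EG cofactor variant required")
  eg_cofactors <- unique(match.arg(eg_cofactors, c("NAD", "NADP"),
                                   several.ok = TRUE))

  fo <- core_formulas()
  mets <- list()
  add_met <- function(base, comp) {
    id <- paste0(base, "_", comp)
    if (is.null(mets[[id]]))
      mets[[id]] <<- metabolite(id, base, comp, fo[[base]])
    id
  }
  rxns <- list()
  add_rxn <- function(id, name, stoich, lb = -DEFAULT_BOUND,
                      ub = DEFAULT_BOUND, subsystem = "", cofactor = "none") {
    if (!is.null(rxns[[id]])) stop("duplicate reaction id ", id)
    for (mid in names(stoich)) add_met(met_base(mid), met_comp(mid))
    rxns[[id]] <<- reaction(id, name, stoich, lb, ub, subsystem, cofactor)
  }

  ## exchanges (positive flux = secretion, negative = uptake)
  add_rxn("EX_glc__D_e", "D-glucose exchange", c(glc__D_e = -1), -10, DEFAULT_BOUND, "exchange")
  add_rxn("EX_xyl__D_e", "D-xylose exchange", c(xyl__D_e = -1), 0, DEFAULT_BOUND, "exchange")
  add_rxn("EX_eg_e", "ethylene glycol exchange", c(eg_e = -1), 0, DEFAULT_BOUND, "exchange")
  add_rxn("EX_glyclt_e", "glycolate exchange", c(glyclt_e = -1), 0, DEFAULT_BOUND, "exchange")
  add_rxn("EX_o2_e", "O2 exchange", c(o2_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  add_rxn("EX_co2_e", "CO2 exchange", c(co2_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  add_rxn("EX_h2o_e", "H2O exchange", c(h2o_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  add_rxn("EX_h_e", "proton exchange", c(h_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  add_rxn("EX_nh4_e", "ammonium exchange", c(nh4_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  add_rxn("EX_pi_e", "phosphate exchange", c(pi_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND, "exchange")
  if (glyoxylate_secretion)
    add_rxn("EX_glx_e", "glyoxylate exchange", c(glx_e = -1), 0, DEFAULT_BOUND, "exchange")

  ## transport
  add_rxn("GLCt", "glucose uptake transport", c(glc__D_e = -1, glc__D_c = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("XYLt", "xylose uptake transport", c(xyl__D_e = -1, xyl__D_c = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("T_eg", "ethylene glycol transport", c(eg_e = -1, eg_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("GLYCLTt", "glycolate transport (cytosol/extracellular)",
          c(glyclt_c = -1, glyclt_e = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  if (glyoxylate_secretion)
    add_rxn("GLXt", "glyoxylate export", c(glx_c = -1, glx_e = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("NH4t", "ammonium uptake", c(nh4_e = -1, nh4_c = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("PIt", "phosphate transport", c(pi_e = -1, pi_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("O2t", "O2 diffusion", c(o2_e = -1, o2_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("O2tm", "O2 diffusion (mito)", c(o2_c = -1, o2_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("O2tp", "O2 diffusion (perox)", c(o2_c = -1, o2_p = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("CO2t", "CO2 diffusion", c(co2_c = -1, co2_e = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("CO2tm", "CO2 diffusion (mito)", c(co2_m = -1, co2_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("H2Ot", "H2O diffusion", c(h2o_e = -1, h2o_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("H2Otm", "H2O diffusion (mito)", c(h2o_c = -1, h2o_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("H2Otp", "H2O diffusion (perox)", c(h2o_c = -1, h2o_p = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("Ht", "proton transport", c(h_e = -1, h_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("Htm", "proton transport (mito)", c(h_c = -1, h_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("PYRt2m", "pyruvate-proton symport (mito)",
          c(pyr_c = -1, h_c = -1, pyr_m = 1, h_m = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("ICITtm", "isocitrate transport (mito/cytosol)", c(icit_m = -1, icit_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("ICITtp", "isocitrate transport (cytosol/perox)", c(icit_c = -1, icit_p = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("SUCCtp", "succinate export (perox)", c(succ_p = -1, succ_c = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("SUCCtm", "succinate transport (mito)", c(succ_c = -1, succ_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("GLXtp", "glyoxylate export (perox to cytosol)", c(glx_p = -1, glx_c = 1), 0, DEFAULT_BOUND, "transport")
  add_rxn("GLXtm", "glyoxylate transport (mito)", c(glx_c = -1, glx_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("GLYCLTtm", "glycolate transport (mito)", c(glyclt_m = -1, glyclt_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("GLYCLTtp", "glycolate transport (perox)", c(glyclt_c = -1, glyclt_p = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("GLUtm", "glutamate transport (mito)", c(glu__L_c = -1, glu__L_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("AKGtm", "2-oxoglutarate transport (mito)", c(akg_m = -1, akg_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("ATPtm", "ADP/ATP antiport", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("PItm", "phosphate transport (mito)", c(pi_c = -1, pi_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")
  add_rxn("NADHtm", "cytosolic NADH shuttle (lumped)",
          c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")

  ## glycolysis
  add_rxn("HEX1", "hexokinase", c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1), 0, DEFAULT_BOUND, "glycolysis")
  add_rxn("PGI", "phosphoglucose isomerase", c(g6p_c = -1, f6p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis")
  add_rxn("PFK", "phosphofructokinase", c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1), 0, DEFAULT_BOUND, "glycolysis")
  add_rxn("FBA", "fructose-bisphosphate aldolase", c(fdp_c = -1, dhap_c = 1, g3p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis")
  add_rxn("TPI", "triose-phosphate isomerase", c(dhap_c = -1, g3p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis")
  add_rxn("GAPD", "glyceraldehyde-3P dehydrogenase",
          c(g3p_c = -1, nad_c = -1, pi_c = -1, `13dpg_c` = 1, nadh_c = 1, h_c = 1),
          -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis", cofactor = "NAD")
  add_rxn("PGK", "phosphoglycerate kinase", c(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis")
  add_rxn("PGM_ENO", "phosphoglycerate mutase + enolase (lumped)", c(`3pg_c` = -1, pep_c = 1, h2o_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "glycolysis")
  add_rxn("PYK", "pyruvate kinase", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1), 0, DEFAULT_BOUND, "glycolysis")

  ## pentose phosphate pathway
  add_rxn("G6PDH_GND", "oxidative PPP (lumped G6P dehydrogenase + 6PG dehydrogenase)",
          c(g6p_c = -1, nadp_c = -2, h2o_c = -1, ru5p__D_c = 1, nadph_c = 2, co2_c = 1, h_c = 2),
          0, DEFAULT_BOUND, "pentose phosphate pathway", cofactor = "NADP")
  add_rxn("RPE", "ribulose-5P 3-epimerase", c(ru5p__D_c = -1, xu5p__D_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "pentose phosphate pathway")
  add_rxn("RPI", "ribose-5P isomerase", c(ru5p__D_c = -1, r5p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "pentose phosphate pathway")
  add_rxn("TKT_TAL", "non-oxidative PPP (lumped transketolase/transaldolase)",
          c(xu5p__D_c = -2, r5p_c = -1, f6p_c = 2, g3p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "pentose phosphate pathway")

  ## xylose assimilation (XR-XDH-XK) and arabitol pair
  add_rxn("XYLR", "xylose reductase (NADPH)",
          c(xyl__D_c = -1, nadph_c = -1, h_c = -1, xylt_c = 1, nadp_c = 1),
          0, DEFAULT_BOUND, "xylose assimilation", cofactor = "NADP")
  add_rxn("XYLTD_D", "xylitol dehydrogenase (NAD)",
          c(xylt_c = -1, nad_c = -1, xylu__D_c = 1, nadh_c = 1, h_c = 1),
          0, DEFAULT_BOUND, "xylose assimilation", cofactor = "NAD")
  add_rxn("XYLK", "xylulokinase", c(xylu__D_c = -1, atp_c = -1, xu5p__D_c = 1, adp_c = 1, h_c = 1), 0, DEFAULT_BOUND, "xylose assimilation")
  add_rxn("DABT2D", "D-arabitol 2-dehydrogenase (NAD, forms D-xylulose)",
          c(abt__D_c = -1, nad_c = -1, xylu__D_c = 1, nadh_c = 1, h_c = 1),
          -DEFAULT_BOUND, DEFAULT_BOUND, "xylose assimilation", cofactor = "NAD")
  add_rxn("DABT4D", "D-arabitol 4-dehydrogenase (NADP, forms D-ribulose)",
          c(abt__D_c = -1, nadp_c = -1, rbl__D_c = 1, nadph_c = 1, h_c = 1),
          -DEFAULT_BOUND, DEFAULT_BOUND, "xylose assimilation", cofactor = "NADP")
  add_rxn("DRBK", "D-ribulokinase", c(rbl__D_c = -1, atp_c = -1, ru5p__D_c = 1, adp_c = 1, h_c = 1), 0, DEFAULT_BOUND, "xylose assimilation")
  if (xylulose1p_route) {
    add_rxn("XYLUK1", "D-xylulose 1-kinase (PFK side activity)",
            c(xylu__D_c = -1, atp_c = -1, xu1p_c = 1, adp_c = 1, h_c = 1), 0, DEFAULT_BOUND, "xylulose-1P route")
    add_rxn("XU1PA", "D-xylulose-1P aldolase (FBA1 side activity)",
            c(xu1p_c = -1, dhap_c = 1, gah_c = 1), 0, DEFAULT_BOUND, "xylulose-1P route")
  }

  ## EG oxidation pathway
  if ("NADP" %in% eg_cofactors)
    add_rxn("EGDH_NADP", "ethylene glycol dehydrogenase (NADP)",
            c(eg_c = -1, nadp_c = -1, gah_c = 1, nadph_c = 1, h_c = 1),
            0, DEFAULT_BOUND, "EG oxidation", cofactor = "NADP")
  if ("NAD" %in% eg_cofactors)
    add_rxn("EGDH_NAD", "ethylene glycol dehydrogenase (NAD)",
            c(eg_c = -1, nad_c = -1, gah_c = 1, nadh_c = 1, h_c = 1),
            0, DEFAULT_BOUND, "EG oxidation", cofactor = "NAD")
  add_rxn("GAHDH_NADP", "glycolaldehyde dehydrogenase (NADP)",
          c(gah_c = -1, nadp_c = -1, h2o_c = -1, glyclt_c = 1, nadph_c = 1, h_c = 2),
          0, DEFAULT_BOUND, "EG oxidation", cofactor = "NADP")
  add_rxn("GAHDH_NAD", "glycolaldehyde dehydrogenase (NAD)",
          c(gah_c = -1, nad_c = -1, h2o_c = -1, glyclt_c = 1, nadh_c = 1, h_c = 2),
          0, DEFAULT_BOUND, "EG oxidation", cofactor = "NAD")
  # GRE2 homolog: reductive direction (GAH -> EG), closed by default
  add_rxn("GRE2", "glycolaldehyde reductase (GRE2 homolog, closed by default)",
          c(gah_c = -1, nadph_c = -1, h_c = -1, eg_c = 1, nadp_c = 1),
          0, 0, "EG oxidation", cofactor = "NADP")

  ## glyoxylate/glycolate redox
  ga_lb <- if (ga_reoxidation) -DEFAULT_BOUND else 0
  add_rxn("GLYCLTDy", "glyoxylate reductase, cytosolic (NADP; GOR1)",
          c(glx_c = -1, nadph_c = -1, h_c = -1, glyclt_c = 1, nadp_c = 1),
          ga_lb, DEFAULT_BOUND, "glyoxylate metabolism", cofactor = "NADP")
  add_rxn("GLYCLTDxm", "glyoxylate reductase, mitochondrial (NAD; GOR1)",
          c(glx_m = -1, nadh_m = -1, h_m = -1, glyclt_m = 1, nad_m = 1),
          ga_lb, DEFAULT_BOUND, "glyoxylate metabolism", cofactor = "NAD")
  add_rxn("GLYCDO1p", "glycolate oxidase, peroxisomal",
          c(glyclt_p = -1, o2_p = -1, glx_p = 1, h2o2_p = 1), 0, DEFAULT_BOUND, "glyoxylate metabolism")
  add_rxn("CATp", "catalase, peroxisomal", c(h2o2_p = -2, h2o_p = 2, o2_p = 1), 0, DEFAULT_BOUND, "glyoxylate metabolism")

  ## TCA cycle (mitochondrial) + anaplerosis + glyoxylate shunt
  add_rxn("PDHm", "pyruvate dehydrogenase",
          c(pyr_m = -1, coa_m = -1, nad_m = -1, accoa_m = 1, co2_m = 1, nadh_m = 1),
          0, DEFAULT_BOUND, "TCA cycle", cofactor = "NAD")
  add_rxn("CSm", "citrate synthase", c(accoa_m = -1, oaa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1, h_m = 1), 0, DEFAULT_BOUND, "TCA cycle")
  add_rxn("ACONTm", "aconitase", c(cit_m = -1, icit_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "TCA cycle")
  add_rxn("ICDHxm", "isocitrate dehydrogenase (NAD)",
          c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
          0, DEFAULT_BOUND, "TCA cycle", cofactor = "NAD")
  add_rxn("AKGDm", "2-oxoglutarate dehydrogenase",
          c(akg_m = -1, coa_m = -1, nad_m = -1, succoa_m = 1, co2_m = 1, nadh_m = 1),
          0, DEFAULT_BOUND, "TCA cycle", cofactor = "NAD")
  add_rxn("SUCOASm", "succinyl-CoA synthetase", c(succoa_m = -1, adp_m = -1, pi_m = -1, succ_m = 1, coa_m = 1, atp_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "TCA cycle")
  add_rxn("SUCDm", "succinate dehydrogenase (NAD-linked, simplified)",
          c(succ_m = -1, nad_m = -1, fum_m = 1, nadh_m = 1, h_m = 1),
          0, DEFAULT_BOUND, "TCA cycle", cofactor = "NAD")
  add_rxn("FUMm", "fumarase", c(fum_m = -1, h2o_m = -1, mal__L_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "TCA cycle")
  add_rxn("MDHm", "malate dehydrogenase",
          c(mal__L_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1, h_m = 1),
          -DEFAULT_BOUND, DEFAULT_BOUND, "TCA cycle", cofactor = "NAD")
  add_rxn("PCm", "pyruvate carboxylase",
          c(pyr_m = -1, co2_m = -1, atp_m = -1, h2o_m = -1, oaa_m = 1, adp_m = 1, pi_m = 1, h_m = 2),
          0, DEFAULT_BOUND, "anaplerosis")
  add_rxn("ICLp", "isocitrate lyase, peroxisomal", c(icit_p = -1, succ_p = 1, glx_p = 1), 0, DEFAULT_BOUND, "glyoxylate shunt")

  ## nitrogen assimilation and glyoxylate transamination
  add_rxn("GLUDy", "glutamate dehydrogenase (NADPH)",
          c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1, glu__L_c = 1, h2o_c = 1, nadp_c = 1),
          0, DEFAULT_BOUND, "nitrogen metabolism", cofactor = "NADP")
  add_rxn("ALATA_Lm", "alanine transaminase (mito)",
          c(glu__L_m = -1, pyr_m = -1, akg_m = 1, ala__L_m = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "nitrogen metabolism")
  add_rxn("AGTim", "alanine-glyoxylate aminotransferase (mito)",
          c(ala__L_m = -1, glx_m = -1, pyr_m = 1, gly_m = 1), 0, DEFAULT_BOUND, "nitrogen metabolism")
  add_rxn("GLYOXm", "glycine oxidation (lumped)",
          c(gly_m = -1, h2o_m = -2, nad_m = -3, co2_m = 2, nh4_m = 1, nadh_m = 3, h_m = 2),
          0, DEFAULT_BOUND, "nitrogen metabolism", cofactor = "NAD")
  add_rxn("NH4tm", "ammonium transport (mito)", c(nh4_m = -1, nh4_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND, "transport")

  ## respiration and maintenance
  add_rxn("RESPm", "respiratory chain + oxidative phosphorylation (lumped, P/O = 2)",
          c(nadh_m = -1, h_m = -3, o2_m = -0.5, adp_m = -2, pi_m = -2,
            nad_m = 1, atp_m = 2, h2o_m = 3),
          0, DEFAULT_BOUND, "oxidative phosphorylation", cofactor = "NAD")
  add_rxn("ATPM", "non-growth ATP maintenance",
          c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1), 0, DEFAULT_BOUND, "maintenance")

  ## biomass: coefficients in mmol per g CDW, flux unit = specific growth rate (1/h)
  comp <- biomass_elements()
  sc <- 1000 / biomass_cmol_mass(comp)  # mmol precursor-Cmol-unit per g biomass
  add_rxn("BIOMASS", "biomass pseudo-reaction (CH1.8O0.5N0.2, NADPH lipid sink)",
          c(g6p_c = -0.1 * sc, pyr_c = -0.1 * sc, accoa_m = -0.05 * sc,
            glu__L_c = -0.2 * sc, atp_c = -atp_per_cmol * sc,
            nadph_c = -nadph_per_cmol * sc, h2o_c = -atp_per_cmol * sc,
            akg_c = 0.2 * sc, coa_m = 0.05 * sc, adp_c = atp_per_cmol * sc,
            pi_c = atp_per_cmol * sc, nadp_c = nadph_per_cmol * sc,
            h_c = atp_per_cmol * sc),
          0, DEFAULT_BOUND, "biomass")

  model <- structure(list(metabolites = mets, reactions = rxns,
                          objective_id = "BIOMASS",
                          biomass_composition = comp),
                     class = "stoichiometric_model")
  validate_model(model)
  model
}

#' Validate structural invariants of a model
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a
#' metabolite, that the objective exists, and that exchange reactions touch
#' exactly one metabolite, in the extracellular compartment.
#'
#' @param model A `stoichiometric_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  mids <- vapply(model$metabolites, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(mids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  if (!model$objective_id %in% rids)
    stop("objective reaction '", model$objective_id, "' not in model")
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), mids)
    if (length(missing))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    if (is_exchange(r)) {
      if (length(r$stoichiometry) != 1)
        stop("exchange ", r$id, " must touch exactly one metabolite")
      comp <- model$metabolites[[names(r$stoichiometry)]]$compartment
      if (comp != "e")
        stop("exchange ", r$id, " metabolite not extracellular")
    }
  }
  invisible(model)
}

#' Is a reaction an exchange (system boundary) reaction?
#' @param rxn A `reaction`.
#' @export
is_exchange <- function(rxn) startsWith(rxn$id, "EX_")

#' Stoichiometric matrix of a model
#'
#' @param model A `stoichiometric_model`.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Reaction bounds of a model
#' @param model A `stoichiometric_model`.
#' @return Data frame with columns `id`, `lower`, `upper`.
#' @export
model_bounds <- function(model) {
  data.frame(id = names(model$reactions),
             lower = vapply(model$reactions, `[[`, 0, "lower_bound"),
             upper = vapply(model$reactions, `[[`, 0, "upper_bound"),
             row.names = NULL)
}

#' Check elemental balance of every reaction
#'
#' Internal reactions (neither exchange nor biomass) must balance C, H, O
#' and N to within `tol`. Exchanges are exempt (they are system boundaries);
#' the biomass pseudo-reaction is exempt except for carbon, which must match
#' the model's biomass composition (net carbon consumed per unit flux equals
#' the carbon content of the biomass formed).
#'
#' @param model A `stoichiometric_model`.
#' @param tol Absolute imbalance tolerance.
#' @return Data frame of violations with columns `reaction`, `element`,
#'   `imbalance` (empty when the model is balanced). Boundary totals of the
#'   exempt reactions are attached as attribute `"exempt"`.
#' @export
check_mass_balance <- function(model, tol = 1e-9) {
  validate_model(model)
  elements <- c("C", "H", "O", "N")
  viol <- list(); exempt <- list()
  for (r in model$reactions) {
    imb <- c(C = 0, H = 0, O = 0, N = 0)
    for (mid in names(r$stoichiometry)) {
      f <- model$metabolites[[mid]]$formula
      for (e in intersect(names(f), elements))
        imb[e] <- imb[e] + r$stoichiometry[[mid]] * f[[e]]
    }
    if (is_exchange(r)) {
      exempt[[r$id]] <- imb
    } else if (r$id == model$objective_id) {
      # must consume exactly the biomass carbon per unit flux (mmol C/g)
      bm_c <- 1000 * model$biomass_composition[["C"]] /
        biomass_cmol_mass(model$biomass_composition)
      dev <- imb[["C"]] + bm_c
      if (abs(dev) > max(tol, 1e-6 * bm_c))
        viol[[length(viol) + 1L]] <- data.frame(
          reaction = r$id, element = "C", imbalance = dev)
      exempt[[r$id]] <- imb
    } else {
      for (e in elements)
        if (abs(imb[e]) > tol)
          viol[[length(viol) + 1L]] <- data.frame(
            reaction = r$id, element = e, imbalance = unname(imb[e]))
    }
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(reaction = character(), element = character(),
               imbalance = numeric())
  attr(out, "exempt") <- exempt
  out
}

#' Human-readable equation string for a reaction
#' @param rxn A `reaction`.
#' @return Character scalar like `"eg_c + nad_c --> gah_c + nadh_c + h_c"`.
#' @export
reaction_equation <- function(rxn) {
  s <- rxn$stoichiometry
  fmt <- function(ids) paste(vapply(ids, function(m) {
    cf <- abs(s[[m]])
    if (abs(cf - 1) < 1e-12) m else paste(format(cf, digits = 10), m)
  }, ""), collapse = " + ")
  lhs <- fmt(names(s)[s < 0]); rhs <- fmt(names(s)[s > 0])
  arrow <- if (rxn$lower_bound < 0) "<=>" else "-->"
  paste(lhs, arrow, rhs)
}

# --- serialization -----------------------------------------------------------

num_to_str <- function(x) sprintf("%.17g", x)

#' Write a model to JSON (plus a TSV reaction table)
#'
#' Numeric stoichiometric coefficients and bounds are stored as decimal
#' strings with 17 significant digits, so a write/read round trip reproduces
#' every double bit-for-bit.
#'
#' @param model A `stoichiometric_model`.
#' @param path Output JSON path.
#' @param tsv_path Output path for the reaction table (`id`, `equation`,
#'   `lb`, `ub`, `subsystem`, `cofactor`); default replaces the JSON
#'   extension with `.tsv`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, tsv_path = NULL) {
  validate_model(model)
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    objective_id = model$objective_id,
    biomass_composition = as.list(vapply(model$biomass_composition,
                                         num_to_str, "")),
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = as.list(vapply(m$formula, num_to_str, "")))),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, name = r$name,
           stoichiometry = as.list(vapply(r$stoichiometry, num_to_str, "")),
           lower_bound = num_to_str(r$lower_bound),
           upper_bound = num_to_str(r$upper_bound),
           subsystem = r$subsystem, cofactor = r$cofactor))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(tsv_path)) tsv_path <- sub("\\.json$", ".tsv", path)
  tab <- data.frame(
    id = names(model$reactions),
    equation = vapply(model$reactions, reaction_equation, ""),
    lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
    ub = vapply(model$reactions, `[[`, 0, "upper_bound"),
    subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
    cofactor = vapply(model$reactions, `[[`, "", "cofactor"),
    row.names = NULL)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `stoichiometric_model`; errors on schema mismatch or dangling
#'   metabolite references (naming the offending id).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema_version) ||
      doc$schema_version != MODEL_SCHEMA_VERSION)
    stop("model schema version mismatch: found '",
         doc$schema_version %||% "<none>", "', expected '",
         MODEL_SCHEMA_VERSION, "'")
  s2n <- function(x) as.numeric(unlist(x))
  mets <- list()
  for (m in doc$metabolites) {
    f <- vapply(m$formula, function(v) as.numeric(v), 0)
    mets[[m$id]] <- metabolite(m$id, m$name, m$compartment, f)
  }
  rxns <- list()
  for (r in doc$reactions) {
    st <- vapply(r$stoichiometry, function(v) as.numeric(v), 0)
    rxns[[r$id]] <- reaction(r$id, r$name, st,
                             as.numeric(r$lower_bound),
                             as.numeric(r$upper_bound),
                             r$subsystem, r$cofactor)
  }
  model <- structure(list(
    metabolites = mets, reactions = rxns,
    objective_id = doc$objective_id,
    biomass_composition = vapply(doc$biomass_composition,
                                 function(v) as.numeric(v), 0)),
    class = "stoichiometric_model")
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat("stoichiometric_model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions; objective:", x$objective_id, "\n")
  invisible(x)
}
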