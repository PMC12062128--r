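# Seeded generator of two-phase batch fermentations: exponential growth
# until ammonium is exhausted, then nitrogen-limited (lipogenic) growth on
# the remaining sugar; glucose-repressed or co-consumed EG oxidation to
# glycolate with configurable yield; off-gas at a configured RQ; %DO as a
# phenomenological proxy of the oxygen-uptake rate.
#
# Integration is piecewise-exact on a fixed step grid: biomass is
# propagated exponentially within each step and regime switches (N,
# glucose, xylose or EG depletion) are located analytically, so the
# configured ground truth (mu, q, yields, RQ) is recovered by the
# estimators to machine precision on noise-free output.

#' Simulation configuration for a synthetic batch culture
#'
#' Defaults emulate a flask culture on 10 g/L glucose at molar C/N 80
#' (0.275 g/L ammonium sulfate) with 150 mM EG: maximum specific growth
#' rate 0.34 1/h, nitrogen-limited growth rate 0.084 1/h, biomass yield
#' 0.41 g/g, GA-on-EG yield 1.01 mol/mol, RQ 1.36, EG oxidized only after
#' nitrogen depletion (or glucose exhaustion).
#'
#' @param glucose,xylose,eg Initial concentrations, g/L.
#' @param ammonium_sulfate Initial (NH4)2SO4, g/L.
#' @param inoculum_cdw Initial biomass, g CDW/L.
#' @param mu_exp,mu_nlim Specific growth rates, 1/h (`mu_nlim <= mu_exp`).
#' @param y_xs Biomass yield on sugar, g/g.
#' @param y_ga_eg GA yield on consumed EG, mol/mol.
#' @param extra_ga_factor Additional GA (mol per mol EG) produced from
#'   sugar carbon, active only while xylose is present during the Nlim
#'   phase (the xylulose-1P route signature); >= 0.
#' @param rq Respiratory quotient of the off-gas traces.
#' @param eg_gating `"glucose_nlim_only"` (EG oxidized only once nitrogen
#'   is depleted or glucose exhausted), `"xylose_coconsume"` (from t = 0),
#'   or `"none"` (ungated).
#' @param q_eg Specific EG uptake rate, mmol/gCDW/h.
#' @param sampling_interval,horizon Sampling grid, h.
#' @param noise_od Multiplicative (log-normal) OD noise sigma.
#' @param noise_conc Additive concentration noise sigma (g/L; mM for
#'   ammonium).
#' @param seed Integer seed; mandatory when any noise is > 0.
#' @param od_coeff OD-to-CDW coefficient used to emit the OD channel.
#' @param do_k %DO depression per unit oxygen-uptake rate.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(glucose = 10, xylose = 0,
                              eg = mm_to_gl(150, MOLAR_MASS[["eg"]]),
                              ammonium_sulfate = 0.275,
                              inoculum_cdw = 0.06,
                              mu_exp = 0.34, mu_nlim = 0.084,
                              y_xs = 0.41, y_ga_eg = 1.01,
                              extra_ga_factor = 0, rq = 1.36,
                              eg_gating = c("glucose_nlim_only",
                                            "xylose_coconsume", "none"),
                              q_eg = 0.06,
                              sampling_interval = 4, horizon = 144,
                              noise_od = 0, noise_conc = 0, seed = NULL,
                              od_coeff = 0.3, do_k = 5) {
  eg_gating <- match.arg(eg_gating)
  stopifnot(glucose >= 0, xylose >= 0, eg >= 0, ammonium_sulfate >= 0,
            inoculum_cdw > 0, mu_exp >= 0, mu_nlim >= 0, y_xs > 0,
            y_ga_eg >= 0, extra_ga_factor >= 0, rq > 0, q_eg >= 0,
            sampling_interval > 0, horizon > 0,
            noise_od >= 0, noise_conc >= 0)
  if (mu_nlim > mu_exp) stop("mu_nlim must not exceed mu_exp")
  if ((noise_od > 0 || noise_conc > 0) && is.null(seed))
    stop("a seed is mandatory when noise is enabled")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a two-phase batch fermentation
#'
#' @param config A [simulation_config()].
#' @param dt Integration step bound, h (<= 0.1).
#' @return A time-series data frame (see [validate_timeseries()]) with a
#'   `"truth"` attribute holding every configured parameter plus derived
#'   ground truth (phase switch time, depletion times, per-phase true
#'   specific rates).
#' @export
simulate_batch <- function(config, dt = 0.05) {
  stopifnot(inherits(config, "simulation_config"), dt > 0, dt <= 0.1)
  cf <- config
  fN <- biomass_n_fraction()        # g N per g CDW (exponential biomass)
  cX <- biomass_c_fraction()        # g C per g CDW
  mw_eg <- MOLAR_MASS[["eg"]]; mw_ga <- MOLAR_MASS[["ga"]]

  X <- cf$inoculum_cdw
  N <- cf$ammonium_sulfate * 2 * MOLAR_MASS[["n"]] / MOLAR_MASS[["as"]]
  glc <- cf$glucose; xyl <- cf$xylose; eg <- cf$eg; ga <- 0
  cum_co2_c <- 0                    # g C/L evolved as CO2, exact

  truth <- list(config = cf, t_nlim = NA_real_, t_glc_depleted = NA_real_,
                t_xyl_depleted = NA_real_, t_eg_depleted = NA_real_)

  eg_active <- function(N, glc, xyl, eg) {
    if (eg <= 0 || cf$q_eg <= 0) return(FALSE)
    switch(cf$eg_gating,
           glucose_nlim_only = (N <= 0) || (glc <= 0),
           xylose_coconsume = TRUE,
           none = TRUE)
  }

  times <- seq(0, cf$horizon, by = cf$sampling_interval)
  rows <- vector("list", length(times))
  co2_cum_mmol <- numeric(length(times))
  emit <- function(i, t) {
    # instantaneous rates in the current regime
    sugar <- if (glc > 0) "glucose" else if (xyl > 0) "xylose" else NA
    mu <- if (!is.na(sugar)) { if (N > 0) cf$mu_exp else cf$mu_nlim } else 0
    egon <- eg_active(N, glc, xyl, eg)
    y_eff <- cf$y_ga_eg +
      if (xyl > 0 && N <= 0) cf$extra_ga_factor else 0
    # GA beyond 1:1 draws sugar carbon; without sugar the yield caps at 1
    if (is.na(sugar)) y_eff <- min(y_eff, 1)
    r_sugar <- mu * X / cf$y_xs
    r_eg <- if (egon) cf$q_eg * X * mw_eg / 1000 else 0
    r_ga <- r_eg / mw_eg * y_eff * mw_ga
    cfrac_s <- if (is.na(sugar)) 0 else CARBON_FRACTION[[sugar]]
    c_co2 <- r_sugar * cfrac_s + r_eg * CARBON_FRACTION[["eg"]] -
      mu * X * cX - r_ga * CARBON_FRACTION[["ga"]]
    if (c_co2 < -1e-9)
      stop("configuration draws more carbon into products than available")
    co2 <- max(0, c_co2) / MOLAR_MASS[["c"]] * 1000   # mmol/L/h
    o2 <- co2 / cf$rq
    do_pct <- min(100, max(0, 100 - cf$do_k * o2))
    rows[[i]] <<- data.frame(
      time_h = t, od = X / cf$od_coeff, do_percent = do_pct,
      glc_g_l = glc, xyl_g_l = xyl, eg_g_l = eg, ga_g_l = ga,
      gly_g_l = 0, nh4_mM = N / MOLAR_MASS[["n"]] * 1000,
      co2_mmol_l_h = co2, o2_mmol_l_h = o2)
    co2_cum_mmol[i] <<- cum_co2_c / MOLAR_MASS[["c"]] * 1000
  }

  emit(1L, 0)
  t <- 0
  for (i in seq_along(times)[-1]) {
    target <- times[i]
    guard <- 0L
    while (t < target - 1e-12) {
      guard <- guard + 1L
      if (guard > 10000L) stop("integration stalled (too many regime events)")
      step <- min(dt, target - t)
      sugar <- if (glc > 0) "glucose" else if (xyl > 0) "xylose" else NA
      mu <- if (!is.na(sugar)) { if (N > 0) cf$mu_exp else cf$mu_nlim } else 0
      egon <- eg_active(N, glc, xyl, eg)
      y_eff <- cf$y_ga_eg + if (xyl > 0 && N <= 0) cf$extra_ga_factor else 0
      if (is.na(sugar)) y_eff <- min(y_eff, 1)
      s_avail <- if (is.na(sugar)) Inf else if (sugar == "glucose") glc else xyl

      # analytic time to each depletion event in the current regime
      tau <- step
      if (mu > 0) {
        grow_to <- function(dX) log(1 + dX / X) / mu  # time for X to gain dX
        if (N > 0) tau <- min(tau, grow_to(N / fN))
        tau <- min(tau, grow_to(s_avail * cf$y_xs))
        if (egon) {
          # EG exhausted when integral of X reaches eg * 1000/(q mw)
          need <- eg * 1000 / (cf$q_eg * mw_eg)        # g h / L of biomass-time
          dX_eg <- need * mu                            # since int X = dX/mu
          tau <- min(tau, grow_to(dX_eg))
        }
      } else if (egon) {
        tau <- min(tau, eg * 1000 / (cf$q_eg * mw_eg) / X)
      }
      tau <- max(tau, 1e-12)

      if (mu > 0) {
        dX <- X * (exp(mu * tau) - 1)
        intX <- dX / mu
      } else {
        dX <- 0
        intX <- X * tau
      }
      if (!is.na(sugar)) {
        dS <- dX / cf$y_xs
        if (sugar == "glucose") glc <- glc - dS else xyl <- xyl - dS
      }
      if (N > 0 && mu > 0) N <- N - fN * dX
      dEG <- 0; dGA <- 0
      if (egon) {
        dEG <- cf$q_eg * intX * mw_eg / 1000
        eg <- eg - dEG
        dGA <- dEG / mw_eg * y_eff * mw_ga
        ga <- ga + dGA
      }
      dS <- if (is.na(sugar)) 0 else dX / cf$y_xs
      cfrac_s <- if (is.na(sugar)) 0 else CARBON_FRACTION[[sugar]]
      cum_co2_c <- cum_co2_c + dS * cfrac_s +
        dEG * CARBON_FRACTION[["eg"]] - dX * cX -
        dGA * CARBON_FRACTION[["ga"]]
      X <- X + dX
      t <- t + tau

      clampz <- function(x) if (x < 0) { if (x < -1e-6) stop(
        "integration instability: concentration fell below zero") else 0 } else x
      glc <- clampz(glc); xyl <- clampz(xyl); eg <- clampz(eg); N <- clampz(N)
      if (N == 0 && is.na(truth$t_nlim)) truth$t_nlim <- t
      if (glc == 0 && cf$glucose > 0 && is.na(truth$t_glc_depleted))
        truth$t_glc_depleted <- t
      if (xyl == 0 && cf$xylose > 0 && is.na(truth$t_xyl_depleted))
        truth$t_xyl_depleted <- t
      if (eg == 0 && cf$eg > 0 && is.na(truth$t_eg_depleted))
        truth$t_eg_depleted <- t
    }
    emit(i, target)
  }
  out <- do.call(rbind, rows)

  # derived true specific rates (mmol/gCDW/h)
  truth$co2_cum_mmol <- co2_cum_mmol          # exact cumulative off-gas
  truth$o2_cum_mmol <- co2_cum_mmol / cf$rq
  truth$q_glc_exp <- -cf$mu_exp / cf$y_xs * 1000 / MOLAR_MASS[["glucose"]]
  truth$q_xyl_exp <- -cf$mu_exp / cf$y_xs * 1000 / MOLAR_MASS[["xylose"]]
  truth$q_eg <- -cf$q_eg
  truth$mu_exp <- cf$mu_exp; truth$mu_nlim <- cf$mu_nlim
  truth$y_ga_eg <- cf$y_ga_eg; truth$rq <- cf$rq

  if (cf$noise_od > 0 || cf$noise_conc > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(cf$seed)
    n <- nrow(out)
    if (cf$noise_od > 0)
      out$od <- out$od * exp(stats::rnorm(n, 0, cf$noise_od))
    if (cf$noise_conc > 0) {
      for (col in c("glc_g_l", "xyl_g_l", "eg_g_l", "ga_g_l", "nh4_mM"))
        out[[col]] <- pmax(0, out[[col]] + stats::rnorm(n, 0, cf$noise_conc))
    }
  }
  validate_timeseries(out)
  attr(out, "truth") <- truth
  out
}

fixture_presets <- function(eg_conc) {
  list(
    glc_cn80 = list(glucose = 10, xylose = 0, ammonium_sulfate = 0.275,
                    mu_exp = 0.34, mu_nlim = 0.084, y_ga_eg = 1.01,
                    eg_gating = "glucose_nlim_only", q_eg = 0.06),
    glc_cn8.8 = list(glucose = 20, xylose = 0, ammonium_sulfate = 5,
                     mu_exp = 0.34, mu_nlim = 0.084, y_ga_eg = 1.01,
                     eg_gating = "glucose_nlim_only", q_eg = 0.06),
    xyl_cn80 = list(glucose = 0, xylose = 10, ammonium_sulfate = 0.275,
                    mu_exp = 0.11, mu_nlim = 0.084, y_ga_eg = 0.9,
                    extra_ga_factor = 0.7,
                    eg_gating = "xylose_coconsume", q_eg = 0.06),
    glcxyl_cn80 = list(glucose = 10, xylose = 10, ammonium_sulfate = 0.550,
                       mu_exp = 0.34, mu_nlim = 0.084, y_ga_eg = 1.01,
                       extra_ga_factor = 0.7,
                       eg_gating = "glucose_nlim_only", q_eg = 0.06)
  )
}

#' Write the standard fixture suite
#'
#' Emits the four flask-scale regimes (glucose C/N 80, glucose C/N 8.8,
#' xylose C/N 80, glucose+xylose C/N 80), each with and without 150 mM EG,
#' as paired time-series CSV and ground-truth JSON files. Deterministic for
#' a given seed.
#'
#' @param directory Output directory (created if absent).
#' @param seed Integer master seed; per-fixture seeds are derived from it.
#' @param noise_od,noise_conc Measurement noise levels applied to every
#'   fixture.
#' @return Character vector of the CSV paths written, invisibly.
#' @export
write_fixture_suite <- function(directory, seed,
                                noise_od = 0.02, noise_conc = 0.05) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  presets <- fixture_presets()
  eg150 <- mm_to_gl(150, MOLAR_MASS[["eg"]])
  paths <- character()
  k <- 0L
  for (nm in names(presets)) {
    for (with_eg in c(FALSE, TRUE)) {
      k <- k + 1L
      args <- presets[[nm]]
      args$eg <- if (with_eg) eg150 else 0
      args$noise_od <- noise_od; args$noise_conc <- noise_conc
      args$seed <- seed + k
      cfg <- do.call(simulation_config, args)
      series <- simulate_batch(cfg)
      stem <- paste0(nm, if (with_eg) "_EG" else "_ctrl")
      csv <- file.path(directory, paste0(stem, ".csv"))
      write_timeseries_csv(series, csv,
                           provenance = list(seed = args$seed,
                                             fixture = stem))
      truth <- attr(series, "truth")
      truth$config <- unclass(truth$config)
      jsonlite::write_json(truth,
                           file.path(directory, paste0(stem, "_truth.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
      paths <- c(paths, csv)
    }
  }
  invisible(paths)
}
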