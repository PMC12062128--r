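# Quantitative batch-fermentation analytics: growth rates, phase detection,
# specific rates, yields, carbon balance, respiratory quotient, and media
# stoichiometry.

TS_COLUMNS <- c("time_h", "od", "do_percent", "glc_g_l", "xyl_g_l",
                "eg_g_l", "ga_g_l", "gly_g_l", "nh4_mM",
                "co2_mmol_l_h", "o2_mmol_l_h")

ANALYTES <- c(glucose = "glc_g_l", xylose = "xyl_g_l", eg = "eg_g_l",
              ga = "ga_g_l", glycerol = "gly_g_l")

#' Validate a batch-culture time series
#'
#' A time series is a data frame with columns `time_h` (strictly
#' increasing), `od`, `do_percent` (in \[0, 100\] up to noise) and the
#' analyte concentration columns `glc_g_l`, `xyl_g_l`, `eg_g_l`, `ga_g_l`,
#' `gly_g_l` (g/L), `nh4_mM` (mM), and optional off-gas rates
#' `co2_mmol_l_h`, `o2_mmol_l_h` (mmol/L/h). Missing channels may be NA.
#'
#' @param series Data frame.
#' @return The series, invisibly; errors on violation.
#' @export
validate_timeseries <- function(series) {
  missing_cols <- setdiff(c("time_h", "od"), names(series))
  if (length(missing_cols))
    stop("time series lacks column(s): ", paste(missing_cols, collapse = ", "))
  t <- series$time_h
  if (any(diff(t) <= 0)) stop("time_h must be strictly increasing")
  for (cl in intersect(c(ANALYTES, "nh4_mM", "od"), names(series))) {
    v <- series[[cl]]
    if (any(v < -1e-9, na.rm = TRUE)) stop("negative values in ", cl)
  }
  if ("do_percent" %in% names(series)) {
    v <- series$do_percent
    if (any(v < -1e-6 | v > 110, na.rm = TRUE))
      stop("do_percent outside [0, 100] beyond tolerance")
  }
  invisible(series)
}

#' Convert optical density to dry cell weight
#'
#' @param od Optical density (600 nm).
#' @param coeff Calibration coefficient, g CDW per L per OD unit
#'   (default 0.3).
#' @return CDW in g/L.
#' @export
od_to_cdw <- function(od, coeff = 0.3) {
  if (any(od < 0, na.rm = TRUE)) stop("od must be non-negative")
  od * coeff
}

#' Millimolar to g/L conversion (and inverse)
#'
#' @param conc Concentration in mM (for [mm_to_gl()]) or g/L (for
#'   [gl_to_mm()]).
#' @param molar_mass Molar mass in g/mol.
#' @return Converted concentration.
#' @export
mm_to_gl <- function(conc, molar_mass) {
  stopifnot(all(conc >= 0), molar_mass > 0)
  conc * molar_mass / 1000
}

#' @rdname mm_to_gl
#' @export
gl_to_mm <- function(conc, molar_mass) {
  stopifnot(all(conc >= 0), molar_mass > 0)
  conc * 1000 / molar_mass
}

#' Ammonium concentration contained in ammonium sulfate
#'
#' Two NH4+ per (NH4)2SO4: 275 mg/L of the salt carries 75 mg/L NH4+.
#'
#' @param as_conc Ammonium sulfate concentration (any mass unit per L).
#' @return NH4+ concentration in the same mass unit per L.
#' @export
ammonium_from_as <- function(as_conc) {
  if (any(as_conc < 0)) stop("ammonium sulfate concentration must be >= 0")
  as_conc * (2 * MOLAR_MASS[["nh4"]] / MOLAR_MASS[["as"]])
}

#' Molar carbon-to-nitrogen ratio of a medium
#'
#' mol carbon from the sugars (EG is deliberately excluded from C/N
#' bookkeeping: it is an energy source, not assimilated) over mol nitrogen
#' from ammonium sulfate.
#'
#' @param sugars Named vector of sugar concentrations in g/L; names among
#'   `glucose`, `xylose`, `glycerol`.
#' @param ammonium_sulfate (NH4)2SO4 concentration in g/L (> 0).
#' @return Molar C/N ratio.
#' @export
cn_ratio_molar <- function(sugars, ammonium_sulfate) {
  if (ammonium_sulfate <= 0) stop("ammonium sulfate must be > 0")
  unknown <- setdiff(names(sugars), names(CARBON_FRACTION))
  if (length(unknown)) stop("unknown sugar(s): ", paste(unknown, collapse = ", "))
  mol_c <- sum(sugars * CARBON_FRACTION[names(sugars)]) / MOLAR_MASS[["c"]]
  mol_n <- ammonium_sulfate * 2 / MOLAR_MASS[["as"]]
  mol_c / mol_n
}

#' Specific growth rate from log-linear OD regression
#'
#' Fits a least-squares regression line to the natural logarithm of OD
#' against time inside `window`; the slope is the specific growth rate.
#'
#' @param series A time series (see [validate_timeseries()]).
#' @param window Numeric length-2 time interval (h); defaults to the whole
#'   series.
#' @param min_od Points with OD at or below this value are excluded (use
#'   e.g. twice the inoculum OD to drop lag-phase points).
#' @return List with `mu` (1/h), `se`, `r_squared`, `n`.
#' @export
fit_growth_rate <- function(series, window = NULL, min_od = 0) {
  validate_timeseries(series)
  if (is.null(window)) window <- range(series$time_h)
  keep <- series$time_h >= window[1] & series$time_h <= window[2] &
    !is.na(series$od) & series$od > max(0, min_od)
  if (sum(keep) < 3)
    stop("need at least 3 points with positive OD in the window")
  t <- series$time_h[keep]; y <- log(series$od[keep])
  if (stats::var(y) < 1e-30)       # constant OD: zero growth
    return(list(mu = 0, se = 0, r_squared = NA_real_, n = sum(keep)))
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))   # noise-free data fits exactly
  list(mu = unname(stats::coef(fit)[["t"]]),
       se = unname(sm$coefficients["t", "Std. Error"]),
       r_squared = sm$r.squared, n = sum(keep))
}

#' Detect exponential and nitrogen-limitation phases
#'
#' With `basis = "ammonium"`, the N-limited (Nlim) phase starts at the
#' first time ammonium falls below `nh4_threshold_mM`. With
#' `basis = "do"`, it starts at the local minimum of the 3-point moving
#' average of %DO that is followed by a sustained rise (the spike in
#' dissolved oxygen when growth slows). The exponential phase ends where
#' the Nlim phase begins.
#'
#' @param series A time series.
#' @param basis `"ammonium"`, `"do"`, or `"manual"`.
#' @param nh4_threshold_mM Ammonium depletion threshold (default 0.1 mM).
#' @param manual For `basis = "manual"`: numeric length-2, start and end of
#'   the Nlim phase.
#' @return A `phase_annotation` list: `exponential` and `nlim` intervals
#'   (each `c(t_start, t_end)`, `nlim` may be `NULL`), `basis`.
#'   If no change-point is found a single-phase annotation is returned with
#'   a warning.
#' @export
detect_phases <- function(series, basis = c("ammonium", "do", "manual"),
                          nh4_threshold_mM = 0.1, manual = NULL) {
  basis <- match.arg(basis)
  validate_timeseries(series)
  t <- series$time_h
  single <- function() {
    warning("no phase change-point found; returning single-phase annotation")
    structure(list(exponential = c(t[1], t[length(t)]), nlim = NULL,
                   basis = basis), class = "phase_annotation")
  }
  if (basis == "manual") {
    if (is.null(manual) || length(manual) != 2)
      stop("manual basis requires a length-2 Nlim interval")
    ann <- list(exponential = c(t[1], manual[1]), nlim = manual,
                basis = basis)
    return(structure(ann, class = "phase_annotation"))
  }
  if (basis == "ammonium") {
    if (!"nh4_mM" %in% names(series) || all(is.na(series$nh4_mM)))
      stop("ammonium channel missing from series")
    idx <- which(series$nh4_mM < nh4_threshold_mM)
    if (!length(idx)) return(single())
    i <- idx[1]
    if (i == 1L) {
      t_n <- t[1]
    } else {
      # interpolate the threshold crossing between samples
      n1 <- series$nh4_mM[i - 1]; n2 <- series$nh4_mM[i]
      t_n <- t[i - 1] + (t[i] - t[i - 1]) *
        (n1 - nh4_threshold_mM) / max(n1 - n2, 1e-12)
    }
  } else {
    if (!"do_percent" %in% names(series) || all(is.na(series$do_percent)))
      stop("%DO channel missing from series")
    x <- series$do_percent
    sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    sm[1] <- x[1]; sm[length(x)] <- x[length(x)]
    sm <- as.numeric(sm)
    # local minimum followed by a clear rise within the next few samples
    cand <- NULL
    for (i in 2:(length(sm) - 2)) {
      if (sm[i] <= sm[i - 1] && sm[i + 1] > sm[i]) {
        ahead <- sm[(i + 1):min(length(sm), i + 3)]
        if (max(ahead) - sm[i] > 5) { cand <- i; break }
      }
    }
    if (is.null(cand)) return(single())
    t_n <- t[cand]
  }
  structure(list(exponential = c(t[1], t_n),
                 nlim = c(t_n, t[length(t)]), basis = basis),
            class = "phase_annotation")
}

phase_window <- function(series, phase) {
  if (inherits(phase, "phase_annotation")) stop("pass a named phase interval")
  phase
}

biomass_time_integral <- function(time_h, cdw) {
  # cumulative integral of CDW over time (g h / L) using the logarithmic
  # mean within each interval: exact for exponentially growing biomass,
  # reduces to the trapezoid when the segment is flat
  x1 <- utils::head(cdw, -1); x2 <- utils::tail(cdw, -1)
  dt <- diff(time_h)
  seg <- ifelse(x1 > 0 & x2 > 0 & abs(x2 - x1) > 1e-9 * pmax(x1, x2),
                (x2 - x1) / log(x2 / x1), (x1 + x2) / 2)
  c(0, cumsum(dt * seg))
}

# last time in `window` at which OD is still rising (drops the stationary
# plateau after substrate exhaustion from fitting windows); OD is smoothed
# with a 3-point moving average first so measurement noise does not extend
# the window across the plateau
trim_growth_window <- function(series, window, plateau_frac = 0.95) {
  keep <- which(series$time_h >= window[1] & series$time_h <= window[2] &
                  !is.na(series$od))
  if (length(keep) < 4) return(window)
  od <- series$od[keep]
  sm <- as.numeric(stats::filter(od, rep(1 / 3, 3), sides = 2))
  sm[1] <- od[1]; sm[length(od)] <- od[length(od)]
  # plateau level from the trailing samples, robust to a noisy maximum
  level <- stats::median(utils::tail(sm, 5))
  cut <- which(sm >= plateau_frac * level)[1]
  if (is.na(cut) || cut < 3) return(window)
  c(window[1], series$time_h[keep[cut]])
}

#' Specific consumption/production rate of an analyte
#'
#' Regresses the analyte amount (mmol/L) on the biomass-time integral
#' (g h / L); the slope is the biomass-specific rate q in
#' mmol/gCDW/h. Consumption is negative, production positive.
#'
#' @param series A time series.
#' @param analyte One of `"glucose"`, `"xylose"`, `"eg"`, `"ga"`,
#'   `"glycerol"`, or `"nh4"`.
#' @param phase Numeric length-2 time interval (h), e.g. from
#'   [detect_phases()].
#' @param od_to_cdw_coeff OD-to-CDW calibration coefficient.
#' @return List with `q` (mmol/gCDW/h), `se`, `n`.
#' @export
specific_rate <- function(series, analyte, phase,
                          od_to_cdw_coeff = 0.3) {
  validate_timeseries(series)
  if (analyte == "nh4") {
    col <- "nh4_mM"; to_mM <- 1
  } else {
    if (!analyte %in% names(ANALYTES)) stop("unknown analyte ", analyte)
    col <- ANALYTES[[analyte]]
    to_mM <- 1000 / MOLAR_MASS[[analyte]]
  }
  keep <- series$time_h >= phase[1] & series$time_h <= phase[2] &
    !is.na(series[[col]]) & !is.na(series$od)
  if (sum(keep) < 3) stop("need at least 3 points inside the phase")
  cdw <- od_to_cdw(series$od, od_to_cdw_coeff)
  if (all(cdw[keep] <= 0)) stop("zero biomass in the phase")
  it <- biomass_time_integral(series$time_h, cdw)[keep]
  mmol <- series[[col]][keep] * to_mM
  if (stats::var(it) < 1e-30) stop("degenerate biomass-time integral")
  if (stats::var(mmol) < 1e-30)
    return(list(q = 0, se = 0, n = sum(keep)))
  fit <- stats::lm(mmol ~ it)
  sm <- suppressWarnings(summary(fit))   # noise-free data fits exactly
  list(q = unname(stats::coef(fit)[["it"]]),
       se = unname(sm$coefficients["it", "Std. Error"]),
       n = sum(keep))
}

#' Molar, Cmol and mass product yields
#'
#' @param delta_product Product formed (mmol, or g for [mass_yield()]).
#' @param delta_substrate Substrate consumed (> 0; mmol or g).
#' @param product,substrate Compound names (for carbon counts / molar
#'   masses); defaults are GA on EG.
#' @return Yield: mol/mol, Cmol/Cmol or g/g.
#' @export
molar_yield <- function(delta_product, delta_substrate) {
  if (delta_substrate <= 0) stop("substrate consumption must be > 0")
  delta_product / delta_substrate
}

#' @rdname molar_yield
#' @export
cmol_yield <- function(delta_product, delta_substrate,
                       product = "ga", substrate = "eg") {
  molar_yield(delta_product, delta_substrate) *
    CARBON_ATOMS[[product]] / CARBON_ATOMS[[substrate]]
}

#' @rdname molar_yield
#' @export
mass_yield <- function(delta_product, delta_substrate,
                       product = "ga", substrate = "eg") {
  molar_yield(delta_product, delta_substrate) *
    MOLAR_MASS[[product]] / MOLAR_MASS[[substrate]]
}

#' Conversion yield from cumulative regression
#'
#' Least-squares slope (free intercept) of cumulative product formed
#' against cumulative substrate consumed; the slope of that line is the
#' conversion yield, robust to a nonzero starting offset.
#'
#' @param substrate_consumed,product_formed Paired cumulative amounts
#'   (mmol), `substrate_consumed` non-decreasing.
#' @return List with `slope` (mol/mol), `se`, `n`.
#' @export
regression_yield <- function(substrate_consumed, product_formed) {
  stopifnot(length(substrate_consumed) == length(product_formed))
  if (length(substrate_consumed) < 3) stop("need at least 3 paired points")
  if (any(diff(substrate_consumed) < -1e-9))
    stop("substrate consumption must be non-decreasing")
  if (stats::var(substrate_consumed) < 1e-30)
    stop("degenerate predictor: substrate consumption is constant")
  fit <- stats::lm(product_formed ~ substrate_consumed)
  sm <- suppressWarnings(summary(fit))   # noise-free data fits exactly
  se <- sm$coefficients["substrate_consumed", "Std. Error"]
  if (!is.finite(se)) se <- 0   # exact fit
  list(slope = unname(stats::coef(fit)[["substrate_consumed"]]),
       se = se, n = length(substrate_consumed))
}

#' Carbon-balance closure
#'
#' Sum of the Cmol/Cmol yields of biomass, CO2 and any net carbon products
#' per Cmol substrate. Product/substrate pairs whose net carbon sum is zero
#' (EG in, GA out at 100% yield) cancel and need not be listed.
#'
#' @param y_x_s_cmol Biomass yield, Cmol/Cmol.
#' @param y_co2_s_cmol CO2 yield, Cmol/Cmol.
#' @param extra_product_cmol_yields Optional numeric vector of further net
#'   product yields (Cmol/Cmol).
#' @return Closure fraction (1 = fully closed). Values above 1.05 are
#'   flagged with a warning.
#' @export
carbon_balance <- function(y_x_s_cmol, y_co2_s_cmol,
                           extra_product_cmol_yields = numeric()) {
  stopifnot(y_x_s_cmol >= 0, y_co2_s_cmol >= 0,
            all(extra_product_cmol_yields >= 0))
  closure <- y_x_s_cmol + y_co2_s_cmol + sum(extra_product_cmol_yields)
  if (closure > 1.05)
    warning(sprintf("carbon closure %.3f exceeds 1.05", closure))
  closure
}

#' Respiratory quotient
#'
#' @param y_co2_x CO2 yield on biomass, mmol/gCDW (or any consistent
#'   CO2 amount).
#' @param y_o2_x O2 yield on biomass in the same unit (> 0).
#' @return RQ = CO2/O2 (mol/mol).
#' @export
respiratory_quotient <- function(y_co2_x, y_o2_x) {
  if (y_o2_x <= 0) stop("O2 yield must be > 0")
  y_co2_x / y_o2_x
}

#' Full physiology summary of a batch run
#'
#' Convenience driver: detects phases (ammonium basis when available,
#' %DO otherwise), fits per-phase growth rates, computes specific rates for
#' every analyte present, substrate-based yields over the Nlim phase (or the
#' whole run when single-phase), GA-on-EG yields, off-gas yields and RQ, and
#' the carbon-balance closure.
#'
#' @param series A time series.
#' @param od_to_cdw_coeff OD-to-CDW coefficient (default 0.3).
#' @param phases Optional `phase_annotation` to reuse.
#' @return A `physiology_summary` list.
#' @export
summarize_physiology <- function(series, od_to_cdw_coeff = 0.3,
                                 phases = NULL) {
  validate_timeseries(series)
  if (is.null(phases)) {
    basis <- if ("nh4_mM" %in% names(series) &&
                 !all(is.na(series$nh4_mM))) "ammonium" else "do"
    phases <- suppressWarnings(detect_phases(series, basis))
  }
  exp_win <- phases$exponential
  nlim_win <- phases$nlim
  if (!is.null(nlim_win))        # stop fitting at the stationary plateau
    nlim_win <- trim_growth_window(series, nlim_win)
  mu_exp <- tryCatch(fit_growth_rate(series, exp_win),
                     error = function(e) NULL)
  mu_nlim <- if (!is.null(nlim_win))
    tryCatch(fit_growth_rate(series, nlim_win), error = function(e) NULL)

  main_win <- nlim_win %||% exp_win
  q <- list()
  for (a in names(ANALYTES)) {
    col <- ANALYTES[[a]]
    if (col %in% names(series) && !all(is.na(series[[col]])))
      q[[a]] <- tryCatch(specific_rate(series, a, main_win,
                                       od_to_cdw_coeff),
                         error = function(e) NULL)
  }

  win_rows <- series$time_h >= main_win[1] & series$time_h <= main_win[2]
  sub <- series[win_rows, , drop = FALSE]
  cdw <- od_to_cdw(sub$od, od_to_cdw_coeff)
  dX <- cdw[nrow(sub)] - cdw[1]

  delta <- function(col) if (col %in% names(sub) && !all(is.na(sub[[col]])))
    sub[[col]][1] - sub[[col]][nrow(sub)] else 0
  dS_g <- delta("glc_g_l") + delta("xyl_g_l")      # sugars consumed, g/L
  dEG_mmol <- delta("eg_g_l") * 1000 / MOLAR_MASS[["eg"]]
  dGA_mmol <- -delta("ga_g_l") * 1000 / MOLAR_MASS[["ga"]]

  y_xs_g <- if (dS_g > 0) dX / dS_g else NA_real_
  cfrac_s <- if (delta("glc_g_l") + delta("xyl_g_l") > 0) {
    (delta("glc_g_l") * CARBON_FRACTION[["glucose"]] +
       delta("xyl_g_l") * CARBON_FRACTION[["xylose"]]) / dS_g
  } else NA_real_
  y_xs_cmol <- if (!is.na(y_xs_g))
    y_xs_g * biomass_c_fraction() / cfrac_s else NA_real_

  # off-gas integrals over the window
  gas_yield <- function(col) {
    if (!col %in% names(sub) || all(is.na(sub[[col]])) || dX <= 0)
      return(NA_real_)
    tot <- sum(diff(sub$time_h) *
                 (utils::head(sub[[col]], -1) + utils::tail(sub[[col]], -1)) / 2)
    tot / dX
  }
  y_co2_x <- gas_yield("co2_mmol_l_h")
  y_o2_x <- gas_yield("o2_mmol_l_h")
  rq <- if (!is.na(y_co2_x) && !is.na(y_o2_x) && y_o2_x > 0)
    respiratory_quotient(y_co2_x, y_o2_x) else NA_real_
  y_co2_s_cmol <- if (!is.na(y_co2_x) && dS_g > 0)
    (y_co2_x * dX / 1000) / (dS_g * cfrac_s / MOLAR_MASS[["c"]]) else NA_real_

  # only meaningful when EG was actually present and consumed beyond noise
  eg_present <- "eg_g_l" %in% names(sub) &&
    max(sub$eg_g_l, na.rm = TRUE) > 0.5 && dEG_mmol > 1
  y_ga_eg <- if (eg_present) {
    list(mol = molar_yield(dGA_mmol, dEG_mmol),
         g = mass_yield(dGA_mmol, dEG_mmol),
         cmol = cmol_yield(dGA_mmol, dEG_mmol))
  } else NULL

  net_ga_cmol <- if (dS_g > 0)
    max(0, (dGA_mmol - dEG_mmol) * 2 / 1000) /
      (dS_g * cfrac_s / MOLAR_MASS[["c"]]) else 0
  closure <- if (!is.na(y_xs_cmol) && !is.na(y_co2_s_cmol))
    carbon_balance(y_xs_cmol, y_co2_s_cmol, net_ga_cmol) else NA_real_

  structure(list(
    phases = phases,
    mu_exp = mu_exp, mu_nlim = mu_nlim,
    q = q,
    yields = list(y_x_s_g = y_xs_g, y_x_s_cmol = y_xs_cmol,
                  y_co2_x = y_co2_x, y_o2_x = y_o2_x,
                  y_co2_s_cmol = y_co2_s_cmol, y_ga_eg = y_ga_eg),
    rq = rq, carbon_closure = closure),
    class = "physiology_summary")
}

#' @export
print.physiology_summary <- function(x, ...) {
  cat("physiology_summary\n")
  if (!is.null(x$mu_exp))
    cat(sprintf("  mu_exp  = %.4f 1/h (se %.4f)\n", x$mu_exp$mu, x$mu_exp$se))
  if (!is.null(x$mu_nlim))
    cat(sprintf("  mu_nlim = %.4f 1/h (se %.4f)\n", x$mu_nlim$mu, x$mu_nlim$se))
  if (!is.na(x$rq)) cat(sprintf("  RQ = %.3f\n", x$rq))
  if (!is.null(x$yields$y_ga_eg))
    cat(sprintf("  Y_GA/EG = %.3f mol/mol (%.3f g/g)\n",
                x$yields$y_ga_eg$mol, x$yields$y_ga_eg$g))
  if (!is.na(x$carbon_closure))
    cat(sprintf("  carbon closure = %.3f\n", x$carbon_closure))
  invisible(x)
}
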