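#' Solute flux from a closed core incubation
#'
#' Computes the net flux of a solute between soil and overlying water from
#' start and end concentrations in the headspace of a sealed core incubation.
#' Positive values are effluxes (release from the soil to the water); an
#' influx is returned as a negative value, never an error.
#'
#' @param c_start,c_end start and end concentrations in the headspace
#'   (umol L-1).
#' @param volume_L headspace water volume (L).
#' @param area_m2 core cross-sectional area (m2).
#' @param duration_d incubation duration (days).
#' @return Flux in mmol m-2 d-1 (vectorized).
#' @details value = (c_end - c_start) * volume / (area * duration), i.e.
#'   umol m-2 d-1, divided by 1000 to give mmol m-2 d-1.
#' @examples
#' compute_flux(10, 14, 0.25, 5.027e-3, 0.1667) # ~1.19 mmol m-2 d-1
#' @export
compute_flux <- function(c_start, c_end, volume_L, area_m2, duration_d) {
  if (any(!is.finite(c_start)) || any(!is.finite(c_end)) ||
      any(c_start < 0) || any(c_end < 0))
    stop_input("concentrations must be finite and >= 0")
  if (any(duration_d <= 0)) stop_input("'duration_d' must be > 0")
  if (any(area_m2 <= 0)) stop_input("'area_m2' must be > 0")
  if (any(volume_L <= 0)) stop_input("'volume_L' must be > 0")
  (c_end - c_start) * volume_L / (area_m2 * duration_d) / 1000
}

#' Dissolved inorganic nitrogen (DIN) flux
#'
#' DIN flux is the sum of the NH4+ and NOx- (NO3- + NO2-) fluxes of the same
#' core and day. Each analyte's share of DIN is reported when DIN > 0.
#'
#' @param nh4,nox either plain numbers (mmol m-2 d-1) or lists with elements
#'   `value` and optionally `core_id` and `day`; when both carry identifiers
#'   they must match.
#' @return A list with `value`, `nh4_share`, `nox_share` (shares are `NA`
#'   when DIN <= 0) and any matched identifiers.
#' @export
compute_din_flux <- function(nh4, nox) {
  as_flux <- function(x) if (is.list(x)) x else list(value = x)
  a <- as_flux(nh4); b <- as_flux(nox)
  for (id in c("core_id", "day")) {
    if (!is.null(a[[id]]) && !is.null(b[[id]]) && !identical(a[[id]], b[[id]]))
      stop_input("NH4+ and NOx- fluxes disagree on '", id, "'")
  }
  din <- a$value + b$value
  shares_ok <- is.finite(din) && din > 0
  list(value = din,
       nh4_share = if (shares_ok) a$value / din else NA_real_,
       nox_share = if (shares_ok) b$value / din else NA_real_,
       core_id = a$core_id %||% b$core_id,
       day = a$day %||% b$day)
}

#' Volumetric NH4+ production rate from an anoxic jar series
#'
#' Fits an ordinary least-squares regression of porewater NH4+ concentration
#' on incubation time. When the slope is significant (two-sided t-test,
#' p < alpha) the volume-specific rate of the bulk soil is the slope
#' multiplied by porosity (1 uM = 1 nmol per cm3 of porewater, so
#' slope [uM d-1] x porosity [-] = nmol cm-3 d-1). Non-significant slopes are
#' reported as not available with the regression diagnostics retained.
#'
#' @param times sampling times (days), strictly increasing, length >= 3.
#' @param conc NH4+ concentrations (uM).
#' @param porosity porewater volume fraction of the bulk soil, in (0, 1).
#' @param alpha significance level of the slope test (default 0.05).
#' @return An object of class `"volumetric_rate"`: list with `slope_uM_d`,
#'   `p_value`, `r_squared`, `significant`, and `rate` (nmol cm-3 d-1, `NA`
#'   when not significant).
#' @export
fit_jar_rate <- function(times, conc, porosity, alpha = 0.05) {
  if (length(times) != length(conc)) stop_input("times and conc differ in length")
  if (length(times) < 3) stop_input("at least 3 time points are required")
  if (any(diff(times) <= 0)) stop_input("times must be strictly increasing")
  if (stats::var(times) == 0) stop_input("zero variance in times")
  check_number(porosity, "porosity", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  fit <- stats::lm(conc ~ times)
  slope <- unname(stats::coef(fit)[2])
  n <- length(times)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((conc - mean(conc))^2)
  se <- sqrt(rss / (n - 2) / sum((times - mean(times))^2))
  # exact collinear fits give se = 0 -> |t| = Inf -> p = 0; a flat exact
  # series gives 0/0 -> NaN, treated as not significant
  p <- 2 * stats::pt(-abs(slope / se), n - 2)
  significant <- is.finite(p) && p < alpha
  structure(list(
    slope_uM_d = slope,
    intercept_uM = unname(stats::coef(fit)[1]),
    p_value = p,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    significant = significant,
    rate = if (significant) slope * porosity else NA_real_,
    porosity = porosity,
    alpha = alpha,
    n = length(times)
  ), class = "volumetric_rate")
}

#' @export
print.volumetric_rate <- function(x, ...) {
  cat(sprintf("Jar regression: slope %.4g uM/d (p = %.3g, r2 = %.3f)\n",
              x$slope_uM_d, x$p_value, x$r_squared))
  if (x$significant)
    cat(sprintf("Volumetric rate: %.4g nmol cm-3 d-1 (porosity %.2f)\n",
                x$rate, x$porosity))
  else
    cat("Slope not significant at alpha =", x$alpha, "- rate not available\n")
  invisible(x)
}

#' Depth-integrate volumetric rates to an areal rate
#'
#' Integrates layer-wise volumetric rates (nmol cm-3 d-1) over a target depth
#' range, filling interior unmeasured intervals by linear interpolation
#' between the midpoints of the neighbouring layers. The areal rate is
#' sum(rate x thickness) in nmol cm-2 d-1, converted to mmol m-2 d-1
#' (x 1e4 cm2 m-2 / 1e6 nmol mmol-1 = x 0.01).
#'
#' @param layers data.frame with columns `top_cm`, `bottom_cm`, `rate`
#'   (nmol cm-3 d-1; `NA` when a required layer's regression was not
#'   significant).
#' @param target_range numeric length-2, integration range in cm
#'   (default c(0, 20)).
#' @return Object of class `"areal_rate"`: `value` (mmol m-2 d-1; `NA` when
#'   incomplete), the augmented layer table, and an `incomplete` flag with
#'   reasons. A missing measured layer makes the result incomplete rather
#'   than silently dropped.
#' @export
depth_integrate <- function(layers, target_range = c(0, 20)) {
  require_columns(layers, c("top_cm", "bottom_cm", "rate"), "depth_integrate")
  layers <- layers[order(layers$top_cm), , drop = FALSE]
  if (nrow(layers) < 2) stop_input("at least two layers are required")
  if (any(layers$bottom_cm <= layers$top_cm))
    stop_input("each layer must have bottom_cm > top_cm")
  if (any(layers$top_cm[-1] < layers$bottom_cm[-nrow(layers)]))
    stop_input("layers overlap")
  if (layers$top_cm[1] != target_range[1] ||
      layers$bottom_cm[nrow(layers)] != target_range[2])
    stop_input("layers must start and end at the target range boundaries")
  mid <- (layers$top_cm + layers$bottom_cm) / 2
  out <- data.frame(top_cm = layers$top_cm, bottom_cm = layers$bottom_cm,
                    rate = layers$rate, interpolated = FALSE)
  # fill interior gaps by midpoint interpolation between adjacent layers
  add <- NULL
  for (i in seq_len(nrow(layers) - 1)) {
    if (layers$top_cm[i + 1] > layers$bottom_cm[i]) {
      g_top <- layers$bottom_cm[i]; g_bot <- layers$top_cm[i + 1]
      g_mid <- (g_top + g_bot) / 2
      w <- (g_mid - mid[i]) / (mid[i + 1] - mid[i])
      r <- (1 - w) * layers$rate[i] + w * layers$rate[i + 1]
      add <- rbind(add, data.frame(top_cm = g_top, bottom_cm = g_bot,
                                   rate = r, interpolated = TRUE))
    }
  }
  out <- rbind(out, add)
  out <- out[order(out$top_cm), , drop = FALSE]
  incomplete <- any(is.na(out$rate))
  value <- if (incomplete) NA_real_ else
    sum(out$rate * (out$bottom_cm - out$top_cm)) * 0.01
  structure(list(value = value, layers = out, incomplete = incomplete,
                 target_range = target_range),
            class = "areal_rate")
}

#' @export
print.areal_rate <- function(x, ...) {
  if (x$incomplete)
    cat("Areal rate: incomplete (missing layer rate)\n")
  else
    cat(sprintf("Areal rate: %.4g mmol m-2 d-1 over %g-%g cm\n",
                x$value, x$target_range[1], x$target_range[2]))
  invisible(x)
}

#' Porewater solute inventory of a depth profile
#'
#' Inventory = sum over layers of concentration (mM = umol cm-3 of porewater)
#' x porosity x thickness (cm), i.e. umol cm-2, converted to mmol m-2 (x10).
#'
#' @param profile data.frame with columns `depth_top_cm`, `depth_bottom_cm`,
#'   `conc_mM`, `porosity`, optionally `analyte`.
#' @param analyte analyte to select when the profile carries several.
#' @return Inventory in mmol m-2.
#' @export
porewater_inventory <- function(profile, analyte = NULL) {
  require_columns(profile, c("depth_top_cm", "depth_bottom_cm", "conc_mM",
                             "porosity"), "porewater_inventory")
  if (!is.null(analyte) && "analyte" %in% names(profile))
    profile <- profile[profile$analyte == analyte, , drop = FALSE]
  if (nrow(profile) == 0) stop_input("empty profile")
  profile <- profile[order(profile$depth_top_cm), , drop = FALSE]
  gaps <- which(profile$depth_top_cm[-1] != profile$depth_bottom_cm[-nrow(profile)])
  if (length(gaps))
    stop_input("profile has gap(s) below ",
               paste(profile$depth_bottom_cm[gaps], collapse = ", "), " cm")
  if (any(!is.finite(profile$conc_mM)) || any(profile$conc_mM < 0))
    stop_input("concentrations must be finite and >= 0")
  sum(profile$conc_mM * profile$porosity *
        (profile$depth_bottom_cm - profile$depth_top_cm)) * 10
}

#' Porewater accumulation rate between two profiles
#'
#' @param profile_t1,profile_t2 porewater profiles (see
#'   [porewater_inventory()]) at times `t1 < t2`; times are taken from a
#'   `time_point` column when not given.
#' @param analyte analyte to select.
#' @param t1,t2 days of the two profiles.
#' @return Rate in mmol m-2 d-1 (negative when the inventory decreased).
#' @export
accumulation_rate <- function(profile_t1, profile_t2, analyte = NULL,
                              t1 = NULL, t2 = NULL) {
  pick_day <- function(p, t) {
    if (!is.null(t)) return(t)
    if ("time_point" %in% names(p)) return(unique(p$time_point)[1])
    stop_input("profile time unknown: give t1/t2 or a time_point column")
  }
  if ("station" %in% names(profile_t1) && "station" %in% names(profile_t2) &&
      !identical(unique(profile_t1$station), unique(profile_t2$station)))
    stop_input("profiles are from different stations")
  t1 <- pick_day(profile_t1, t1); t2 <- pick_day(profile_t2, t2)
  if (t2 <= t1) stop_input("t2 must be > t1")
  (porewater_inventory(profile_t2, analyte) -
     porewater_inventory(profile_t1, analyte)) / (t2 - t1)
}

#' Nitrogen mass balance for one station and sectioning time point
#'
#' Potential denitrification is the NH4+ production not accounted for by the
#' DIN efflux or by porewater NH4+ accumulation; the missing nitrogen is
#' assumed lost as gaseous N (N2, N2O). A negative raw residual is clamped to
#' zero and flagged (denitrification negligible). Potential NH4+ oxidation is
#' the clamped potential denitrification plus the NOx- efflux.
#'
#' @param production areal NH4+ production, either a number (mmol m-2 d-1) or
#'   an [depth_integrate()] result (an incomplete one marks the budget
#'   incomplete).
#' @param din_efflux,nox_efflux aggregated effluxes (mmol m-2 d-1).
#' @param accumulation porewater NH4+ accumulation rate (mmol m-2 d-1).
#' @param station,time_point optional identifiers carried through.
#' @return Object of class `"nitrogen_budget"` with raw and clamped potential
#'   denitrification, potential NH4+ oxidation and the denitrified fraction
#'   of production (clamped / production, in [0, 1] when production > 0).
#' @export
nitrogen_budget <- function(production, din_efflux, nox_efflux, accumulation,
                            station = NA_character_, time_point = NA_real_) {
  incomplete <- FALSE
  if (inherits(production, "areal_rate")) {
    incomplete <- production$incomplete
    production <- production$value
  }
  if (incomplete || is.na(production)) {
    out <- list(station = station, time_point = time_point,
                production = NA_real_, din_efflux = din_efflux,
                nox_efflux = nox_efflux, accumulation = accumulation,
                denit_raw = NA_real_, denit = NA_real_,
                negligible = NA, nh4_oxidation = NA_real_,
                denit_fraction = NA_real_, incomplete = TRUE)
    return(structure(out, class = "nitrogen_budget"))
  }
  raw <- production - din_efflux - accumulation
  clamped <- max(raw, 0)
  structure(list(
    station = station, time_point = time_point,
    production = production, din_efflux = din_efflux,
    nox_efflux = nox_efflux, accumulation = accumulation,
    denit_raw = raw, denit = clamped,
    negligible = raw < 0,
    nh4_oxidation = clamped + nox_efflux,
    denit_fraction = if (production > 0) clamped / production else NA_real_,
    incomplete = FALSE
  ), class = "nitrogen_budget")
}

#' @export
print.nitrogen_budget <- function(x, ...) {
  hdr <- sprintf("Nitrogen budget%s%s",
                 if (!is.na(x$station)) paste0(" - station ", x$station) else "",
                 if (!is.na(x$time_point)) paste0(", day ", x$time_point) else "")
  cat(hdr, "\n")
  if (x$incomplete) { cat("  incomplete (missing production)\n"); return(invisible(x)) }
  cat(sprintf("  NH4+ production:        %8.3f mmol m-2 d-1\n", x$production))
  cat(sprintf("  DIN efflux:             %8.3f mmol m-2 d-1\n", x$din_efflux))
  cat(sprintf("  porewater accumulation: %8.3f mmol m-2 d-1\n", x$accumulation))
  cat(sprintf("  potential denitrif.:    %8.3f (raw %.3f%s)\n", x$denit,
              x$denit_raw, if (x$negligible) ", negligible" else ""))
  cat(sprintf("  potential NH4+ oxid.:   %8.3f mmol m-2 d-1\n", x$nh4_oxidation))
  if (!is.na(x$denit_fraction))
    cat(sprintf("  denitrified fraction:   %8.3f\n", x$denit_fraction))
  invisible(x)
}

#' Aggregate replicate-core fluxes over a time window
#'
#' Per measurement day, fluxes are averaged across replicate cores (SEM
#' across cores); the per-day means are then combined by a time-weighted mean
#' over the window, each day weighted by the span of the window it represents
#' (midpoints between neighbouring days, clipped to the window).
#'
#' @param fluxes data.frame with columns `day`, `core_id`, `value`
#'   (mmol m-2 d-1).
#' @param window numeric length-2 `(day_from, day_to]`; measurements with
#'   `day_from < day <= day_to` are used.
#' @return List with `value`, `sem` (`NA` with a flag when only one core
#'   measurement exists), `n_days`, `days`.
#' @export
aggregate_fluxes <- function(fluxes, window) {
  require_columns(fluxes, c("day", "core_id", "value"), "aggregate_fluxes")
  sel <- fluxes$day > window[1] & fluxes$day <= window[2]
  f <- fluxes[sel, , drop = FALSE]
  if (nrow(f) == 0) stop_input("no flux measurements in window (",
                               window[1], ", ", window[2], "]")
  days <- sort(unique(f$day))
  mu <- sem <- numeric(length(days))
  for (i in seq_along(days)) {
    v <- f$value[f$day == days[i]]
    mu[i] <- mean(v)
    sem[i] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  bounds <- c(window[1], (days[-1] + days[-length(days)]) / 2, window[2])
  w <- diff(bounds); w <- w / sum(w)
  list(value = sum(w * mu),
       sem = if (all(is.na(sem))) NA_real_ else
         sqrt(sum((w * sem)^2, na.rm = TRUE)),
       single_measurement = nrow(f) == 1,
       n_days = length(days), days = days, weights = w)
}

#' Estimate nitrogen budgets for a whole dataset
#'
#' Runs the full mass-balance chain on tabular inputs: per-core fluxes ->
#' aggregated NH4+/NOx-/DIN effluxes per sectioning window; jar series ->
#' layer regressions -> depth-integrated areal NH4+ production; porewater
#' profiles -> NH4+ inventories -> accumulation rates; and combines them into
#' one budget per station and sectioning time point. The flux window for the
#' budget at sectioning day T is (previous sectioning, T], starting at the
#' pre-flood day for the first sectioning.
#'
#' @param fluxes data.frame: `core_id, station, day, analyte, c_start_uM,
#'   c_end_uM, volume_L, area_m2, duration_d` (analytes `"NH4"`, `"NOx"`).
#' @param jars data.frame: `station, time_point, depth_top_cm,
#'   depth_bottom_cm, day, nh4_uM, porosity`.
#' @param porewater data.frame: `station, time_point, depth_top_cm,
#'   depth_bottom_cm, analyte, conc_mM, porosity`.
#' @param alpha significance level for jar regressions.
#' @param target_range depth-integration range (cm).
#' @param baseline_day day of the pre-flood porewater baseline (default 0).
#' @return A data.frame of class `"nitrogen_budget_table"`, one row per
#'   station x sectioning time point, with all budget components, the SEM of
#'   the DIN efflux, and incompleteness flags.
#' @export
estimate_nitrogen_budgets <- function(fluxes, jars, porewater, alpha = 0.05,
                                      target_range = c(0, 20),
                                      baseline_day = 0) {
  require_columns(fluxes, c("core_id", "station", "day", "analyte",
                            "c_start_uM", "c_end_uM", "volume_L", "area_m2",
                            "duration_d"), "fluxes")
  require_columns(jars, c("station", "time_point", "depth_top_cm",
                          "depth_bottom_cm", "day", "nh4_uM", "porosity"),
                  "jars")
  require_columns(porewater, c("station", "time_point", "depth_top_cm",
                               "depth_bottom_cm", "analyte", "conc_mM",
                               "porosity"), "porewater")
  fluxes$value <- compute_flux(fluxes$c_start_uM, fluxes$c_end_uM,
                               fluxes$volume_L, fluxes$area_m2,
                               fluxes$duration_d)
  stations <- sort(unique(jars$station))
  tps <- sort(unique(jars$time_point))
  rows <- vector("list", length(stations) * length(tps))
  idx <- 0
  for (st in stations) {
    prev <- baseline_day
    for (tp in tps) {
      idx <- idx + 1
      jsub <- jars[jars$station == st & jars$time_point == tp, , drop = FALSE]
      lay <- unique(jsub[, c("depth_top_cm", "depth_bottom_cm")])
      lay <- lay[order(lay$depth_top_cm), , drop = FALSE]
      rates <- vapply(seq_len(nrow(lay)), function(i) {
        s <- jsub[jsub$depth_top_cm == lay$depth_top_cm[i] &
                    jsub$depth_bottom_cm == lay$depth_bottom_cm[i], ]
        s <- s[order(s$day), ]
        fit_jar_rate(s$day, s$nh4_uM, s$porosity[1], alpha)$rate
      }, numeric(1))
      prod <- depth_integrate(
        data.frame(top_cm = lay$depth_top_cm, bottom_cm = lay$depth_bottom_cm,
                   rate = rates), target_range)
      win <- c(prev, tp)
      fsub <- fluxes[fluxes$station == st, , drop = FALSE]
      nh4 <- aggregate_fluxes(fsub[fsub$analyte == "NH4", ], win)
      nox <- aggregate_fluxes(fsub[fsub$analyte == "NOx", ], win)
      din <- compute_din_flux(nh4$value, nox$value)
      pw <- porewater[porewater$station == st & porewater$analyte == "NH4", ]
      acc <- accumulation_rate(pw[pw$time_point == prev, ],
                               pw[pw$time_point == tp, ],
                               t1 = prev, t2 = tp)
      b <- nitrogen_budget(prod, din$value, nox$value, acc,
                           station = st, time_point = tp)
      rows[[idx]] <- data.frame(
        station = st, time_point = tp,
        production = b$production, nh4_efflux = nh4$value,
        nox_efflux = nox$value, din_efflux = b$din_efflux,
        din_sem = sqrt(sum(c(nh4$sem, nox$sem)^2, na.rm = TRUE)),
        accumulation = b$accumulation, denit_raw = b$denit_raw,
        denit = b$denit, negligible = b$negligible,
        nh4_oxidation = b$nh4_oxidation,
        denit_fraction = b$denit_fraction, incomplete = b$incomplete,
        stringsAsFactors = FALSE)
      prev <- tp
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nitrogen_budget_table", "data.frame")
  out
}

#' @export
print.nitrogen_budget_table <- function(x, ...) {
  cat("Nitrogen budgets (mmol m-2 d-1):\n")
  print.data.frame(format_sig(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}
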