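#' Configuration of a synthetic microcosm scenario
#'
#' Defines the ground-truth parameters and experimental design of a seeded
#' synthetic dataset: two stations with contrasting organic-matter content
#' ("UC" rich, "C" poor), six porewater sectioning depth intervals, four
#' pooled jar depth intervals (with the 10-15 cm layer deliberately
#' unmeasured), four sectioning time points plus a pre-flood state, flux
#' incubations on replicate cores throughout, modular OTU community turnover
#' and a closed nitrogen budget with known denitrified fractions.
#'
#' All randomness downstream flows from `seed` through named substreams (one
#' per data type), so regenerating one table never perturbs another.
#'
#' @param seed master integer seed.
#' @param stations station labels.
#' @param depth_intervals_porewater,depth_intervals_jar two-column matrices
#'   of (top_cm, bottom_cm); porewater layers must be contiguous, ordered and
#'   non-overlapping; jar layers may leave the interpolated 10-15 cm gap.
#' @param sectioning_days days after flooding at which cores were sectioned.
#' @param preflood_day day label of the pre-flood state (default 0).
#' @param flux_days days of the replicate-core flux incubations.
#' @param jar_days sampling days of the anoxic jar incubations.
#' @param n_replicate_cores replicate cores per flux day (default 3).
#' @param otu_pool_size number of OTUs in the simulated pool.
#' @param n_modules number of boom-and-bust OTU co-occurrence modules.
#' @param size_jitter_sd Gaussian fragment-size jitter (bp) of observed
#'   peaks around their OTU centroid.
#' @param noise_peak_rate expected Poisson count of baseline noise peaks per
#'   electropherogram.
#' @param noise_area_mean,noise_area_rel_halfwidth,noise_area_dist noise-peak
#'   areas; default a narrow uniform band `mean * (1 +/- halfwidth)`,
#'   emulating peaks just above the instrument calling floor (`"exponential"`
#'   is available but is largely promoted to signal by the iterative filter).
#' @param total_area,area_lognorm_sd total signal fluorescence per sample and
#'   the multiplicative lognormal noise sd of individual peak areas.
#' @param detection_area_min instrument peak-calling floor: true-fragment
#'   peaks whose area falls below this are not called (0 disables). The
#'   default keeps called fragments above the baseline noise band.
#' @param true_denit_fraction stations x sectioning-days matrix of the true
#'   denitrified fraction of areal NH4+ production, in [0, 1].
#' @param true_production_profile stations x jar-layers matrix of volumetric
#'   NH4+ production (nmol cm-3 d-1) at multiplier 1.
#' @param production_multiplier stations x sectioning-days matrix scaling the
#'   production profile over time.
#' @param porosity_profile stations x porewater-layers matrix of porosity in
#'   (0, 1).
#' @param accumulation_share share of non-denitrified production routed to
#'   porewater accumulation (the rest is DIN efflux).
#' @param nox_share per-sectioning-day NOx- share of the DIN efflux.
#' @param jar_c0_uM initial jar porewater NH4+ concentration.
#' @param core_area_m2,core_volume_L,core_duration_d flux-core geometry and
#'   incubation duration.
#' @param ambient_nh4_uM,ambient_nox_uM headspace start concentrations.
#' @param qpcr_efficiency,qpcr_intercept amplification efficiency and Cq at
#'   one copy of the simulated standard curves.
#' @param qpcr_template_uL,qpcr_elution_uL,qpcr_wet_mass_g extraction chain.
#' @param water_content per-station gravimetric water content.
#' @param n_seawater_samples seawater control samples (community only).
#' @param measurement_noise list of per-instrument noise levels:
#'   `flux_rel` (relative, across cores), `jar_uM` (absolute, uM),
#'   `porewater_rel` (relative), `cq_sd` and `standards_cq_sd` (Cq units).
#'   Set all to zero for a noise-free scenario.
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(
    seed = 1L,
    stations = c("UC", "C"),
    depth_intervals_porewater = cbind(c(0, 1, 2, 5, 10, 15),
                                      c(1, 2, 5, 10, 15, 20)),
    depth_intervals_jar = cbind(c(0, 2, 5, 15), c(2, 5, 10, 20)),
    sectioning_days = c(7, 60, 120, 180),
    preflood_day = 0,
    flux_days = c(4, 11, 18, 25, 32, 46, 60, 74, 88, 102, 116, 148, 180),
    jar_days = c(0, 7, 14, 21, 28),
    n_replicate_cores = 3L,
    otu_pool_size = 150L,
    n_modules = 4L,
    size_jitter_sd = 0.15,
    noise_peak_rate = 20,
    noise_area_mean = 30,
    noise_area_rel_halfwidth = 0.1,
    noise_area_dist = c("uniform_band", "exponential"),
    total_area = 50000,
    area_lognorm_sd = 0.3,
    detection_area_min = 50,
    true_denit_fraction = rbind(UC = c(0.65, 0.75, 0.89, 0.80),
                                C = c(0.53, 0.40, 0.10, 0.0)),
    true_production_profile = rbind(UC = c(150, 80, 40, 15),
                                    C = c(60, 25, 10, 4)),
    production_multiplier = rbind(UC = c(0.5, 0.9, 1.33, 1.0),
                                  C = c(1.13, 0.6, 0.2, 0.01)),
    porosity_profile = rbind(UC = c(0.85, 0.80, 0.75, 0.70, 0.65, 0.60),
                             C = rep(0.45, 6)),
    accumulation_share = 0.3,
    nox_share = c(0.05, 0.35, 0.55, 0.70),
    jar_c0_uM = 100,
    core_area_m2 = 5.027e-3,
    core_volume_L = 0.25,
    core_duration_d = 4 / 24,
    ambient_nh4_uM = 5,
    ambient_nox_uM = 2,
    qpcr_efficiency = 0.95,
    qpcr_intercept = 37,
    qpcr_template_uL = 0.25,
    qpcr_elution_uL = 200,
    qpcr_wet_mass_g = 0.35,
    water_content = c(UC = 0.60, C = 0.35),
    n_seawater_samples = 5L,
    measurement_noise = list(flux_rel = 0.05, jar_uM = 0,
                             porewater_rel = 0.01, cq_sd = 0.15,
                             standards_cq_sd = 0.05)) {
  cfg_err <- function(field, why)
    stop_input("configuration error in '", field, "': ", why)
  check_intervals <- function(x, field, contiguous) {
    x <- as.matrix(x)
    if (ncol(x) != 2 || any(x[, 2] <= x[, 1]))
      cfg_err(field, "intervals need bottom > top")
    if (is.unsorted(x[, 1], strictly = TRUE))
      cfg_err(field, "intervals must be ordered")
    if (any(x[-1, 1] < x[-nrow(x), 2])) cfg_err(field, "intervals overlap")
    if (contiguous && any(x[-1, 1] != x[-nrow(x), 2]))
      cfg_err(field, "intervals must be contiguous")
    x
  }
  depth_intervals_porewater <-
    check_intervals(depth_intervals_porewater, "depth_intervals_porewater", TRUE)
  depth_intervals_jar <-
    check_intervals(depth_intervals_jar, "depth_intervals_jar", FALSE)
  if (length(seed) != 1 || is.na(seed)) cfg_err("seed", "one integer required")
  n_st <- length(stations); n_tp <- length(sectioning_days)
  shape_ok <- function(m, field, nc) {
    m <- as.matrix(m)
    if (nrow(m) != n_st || ncol(m) != nc)
      cfg_err(field, sprintf("expected %d x %d matrix", n_st, nc))
    m
  }
  true_denit_fraction <- shape_ok(true_denit_fraction, "true_denit_fraction", n_tp)
  if (any(true_denit_fraction < 0 | true_denit_fraction > 1))
    cfg_err("true_denit_fraction", "must lie in [0, 1]")
  true_production_profile <- shape_ok(true_production_profile,
                                      "true_production_profile",
                                      nrow(depth_intervals_jar))
  production_multiplier <- shape_ok(production_multiplier,
                                    "production_multiplier", n_tp)
  porosity_profile <- shape_ok(porosity_profile, "porosity_profile",
                               nrow(depth_intervals_porewater))
  if (any(porosity_profile <= 0 | porosity_profile >= 1))
    cfg_err("porosity_profile", "porosity must lie in (0, 1)")
  if (accumulation_share < 0 || accumulation_share >= 1)
    cfg_err("accumulation_share", "must lie in [0, 1)")
  if (length(nox_share) != n_tp || any(nox_share < 0 | nox_share > 1))
    cfg_err("nox_share", "one value in [0, 1] per sectioning day")
  if (is.unsorted(sectioning_days, strictly = TRUE) ||
      any(sectioning_days <= preflood_day))
    cfg_err("sectioning_days", "must be strictly increasing and after preflood_day")
  if (qpcr_efficiency <= 0 || qpcr_efficiency > 1.2)
    cfg_err("qpcr_efficiency", "implausible value")
  if (size_jitter_sd < 0) cfg_err("size_jitter_sd", "must be >= 0")
  if (noise_peak_rate < 0) cfg_err("noise_peak_rate", "must be >= 0")
  noise <- list(flux_rel = 0, jar_uM = 0, porewater_rel = 0, cq_sd = 0,
                standards_cq_sd = 0)
  if (is.numeric(measurement_noise) && length(measurement_noise) == 1) {
    noise[] <- measurement_noise
  } else {
    bad <- setdiff(names(measurement_noise), names(noise))
    if (length(bad)) cfg_err("measurement_noise",
                             paste("unknown component", bad[1]))
    noise[names(measurement_noise)] <- measurement_noise
  }
  if (any(unlist(noise) < 0)) cfg_err("measurement_noise", "must be >= 0")
  structure(list(
    seed = as.integer(seed), stations = stations,
    depth_intervals_porewater = depth_intervals_porewater,
    depth_intervals_jar = depth_intervals_jar,
    sectioning_days = sectioning_days, preflood_day = preflood_day,
    flux_days = flux_days, jar_days = jar_days,
    n_replicate_cores = as.integer(n_replicate_cores),
    otu_pool_size = as.integer(otu_pool_size),
    n_modules = as.integer(n_modules),
    size_jitter_sd = size_jitter_sd, noise_peak_rate = noise_peak_rate,
    noise_area_mean = noise_area_mean,
    noise_area_rel_halfwidth = noise_area_rel_halfwidth,
    noise_area_dist = match.arg(noise_area_dist),
    total_area = total_area, area_lognorm_sd = area_lognorm_sd,
    detection_area_min = detection_area_min,
    true_denit_fraction = true_denit_fraction,
    true_production_profile = true_production_profile,
    production_multiplier = production_multiplier,
    porosity_profile = porosity_profile,
    accumulation_share = accumulation_share, nox_share = nox_share,
    jar_c0_uM = jar_c0_uM, core_area_m2 = core_area_m2,
    core_volume_L = core_volume_L, core_duration_d = core_duration_d,
    ambient_nh4_uM = ambient_nh4_uM, ambient_nox_uM = ambient_nox_uM,
    qpcr_efficiency = qpcr_efficiency, qpcr_intercept = qpcr_intercept,
    qpcr_template_uL = qpcr_template_uL, qpcr_elution_uL = qpcr_elution_uL,
    qpcr_wet_mass_g = qpcr_wet_mass_g, water_content = water_content,
    n_seawater_samples = as.integer(n_seawater_samples),
    measurement_noise = noise), class = "scenario_config")
}

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

jar_layer_porosity <- function(config, st_i) {
  pw <- config$depth_intervals_porewater
  phi <- config$porosity_profile[st_i, ]
  vapply(seq_len(nrow(config$depth_intervals_jar)), function(j) {
    top <- config$depth_intervals_jar[j, 1]
    bot <- config$depth_intervals_jar[j, 2]
    ov <- pmax(0, pmin(pw[, 2], bot) - pmax(pw[, 1], top))
    sum(phi * ov) / sum(ov)
  }, numeric(1))
}

#' Simulate one electropherogram from true OTU abundances
#'
#' Produces one peak per present OTU at its centroid fragment size plus
#' Gaussian jitter (`size_jitter_sd`), with area proportional to abundance
#' under multiplicative lognormal noise, and a Poisson number of baseline
#' noise peaks uniform over the 50-550 bp window with areas from the
#' configured noise-area distribution. Uses the current RNG state; seed the
#' generator (or call via [generate_scenario()]) for reproducibility.
#'
#' @param abundances named vector of true relative abundances (present OTUs
#'   nonzero; must sum to 1).
#' @param centroids named vector of OTU centroid fragment sizes (bp).
#' @param config a [scenario_config()].
#' @param sample_id sample label for the output rows.
#' @return Peak table (`sample_id`, `size_bp`, `area`) with a logical
#'   `is_noise` column recording the truth.
#' @export
generate_electropherogram <- function(abundances, centroids,
                                      config = scenario_config(),
                                      sample_id = "S1") {
  if (abs(sum(abundances) - 1) > 1e-6)
    stop_input("abundances must sum to 1")
  present <- which(abundances > 0)
  sizes <- centroids[names(abundances)[present]] +
    stats::rnorm(length(present), 0, config$size_jitter_sd)
  areas <- config$total_area * abundances[present] *
    exp(stats::rnorm(length(present), 0, config$area_lognorm_sd))
  called <- areas >= config$detection_area_min
  sizes <- sizes[called]; areas <- areas[called]
  n_noise <- stats::rpois(1, config$noise_peak_rate)
  noise_sizes <- stats::runif(n_noise, 50, 550)
  noise_areas <- if (config$noise_area_dist == "uniform_band") {
    hw <- config$noise_area_rel_halfwidth
    stats::runif(n_noise, config$noise_area_mean * (1 - hw),
                 config$noise_area_mean * (1 + hw))
  } else stats::rexp(n_noise, 1 / config$noise_area_mean)
  data.frame(
    sample_id = sample_id,
    size_bp = c(unname(sizes), noise_sizes),
    area = c(unname(areas), noise_areas),
    is_noise = rep(c(FALSE, TRUE), c(length(areas), n_noise)),
    stringsAsFactors = FALSE)
}

#' Simulate an anoxic jar concentration series
#'
#' concentration(t) = c0 + (layer_rate / porosity) * t + Gaussian noise. The
#' porewater slope has units uM d-1 (1 uM = 1 nmol cm-3 of porewater), so a
#' bulk volumetric rate divided by porosity gives the porewater slope.
#'
#' @param layer_rate bulk volumetric NH4+ production (nmol cm-3 d-1).
#' @param porosity porosity in (0, 1); zero porosity is a modelling error.
#' @param c0 initial concentration (uM).
#' @param times sampling days, strictly increasing.
#' @param noise_sd Gaussian measurement noise (uM).
#' @return data.frame with `day` and `nh4_uM`.
#' @export
generate_jar_series <- function(layer_rate, porosity, c0, times,
                                noise_sd = 0) {
  check_number(porosity, "porosity", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  if (any(diff(times) <= 0)) stop_input("times must be strictly increasing")
  conc <- c0 + (layer_rate / porosity) * times +
    stats::rnorm(length(times), 0, noise_sd)
  data.frame(day = times, nh4_uM = pmax(conc, 0))
}

# module occupancy windows over (time point x depth band); cells are pairs
# (tp index 1..n_tp+1 with 1 = pre-flood, band 1..2)
module_windows <- function(n_modules, n_tp_all) {
  lapply(seq_len(n_modules), function(m) {
    band <- 1 + (m - 1) %/% 2 %% 2
    start <- 2 + (m - 1) %% (n_tp_all - 1)
    tps <- unique(pmin(c(start, start + 1), n_tp_all))
    list(tps = tps, band = band)
  })
}

#' Generate a complete synthetic microcosm dataset with known truth
#'
#' Builds, from a seeded [scenario_config()], a ground-truth object and a
#' dataset bundle containing every table the analysis pipeline consumes:
#' per-core flux incubations, anoxic jar series, porewater depth profiles
#' (NH4+, NOx-, Cl-), T-RFLP peak tables, qPCR measurements with dilution
#' standards, and sample metadata. The generated budget closes exactly
#' before noise: areal production = DIN efflux + porewater accumulation +
#' denitrified amount, per station and sectioning day.
#'
#' @param config a [scenario_config()].
#' @return Object of class `"nitroflood_scenario"`: list with `truth`
#'   (budget truth table, volumetric layer rates, porewater inventories,
#'   true OTU relative-abundance matrix, OTU module map and centroid sizes,
#'   true gene copies) and `bundle` (data.frames `fluxes`, `jars`,
#'   `porewater`, `peaks`, `qpcr`, `standards`, `metadata`).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  st <- config$stations
  n_st <- length(st)
  tps <- config$sectioning_days
  n_tp <- length(tps)
  all_days <- c(config$preflood_day, tps)   # tp index 1 = pre-flood
  jar_iv <- config$depth_intervals_jar
  pw_iv <- config$depth_intervals_porewater
  noise <- config$measurement_noise

  ## ---- budget truth -------------------------------------------------
  vol_rows <- list(); budget_rows <- list(); inv_rows <- list()
  inv_shape <- c(0.5, 0.7, 1.0, 1.3, 1.3, 0.9)   # NH4+ peaks at 5-15 cm
  if (nrow(pw_iv) != length(inv_shape))
    inv_shape <- rep(1, nrow(pw_iv))
  inventory0 <- 0.5  # mmol m-2, pre-flood NH4+ porewater inventory
  truth_pw_conc <- list()
  for (i in seq_len(n_st)) {
    phi_jar <- jar_layer_porosity(config, i)
    inv_prev <- inventory0
    inv_rows[[length(inv_rows) + 1]] <-
      data.frame(station = st[i], time_point = config$preflood_day,
                 inventory_nh4 = inventory0)
    day_prev <- config$preflood_day
    for (k in seq_len(n_tp)) {
      rates <- config$true_production_profile[i, ] *
        config$production_multiplier[i, k]
      vol_rows[[length(vol_rows) + 1]] <- data.frame(
        station = st[i], time_point = tps[k],
        top_cm = jar_iv[, 1], bottom_cm = jar_iv[, 2],
        rate = rates, porosity = phi_jar)
      prod <- depth_integrate(
        data.frame(top_cm = jar_iv[, 1], bottom_cm = jar_iv[, 2],
                   rate = rates),
        range(pw_iv))$value
      f <- config$true_denit_fraction[i, k]
      denit <- f * prod
      rest <- prod - denit
      acc <- config$accumulation_share * rest
      din <- rest - acc
      nox_eff <- config$nox_share[k] * din
      nh4_eff <- din - nox_eff
      inv_now <- inv_prev + acc * (tps[k] - day_prev)
      inv_rows[[length(inv_rows) + 1]] <-
        data.frame(station = st[i], time_point = tps[k],
                   inventory_nh4 = inv_now)
      budget_rows[[length(budget_rows) + 1]] <- data.frame(
        station = st[i], time_point = tps[k],
        production = prod, din_efflux = din, nh4_efflux = nh4_eff,
        nox_efflux = nox_eff, accumulation = acc, denit = denit,
        denit_fraction = f, stringsAsFactors = FALSE)
      inv_prev <- inv_now; day_prev <- tps[k]
    }
  }
  budget_truth <- do.call(rbind, budget_rows)
  vol_truth <- do.call(rbind, vol_rows)
  inv_truth <- do.call(rbind, inv_rows)

  ## ---- jar series ---------------------------------------------------
  jars <- with_substream(config$seed, "jars", {
    out <- list()
    for (r in seq_len(nrow(vol_truth))) {
      v <- vol_truth[r, ]
      ser <- generate_jar_series(v$rate, v$porosity, config$jar_c0_uM,
                                 config$jar_days, noise$jar_uM)
      out[[r]] <- data.frame(
        station = v$station, time_point = v$time_point,
        depth_top_cm = v$top_cm, depth_bottom_cm = v$bottom_cm,
        day = ser$day, nh4_uM = ser$nh4_uM, porosity = v$porosity,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  ## ---- flux incubations --------------------------------------------
  fluxes <- with_substream(config$seed, "fluxes", {
    out <- list()
    for (i in seq_len(n_st)) {
      for (d in config$flux_days) {
        k <- which(tps >= d)[1]
        if (is.na(k)) next
        bt <- budget_truth[budget_truth$station == st[i] &
                             budget_truth$time_point == tps[k], ]
        for (analyte in c("NH4", "NOx")) {
          true_val <- if (analyte == "NH4") bt$nh4_efflux else bt$nox_efflux
          c0 <- if (analyte == "NH4") config$ambient_nh4_uM else
            config$ambient_nox_uM
          for (core in seq_len(config$n_replicate_cores)) {
            val <- true_val * (1 + stats::rnorm(1, 0, noise$flux_rel))
            dC <- val * 1000 * config$core_area_m2 * config$core_duration_d /
              config$core_volume_L
            out[[length(out) + 1]] <- data.frame(
              core_id = sprintf("%s_d%03d_c%d", st[i], d, core),
              station = st[i], day = d, analyte = analyte,
              c_start_uM = c0, c_end_uM = max(c0 + dC, 0),
              volume_L = config$core_volume_L,
              area_m2 = config$core_area_m2,
              duration_d = config$core_duration_d,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, out)
  })

  ## ---- porewater profiles ------------------------------------------
  porewater <- with_substream(config$seed, "porewater", {
    out <- list()
    thick <- pw_iv[, 2] - pw_iv[, 1]
    mid <- (pw_iv[, 1] + pw_iv[, 2]) / 2
    for (i in seq_len(n_st)) {
      phi <- config$porosity_profile[i, ]
      denom <- 10 * sum(inv_shape * phi * thick)
      for (t_idx in seq_along(all_days)) {
        day <- all_days[t_idx]
        inv <- inv_truth$inventory_nh4[inv_truth$station == st[i] &
                                         inv_truth$time_point == day]
        nh4 <- inv / denom * inv_shape
        nox <- if (t_idx == 1) rep(0.002, nrow(pw_iv)) else
          c(0.05, 0.02, rep(0.005, nrow(pw_iv) - 2))
        cl <- if (t_idx == 1) rep(5, nrow(pw_iv)) else
          5 + 355 * erfc_(mid / (2 * sqrt(0.8 * day)))
        for (an in c("NH4", "NOx", "Cl")) {
          conc <- switch(an, NH4 = nh4, NOx = nox, Cl = cl)
          conc <- conc * (1 + stats::rnorm(length(conc), 0,
                                           noise$porewater_rel / sqrt(3)))
          out[[length(out) + 1]] <- data.frame(
            station = st[i], time_point = day,
            depth_top_cm = pw_iv[, 1], depth_bottom_cm = pw_iv[, 2],
            analyte = an, conc_mM = pmax(conc, 0), porosity = phi,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })

  ## ---- community truth and peaks -----------------------------------
  pool <- config$otu_pool_size
  otu_ids <- sprintf("sOTU_%03d", seq_len(pool))
  community <- with_substream(config$seed, "community", {
    grid <- seq(51, 549, by = 3)
    if (pool > length(grid))
      stop_input("otu_pool_size too large for >= 2 bp centroid spacing")
    centroids <- sort(sample(grid, pool)) + stats::runif(pool, -0.5, 0.5)
    names(centroids) <- otu_ids
    n_bg <- max(2L, round(0.4 * pool))
    modules <- integer(pool)                     # 0 = background
    modules[(n_bg + 1):pool] <-
      rep_len(seq_len(config$n_modules), pool - n_bg)
    names(modules) <- otu_ids
    aff <- sample(c("UC+C+SW", "UC+C", "UC", "C", "SW", "UC+SW", "C+SW"),
                  pool, replace = TRUE,
                  prob = c(0.30, 0.25, 0.15, 0.15, 0.10, 0.025, 0.025))
    in_group <- function(g) grepl(g, aff, fixed = TRUE)
    wins <- module_windows(config$n_modules, length(all_days))

    meta_rows <- list(); abund_rows <- list(); peak_rows <- list()
    add_sample <- function(sid, station, day, top, bot, band_i, tp_i) {
      present <- if (station == "SW") in_group("SW") else {
        ok_station <- in_group(station)
        ok_module <- modules == 0 | vapply(modules, function(m) {
          m > 0 && band_i %in% wins[[m]]$band && tp_i %in% wins[[m]]$tps
        }, logical(1))
        ok_station & ok_module
      }
      if (!any(present)) present[1] <- TRUE
      alpha <- ifelse(modules > 0, 2.5, 0.5)
      w <- numeric(pool)
      w[present] <- stats::rgamma(sum(present), shape =
                                    if (station == "SW") 1 else
                                      alpha[present])
      ab <- w / sum(w)
      names(ab) <- otu_ids
      abund_rows[[length(abund_rows) + 1]] <<- ab
      meta_rows[[length(meta_rows) + 1]] <<- data.frame(
        sample_id = sid, station = station, time_point = day,
        depth_top_cm = top, depth_bottom_cm = bot,
        depth_cm = if (is.na(top)) NA_real_ else (top + bot) / 2,
        depth_band = if (is.na(top)) NA_character_ else
          if (bot <= 2) "0-2" else "2-20",
        stringsAsFactors = FALSE)
      peak_rows[[length(peak_rows) + 1]] <<-
        generate_electropherogram(ab, centroids, config, sid)
    }
    for (i in seq_len(n_st)) {
      for (t_idx in seq_along(all_days)) {
        for (l in seq_len(nrow(pw_iv))) {
          band_i <- if (pw_iv[l, 2] <= 2) 1 else 2
          add_sample(sprintf("%s_T%d_D%d", st[i], t_idx - 1, l), st[i],
                     all_days[t_idx], pw_iv[l, 1], pw_iv[l, 2],
                     band_i, t_idx)
        }
      }
    }
    if (config$n_seawater_samples > 0) {
      sw_days <- all_days[1 + (seq_len(config$n_seawater_samples) - 1) %%
                            (length(all_days) - 1)]
      for (s in seq_len(config$n_seawater_samples))
        add_sample(sprintf("SW_%d", s), "SW", sw_days[s], NA, NA, NA, NA)
    }
    abund <- do.call(rbind, abund_rows)
    meta <- do.call(rbind, meta_rows)
    rownames(abund) <- meta$sample_id
    list(abundance = abund, modules = modules, centroids = centroids,
         affinity = aff, metadata = meta,
         peaks = do.call(rbind, peak_rows))
  })

  ## ---- qPCR ---------------------------------------------------------
  genes <- c("16S", "nirK", "nirS", "amoA_AOB", "amoA_AOA")
  slope <- -1 / log10(1 + config$qpcr_efficiency)
  soil_meta <- community$metadata[community$metadata$station != "SW", ]
  qpcr_data <- with_substream(config$seed, "qpcr", {
    base <- c(`16S` = 8e9, nirK = 8e5, nirS = 6e7,
              amoA_AOB = 2e5, amoA_AOA = 8e4)
    tmult <- rbind(`16S` = c(1, 1.6, 1.2, 0.25, 0.15),
                   nirK = c(1, 2, 6, 18, 14),
                   nirS = c(1, 1.4, 1.1, 0.2, 0.12),
                   amoA_AOB = c(0.05, 0.3, 1, 3, 2.5),
                   amoA_AOA = c(0.8, 1, 1.5, 2.5, 4))
    truth <- list(); meas <- list()
    for (r in seq_len(nrow(soil_meta))) {
      m <- soil_meta[r, ]
      i <- match(m$station, st)
      t_idx <- match(m$time_point, all_days)
      wc <- config$water_content[[m$station]]
      dry <- config$qpcr_wet_mass_g * (1 - wc)
      for (g in genes) {
        station_scale <- if (m$station == st[1]) 1 else 0.4
        cpg <- base[[g]] * tmult[g, t_idx] * station_scale *
          exp(-m$depth_cm / 8)
        copies_rxn <- cpg * dry *
          (config$qpcr_template_uL / config$qpcr_elution_uL)
        cq_true <- config$qpcr_intercept + slope * log10(copies_rxn)
        truth[[length(truth) + 1]] <- data.frame(
          sample_id = m$sample_id, gene = g, copies_per_g_dry = cpg,
          stringsAsFactors = FALSE)
        meas[[length(meas) + 1]] <- data.frame(
          sample_id = m$sample_id, gene = g,
          cq_rep1 = cq_true + stats::rnorm(1, 0, noise$cq_sd),
          cq_rep2 = cq_true + stats::rnorm(1, 0, noise$cq_sd),
          template_uL = config$qpcr_template_uL,
          elution_uL = config$qpcr_elution_uL,
          wet_mass_g = config$qpcr_wet_mass_g,
          water_content = wc, stringsAsFactors = FALSE)
      }
    }
    std <- list()
    for (g in genes) {
      copies <- 10^(1:7)
      std[[g]] <- data.frame(
        gene = g, copies = copies,
        cq = config$qpcr_intercept + slope * log10(copies) +
          stats::rnorm(7, 0, noise$standards_cq_sd),
        stringsAsFactors = FALSE)
    }
    list(truth = do.call(rbind, truth), qpcr = do.call(rbind, meas),
         standards = do.call(rbind, std))
  })

  truth <- list(
    budget = budget_truth,
    volumetric_rates = vol_truth,
    inventories = inv_truth,
    otu_abundance = community$abundance,
    otu_modules = community$modules,
    otu_centroids = community$centroids,
    otu_affinity = community$affinity,
    gene_copies = qpcr_data$truth,
    config = config)
  bundle <- list(
    fluxes = fluxes, jars = jars, porewater = porewater,
    peaks = community$peaks[, c("sample_id", "size_bp", "area", "is_noise")],
    qpcr = qpcr_data$qpcr, standards = qpcr_data$standards,
    metadata = community$metadata)
  structure(list(truth = truth, bundle = bundle),
            class = "nitroflood_scenario")
}

#' @export
print.nitroflood_scenario <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic microcosm scenario (seed", cfg$seed, ")\n")
  cat(sprintf("  %d stations x %d sectioning days (+ pre-flood), %d samples\n",
              length(cfg$stations), length(cfg$sectioning_days),
              nrow(x$bundle$metadata)))
  cat(sprintf("  %d OTUs in pool, %d modules; %d peak rows; %d flux rows\n",
              cfg$otu_pool_size, cfg$n_modules, nrow(x$bundle$peaks),
              nrow(x$bundle$fluxes)))
  invisible(x)
}
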