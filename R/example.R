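#' A miniature hand-checkable nitrogen-budget dataset
#'
#' One station ("S") with a single sectioning at day 10, built so every
#' number in the resulting budget can be verified by hand: four exactly
#' collinear jar series whose volumetric rates (200, 100, 20, 20 nmol cm-3
#' d-1 at porosity 0.5) depth-integrate to an areal NH4+ production of
#' exactly 10 mmol m-2 d-1 (the unmeasured 10-15 cm layer interpolates to
#' 20); triplicate-core fluxes on day 5 giving an NH4+ efflux of 2 (core
#' values 1, 2, 3) and an NOx- efflux of 1 mmol m-2 d-1; and uniform
#' porewater profiles whose NH4+ inventory grows from 100 to 110 mmol m-2
#' over the 10 days (accumulation 1 mmol m-2 d-1). The budget therefore
#' closes at potential denitrification 10 - 3 - 1 = 6, potential NH4+
#' oxidation 6 + 1 = 7 and a denitrified fraction of 0.60.
#'
#' @return List with `fluxes`, `jars` and `porewater` data.frames in the
#'   schemas [estimate_nitrogen_budgets()] reads.
#' @export
example_budget_dataset <- function() {
  jar_layers <- data.frame(top = c(0, 2, 5, 15), bottom = c(2, 5, 10, 20),
                           rate = c(200, 100, 20, 20))
  days <- c(0, 7, 14, 21, 28)
  jars <- do.call(rbind, lapply(seq_len(nrow(jar_layers)), function(i) {
    data.frame(station = "S", time_point = 10,
               depth_top_cm = jar_layers$top[i],
               depth_bottom_cm = jar_layers$bottom[i],
               day = days,
               nh4_uM = 100 + jar_layers$rate[i] / 0.5 * days,
               porosity = 0.5)
  }))
  # per-core NH4+ fluxes 1, 2, 3 and NOx- flux 1 mmol m-2 d-1:
  # dC = value * 1000 * area * duration / volume = value * 4 uM
  fluxes <- rbind(
    data.frame(core_id = paste0("c", 1:3), station = "S", day = 5,
               analyte = "NH4", c_start_uM = 10,
               c_end_uM = 10 + 4 * (1:3), volume_L = 0.25, area_m2 = 5e-3,
               duration_d = 0.2),
    data.frame(core_id = paste0("c", 1:3), station = "S", day = 5,
               analyte = "NOx", c_start_uM = 2, c_end_uM = 6,
               volume_L = 0.25, area_m2 = 5e-3, duration_d = 0.2))
  pw_layers <- data.frame(top = c(0, 1, 2, 5, 10, 15),
                          bottom = c(1, 2, 5, 10, 15, 20))
  porewater <- do.call(rbind, lapply(c(0, 10), function(tp) {
    data.frame(station = "S", time_point = tp,
               depth_top_cm = pw_layers$top,
               depth_bottom_cm = pw_layers$bottom,
               analyte = "NH4", conc_mM = if (tp == 0) 1 else 1.1,
               porosity = 0.5)
  }))
  list(fluxes = fluxes, jars = jars, porewater = porewater)
}
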