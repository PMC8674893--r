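#' Configuration for the stratified-lake profile simulator
#'
#' Parameters of the synthetic seasonally stratified lake used to exercise the
#' oxythermal metrics. The temperature profile is a logistic thermocline
#' between a seasonally varying epilimnion and a 4 degree C hypolimnion; the
#' dissolved-oxygen profile starts uniform and decays linearly in time below
#' the thermocline, mimicking hypolimnetic oxygen depletion over summer.
#'
#' @param max_depth lake maximum depth (m).
#' @param surface_area lake surface area (km^2).
#' @param epilimnion_temp_peak mid-season epilimnion temperature (degree C).
#' @param thermocline_depth depth of the thermocline midpoint (m).
#' @param hypolimnetic_do_decay DO loss rate below the thermocline
#'   (mg L^-1 day^-1).
#' @param n_days number of simulated days (one profile per day).
#' @param depth_step vertical grid spacing (m).
#' @param seed integer seed (kept for interface symmetry; the generator is
#'   deterministic unless `temp_noise_sd > 0`).
#' @param hypolimnion_temp deep-water temperature (degree C).
#' @param do_surface initial/surface dissolved oxygen (mg/L).
#' @param thermocline_width logistic width of the thermocline (m).
#' @param temp_noise_sd optional iid noise added to temperatures.
#' @return a validated list of class `lake_sim_config`.
#' @export
lake_sim_config <- function(max_depth = 30, surface_area = 5,
                            epilimnion_temp_peak = 26, thermocline_depth = 8,
                            hypolimnetic_do_decay = 0.05, n_days = 180,
                            depth_step = 0.5, seed = 1,
                            hypolimnion_temp = 4, do_surface = 10,
                            thermocline_width = 2, temp_noise_sd = 0) {
  check_that(max_depth > 0, "`max_depth` must be positive")
  check_that(depth_step > 0, "`depth_step` must be positive")
  check_that(is_count(n_days), "`n_days` must be >= 1")
  check_that(surface_area > 0, "`surface_area` must be positive")
  check_that(hypolimnetic_do_decay >= 0, "`hypolimnetic_do_decay` must be >= 0")
  check_that(thermocline_width > 0, "`thermocline_width` must be positive")
  structure(as.list(environment()), class = "lake_sim_config")
}

#' Simulate daily temperature/DO depth profiles for a stratified lake
#'
#' Produces one temperature and dissolved-oxygen profile per day on a regular
#' depth grid, plus a truth block with the closed-form threshold crossing
#' depths (DO = 3 mg/L, T = 17 degree C), the exact TDO3 and the habitat
#' thickness for every day, so the interpolating metric code can be checked
#' against analytic values.
#'
#' @param config a [lake_sim_config()].
#' @param lake_id label used in the output tables.
#' @return list with `profiles` (long tibble lake_id/day/depth_m/temp_c/
#'   do_mg_l), `truth` (daily tibble of analytic crossings) and
#'   `surface_area`.
#' @export
simulate_lake_profiles <- function(config, lake_id = "lake1") {
  check_that(inherits(config, "lake_sim_config"),
             "`config` must come from lake_sim_config()")
  c_ <- config
  z <- seq(0, c_$max_depth, by = c_$depth_step)
  if (z[length(z)] < c_$max_depth) z <- c(z, c_$max_depth)
  days <- seq_len(c_$n_days)
  # seasonal epilimnion temperature, peaking mid-season
  epi <- c_$hypolimnion_temp +
    (c_$epilimnion_temp_peak - c_$hypolimnion_temp) * sin(pi * days / (c_$n_days + 1))
  w <- c_$thermocline_width
  th <- c_$thermocline_depth
  hyp <- c_$hypolimnion_temp
  grid <- expand.grid(depth_m = z, day = days)
  temp <- hyp + (epi[grid$day] - hyp) * plogis((th - grid$depth_m) / w)
  do <- c_$do_surface -
    (c_$hypolimnetic_do_decay * grid$day) * plogis((grid$depth_m - th) / w)
  do <- pmax(do, 0)
  if (c_$temp_noise_sd > 0) {
    temp <- with_seed(c_$seed, temp + stats::rnorm(length(temp), 0, c_$temp_noise_sd))
  }
  profiles <- tibble(lake_id = lake_id, day = grid$day,
                     depth_m = grid$depth_m, temp_c = temp, do_mg_l = do)

  # analytic crossings ----------------------------------------------------
  logit <- function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  truth <- tibble(lake_id = lake_id, day = days) |>
    mutate(
      z_t17 = {
        s <- (17 - hyp) / (epi - hyp)
        zz <- ifelse(s >= 1 | s <= 0, NA_real_, th - w * logit(s))
        # whole column below 17 C -> crossing pinned to the surface
        ifelse(is.na(zz) | zz < 0, 0, zz)
      },
      z_do3 = {
        drop <- c_$hypolimnetic_do_decay * days
        u <- (c_$do_surface - 3) / drop
        zz <- ifelse(drop <= 0 | u >= 1, NA_real_, th + w * logit(pmin(u, 1 - 1e-12)))
        ifelse(!is.na(zz) & zz > c_$max_depth, NA_real_, pmax(zz, 0))
      },
      tdo3 = ifelse(is.na(.data$z_do3), NA_real_,
                    hyp + (epi - hyp) * plogis((th - .data$z_do3) / w)),
      thickness = ifelse(is.na(.data$z_do3), c_$max_depth - .data$z_t17,
                         .data$z_do3 - .data$z_t17)
    )
  list(profiles = profiles, truth = truth, surface_area = c_$surface_area)
}
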