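# Oxythermal habitat metrics from daily temperature/DO depth profiles.
# Cold-water fish need water that is simultaneously cold (< 17 C) and
# oxygenated (> 3 mg/L); these metrics quantify how much of the water column
# offers that, and how hot the water at the oxygen boundary gets.

#' First threshold crossing depth in a profile
#'
#' Scans downward from the surface and linearly interpolates the depth at
#' which the profile value first crosses `threshold` (first bracketing pair
#' convention; a grid value exactly at the threshold returns that grid
#' depth). Returns `NA` when the threshold is never bracketed.
#'
#' @param depth strictly increasing depth grid (m).
#' @param value profile values at those depths.
#' @param threshold crossing value.
#' @return depth in m, or `NA`.
#' @export
crossing_depth <- function(depth, value, threshold) {
  check_that(length(depth) == length(value) && length(depth) >= 2,
             "need matching depth/value vectors of length >= 2")
  check_that(all(diff(depth) > 0), "depth grid must be strictly increasing")
  for (i in seq_along(depth)) {
    if (!is.na(value[i]) && value[i] == threshold) return(depth[i])
    if (i < length(depth) && !is.na(value[i]) && !is.na(value[i + 1]) &&
        (value[i] - threshold) * (value[i + 1] - threshold) < 0) {
      return(depth[i] + (threshold - value[i]) /
               (value[i + 1] - value[i]) * (depth[i + 1] - depth[i]))
    }
  }
  NA_real_
}

#' Daily oxythermal metrics from lake profiles
#'
#' For each lake-day: `tdo3`, the temperature interpolated at the depth where
#' dissolved oxygen first reaches 3 mg/L (undefined when the column stays
#' oxygenated to the bottom), and the oxythermal habitat `thickness`,
#' `z(DO = 3) - z(T = 17)` in m. Conventions: if the whole column is below
#' 17 C the thermal crossing is pinned to the surface (0 m); if DO never
#' reaches 3 the thickness extends to the bottom; thickness is negative when
#' the 3 mg/L depth sits above the 17 C depth (oxygenated-but-warm columns).
#' Days with fewer than 2 depths are skipped with a log entry in the
#' `skipped` attribute.
#'
#' @param profiles long tibble: lake_id, day (or date), depth_m, temp_c,
#'   do_mg_l.
#' @return tibble of class `oxythermal_daily`: lake_id, day, z_do3, z_t17,
#'   tdo3, thickness.
#' @export
oxythermal_daily <- function(profiles) {
  profiles <- as_tibble(profiles)
  day_col <- if ("day" %in% names(profiles)) "day" else "date"
  skipped <- list()
  out <- profiles |>
    group_by(.data$lake_id, day = .data[[day_col]]) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$depth_m)
      if (nrow(d) < 2) {
        skipped[[length(skipped) + 1]] <<- key
        return(tibble())
      }
      z_do3 <- crossing_depth(d$depth_m, d$do_mg_l, 3)
      if (is.na(z_do3) && d$do_mg_l[1] < 3) z_do3 <- 0  # anoxic at the surface
      z_t17 <- crossing_depth(d$depth_m, d$temp_c, 17)
      if (is.na(z_t17) && max(d$temp_c, na.rm = TRUE) < 17) z_t17 <- 0
      bottom <- max(d$depth_m)
      tdo3 <- if (is.na(z_do3)) NA_real_ else
        approx(d$depth_m, d$temp_c, xout = z_do3)$y
      thickness <- if (is.na(z_do3)) bottom - z_t17 else z_do3 - z_t17
      tibble(z_do3 = z_do3, z_t17 = z_t17, tdo3 = tdo3, thickness = thickness)
    }) |>
    ungroup()
  structure(out, skipped = bind_rows(skipped),
            class = c("oxythermal_daily", class(out)))
}

# max of centered moving averages over defined values; windows with < 50%
# defined days are undefined.
moving_max <- function(day, x, window) {
  half <- window %/% 2
  vals <- vapply(seq_along(day), function(i) {
    inwin <- abs(day - day[i]) <= half
    v <- x[inwin]
    if (sum(!is.na(v)) < window / 2) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
}

#' Yearly oxythermal metrics
#'
#' Aggregates the daily series per lake-year: `tdo3_max` (max defined daily
#' TDO3), `tdo3_7day` / `tdo3_30day` (max of 7/30-day centered moving
#' averages over defined days), `cosd` (cumulative oxythermal stress dosage,
#' the summed daily exceedance of TDO3 above 17 C; undefined days contribute
#' 0), `min_thickness` and `min_volume` (min thickness times lake surface
#' area, km^2 m). Lake-years with fewer than 30 defined TDO3 days are flagged
#' for the windowed metrics.
#'
#' @param daily an [oxythermal_daily()] result. May span multiple years if a
#'   `year` column is present; otherwise all days are one year.
#' @param surface_area named vector of lake surface areas in km^2 (names are
#'   lake ids), or a single value.
#' @param window optional integer range `c(first_day, last_day)` restricting
#'   the season (e.g. an open-water period); default uses all days.
#' @return tibble of class `oxythermal_yearly`.
#' @export
oxythermal_yearly <- function(daily, surface_area, window = NULL) {
  d <- as_tibble(daily)
  if (!"year" %in% names(d)) d$year <- 1L
  if (!is.null(window)) {
    check_that(length(window) == 2 && window[1] <= window[2],
               "`window` must be c(first_day, last_day)")
    d <- filter(d, .data$day >= window[1], .data$day <= window[2])
    check_that(nrow(d) > 0, "empty window")
  }
  area_of <- function(lk) {
    if (length(surface_area) == 1 && is.null(names(surface_area)))
      return(surface_area)
    check_that(lk %in% names(surface_area),
               paste0("no surface area for lake ", lk))
    surface_area[[lk]]
  }
  d |>
    group_by(.data$lake_id, .data$year) |>
    dplyr::group_modify(function(g, key) {
      def <- !is.na(g$tdo3)
      tibble(
        tdo3_max = if (any(def)) max(g$tdo3[def]) else NA_real_,
        tdo3_7day = moving_max(g$day, g$tdo3, 7),
        tdo3_30day = moving_max(g$day, g$tdo3, 30),
        cosd = sum(pmax(0, g$tdo3[def] - 17)),
        min_thickness = min(g$thickness, na.rm = TRUE),
        n_defined = sum(def),
        flagged = sum(def) < 30
      )
    }) |>
    ungroup() |>
    mutate(min_volume = .data$min_thickness *
             unname(vapply(.data$lake_id, area_of, numeric(1)))) |>
    (\(x) structure(x, class = c("oxythermal_yearly", class(x))))()
}

#' Long-term summary of yearly oxythermal metrics
#'
#' Per lake and metric: the mean over years and the bottleneck extreme - the
#' maximum for the heat metrics (TDO3 variants, COSD), the minimum for
#' habitat thickness and volume, i.e. always the worst year for a cold-water
#' fish.
#'
#' @param yearly an [oxythermal_yearly()] result.
#' @return tibble: lake_id, metric, mean, extreme.
#' @export
longterm_summary <- function(yearly) {
  long <- tidyr::pivot_longer(
    as_tibble(yearly)[, c("lake_id", "year", "tdo3_max", "tdo3_7day",
                          "tdo3_30day", "cosd", "min_thickness", "min_volume")],
    cols = -c("lake_id", "year"), names_to = "metric", values_to = "value")
  long |>
    group_by(.data$lake_id, .data$metric) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      extreme = if (all(is.na(.data$value))) NA_real_
        else if (unique(.data$metric) %in% c("min_thickness", "min_volume"))
          min(.data$value, na.rm = TRUE)
        else max(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
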