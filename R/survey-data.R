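#' Compiled survey of 29 southern inland-lake cisco populations
#'
#' Site metadata and per-population genetic metrics from a compiled survey of
#' cisco (*Coregonus artedi*) populations in 29 inland lakes near the
#' species' southern range margin (Minnesota, Wisconsin, Michigan, Indiana).
#' `cisco_sites()` returns lake coordinates, maximum depth (m), surface area
#' (km^2) and the long-term maximum TDO3 (degree C) from hydrodynamic
#' modelling. `cisco_population_metrics()` returns, per population: Rapture
#' sample size, observed/expected heterozygosity, the G_IS inbreeding
#' coefficient, the proportion of polymorphic loci, LD-based N_e with
#' confidence bounds (`Inf` marks samples too small for a finite estimate),
#' mutational-load metrics (af_del, prop_del), and MHC metrics (sample size,
#' rarefied haplotype count, proportion of multi- and >2-haplotype
#' individuals), with the lineage label (MS = Mississippian,
#' GL = Great Lakes).
#'
#' These tables serve as a realistic worked-example input for the correlation
#' stage and as reference values in the test-suite.
#'
#' @return a tibble.
#' @export
cisco_sites <- function() {
  as_tibble(read.csv(system.file("extdata", "cisco_sites.csv",
                                 package = "ciscogen")))
}

#' @rdname cisco_sites
#' @export
cisco_population_metrics <- function() {
  as_tibble(read.csv(system.file("extdata", "cisco_population_metrics.csv",
                                 package = "ciscogen")))
}

#' Assemble the metrics-by-predictors table for the correlation stage
#'
#' Joins per-population genetic metrics to site predictors by site code.
#' N_e is carried along but excluded from response matrices by default
#' (infinite estimates and sample-size sensitivity make it unsuitable as a
#' response).
#'
#' @param metrics tibble like [cisco_population_metrics()] (needs a `site`
#'   column).
#' @param sites tibble like [cisco_sites()] (needs a `site` column).
#' @return joined tibble, one row per population.
#' @export
build_metrics_table <- function(metrics = cisco_population_metrics(),
                                sites = cisco_sites()) {
  left_join(as_tibble(metrics), as_tibble(sites), by = "site")
}
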