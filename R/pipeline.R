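#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects seeds, stage toggles and per-stage thresholds for
#' [run_pipeline()]. Defaults give a small but fully structured study: two
#' lineages of three lake populations, a few hundred SNPs, a multi-copy MHC
#' panel and one stratified lake per population.
#'
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param genotypes a [sim_config()] for the SNP simulator.
#' @param cds_loci,cds_codons,cds_prop_nonsyn coding-allele simulator size.
#' @param mhc_per_pop MHC-genotyped individuals per population.
#' @param mhc_hap_pool circulating true MHC haplotypes.
#' @param run_mhc,run_oxythermal,run_amova stage toggles.
#' @param permutations permutation count for AMOVA/RDA tests.
#' @param filter_args,hdplot_args,mhc_call_args named lists of threshold
#'   overrides for the respective stages.
#' @param delmut_threshold deleterious effect-score cut-off.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            genotypes = sim_config(n_loci = 400,
                                                   n_individuals_per_pop = 20,
                                                   loci_per_tag = 2,
                                                   missing_rate = 0.05,
                                                   seed = seed),
                            cds_loci = 60, cds_codons = 50,
                            cds_prop_nonsyn = 0.6,
                            mhc_per_pop = 12, mhc_hap_pool = 24,
                            run_mhc = TRUE, run_oxythermal = TRUE,
                            run_amova = FALSE, permutations = 199,
                            filter_args = list(), hdplot_args = list(),
                            mhc_call_args = list(),
                            delmut_threshold = -2.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order - simulate, filter (call-rate /
#' missingness / MAF / paralog screen / one SNP per tag), population-genetic
#' statistics, deleterious-mutation load, MHC haplotype diversity, oxythermal
#' habitat metrics, then the metrics join and the correlation stack - and
#' returns every intermediate table plus a manifest of seeds, thresholds and
#' content hashes sufficient to verify bit-identical reruns.
#'
#' @param config a [pipeline_config()].
#' @return named list of stage outputs with a `manifest` tibble.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  check_that(inherits(config, "pipeline_config"),
             "`config` must come from pipeline_config()")
  seeds <- config$seed + seq_len(8) * 1000L
  manifest <- list()
  note <- function(stage, seed, obj) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, seed = seed, hash = rlang::hash(obj))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e))))
  }

  ds <- run_stage("simulate", simulate_genotypes(config$genotypes))
  note("simulate", config$genotypes$seed, ds$geno)

  filt <- run_stage("filter", {
    f <- do.call(filter_genotypes, c(list(ds), config$filter_args))
    hd <- do.call(hdplot_screen, c(list(f$dataset), config$hdplot_args))
    list(dataset = select_snp_per_tag(hd$dataset),
         report = f$report, paralog_stats = hd$stats)
  })
  dsf <- filt$dataset
  note("filter", NA, dsf$geno)

  popgen <- run_stage("popgen", {
    out <- list(diversity = diversity_stats(dsf),
                fst = pairwise_fst(dsf),
                nei_da = nei_da(dsf),
                ldne = ldne(dsf))
    if (config$run_amova)
      out$amova <- amova(dsf, permutations = config$permutations,
                         seed = seeds[1])
    out
  })
  note("popgen", seeds[1], popgen$diversity)

  delmut <- run_stage("delmut", {
    cds <- simulate_cds_alleles(min(config$cds_loci, n_loci(dsf)),
                                config$cds_codons, config$cds_prop_nonsyn,
                                seed = seeds[2],
                                threshold = config$delmut_threshold)
    ann <- annotate_coding(cds$sequences, cds$hits)
    cat0 <- classify_deleterious(ann, cds$scores,
                                 threshold = config$delmut_threshold)
    # graft the catalog onto dataset loci so frequencies are observable
    map <- setNames(head(dsf$loci$locus, nrow(cds$truth)), cds$truth$locus)
    cat0$locus <- unname(map[cat0$locus])
    list(catalog = cat0, truth = cds$truth,
         load = load_metrics(dsf, cat0))
  })
  note("delmut", seeds[2], delmut$load)

  mhc <- NULL
  if (config$run_mhc) {
    mhc <- run_stage("mhc", {
      pops <- unique(dsf$samples$population)
      sim <- simulate_mhc_reads(config$mhc_per_pop * length(pops),
                                config$mhc_hap_pool, seed = seeds[3])
      popmap <- tibble(individual = unique(sim$reads$individual)) |>
        mutate(population = rep(pops, each = config$mhc_per_pop)[
          seq_len(dplyr::n())])
      hm <- do.call(call_haplotypes, c(list(sim$reads), config$mhc_call_args))
      div <- mhc_diversity(hm, popmap, seed = seeds[4])
      called <- colnames(hm$presence)
      zt <- nei_gojobori_ztest(
        sim$haplotypes$seq[sim$haplotypes$haplotype %in% called],
        bootstrap = 200, seed = seeds[5])
      list(truth = sim$truth, matrix = hm, diversity = div, ztest = zt)
    })
    note("mhc", seeds[3], mhc$diversity$populations)
  }

  oxy <- NULL
  pops <- unique(dsf$samples$population)
  # lake attributes drawn once, deterministically: independent variation in
  # latitude, size and depth keeps the predictor block full rank
  lake_meta <- with_seed(seeds[6], tibble(
    population = pops,
    latitude = runif(length(pops), 42, 47),
    longitude = runif(length(pops), -94, -85),
    surface_area = exp(runif(length(pops), -1, 4)),
    max_depth = runif(length(pops), 15, 40),
    epi_peak = 29 - 1.2 * (.data$latitude - 42) + runif(length(pops), -1, 1),
    do_decay = runif(length(pops), 0.06, 0.12)))
  if (config$run_oxythermal) {
    oxy <- run_stage("oxythermal", {
      sims <- lapply(seq_along(pops), function(i) {
        cfg <- lake_sim_config(
          max_depth = lake_meta$max_depth[i],
          surface_area = lake_meta$surface_area[i],
          epilimnion_temp_peak = lake_meta$epi_peak[i],
          hypolimnetic_do_decay = lake_meta$do_decay[i],
          seed = seeds[6] + i)
        simulate_lake_profiles(cfg, lake_id = pops[i])
      })
      profiles <- bind_rows(lapply(sims, `[[`, "profiles"))
      areas <- setNames(lake_meta$surface_area, pops)
      daily <- oxythermal_daily(profiles)
      yearly <- oxythermal_yearly(daily, areas)
      list(daily = daily, yearly = yearly,
           longterm = longterm_summary(yearly), areas = areas)
    })
    lake_meta$tdo3_max <- oxy$yearly$tdo3_max[match(pops, oxy$yearly$lake_id)]
    note("oxythermal", seeds[6], oxy$yearly)
  }
  lake_meta <- select(lake_meta, -"epi_peak", -"do_decay")

  metrics <- run_stage("join", {
    m <- popgen$diversity |>
      left_join(delmut$load, by = "population") |>
      left_join(popgen$ldne[, c("population", "ne")], by = "population")
    if (!is.null(mhc)) {
      m <- left_join(
        m, mhc$diversity$populations[, c("population", "n_hap", "prop_poly",
                                         "prop_gt2")] |>
          dplyr::rename(prop_poly_mhc = "prop_poly"),
        by = "population")
    } else {
      warn("MHC stage disabled: correlation runs without MHC columns")
    }
    left_join(m, lake_meta, by = "population")
  })
  note("join", NA, metrics)

  correlate <- run_stage("correlate", {
    responses <- intersect(
      c("Ho", "prop_poly", "G_IS", "af_del", "prop_del", "n_hap",
        "prop_poly_mhc"), names(metrics))
    predictors <- intersect(c("latitude", "surface_area", "max_depth",
                              "tdo3_max"), names(metrics))
    Y <- metrics[, responses]; X <- metrics[, predictors]
    fit <- rda_genetics(Y, X, permutations = config$permutations,
                        seed = seeds[7])
    lmg <- lapply(responses, function(rs) mlr_lmg(metrics[[rs]], X))
    names(lmg) <- responses
    list(rda = fit, lmg = lmg)
  })
  note("correlate", seeds[7], glance(correlate$rda))

  list(dataset = ds, filtered = filt, popgen = popgen, delmut = delmut,
       mhc = mhc, oxythermal = oxy, metrics = metrics, correlate = correlate,
       manifest = bind_rows(manifest))
}
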