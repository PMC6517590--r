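#' Configure a synthetic community-assembly scenario
#'
#' Describes a multi-lake, century-long study: a regional taxon pool that
#' grows through time, lakes spread over a region, per-lake annual
#' environmental series with a warming trend that steepens after 1980 and a
#' eutrophication-then-remediation phosphorus trajectory, and sediment-layer
#' communities assembled under one of three regimes: `"neutral"` (uniform
#' draws from the pool), `"filtering"` (Gaussian trait-environment matching
#' of phylogenetically conserved Brownian traits), or `"dispersal_limited"`
#' (exponential distance kernel around fixed taxon home lakes).
#'
#' @param n_taxa Regional pool size (tips of the simulated phylogeny).
#' @param n_lakes Number of lakes.
#' @param years Two integers, first and last study year.
#' @param layers_per_lake Dated sediment layers per lake, evenly spaced.
#' @param regime Assembly regime.
#' @param trait_sigma2 Brownian-motion rate of trait evolution (trait
#'   units^2 per unit branch length).
#' @param sigma_niche Niche breadth of the filtering regime (trait units;
#'   smaller = stronger filtering). The default 0.25 is strong filtering
#'   relative to the regional trait spread of the default tree.
#' @param dispersal_scale_km Exponential dispersal-kernel scale; the default
#'   25 km is well below typical inter-lake distances in the default region,
#'   i.e. marked dispersal limitation.
#' @param richness_mean Mean per-sample richness (Poisson, clipped to
#'   \[5, pool size\]). The default of 50 taxa is typical of rarefied
#'   amplicon assemblages and gives the tip-sensitive MNTD metric adequate
#'   per-sample power.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters;
#'   depths are clipped below at `depth_min` so samples survive rarefaction.
#' @param depth_min Minimum sequencing depth.
#' @param initial_pool_fraction Fraction of the pool present in the first
#'   decade; the pool grows linearly (in taxa per decade) to the full
#'   `n_taxa` by the last decade.
#' @param lat_range,lon_range Bounding box the lakes are placed in
#'   (defaults span a peri-Alpine-sized region, roughly 200 x 250 km).
#' @param temp_baseline_range Per-lake mean annual air temperature
#'   baselines (deg C), assigned at random (independently of geography).
#' @param temp_slope_pre,temp_slope_post Warming trends (deg C per year)
#'   before and after 1980.
#' @param temp_noise Interannual temperature SD (deg C).
#' @param tp_base,tp_peak,tp_peak_year,tp_width,tp_noise Total-phosphorus
#'   trajectory (ug/L): baseline plus a Gaussian eutrophication peak.
#' @param no3_mean,no3_sd,nh4_mean,nh4_sd Stationary nitrate / ammonium
#'   levels (mg/L).
#' @param ssi_base,ssi_per_degree,ssi_noise Schmidt stability index as a
#'   linear response to air temperature.
#' @param seed Master seed; all streams derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_taxa = 256L, n_lakes = 10L,
                            years = c(1900L, 2016L), layers_per_lake = 12L,
                            regime = c("neutral", "filtering", "dispersal_limited"),
                            trait_sigma2 = 1, sigma_niche = 0.25,
                            dispersal_scale_km = 25,
                            richness_mean = 50,
                            depth_meanlog = log(8000), depth_sdlog = 0.25,
                            depth_min = 3000L,
                            initial_pool_fraction = 0.4,
                            lat_range = c(45.7, 47.6), lon_range = c(6.2, 9.5),
                            temp_baseline_range = c(9, 13),
                            temp_slope_pre = 0.01, temp_slope_post = 0.04,
                            temp_noise = 0.3,
                            tp_base = 15, tp_peak = 90, tp_peak_year = 1975,
                            tp_width = 20, tp_noise = 4,
                            no3_mean = 1, no3_sd = 0.15,
                            nh4_mean = 0.05, nh4_sd = 0.01,
                            ssi_base = 500, ssi_per_degree = 90, ssi_noise = 30,
                            seed = 1L) {
  regime <- match.arg(regime)
  cfg <- as.list(environment())
  if (n_taxa < 2) abort("`n_taxa` must be >= 2.")
  if (n_lakes < 2) abort("`n_lakes` must be >= 2.")
  if (years[2] <= years[1]) abort("`years` must be increasing.")
  bad <- c(trait_sigma2, sigma_niche, dispersal_scale_km, temp_noise,
           tp_noise, no3_sd, nh4_sd, ssi_noise) < 0
  if (any(bad)) abort("Rates, scales and noise SDs must all be >= 0.")
  if (initial_pool_fraction <= 0 || initial_pool_fraction > 1) {
    abort("`initial_pool_fraction` must be in (0, 1].")
  }
  structure(cfg, class = "scenario_config")
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree with unit birth rate via [ape::rphylo()]; a stand-in for
#' an estimated OTU phylogeny with known, well-behaved branch lengths.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) abort("`n_taxa` must be >= 2.")
  with_local_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
}

#' Simulate phylogenetically conserved traits by Brownian motion
#'
#' Traits evolve from a root value of 0 with rate `sigma2` along branches
#' ([ape::rTraitCont()]), so close relatives have similar trait values —
#' the precondition for environmental filtering to leave a phylogenetic
#' clustering signal.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate (>= 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, sigma2 = 1, seed = 1L) {
  if (sigma2 < 0) abort("`sigma2` must be >= 0.")
  with_local_seed(seed,
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0))
}

#' Simulate per-lake annual environmental series
#'
#' Air temperature rises linearly with a steeper slope after 1980 around a
#' per-lake baseline; total phosphorus follows a rise-peak-decline
#' (eutrophication then re-oligotrophication) trajectory; the Schmidt
#' stability index tracks temperature; nitrate and ammonium are stationary
#' noise. All series are annual means.
#'
#' @param config A [scenario_config()].
#' @param lakes Tibble with `lake_id` and `temp_baseline` (see
#'   [simulate_bundle()]); defaults to baselines drawn from the config.
#' @return A long tibble: `lake_id`, `variable`, `year`, `value` with
#'   variables `air_temp` (deg C), `TP` (ug/L), `NO3` (mg/L), `NH4` (mg/L),
#'   `SSI` (dimensionless).
#' @export
simulate_environment <- function(config, lakes = NULL) {
  yrs <- config$years[1]:config$years[2]
  if (is.null(lakes)) {
    lakes <- with_local_seed(derive_seed(config$seed, "lakes"),
                             simulate_lakes(config))
  }
  with_local_seed(derive_seed(config$seed, "environment"), {
    purrr::map_dfr(seq_len(nrow(lakes)), function(i) {
      base <- lakes$temp_baseline[i]
      warm <- config$temp_slope_pre * (yrs - config$years[1]) +
        config$temp_slope_post * pmax(yrs - 1980, 0)
      temp <- base + warm + rnorm(length(yrs), 0, config$temp_noise)
      tp <- pmax(config$tp_base +
                   config$tp_peak * exp(-((yrs - config$tp_peak_year) / config$tp_width)^2) +
                   rnorm(length(yrs), 0, config$tp_noise), 1)
      ssi <- config$ssi_base + config$ssi_per_degree * (temp - base) +
        rnorm(length(yrs), 0, config$ssi_noise)
      no3 <- pmax(rnorm(length(yrs), config$no3_mean, config$no3_sd), 0)
      nh4 <- pmax(rnorm(length(yrs), config$nh4_mean, config$nh4_sd), 0)
      tibble::tibble(lake_id = lakes$lake_id[i],
                     variable = rep(c("air_temp", "TP", "NO3", "NH4", "SSI"),
                                    each = length(yrs)),
                     year = rep(yrs, 5L),
                     value = c(temp, tp, no3, nh4, ssi))
    })
  })
}

# Lake table: coordinates uniform in the bounding box, temperature baselines
# assigned by an independent draw so geography and climate are uncorrelated.
simulate_lakes <- function(config) {
  n <- config$n_lakes
  tibble::tibble(
    lake_id = sprintf("lake_%02d", seq_len(n)),
    lat = runif(n, config$lat_range[1], config$lat_range[2]),
    lon = runif(n, config$lon_range[1], config$lon_range[2]),
    temp_baseline = runif(n, config$temp_baseline_range[1],
                          config$temp_baseline_range[2]))
}

#' Assemble one community under an assembly regime
#'
#' Draws `richness` taxa from the pool without replacement. `"neutral"`:
#' uniformly. `"filtering"`: with weight proportional to
#' `exp(-(trait - env_optimum)^2 / (2 sigma_niche^2))`; `sigma_niche = 0`
#' deterministically picks the `richness` taxa nearest the optimum.
#' `"dispersal_limited"`: with weight proportional to
#' `exp(-home_distance_km / dispersal_scale_km)`, where `home_distance_km`
#' is each taxon's distance from its fixed home lake to the focal lake.
#' Uses the caller's RNG stream.
#'
#' @param pool Character vector of available taxa.
#' @param richness Number of taxa to draw (<= pool size).
#' @param regime Assembly regime.
#' @param traits Named trait vector (filtering).
#' @param env_optimum Optimal trait value at this lake and time (filtering).
#' @param sigma_niche Niche breadth, trait units (filtering).
#' @param home_distance_km Named vector of home-lake distances (dispersal).
#' @param dispersal_scale_km Kernel scale, km (dispersal).
#' @return Character vector of `richness` taxa.
#' @export
assemble_community <- function(pool, richness,
                               regime = c("neutral", "filtering", "dispersal_limited"),
                               traits = NULL, env_optimum = NULL,
                               sigma_niche = 0.25,
                               home_distance_km = NULL, dispersal_scale_km = 25) {
  regime <- match.arg(regime)
  if (richness > length(pool)) {
    abort(sprintf("Richness %d exceeds pool size %d.", richness, length(pool)))
  }
  if (regime == "neutral") return(sample(pool, richness))
  if (regime == "filtering") {
    if (is.null(traits) || is.null(env_optimum)) {
      abort("Filtering needs `traits` and `env_optimum`.")
    }
    dev <- abs(traits[pool] - env_optimum)
    if (sigma_niche == 0) {
      return(pool[order(dev)][seq_len(richness)])
    }
    logw <- -dev^2 / (2 * sigma_niche^2)
    # Gumbel top-k: weighted sampling without replacement in log space, so
    # steep niches cannot underflow for optima far into one trait tail
    key <- logw - log(-log(runif(length(pool))))
    return(pool[order(key, decreasing = TRUE)[seq_len(richness)]])
  }
  if (is.null(home_distance_km)) {
    abort("Dispersal limitation needs `home_distance_km`.")
  }
  w <- exp(-home_distance_km[pool] / dispersal_scale_km)
  sample(pool, richness, prob = w)
}

#' Generate a complete synthetic study bundle
#'
#' Produces everything the pipeline consumes — phylogeny, traits, lakes,
#' annual environmental series, decade-growing taxon pools, sediment-layer
#' communities with multinomial sequencing counts — plus a ground-truth
#' table recording the regime and assembly parameters of every sample. The
#' same config (including its seed) always yields an identical bundle.
#'
#' Under the filtering regime, each lake-year's trait optimum is a fixed
#' linear map of that year's air temperature onto the central trait range;
#' the map coefficients are stored in the ground truth.
#'
#' @param config A [scenario_config()].
#' @return An `assembly_bundle` list: `tree`, `traits`, `lakes`, `env`,
#'   `community`, `metadata`, `ground_truth`, `pools`, `config`.
#' @export
simulate_bundle <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must come from scenario_config().")
  }
  seed <- config$seed
  tree <- simulate_tree(config$n_taxa, derive_seed(seed, "tree"))
  traits <- simulate_traits(tree, config$trait_sigma2, derive_seed(seed, "traits"))
  lakes <- with_local_seed(derive_seed(seed, "lakes"), simulate_lakes(config))
  env <- simulate_environment(config, lakes)

  # pool schedule: a fixed random taxon order, unveiled decade by decade
  taxon_order <- with_local_seed(derive_seed(seed, "pool"), sample(tree$tip.label))
  decades <- unique(decade_bin(config$years[1]:config$years[2]))
  n0 <- max(2L, ceiling(config$initial_pool_fraction * config$n_taxa))
  sizes <- round(seq(n0, config$n_taxa, length.out = length(decades)))
  pools <- tibble::tibble(bin = decades, n_taxa = as.integer(sizes),
                          taxa = lapply(sizes, function(s) taxon_order[seq_len(s)]))

  home <- with_local_seed(derive_seed(seed, "home"),
                          setNames(sample(lakes$lake_id, config$n_taxa,
                                          replace = TRUE), tree$tip.label))
  lake_d <- haversine_matrix(lakes)

  # temperature -> trait-optimum map (filtering): the realized temperature
  # range across lakes and years spans the central trait range, so lakes
  # with different climates select distinct portions of the regional pool
  temp_tbl <- env[env$variable == "air_temp", ]
  t_rng <- range(temp_tbl$value)
  q <- quantile(traits, c(0.05, 0.95), names = FALSE)
  opt_slope <- (q[2] - q[1]) / (t_rng[2] - t_rng[1])
  opt_intercept <- q[1] - opt_slope * t_rng[1]

  layer_years <- round(seq(config$years[1] + 1, config$years[2] - 1,
                           length.out = config$layers_per_lake))
  grid <- tidyr::expand_grid(lake_id = lakes$lake_id, year = layer_years)
  grid$sample_id <- sprintf("%s_%d", grid$lake_id, grid$year)

  counts <- matrix(0L, nrow(grid), config$n_taxa,
                   dimnames = list(grid$sample_id, tree$tip.label))
  gt <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sid <- grid$sample_id[i]
    lk <- grid$lake_id[i]
    yr <- grid$year[i]
    pool <- pools$taxa[[match(decade_bin(yr), pools$bin)]]
    temp_y <- temp_tbl$value[temp_tbl$lake_id == lk & temp_tbl$year == yr]
    optimum <- opt_intercept + opt_slope * temp_y
    hd <- lake_d[home, lk]
    names(hd) <- names(home)
    res <- with_local_seed(derive_seed(seed, paste0("sample::", sid)), {
      richness <- min(max(5L, stats::rpois(1L, config$richness_mean)), length(pool))
      taxa <- assemble_community(pool, richness, config$regime,
                                 traits = traits, env_optimum = optimum,
                                 sigma_niche = config$sigma_niche,
                                 home_distance_km = hd,
                                 dispersal_scale_km = config$dispersal_scale_km)
      depth <- max(config$depth_min,
                   round(stats::rlnorm(1L, config$depth_meanlog, config$depth_sdlog)))
      reads <- rmultinom(1L, depth, rep(1 / richness, richness))[, 1L]
      list(richness = richness, taxa = taxa, reads = reads, depth = depth)
    })
    counts[i, res$taxa] <- as.integer(res$reads)
    gt[[i]] <- tibble::tibble(
      sample_id = sid, lake_id = lk, year = yr, regime = config$regime,
      richness_drawn = res$richness, depth = res$depth,
      air_temp_true = temp_y, env_optimum = optimum,
      opt_slope = opt_slope, opt_intercept = opt_intercept,
      expected_structure = switch(config$regime,
                                  neutral = "random",
                                  filtering = "clustered",
                                  dispersal_limited = "random"))
  }
  metadata <- tibble::tibble(sample_id = grid$sample_id, lake_id = grid$lake_id,
                             year = as.integer(grid$year),
                             lat = lakes$lat[match(grid$lake_id, lakes$lake_id)],
                             lon = lakes$lon[match(grid$lake_id, lakes$lake_id)])
  structure(list(tree = tree, traits = traits, lakes = lakes, env = env,
                 community = as_community_tbl(counts), metadata = metadata,
                 ground_truth = dplyr::bind_rows(gt), pools = pools,
                 config = config, home_lakes = home),
            class = "assembly_bundle")
}

#' @export
print.assembly_bundle <- function(x, ...) {
  cat(sprintf(
    "<assembly_bundle> regime = %s: %d taxa, %d lakes, %d samples (%d-%d), seed %d\n",
    x$config$regime, x$config$n_taxa, x$config$n_lakes, nrow(x$metadata),
    x$config$years[1], x$config$years[2], x$config$seed))
  invisible(x)
}

#' Write / read a synthetic bundle as plain-text files
#'
#' Writes `tree.nwk`, `community.tsv`, `metadata.tsv`, `env.tsv`,
#' `lakes.tsv`, `ground_truth.tsv` and `traits.tsv` — the exact formats the
#' readers in this package consume.
#'
#' @param bundle An `assembly_bundle`.
#' @param dir Output directory (created if needed).
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: a list with
#'   the parsed `tree`, `community`, `metadata`, `env` (plus ground truth
#'   when present).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylogeny(bundle$tree, file.path(dir, "tree.nwk"))
  write_community_table(bundle$community, file.path(dir, "community.tsv"))
  readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(bundle$env, file.path(dir, "env.tsv"))
  readr::write_tsv(bundle$lakes, file.path(dir, "lakes.tsv"))
  readr::write_tsv(bundle$ground_truth, file.path(dir, "ground_truth.tsv"))
  readr::write_tsv(tibble::tibble(taxon = names(bundle$traits),
                                  trait = unname(bundle$traits)),
                   file.path(dir, "traits.tsv"))
  invisible(dir)
}

#' @param dir Directory written by [write_bundle()].
#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  out <- list(tree = read_phylogeny(file.path(dir, "tree.nwk")),
              community = read_community_table(file.path(dir, "community.tsv")),
              metadata = read_sample_metadata(file.path(dir, "metadata.tsv")),
              env = read_env_series(file.path(dir, "env.tsv")))
  gt <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt)) out$ground_truth <- readr::read_tsv(gt, show_col_types = FALSE)
  out
}
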