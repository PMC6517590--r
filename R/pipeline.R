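#' Validate a study bundle against the pipeline's input invariants
#'
#' Dry-run check of every input contract: tree well-formed, community counts
#' non-negative integers with unique IDs, community taxa present on the
#' tree, samples matched to metadata, coordinates and years in range,
#' environmental series unique per lake-variable-year.
#'
#' @param bundle A list with `tree`, `community`, `metadata`, `env` (an
#'   `assembly_bundle` or the result of [read_bundle()]).
#' @param error Abort on the first failed check (default) or return the
#'   report with failures flagged?
#' @return A tibble of checks (`check`, `ok`, `detail`), invisibly when
#'   `error = TRUE`.
#' @export
validate_bundle <- function(bundle, error = TRUE) {
  checks <- list()
  note <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail)
  }
  try_check <- function(check, expr) {
    res <- tryCatch({ expr; "" }, error = function(e) conditionMessage(e))
    note(check, !nzchar(res), res)
  }
  try_check("tree", validate_phylogeny(bundle$tree))
  try_check("community", {
    m <- community_matrix(bundle$community)
    if (nrow(m) == 0) abort("Community table is empty.")
    if (any(rowSums(m) == 0)) abort("Community has all-zero samples.")
  })
  try_check("taxa_on_tree", {
    m <- community_matrix(bundle$community)
    miss <- setdiff(colnames(m)[colSums(m) > 0], bundle$tree$tip.label)
    if (length(miss) > 0) {
      abort(paste0("Community taxa missing from the tree: ",
                   paste(head(miss, 5L), collapse = ", ")))
    }
  })
  try_check("metadata", {
    validate_metadata(bundle$metadata)
    miss <- setdiff(bundle$community$sample_id, bundle$metadata$sample_id)
    if (length(miss) > 0) {
      abort(paste0("Samples missing from metadata: ",
                   paste(head(miss, 5L), collapse = ", ")))
    }
  })
  try_check("environment", {
    env <- bundle$env
    if (!all(c("lake_id", "variable", "year", "value") %in% names(env))) {
      abort("Environmental series lacks lake_id/variable/year/value columns.")
    }
    key <- paste(env$lake_id, env$variable, env$year)
    if (anyDuplicated(key)) abort("Duplicated lake/variable/year rows.")
  })
  report <- dplyr::bind_rows(checks)
  if (error && any(!report$ok)) {
    bad <- report[!report$ok, ]
    abort(paste0("Bundle validation failed:\n  ",
                 paste(bad$check, bad$detail, sep = ": ", collapse = "\n  ")))
  }
  if (error) invisible(report) else report
}

#' Run the full community-assembly analysis
#'
#' Orchestrates every stage on one input bundle: validation, rarefaction to
#' a common depth, decade-resolved species pools and per-sample NTI against
#' the tip-shuffle null, all-pairs beta diversity for each requested metric,
#' the pairwise distance frame, and the distance-decay statistics —
#' per-decade geographic Mantel tests (binning removes the factor time),
#' pooled OLS fits of beta diversity on log geographic distance
#' (same-decade pairs), log temporal distance (same-lake pairs) and each
#' smoothed environmental gradient (restricted to non-random pairs).
#'
#' When `outdir` is given, writes `nti_per_sample.tsv`, one
#' `beta_<metric>.tsv` per metric, `pairwise_frame.tsv`,
#' `decay_summary.tsv`, `mantel_geographic_by_decade.tsv`, figure-ready
#' point tables (`nti_timeseries.tsv`, `geographic_decay_points.tsv`,
#' `temporal_decay_points.tsv`, `env_decay_points.tsv`) and a
#' `manifest.json` with the config hash, seed and output checksums. A rerun
#' with the same inputs and seed reproduces every table bit for bit.
#'
#' @param bundle Input bundle (an `assembly_bundle`, a [read_bundle()] list,
#'   or a directory path understood by [read_bundle()]).
#' @param outdir Optional output directory.
#' @param depth Rarefaction depth; default 2744 reads.
#' @param n_rand Null-model randomisations per sample; default 999.
#' @param n_perm Mantel permutations; default 999.
#' @param seed Master seed for rarefaction, null models and Mantel tests.
#' @param metrics Beta-diversity metrics to compute.
#' @param min_bin_samples Decade bins with fewer samples are excluded from
#'   the geographic analysis.
#' @param env_window Smoothing window (years) for environmental values.
#' @param env_vars Environmental variables to analyse; default all in `env`.
#' @return A list: `nti`, `betas`, `frame`, `decay_summary`,
#'   `mantel_geographic`, `pools`, `manifest` (invisibly if `outdir` given).
#' @export
run_pipeline <- function(bundle, outdir = NULL, depth = 2744L,
                         n_rand = 999L, n_perm = 999L, seed = 1L,
                         metrics = c("beta_mntd", "beta_mpd", "unifrac"),
                         min_bin_samples = 2L, env_window = 3L,
                         env_vars = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  validate_bundle(bundle)
  metrics <- match.arg(metrics, several.ok = TRUE)
  env_vars <- env_vars %||% sort(unique(bundle$env$variable))

  comm <- rarefy_counts(bundle$community, depth = depth,
                        seed = derive_seed(seed, "rarefy"))
  meta <- bundle$metadata[bundle$metadata$sample_id %in% comm$sample_id, ]
  meta$bin <- decade_bin(meta$year)

  pools <- build_pools(comm, meta)
  nti <- nti_series(comm, bundle$tree, meta, n_rand = n_rand, seed = seed,
                    pools = pools)

  betas <- lapply(setNames(metrics, metrics), function(mt) {
    pairwise_beta(comm, bundle$tree, metric = mt)
  })

  meta_env <- attach_env(meta, bundle$env, variables = env_vars,
                         window = env_window)
  frame <- build_pairwise_frame(betas, meta_env, env_vars = env_vars, nti = nti)

  # geographic analysis: same-decade pairs, sparse decades excluded
  kept_bins <- filter_bins(meta, min_samples = min_bin_samples)$bin
  geo_frame <- frame[frame$same_decade & frame$decade_1 %in% kept_bins, ]
  lake_geo <- haversine_matrix(dplyr::distinct(meta, .data$lake_id,
                                               .data$lat, .data$lon))
  ln_geo <- log(lake_geo + 1)

  summary_rows <- list()
  mantel_geo_all <- list()
  for (mt in metrics) {
    bcol <- paste0("beta_", sub("^beta_", "", mt))
    mg <- mantel_by_bin(betas[[mt]], meta, ln_geo, n_perm = n_perm,
                        seed = derive_seed(seed, paste0("mantel::", mt)),
                        min_samples = max(3L, min_bin_samples))
    mantel_geo_all[[mt]] <- dplyr::bind_cols(tibble::tibble(metric = mt), mg)
    fits <- list(
      safe_decay(geo_frame, bcol, "ln_geographic", "all"),
      safe_decay(frame[frame$same_lake, ], bcol, "ln_temporal", "all"))
    for (v in env_vars) {
      fits <- c(fits, list(safe_decay(frame, bcol, paste0("d_", v), "non_random")))
    }
    fits <- fits[!vapply(fits, is.null, logical(1))]
    rows <- dplyr::bind_rows(lapply(fits, glance))
    rows <- dplyr::bind_cols(tibble::tibble(metric = mt), rows)
    rows$mantel_fisher_p <- ifelse(rows$predictor == "ln_geographic",
                                   attr(mg, "fisher_p"), NA_real_)
    summary_rows[[mt]] <- rows
  }
  decay_summary <- dplyr::bind_rows(summary_rows)
  mantel_geographic <- dplyr::bind_rows(mantel_geo_all)

  manifest <- list(
    config = list(depth = depth, n_rand = n_rand, n_perm = n_perm, seed = seed,
                  metrics = metrics, min_bin_samples = min_bin_samples,
                  env_window = env_window, env_vars = env_vars),
    config_hash = rlang::hash(list(depth, n_rand, n_perm, seed, metrics,
                                   min_bin_samples, env_window, env_vars)),
    n_samples_in = nrow(bundle$community),
    n_samples_rarefied = nrow(comm),
    n_samples_scored = nrow(nti),
    n_pairs = nrow(frame),
    package_version = as.character(utils::packageVersion("phylodecay")))

  result <- list(nti = nti, betas = betas, frame = frame,
                 decay_summary = decay_summary,
                 mantel_geographic = mantel_geographic,
                 pools = pools, meta = meta_env, manifest = manifest)
  if (is.null(outdir)) return(result)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  readr::write_tsv(tibble::as_tibble(nti), out("nti_per_sample.tsv"))
  for (mt in metrics) {
    write_beta_matrix(betas[[mt]], out(paste0(mt, ".tsv")))
  }
  readr::write_tsv(frame, out("pairwise_frame.tsv"))
  readr::write_tsv(decay_summary, out("decay_summary.tsv"))
  readr::write_tsv(mantel_geographic, out("mantel_geographic_by_decade.tsv"))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(nti), "sample_id", "lake_id", "year",
                  "nti", "q025", "q975", "classification"),
    out("nti_timeseries.tsv"))
  beta_cols <- paste0("beta_", sub("^beta_", "", metrics))
  readr::write_tsv(
    dplyr::select(geo_frame, "sample_1", "sample_2", "lake_1", "lake_2",
                  "decade_1", "geographic_km", "ln_geographic",
                  dplyr::all_of(beta_cols)),
    out("geographic_decay_points.tsv"))
  readr::write_tsv(
    dplyr::select(frame[frame$same_lake, ], "sample_1", "sample_2", "lake_1",
                  "temporal_years", "ln_temporal", dplyr::all_of(beta_cols)),
    out("temporal_decay_points.tsv"))
  env_cols <- paste0("d_", env_vars)
  readr::write_tsv(
    dplyr::select(frame[frame$non_random_both, ], "sample_1", "sample_2",
                  dplyr::all_of(env_cols), dplyr::all_of(beta_cols)),
    out("env_decay_points.tsv"))
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest$output_checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$output_checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

safe_decay <- function(frame, response, predictor, subset) {
  tryCatch(distance_decay(frame, response, predictor, subset = subset),
           error = function(e) NULL)
}
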