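#' Decade-resolved species pools
#'
#' The null model draws random communities from the pool of taxa that was
#' actually observed in the study region during a sample's time bin, so that
#' temporal change in the size of the regional species pool is respected.
#' The pool of a bin is the union of taxa observed (count > 0) in any
#' sample assigned to that bin, across all lakes.
#'
#' @param comm Community tibble.
#' @param metadata Sample metadata with `sample_id` and `year`.
#' @param bin_fun Function mapping years to bin labels; default [decade_bin()].
#' @return A tibble with columns `bin`, `n_taxa` and a list-column `taxa`.
#' @export
build_pools <- function(comm, metadata, bin_fun = decade_bin) {
  m <- community_matrix(comm)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort(paste0("Samples missing from metadata: ",
                 paste(setdiff(rownames(m), metadata$sample_id), collapse = ", ")))
  }
  if (anyNA(meta$year)) {
    abort(paste0("Samples with no year (cannot be binned): ",
                 paste(meta$sample_id[is.na(meta$year)], collapse = ", ")))
  }
  bins <- bin_fun(meta$year)
  pools <- lapply(split(seq_len(nrow(m)), bins), function(rows) {
    colnames(m)[colSums(m[rows, , drop = FALSE] > 0) > 0]
  })
  tibble::tibble(bin = names(pools),
                 n_taxa = unname(lengths(pools)),
                 taxa = unname(pools))
}

#' Random tip-label permutation over a species pool
#'
#' One draw of the null model: taxon labels are shuffled uniformly at random
#' across the tip positions of the pool's phylogeny (restricted to the
#' pool's submatrix, so taxa absent in an era cannot enter its nulls).
#' Community membership vectors are untouched, so species richness is
#' preserved by construction.
#'
#' @param pool Character vector of pool taxa.
#' @return A named character vector mapping each taxon to the tip whose
#'   position it takes under the permutation.
#' @export
randomize_tips <- function(pool) {
  setNames(sample(pool), pool)
}

null_metric_values <- function(metric, D_pool, richness, n_rand) {
  m <- nrow(D_pool)
  vapply(seq_len(n_rand), function(k) {
    idx <- sample.int(m, richness)
    sub <- D_pool[idx, idx, drop = FALSE]
    if (metric == "mntd") {
      diag(sub) <- Inf
      mean(row_mins(sub))
    } else {
      mean(sub[lower.tri(sub)])
    }
  }, numeric(1))
}

exhaustive_metric_values <- function(metric, D_pool, richness, limit = 2e5) {
  m <- nrow(D_pool)
  if (choose(m, richness) > limit) {
    abort(sprintf("Exhaustive null over C(%d, %d) subsets is too large.", m, richness))
  }
  combs <- combn(m, richness)
  apply(combs, 2L, function(idx) {
    sub <- D_pool[idx, idx, drop = FALSE]
    if (metric == "mntd") {
      diag(sub) <- Inf
      mean(row_mins(sub))
    } else {
      mean(sub[lower.tri(sub)])
    }
  })
}

#' Standardised effect size of MNTD (or MPD) against the tip-shuffle null
#'
#' Compares a community's observed mean nearest taxon distance with its
#' distribution under random assembly: `n_rand` independent tip-label
#' randomisations over the species pool at fixed richness. Reports
#' `ses = (observed - mean(null)) / sd(null)`, the nearest taxon index
#' `nti = -ses`, the empirical 2.5% / 97.5% null quantiles, and the
#' classification: `"clustered"` when the observed value falls below the
#' 2.5% quantile (taxa closer relatives than expected), `"overdispersed"`
#' above the 97.5% quantile, `"random"` otherwise. With `exhaustive = TRUE`
#' the null enumerates all equally likely richness-sized subsets of the pool
#' instead of sampling (feasible only for small pools).
#'
#' A community that exhausts its pool has a degenerate null (SD 0): `ses`
#' is reported as `NA` and the classification is `"random"`.
#'
#' @param taxa Taxa present in the community (richness >= 2).
#' @param D Patristic distance matrix covering the pool.
#' @param pool Character vector of pool taxa (a superset of `taxa`).
#' @param metric `"mntd"` (default, the tip-sensitive metric) or `"mpd"`.
#' @param n_rand Number of randomisations; default 999.
#' @param seed Optional integer seed for this sample's null draws.
#' @param exhaustive Enumerate the exact null instead of sampling it?
#' @return A one-row tibble (`ses_result`).
#' @export
ses_phylo <- function(taxa, D, pool, metric = c("mntd", "mpd"),
                      n_rand = 999L, seed = NULL, exhaustive = FALSE) {
  metric <- match.arg(metric)
  taxa <- check_sample(taxa, D)
  if (!exhaustive && (length(n_rand) != 1L || is.na(n_rand) || n_rand < 1)) {
    abort("`n_rand` must be a positive integer.")
  }
  extra <- setdiff(taxa, pool)
  if (length(extra) > 0) {
    abort(paste0("Community taxa outside the pool: ", paste(extra, collapse = ", ")))
  }
  miss <- setdiff(pool, rownames(D))
  if (length(miss) > 0) {
    abort(paste0("Pool taxa absent from the distance matrix: ",
                 paste(miss, collapse = ", ")))
  }
  r <- length(taxa)
  observed <- if (metric == "mntd") comm_mntd(taxa, D) else comm_mpd(taxa, D)
  D_pool <- D[pool, pool, drop = FALSE]

  if (r == length(pool)) {
    # every permutation maps the community onto the whole pool: degenerate null
    return(ses_result_row(metric, r, length(pool), observed,
                          null_mean = observed, null_sd = 0,
                          ses = NA_real_, q = c(observed, observed),
                          classification = "random",
                          n_rand = if (exhaustive) 1L else as.integer(n_rand),
                          exhaustive = exhaustive))
  }

  null_vals <- if (exhaustive) {
    exhaustive_metric_values(metric, D_pool, r)
  } else {
    with_local_seed(seed, null_metric_values(metric, D_pool, r, n_rand))
  }
  null_mean <- mean(null_vals)
  null_sd <- sd(null_vals)
  q <- unname(quantile(null_vals, c(0.025, 0.975)))
  if (null_sd == 0) {
    ses <- NA_real_
    classification <- "random"
  } else {
    ses <- (observed - null_mean) / null_sd
    classification <- if (observed < q[1]) "clustered"
      else if (observed > q[2]) "overdispersed" else "random"
  }
  ses_result_row(metric, r, length(pool), observed, null_mean, null_sd, ses, q,
                 classification, length(null_vals), exhaustive)
}

ses_result_row <- function(metric, richness, pool_size, observed, null_mean,
                           null_sd, ses, q, classification, n_rand, exhaustive) {
  tibble::tibble(metric = metric, richness = as.integer(richness),
                 pool_size = as.integer(pool_size), observed = observed,
                 null_mean = null_mean, null_sd = null_sd, ses = ses,
                 nti = -ses, q025 = q[1], q975 = q[2],
                 classification = classification,
                 n_randomizations = as.integer(n_rand), exhaustive = exhaustive)
}

#' Nearest-taxon-index time series for a whole study
#'
#' Runs [ses_phylo()] for every sample against the species pool of its time
#' bin. Each sample gets its own RNG stream derived from `(seed, sample_id)`,
#' so the result does not depend on sample order. Samples that cannot be
#' scored (richness below 2, missing metadata) are dropped with a warning
#' rather than aborting the batch.
#'
#' @param comm Community tibble (typically rarefied).
#' @param tree Phylogeny containing all community taxa.
#' @param metadata Sample metadata (`sample_id`, `lake_id`, `year`).
#' @param metric `"mntd"` (default) or `"mpd"`.
#' @param n_rand Randomisations per sample; default 999.
#' @param seed Master seed.
#' @param bin_fun Year-to-bin function; default [decade_bin()].
#' @param pools Optional precomputed [build_pools()] result.
#' @return A tibble of class `nti_tbl`, one row per scored sample, with
#'   `sample_id`, `lake_id`, `year`, `bin` and the [ses_phylo()] columns.
#' @export
nti_series <- function(comm, tree, metadata, metric = c("mntd", "mpd"),
                       n_rand = 999L, seed = 1L, bin_fun = decade_bin,
                       pools = NULL) {
  metric <- match.arg(metric)
  m <- community_matrix(comm)
  D <- patristic_matrix(tree)
  miss <- setdiff(colnames(m)[colSums(m) > 0], rownames(D))
  if (length(miss) > 0) {
    abort(paste0("Community taxa absent from the tree: ",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  pools <- pools %||% build_pools(comm, metadata, bin_fun)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  bins <- bin_fun(meta$year)
  rows <- vector("list", nrow(m))
  failures <- character(0)
  for (i in seq_len(nrow(m))) {
    sid <- rownames(m)[i]
    pool <- pools$taxa[[match(bins[i], pools$bin)]]
    res <- tryCatch(
      ses_phylo(colnames(m)[m[i, ] > 0], D, pool, metric = metric,
                n_rand = n_rand, seed = derive_seed(seed, sid)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, paste0(sid, ": ", res))
    } else {
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = sid, lake_id = meta$lake_id[i],
                       year = meta$year[i], bin = bins[i]), res)
    }
  }
  if (length(failures) > 0) {
    warn(paste0("Skipped ", length(failures), " sample(s):\n  ",
                paste(failures, collapse = "\n  ")))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nti_tbl", class(out))
  out
}

#' @exportS3Method generics::glance
glance.nti_tbl <- function(x, ...) {
  non_random <- x$classification != "random"
  tibble::tibble(
    n_samples = nrow(x),
    n_non_random = sum(non_random),
    fraction_non_random = mean(non_random),
    fraction_clustered = mean(x$classification == "clustered"),
    fraction_overdispersed = mean(x$classification == "overdispersed"),
    mean_nti = mean(x$nti, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.nti_tbl <- function(x, ...) {
  tibble::as_tibble(x)
}
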