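#' Great-circle distance matrix between lakes
#'
#' Haversine distances on a sphere of radius `radius_km` (default the mean
#' Earth radius, 6371 km), via [geosphere::distHaversine()].
#'
#' @param coords Tibble with columns `lake_id`, `lat`, `lon` (one row per lake).
#' @param radius_km Sphere radius in kilometres.
#' @return A symmetric matrix of distances in km, lake IDs as dimnames.
#' @export
haversine_matrix <- function(coords, radius_km = 6371) {
  stopifnot(all(c("lake_id", "lat", "lon") %in% names(coords)))
  coords <- dplyr::distinct(coords, .data$lake_id, .data$lat, .data$lon)
  if (anyDuplicated(coords$lake_id)) {
    abort("A lake has more than one coordinate pair.")
  }
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    abort("Invalid coordinates (|lat| <= 90, |lon| <= 180 required).")
  }
  p <- as.matrix(coords[, c("lon", "lat")])
  d <- geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = radius_km)
  })
  dimnames(d) <- list(coords$lake_id, coords$lake_id)
  d
}

#' Decade bin label for a calendar year
#'
#' A decade spans years `[d0, d0 + 9]`, labelled e.g. `"1930s"`.
#'
#' @param year Integer vector of years CE (>= 1800).
#' @return Character vector of labels.
#' @export
decade_bin <- function(year) {
  if (any(year < 1800, na.rm = TRUE)) abort("Years before 1800 are not supported.")
  paste0(floor(year / 10) * 10, "s")
}

#' Drop time bins with too few samples
#'
#' Reproduces the exclusion of sparsely sampled early decades: bins holding
#' fewer than `min_samples` samples are removed, with a note.
#'
#' @param metadata Sample metadata (or any tibble with a `bin` column, else
#'   one is derived from `year`).
#' @param min_samples Minimum samples a bin must hold to be kept.
#' @param bin_fun Year-to-bin function used when `bin` is absent.
#' @return The filtered tibble (with a `bin` column).
#' @export
filter_bins <- function(metadata, min_samples = 2L, bin_fun = decade_bin) {
  if (!"bin" %in% names(metadata)) metadata$bin <- bin_fun(metadata$year)
  counts <- table(metadata$bin)
  drop <- names(counts)[counts < min_samples]
  if (length(drop) > 0) {
    inform(paste0("Excluding bin(s) with fewer than ", min_samples,
                  " samples: ", paste(drop, collapse = ", ")))
  }
  metadata[!metadata$bin %in% drop, , drop = FALSE]
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

mantel_r <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "pearson"))
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' simultaneous row/column permutations of the second matrix. The p-value is
#' one-sided (greater), the convention for distance-decay tests:
#' `p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1)`. With
#' `exhaustive = TRUE` all `n!` relabelings are enumerated (n <= 8) and
#' `p = #\{r_perm >= r_obs\} / n!`, the identity included.
#'
#' @param Dx,Dy Square symmetric matrices over the same samples in the same
#'   order (checked via dimnames when present).
#' @param n_perm Number of random permutations; default 999.
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all permutations instead of sampling?
#' @return A one-row tibble: `r`, `p`, `n_perm`, `n`, `method`.
#' @export
mantel_test <- function(Dx, Dy, n_perm = 999L, seed = NULL, exhaustive = FALSE) {
  Dx <- as.matrix(Dx); Dy <- as.matrix(Dy)
  n <- nrow(Dx)
  if (!all(dim(Dx) == n) || !all(dim(Dy) == n)) {
    abort("`Dx` and `Dy` must be square matrices of the same size.")
  }
  if (n < 3) abort("A Mantel test needs at least 3 samples.")
  if (!is.null(rownames(Dx)) && !is.null(rownames(Dy)) &&
      !identical(rownames(Dx), rownames(Dy))) {
    abort("`Dx` and `Dy` sample orders differ.")
  }
  lt <- lower.tri(Dx)
  x <- Dx[lt]
  if (sd(x) == 0 || sd(Dy[lt]) == 0) {
    warn("Zero variance among off-diagonal distances; Mantel r is undefined.")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n_perm = 0L, n = n,
                          method = "undefined"))
  }
  r_obs <- mantel_r(x, Dy[lt])
  eps <- 1e-12
  if (exhaustive) {
    if (n > 8) abort("Exhaustive Mantel is limited to n <= 8.")
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, function(p) mantel_r(x, Dy[p, p][lt]))
    p_val <- mean(r_perm >= r_obs - eps)
    return(tibble::tibble(r = r_obs, p = p_val, n_perm = nrow(perms), n = n,
                          method = "exhaustive"))
  }
  count <- with_local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      mantel_r(x, Dy[p, p][lt]) >= r_obs - eps
    }, logical(1)))
  })
  tibble::tibble(r = r_obs, p = (1 + count) / (n_perm + 1),
                 n_perm = as.integer(n_perm), n = n, method = "permutation")
}

#' Fisher's method for combining independent p-values
#'
#' @param p Vector of p-values (NA dropped).
#' @return The combined p-value, or `NA` when none are available.
#' @export
combine_pvalues_fisher <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  stat <- -2 * sum(log(p))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Per-bin geographic Mantel tests
#'
#' Runs one Mantel test per time bin between a beta-diversity matrix and a
#' predictor distance defined per lake (e.g. log geographic distance),
#' restricted to that bin's samples. Binning removes the factor time from
#' the geographic comparison: no cross-bin pair ever enters a test.
#'
#' @param beta A `beta_matrix` over samples.
#' @param metadata Sample metadata with `sample_id`, `lake_id`, `year`.
#' @param lake_dist Square matrix of predictor distances between lakes.
#' @param n_perm Permutations per test.
#' @param seed Master seed (per-bin streams derived from it).
#' @param min_samples Bins with fewer samples are skipped.
#' @param bin_fun Year-to-bin function.
#' @return A tibble with one row per tested bin (`bin`, `n`, `r`, `p`) plus
#'   an attribute `fisher_p`, the Fisher-combined p over bins.
#' @export
mantel_by_bin <- function(beta, metadata, lake_dist, n_perm = 999L, seed = 1L,
                          min_samples = 3L, bin_fun = decade_bin) {
  meta <- metadata[match(rownames(beta), metadata$sample_id), ]
  meta$bin <- bin_fun(meta$year)
  res <- lapply(split(seq_len(nrow(meta)), meta$bin), function(rows) {
    if (length(rows) < min_samples) return(NULL)
    ids <- meta$sample_id[rows]
    Dx <- unclass(beta)[ids, ids]
    Dy <- lake_dist[meta$lake_id[rows], meta$lake_id[rows]]
    dimnames(Dy) <- list(ids, ids)
    mt <- mantel_test(Dx, Dy, n_perm = n_perm,
                      seed = derive_seed(seed, paste0("mantel::", meta$bin[rows[1]])))
    dplyr::bind_cols(tibble::tibble(bin = meta$bin[rows[1]]), mt[, c("r", "p", "n")])
  })
  out <- dplyr::bind_rows(res)
  attr(out, "fisher_p") <- combine_pvalues_fisher(out$p)
  out
}

#' Pairwise environmental gradient
#'
#' One-dimensional Euclidean distance `|v_i - v_j|` of a smoothed
#' environmental variable between all unordered sample pairs, in the
#' variable's own units. Pairs where either value is missing are dropped
#' from this gradient only.
#'
#' @param metadata Sample metadata carrying the smoothed variable as a
#'   column (see [attach_env()]).
#' @param variable Column name of the variable.
#' @return A tibble: `sample_1`, `sample_2`, `delta`.
#' @export
env_gradient <- function(metadata, variable) {
  if (!variable %in% names(metadata)) {
    abort(paste0("Unknown environmental variable: ", variable))
  }
  v <- metadata[[variable]]
  idx <- which(upper.tri(diag(nrow(metadata))), arr.ind = TRUE)
  out <- tibble::tibble(sample_1 = metadata$sample_id[idx[, 1L]],
                        sample_2 = metadata$sample_id[idx[, 2L]],
                        delta = abs(v[idx[, 1L]] - v[idx[, 2L]]))
  out[!is.na(out$delta), ]
}

#' Assemble the long-form pairwise analysis frame
#'
#' One row per unordered sample pair, carrying every beta-diversity value
#' together with the geographic, temporal and environmental distances that
#' the decay analyses regress against. Geographic distance is between lakes
#' (0 for same-lake pairs); `ln_geographic = log(km + 1)` and
#' `ln_temporal = log(years + 1)` handle the zero distances of same-lake /
#' same-year pairs. When an `nti` table is given, each pair is annotated
#' with both members' null-model classifications.
#'
#' @param betas A `beta_matrix` or named list of them (names default to the
#'   metric tags).
#' @param metadata Sample metadata (`sample_id`, `lake_id`, `year`, `lat`,
#'   `lon`, plus any smoothed environmental columns).
#' @param env_vars Environmental columns to difference; default: every
#'   non-standard numeric column of `metadata`.
#' @param nti Optional `nti_tbl` from [nti_series()].
#' @param bin_fun Year-to-bin function.
#' @return A tibble, one row per unordered pair.
#' @export
build_pairwise_frame <- function(betas, metadata, env_vars = NULL, nti = NULL,
                                 bin_fun = decade_bin) {
  if (inherits(betas, "beta_matrix")) {
    betas <- setNames(list(betas), attr(betas, "metric"))
  }
  ids <- rownames(betas[[1L]])
  for (b in betas) {
    if (!identical(rownames(b), ids)) abort("Beta matrices have differing sample sets.")
  }
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort("Beta-matrix samples missing from metadata.")
  }
  std <- c("sample_id", "lake_id", "year", "lat", "lon", "bin")
  env_vars <- env_vars %||%
    names(meta)[vapply(meta, is.numeric, logical(1)) & !names(meta) %in% std]

  idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  geo <- haversine_matrix(meta[, c("lake_id", "lat", "lon")])
  km <- geo[cbind(match(meta$lake_id[i], rownames(geo)),
                  match(meta$lake_id[j], colnames(geo)))]
  yrs <- abs(meta$year[i] - meta$year[j])
  out <- tibble::tibble(
    sample_1 = ids[i], sample_2 = ids[j],
    lake_1 = meta$lake_id[i], lake_2 = meta$lake_id[j],
    year_1 = meta$year[i], year_2 = meta$year[j],
    decade_1 = bin_fun(meta$year[i]), decade_2 = bin_fun(meta$year[j]),
    same_lake = meta$lake_id[i] == meta$lake_id[j],
    same_decade = bin_fun(meta$year[i]) == bin_fun(meta$year[j]),
    geographic_km = km, ln_geographic = log(km + 1),
    temporal_years = yrs, ln_temporal = log(yrs + 1))
  for (nm in names(betas)) {
    out[[paste0("beta_", sub("^beta_", "", nm))]] <- betas[[nm]][cbind(i, j)]
  }
  for (v in env_vars) {
    out[[paste0("d_", v)]] <- abs(meta[[v]][i] - meta[[v]][j])
  }
  if (!is.null(nti)) {
    cls <- nti$classification[match(ids, nti$sample_id)]
    out$classification_1 <- cls[i]
    out$classification_2 <- cls[j]
    out$non_random_both <- cls[i] != "random" & cls[j] != "random"
    out$non_random_either <- cls[i] != "random" | cls[j] != "random"
  }
  out
}

#' Distance-decay regression on the pairwise frame
#'
#' Simple ordinary least squares of a beta-diversity column on one distance
#' predictor, optionally restricted to non-random pairs — pairs whose
#' members were classified non-random by the null model (`pair_rule =
#' "both"` requires both members non-random, `"either"` at least one).
#' Pairs with a missing response or predictor are dropped. The fit ignores
#' the non-independence of pairs sharing a sample, as is conventional for
#' distance-decay plots; pair it with [mantel_test()] for a
#' dependence-robust companion.
#'
#' @param frame Pairwise frame from [build_pairwise_frame()].
#' @param response Name of the beta column (e.g. `"beta_mntd"`).
#' @param predictor Name of the distance column (e.g. `"ln_geographic"`,
#'   `"ln_temporal"`, `"d_air_temp"`).
#' @param subset `"all"` pairs or `"non_random"` only.
#' @param pair_rule `"both"` (default) or `"either"`, for `"non_random"`.
#' @param exclude_same_lake Drop same-lake (zero-distance) pairs?
#' @return A `decay_fit` object; see [tidy.decay_fit()] / [glance.decay_fit()].
#' @export
distance_decay <- function(frame, response, predictor,
                           subset = c("all", "non_random"),
                           pair_rule = c("both", "either"),
                           exclude_same_lake = FALSE) {
  subset <- match.arg(subset)
  pair_rule <- match.arg(pair_rule)
  for (col in c(response, predictor)) {
    if (!col %in% names(frame)) abort(paste0("Column not in frame: ", col))
  }
  dat <- frame
  if (subset == "non_random") {
    flag <- if (pair_rule == "both") "non_random_both" else "non_random_either"
    if (!flag %in% names(dat)) {
      abort("Frame lacks null-model classifications; build it with `nti =`.")
    }
    dat <- dat[dat[[flag]], ]
  }
  if (exclude_same_lake) dat <- dat[!dat$same_lake, ]
  dat <- dat[!is.na(dat[[response]]) & !is.na(dat[[predictor]]), ]
  if (nrow(dat) < 3) {
    abort(sprintf("Too few pairs (%d) for subset '%s' on %s ~ %s.",
                  nrow(dat), subset, response, predictor))
  }
  fit <- lm(stats::reformulate(predictor, response), data = dat)
  structure(list(fit = fit, response = response, predictor = predictor,
                 subset = subset, pair_rule = pair_rule,
                 n = nrow(dat), data = dat),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<decay_fit> %s ~ %s (%s pairs, n = %d)\n  slope = %.4g, p = %.3g, adj R^2 = %.4g, DF = %d\n",
    x$response, x$predictor, x$subset, x$n,
    g$slope, g$p_slope, g$adj_r_squared, g$df_residual))
  invisible(x)
}

#' Tidy / summarise a distance-decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient. `glance()`: a one-row tibble
#'   with `slope`, `intercept`, `p_slope`, `r_squared`, `adj_r_squared`,
#'   `df_residual`, `n`, plus the response/predictor/subset labels.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1L], std_error = s[, 2L],
                 statistic = s[, 3L], p_value = s[, 4L])
}

#' @rdname tidy.decay_fit
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble::tibble(response = x$response, predictor = x$predictor,
                 subset = x$subset, n = x$n,
                 slope = co[2L, 1L], intercept = co[1L, 1L],
                 p_slope = co[2L, 4L],
                 r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 df_residual = as.integer(s$df[2L]))
}
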