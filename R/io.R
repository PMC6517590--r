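#' Read and validate a rooted phylogeny from newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream metrics rely on: unique non-empty tip labels, branch lengths
#' present on every edge and non-negative.
#'
#' @param file Path to a newick file. Exactly one of `file`/`text`.
#' @param text A newick string.
#' @return An object of class `phylo`.
#' @export
read_phylogeny <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text)) {
    abort("Provide exactly one of `file` or `text`.")
  }
  tree <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) abort("Malformed newick: could not be parsed.")
  validate_phylogeny(tree)
  tree
}

#' Validate the invariants of a phylogeny
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) abort("Phylogeny has empty tip labels.")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    abort("Phylogeny has no branch lengths; they are required.")
  }
  if (anyNA(tree$edge.length)) abort("Phylogeny has missing branch lengths.")
  if (any(tree$edge.length < 0)) abort("Phylogeny has negative branch lengths.")
  invisible(tree)
}

#' Write a phylogeny to newick
#'
#' @param tree A `phylo` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_phylogeny <- function(tree, file) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Read a samples-by-taxa count table from TSV
#'
#' The file has one header row of taxon identifiers and one sample identifier
#' per row (first column), or the transpose with `taxa = "rows"`. Cells must
#' be non-negative integers; any non-integer cell is rejected with its
#' location. Samples whose counts sum to zero are dropped with a warning.
#'
#' @param file Path to a tab-separated table.
#' @param taxa Orientation: are taxa in `"columns"` (default) or `"rows"`?
#' @return A tibble with a `sample_id` column followed by one integer column
#'   per taxon.
#' @export
read_community_table <- function(file, taxa = c("columns", "rows")) {
  taxa <- match.arg(taxa)
  raw <- read.delim(file, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (taxa == "rows") m <- t(m)
  bad <- which(!grepl("^[0-9]+$", m))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1L], dim(m))
    abort(sprintf(
      "Non-integer count '%s' at sample '%s', taxon '%s' in %s.",
      m[bad[1L]], rownames(m)[i[1L]], colnames(m)[i[2L]], file))
  }
  storage.mode(m) <- "integer"
  check_unique <- function(x, what) {
    dup <- unique(x[duplicated(x)])
    if (length(dup) > 0) {
      abort(paste0("Duplicated ", what, " IDs: ", paste(dup, collapse = ", ")))
    }
  }
  check_unique(rownames(m), "sample")
  check_unique(colnames(m), "taxon")
  as_community_tbl(m)
}

#' Convert between the tibble and matrix forms of a community table
#'
#' @param comm A community tibble (`sample_id` + taxon count columns).
#' @return `community_matrix()`: a named integer matrix, samples in rows.
#' @export
community_matrix <- function(comm) {
  stopifnot(is.data.frame(comm), "sample_id" %in% names(comm))
  m <- as.matrix(comm[, setdiff(names(comm), "sample_id"), drop = FALSE])
  rownames(m) <- comm$sample_id
  if (any(m < 0)) abort("Community counts must be non-negative.")
  storage.mode(m) <- "integer"
  m
}

#' @param m A samples-by-taxa count matrix with dimnames. All-zero samples
#'   are dropped with a warning.
#' @rdname community_matrix
#' @export
as_community_tbl <- function(m) {
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty) > 0) {
    warn(paste0("Dropping sample(s) with zero total counts: ",
                paste(empty, collapse = ", ")))
    m <- m[rowSums(m) > 0, , drop = FALSE]
  }
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Write a community table to TSV
#'
#' @param comm Community tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_community_table <- function(comm, file) {
  readr::write_tsv(comm, file)
  invisible(file)
}

#' Read per-sample metadata
#'
#' Expects tab-separated columns `sample_id`, `lake_id`, `year`, `lat`, `lon`.
#' Coordinates are validated; years must fall in `year_range`.
#'
#' @param file Path to the metadata TSV.
#' @param year_range Two integers giving the admissible study window.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(file, year_range = c(1800L, 2100L)) {
  meta <- readr::read_tsv(file, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            lake_id = readr::col_character(),
                            year = readr::col_integer(),
                            lat = readr::col_double(),
                            lon = readr::col_double()))
  validate_metadata(meta, year_range)
  meta
}

validate_metadata <- function(meta, year_range = c(1800L, 2100L)) {
  need <- c("sample_id", "lake_id", "year", "lat", "lon")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("Metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated sample IDs in metadata: ", paste(dup, collapse = ", ")))
  }
  if (any(abs(meta$lat) > 90, na.rm = TRUE)) abort("Latitude outside [-90, 90].")
  if (any(abs(meta$lon) > 180, na.rm = TRUE)) abort("Longitude outside [-180, 180].")
  out <- meta$year < year_range[1] | meta$year > year_range[2]
  if (any(out, na.rm = TRUE)) {
    abort(paste0("Sample year(s) outside the study window: ",
                 paste(meta$sample_id[which(out)], collapse = ", ")))
  }
  invisible(meta)
}

#' Read long-form annual environmental series
#'
#' Expects tab-separated columns `lake_id`, `variable`, `year`, `value`, one
#' row per lake-variable-year (annual means). Missing values are encoded as
#' `NA` and kept explicit; they are never silently zeroed.
#'
#' @param file Path to the environmental TSV.
#' @return A tibble.
#' @export
read_env_series <- function(file) {
  env <- readr::read_tsv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           lake_id = readr::col_character(),
                           variable = readr::col_character(),
                           year = readr::col_integer(),
                           value = readr::col_double()))
  key <- paste(env$lake_id, env$variable, env$year)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated lake/variable/year rows: ",
                 paste(head(dup, 5L), collapse = "; ")))
  }
  env
}

#' Rarefy a community table to a common sequencing depth
#'
#' Uniform random subsampling of each sample's reads without replacement
#' (hypergeometric rarefaction) to exactly `depth` reads, via
#' [vegan::rrarefy()]. Samples with fewer than `depth` reads are dropped with
#' a warning. The default depth of 2744 reads is the depth used for the
#' cyanobacterial sediment series this pipeline was built around.
#'
#' @param comm Community tibble.
#' @param depth Target depth (positive integer).
#' @param seed Optional integer; the same seed gives an identical result.
#' @return A rarefied community tibble (row sums all equal `depth`).
#' @export
rarefy_counts <- function(comm, depth = 2744L, seed = NULL) {
  if (length(depth) != 1L || is.na(depth) || depth < 1) {
    abort("`depth` must be a positive integer.")
  }
  m <- community_matrix(comm)
  shallow <- rownames(m)[rowSums(m) < depth]
  if (length(shallow) > 0) {
    warn(paste0("Dropping sample(s) below rarefaction depth ", depth, ": ",
                paste(shallow, collapse = ", ")))
    m <- m[!rownames(m) %in% shallow, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("No samples reach the rarefaction depth.")
  if (ncol(m) == 1) {
    # single-taxon table: subsampling is deterministic (and vegan would
    # read a one-column matrix as a single community vector)
    r <- matrix(as.integer(depth), nrow(m), 1L, dimnames = dimnames(m))
    return(as_community_tbl(r))
  }
  r <- with_local_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  storage.mode(r) <- "integer"
  as_community_tbl(r)
}

#' Smooth an annual environmental series around a dated layer
#'
#' Returns the arithmetic mean of `window` consecutive annual values around
#' `layer_year`, to buffer sediment-dating uncertainty. `align = "center"`
#' (default) uses years `layer_year - 1 .. layer_year + 1` for a 3-year
#' window; `align = "trailing"` uses the `window` years ending at
#' `layer_year`. Missing years inside the window are skipped; if no value is
#' available the result is `NA`.
#'
#' @param env Environmental series tibble (see [read_env_series()]).
#' @param lake,variable Which series to smooth.
#' @param layer_year Integer year of the dated layer.
#' @param window Number of consecutive years (>= 1); default 3.
#' @param align `"center"` or `"trailing"`.
#' @return A single numeric value (possibly `NA`).
#' @export
smooth_env <- function(env, lake, variable, layer_year, window = 3L,
                       align = c("center", "trailing")) {
  align <- match.arg(align)
  if (window < 1) abort("`window` must be >= 1.")
  years <- if (align == "center") {
    (layer_year - floor((window - 1) / 2)):(layer_year + ceiling((window - 1) / 2))
  } else {
    (layer_year - window + 1L):layer_year
  }
  v <- env$value[env$lake_id == lake & env$variable == variable &
                   env$year %in% years]
  if (all(is.na(v)) || length(v) == 0) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Attach smoothed environmental values to sample metadata
#'
#' Adds one column per environmental variable holding the window-smoothed
#' annual value for each sample's lake and layer year (see [smooth_env()]).
#'
#' @inheritParams smooth_env
#' @param metadata Sample metadata tibble.
#' @param variables Variables to attach; default all present in `env`.
#' @return `metadata` with one extra numeric column per variable.
#' @export
attach_env <- function(metadata, env, variables = NULL, window = 3L,
                       align = c("center", "trailing")) {
  align <- match.arg(align)
  variables <- variables %||% sort(unique(env$variable))
  for (v in variables) {
    metadata[[v]] <- purrr::map2_dbl(
      metadata$lake_id, metadata$year,
      function(l, y) smooth_env(env, l, v, y, window = window, align = align))
  }
  metadata
}
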