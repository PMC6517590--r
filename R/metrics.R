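#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#' Computed once per tree and reused by all metrics.
#'
#' @param tree A `phylo` object with at least two tips.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2) {
    abort("Patristic distances need a tree with >= 2 tips.")
  }
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

check_sample <- function(taxa, D, min_richness = 2L) {
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, rownames(D))
  if (length(missing) > 0) {
    abort(paste0("Taxa absent from the distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(taxa) < min_richness) {
    abort(sprintf("Metric undefined for richness %d (need >= %d).",
                  length(taxa), min_richness))
  }
  taxa
}

#' Mean pairwise phylogenetic distance of one community
#'
#' Mean patristic distance over all unordered pairs of distinct co-occurring
#' taxa; sensitive to basal tree structure. The default is presence/absence;
#' supplying `weights` (named abundances) gives the abundance-weighted mean
#' with pair weight proportional to the product of abundances.
#'
#' @param taxa Character vector of taxa present in the community.
#' @param D Patristic distance matrix (see [patristic_matrix()]).
#' @param weights Optional named non-negative abundances for `taxa`.
#' @return A single numeric value.
#' @export
comm_mpd <- function(taxa, D, weights = NULL) {
  taxa <- check_sample(taxa, D)
  sub <- D[taxa, taxa, drop = FALSE]
  if (is.null(weights)) return(mean(sub[lower.tri(sub)]))
  w <- weights[taxa]
  ww <- outer(w, w)
  diag(ww) <- 0
  sum(ww * sub) / sum(ww)
}

#' Mean nearest taxon distance of one community
#'
#' Mean, over taxa in the community, of the patristic distance to the closest
#' co-occurring relative; sensitive to structure at the tips of the
#' phylogeny. `weights` gives the abundance-weighted mean of the per-taxon
#' nearest-neighbour distances.
#'
#' @inheritParams comm_mpd
#' @return A single numeric value.
#' @export
comm_mntd <- function(taxa, D, weights = NULL) {
  taxa <- check_sample(taxa, D)
  sub <- D[taxa, taxa, drop = FALSE]
  diag(sub) <- Inf
  nn <- row_mins(sub)
  if (is.null(weights)) return(mean(nn))
  w <- weights[taxa]
  sum(w * nn) / sum(w)
}

# Fast row minima of a numeric matrix (no apply()).
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

#' Between-community nearest taxon distance (beta-MNTD)
#'
#' Average of (i) the mean distance from each taxon of community 1 to its
#' nearest taxon in community 2 and (ii) the converse. Shared taxa contribute
#' zero. With abundances, each directional mean is abundance-weighted.
#'
#' @param s1,s2 Character vectors of taxa in the two communities.
#' @param D Patristic distance matrix.
#' @param w1,w2 Optional named abundances for `s1` and `s2`.
#' @return A single numeric value.
#' @export
beta_mntd <- function(s1, s2, D, w1 = NULL, w2 = NULL) {
  s1 <- check_sample(s1, D, min_richness = 1L)
  s2 <- check_sample(s2, D, min_richness = 1L)
  cross <- D[s1, s2, drop = FALSE]
  nn1 <- row_mins(cross)
  nn2 <- row_mins(t(cross))
  m1 <- if (is.null(w1)) mean(nn1) else sum(w1[s1] * nn1) / sum(w1[s1])
  m2 <- if (is.null(w2)) mean(nn2) else sum(w2[s2] * nn2) / sum(w2[s2])
  (m1 + m2) / 2
}

#' Between-community mean pairwise distance (beta-MPD)
#'
#' Mean patristic distance over all cross pairs (one taxon from each
#' community); taxa occurring in both contribute zero for the pairs where
#' they meet themselves. Note the formula gives a nonzero value for a
#' community against itself; [pairwise_beta()] sets the matrix diagonal to
#' zero by convention and self-pairs are never used in regressions.
#'
#' @inheritParams beta_mntd
#' @return A single numeric value.
#' @export
beta_mpd <- function(s1, s2, D, w1 = NULL, w2 = NULL) {
  s1 <- check_sample(s1, D, min_richness = 1L)
  s2 <- check_sample(s2, D, min_richness = 1L)
  cross <- D[s1, s2, drop = FALSE]
  if (is.null(w1) && is.null(w2)) return(mean(cross))
  a <- if (is.null(w1)) rep(1, length(s1)) else w1[s1]
  b <- if (is.null(w2)) rep(1, length(s2)) else w2[s2]
  ww <- outer(a, b)
  sum(ww * cross) / sum(ww)
}

# Edge-by-tip incidence: entry [e, t] is TRUE when tip t descends from the
# child node of edge e. Computed once per tree for the UniFrac family.
branch_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- nt + tree$Nnode
  below <- matrix(FALSE, nnode, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  inc <- below[tree$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' UniFrac distance between two communities
#'
#' Unweighted mode (default): the fraction of total branch length (over
#' branches with at least one descendant in either community) that leads
#' exclusively to tips of one community. Weighted mode: branch lengths
#' weighted by the absolute difference in relative abundance descending each
#' branch, normalised to lie in \[0, 1\].
#'
#' @inheritParams beta_mntd
#' @param tree A `phylo` object containing every taxon of both communities.
#' @param mode `"unweighted"` (default) or `"weighted"`.
#' @param incidence Optional precomputed [branch_incidence()] for `tree`.
#' @return A numeric value in \[0, 1\].
#' @export
unifrac_pair <- function(s1, s2, tree, mode = c("unweighted", "weighted"),
                         w1 = NULL, w2 = NULL, incidence = NULL) {
  mode <- match.arg(mode)
  if (length(s1) == 0 || length(s2) == 0) abort("UniFrac needs non-empty communities.")
  inc <- incidence %||% branch_incidence(tree)
  missing <- setdiff(unique(c(s1, s2)), colnames(inc))
  if (length(missing) > 0) {
    abort(paste0("Taxa absent from the tree: ", paste(missing, collapse = ", ")))
  }
  bl <- tree$edge.length
  if (mode == "unweighted") {
    in1 <- inc[, colnames(inc) %in% s1, drop = FALSE]
    in2 <- inc[, colnames(inc) %in% s2, drop = FALSE]
    has1 <- rowSums(in1) > 0
    has2 <- rowSums(in2) > 0
    union_len <- sum(bl[has1 | has2])
    if (union_len == 0) return(0)
    sum(bl[xor(has1, has2)]) / union_len
  } else {
    a <- if (is.null(w1)) setNames(rep(1, length(s1)), s1) else w1[s1]
    b <- if (is.null(w2)) setNames(rep(1, length(s2)), s2) else w2[s2]
    pa <- pb <- numeric(ncol(inc))
    names(pa) <- names(pb) <- colnames(inc)
    pa[s1] <- a / sum(a)
    pb[s2] <- b / sum(b)
    fa <- as.numeric(inc %*% pa)
    fb <- as.numeric(inc %*% pb)
    denom <- sum(bl * (fa + fb))
    if (denom == 0) return(0)
    sum(bl * abs(fa - fb)) / denom
  }
}

#' All-pairs phylogenetic beta diversity
#'
#' Builds the symmetric matrix of one beta-diversity metric over every pair
#' of samples in a community table. The diagonal is 0 by convention.
#'
#' @param comm Community tibble (`sample_id` + taxon counts).
#' @param tree Phylogeny containing every taxon with nonzero counts.
#' @param metric One of `"beta_mntd"`, `"beta_mpd"`, `"unifrac"`.
#' @param weighted Use abundance weighting? Default `FALSE`
#'   (presence/absence, the conventional default of these metrics).
#' @return A `beta_matrix` object: the values matrix with attributes
#'   `metric` and `weighted`.
#' @export
pairwise_beta <- function(comm, tree,
                          metric = c("beta_mntd", "beta_mpd", "unifrac"),
                          weighted = FALSE) {
  metric <- match.arg(metric)
  m <- community_matrix(comm)
  if (nrow(m) < 2) abort("Pairwise beta diversity needs >= 2 samples.")
  taxa_lists <- apply(m > 0, 1L, function(r) colnames(m)[r], simplify = FALSE)
  wts <- if (weighted) {
    apply(m, 1L, function(r) setNames(as.numeric(r), colnames(m)),
          simplify = FALSE)
  }
  n <- nrow(m)
  V <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "unifrac") {
    # vectorised over samples: per-sample branch presence / abundance flow
    inc <- branch_incidence(tree)
    missing <- setdiff(colnames(m)[colSums(m) > 0], colnames(inc))
    if (length(missing) > 0) {
      abort(paste0("Taxa absent from the tree: ", paste(missing, collapse = ", ")))
    }
    keep <- intersect(colnames(m), colnames(inc))
    inc_m <- inc[, keep, drop = FALSE]
    bl <- tree$edge.length
    if (weighted) {
      R <- t(m[, keep, drop = FALSE] / rowSums(m))
      Fm <- inc_m %*% R
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          denom <- sum(bl * (Fm[, i] + Fm[, j]))
          V[i, j] <- V[j, i] <-
            if (denom == 0) 0 else sum(bl * abs(Fm[, i] - Fm[, j])) / denom
        }
      }
    } else {
      E <- (inc_m %*% t((m[, keep, drop = FALSE] > 0) * 1)) > 0
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          tot <- sum(bl[E[, i] | E[, j]])
          V[i, j] <- V[j, i] <-
            if (tot == 0) 0 else sum(bl[xor(E[, i], E[, j])]) / tot
        }
      }
    }
    return(structure(V, metric = metric, weighted = weighted,
                     class = c("beta_matrix", "matrix", "array")))
  }
  D <- patristic_matrix(tree)
  pair_fun <- function(i, j) {
    s1 <- taxa_lists[[i]]; s2 <- taxa_lists[[j]]
    w1 <- if (weighted) wts[[i]]; w2 <- if (weighted) wts[[j]]
    switch(metric,
      beta_mntd = beta_mntd(s1, s2, D, w1, w2),
      beta_mpd  = beta_mpd(s1, s2, D, w1, w2))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- tryCatch(pair_fun(i, j), error = function(e) {
        abort(sprintf("Beta diversity failed for pair (%s, %s): %s",
                      rownames(m)[i], rownames(m)[j], conditionMessage(e)))
      })
      V[i, j] <- V[j, i] <- v
    }
  }
  structure(V, metric = metric, weighted = weighted,
            class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> metric = %s (%s), %d samples\n",
              attr(x, "metric"), if (attr(x, "weighted")) "weighted" else "unweighted",
              nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Long-form tibble of a beta-diversity matrix
#'
#' @param x A `beta_matrix`.
#' @param ... Unused.
#' @return One row per unordered sample pair: `sample_1`, `sample_2`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.beta_matrix <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(sample_1 = rownames(x)[idx[, 1L]],
                 sample_2 = colnames(x)[idx[, 2L]],
                 value = x[idx])
}

#' Write / read a beta-diversity matrix as square TSV
#'
#' The metric tag and weighting are stored in a `#`-prefixed sidecar line at
#' the top of the file.
#'
#' @param x A `beta_matrix`.
#' @param file Path.
#' @return `write_beta_matrix()`: `file`, invisibly. `read_beta_matrix()`:
#'   the `beta_matrix`.
#' @export
write_beta_matrix <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s\tweighted: %s", attr(x, "metric"),
                     tolower(attr(x, "weighted"))), con)
  writeLines(paste(c("sample_id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], format(x[i, ], digits = 15L, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1L]
  if (!startsWith(hdr, "# metric:")) abort("Missing metric sidecar line.")
  metric <- sub("^# metric: (\\S+).*$", "\\1", hdr)
  weighted <- grepl("weighted: true", hdr)
  tab <- read.delim(text = lines[-1L], sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  structure(m, metric = metric, weighted = weighted,
            class = c("beta_matrix", "matrix", "array"))
}
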