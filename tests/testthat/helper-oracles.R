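# Independent brute-force oracles: patristic distances via shortest paths on
# the tree's edge graph (igraph), metrics via naive loops over taxa. These
# never touch the package's own computation paths.

oracle_patristic <- function(tree) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  tip_ids <- as.character(seq_along(tree$tip.label))
  d <- d[tip_ids, tip_ids]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

oracle_mpd <- function(taxa, D) {
  vals <- c()
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (i < j) vals <- c(vals, D[taxa[i], taxa[j]])
    }
  }
  mean(vals)
}

oracle_mntd <- function(taxa, D) {
  mean(sapply(taxa, function(a) {
    min(sapply(setdiff(taxa, a), function(b) D[a, b]))
  }))
}

oracle_beta_mntd <- function(s1, s2, D) {
  m1 <- mean(sapply(s1, function(a) min(sapply(s2, function(b) D[a, b]))))
  m2 <- mean(sapply(s2, function(b) min(sapply(s1, function(a) D[a, b]))))
  (m1 + m2) / 2
}

oracle_beta_mpd <- function(s1, s2, D) {
  vals <- c()
  for (a in s1) for (b in s2) vals <- c(vals, D[a, b])
  mean(vals)
}

t1_tree <- function() {
  read_phylogeny(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

random_test_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
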