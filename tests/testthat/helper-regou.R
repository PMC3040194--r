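# Shared fixtures, built in code.

# Random topology without branch lengths (for Pagel-length properties).
random_topology <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- NULL
  tr
}

# Random ultrametric height-1 tree.
random_ultrametric <- function(n) {
  rescale_tree_height(ape::rcoal(n))
}

# Brute-force BM covariance by explicit path enumeration: for each pair of
# tips, walk both root paths and sum the shared branch lengths.
bm_by_path_enumeration <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  v <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      v[i, j] <- sum(elen[shared])
    }
  }
  v
}

# Minimal valid trait tibble.
toy_traits <- function() {
  tibble::tibble(
    species = c("a", "b", "c", "d", "e"),
    hct = c(20, 22, 25, 30, 33),
    habitat = c("Terrestrial", "Terrestrial", "Terrestrial", "Marine", "Marine"),
    clade = rep("Colubrinae", 5)
  )
}
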