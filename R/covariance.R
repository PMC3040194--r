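# Residual covariance models for the GLS engine.
#
# Three models of residual covariance among species are supported, all on a
# tree rescaled to height 1:
#   star — the identity matrix (no phylogenetic structure; plain OLS);
#   bm   — Brownian motion on the tree: cov(i, j) is the height of the most
#          recent common ancestor of tips i and j measured from the root;
#   ou   — an Ornstein-Uhlenbeck branch-length transform indexed by an
#          attenuation parameter d in [0, 1]. Writing d = exp(-alpha), a
#          pair whose MRCA sits at height s has covariance
#              d^(2(1-s)) * (1 - d^(2s)) / (1 - d^2),
#          which is the stationary OU covariance scaled so the diagonal is
#          exactly 1. d = 1 recovers the Brownian matrix, d -> 0 the star.
#
# Matrices are built dense (n is on the order of tens of species) and carry
# the species order as dimnames; the smallest eigenvalue is checked against
# a hard PSD floor rather than jittered.

PSD_TOL <- 1e-10

new_covariance <- function(matrix, kind, d = NA_real_) {
  ev_min <- min(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -PSD_TOL) {
    abort(sprintf("Covariance matrix is not positive semi-definite (min eigenvalue %.3g).", ev_min))
  }
  structure(matrix, kind = kind, d = d, class = c("regou_cov", "matrix", "array"))
}

#' Star-phylogeny (identity) covariance
#'
#' @param species Character vector of species names fixing row/column order.
#' @return An identity matrix with species dimnames; `attr(, "kind")` is
#'   `"star"`.
#' @export
star_covariance <- function(species) {
  n <- length(species)
  m <- diag(n)
  dimnames(m) <- list(species, species)
  new_covariance(m, "star")
}

#' Brownian-motion covariance on a height-1 tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal is 1 on a height-1 ultrametric tree.
#'
#' @param tree An ultrametric `ape::phylo` tree rescaled to height 1
#'   (see [rescale_tree_height()]).
#' @param tol Ultrametricity tolerance.
#' @return The n x n covariance matrix, tips in `tree$tip.label` order.
#' @export
#' @examples
#' tr <- rescale_tree_height(parse_newick("((A:1,B:1):1,C:2);"))
#' bm_covariance(tr)
bm_covariance <- function(tree, tol = 1e-9) {
  h <- tree_height(tree, tol = tol)
  if (abs(h - 1) > 1e-8) {
    abort("Tree must be rescaled to height 1 before covariance construction.")
  }
  v <- ape::vcv.phylo(tree)
  v <- v[tree$tip.label, tree$tip.label]
  new_covariance(v, "bm")
}

# Elementwise OU transform of an MRCA-height matrix. Stable near d = 1 via
# expm1; exact limits at d = 0 and d = 1.
ou_transform <- function(s, d) {
  if (d == 1) return(s)
  if (d == 0) return(ifelse(s >= 1, 1, 0))
  ln_d <- log(d)
  exp(2 * (1 - s) * ln_d) * expm1(2 * s * ln_d) / expm1(2 * ln_d)
}

#' Ornstein-Uhlenbeck transformed covariance
#'
#' Applies the OU branch-length transform with attenuation parameter `d` to
#' the Brownian covariance of a height-1 tree. `d = 1` returns the Brownian
#' matrix; `d` near 0 returns (numerically) the identity; off-diagonal
#' entries increase monotonically in `d`.
#'
#' @inheritParams bm_covariance
#' @param d Attenuation parameter in `[0, 1]` (`d = exp(-alpha)` per unit
#'   tree height).
#' @return The transformed n x n covariance matrix with unit diagonal.
#' @export
#' @examples
#' tr <- rescale_tree_height(parse_newick("((A:1,B:1):1,C:2);"))
#' ou_covariance(tr, d = 0.5)
ou_covariance <- function(tree, d, tol = 1e-9) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1) {
    abort("`d` must be a single number in [0, 1].")
  }
  s <- bm_covariance(tree, tol = tol)
  v <- ou_transform(unclass(s), d)
  diag(v) <- 1
  new_covariance(v, "ou", d = d)
}

#' Export a covariance matrix as TSV
#'
#' @param v A covariance matrix with species dimnames.
#' @param path Output TSV path; species form the header row and first column.
#' @return The input, invisibly.
#' @export
write_covariance_tsv <- function(v, path) {
  df <- data.frame(species = rownames(v), unclass(v), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(v)
}
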