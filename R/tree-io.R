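# Newick tree input/output and branch-length conventions.
#
# Trees are `ape::phylo` objects throughout. Parsing and serialization are
# delegated to ape; the wrappers here add strict validation (balanced
# parentheses, unique non-empty tip labels, a single rooted statement) and
# the branch-length conventions the regression engine expects: Pagel
# arbitrary lengths for topologies without measured lengths, and rescaling
# to total height 1 so the OU parameter d is scale-free.

#' Parse a Newick string into a phylogenetic tree
#'
#' Accepts a single rooted Newick statement (terminated by `;`). Polytomies
#' are permitted and retained; branch lengths are optional. Tip order is the
#' left-to-right order of the Newick string.
#'
#' @param text A length-1 character vector holding one Newick statement.
#' @return An `ape::phylo` tree with unique, non-empty tip labels.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    abort("`text` must be a single non-empty Newick string.")
  }
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(sprintf("Unbalanced parentheses in Newick string: unmatched ')' at position %d.", i))
    }
  }
  if (depth != 0L) {
    abort(sprintf("Unbalanced parentheses in Newick string: %d unmatched '('.", depth))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort("Newick statement must be terminated by ';'.")
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort("ape could not parse the Newick string.")
  if (inherits(tree, "multiPhylo")) {
    abort("Expected a single tree, found several Newick statements.")
  }
  validate_tree(tree)
  tree
}

#' Read a Newick tree from a file
#'
#' Reads one tree from a `.phy`/`.nwk`/`.tre` file via [parse_newick()].
#'
#' @param path Path to a file holding a single Newick statement.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("Tree file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Serialize a tree to Newick
#'
#' Round-trip property: `parse_newick(write_newick(t))` reproduces the same
#' topology, labels and branch lengths (to 1e-12).
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Structural validation shared by all entry points taking a tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an `ape::phylo` object.")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) abort("Tree has empty tip labels.")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    abort(sprintf("Duplicate tip labels in tree: %s", paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("Tree has negative branch lengths.")
  }
  invisible(tree)
}

# Root-to-tip distances for an edge-length tree, without assuming binary
# topology. Returns a vector over all nodes (tips first, ape numbering).
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  # cladewise order visits each parent before its children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]
    ch <- ord$edge[i, 2]
    depth[ch] <- depth[p] + ord$edge.length[i]
  }
  depth
}

#' Total height of an ultrametric tree
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tol Relative tolerance on root-to-tip path differences.
#' @return The common root-to-tip depth.
#' @export
tree_height <- function(tree, tol = 1e-9) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  depth <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depth)
  if (h <= 0) abort("Tree height is zero.")
  if (any(abs(depth - h) > tol * h)) {
    abort(sprintf(
      "Tree is not ultrametric: root-to-tip depths range %.6g to %.6g.",
      min(depth), h
    ))
  }
  h
}

#' Assign Pagel arbitrary branch lengths
#'
#' Implements the node-height convention used by PDTREE/Mesquite for
#' topologies without meaningful branch lengths: each internal node gets
#' height (number of descendant tips - 1), tips get height 0, and each branch
#' length is the parent height minus the child height. Existing lengths are
#' discarded. The result is ultrametric with root height `n_tips - 1`;
#' zero-length branches can arise at polytomies and are legal downstream.
#'
#' @param tree An `ape::phylo` topology (branch lengths, if any, ignored).
#' @return The same topology with Pagel branch lengths.
#' @export
#' @examples
#' tr <- assign_pagel_branch_lengths(parse_newick("((A,B),(C,D));"))
#' tree_height(tr)  # 3
assign_pagel_branch_lengths <- function(tree) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  # descendant tip counts per node, via postorder accumulation
  tips_below <- numeric(n_node)
  tips_below[seq_len(ntip)] <- 1
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]
    ch <- ord$edge[i, 2]
    tips_below[p] <- tips_below[p] + tips_below[ch]
  }
  height <- pmax(tips_below - 1, 0)
  out <- tree
  out$edge.length <- height[tree$edge[, 1]] - height[tree$edge[, 2]]
  stopifnot(all(out$edge.length >= 0))
  out
}

#' Rescale a tree to total height 1
#'
#' All covariance construction operates on height-1 trees so that the OU
#' attenuation parameter d is scale-free and log-likelihoods are comparable
#' across residual models.
#'
#' @inheritParams tree_height
#' @return The tree with branch lengths divided by its height.
#' @export
rescale_tree_height <- function(tree, tol = 1e-9) {
  h <- tree_height(tree, tol = tol)
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Dump the node table of a tree
#'
#' Debug view of the tree structure: one row per node with its parent, the
#' branch length to the parent, and the tip label where applicable.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional TSV output path.
#' @return A tibble with columns `node`, `parent`, `length`, `label`.
#' @export
tree_node_table <- function(tree, path = NULL) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  len <- rep(NA_real_, n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  out <- tibble::tibble(
    node = seq_len(n_node),
    parent = parent,
    length = len,
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode))
  )
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# Canonical species-name form for matching trait rows to tip labels:
# trim surrounding whitespace and unify underscores/spaces. No fuzzy match.
normalize_species <- function(x) {
  gsub("[ _]+", "_", trimws(x))
}

#' Align a trait table to a tree's tip order
#'
#' Matches `traits$species` to `tree$tip.label` exactly after trimming
#' whitespace and unifying underscore/space. Any mismatch in either
#' direction is a hard error listing the unmatched names.
#'
#' @param traits A trait table (see [validate_traits()]).
#' @param tree An `ape::phylo` tree.
#' @return `traits` reordered to the tree's tip order.
#' @export
align_traits_to_tree <- function(traits, tree) {
  traits <- validate_traits(traits)
  validate_tree(tree)
  tips <- normalize_species(tree$tip.label)
  sp <- normalize_species(traits$species)
  missing_in_traits <- setdiff(tips, sp)
  missing_in_tree <- setdiff(sp, tips)
  if (length(missing_in_traits) || length(missing_in_tree)) {
    abort(paste0(
      "Species mismatch between trait table and tree.",
      if (length(missing_in_tree)) {
        paste0("\n  In traits but not tree: ", paste(missing_in_tree, collapse = ", "))
      },
      if (length(missing_in_traits)) {
        paste0("\n  In tree but not traits: ", paste(missing_in_traits, collapse = ", "))
      }
    ))
  }
  traits[match(tips, sp), , drop = FALSE]
}
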