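#' Simulate an ultrametric species tree
#'
#' Draws a pure-birth (Yule) tree with `n_species` leaves and assigns each
#' leaf to a taxonomic group by cutting the tree into clades. The tree plays
#' the role of the taxonomy used by the phylogeny-aware regression models.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed; the same seed yields an identical tree.
#' @param n_groups number of taxonomic groups to label (capped at
#'   `n_species`).
#' @return an object of class `mc_tree`: a list with `phy` (an
#'   [ape::rphylo()] phylo object with tips `sp01`, `sp02`, ...) and
#'   `groups` (named character vector, one group label per leaf).
#' @export
simulate_tree <- function(n_species, seed = 1L, n_groups = min(4L, n_species %/% 2L)) {
  if (!is.numeric(n_species) || n_species < 2) {
    stop("n_species must be >= 2", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  n_groups <- max(1L, min(as.integer(n_groups), n_species))
  phy <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  phy$tip.label <- sprintf("sp%02d", seq_len(n_species))
  d <- stats::cophenetic(phy)
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"),
                      k = n_groups)
  groups <- setNames(paste0("g", cl[phy$tip.label]), phy$tip.label)
  structure(list(phy = phy, groups = groups), class = "mc_tree")
}

#' @export
print.mc_tree <- function(x, ...) {
  cat("mc_tree:", length(x$phy$tip.label), "species,",
      length(unique(x$groups)), "groups\n")
  invisible(x)
}

#' Newick string of a simulated tree
#' @param tree an `mc_tree` or `phylo` object.
#' @return single Newick string.
#' @export
tree_newick <- function(tree) {
  phy <- if (inherits(tree, "mc_tree")) tree$phy else tree
  ape::write.tree(phy)
}
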