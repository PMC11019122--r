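# Pairwise taxonomic and functional-tree beta diversity, partitioned
# into replacement and richness-difference components (Jaccard family).

beta_from_shared <- function(A, tot, mode) {
  # A: pairwise shared amount (species counts or branch lengths);
  # tot: per-site total amount.  b = tot_i - a, c = tot_j - a.
  n <- nrow(A)
  B <- matrix(tot, n, n) - A        # unique to row site
  C <- t(B)                          # unique to column site
  denom <- A + B + C
  if (any(denom[upper.tri(denom)] <= 0))
    stop("site pair with empty union; analyzed sites must be non-empty")
  total <- (B + C) / denom
  repl <- 2 * pmin(B, C) / denom
  rich <- abs(B - C) / denom
  diag(total) <- diag(repl) <- diag(rich) <- 0
  dn <- dimnames(A)
  dimnames(total) <- dimnames(repl) <- dimnames(rich) <- dn
  structure(list(total = total, repl = repl, rich = rich, mode = mode),
            class = "beta_triplet")
}

#' Taxonomic beta diversity with replacement/richness partitioning
#'
#' For each site pair with a shared species, b and c unique species:
#' beta_total = (b+c)/(a+b+c) (Jaccard dissimilarity),
#' beta_repl = 2 min(b,c)/(a+b+c) (replacement/turnover),
#' beta_rich = |b-c|/(a+b+c) (richness difference), so that
#' beta_total = beta_repl + beta_rich on every pair.
#'
#' @param cm 0/1 site-by-species matrix (no all-zero site rows).
#' @return object of class `beta_triplet`: list of the three symmetric
#'   site-by-site matrices `total`, `repl`, `rich` plus `mode`.
#' @export
beta_taxonomic <- function(cm) {
  cm <- validate_community(cm)
  A <- tcrossprod(cm)               # shared species counts
  beta_from_shared(A, rowSums(cm), "taxonomic")
}

# branch-length incidence: edges x species matrix (1 if the edge lies on
# the root-to-tip path of the species) and edge lengths
tree_edge_incidence <- function(phy) {
  if (inherits(phy, "functional_tree")) phy <- phy$phylo
  if (inherits(phy, "hclust")) phy <- ape::as.phylo(phy)
  if (!inherits(phy, "phylo")) stop("tree must be a phylo/hclust/functional_tree")
  ntip <- length(phy$tip.label)
  ne <- nrow(phy$edge)
  inc <- matrix(0L, ne, ntip, dimnames = list(NULL, phy$tip.label))
  # children of each edge: propagate tip sets from tips to root (postorder)
  po <- ape::reorder.phylo(phy, "postorder")
  tipsets <- vector("list", ntip + phy$Nnode)
  for (t in seq_len(ntip)) tipsets[[t]] <- t
  for (e in seq_len(ne)) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[child]])
  }
  for (e in seq_len(ne)) inc[e, tipsets[[po$edge[e, 2]]]] <- 1L
  list(incidence = inc, length = po$edge.length, phylo = po)
}

#' Functional (tree-based) beta diversity
#'
#' Replaces the species counts a, b, c of [beta_taxonomic()] by branch
#' lengths of the functional dendrogram spanned by both communities, by
#' only the first, and by only the second.  A branch is spanned by a
#' community when it lies on the root-to-tip path of at least one of the
#' community's species (only edges below the root count).
#'
#' @param cm 0/1 site-by-species matrix; every species must be a tip of
#'   the tree.
#' @param tree a `phylo`, `hclust`/`upgma`, or [functional_tree()] object.
#' @return `beta_triplet` with mode `"functional"`.
#' @export
beta_functional <- function(cm, tree) {
  cm <- validate_community(cm)
  te <- tree_edge_incidence(tree)
  missing <- setdiff(colnames(cm), colnames(te$incidence))
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  inc <- te$incidence[, colnames(cm), drop = FALSE]
  # edges x sites: does the site span the edge?
  span <- (inc %*% t(cm)) > 0
  M <- span * sqrt(te$length)
  A <- crossprod(M)                 # shared branch length per pair
  beta_from_shared(A, diag(A), "functional")
}

#' Mean and SD of beta components over site pairs
#'
#' @param bt a `beta_triplet`.
#' @return data.frame with one row per component (`total`, `repl`,
#'   `rich`) and columns `mean`, `sd` computed over the strict lower
#'   triangle.
#' @export
summarize_beta <- function(bt) {
  stopifnot(inherits(bt, "beta_triplet"))
  if (nrow(bt$total) < 2) stop("need at least 2 sites")
  comp <- c("total", "repl", "rich")
  vals <- lapply(comp, function(k) bt[[k]][lower.tri(bt[[k]])])
  data.frame(component = comp,
             mean = vapply(vals, mean, 0),
             sd = vapply(vals, sd, 0))
}

#' @export
print.beta_triplet <- function(x, ...) {
  s <- summarize_beta(x)
  cat(sprintf("%s beta diversity over %d sites\n", x$mode, nrow(x$total)))
  cat(sprintf("  beta_%s = %.2f +/- %.2f\n", s$component, s$mean, s$sd), sep = "")
  invisible(x)
}
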