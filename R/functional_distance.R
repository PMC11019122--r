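# Trait distances: per-trait Gower components, equal-contribution weight
# optimization, and the UPGMA functional dendrogram.

#' Per-trait Gower distance components
#'
#' For each continuous trait k, d_k(i,j) = |x_ik - x_jk| / range_k, so
#' every component lies in [0, 1].  Traits with zero range carry no
#' information and are dropped with a warning.
#'
#' @param traits data.frame or matrix of numeric traits, one row per
#'   species (rownames = species ids).
#' @return named list of symmetric species-by-species matrices.
#' @export
gower_per_trait <- function(traits) {
  x <- as.matrix(traits)
  if (is.null(rownames(x))) stop("traits need species rownames")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("all trait values must be finite numerics")
  out <- list()
  for (k in colnames(x)) {
    rng <- diff(range(x[, k]))
    if (rng == 0) {
      warning("trait '", k, "' has zero range and was dropped")
      next
    }
    d <- abs(outer(x[, k], x[, k], "-")) / rng
    out[[k]] <- d
  }
  if (!length(out)) stop("no trait with non-zero range")
  out
}

stat_vec <- function(m) m[lower.tri(m)]

weights_objective <- function(w, dv) {
  D <- as.vector(dv %*% w)
  if (sd(D) == 0) return(Inf)
  r <- apply(dv, 2, function(dk) suppressWarnings(cor(dk, D)))
  sd(r)
}

#' Optimize trait weights for equal contribution
#'
#' Finds weights w (w_k >= w_min, sum(w) = 1) of the combined Gower
#' distance D = sum_k w_k d_k that minimize the standard deviation of the
#' trait-contribution correlations r_k = cor(d_k, D), so that every trait
#' correlates (nearly) equally with the combined distance.  Deterministic
#' multi-start Nelder-Mead on a softmax reparameterization.
#'
#' @param d_list list of per-trait distance matrices from
#'   [gower_per_trait()] (at least 2).
#' @param w_min lower bound on each weight (default 0.01, avoids
#'   degenerate zero-weight solutions).
#' @param n_starts number of deterministic starting points.
#' @return object of class `trait_distance`: list with `distance` (the
#'   combined matrix), `weights`, `cors` (per-trait r_k), `sd_cor`
#'   (achieved objective), `converged`.
#' @export
optimize_trait_weights <- function(d_list, w_min = 0.01, n_starts = 8L) {
  K <- length(d_list)
  if (K < 2) stop("need at least 2 trait distance matrices")
  dv <- sapply(d_list, stat_vec)  # pairs x K
  span <- 1 - K * w_min
  if (span <= 0) stop("w_min too large for ", K, " traits")
  to_w <- function(theta) {
    e <- exp(theta - max(theta))
    w_min + span * e / sum(e)
  }
  obj <- function(theta) weights_objective(to_w(theta), dv)
  # deterministic starts: equal weights plus corners leaning on each trait
  starts <- list(rep(0, K))
  for (k in seq_len(K)) starts[[length(starts) + 1]] <- ifelse(seq_len(K) == k, 2, 0)
  h <- seq_len(max(0, n_starts - length(starts)))
  for (i in h) starts[[length(starts) + 1]] <- sin(seq_len(K) * i * 2.399)
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- is.finite(best$value)
  if (!converged) warning("weight optimizer did not converge; returning best candidate")
  w <- to_w(best$par)
  names(w) <- names(d_list)
  D <- Reduce(`+`, Map(`*`, d_list, w))
  r <- apply(dv, 2, function(dk) suppressWarnings(cor(dk, as.vector(dv %*% w))))
  structure(list(distance = D, weights = w, cors = setNames(r, names(d_list)),
                 sd_cor = best$value, converged = converged),
            class = "trait_distance")
}

#' @export
print.trait_distance <- function(x, ...) {
  cat("Equal-contribution weighted Gower distance\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat("  sd of trait correlations:", format(x$sd_cor, digits = 4), "\n")
  invisible(x)
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Builds an ultrametric dendrogram by unweighted pair-group average
#' linkage.  Ties in the minimum inter-cluster distance are broken
#' deterministically toward the pair whose lexicographically smallest
#' member label sorts first (then by the second label), so the tree is
#' reproducible regardless of input order.  Merge heights follow the
#' `hclust` convention (height = average distance between the merged
#' clusters), hence `stats::cophenetic` on the result returns the average
#' inter-cluster distance, and the ultrametric node sits at height/2 in
#' the [ape::as.phylo] conversion.
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix with
#'   dimnames (or a `dist`).
#' @return object of classes `upgma`/`hclust`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  if (any(d < 0)) stop("d must be non-negative")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active clusters: id (<0 leaf, >0 merge row), size, minimum member label
  id <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    diag(Dm) <- Inf
    dmin <- min(Dm)
    cand <- which(Dm <= dmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on (smaller, larger) member labels
    lab1 <- pmin(minlab[active[cand[, 1]]], minlab[active[cand[, 2]]])
    lab2 <- pmax(minlab[active[cand[, 1]]], minlab[active[cand[, 2]]])
    pick <- order(lab1, lab2)[1L]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmin
    # unweighted average linkage update into slot i
    ni <- size[i]; nj <- size[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    id[i] <- step
    size[i] <- ni + nj
    minlab[i] <- min(minlab[i], minlab[j])
    active <- setdiff(active, j)
  }
  out <- structure(list(merge = merge, height = height,
                        order = integer(n), labels = labels,
                        method = "upgma",
                        call = match.call(), dist.method = "user"),
                   class = c("upgma", "hclust"))
  out$order <- order_dendrogram(merge, n)
  out
}

# leaf ordering by left-to-right traversal of the merge tree
order_dendrogram <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Build the functional dendrogram from a trait table
#'
#' Species-level trait averaging (if specimen-level rows are supplied,
#' average them per species beforehand), per-trait Gower components,
#' equal-contribution weight optimization, then UPGMA.
#'
#' @param traits numeric trait table, one row per species.
#' @param w_min passed to [optimize_trait_weights()].
#' @return list of class `functional_tree` with `phylo` (ultrametric
#'   [ape] tree), `hclust` (the UPGMA object), and `trait_distance`.
#' @export
functional_tree <- function(traits, w_min = 0.01) {
  dl <- gower_per_trait(traits)
  td <- if (length(dl) >= 2) optimize_trait_weights(dl, w_min = w_min) else
    structure(list(distance = dl[[1]], weights = c(1), cors = c(1),
                   sd_cor = 0, converged = TRUE), class = "trait_distance")
  hc <- upgma(td$distance)
  structure(list(phylo = ape::as.phylo(hc), hclust = hc,
                 trait_distance = td),
            class = "functional_tree")
}

#' @export
print.functional_tree <- function(x, ...) {
  cat("Functional UPGMA tree with", length(x$phylo$tip.label), "species\n")
  print(x$trait_distance)
  invisible(x)
}

#' Average specimen-level trait measurements per species
#'
#' @param specimens data.frame with a `species` column and numeric trait
#'   columns; one row per measured specimen.
#' @return data.frame of species-mean traits with species rownames and a
#'   `sample_n` attribute column per trait count.
#' @export
species_trait_means <- function(specimens) {
  if (!"species" %in% names(specimens)) stop("need a 'species' column")
  sp <- as.character(specimens$species)
  num <- specimens[vapply(specimens, is.numeric, logical(1))]
  agg <- aggregate(num, by = list(species = sp), FUN = mean)
  out <- agg[, -1, drop = FALSE]
  rownames(out) <- agg$species
  attr(out, "sample_n") <- table(sp)
  out
}
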