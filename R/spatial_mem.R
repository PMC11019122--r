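# Spatial predictors: neighbor graphs (Delaunay, Gabriel, relative
# neighborhood, minimum spanning tree), Moran's eigenvector maps, and
# Blanchet-style double-stopping forward selection.

GRAPH_METHODS <- c("delaunay", "gabriel", "relative_neighborhood", "mst")

#' Great-circle distance matrix between site centroids
#'
#' @param sites validated site table.
#' @return symmetric matrix of Haversine distances in km.
#' @export
site_distances_km <- function(sites) {
  sites <- validate_sites(sites)
  m <- geosphere::distm(cbind(sites$lon, sites$lat),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(sites$site_id, sites$site_id)
  m
}

# planar projection (km) for the Delaunay circumcircle test; adequate for
# the archipelago's extent, with great-circle distances used everywhere a
# pure distance suffices
project_planar <- function(sites) {
  latm <- mean(sites$lat)
  cbind(x = sites$lon * 111.32 * cos(latm * pi / 180),
        y = sites$lat * 110.57)
}

delaunay_edges <- function(xy) {
  n <- nrow(xy)
  adj <- matrix(FALSE, n, n)
  if (n == 2) { adj[1, 2] <- adj[2, 1] <- TRUE; return(adj) }
  x <- xy[, 1]; y <- xy[, 2]
  eps <- 1e-9 * max(diff(range(x)), diff(range(y)))^2
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    # circumcircle of (i, j, k); skip (near-)collinear triples
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    inside <- d2 < r2 - eps
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
    }
  }
  adj
}

#' Build a spatial neighbor graph over sites
#'
#' Standard constructions: Gabriel graph (edge i-j iff no third point
#' falls inside the circle with diameter ij), relative neighborhood graph
#' (iff no k with max(d(i,k), d(j,k)) < d(i,j)), minimum spanning tree of
#' the complete great-circle-distance graph, and Delaunay triangulation
#' (empty-circumcircle triangles on a local planar projection).
#'
#' @param sites validated site table (unique coordinates required).
#' @param method one of `"delaunay"`, `"gabriel"`,
#'   `"relative_neighborhood"`, `"mst"`.
#' @param weight_style `"binary"` (default) or `"inverse_distance"`.
#' @return object of class `spatial_graph`: list with `adjacency`
#'   (logical), `W` (weight matrix), `method`, `connected`, `site_id`.
#' @export
build_graph <- function(sites, method = GRAPH_METHODS,
                        weight_style = c("binary", "inverse_distance")) {
  method <- match.arg(method)
  weight_style <- match.arg(weight_style)
  sites <- validate_sites(sites)
  n <- nrow(sites)
  if (n < 2) stop("need at least 2 sites")
  D <- site_distances_km(sites)
  if (any(D[upper.tri(D)] == 0)) stop("duplicate site coordinates")
  adj <- switch(method,
    delaunay = {
      if (n < 3) stop("Delaunay needs at least 3 sites")
      delaunay_edges(project_planar(sites))
    },
    gabriel = {
      a <- matrix(FALSE, n, n)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        ok <- TRUE
        for (k in seq_len(n)) if (k != i && k != j &&
              D[i, k]^2 + D[j, k]^2 < D[i, j]^2 - 1e-9) { ok <- FALSE; break }
        if (ok) a[i, j] <- a[j, i] <- TRUE
      }
      a
    },
    relative_neighborhood = {
      a <- matrix(FALSE, n, n)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        ok <- TRUE
        for (k in seq_len(n)) if (k != i && k != j &&
              max(D[i, k], D[j, k]) < D[i, j] - 1e-9) { ok <- FALSE; break }
        if (ok) a[i, j] <- a[j, i] <- TRUE
      }
      a
    },
    mst = {
      m <- ape::mst(D)
      matrix(as.logical(m), n, n)
    })
  dimnames(adj) <- dimnames(D)
  W <- if (weight_style == "binary") adj * 1 else ifelse(adj, 1 / D, 0)
  diag(W) <- 0
  # connectivity via breadth-first reach
  reach <- logical(n); reach[1] <- TRUE
  repeat {
    new <- reach | (colSums(adj[reach, , drop = FALSE]) > 0)
    if (all(new == reach)) break
    reach <- new
  }
  structure(list(adjacency = adj, W = W, method = method,
                 weight_style = weight_style, connected = all(reach),
                 site_id = sites$site_id),
            class = "spatial_graph")
}

#' Moran's eigenvector maps from a spatial graph
#'
#' Eigen-decomposes the doubly centered weight matrix H W H (H = I -
#' 11'/n).  Eigenvectors with eigenvalue above `tol` model positive
#' spatial autocorrelation and form the default candidate set; each
#' retained vector is centered (orthogonal to the unit vector) and unit
#' norm, and Moran's I = (n / sum(W)) (v' W v)/(v' v) is reported.
#'
#' @param graph a `spatial_graph`.
#' @param which `"positive"` (default) or `"all"` non-null eigenvectors.
#' @param tol eigenvalue magnitude below which vectors are discarded.
#' @return object of class `mem_basis`: list with `vectors` (sites x m,
#'   columns MEM1, MEM2, ...), `values` (retained eigenvalues),
#'   `values_all` (full spectrum of H W H), `moran`, `method`.
#' @export
mem_eigenvectors <- function(graph, which = c("positive", "all"), tol = 1e-9) {
  which <- match.arg(which)
  stopifnot(inherits(graph, "spatial_graph"))
  W <- graph$W
  n <- nrow(W)
  if (n < 3) stop("need at least 3 sites for MEMs")
  H <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(H %*% W %*% H, symmetric = TRUE)
  keep <- if (which == "positive") e$values > tol else abs(e$values) > tol
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  o <- order(lam, decreasing = TRUE)
  V <- V[, o, drop = FALSE]; lam <- lam[o]
  moran <- if (ncol(V)) (n / sum(W)) * colSums((W %*% V) * V) / colSums(V * V)
           else numeric(0)
  if (ncol(V)) {
    colnames(V) <- paste0("MEM", seq_len(ncol(V)))
    rownames(V) <- graph$site_id
  }
  structure(list(vectors = V, values = lam, values_all = e$values,
                 moran = moran, method = graph$method), class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("MEM basis (%s graph): %d eigenvectors\n", x$method,
              ncol(x$vectors)))
  invisible(x)
}

#' Forward selection of MEMs with the double stopping rule
#'
#' First a global permutation test of the full candidate set against the
#' response dissimilarity (if non-significant, nothing is selected).
#' Then eigenvectors are added greedily by added R-squared; selection
#' stops when the added candidate is non-significant at `alpha` or when
#' the cumulative adjusted R-squared exceeds that of the global model.
#'
#' @param D site-by-site response dissimilarity matrix.
#' @param basis a `mem_basis` (candidates) or numeric matrix.
#' @param alpha significance level (default 0.05).
#' @param nperm permutations per test (default 999).
#' @param seed integer seed making the permutation stream reproducible.
#' @return list with `selected` (column indices), `names`, `global_p`,
#'   `global_adjr2`, `adjr2` (cumulative path), `pvals`.
#' @export
forward_select <- function(D, basis, alpha = 0.05, nperm = 999, seed = 1) {
  V <- if (inherits(basis, "mem_basis")) basis$vectors else as.matrix(basis)
  empty <- list(selected = integer(0), names = character(0), global_p = NA_real_,
                global_adjr2 = NA_real_, adjr2 = numeric(0), pvals = numeric(0))
  if (is.null(V) || ncol(V) == 0) return(empty)
  Y <- pcoa_axes(D)$axes
  n <- nrow(Y)
  tot <- sum(Y^2)
  rng <- local_rng(seed)
  perms <- replicate(nperm, sample.int(n), simplify = FALSE)
  r2 <- function(X, Yp) { # R2 of Yp on centered X (rank-truncated)
    q <- qr(scale(X, scale = FALSE))
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    sum(crossprod(Q, Yp)^2) / tot
  }
  # global test
  r2_all <- r2(V, Y)
  p_all <- ncol(V)
  stat_perm <- vapply(perms, function(p) r2(V, Y[p, , drop = FALSE]), 0)
  global_p <- (sum(stat_perm >= r2_all) + 1) / (nperm + 1)
  global_adjr2 <- adj_r2(r2_all, n, p_all)
  if (global_p > alpha) { empty$global_p <- global_p
                          empty$global_adjr2 <- global_adjr2
                          return(empty) }
  selected <- integer(0); pvals <- numeric(0); adjr2 <- numeric(0)
  r2_sel <- 0
  remaining <- seq_len(ncol(V))
  while (length(remaining)) {
    gains <- vapply(remaining, function(j)
      r2(V[, c(selected, j), drop = FALSE], Y) - r2_sel, 0)
    j <- remaining[which.max(gains)]
    gain_obs <- max(gains)
    gain_perm <- vapply(perms, function(p) {
      Yp <- Y[p, , drop = FALSE]
      r2(V[, c(selected, j), drop = FALSE], Yp) -
        (if (length(selected)) r2(V[, selected, drop = FALSE], Yp) else 0)
    }, 0)
    pj <- (sum(gain_perm >= gain_obs) + 1) / (nperm + 1)
    if (pj > alpha) break
    selected <- c(selected, j)
    r2_sel <- r2_sel + gain_obs
    pvals <- c(pvals, pj)
    adjr2 <- c(adjr2, adj_r2(r2_sel, n, length(selected)))
    if (adjr2[length(adjr2)] > global_adjr2) break
    remaining <- setdiff(remaining, j)
  }
  rng$restore()
  list(selected = selected, names = colnames(V)[selected],
       global_p = global_p, global_adjr2 = global_adjr2,
       adjr2 = adjr2, pvals = pvals)
}

#' Choose the spatial weighting matrix by adjusted R-squared
#'
#' Runs [forward_select()] on the MEM candidates of each graph
#' construction and returns the method whose selected eigenvectors give
#' the highest adjusted R-squared on the response; ties resolve toward
#' the canonical order delaunay, gabriel, relative_neighborhood, mst.
#'
#' @param D response dissimilarity matrix.
#' @param sites validated site table.
#' @param methods subset of the four graph methods.
#' @param weight_style,alpha,nperm,seed passed through.
#' @return list of class `swm_choice`: `method`, `graph`, `basis`,
#'   `selection`, `adjr2`, `mems` (selected eigenvector matrix, possibly
#'   0 columns), and `per_method` summary.
#' @export
choose_swm <- function(D, sites, methods = GRAPH_METHODS,
                       weight_style = "binary", alpha = 0.05, nperm = 999,
                       seed = 1) {
  methods <- match.arg(methods, GRAPH_METHODS, several.ok = TRUE)
  fits <- list()
  for (m in methods) {
    g <- build_graph(sites, m, weight_style)
    b <- mem_eigenvectors(g)
    sel <- if (ncol(b$vectors)) forward_select(D, b, alpha, nperm, seed)
           else list(selected = integer(0), adjr2 = numeric(0))
    score <- if (length(sel$selected)) sel$adjr2[length(sel$adjr2)] else -Inf
    fits[[m]] <- list(graph = g, basis = b, selection = sel, score = score)
  }
  scores <- vapply(fits, `[[`, 0, "score")
  if (all(!is.finite(scores))) {
    warning("no method selected any MEM; spatial factor set is empty")
    best <- methods[1]
  } else best <- methods[which.max(scores)]  # which.max keeps canonical order on ties
  f <- fits[[best]]
  mems <- f$basis$vectors[, f$selection$selected, drop = FALSE]
  structure(list(method = best, graph = f$graph, basis = f$basis,
                 selection = f$selection,
                 adjr2 = if (is.finite(f$score)) f$score else NA_real_,
                 mems = mems,
                 per_method = data.frame(method = methods,
                                         adjr2 = ifelse(is.finite(scores),
                                                        scores, NA))),
            class = "swm_choice")
}

#' @export
print.swm_choice <- function(x, ...) {
  cat(sprintf("SWM choice: %s graph, %d MEMs selected, adjR2 = %s\n",
              x$method, ncol(x$mems), format(x$adjr2, digits = 3)))
  invisible(x)
}

# scoped RNG: set a seed, hand back a restorer for the prior state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
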