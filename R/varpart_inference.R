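# Distance-based RDA, adjusted R-squared, three-set variation
# partitioning, and the row-permutation significance test.

FRACTION_NAMES <- c("S|(E&H)", "E|(S&H)", "H|(S&E)", "S&E|H", "E&H|S",
                    "S&H|E", "E&S&H")
TOTAL_NAMES <- c("Total S", "Total E", "Total H")

#' Classical adjusted R-squared
#'
#' @param r2 unadjusted R-squared.
#' @param n number of sites.
#' @param p number of predictor columns.
#' @return 1 - (1 - r2) (n - 1)/(n - p - 1).
#' @export
adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Principal-coordinate axes of a dissimilarity matrix
#'
#' Square-root transforms the dissimilarities (which renders
#' Jaccard-family matrices Euclidean-embeddable, so eigenvalues stay
#' non-negative), applies Gower double centering, and returns the axes
#' with eigenvalue above `tol`.  A Lingoes correction is available for
#' dissimilarities that remain non-Euclidean.
#'
#' @param D symmetric zero-diagonal dissimilarity matrix.
#' @param sqrt_transform apply the square-root transform (default TRUE).
#' @param correction `"none"` or `"lingoes"`.
#' @param tol eigenvalue threshold.
#' @return list with `axes` (n x m matrix scaled by sqrt(eigenvalue)),
#'   `values` (all eigenvalues), `neg` (most negative eigenvalue).
#' @export
pcoa_axes <- function(D, sqrt_transform = TRUE, correction = c("none", "lingoes"),
                      tol = 1e-9) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  if (sqrt_transform) D <- sqrt(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  H <- diag(n) - matrix(1 / n, n, n)
  G <- H %*% A %*% H
  e <- eigen(G, symmetric = TRUE)
  neg <- min(e$values)
  if (correction == "lingoes" && neg < -tol) {
    c1 <- -neg
    D2 <- sqrt(D^2 + 2 * c1)
    diag(D2) <- 0
    G <- H %*% (-0.5 * D2^2) %*% H
    e <- eigen(G, symmetric = TRUE)
  }
  keep <- e$values > tol
  axes <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(axes) <- rownames(D)
  list(axes = axes, values = e$values, neg = neg)
}

check_predictors <- function(X, n) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X)) stop("missing values in predictors; refusing to impute")
  Xc <- scale(X, scale = FALSE)
  if (any(apply(Xc, 2, function(v) all(abs(v) < 1e-12))))
    stop("constant predictor column(s): ",
         paste(colnames(X)[apply(Xc, 2, function(v) all(abs(v) < 1e-12))],
               collapse = ", "))
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    bad <- colnames(Xc)[q$pivot[(q$rank + 1):ncol(Xc)]]
    stop("collinear predictor column(s): ", paste(bad, collapse = ", "))
  }
  if (n <= ncol(X) + 1) stop("n must exceed number of predictors + 1")
  Xc
}

# R2 of response axes Y on centered predictors (orthonormalized once)
r2_on_axes <- function(Y, Q, tot = sum(Y^2)) sum(crossprod(Q, Y)^2) / tot

# rank-truncated orthonormal basis of a (centered) predictor block;
# combined sets in variation partitioning may be collinear by design
ortho_basis <- function(X) {
  q <- qr(X)
  list(Q = qr.Q(q)[, seq_len(q$rank), drop = FALSE], rank = q$rank)
}

#' Distance-based redundancy analysis
#'
#' Regresses the principal-coordinate axes of a dissimilarity matrix on
#' a predictor matrix.  R-squared is the explained share of the total
#' trace; adjusted R-squared applies the classical n/p correction.
#'
#' @param D site dissimilarity matrix.
#' @param X predictor matrix (full column rank after centering; n rows).
#' @param sqrt_transform,correction passed to [pcoa_axes()].
#' @return object of class `dbrda_model`: list with `r2`, `adj_r2`, `n`,
#'   `p`, `axes`, `fitted_trace`.
#' @export
dbrda <- function(D, X, sqrt_transform = TRUE, correction = "none") {
  p <- pcoa_axes(D, sqrt_transform, correction)
  Y <- p$axes
  n <- nrow(Y)
  Xc <- check_predictors(X, n)
  Q <- qr.Q(qr(Xc))
  r2 <- r2_on_axes(Y, Q)
  structure(list(r2 = r2, adj_r2 = adj_r2(r2, n, ncol(Xc)), n = n,
                 p = ncol(Xc), axes = Y, values = p$values),
            class = "dbrda_model")
}

#' @export
print.dbrda_model <- function(x, ...) {
  cat(sprintf("dbRDA: n = %d, p = %d, R2 = %.4f, adjR2 = %.4f\n",
              x$n, x$p, x$r2, x$adj_r2))
  invisible(x)
}

# adjusted R2 of the seven nested models, from precomputed Q bases
seven_adjr2 <- function(Y, Qs, ns, tot = sum(Y^2)) {
  n <- nrow(Y)
  vapply(seq_along(Qs), function(i)
    adj_r2(r2_on_axes(Y, Qs[[i]], tot), n, ns[i]), 0)
}

#' Unique and shared fractions from the seven model R-squared values
#'
#' Inclusion-exclusion step of three-set variation partitioning: given
#' the (adjusted) R-squared of the models on S, E, H, S+E, S+H, E+H and
#' S+E+H, returns the three unique fractions, three pairwise shared
#' fractions and the three-way shared fraction.  They sum to the
#' full-model value; the residual is 1 minus that value.
#'
#' @param r named numeric vector with elements `S`, `E`, `H`, `SE`,
#'   `SH`, `EH`, `SEH`.
#' @return named numeric vector of the seven fractions.
#' @examples
#' varpart_fractions(c(S = .4, E = .3, H = .2, SE = .55, SH = .45,
#'                     EH = .35, SEH = .6))
#' @export
varpart_fractions <- function(r) {
  stopifnot(all(c("S", "E", "H", "SE", "SH", "EH", "SEH") %in% names(r)))
  fractions_from_r2(r)
}

# order of `r`: S, E, H, SE, SH, EH, SEH
fractions_from_r2 <- function(r) {
  Su <- r["SEH"] - r["EH"]
  Eu <- r["SEH"] - r["SH"]
  Hu <- r["SEH"] - r["SE"]
  SE <- r["SEH"] - r["H"] - Su - Eu
  SH <- r["SEH"] - r["E"] - Su - Hu
  EH <- r["SEH"] - r["S"] - Eu - Hu
  SEH <- r["SEH"] - (Su + Eu + Hu + SE + SH + EH)
  out <- c(Su, Eu, Hu, SE, EH, SH, SEH)
  names(out) <- FRACTION_NAMES
  out
}

#' Three-set variation partitioning of a dissimilarity matrix
#'
#' Fits the seven dbRDA models (S, E, H, S+E, S+H, E+H, S+E+H) and
#' decomposes the full-model adjusted R-squared into the seven unique and
#' shared fractions by inclusion-exclusion.  Shared fractions may be
#' negative (suppression).
#'
#' @param D site dissimilarity matrix (response).
#' @param X_S,X_E,X_H spatial, environmental, historical predictor
#'   matrices.
#' @param sqrt_transform,correction passed to [pcoa_axes()].
#' @return object of class `varpart_result`: `fractions` (7 named
#'   values), `residual`, `totals` (marginal adjusted R2 of S, E, H),
#'   `model_r2` (the seven model adjusted R2), `n`.
#' @export
varpart3 <- function(D, X_S, X_E, X_H, sqrt_transform = TRUE,
                     correction = "none") {
  Y <- pcoa_axes(D, sqrt_transform, correction)$axes
  varpart3_axes(Y, X_S, X_E, X_H)
}

varpart3_axes <- function(Y, X_S, X_E, X_H) {
  n <- nrow(Y)
  XS <- check_predictors(X_S, n); XE <- check_predictors(X_E, n)
  XH <- check_predictors(X_H, n)
  sets <- list(S = XS, E = XE, H = XH, SE = cbind(XS, XE),
               SH = cbind(XS, XH), EH = cbind(XE, XH),
               SEH = cbind(XS, XE, XH))
  ob <- lapply(sets, ortho_basis)
  ns <- vapply(ob, `[[`, 0L, "rank")
  if (any(n <= ns + 1)) stop("n must exceed predictors + 1 in every subset model")
  Qs <- lapply(ob, `[[`, "Q")
  r <- setNames(seven_adjr2(Y, Qs, ns), names(sets))
  fr <- fractions_from_r2(r)
  structure(list(fractions = fr, residual = 1 - r[["SEH"]],
                 totals = setNames(r[c("S", "E", "H")], TOTAL_NAMES),
                 model_r2 = r, n = n),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Three-set variation partitioning (adjusted R2)\n")
  df <- data.frame(fraction = c(names(x$fractions), names(x$totals), "Residual"),
                   adj_r2 = round(c(x$fractions, x$totals, x$residual), 4))
  if (!is.null(x$p_values))
    df$p <- c(round(x$p_values[c(names(x$fractions), names(x$totals))], 4),
              NA)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Row-permutation significance test for variation partitioning
#'
#' Permutes the site rows of the community matrix (breaking the link
#' between assemblages and site-level predictors), regenerates the
#' response dissimilarity, re-runs the partitioning, and reports
#' p = (# permuted >= observed + 1)/(nperm + 1) for each of the seven
#' fractions and the three marginal totals.
#'
#' Because the Jaccard-family dissimilarities are functions of the rows,
#' the dissimilarity of a row-permuted community equals the jointly
#' row/column-permuted dissimilarity, so by default the principal
#' coordinates are computed once and only re-ordered per iteration
#' (`recompute = TRUE` re-derives the dissimilarity from the permuted
#' matrix literally and gives identical fractions).
#'
#' @param cm community matrix (rows aligned with the predictors).
#' @param response_fun function(cm) returning the response dissimilarity
#'   matrix, e.g. `function(m) beta_taxonomic(m)$repl`.
#' @param X_S,X_E,X_H predictor matrices.
#' @param nperm number of permutations (paper-scale default 9999; use
#'   199-999 for interactive work).
#' @param seed integer seed.
#' @param recompute literal recomputation of the response per iteration.
#' @param sqrt_transform,correction passed to [pcoa_axes()].
#' @return `varpart_result` with `p_values` and `nperm` added.
#' @export
varpart_permutation <- function(cm, response_fun, X_S, X_E, X_H,
                                nperm = 999, seed = 1, recompute = FALSE,
                                sqrt_transform = TRUE, correction = "none") {
  if (nperm < 1) stop("nperm must be >= 1")
  D <- response_fun(cm)
  Y <- pcoa_axes(D, sqrt_transform, correction)$axes
  obs <- varpart3_axes(Y, X_S, X_E, X_H)
  n <- nrow(Y)
  XS <- check_predictors(X_S, n); XE <- check_predictors(X_E, n)
  XH <- check_predictors(X_H, n)
  sets <- list(S = XS, E = XE, H = XH, SE = cbind(XS, XE),
               SH = cbind(XS, XH), EH = cbind(XE, XH),
               SEH = cbind(XS, XE, XH))
  ob <- lapply(sets, ortho_basis)
  ns <- vapply(ob, `[[`, 0L, "rank")
  Qs <- lapply(ob, `[[`, "Q")
  stat_obs <- c(obs$fractions, obs$totals)
  exceed <- numeric(length(stat_obs))
  rng <- local_rng(seed)
  for (b in seq_len(nperm)) {
    perm <- sample.int(n)
    Yp <- if (recompute) {
      cmp <- cm[perm, , drop = FALSE]
      rownames(cmp) <- rownames(cm)
      pcoa_axes(response_fun(cmp), sqrt_transform, correction)$axes
    } else Y[perm, , drop = FALSE]
    r <- setNames(seven_adjr2(Yp, Qs, ns), names(sets))
    stat_perm <- c(fractions_from_r2(r), setNames(r[c("S", "E", "H")], TOTAL_NAMES))
    exceed <- exceed + (stat_perm >= stat_obs)
  }
  rng$restore()
  obs$p_values <- setNames((exceed + 1) / (nperm + 1), names(stat_obs))
  obs$nperm <- nperm
  obs
}
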