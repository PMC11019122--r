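test_that("adjusted R2 follows the classical correction", {
  expect_equal(adj_r2(0.5, 10, 2), 1 - 0.5 * 9 / 7)
  expect_equal(adj_r2(0.5, 10, 2), 0.3571429, tolerance = 1e-6)
  expect_equal(adj_r2(1, 20, 3), 1)
})

test_that("dbRDA recovers a perfect fit and rejects bad predictors", {
  set.seed(4)
  n <- 12
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 2 * X[, 1] - X[, 2]
  D <- as.matrix(dist(y))^2          # sqrt transform recovers dist(y)
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  fit <- dbrda(D, X)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_error(dbrda(D, cbind(k = rep(2, n))), "constant")
  expect_error(dbrda(D, cbind(a = X[, 1], b = X[, 1] * 3)), "collinear.*b")
  expect_error(dbrda(D[1:3, 1:3], X[1:3, ]), "exceed")
})

test_that("dbRDA R2 matches a brute-force least-squares oracle", {
  set.seed(9)
  n <- 15
  Y0 <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(Y0))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  fit <- dbrda(D, X, sqrt_transform = FALSE)
  # oracle: explicit PCoA + per-axis lm, R2 = explained SS / total SS
  G <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  Y <- e$vectors[, e$values > 1e-9] %*% diag(sqrt(e$values[e$values > 1e-9]))
  ess <- sum(apply(Y, 2, function(y) sum(lm.fit(cbind(1, X), y)$fitted.values^2) -
                     length(y) * mean(y)^2))
  expect_equal(fit$r2, ess / sum(scale(Y, scale = FALSE)^2), tolerance = 1e-9)
})

test_that("dbRDA agrees with vegan's capscale on the same dissimilarity", {
  skip_if_not_installed("vegan")
  set.seed(10)
  a <- simulate_archipelago(scenario_config("MIXED", seed = 10,
    n_sites_per_region = c(HKD = 5, HSK = 10, NNS = 5), n_species = 15))
  D <- beta_taxonomic(a$community)$total
  X <- a$env[, c("temperature", "precipitation")]
  fit <- dbrda(D, X)
  ref <- vegan::capscale(as.dist(sqrt(D)) ~ temperature + precipitation,
                         data = as.data.frame(X))
  expect_equal(fit$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-6)
  expect_equal(fit$adj_r2, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-6)
})

test_that("inclusion-exclusion reproduces the worked fraction example", {
  fr <- varpart_fractions(c(S = 0.4, E = 0.3, H = 0.2, SE = 0.55,
                            SH = 0.45, EH = 0.35, SEH = 0.6))
  expect_equal(unname(fr["S|(E&H)"]), 0.25)
  expect_equal(unname(fr["E|(S&H)"]), 0.15)
  expect_equal(unname(fr["H|(S&E)"]), 0.05)
  expect_equal(unname(fr["S&E|H"]), 0)
  expect_equal(unname(fr["S&H|E"]), 0)
  expect_equal(unname(fr["E&H|S"]), 0)
  expect_equal(unname(fr["E&S&H"]), 0.15)
  expect_equal(sum(fr), 0.6)            # residual 0.4
})

test_that("fractions close on the full-model adjusted R2 and flag structure", {
  set.seed(14)
  a <- simulate_archipelago(scenario_config("MIXED", seed = 14))
  D <- beta_taxonomic(a$community)$total
  b <- mem_eigenvectors(build_graph(a$sites, "gabriel"))
  Xs <- b$vectors[, 1:5]
  vp <- varpart3(D, Xs, a$env, a$hist)
  expect_lt(abs(sum(vp$fractions) - vp$model_r2[["SEH"]]), 1e-9)
  expect_equal(vp$residual, 1 - vp$model_r2[["SEH"]])
  # an H set orthogonal to response and other predictors contributes nothing
  n <- nrow(D)
  set.seed(15)
  Xh_noise <- matrix(rnorm(n * 3), n, dimnames = list(rownames(D), paste0("h", 1:3)))
  vp2 <- varpart3(D, Xs, a$env, Xh_noise)
  expect_lt(abs(vp2$fractions[["H|(S&E)"]]), 0.06)
  expect_lt(abs(vp2$fractions[["S&H|E"]]), 0.06)
  expect_lt(abs(vp2$fractions[["E&H|S"]]), 0.06)
  # duplicated sets: uniques vanish, shared carries the signal
  vp3 <- varpart3(D, a$env, a$env + 0, a$hist)
  expect_lt(abs(vp3$fractions[["S|(E&H)"]]), 1e-9)
  expect_lt(abs(vp3$fractions[["E|(S&H)"]]), 1e-9)
  expect_equal(vp3$fractions[["S&E|H"]] + vp3$fractions[["E&S&H"]],
               vp3$model_r2[["S"]], tolerance = 1e-9)
})

test_that("three-set fractions agree with vegan's varpart on the same axes", {
  skip_if_not_installed("vegan")
  set.seed(23)
  a <- simulate_archipelago(scenario_config("MIXED", seed = 23))
  D <- beta_taxonomic(a$community)$repl
  b <- mem_eigenvectors(build_graph(a$sites, "gabriel"))
  Xs <- b$vectors[, 1:4]
  vp <- varpart3(D, Xs, a$env, a$hist)
  Y <- pcoa_axes(D)$axes
  ref <- vegan::varpart(Y, Xs, a$env, a$hist)
  f <- ref$part$indfract$Adj.R.square
  # vegan order: [a] X1, [b] X2, [c] X3, [d] X1&X2, [e] X2&X3, [f] X1&X3, [g]
  expect_equal(unname(vp$fractions["S|(E&H)"]), f[1], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["E|(S&H)"]), f[2], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["H|(S&E)"]), f[3], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["S&E|H"]), f[4], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["E&H|S"]), f[5], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["S&H|E"]), f[6], tolerance = 1e-9)
  expect_equal(unname(vp$fractions["E&S&H"]), f[7], tolerance = 1e-9)
})

test_that("the fast permutation path equals literal recomputation", {
  set.seed(30)
  a <- simulate_archipelago(scenario_config("HIST_ONLY", seed = 30,
    n_sites_per_region = c(HKD = 5, HSK = 10, NNS = 5), n_species = 14))
  b <- mem_eigenvectors(build_graph(a$sites, "gabriel"))
  Xs <- b$vectors[, 1:3]
  rf <- function(m) beta_taxonomic(m)$total
  fast <- varpart_permutation(a$community, rf, Xs, a$env, a$hist,
                              nperm = 19, seed = 5, recompute = FALSE)
  slow <- varpart_permutation(a$community, rf, Xs, a$env, a$hist,
                              nperm = 19, seed = 5, recompute = TRUE)
  expect_equal(fast$p_values, slow$p_values, tolerance = 1e-12)
  expect_equal(fast$fractions, slow$fractions, tolerance = 1e-12)
})

test_that("permutation p-values are reproducible and respect the +1 floor", {
  set.seed(31)
  a <- simulate_archipelago(scenario_config("HIST_ONLY", seed = 31))
  b <- mem_eigenvectors(build_graph(a$sites, "gabriel"))
  Xs <- b$vectors[, 1:4]
  rf <- function(m) beta_taxonomic(m)$total
  v1 <- varpart_permutation(a$community, rf, Xs, a$env, a$hist,
                            nperm = 99, seed = 9)
  v2 <- varpart_permutation(a$community, rf, Xs, a$env, a$hist,
                            nperm = 99, seed = 9)
  expect_identical(v1$p_values, v2$p_values)
  expect_true(all(v1$p_values >= 1 / 100))
  expect_true(all(v1$p_values <= 1))
  # strong historical structure beats every permutation: p at the floor
  expect_equal(unname(v1$p_values["Total H"]), 0.01)
  expect_error(varpart_permutation(a$community, rf, Xs, a$env, a$hist,
                                   nperm = 0), "nperm")
})

test_that("relabeling sites jointly leaves fractions unchanged", {
  set.seed(33)
  a <- simulate_archipelago(scenario_config("MIXED", seed = 33,
    n_sites_per_region = c(HKD = 5, HSK = 10, NNS = 5), n_species = 14))
  b <- mem_eigenvectors(build_graph(a$sites, "gabriel"))
  Xs <- b$vectors[, 1:3]
  D <- beta_taxonomic(a$community)$total
  vp <- varpart3(D, Xs, a$env, a$hist)
  perm <- sample(nrow(D))
  vp2 <- varpart3(D[perm, perm], Xs[perm, , drop = FALSE],
                  a$env[perm, ], a$hist[perm, ])
  expect_equal(vp$fractions, vp2$fractions, tolerance = 1e-9)
})
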