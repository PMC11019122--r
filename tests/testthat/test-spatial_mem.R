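test_that("triangle geometry yields full Delaunay and the two shortest MST edges", {
  sites <- make_sites(lat = c(35, 35.5, 36.4), lon = c(139, 140, 139.2))
  del <- build_graph(sites, "delaunay")
  expect_equal(sum(del$adjacency) / 2, 3)
  mst <- build_graph(sites, "mst")
  expect_equal(sum(mst$adjacency) / 2, 2)
  D <- site_distances_km(sites)
  longest <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_false(mst$adjacency[longest[1], longest[2]])
  expect_true(mst$connected)
})

test_that("collinear equidistant points give a Gabriel chain", {
  sites <- make_sites(lat = c(33, 34, 35, 36), lon = rep(139, 4))
  g <- build_graph(sites, "gabriel")
  a <- g$adjacency
  expect_true(a[1, 2] && a[2, 3] && a[3, 4])
  expect_false(a[1, 3] || a[1, 4] || a[2, 4])
})

test_that("RNG is contained in Gabriel is contained in Delaunay", {
  set.seed(31)
  # compact window so planar and great-circle geometry agree
  sites <- make_sites(lat = runif(50, 35, 37), lon = runif(50, 138, 140))
  rng <- build_graph(sites, "relative_neighborhood")$adjacency
  gab <- build_graph(sites, "gabriel")$adjacency
  del <- build_graph(sites, "delaunay")$adjacency
  expect_true(all(gab[rng]))
  expect_true(all(del[gab]))
})

test_that("inverse-distance weights decay with edge length", {
  sites <- make_sites(lat = c(35, 35.5, 37), lon = rep(139, 3))
  g <- build_graph(sites, "mst", weight_style = "inverse_distance")
  expect_gt(g$W[1, 2], g$W[2, 3])
  expect_error(build_graph(make_sites(lat = c(35, 35), lon = c(139, 139)), "mst"),
               "duplicate")
})

test_that("the 3-node chain has spectrum {-4/3, 0, 0} and no positive MEMs", {
  sites <- make_sites(lat = c(35, 36, 37), lon = rep(139, 3))
  g <- build_graph(sites, "mst")
  b <- mem_eigenvectors(g)
  expect_equal(sort(b$values_all), c(-4 / 3, 0, 0), tolerance = 1e-9)
  expect_identical(ncol(b$vectors), 0L)
})

test_that("the binary 4-cycle spectrum is {0, 0, 0, -2} after centering", {
  # square of sites: Gabriel graph is the 4-cycle
  sites <- make_sites(lat = c(35, 35, 36, 36), lon = c(139, 140, 140, 139))
  g <- build_graph(sites, "gabriel")
  expect_equal(sum(g$adjacency) / 2, 4)
  b <- mem_eigenvectors(g)
  expect_equal(sort(b$values_all), c(-2, 0, 0, 0), tolerance = 1e-6)
})

test_that("MEM bases are centered, orthonormal, and reconstruct H W H", {
  set.seed(8)
  for (n in c(6, 9, 12)) for (m in c("gabriel", "mst", "delaunay")) {
    sites <- make_sites(lat = runif(n, 30, 42), lon = runif(n, 132, 141))
    g <- build_graph(sites, m)
    b <- mem_eigenvectors(g, which = "all")
    V <- b$vectors
    if (ncol(V) == 0) next
    expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-9)
    expect_lt(max(abs(colSums(V))), 1e-9)
    # dense oracle: rebuild the centered matrix and check the eigenpairs
    W <- g$W
    H <- diag(n) - matrix(1 / n, n, n)
    M <- H %*% W %*% H
    expect_lt(max(abs(M %*% V - V %*% diag(b$values, ncol(V)))), 1e-8)
    ref <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(b$values_all), sort(ref), tolerance = 1e-9)
  }
})

test_that("Moran's I is monotone in the eigenvalue on a regular graph", {
  # 8-node ring (longitude stretched so great-circle spacing is regular):
  # constant row sums, so I is proportional to lambda
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  sites <- make_sites(lat = 36 + sin(th),
                      lon = 139 + cos(th) / cos(36 * pi / 180))
  g <- build_graph(sites, "relative_neighborhood")
  expect_true(all(rowSums(g$adjacency) == 2))
  b <- mem_eigenvectors(g, which = "all")
  expect_true(all(diff(b$moran) <= 1e-8))
  expect_equal(order(b$values, decreasing = TRUE), seq_along(b$values))
})

test_that("forward selection finds a planted eigenvector and stops on noise", {
  set.seed(12)
  sites <- make_sites(lat = sort(runif(25, 30, 42)), lon = runif(25, 132, 141))
  g <- build_graph(sites, "gabriel")
  b <- mem_eigenvectors(g)
  # response distances generated from MEM1 alone
  y <- b$vectors[, 1]
  D <- as.matrix(dist(y))^2 / max(dist(y))^2
  dimnames(D) <- list(sites$site_id, sites$site_id)
  sel <- forward_select(D, b, nperm = 199, seed = 4)
  expect_identical(sel$selected[1], 1L)
  # empty candidate set selects nothing
  none <- forward_select(D, b$vectors[, 0, drop = FALSE], nperm = 99, seed = 1)
  expect_length(none$selected, 0)
  # spatially unstructured response rarely selects anything
  set.seed(77)
  hits <- sum(vapply(1:10, function(i) {
    Dn <- as.matrix(dist(rnorm(25)))
    dimnames(Dn) <- dimnames(D)
    length(forward_select(Dn, b, nperm = 99, seed = i)$selected) > 0
  }, logical(1)))
  expect_lte(hits, 3)
})

test_that("forward selection is reproducible under a fixed seed", {
  set.seed(2)
  sites <- make_sites(lat = runif(20, 30, 42), lon = runif(20, 132, 141))
  g <- build_graph(sites, "mst")
  b <- mem_eigenvectors(g)
  a <- simulate_archipelago(scenario_config("SPACE_ONLY", seed = 1,
    n_sites_per_region = c(HKD = 5, HSK = 10, NNS = 5), n_species = 12))
  D <- beta_taxonomic(a$community)$total[1:20, 1:20]
  dimnames(D) <- list(sites$site_id, sites$site_id)
  s1 <- forward_select(D, b, nperm = 99, seed = 7)
  s2 <- forward_select(D, b, nperm = 99, seed = 7)
  expect_identical(s1, s2)
})

test_that("SWM choice prefers the graph whose MEM generated the response", {
  wins <- 0
  for (sd in 1:5) {
    set.seed(sd)
    sites <- make_sites(lat = sort(runif(30, 30, 42)), lon = runif(30, 132, 141))
    b <- mem_eigenvectors(build_graph(sites, "gabriel"))
    y <- b$vectors[, 1] + rnorm(30, 0, 0.05)
    D <- as.matrix(dist(y)); D <- D / max(D)
    dimnames(D) <- list(sites$site_id, sites$site_id)
    sw <- suppressWarnings(choose_swm(D, sites, nperm = 99, seed = sd))
    wins <- wins + (sw$method == "gabriel")
  }
  expect_gte(wins, 3)
})

test_that("a single available method is returned trivially", {
  set.seed(1)
  sites <- make_sites(lat = runif(12, 30, 42), lon = runif(12, 132, 141))
  a <- rand_community(12, 10)
  rownames(a) <- sites$site_id
  D <- beta_taxonomic(a)$total
  sw <- suppressWarnings(choose_swm(D, sites, methods = "mst", nperm = 99, seed = 1))
  expect_identical(sw$method, "mst")
})
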