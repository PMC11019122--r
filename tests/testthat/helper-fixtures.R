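# in-code fixtures shared across the suite

rand_community <- function(n, S, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cm <- matrix(rbinom(n * S, 1, p), n, S)
  while (any(rowSums(cm) == 0)) {
    i <- which(rowSums(cm) == 0)
    cm[i, ] <- rbinom(length(i) * S, 1, p)
  }
  dimnames(cm) <- list(sprintf("site%02d", seq_len(n)),
                       sprintf("sp%02d", seq_len(S)))
  cm
}

make_sites <- function(lat, lon, region = NULL, kind = "grid",
                       on_main = NULL, area = 6400) {
  n <- length(lat)
  if (is.null(region)) region <- rep("HSK", n)
  if (is.null(on_main)) on_main <- region != "NNS"
  validate_sites(data.frame(
    site_id = sprintf("s%02d", seq_len(n)), kind = rep(kind, length.out = n),
    lon = lon, lat = lat, region = region, on_main_island = on_main,
    area_km2 = rep(area, length.out = n)))
}

# a unit-branch star tree over the given species ids
star_tree <- function(species) {
  n <- length(species)
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = rep(1, n), Nnode = 1L,
                 tip.label = species), class = "phylo")
}

# community matrix from a list of species-id sets
cm_from_sets <- function(sets, species) {
  cm <- matrix(0L, length(sets), length(species),
               dimnames = list(names(sets) %||% paste0("site", seq_along(sets)),
                               species))
  for (i in seq_along(sets)) cm[i, sets[[i]]] <- 1L
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
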