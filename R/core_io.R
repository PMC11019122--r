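# Domain types, readers/writers, mesh-code arithmetic, covariate
# aggregation and scale filtering shared by every downstream stage.

REGIONS <- c("HKD", "HSK", "NNS")
SITE_KINDS <- c("grid", "island")

#' Primary mesh code of the Japanese standard grid
#'
#' Maps a coordinate to the 4-digit code of the national primary mesh
#' (1 degree longitude by 40 minutes latitude, roughly 6400 km^2), the
#' sampling unit used for gridded assemblages.  Cells are closed on their
#' lower-left and open on their upper-right boundary, so every point maps
#' to exactly one cell.
#'
#' @param lat,lon numeric vectors of latitude and longitude in decimal
#'   degrees.  Must lie inside the Japan domain: lat in (20, 50), lon in
#'   (120, 150).
#' @return integer vector of 4-digit mesh codes.
#' @examples
#' latlon_to_mesh1(35.0, 139.0)  # 5239
#' @export
latlon_to_mesh1 <- function(lat, lon) {
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  bad <- !is.finite(lat) | !is.finite(lon) |
    lat <= 20 | lat >= 50 | lon <= 120 | lon >= 150
  if (any(bad)) {
    stop("coordinates outside the supported domain (lat 20-50, lon 120-150): ",
         paste(which(bad), collapse = ", "))
  }
  as.integer(floor(lat * 1.5) * 100 + (floor(lon) - 100))
}

#' Validate a site table
#'
#' @param sites data.frame with columns `site_id`, `kind` ("grid" or
#'   "island"), `lon`, `lat`, `region` ("HKD", "HSK", "NNS"),
#'   `on_main_island` (logical or 0/1), `area_km2`.
#' @return the validated data.frame (invisibly coerced types).
#' @export
validate_sites <- function(sites) {
  need <- c("site_id", "kind", "lon", "lat", "region", "on_main_island",
            "area_km2")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites table missing columns: ",
                         paste(miss, collapse = ", "))
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id values")
  if (!all(sites$kind %in% SITE_KINDS)) stop("kind must be grid or island")
  if (!all(sites$region %in% REGIONS)) stop("region must be one of HKD/HSK/NNS")
  if (any(sites$lon < -180 | sites$lon > 180)) stop("lon out of [-180, 180]")
  if (any(sites$lat < -90 | sites$lat > 90)) stop("lat out of [-90, 90]")
  sites$on_main_island <- as.logical(sites$on_main_island)
  if (anyNA(sites$on_main_island)) stop("on_main_island must be logical/0-1")
  if (any(sites$area_km2 < 0)) stop("area_km2 must be non-negative")
  sites
}

#' Validate a site-by-species presence/absence matrix
#'
#' @param cm numeric matrix of 0/1 occurrences, sites in rows (rownames =
#'   site ids), species in columns (colnames = species ids).
#' @param allow_empty_sites keep all-zero site rows (default FALSE: an
#'   analyzed site must hold at least one species).
#' @return the validated integer matrix.
#' @export
validate_community <- function(cm, allow_empty_sites = FALSE) {
  cm <- as.matrix(cm)
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    stop("community matrix needs site rownames and species colnames")
  if (!all(cm %in% c(0, 1))) stop("community matrix must be 0/1")
  storage.mode(cm) <- "integer"
  if (!allow_empty_sites && any(rowSums(cm) == 0))
    stop("all-zero site rows: ",
         paste(rownames(cm)[rowSums(cm) == 0], collapse = ", "))
  cm
}

#' Read the standard CSV inputs
#'
#' `read_sites`, `read_community`, `read_traits` and `read_factors` load
#' the interchange CSVs (UTF-8, first column = id) used by the pipeline.
#'
#' @param path CSV file path.
#' @return `read_sites`: validated site data.frame; `read_community`:
#'   0/1 integer matrix; `read_traits`: data.frame with species rownames;
#'   `read_factors`: numeric matrix with site rownames.
#' @export
read_sites <- function(path) {
  validate_sites(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sites
#' @export
read_community <- function(path) {
  x <- read.csv(path, row.names = 1, check.names = FALSE)
  validate_community(as.matrix(x))
}

#' @rdname read_sites
#' @export
read_traits <- function(path) {
  x <- read.csv(path, row.names = 1, check.names = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate species ids in traits")
  x
}

#' @rdname read_sites
#' @export
read_factors <- function(path) {
  x <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(x)
}

#' Strait indicator variables
#'
#' Builds the two land-connection history indicators: `tsugaru` is 1 for
#' sites north of the Tsugaru Strait (region HKD) and `tokara` is 1 for
#' sites south of the Tokara Strait (region NNS).
#'
#' @param sites validated site table.
#' @return integer matrix (sites x 2) with columns `tsugaru`, `tokara`.
#' @export
strait_indicators <- function(sites) {
  sites <- validate_sites(sites)
  out <- cbind(tsugaru = as.integer(sites$region == "HKD"),
               tokara = as.integer(sites$region == "NNS"))
  rownames(out) <- sites$site_id
  out
}

#' Aggregate fine-grid covariate values to sites
#'
#' Averages point values of a fine raster-like table within each site.
#' Grid sites collect the points falling in their primary mesh cell
#' (via [latlon_to_mesh1] on the site centroid); island sites collect
#' points tagged with their `site_id` in the optional `island_id` column
#' of `fine`.  Sites containing no points are returned as `NA` (explicit
#' missing, never silent zero).
#'
#' @param fine data.frame with columns `lat`, `lon`, `value`, and
#'   optionally `island_id` for points belonging to island sites.
#' @param sites validated site table.
#' @return named numeric vector (one mean per site, `NA` = missing).
#' @export
aggregate_to_sites <- function(fine, sites) {
  sites <- validate_sites(sites)
  if (!all(c("lat", "lon", "value") %in% names(fine)))
    stop("fine table needs lat, lon, value columns")
  out <- setNames(rep(NA_real_, nrow(sites)), sites$site_id)
  grid <- sites$kind == "grid"
  if (any(grid)) {
    site_mesh <- latlon_to_mesh1(sites$lat[grid], sites$lon[grid])
    if (anyDuplicated(site_mesh)) stop("two grid sites share one mesh cell")
    pt <- !is.na(fine$lat) & !is.na(fine$lon)
    if (!is.null(fine$island_id)) pt <- pt & is.na(fine$island_id)
    if (any(pt)) {
      pm <- latlon_to_mesh1(fine$lat[pt], fine$lon[pt])
      m <- tapply(fine$value[pt], factor(pm, levels = site_mesh), mean,
                  na.rm = TRUE)
      out[grid] <- as.numeric(m)
    }
  }
  if (!is.null(fine$island_id)) {
    isl <- !is.na(fine$island_id)
    if (any(isl)) {
      m <- tapply(fine$value[isl],
                  factor(fine$island_id[isl], levels = sites$site_id), mean,
                  na.rm = TRUE)
      out[!is.na(m)] <- m[!is.na(m)]
    }
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Restrict community and sites to an analysis scale
#'
#' The two study scales are the entire archipelago and the main islands
#' only (sites flagged `on_main_island`, which excludes the minor islands
#' and the whole NNS region).  Species missing from every retained site
#' are dropped and reported.
#'
#' @param cm validated community matrix.
#' @param sites validated site table matching `rownames(cm)`.
#' @param scale `"entire"` or `"main_islands"`.
#' @return list with `community`, `sites`, and `dropped_species`.
#' @export
filter_scale <- function(cm, sites, scale = c("entire", "main_islands")) {
  scale <- match.arg(scale)
  sites <- validate_sites(sites)
  cm <- validate_community(cm)
  if (!identical(rownames(cm), sites$site_id))
    stop("community rownames must equal sites$site_id (same order)")
  keep <- if (scale == "entire") rep(TRUE, nrow(sites)) else sites$on_main_island
  if (sum(keep) < 4)
    stop("fewer than 4 sites at scale '", scale,
         "'; downstream ordination undefined")
  cm2 <- cm[keep, , drop = FALSE]
  empty <- colSums(cm2) == 0
  list(community = cm2[, !empty, drop = FALSE],
       sites = sites[keep, , drop = FALSE],
       dropped_species = colnames(cm2)[empty])
}

#' Write a labeled square matrix as CSV
#'
#' @param m square matrix with dimnames.
#' @param path output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
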