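# Biogeographical regionalization: UPGMA clustering of sites on beta
# matrices, border concordance at a strait, and species-mode clustering.

#' Cluster sites on a beta-diversity matrix
#'
#' UPGMA dendrogram of sites from any pairwise dissimilarity component
#' (the replacement component is the recommended choice for border
#' detection because it is richness-independent; total and
#' richness-difference clusterings complement it).
#'
#' @param d site-by-site dissimilarity matrix (e.g. `bt$repl`).
#' @return `upgma`/`hclust` dendrogram over sites.
#' @export
cluster_sites <- function(d) upgma(d)

#' Concordance between a 2-cluster cut and a strait side
#'
#' Cuts the dendrogram at k = 2 and measures the fraction of sites whose
#' cluster matches their side of the strait (maximized over the two
#' possible label pairings, so the score is invariant to label swaps).
#' The Tsugaru side split is HKD vs. the rest; the Tokara split is NNS
#' vs. the rest.
#'
#' @param dend dendrogram from [cluster_sites()] whose labels are site
#'   ids present in `sites`.
#' @param sites validated site table.
#' @param strait `"tsugaru"` or `"tokara"`.
#' @return concordance fraction in [0, 1].
#' @export
border_concordance <- function(dend, sites, strait = c("tsugaru", "tokara")) {
  strait <- match.arg(strait)
  sites <- validate_sites(sites)
  lab <- dend$labels
  side <- setNames(if (strait == "tsugaru") sites$region == "HKD"
                   else sites$region == "NNS", sites$site_id)[lab]
  if (anyNA(side)) stop("dendrogram labels missing from sites table")
  if (length(unique(side)) < 2)
    stop("dendrogram does not span the ", strait, " strait")
  cl <- cutree(dend, k = 2) == 1
  max(mean(cl == side), mean(cl == !side))
}

#' Species-mode clustering of distribution patterns
#'
#' Euclidean distance between species occurrence vectors across sites,
#' then UPGMA: species with similar distributions (e.g. confined to the
#' same region) cluster together.
#'
#' @param cm 0/1 site-by-species matrix.
#' @return `upgma`/`hclust` dendrogram over species.
#' @export
cluster_species <- function(cm) {
  cm <- validate_community(cm, allow_empty_sites = TRUE)
  if (ncol(cm) < 2) stop("need at least 2 species")
  upgma(as.matrix(dist(t(cm), method = "euclidean")))
}

#' Cluster membership table at a cut
#'
#' @param dend dendrogram.
#' @param k number of clusters.
#' @return data.frame with `id` and `cluster`.
#' @export
cluster_membership <- function(dend, k = 2) {
  cl <- cutree(dend, k = k)
  data.frame(id = names(cl), cluster = as.integer(cl), row.names = NULL)
}
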