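# Orchestration: the six-response x two-scale variation-partitioning
# table and the one-command pipeline with its artifact bundle.

drop_constant_cols <- function(X) {
  keep <- apply(X, 2, function(v) diff(range(v)) > 1e-12)
  X[, keep, drop = FALSE]
}

#' Variation partitioning across responses and scales
#'
#' For every requested scale (entire archipelago, main islands) and
#' response (taxonomic/functional x total/replacement/richness), selects
#' the spatial weighting matrix and significant MEMs, runs the three-set
#' partitioning, and attaches row-permutation p-values.  Produces the
#' long-format analogue of a factors-by-responses results table.
#'
#' Predictor columns that become constant at a scale (e.g. the Tokara
#' indicator once the NNS region is excluded) are dropped before
#' fitting.  If forward selection retains no MEM, the first (broadest
#' scale) candidate of the best graph is used so the spatial set stays
#' non-empty, and this is flagged in the returned metadata.
#'
#' @param community 0/1 site-by-species matrix.
#' @param sites validated site table aligned with the community rows.
#' @param traits species trait table (rownames = species).
#' @param env,hist environmental and historical predictor matrices
#'   aligned with the sites.
#' @param scales character subset of `c("entire", "main_islands")`.
#' @param responses subset of the six response names
#'   (`"taxonomic_total"`, ..., `"functional_rich"`).
#' @param nperm permutations for the significance test (paper-scale
#'   9999; smaller values for interactive use).
#' @param nperm_select permutations for MEM forward selection.
#' @param seed integer seed.
#' @return object of class `varpart_table`: `table` (long data.frame
#'   with scale, response, fraction, adj_r2, p_value), `details` (per
#'   scale/response: swm method, MEM names, model R2), `meta`.
#' @export
run_table1 <- function(community, sites, traits, env, hist,
                       scales = c("entire", "main_islands"),
                       responses = RESPONSE_NAMES,
                       nperm = 999, nperm_select = 199, seed = 1) {
  responses <- match.arg(responses, RESPONSE_NAMES, several.ok = TRUE)
  ftree <- functional_tree(traits[colnames(community), , drop = FALSE])
  rows <- list(); details <- list()
  for (sc in scales) {
    fs <- filter_scale(community, sites, sc)
    cm <- fs$community; st <- fs$sites
    Xe <- drop_constant_cols(env[st$site_id, , drop = FALSE])
    Xh <- drop_constant_cols(hist[st$site_id, , drop = FALSE])
    for (resp in responses) {
      rf <- response_builder(resp, ftree)
      D <- rf(cm)
      swm <- choose_swm(D, st, nperm = nperm_select, seed = seed)
      Xs <- swm$mems
      fellback <- FALSE
      if (ncol(Xs) == 0) {
        Xs <- swm$basis$vectors[, 1, drop = FALSE]
        fellback <- TRUE
        warning("no MEM selected for ", sc, "/", resp,
                "; using the first candidate eigenvector")
      }
      vp <- varpart_permutation(cm, rf, Xs, Xe, Xh, nperm = nperm,
                                seed = seed)
      key <- paste(sc, resp, sep = ".")
      details[[key]] <- list(swm_method = swm$method,
                             mems = colnames(Xs), fallback = fellback,
                             model_r2 = vp$model_r2)
      nm <- c(names(vp$fractions), names(vp$totals))
      rows[[key]] <- data.frame(scale = sc, response = resp, fraction = nm,
                                adj_r2 = as.numeric(c(vp$fractions, vp$totals)),
                                p_value = as.numeric(vp$p_values[nm]),
                                row.names = NULL)
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details,
                 meta = list(nperm = nperm, nperm_select = nperm_select,
                             seed = seed, scales = scales)),
            class = "varpart_table")
}

RESPONSE_NAMES <- c("taxonomic_total", "taxonomic_repl", "taxonomic_rich",
                    "functional_total", "functional_repl", "functional_rich")

response_builder <- function(resp, ftree) {
  parts <- strsplit(resp, "_")[[1]]
  comp <- parts[2]
  if (parts[1] == "taxonomic") function(cm) beta_taxonomic(cm)[[comp]]
  else function(cm) beta_functional(cm, ftree)[[comp]]
}

#' @export
print.varpart_table <- function(x, ...) {
  cat("Variation partitioning table (", x$meta$nperm, "permutations )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline and write its artifact bundle
#'
#' Executes the whole workflow: input loading (or simulation), the
#' functional tree, beta matrices, regionalization, MEM construction and
#' the two-scale variation-partitioning table, then writes beta CSVs,
#' Newick dendrograms, cluster memberships, a MEM report and the results
#' table plus a JSON manifest into `out_dir`.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   either `simulate` (a scenario name) or `inputs` (named paths
#'   sites/community/traits/env/hist); optional `scales`, `responses`,
#'   `nperm`, `nperm_select`, `seed`, `out_dir`.
#' @return the `varpart_table`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(scales = c("entire", "main_islands"),
                                responses = RESPONSE_NAMES, nperm = 999,
                                nperm_select = 199, seed = 1,
                                out_dir = "archbeta_out"), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  if (!is.null(cfg$simulate)) {
    arch <- simulate_archipelago(scenario_config(cfg$simulate, seed = cfg$seed))
    sites <- arch$sites; community <- arch$community
    traits <- arch$traits; env <- arch$env; hist <- arch$hist
    write_archipelago(arch, file.path(cfg$out_dir, "inputs"))
  } else if (!is.null(cfg$inputs)) {
    sites <- read_sites(cfg$inputs$sites)
    community <- read_community(cfg$inputs$community)
    traits <- read_traits(cfg$inputs$traits)
    env <- read_factors(cfg$inputs$env)
    hist <- read_factors(cfg$inputs$hist)
  } else stop("config needs either 'simulate' or 'inputs'")
  if (any(grepl("^functional", cfg$responses)) && is.null(traits))
    stop("functional responses requested but no trait table available")
  ftree <- functional_tree(traits[colnames(community), , drop = FALSE])
  bt <- beta_taxonomic(community)
  bf <- beta_functional(community, ftree)
  for (k in c("total", "repl", "rich")) {
    write_matrix_csv(bt[[k]], file.path(cfg$out_dir, paste0("beta_tax_", k, ".csv")))
    write_matrix_csv(bf[[k]], file.path(cfg$out_dir, paste0("beta_fun_", k, ".csv")))
  }
  dend <- cluster_sites(bt$repl)
  ape::write.tree(ape::as.phylo(dend), file.path(cfg$out_dir, "sites_upgma.nwk"))
  ape::write.tree(ftree$phylo, file.path(cfg$out_dir, "functional_tree.nwk"))
  write.csv(cluster_membership(dend, 2), file.path(cfg$out_dir, "clusters_k2.csv"),
            row.names = FALSE)
  write.csv(cluster_membership(dend, 3), file.path(cfg$out_dir, "clusters_k3.csv"),
            row.names = FALSE)
  spd <- cluster_species(community)
  ape::write.tree(ape::as.phylo(spd), file.path(cfg$out_dir, "species_upgma.nwk"))
  tab <- run_table1(community, sites, traits, env, hist,
                    scales = cfg$scales, responses = cfg$responses,
                    nperm = cfg$nperm, nperm_select = cfg$nperm_select,
                    seed = cfg$seed)
  write.csv(tab$table, file.path(cfg$out_dir, "varpart_table.csv"),
            row.names = FALSE)
  mem_report <- lapply(tab$details, function(d)
    list(swm_method = d$swm_method, mems = as.list(d$mems),
         fallback = d$fallback))
  jsonlite::write_json(mem_report, file.path(cfg$out_dir, "mem_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("archbeta")),
                   r_version = R.version.string,
                   seed = cfg$seed, nperm = cfg$nperm,
                   scales = cfg$scales, responses = cfg$responses,
                   runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
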