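#' Default end-to-end run configuration
#'
#' A run configuration is a plain nested list (serialisable as YAML)
#' naming the inputs and the stage parameters. Inputs are either on-disk
#' (`input$manifest`, `input$spectra_dir`, `input$fasta`) or synthetic
#' (`input$simulate = TRUE`, in which case the generator writes them into
#' `<out_dir>/inputs` first).
#'
#' @param out_dir output directory for the artifact bundle
#' @param seed integer seed recorded in the run log and driving every
#'   stage's randomness
#' @return nested configuration list
#' @export
default_run_config <- function(out_dir = "msfinger_run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    input = list(simulate = TRUE),
    sim = list(),  # overrides passed to sim_config()
    grid = list(start = 2000, stop = 20000, step = 1),
    preprocess = list(order = "log_then_denoise"),
    denoise = list(window = 100, keep_fraction = 0.2, step = 1,
                   combine_rule = "union"),
    cci = list(n_intervals = 10),
    cluster = list(distance = "cci", k = 4),
    phylo = list(model = "jc69", bootstrap_reps = 100),
    concordance = list(method = "spanning_clade")
  )
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file
#' @return configuration list
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_lists <- function(base, override) {
    for (k in names(override)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
        merge_lists(base[[k]], override[[k]])
      } else {
        override[[k]]
      }
    }
    base
  }
  merge_lists(cfg, user)
}

write_labeled_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), round(m, 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full fingerprint analysis end to end
#'
#' Stages: load (or simulate) and preprocess the spectra; compute the CCI
#' matrix and its bin summary; compute the Bray-Curtis matrix and PCoA
#' coordinates; build the single-linkage dendrogram on the strain-level
#' `1 - CCI` distance; build the NJ tree (with bootstrap supports unless
#' `bootstrap_reps = 0`) from the aligned sequences; compare the two trees
#' (per-species consistency, grouping similarity, Sankey edge table).
#'
#' Artifacts written to `cfg$out_dir`: `cci_matrix.csv`,
#' `cci_summary.csv`, `bray_curtis.csv`, `pcoa_coordinates.csv`,
#' `dendrogram.nwk`, `nj_tree.nwk`, `concordance_report.csv`,
#' `sankey.csv`, plus `run_log.txt` (all parameters, no timestamps, so
#' identical config + seed gives byte-identical output).
#'
#' @param cfg configuration list (see [default_run_config()]) or a YAML
#'   path
#' @return invisibly, a list with the in-memory results (`set`,
#'   `cci`, `cci_strain`, `bray_curtis`, `pcoa`, `dendrogram`, `nj_tree`,
#'   `report`, `sankey`, `paths`)
#' @export
run_end_to_end <- function(cfg = default_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- grid_spec(cfg$grid$start, cfg$grid$stop, cfg$grid$step)
  dp <- denoise_params(cfg$denoise$window, cfg$denoise$keep_fraction,
                       cfg$denoise$step, cfg$denoise$combine_rule)

  if (isTRUE(cfg$input$simulate)) {
    sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    h <- simulate_hierarchy(sim_cfg)
    paths_in <- write_synthetic_inputs(h, file.path(cfg$out_dir, "inputs"))
    cfg$input$manifest <- paths_in$manifest
    cfg$input$spectra_dir <- paths_in$spectra_dir
    cfg$input$fasta <- paths_in$fasta
  }
  set <- load_spectrum_set(cfg$input$manifest, cfg$input$spectra_dir,
                           grid = grid, denoise_params = dp,
                           order = cfg$preprocess$order)
  aln <- read_alignment(cfg$input$fasta)

  cp <- cci_params(n_intervals = cfg$cci$n_intervals)
  cci_m <- cci_matrix(set, cp)
  cci_strain <- aggregate_to_strains(cci_m, set$manifest$strain_id)
  bc <- bray_curtis_matrix(set)
  ord <- pcoa(bc)

  dist_strain <- switch(cfg$cluster$distance,
    cci = 1 - cci_strain,
    bray_curtis = aggregate_to_strains(1 - bc, set$manifest$strain_id),
    stop("unknown cluster distance: ", cfg$cluster$distance))
  if (cfg$cluster$distance == "bray_curtis") {
    dist_strain <- 1 - dist_strain  # aggregation ran on similarity scale
  }
  diag(dist_strain) <- 0
  dend <- linkage_single(dist_strain)

  nj <- if (cfg$phylo$bootstrap_reps > 0) {
    bootstrap_support(aln, model = cfg$phylo$model,
                      n_reps = cfg$phylo$bootstrap_reps, seed = cfg$seed)
  } else {
    neighbor_joining(pairwise_distance(aln, cfg$phylo$model))
  }

  strain_manifest <- unique(set$manifest[, c("strain_id", "species", "genus")])
  dend_phy <- as_phylo_dendrogram(dend)
  nj_rooted <- midpoint_root(nj)
  report <- grouping_similarity(dend_phy, nj_rooted, strain_manifest)

  k <- cfg$cluster$k
  g_dend <- cut_dendrogram(dend, k)
  g_nj <- cut_tree_k(nj_rooted, k)
  sankey <- sankey_table(g_dend, g_nj)

  paths <- list(
    cci_matrix = file.path(cfg$out_dir, "cci_matrix.csv"),
    cci_summary = file.path(cfg$out_dir, "cci_summary.csv"),
    bray_curtis = file.path(cfg$out_dir, "bray_curtis.csv"),
    pcoa = file.path(cfg$out_dir, "pcoa_coordinates.csv"),
    dendrogram = file.path(cfg$out_dir, "dendrogram.nwk"),
    nj_tree = file.path(cfg$out_dir, "nj_tree.nwk"),
    concordance = file.path(cfg$out_dir, "concordance_report.csv"),
    sankey = file.path(cfg$out_dir, "sankey.csv"),
    run_log = file.path(cfg$out_dir, "run_log.txt"))

  write_labeled_matrix(cci_m, paths$cci_matrix)
  write.csv(cci_summary(cci_m), paths$cci_summary, row.names = FALSE,
            quote = FALSE)
  write_labeled_matrix(bc, paths$bray_curtis)
  co <- data.frame(label = ord$labels, round(ord$coordinates, 10),
                   check.names = FALSE)
  write.csv(co, paths$pcoa, row.names = FALSE, quote = FALSE)
  to_newick(dend, paths$dendrogram)
  to_newick(nj, paths$nj_tree)
  rep_df <- report$per_species
  rep_df$grouping_similarity <- report$grouping_similarity
  write.csv(rep_df, paths$concordance, row.names = FALSE, quote = FALSE)
  write.csv(sankey, paths$sankey, row.names = FALSE, quote = FALSE)
  log_lines <- c("msfinger run log",
                 sprintf("seed: %d", cfg$seed),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(
                   cfg[setdiff(names(cfg), c("out_dir", "input"))]),
                   "\n")[[1]]))
  writeLines(log_lines, paths$run_log)

  invisible(list(set = set, cci = cci_m, cci_strain = cci_strain,
                 bray_curtis = bc, pcoa = ord, dendrogram = dend,
                 nj_tree = nj, report = report, sankey = sankey,
                 grouping = list(dendrogram = g_dend, nj = g_nj),
                 paths = paths))
}

#' Cut a rooted phylogeny into k groups by branch length
#'
#' Converts patristic distances to a single-linkage merge tree and cuts
#' it, yielding a flat partition comparable with a dendrogram cut.
#'
#' @param tree rooted `ape::phylo`
#' @param k number of groups
#' @return grouping (named vector strain -> group id)
#' @export
cut_tree_k <- function(tree, k) {
  d <- ape::cophenetic.phylo(tree)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  cut_dendrogram(linkage_single(d), k)
}
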