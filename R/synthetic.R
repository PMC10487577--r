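#' Synthetic study configuration
#'
#' Parameters of the synthetic fingerprint-and-sequence generator. The
#' default preset mirrors a realistic endophyte survey: 4 genera, 22
#' species, 61 strains with 3 technical replicates each, peaks on the
#' 2-20 kDa window with genus-conserved and species-specific peaks, and
#' 16S-like sequences co-evolved on the same species tree.
#'
#' Intra-species variation is intensity-dominated: every strain carries
#' fixed log-normal multipliers of its species' peak intensities, and each
#' replicate adds log-normal measurement scatter, peak dropout and small
#' m/z jitter, plus a sparse low-intensity baseline of noise peaks.
#'
#' @param n_genera number of genera
#' @param species_per_genus species count per genus (scalar or length
#'   `n_genera`)
#' @param strains_per_species strain count per species (scalar or one per
#'   species)
#' @param replicates spectra per strain
#' @param n_genus_peaks genus-conserved peaks per genus
#' @param n_species_peaks species-specific peaks per species
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of
#'   species-level base peak intensities (arbitrary units)
#' @param strain_sdlog log-sd of the per-strain intensity multipliers
#' @param replicate_sdlog log-sd of per-replicate intensity scatter
#' @param dropout probability a species peak is missing from a replicate
#' @param mz_jitter half-width (Da) of uniform per-replicate m/z jitter
#' @param noise_density expected baseline noise peaks per Da of grid
#' @param noise_meanlog,noise_sdlog log-normal parameters of noise
#'   intensities
#' @param seq_length length of the simulated 16S-like alignment (sites)
#' @param branch_scale scale (substitutions/site) of within-genus species
#'   branches
#' @param genus_depth multiplier applied to `branch_scale` for the
#'   between-genus backbone branches
#' @param strain_branch pendant branch length of each strain below its
#'   species node
#' @param mz_min,mz_max detection window (Da)
#' @param seed integer seed; all generator randomness derives from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_genera = 4,
                       species_per_genus = c(7, 5, 5, 5),
                       strains_per_species = NULL,
                       replicates = 3,
                       n_genus_peaks = 8,
                       n_species_peaks = 12,
                       intensity_meanlog = log(800),
                       intensity_sdlog = 0.7,
                       strain_sdlog = 0.4,
                       replicate_sdlog = 0.25,
                       dropout = 0.05,
                       mz_jitter = 0.3,
                       noise_density = 0.005,
                       noise_meanlog = log(30),
                       noise_sdlog = 0.7,
                       seq_length = 1200,
                       branch_scale = 0.02,
                       genus_depth = 5,
                       strain_branch = 0.002,
                       mz_min = 2000, mz_max = 20000,
                       seed = 1) {
  if (length(species_per_genus) == 1) {
    species_per_genus <- rep(species_per_genus, n_genera)
  }
  if (length(species_per_genus) != n_genera) {
    stop("species_per_genus must have length 1 or n_genera")
  }
  n_species <- sum(species_per_genus)
  if (is.null(strains_per_species)) {
    # default preset: 61 strains over 22 species
    strains_per_species <- if (n_species == 22) {
      c(rep(3, 17), rep(2, 5))
    } else {
      rep(3, n_species)
    }
  }
  if (length(strains_per_species) == 1) {
    strains_per_species <- rep(strains_per_species, n_species)
  }
  if (length(strains_per_species) != n_species) {
    stop("strains_per_species must have length 1 or the number of species")
  }
  stopifnot(n_genera >= 1, all(species_per_genus >= 1),
            all(strains_per_species >= 1), replicates >= 1,
            n_genus_peaks >= 1, n_species_peaks >= 0,
            dropout >= 0, dropout <= 1, mz_jitter >= 0,
            noise_density >= 0, seq_length >= 1,
            branch_scale >= 0, strain_branch >= 0, mz_min < mz_max)
  structure(as.list(environment()), class = "sim_config")
}

# random binary topology over labels as a nested structure;
# bl() draws one branch length
rand_topology <- function(labels, bl) {
  if (length(labels) == 1) return(list(leaf = labels))
  labels <- sample(labels)
  k <- if (length(labels) == 2) 1 else sample.int(length(labels) - 1, 1)
  list(children = list(rand_topology(labels[seq_len(k)], bl),
                       rand_topology(labels[-seq_len(k)], bl)),
       lengths = c(bl(), bl()))
}

topology_newick <- function(node, tip_fun) {
  if (!is.null(node$leaf)) return(tip_fun(node$leaf))
  sprintf("(%s:%.10f,%s:%.10f)",
          topology_newick(node$children[[1]], tip_fun), node$lengths[1],
          topology_newick(node$children[[2]], tip_fun), node$lengths[2])
}

#' Simulate a genus/species/strain truth hierarchy
#'
#' Draws disjoint genus-level peak sets, augments each species with fresh
#' species-specific peaks, assigns per-strain intensity multipliers, and
#' generates a random rooted species tree in which genera are monophyletic
#' (within-genus branches at `branch_scale`, between-genus backbone
#' branches `genus_depth` times longer). Fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return object of class `truth_hierarchy`: taxon tables, per-species
#'   peak tables, per-strain multipliers, the rooted species tree and the
#'   strain-level tree (strains as short pendant branches below their
#'   species), and `cfg`
#' @export
simulate_hierarchy <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genera <- sprintf("G%d", seq_len(cfg$n_genera))
  species <- unlist(lapply(seq_len(cfg$n_genera), function(g) {
    sprintf("%sS%02d", genera[g], seq_len(cfg$species_per_genus[g]))
  }))
  genus_of_species <- rep(genera, cfg$species_per_genus)
  strain_counts <- cfg$strains_per_species
  strains <- unlist(lapply(seq_along(species), function(s) {
    sprintf("%sT%d", species[s], seq_len(strain_counts[s]))
  }))
  species_of_strain <- rep(species, strain_counts)
  genus_of_strain <- rep(genus_of_species, strain_counts)

  n_species <- length(species)
  total_peaks <- cfg$n_genera * cfg$n_genus_peaks +
    n_species * cfg$n_species_peaks
  grid_positions <- seq(cfg$mz_min + 50, cfg$mz_max - 50)
  if (total_peaks > length(grid_positions)) {
    stop("requested peaks exceed grid capacity")
  }
  pos <- sample(grid_positions, total_peaks)
  genus_peaks <- split(pos[seq_len(cfg$n_genera * cfg$n_genus_peaks)],
                       rep(genera, each = cfg$n_genus_peaks))
  rest <- pos[-seq_len(cfg$n_genera * cfg$n_genus_peaks)]
  species_own <- if (cfg$n_species_peaks > 0) {
    split(rest, rep(species, each = cfg$n_species_peaks))
  } else {
    stats::setNames(rep(list(numeric(0)), n_species), species)
  }
  peaks <- stats::setNames(vector("list", n_species), species)
  for (s in seq_len(n_species)) {
    sp <- species[s]
    mz <- sort(c(genus_peaks[[genus_of_species[s]]], species_own[[sp]]))
    peaks[[sp]] <- data.frame(
      mz = as.numeric(mz),
      base_intensity = rlnorm(length(mz), cfg$intensity_meanlog,
                              cfg$intensity_sdlog))
  }
  strain_mult <- stats::setNames(vector("list", length(strains)), strains)
  for (t in seq_along(strains)) {
    strain_mult[[t]] <- rlnorm(nrow(peaks[[species_of_strain[t]]]),
                               0, cfg$strain_sdlog)
  }

  # species tree: random topology per genus, random backbone over genera,
  # genera monophyletic by construction
  species_bl <- function() cfg$branch_scale * runif(1, 0.5, 1.5)
  genus_bl <- function() cfg$branch_scale * cfg$genus_depth * runif(1, 0.5, 1.5)
  genus_nodes <- lapply(genera, function(g) {
    rand_topology(species[genus_of_species == g], species_bl)
  })
  names(genus_nodes) <- genera
  backbone <- rand_topology(genera, genus_bl)
  graft <- function(node) {
    if (!is.null(node$leaf)) return(genus_nodes[[node$leaf]])
    node$children <- lapply(node$children, graft)
    node
  }
  full <- graft(backbone)
  strains_of <- split(strains, factor(species_of_strain, levels = species))
  strain_tip <- function(sp) {
    st <- strains_of[[sp]]
    if (length(st) == 1) return(st)
    sprintf("(%s)", paste(sprintf("%s:%.10f", st, cfg$strain_branch),
                          collapse = ","))
  }
  root_nwk <- function(node, tip_fun) {
    if (!is.null(node$leaf)) {
      # degenerate single-genus / single-species cases
      return(sprintf("(%s:0);", tip_fun(node$leaf)))
    }
    sprintf("(%s:%.10f,%s:%.10f);",
            topology_newick(node$children[[1]], tip_fun), node$lengths[1],
            topology_newick(node$children[[2]], tip_fun), node$lengths[2])
  }
  species_tree <- ape::read.tree(text = root_nwk(full, identity))
  strain_tree <- ape::read.tree(text = root_nwk(full, strain_tip))

  structure(list(
    genera = genera,
    species_df = data.frame(species = species, genus = genus_of_species,
                            stringsAsFactors = FALSE),
    strain_df = data.frame(strain_id = strains,
                           species = species_of_strain,
                           genus = genus_of_strain,
                           stringsAsFactors = FALSE),
    peaks = peaks,
    strain_mult = strain_mult,
    species_tree = species_tree,
    strain_tree = strain_tree,
    cfg = cfg), class = "truth_hierarchy")
}

#' @export
print.truth_hierarchy <- function(x, ...) {
  cat(sprintf("truth_hierarchy: %d genera, %d species, %d strains (seed %d)\n",
              length(x$genera), nrow(x$species_df), nrow(x$strain_df),
              x$cfg$seed))
  invisible(x)
}

#' Simulate raw spectra from a truth hierarchy
#'
#' Each replicate of a strain realises the strain's species peak set:
#' every peak is present with probability `1 - dropout`, its m/z jittered
#' uniformly by up to `mz_jitter` Da, its intensity log-normal around the
#' species base intensity times the strain multiplier. Sparse baseline
#' noise peaks are added at `noise_density` per Da. Randomness derives
#' from `cfg$seed` (spectra substream).
#'
#' @param h a [simulate_hierarchy()] result
#' @param cfg a [sim_config()]; defaults to the hierarchy's own
#' @return list with `spectra` (list of [raw_spectrum()]) and `manifest`
#'   (data frame `strain_id, species, genus, replicate_id`)
#' @export
simulate_spectra <- function(h, cfg = h$cfg) {
  set.seed(cfg$seed + 1L)
  sd_ <- h$strain_df
  n_spec <- nrow(sd_) * cfg$replicates
  spectra <- vector("list", n_spec)
  manifest <- data.frame(strain_id = character(n_spec),
                         species = character(n_spec),
                         genus = character(n_spec),
                         replicate_id = character(n_spec),
                         stringsAsFactors = FALSE)
  k <- 0
  extent <- cfg$mz_max - cfg$mz_min
  for (t in seq_len(nrow(sd_))) {
    pk <- h$peaks[[sd_$species[t]]]
    mult <- h$strain_mult[[sd_$strain_id[t]]]
    for (r in seq_len(cfg$replicates)) {
      k <- k + 1
      present <- runif(nrow(pk)) >= cfg$dropout
      mz <- pk$mz[present] +
        runif(sum(present), -cfg$mz_jitter, cfg$mz_jitter)
      it <- rlnorm(sum(present),
                   log(pk$base_intensity[present] * mult[present]),
                   cfg$replicate_sdlog)
      n_noise <- rpois(1, cfg$noise_density * extent)
      if (n_noise > 0) {
        mz <- c(mz, runif(n_noise, cfg$mz_min, cfg$mz_max))
        it <- c(it, rlnorm(n_noise, cfg$noise_meanlog, cfg$noise_sdlog))
      }
      mz <- pmin(pmax(mz, cfg$mz_min), cfg$mz_max)
      rep_id <- sprintf("r%d", r)
      spectra[[k]] <- suppressWarnings(
        raw_spectrum(mz, it, strain_id = sd_$strain_id[t],
                     replicate_id = rep_id,
                     mz_min = cfg$mz_min, mz_max = cfg$mz_max))
      manifest$strain_id[k] <- sd_$strain_id[t]
      manifest$species[k] <- sd_$species[t]
      manifest$genus[k] <- sd_$genus[t]
      manifest$replicate_id[k] <- rep_id
    }
  }
  list(spectra = spectra, manifest = manifest)
}

#' Preprocess a list of raw spectra into a spectrum set
#'
#' @param raw list with `spectra` and `manifest` as returned by
#'   [simulate_spectra()]
#' @param grid a [grid_spec()]
#' @param denoise_params a [denoise_params()]
#' @param order preprocessing order, see [preprocess_pipeline()]
#' @return a [spectrum_set()]
#' @export
preprocess_set <- function(raw, grid = grid_spec(),
                           denoise_params = msfinger::denoise_params(),
                           order = "log_then_denoise") {
  spectra <- lapply(raw$spectra, preprocess_pipeline, grid = grid,
                    p = denoise_params, order = order)
  spectrum_set(spectra, raw$manifest, grid)
}

#' Simulate a co-evolved 16S-like alignment
#'
#' Evolves sequences along the hierarchy's strain-level tree under the
#' Jukes-Cantor model (equal base frequencies and exchange rates, branch
#' lengths in expected substitutions/site), so the alignment's true
#' phylogeny is known exactly. No indels are introduced; the output is
#' aligned by construction. Randomness derives from `cfg$seed` (sequence
#' substream).
#'
#' @param h a [simulate_hierarchy()] result
#' @param cfg a [sim_config()]; defaults to the hierarchy's own
#' @return list with `alignment` (matrix, see [as_alignment()]),
#'   `tree` (true strain-level tree) and `species_tree`
#' @export
simulate_sequences <- function(h, cfg = h$cfg) {
  set.seed(cfg$seed + 2L)
  sim <- phangorn::simSeq(h$strain_tree, l = cfg$seq_length, type = "DNA")
  m <- toupper(as.character(sim))
  aln <- as_alignment(m[h$strain_df$strain_id, , drop = FALSE])
  list(alignment = aln, tree = h$strain_tree, species_tree = h$species_tree)
}

#' Write a synthetic data set to disk
#'
#' Materialises a hierarchy as the pipeline's on-disk input formats: one
#' peak table per spectrum, a `manifest.csv`, an aligned FASTA, the true
#' species and strain trees as Newick, and a `truth.json` with the taxon
#' tables.
#'
#' @param h a [simulate_hierarchy()] result
#' @param dir output directory (created if needed)
#' @param cfg a [sim_config()]; defaults to the hierarchy's own
#' @return invisibly, a list of the written paths
#' @export
write_synthetic_inputs <- function(h, dir, cfg = h$cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- simulate_spectra(h, cfg)
  seqs <- simulate_sequences(h, cfg)
  files <- sprintf("%s_%s.tsv", raw$manifest$strain_id,
                   raw$manifest$replicate_id)
  for (i in seq_along(raw$spectra)) {
    write_peak_table(raw$spectra[[i]], file.path(dir, files[i]))
  }
  manifest <- cbind(raw$manifest[, c("strain_id", "species", "genus")],
                    file = files)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  fasta_path <- file.path(dir, "sequences.fasta")
  write_alignment(seqs$alignment, fasta_path)
  species_tree_path <- file.path(dir, "true_species_tree.nwk")
  to_newick(h$species_tree, species_tree_path)
  strain_tree_path <- file.path(dir, "true_strain_tree.nwk")
  to_newick(h$strain_tree, strain_tree_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(strains = h$strain_df, species = h$species_df),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest_path, spectra_dir = dir,
                 fasta = fasta_path, species_tree = species_tree_path,
                 strain_tree = strain_tree_path, truth = truth_path))
}
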