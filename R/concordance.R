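#' Species co-group sets from a rooted tree
#'
#' For each species, the spanning clade is the smallest clade containing
#' all of its strains; the species' co-group set is the set of species
#' with at least one strain inside that clade. A species whose spanning
#' clade contains only itself is cleanly monophyletic and separated;
#' species that interleave appear in each other's co-group sets.
#'
#' @param tree rooted `ape::phylo` whose tips are strain ids
#' @param manifest data frame with columns `strain_id`, `species` (one row
#'   per strain; replicate rows are collapsed)
#' @return named list: species -> sorted character vector of co-grouped
#'   species
#' @export
species_cogroup_sets <- function(tree, manifest) {
  strains <- unique(manifest[, c("strain_id", "species")])
  extra_tips <- setdiff(tree$tip.label, strains$strain_id)
  extra_strains <- setdiff(strains$strain_id, tree$tip.label)
  if (length(extra_tips) || length(extra_strains)) {
    stop("tree/manifest mismatch; only in tree: ",
         paste(extra_tips, collapse = ", "), "; only in manifest: ",
         paste(extra_strains, collapse = ", "))
  }
  species_of <- stats::setNames(strains$species, strains$strain_id)
  species <- sort(unique(strains$species))
  out <- vector("list", length(species))
  names(out) <- species
  for (sp in species) {
    tips <- strains$strain_id[strains$species == sp]
    if (length(tips) == 1) {
      clade_tips <- tips
    } else {
      node <- ape::getMRCA(tree, tips)
      desc <- phangorn::Descendants(tree, node, type = "tips")[[1]]
      clade_tips <- tree$tip.label[desc]
    }
    out[[sp]] <- sort(unique(unname(species_of[clade_tips])))
  }
  out
}

#' Grouping concordance between two rooted trees
#'
#' A species is consistently grouped when its co-group set (see
#' [species_cogroup_sets()]) is identical in both trees; the grouping
#' similarity is the fraction of consistent species. Symmetric in its two
#' tree arguments.
#'
#' @param tree_a,tree_b rooted `ape::phylo` objects over the same strain
#'   tips (e.g. the mass-profile dendrogram and the midpoint-rooted 16S
#'   tree)
#' @param manifest data frame with `strain_id`, `species`
#' @return object of class `concordance_report`: list with `per_species`
#'   (data frame `species, consistent, cogroup_a, cogroup_b`),
#'   `grouping_similarity`, `n_consistent`, `n_species`
#' @export
grouping_similarity <- function(tree_a, tree_b, manifest) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets")
  }
  cg_a <- species_cogroup_sets(tree_a, manifest)
  cg_b <- species_cogroup_sets(tree_b, manifest)
  species <- names(cg_a)
  consistent <- vapply(species, function(sp) {
    setequal(cg_a[[sp]], cg_b[[sp]])
  }, logical(1))
  per_species <- data.frame(
    species = species,
    consistent = unname(consistent),
    cogroup_a = vapply(cg_a, paste, "", collapse = "|"),
    cogroup_b = vapply(cg_b, paste, "", collapse = "|"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_species = per_species,
                 grouping_similarity = mean(consistent),
                 n_consistent = sum(consistent),
                 n_species = length(species)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d/%d species consistent, grouping similarity %.1f%%\n",
              x$n_consistent, x$n_species, 100 * x$grouping_similarity))
  mixed <- x$per_species$species[!x$per_species$consistent]
  if (length(mixed)) cat("inconsistent:", paste(mixed, collapse = ", "), "\n")
  invisible(x)
}

#' Cut-based grouping similarity
#'
#' Alternative concordance criterion: both trees are reduced to flat
#' partitions and a species is consistent when the set of species it
#' shares a group with is identical under both partitions.
#'
#' @param g_a,g_b groupings (named vectors strain -> group id) over the
#'   same strains
#' @param manifest data frame with `strain_id`, `species`
#' @return a `concordance_report` (without spanning-clade co-groups)
#' @export
grouping_similarity_cut <- function(g_a, g_b, manifest) {
  if (!setequal(names(g_a), names(g_b))) stop("groupings differ in strains")
  strains <- unique(manifest[, c("strain_id", "species")])
  species_of <- stats::setNames(strains$species, strains$strain_id)
  cogroups <- function(g) {
    lapply(split(names(g), unname(g)), function(members) {
      sort(unique(unname(species_of[members])))
    })
  }
  co_a <- cogroups(g_a)
  co_b <- cogroups(g_b)
  species <- sort(unique(strains$species))
  set_for <- function(co, sp) {
    sort(unique(unlist(co[vapply(co, function(s) sp %in% s, logical(1))])))
  }
  consistent <- vapply(species, function(sp) {
    setequal(set_for(co_a, sp), set_for(co_b, sp))
  }, logical(1))
  structure(list(
    per_species = data.frame(species = species,
                             consistent = unname(consistent),
                             row.names = NULL, stringsAsFactors = FALSE),
    grouping_similarity = mean(consistent),
    n_consistent = sum(consistent),
    n_species = length(species)), class = "concordance_report")
}

#' Sankey edge table of two groupings
#'
#' The contingency table of two partitions of the same strains, as edge
#' rows suitable for Sankey plotting. Row and column sums reconstruct the
#' group sizes of each partition.
#'
#' @param g_a,g_b groupings (named vectors strain -> group id)
#' @return data frame `source, target, count`, sorted by source then
#'   target
#' @export
sankey_table <- function(g_a, g_b) {
  if (!setequal(names(g_a), names(g_b))) stop("groupings differ in strains")
  g_b <- g_b[names(g_a)]
  tab <- table(source = unname(g_a), target = unname(g_b))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "count"
  df <- df[df$count > 0, ]
  df <- df[order(df$source, df$target), ]
  rownames(df) <- NULL
  df
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the trees' non-trivial
#' bipartitions; 0 for topologically identical trees, at most `2(n - 3)`
#' for fully resolved trees on `n` shared leaves.
#'
#' @param t1,t2 `ape::phylo` objects on the same leaf set
#' @return integer RF distance
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees differ in leaves")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
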