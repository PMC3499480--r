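# Full study replica: per-trait signal table (chemistry and bioactivity
# sections), species- and genus-level Mantel analyses, and the congener
# chemical-difference summary, with provenance for every random choice.

#' Per-trait phylogenetic-signal analysis (signal table)
#'
#' Reconciles tree and trait matrix, excludes uninformative traits (logged,
#' never silent), prunes species missing a trait's value from that trait's
#' tree only, resolves any polytomies with seeded zero-length branches, and
#' computes a Fritz-Purvis D row per kept trait. Rows are split into a
#' chemical-components section and a biological-activity section.
#'
#' @param tree A `"phylo"` tree (need not be bifurcating).
#' @param traits A [trait_matrix()].
#' @param n_permutations,n_simulations Null draws per trait (1000/1000).
#' @param seed Master seed; per-trait substreams are derived from it.
#' @param correct See [compute_d()].
#' @return Object of class `"signal_report"`: `table` (one data-frame row
#'   per kept trait: trait, kind, n, k, s_obs, mean_sr, mean_sb, D,
#'   p_random, p_brownian), `excluded`, `dropped`, `results` (the full
#'   `"phylo_d"` objects), `provenance`.
#' @export
run_signal_analysis <- function(tree, traits, n_permutations = 1000,
                                n_simulations = 1000, seed = 1,
                                correct = FALSE) {
  rec <- reconcile(traits, tree)
  info <- informative_traits(rec$matrix)
  if (length(info$kept) == 0) {
    stop_chemophylo("no informative traits: every trait lacks variation ",
                    "(>= 2 species in each state required)")
  }
  polytomies <- !ape::is.binary(rec$tree)
  results <- lapply(info$kept, function(tr) {
    sp <- rec$trait_species[[tr]]
    tree_tr <- if (length(sp) < ape::Ntip(rec$tree)) {
      prune_to_tips(rec$tree, sp)
    } else {
      rec$tree
    }
    tree_tr <- resolve_polytomies(tree_tr, seed = derive_seed(seed, "polytomy"))
    phylo_d(tree_tr, rec$matrix, tr, n_permutations, n_simulations,
            seed = seed, correct = correct)
  })
  names(results) <- info$kept
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(trait = r$trait, kind = unname(rec$matrix$kind[r$trait]),
               n = r$n, k = r$k, s_obs = r$s_obs, mean_sr = r$mean_sr,
               mean_sb = r$mean_sb, D = r$D, p_random = r$p_random,
               p_brownian = r$p_brownian, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    excluded = info$excluded,
    dropped = rec$dropped,
    results = results,
    provenance = list(seed = seed, n_permutations = n_permutations,
                      n_simulations = n_simulations,
                      polytomies_resolved = polytomies,
                      p_value_tail = "one-tailed",
                      config_hash = config_hash(list(seed, n_permutations,
                                                     n_simulations, correct)))
  ), class = "signal_report")
}

#' @export
print.signal_report <- function(x, ...) {
  fmt <- function(rows, header) {
    cat(header, "\n")
    cat(sprintf("%-16s %8s %10s %10s\n", "", "D", "P(D=1)", "P(D=0)"))
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("%-16s %8.4f %10.4g %10.4g\n", rows$trait[i], rows$D[i],
                  rows$p_random[i], rows$p_brownian[i]))
    }
  }
  cat("Phylogenetic signal in chemistry and biological activity\n\n")
  chem <- x$table[x$table$kind == "alkaloid", ]
  bio <- x$table[x$table$kind == "bioassay", ]
  if (nrow(chem) > 0) fmt(chem, "a) Chemical components")
  if (nrow(bio) > 0) fmt(bio, "\nb) Biological activity")
  if (nrow(x$excluded) > 0) {
    cat("\nExcluded traits:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat("  ", x$excluded$trait[i], ": ", x$excluded$reason[i], "\n", sep = "")
    }
  }
  cat("\nP-values are one-tailed fractions of", x$provenance$n_permutations,
      "permutation /", x$provenance$n_simulations, "Brownian null draws.\n")
  invisible(x)
}

#' Species- or genus-level Mantel analysis
#'
#' Species level: patristic distances vs binary squared Euclidean
#' chemical-profile distances over the reconciled species (species with
#' incomplete alkaloid profiles are dropped with a warning). Genus level:
#' the tree is reduced to genus clades (both clades of a polyphyletic
#' genus retained), profiles are aggregated by union, and exemplar-based
#' patristic distances are compared to the aggregated profiles.
#'
#' @param tree A `"phylo"` tree.
#' @param traits A [trait_matrix()].
#' @param level `"species"` or `"genus"`.
#' @param n_permutations Mantel permutations (999).
#' @param seed Integer seed.
#' @param genus_map Optional named species -> genus map; defaults to the
#'   matrix's genus column, then to parsing `Genus_species` tip labels.
#' @return A `"mantel_result"`.
#' @export
run_mantel_analysis <- function(tree, traits, level = c("species", "genus"),
                                n_permutations = 999, seed = 1,
                                genus_map = NULL) {
  level <- match.arg(level)
  rec <- reconcile(traits, tree)
  prof <- chemical_profiles(rec$matrix)
  if (nrow(prof) < 4) stop_chemophylo("fewer than 4 species with profiles")
  tree_p <- prune_to_tips(rec$tree, rownames(prof))
  prof <- prof[tree_p$tip.label, , drop = FALSE]
  if (level == "species") {
    A <- patristic_matrix(tree_p)
    B <- binary_squared_euclidean_matrix(prof)
    return(mantel_test(A, B, n_permutations, seed = seed))
  }
  genus_map <- genus_map %||% rec$matrix$genus %||%
    genus_map_from_labels(tree_p$tip.label)
  clades <- genus_clades(tree_p, genus_map)
  if (length(clades) < 4) stop_chemophylo("fewer than 4 genus clades")
  dm <- genus_distance_matrices(tree_p, clades, prof)
  mantel_test(dm$phylo, dm$chem, n_permutations, seed = seed)
}

#' Chemical difference between congeners
#'
#' Mean (with standard error) binary squared Euclidean distance over all
#' unordered pairs of species in the same (taxonomic) genus — the
#' "alkaloid types differing between congeners" summary.
#'
#' @param traits A [trait_matrix()] (alkaloid columns are used).
#' @param genus_map Optional species -> genus map (defaults as in
#'   [run_mantel_analysis()]).
#' @return List: `mean`, `se`, `n_pairs`, `n_genera_with_pairs`.
#' @export
congener_difference_summary <- function(traits, genus_map = NULL) {
  prof <- chemical_profiles(traits)
  genus_map <- genus_map %||% traits$genus %||%
    genus_map_from_labels(rownames(prof))
  genus <- genus_map[rownames(prof)]
  d <- binary_squared_euclidean_matrix(prof)
  vals <- numeric(0)
  genera_used <- character(0)
  for (g in unique(genus)) {
    sp <- rownames(prof)[genus == g]
    if (length(sp) < 2) next
    pairs <- utils::combn(sp, 2)
    vals <- c(vals, d[cbind(pairs[1, ], pairs[2, ])])
    genera_used <- c(genera_used, g)
  }
  if (length(vals) == 0) stop_chemophylo("no congeneric species pairs")
  list(mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_pairs = length(vals),
       n_genera_with_pairs = length(genera_used))
}

#' Run the full study replica
#'
#' Simulates (or accepts) a study, then produces the signal table, the
#' species- and genus-level Mantel tests, and the congener summary, with a
#' provenance block tying every number to the master seed.
#'
#' @param config A [study_config()] (used when `tree`/`traits` are not
#'   supplied).
#' @param tree,traits Optional real data inputs.
#' @param n_permutations,n_simulations D-statistic null draws (1000/1000).
#' @param n_mantel_permutations Mantel permutations (999).
#' @param seed Master seed (defaults to `config$seed`).
#' @return Object of class `"study_report"`.
#' @export
run_study <- function(config = study_config(), tree = NULL, traits = NULL,
                      n_permutations = 1000, n_simulations = 1000,
                      n_mantel_permutations = 999, seed = NULL) {
  seed <- seed %||% config$seed
  synthetic <- is.null(traits)
  if (synthetic) {
    config$seed <- seed
    study <- simulate_profiles(tree, config)
    tree <- study$tree
    traits <- study$traits
  }
  signal <- run_signal_analysis(tree, traits, n_permutations, n_simulations,
                                seed = seed)
  mantel_sp <- run_mantel_analysis(tree, traits, "species",
                                   n_mantel_permutations,
                                   seed = derive_seed(seed, "mantel_species"))
  mantel_gen <- run_mantel_analysis(tree, traits, "genus",
                                    n_mantel_permutations,
                                    seed = derive_seed(seed, "mantel_genus"))
  congener <- congener_difference_summary(traits)
  structure(list(
    signal = signal,
    mantel_species = mantel_sp,
    mantel_genus = mantel_gen,
    congener = congener,
    provenance = list(
      seed = seed,
      synthetic = synthetic,
      config = if (synthetic) unclass(config) else NULL,
      config_hash = config_hash(list(config, n_permutations, n_simulations,
                                     n_mantel_permutations, seed)),
      package_version = as.character(utils::packageVersion("chemophylo"))
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  print(x$signal)
  cat("\nSpecies-level ")
  print(x$mantel_species)
  cat("Genus-level   ")
  print(x$mantel_genus)
  cat(sprintf("\nMean chemical difference between congeners: %.2f (s.e. %.2f, %d pairs)\n",
              x$congener$mean, x$congener$se, x$congener$n_pairs))
  invisible(x)
}

#' Write a study report to disk
#'
#' `signal_table.tsv` (machine-readable), `report.md` (human-readable
#' mirror of the signal table plus Mantel and congener results) and
#' `provenance.json`.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$signal$table, file.path(dir, "signal_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  md <- c("# Phylogenetic signal in chemistry and biological activity", "",
          "| Trait | Kind | n | k | D | P(D=1) | P(D=0) |",
          "|---|---|---|---|---|---|---|",
          sprintf("| %s | %s | %d | %d | %.4f | %.4g | %.4g |",
                  report$signal$table$trait, report$signal$table$kind,
                  report$signal$table$n, report$signal$table$k,
                  report$signal$table$D, report$signal$table$p_random,
                  report$signal$table$p_brownian),
          "",
          sprintf("Species-level Mantel: r = %.3f, p = %.4g (%d permutations)",
                  report$mantel_species$r, report$mantel_species$p,
                  report$mantel_species$n_permutations),
          sprintf("Genus-level Mantel: r = %.3f, p = %.4g (%d permutations)",
                  report$mantel_genus$r, report$mantel_genus$p,
                  report$mantel_genus$n_permutations),
          sprintf("Congener chemical difference: mean %.2f, s.e. %.2f (%d pairs)",
                  report$congener$mean, report$congener$se,
                  report$congener$n_pairs),
          "",
          "P-values are one-tailed.")
  if (nrow(report$signal$excluded) > 0) {
    md <- c(md, "", "Excluded traits:",
            sprintf("- %s: %s", report$signal$excluded$trait,
                    report$signal$excluded$reason))
  }
  writeLines(md, file.path(dir, "report.md"))
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(dir)
}
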