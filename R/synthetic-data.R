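# Synthetic studies with the statistical structure the analysis assumes:
# an ultrametric pure-birth tree with genus structure, binary alkaloid
# traits with tunable phylogenetic signal, singleton traits, and two
# bioassay traits tied to the chemistry.

#' Configuration of a synthetic study
#'
#' Defaults emulate the structure of the real study: 108 species in 43
#' genera (some polyphyletic), 9 recorded alkaloid types of which 2 are
#' singletons (found in one species each), two bioassay traits (AChE,
#' SERT), and 8 species without SERT determinations. Informative-trait
#' prevalences step from 0.40 down to 0.10, reflecting that a few types
#' (e.g. lycorine-like) are widespread while others are rare. The signal
#' level `w` is the probability that a trait evolves by the
#' Brownian-threshold model rather than at random; the default 0.5 targets
#' the moderate signal regime (D between 0 and 1) seen in real profiles.
#'
#' @param n_species Number of tips (108).
#' @param n_alkaloid_types Number of alkaloid trait columns (9).
#' @param n_singletons How many of those have exactly one carrier (2).
#' @param prevalence Per-informative-trait prevalence targets, recycled.
#' @param signal_level Mixture weight `w` in \[0, 1\] per informative
#'   trait, recycled: probability of the Brownian-threshold model.
#' @param n_bioassays Number of bioassay traits (2: AChE, SERT).
#' @param bioassay_prevalence Prevalence of the bioassay traits (0.3).
#' @param bioassay_overlap_floor Minimum Jaccard overlap between each
#'   bioassay trait and its anchor alkaloid trait (0.2), mimicking
#'   chemistry-driven activity.
#' @param n_missing_sert Species without a value for the last bioassay
#'   trait (8), pruned only from that trait's analyses.
#' @param birth_rate Yule speciation rate (1.0; the tree is rescaled to
#'   unit depth so only the shape matters).
#' @param n_genera Number of genus labels painted on the tree (43 at 108
#'   species, scaled proportionally otherwise).
#' @param polyphyly_fraction Fraction of genera made polyphyletic by
#'   grafting in a tip from elsewhere (0.1).
#' @param seed Master seed.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_species = 108,
                         n_alkaloid_types = 9,
                         n_singletons = 2,
                         prevalence = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10),
                         signal_level = 0.5,
                         n_bioassays = 2,
                         bioassay_prevalence = 0.3,
                         bioassay_overlap_floor = 0.2,
                         n_missing_sert = 8,
                         birth_rate = 1,
                         n_genera = NULL,
                         polyphyly_fraction = 0.1,
                         seed = 1) {
  if (n_singletons >= n_alkaloid_types) {
    stop_chemophylo("n_singletons must be < n_alkaloid_types")
  }
  if (any(signal_level < 0 | signal_level > 1)) {
    stop_chemophylo("signal_level must be in [0, 1]")
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_chemophylo("prevalences must be in (0, 1)")
  }
  cfg <- list(
    n_species = n_species, n_alkaloid_types = n_alkaloid_types,
    n_singletons = n_singletons, prevalence = prevalence,
    signal_level = signal_level, n_bioassays = n_bioassays,
    bioassay_prevalence = bioassay_prevalence,
    bioassay_overlap_floor = bioassay_overlap_floor,
    n_missing_sert = n_missing_sert, birth_rate = birth_rate,
    n_genera = n_genera %||% max(2L, round(n_species * 43 / 108)),
    polyphyly_fraction = polyphyly_fraction, seed = seed
  )
  class(cfg) <- "study_config"
  cfg
}

#' Simulate an ultrametric pure-birth (Yule) tree with genus structure
#'
#' Tips are labelled `Genus{g}_sp{s}`. Genera are painted on the tree as
#' actual clades (the tree is recursively split at its deepest nodes until
#' `n_genera` blocks exist); a fraction of genera is then made
#' polyphyletic by relabelling one tip from another genus, so the
#' genus-clade machinery is exercised. The tree is rescaled to unit depth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed; the same seed gives an identical Newick
#'   string.
#' @param n_genera Number of genera (default about 40% of tips).
#' @param polyphyly_fraction Fraction of genera to make polyphyletic.
#' @return An ultrametric bifurcating `"phylo"` tree.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               n_genera = max(2L, round(n_tips * 43 / 108)),
                               polyphyly_fraction = 0.1) {
  if (n_tips < 2) stop_chemophylo("n_tips must be >= 2")
  if (birth_rate <= 0) stop_chemophylo("birth_rate must be > 0")
  n_genera <- min(n_genera, n_tips)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- genus_species_labels(tree, n_genera, polyphyly_fraction)
    tree
  })
}

# Assign Genus{g}_sp{s} labels: split the tree into n_genera clades by
# repeatedly dividing the clade with the most tips, then relabel one
# foreign tip into each genus selected for polyphyly.
genus_species_labels <- function(tree, n_genera, polyphyly_fraction) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  clade_tips <- function(v) {
    if (v <= nt) return(v)
    unlist(lapply(kids[[as.character(v)]], clade_tips))
  }
  blocks <- list(root)
  while (length(blocks) < n_genera) {
    sizes <- vapply(blocks, function(v) length(clade_tips(v)), numeric(1))
    i <- which.max(sizes)
    v <- blocks[[i]]
    if (v <= nt) break  # cannot split a tip further
    blocks <- append(blocks[-i], as.list(kids[[as.character(v)]]))
  }
  genus_of_tip <- integer(nt)
  for (g in seq_along(blocks)) genus_of_tip[clade_tips(blocks[[g]])] <- g

  n_poly <- round(polyphyly_fraction * length(blocks))
  if (n_poly > 0) {
    targets <- sample(seq_along(blocks), n_poly)
    for (g in targets) {
      donors <- which(genus_of_tip != g &
                        tabulate(genus_of_tip, length(blocks))[genus_of_tip] > 1)
      if (length(donors) == 0) next
      genus_of_tip[donors[sample.int(length(donors), 1)]] <- g
    }
  }
  sp_counter <- integer(length(blocks))
  labels <- character(nt)
  for (tip in seq_len(nt)) {
    g <- genus_of_tip[tip]
    sp_counter[g] <- sp_counter[g] + 1L
    labels[tip] <- sprintf("Genus%d_sp%d", g, sp_counter[g])
  }
  labels
}

#' Simulate one binary trait on a tree
#'
#' `"brownian_threshold"`: Brownian tip values, the `round(prevalence * n)`
#' largest get state 1 (strong phylogenetic clumping, D near 0).
#' `"random"`: a uniform random subset of that size (no signal, D near 1).
#' Either way exactly `k` tips carry state 1.
#'
#' @param tree A bifurcating `"phylo"` tree.
#' @param model `"brownian_threshold"` or `"random"`.
#' @param prevalence Target fraction of state-1 tips, in (0, 1).
#' @param seed Integer seed.
#' @return Named 0/1 vector over the tips.
#' @export
simulate_binary_trait <- function(tree,
                                  model = c("brownian_threshold", "random"),
                                  prevalence = 0.5, seed = NULL) {
  model <- match.arg(model)
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  k <- round(prevalence * n)
  if (k < 1 || k > n - 1) stop_chemophylo("degenerate prevalence: k = ", k)
  states <- with_seed(seed, {
    if (model == "brownian_threshold") {
      drop(top_k_binary(bm_tip_values(tree, 1), k))
    } else {
      out <- numeric(n)
      out[sample.int(n, k)] <- 1
      out
    }
  })
  names(states) <- tree$tip.label
  states
}

#' Simulate a full synthetic study
#'
#' Generates the tree (unless supplied) and a [trait_matrix()] emulating
#' the study's structure. Each informative alkaloid trait is drawn from
#' the Brownian-threshold model with probability `signal_level` (its
#' mixture weight `w`), otherwise at random, so the long-run expectation
#' of D interpolates between 0 (`w = 1`) and 1 (`w = 0`). Singleton traits
#' get exactly one carrier. Bioassay traits are Brownian-threshold traits
#' accepted only if their Jaccard overlap with an anchor alkaloid trait
#' reaches the configured floor (AChE is anchored to the second
#' informative trait — galanthamine under the default vocabulary, the
#' classic AChE inhibitor class — SERT to the first); the last bioassay
#' trait is masked to `NA` for `n_missing_sert` species drawn from the
#' largest genus, mimicking the missing SERT block.
#'
#' @param tree Optional tree; by default simulated from `config`.
#' @param config A [study_config()].
#' @return List of class `"synthetic_study"`: `tree`, `traits` (a
#'   [trait_matrix()]), and `truth` (model choice, anchor, seed and retry
#'   bookkeeping for every trait).
#' @export
simulate_profiles <- function(tree = NULL, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  if (is.null(tree)) {
    tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                               seed = derive_seed(seed, "tree"),
                               n_genera = config$n_genera,
                               polyphyly_fraction = config$polyphyly_fraction)
  }
  n <- ape::Ntip(tree)
  n_inf <- config$n_alkaloid_types - config$n_singletons
  inf_names <- trait_name_pool(amaryllidaceae_alkaloid_types[1:7], n_inf,
                               "alkaloid_type")
  singleton_names <- trait_name_pool(c("belladine", "cherylline"),
                                     config$n_singletons, "singleton_type")
  prevalence <- rep_len(config$prevalence, n_inf)
  w <- rep_len(config$signal_level, n_inf)

  truth <- list(seed = seed, config = config, traits = list())
  vals <- matrix(NA_real_, n, 0, dimnames = list(tree$tip.label, NULL))

  for (i in seq_len(n_inf)) {
    nm <- inf_names[i]
    s_model <- with_seed(derive_seed(seed, paste0("model_", nm)), {
      if (stats::runif(1) < w[i]) "brownian_threshold" else "random"
    })
    states <- simulate_binary_trait(tree, s_model, prevalence[i],
                                    seed = derive_seed(seed, nm))
    vals <- cbind(vals, states)
    colnames(vals)[ncol(vals)] <- nm
    truth$traits[[nm]] <- list(kind = "alkaloid", model = s_model,
                               prevalence = prevalence[i], w = w[i])
  }
  for (nm in singleton_names) {
    states <- numeric(n)
    states[with_seed(derive_seed(seed, nm), sample.int(n, 1))] <- 1
    vals <- cbind(vals, states)
    colnames(vals)[ncol(vals)] <- nm
    truth$traits[[nm]] <- list(kind = "alkaloid", model = "singleton")
  }

  bio_names <- trait_name_pool(default_bioassay_traits, config$n_bioassays,
                               "bioassay")
  anchors <- rep_len(c(inf_names[min(2, n_inf)], inf_names[1]),
                     config$n_bioassays)
  for (i in seq_len(config$n_bioassays)) {
    nm <- bio_names[i]
    drawn <- draw_overlapping_trait(tree, vals[, anchors[i]],
                                    config$bioassay_prevalence,
                                    config$bioassay_overlap_floor,
                                    seed = derive_seed(seed, nm))
    vals <- cbind(vals, drawn$states)
    colnames(vals)[ncol(vals)] <- nm
    truth$traits[[nm]] <- list(kind = "bioassay", model = "brownian_threshold",
                               anchor = anchors[i], jaccard = drawn$jaccard,
                               retries = drawn$retries)
  }

  genus <- genus_map_from_labels(tree$tip.label)
  if (config$n_missing_sert > 0 && config$n_bioassays > 0) {
    missing_sp <- with_seed(derive_seed(seed, "sert_missing"), {
      largest <- names(which.max(table(genus)))
      pool <- names(genus)[genus == largest]
      if (length(pool) < config$n_missing_sert) {
        pool <- c(pool, sample(setdiff(names(genus), pool),
                               config$n_missing_sert - length(pool)))
      }
      sort(pool[seq_len(min(config$n_missing_sert, length(pool)))])
    })
    vals[missing_sp, bio_names[length(bio_names)]] <- NA
    truth$missing_species <- missing_sp
  }

  kind <- c(rep("alkaloid", n_inf + config$n_singletons),
            rep("bioassay", config$n_bioassays))
  structure(list(
    tree = tree,
    traits = trait_matrix(vals, kind, genus),
    truth = truth
  ), class = "synthetic_study")
}

trait_name_pool <- function(preferred, n, stem) {
  if (n <= length(preferred)) return(preferred[seq_len(n)])
  c(preferred, paste0(stem, "_", seq_len(n - length(preferred)) +
                        length(preferred)))
}

# Rejection-sample a Brownian-threshold trait until it overlaps the anchor
# trait (Jaccard on carrier sets) at or above the floor.
draw_overlapping_trait <- function(tree, anchor, prevalence, floor, seed,
                                   max_retries = 200) {
  best <- NULL
  best_j <- -1
  for (try in seq_len(max_retries)) {
    states <- simulate_binary_trait(tree, "brownian_threshold", prevalence,
                                    seed = seed + try - 1L)
    j <- sum(states == 1 & anchor == 1) / sum(states == 1 | anchor == 1)
    if (j > best_j) {
      best <- states; best_j <- j
    }
    if (j >= floor) {
      return(list(states = states, jaccard = j, retries = try - 1L))
    }
  }
  stop_chemophylo("could not reach Jaccard overlap >= ", floor,
                  " with anchor trait after ", max_retries,
                  " retries (best ", signif(best_j, 3), ")")
}

#' Write a synthetic study to disk
#'
#' Writes `tree.nwk`, `traits.csv` (species, genus, trait columns; missing
#' = empty cell) and `truth.json`. Byte-identical for identical
#' configurations.
#'
#' @param study A `"synthetic_study"`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  df <- data.frame(species = rownames(study$traits$values),
                   genus = unname(study$traits$genus),
                   study$traits$values, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "traits.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(dir)
}
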