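# Fritz-Purvis D for binary traits: observed sister-clade change sum,
# tip-permutation and Brownian-threshold nulls, and the standardized
# statistic D = (s_obs - mean(s_b)) / (mean(s_r) - mean(s_b)).

# Postorder bookkeeping reused by every change-sum evaluation on a tree:
# internal-node processing order (children always before parents) and the
# two children of each internal node. Bifurcating trees only.
postorder_index <- function(tree) {
  if (!ape::is.binary(tree)) {
    stop_chemophylo("tree has polytomies; apply resolve_polytomies() first")
  }
  post <- ape::reorder.phylo(tree, "postorder")
  e <- post$edge
  parents <- unique(e[, 1])
  kids <- split(e[, 2], factor(e[, 1], levels = parents))
  kid_mat <- matrix(unlist(kids, use.names = FALSE), nrow = 2)
  list(
    ntip = ape::Ntip(tree),
    nnode_total = ape::Ntip(tree) + tree$Nnode,
    parents = parents,
    child1 = kid_mat[1, ],
    child2 = kid_mat[2, ],
    tip_labels = tree$tip.label
  )
}

# Sister-clade change sums for a matrix of tip states (tips x replicates).
# Each internal node takes the unweighted mean of its two daughters; the
# change sum is the total absolute daughter difference over internal nodes.
# Branch lengths play no role here (they enter only the Brownian null).
sister_change_sums <- function(idx, states_matrix) {
  val <- matrix(0, idx$nnode_total, ncol(states_matrix))
  val[seq_len(idx$ntip), ] <- states_matrix
  s <- numeric(ncol(states_matrix))
  for (i in seq_along(idx$parents)) {
    a <- val[idx$child1[i], ]
    b <- val[idx$child2[i], ]
    s <- s + abs(a - b)
    val[idx$parents[i], ] <- (a + b) / 2
  }
  s
}

check_states <- function(tree, states) {
  if (is.null(names(states))) stop_chemophylo("states must be named by tip label")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0) {
    stop_chemophylo("states missing for tips: ", paste(missing, collapse = ", "))
  }
  states <- states[tree$tip.label]
  if (anyNA(states) || !all(states %in% c(0, 1))) {
    stop_chemophylo("states must be 0/1 with no missing values")
  }
  as.numeric(states)
}

#' Observed number of changes in a binary trait
#'
#' The observed change sum `s_obs` underlying the D statistic: tips carry
#' their 0/1 state, every internal node the unweighted mean of its two
#' daughters (postorder), and `s_obs` is the sum over internal nodes of the
#' absolute difference between the daughters. Branch lengths are ignored;
#' they matter only for the Brownian null, and D self-normalizes because
#' the same statistic is applied to the observation and both nulls.
#'
#' @param tree A bifurcating `"phylo"` tree.
#' @param states Named 0/1 vector covering every tip.
#' @return Numeric scalar `s_obs`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
#' observed_changes(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' @export
observed_changes <- function(tree, states) {
  tree <- validate_phylogeny(tree)
  v <- check_states(tree, states)
  idx <- postorder_index(tree)
  sister_change_sums(idx, matrix(v, ncol = 1))
}

#' Permutation null distribution of the change sum
#'
#' Shuffles the multiset of tip states uniformly at random (preserving the
#' number of 1-tips) and records the change sum of each shuffle. The mean
#' of the returned values is the `s_r`-bar of the D statistic.
#'
#' @inheritParams observed_changes
#' @param n_permutations Number of shuffles (1000 by default).
#' @param seed Integer seed; same seed gives the identical value list.
#' @return Numeric vector of `n_permutations` change sums.
#' @export
permutation_null <- function(tree, states, n_permutations = 1000, seed = NULL) {
  tree <- validate_phylogeny(tree)
  v <- check_states(tree, states)
  idx <- postorder_index(tree)
  n <- length(v)
  with_seed(seed, {
    perm <- matrix(0, n, n_permutations)
    for (j in seq_len(n_permutations)) perm[, j] <- v[sample.int(n)]
    sister_change_sums(idx, perm)
  })
}

# Brownian-motion tip values: root 0, each branch adds an independent
# N(0, branch length) increment (preorder accumulation). Zero-length
# branches (e.g. from polytomy resolution) contribute zero variance.
# Returns a tips x nsim matrix in tip-index order. Uses the current RNG.
bm_tip_values <- function(tree, nsim) {
  pre <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(pre$edge)
  val <- matrix(0, ape::Ntip(tree) + tree$Nnode, nsim)
  inc <- matrix(stats::rnorm(ne * nsim), ne, nsim) * sqrt(pre$edge.length)
  for (e in seq_len(ne)) {
    val[pre$edge[e, 2], ] <- val[pre$edge[e, 1], ] + inc[e, ]
  }
  val[seq_len(ape::Ntip(tree)), , drop = FALSE]
}

# Rank-based threshold: the k largest values in each column get state 1.
# Exactly enforces the observed prevalence; equivalent to a numeric
# threshold for continuous values (ties have probability zero).
top_k_binary <- function(x, k) {
  apply(x, 2, function(v) {
    out <- numeric(length(v))
    out[order(v, decreasing = TRUE)[seq_len(k)]] <- 1
    out
  })
}

#' Brownian-threshold null distribution of the change sum
#'
#' Simulates a continuous character along the tree by Brownian motion
#' (root value 0, unit diffusion rate; D is invariant to both choices) and
#' assigns state 1 to the `k` tips with the largest simulated values, so
#' every simulation reproduces the observed number of tips in each state.
#' The mean of the returned change sums is the `s_b`-bar of the D
#' statistic.
#'
#' @param tree A bifurcating `"phylo"` tree with branch lengths.
#' @param k Number of state-1 tips to produce (0 < k < number of tips).
#' @param n_simulations Number of simulations (1000 by default).
#' @param seed Integer seed.
#' @return Numeric vector of `n_simulations` change sums.
#' @export
brownian_null <- function(tree, k, n_simulations = 1000, seed = NULL) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (k <= 0 || k >= n) stop_chemophylo("k must satisfy 0 < k < number of tips")
  if (max(ape::node.depth.edgelength(tree)) == 0) {
    stop_chemophylo("tree has zero total depth; Brownian simulation undefined")
  }
  idx <- postorder_index(tree)
  with_seed(seed, {
    tips <- bm_tip_values(tree, n_simulations)
    sister_change_sums(idx, top_k_binary(tips, k))
  })
}

#' Assemble a D-statistic result from observed and null change sums
#'
#' Computes `D = (s_obs - mean(s_b)) / (mean(s_r) - mean(s_b))`, where
#' `s_r` are permutation-null and `s_b` Brownian-threshold-null change
#' sums. D is 1 when the trait is phylogenetically random, 0 when it is as
#' clumped as Brownian motion predicts, negative when more clumped, and
#' above 1 when overdispersed. One-tailed significance follows the rule
#' that a trait is more structured than random when at least 95% of the
#' `s_r` exceed `s_obs`:
#' `P(D = 1)` is the fraction of `s_r <= s_obs` (small values = structure)
#' and `P(D = 0)` the fraction of `s_b >= s_obs` (large values = less
#' clumped than Brownian).
#'
#' @param s_obs Observed change sum.
#' @param sr_values Permutation-null change sums.
#' @param sb_values Brownian-threshold-null change sums.
#' @param correct Use the (count + 1)/(n + 1) p-value variant instead of
#'   the plain fraction (default `FALSE`, matching the stated decision
#'   rule).
#' @return An object of class `"phylo_d"`.
#' @export
compute_d <- function(s_obs, sr_values, sb_values, correct = FALSE) {
  if (length(sr_values) == 0 || length(sb_values) == 0) {
    stop_chemophylo("both null samples must be nonempty")
  }
  mean_sr <- mean(sr_values)
  mean_sb <- mean(sb_values)
  denom <- mean_sr - mean_sb
  if (abs(denom) < 1e-8 * max(1, abs(mean_sr))) {
    stop_chemophylo("nulls indistinguishable: mean permutation and Brownian ",
                    "change sums coincide; D is undefined for this trait")
  }
  pfun <- if (correct) {
    function(count, n) (count + 1) / (n + 1)
  } else {
    function(count, n) count / n
  }
  res <- list(
    trait = NA_character_,
    n = NA_integer_,
    k = NA_integer_,
    s_obs = s_obs,
    sr_values = sr_values,
    sb_values = sb_values,
    mean_sr = mean_sr,
    mean_sb = mean_sb,
    D = (s_obs - mean_sb) / denom,
    p_random = pfun(sum(sr_values <= s_obs), length(sr_values)),
    p_brownian = pfun(sum(sb_values >= s_obs), length(sb_values)),
    seed = NA_integer_
  )
  class(res) <- "phylo_d"
  res
}

#' Phylogenetic signal of one binary trait (Fritz-Purvis D)
#'
#' Full per-trait analysis: observed change sum, permutation null,
#' Brownian-threshold null (at the observed prevalence), D, and both
#' one-tailed p-values. The per-trait RNG substream is derived
#' deterministically from `seed` and the trait name, so results do not
#' depend on the order in which traits are analysed.
#'
#' @param tree A bifurcating `"phylo"` tree, already reconciled with the
#'   trait data (see [reconcile()]).
#' @param traits A [trait_matrix()] (or a named 0/1 vector in `trait`'s
#'   place via `states`).
#' @param trait Trait (column) name to analyse.
#' @param n_permutations,n_simulations Null sample sizes (1000/1000).
#' @param seed Master integer seed.
#' @param correct See [compute_d()].
#' @return A `"phylo_d"` object.
#' @export
phylo_d <- function(tree, traits, trait, n_permutations = 1000,
                    n_simulations = 1000, seed = NULL, correct = FALSE) {
  tree <- validate_phylogeny(tree)
  states <- trait_states(traits, trait, tree$tip.label)
  k <- sum(states == 1)
  n <- length(states)
  if (k < 1 || k > n - 1) {
    stop_chemophylo("trait '", trait, "' shows no variation on this tree; ",
                    "apply informative_traits() first")
  }
  sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, trait)
  s_obs <- observed_changes(tree, states)
  sr <- permutation_null(tree, states, n_permutations, seed = sub_seed)
  sb <- brownian_null(tree, k, n_simulations,
                      seed = if (is.null(sub_seed)) NULL else sub_seed + 1L)
  res <- compute_d(s_obs, sr, sb, correct = correct)
  res$trait <- trait
  res$n <- n
  res$k <- as.integer(k)
  res$seed <- seed %||% NA_integer_
  res
}

# Accept either a trait_matrix + column name or a bare named vector.
trait_states <- function(traits, trait, tip_labels) {
  if (inherits(traits, "trait_matrix")) {
    if (!trait %in% colnames(traits$values)) {
      stop_chemophylo("unknown trait: ", trait)
    }
    v <- traits$values[, trait]
    v <- v[!is.na(v)]
  } else {
    v <- traits
  }
  missing <- setdiff(tip_labels, names(v))
  if (length(missing) > 0) {
    stop_chemophylo("trait '", trait, "' has no value for tips: ",
                    paste(missing, collapse = ", "),
                    " (prune the tree to scored species first)")
  }
  v[tip_labels]
}

#' @export
print.phylo_d <- function(x, ...) {
  cat("Phylogenetic signal (Fritz-Purvis D) for binary trait",
      if (!is.na(x$trait)) sQuote(x$trait) else "", "\n")
  if (!is.na(x$n)) cat("  tips:", x$n, "  state-1 tips:", x$k, "\n")
  cat(sprintf("  s_obs = %.4g   mean s_r = %.4g   mean s_b = %.4g\n",
              x$s_obs, x$mean_sr, x$mean_sb))
  cat(sprintf("  D = %.4f   P(D=1) = %.4g   P(D=0) = %.4g\n",
              x$D, x$p_random, x$p_brownian))
  invisible(x)
}
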