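#' Read a rooted phylogeny from Newick text or a file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is treated as
#' rooted as written. Missing branch lengths are defaulted to 1. Malformed
#' input is rejected before parsing with the character offset of the first
#' syntax problem; duplicated tip labels and negative branch lengths are
#' errors.
#'
#' @param file Path to a Newick file (one `;`-terminated tree).
#' @param text Newick string; overrides `file` when given.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2):0;")
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop_chemophylo("supply either `file` or `text`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop_chemophylo("Newick parse failed")
  validate_phylogeny(tree)
}

# Pre-parse scan so syntax errors carry a character offset, which
# ape::read.tree does not report.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_chemophylo("Newick parse error at character ", i,
                        ": unmatched ')'")
      }
    }
  }
  if (depth > 0L) {
    stop_chemophylo("Newick parse error at character ", length(chars),
                    ": ", depth, " unclosed '('")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop_chemophylo("Newick parse error at character ", length(chars),
                    ": missing terminating ';'")
  }
  invisible(TRUE)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_chemophylo("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_chemophylo("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    stop_chemophylo("negative branch lengths are not allowed")
  }
  tree
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree A `"phylo"` tree.
#' @param file Optional output path; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' All root-to-tip path lengths must agree with the maximum tip depth within
#' `rel_tol * max depth`. Patristic distances, the Brownian-threshold null
#' and the genus-level exemplar construction all assume an ultrametric tree.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param rel_tol Relative tolerance on tip depths (default `1e-6`).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  tree <- validate_phylogeny(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dmax <- max(depths)
  if (dmax == 0) return(TRUE)  # degenerate all-zero tree
  all(abs(depths - dmax) <= rel_tol * dmax)
}

#' Patristic distance matrix
#'
#' Pairwise sums of branch lengths along the tip-to-tip paths, in branch
#' length units, with rows/columns ordered as `tree$tip.label`.
#'
#' @param tree A `"phylo"` tree.
#' @return Symmetric zero-diagonal numeric matrix with tip-label dimnames.
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Prune a tree to a subset of tips
#'
#' The induced tree on `keep`: unary nodes are suppressed with branch
#' lengths summed, so patristic distances among kept tips are unchanged.
#'
#' @param tree A `"phylo"` tree.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @export
prune_to_tips <- function(tree, keep) {
  tree <- validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop_chemophylo("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2) stop_chemophylo("need at least 2 tips to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Resolve polytomies into a bifurcating tree
#'
#' Each multifurcation is replaced by a random (seeded) sequence of
#' zero-length internal branches, so every pairwise patristic distance is
#' preserved while the sister-clade change-count recursion of the D
#' statistic becomes well defined.
#'
#' @param tree A `"phylo"` tree.
#' @param seed Integer seed for the random resolution (reproducibility).
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  tree <- validate_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Derive a genus map from "Genus_species" tip labels
#'
#' Splits each label on the first underscore; a label without an underscore
#' is its own genus.
#'
#' @param labels Character vector of tip labels.
#' @return Named character vector (tip label -> genus).
#' @export
genus_map_from_labels <- function(labels) {
  genus <- sub("_.*$", "", labels)
  names(genus) <- labels
  genus
}

#' Read a tip-to-genus map from a two-column CSV
#'
#' @param file CSV with columns tip, genus (header optional names).
#' @export
read_genus_map <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_chemophylo("genus map CSV needs 2 columns (tip, genus)")
  genus <- as.character(df[[2]])
  names(genus) <- as.character(df[[1]])
  genus
}

#' Partition tips into maximal single-genus clades
#'
#' Tips are grouped into maximal sets of same-genus tips whose most recent
#' common ancestor subtends only tips of that genus. A monophyletic genus
#' yields one clade; a polyphyletic genus yields two or more, labelled
#' `genus-1`, `genus-2`, ... in preorder traversal order (stable across
#' runs). Both clades of a polyphyletic genus are retained in all
#' downstream genus-level analyses.
#'
#' @param tree A `"phylo"` tree.
#' @param genus_map Named character vector mapping every tip label to a
#'   genus (see [genus_map_from_labels()]).
#' @return Named list of character vectors (clade label -> tips), with a
#'   `"genus"` attribute giving each clade's genus.
#' @export
genus_clades <- function(tree, genus_map) {
  tree <- validate_phylogeny(tree)
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(genus_map))
  if (length(unmapped) > 0) {
    stop_chemophylo("tips missing from genus map: ",
                    paste(unmapped, collapse = ", "))
  }
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- nt + 1L

  # genus of each node if its clade is pure, NA otherwise (postorder pass)
  post <- ape::reorder.phylo(tree, "postorder")
  node_genus <- rep(NA_character_, nt + nn)
  node_genus[seq_len(nt)] <- unname(genus_map[tips])
  kids <- split(post$edge[, 2], post$edge[, 1])
  for (p in unique(post$edge[, 1])) {
    g <- unique(node_genus[kids[[as.character(p)]]])
    if (length(g) == 1 && !is.na(g)) node_genus[p] <- g
  }

  parent <- integer(nt + nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # preorder node sequence for stable clade ordering
  clade_order <- c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  maximal <- clade_order[vapply(clade_order, function(v) {
    !is.na(node_genus[v]) && (v == root || is.na(node_genus[parent[v]]))
  }, logical(1))]

  clade_tips <- lapply(maximal, function(v) {
    if (v <= nt) tips[v] else ape::extract.clade(tree, v)$tip.label
  })
  genera <- node_genus[maximal]
  labels <- genera
  for (g in unique(genera)) {
    idx <- which(genera == g)
    if (length(idx) > 1) labels[idx] <- paste0(g, "-", seq_along(idx))
  }
  names(clade_tips) <- labels
  attr(clade_tips, "genus") <- genera
  clade_tips
}
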