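# Chemical-profile distance matrices and genus-level aggregation.

#' Extract binary chemical profiles from a trait matrix
#'
#' Returns the alkaloid-kind columns as a complete 0/1 matrix. Species with
#' a missing alkaloid value cannot enter a profile distance and are dropped
#' with a warning (bioassay missingness does not affect profiles).
#'
#' @param x A [trait_matrix()].
#' @return Binary matrix, species x alkaloid types.
#' @export
chemical_profiles <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  prof <- x$values[, x$kind == "alkaloid", drop = FALSE]
  if (ncol(prof) == 0) stop_chemophylo("no alkaloid traits in matrix")
  incomplete <- rownames(prof)[rowSums(is.na(prof)) > 0]
  if (length(incomplete) > 0) {
    warning(length(incomplete), " species with incomplete alkaloid profiles ",
            "dropped: ", paste(incomplete, collapse = ", "), call. = FALSE)
    prof <- prof[setdiff(rownames(prof), incomplete), , drop = FALSE]
  }
  prof
}

#' Binary squared Euclidean distance matrix between chemical profiles
#'
#' For 0/1 presence/absence vectors the squared Euclidean distance is the
#' number of alkaloid types present in exactly one of the two taxa (the
#' mismatch, or Hamming, count), in trait-count units.
#'
#' @param profiles Binary matrix, taxa x types (rownames = taxon labels).
#' @return Symmetric zero-diagonal integer-valued matrix.
#' @export
binary_squared_euclidean_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || !all(profiles %in% c(0, 1))) {
    stop_chemophylo("profiles must be 0/1 with no missing values")
  }
  if (is.null(rownames(profiles))) stop_chemophylo("profiles need taxon rownames")
  k <- rowSums(profiles)
  shared <- tcrossprod(profiles)
  d <- outer(k, k, "+") - 2 * shared
  diag(d) <- 0
  d
}

#' Aggregate species profiles to genus-clade profiles
#'
#' The profile of a clade is the elementwise union (logical OR) of its
#' members' profiles: a type is present in the clade if any member carries
#' it. Each clade of a polyphyletic genus keeps its own row, labelled as in
#' [genus_clades()].
#'
#' @param profiles Binary species x types matrix.
#' @param clades Output of [genus_clades()].
#' @return Binary clades x types matrix.
#' @export
genus_profiles <- function(profiles, clades) {
  out <- t(vapply(clades, function(members) {
    missing <- setdiff(members, rownames(profiles))
    if (length(missing) > 0) {
      stop_chemophylo("clade member(s) without profile: ",
                      paste(missing, collapse = ", "))
    }
    as.numeric(colSums(profiles[members, , drop = FALSE]) > 0)
  }, numeric(ncol(profiles))))
  colnames(out) <- colnames(profiles)
  out
}

#' Genus-level phylogenetic and chemical distance matrices
#'
#' The phylogenetic distance between two clades is the patristic distance
#' between one exemplar tip from each (the lexicographically first); on an
#' ultrametric tree every cross-clade tip pair passes through the same
#' most recent common ancestor depth, so the choice of exemplar does not
#' matter. The chemical matrix is the binary squared Euclidean distance
#' between union profiles.
#'
#' @param tree Ultrametric `"phylo"` tree.
#' @param clades Output of [genus_clades()].
#' @param profiles Binary species x types matrix covering all clade members.
#' @param force Allow a non-ultrametric tree (exemplar invariance is then
#'   not guaranteed).
#' @param rel_tol Ultrametricity tolerance, see [is_ultrametric()].
#' @return List with `phylo` and `chem` matrices over clade labels.
#' @export
genus_distance_matrices <- function(tree, clades, profiles, force = FALSE,
                                    rel_tol = 1e-6) {
  tree <- validate_phylogeny(tree)
  if (!force && !is_ultrametric(tree, rel_tol)) {
    stop_chemophylo("tree is not ultrametric; genus-level exemplar distances ",
                    "are not exemplar-free (use force = TRUE to override)")
  }
  exemplars <- vapply(clades, function(members) sort(members)[1], character(1))
  full <- patristic_matrix(tree)
  phylo <- full[exemplars, exemplars, drop = FALSE]
  dimnames(phylo) <- list(names(clades), names(clades))
  chem <- binary_squared_euclidean_matrix(genus_profiles(profiles, clades))
  list(phylo = phylo, chem = chem)
}

#' Write a labeled square distance matrix as TSV
#'
#' @param m Square matrix with dimnames.
#' @param file Output path.
#' @export
write_distance_matrix <- function(m, file) {
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a labeled square distance matrix from TSV
#' @param file TSV written by [write_distance_matrix()].
#' @export
read_distance_matrix <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) {
    stop_chemophylo("row and column labels disagree")
  }
  m
}
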