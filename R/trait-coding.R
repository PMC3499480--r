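# Binary trait matrices: alkaloid-type presence/absence and binarized
# bioassay activity, with the exclusion and reconciliation rules used in
# the signal and correlation analyses.

#' Alkaloid types recorded in Amaryllidoideae profiles
#'
#' Controlled vocabulary of alkaloid structural types (classification by
#' hypothetical biosynthetic pathway) recognised by the default trait-table
#' schema. These are the nine types recorded in Amaryllidaceae subfamily
#' Amaryllidoideae bulb profiles; additional types may be declared per
#' table via `alkaloid_traits=`.
#' @export
amaryllidaceae_alkaloid_types <- c(
  "crinine", "galanthamine", "lycorine", "galanthindole", "homolycorine",
  "montanine", "tazettine", "belladine", "cherylline"
)

default_bioassay_traits <- c("AChE", "SERT")

#' Construct a binary species-by-trait matrix
#'
#' @param values Numeric/integer matrix, rows = species (rownames), columns
#'   = traits (colnames); entries 0, 1 or `NA` (missing).
#' @param kind Character vector, one of `"alkaloid"` or `"bioassay"` per
#'   column.
#' @param genus Optional named character vector (species -> genus).
#' @return An object of class `"trait_matrix"` with fields `values`,
#'   `kind`, `genus`.
#' @export
trait_matrix <- function(values, kind, genus = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_chemophylo("values must have species rownames and trait colnames")
  }
  if (anyDuplicated(rownames(values))) stop_chemophylo("duplicate species rows")
  bad <- !(values %in% c(0, 1) | is.na(values))
  if (any(bad)) {
    j <- unique(colnames(values)[col(values)[bad]])
    stop_chemophylo("non-binary values in trait column(s): ",
                    paste(j, collapse = ", "))
  }
  kind <- rep_len(as.character(kind), ncol(values))
  if (!all(kind %in% c("alkaloid", "bioassay"))) {
    stop_chemophylo("kind must be 'alkaloid' or 'bioassay'")
  }
  names(kind) <- colnames(values)
  if (!is.null(genus)) genus <- genus[rownames(values)]
  structure(list(values = values, kind = kind, genus = genus),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Binary trait matrix:", nrow(x$values), "species x",
      ncol(x$values), "traits (",
      sum(x$kind == "alkaloid"), "alkaloid,",
      sum(x$kind == "bioassay"), "bioassay )\n")
  cat("  missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Load a species trait table from CSV
#'
#' Expected layout: column 1 species id, optional column `genus`, remaining
#' columns binary traits (empty cell = missing). Columns are classified as
#' alkaloid or bioassay against the declared vocabularies; undeclared
#' columns are an error, so typos cannot silently enter an analysis.
#'
#' @param file CSV path.
#' @param alkaloid_traits Accepted alkaloid column names (defaults to
#'   [amaryllidaceae_alkaloid_types]).
#' @param bioassay_traits Accepted bioassay column names (default
#'   `c("AChE", "SERT")`).
#' @return A [trait_matrix()].
#' @export
load_trait_table <- function(file,
                             alkaloid_traits = amaryllidaceae_alkaloid_types,
                             bioassay_traits = default_bioassay_traits) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop_chemophylo("empty trait table")
  species <- as.character(df[[1]])
  if (anyDuplicated(species)) {
    stop_chemophylo("duplicate species rows: ",
                    paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  df <- df[-1]
  genus <- NULL
  if ("genus" %in% names(df)) {
    genus <- as.character(df$genus)
    names(genus) <- species
    df$genus <- NULL
  }
  unknown <- setdiff(names(df), c(alkaloid_traits, bioassay_traits))
  if (length(unknown) > 0) {
    stop_chemophylo("unknown trait column(s): ", paste(unknown, collapse = ", "),
                    "; declare them via alkaloid_traits/bioassay_traits")
  }
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.character(v)) v[trimws(v) == ""] <- NA
    v_num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (is.na(v_num) | !(v_num %in% c(0, 1)))
    if (any(bad)) {
      stop_chemophylo("non-binary value ", sQuote(v[which(bad)[1]]),
                      " in trait column ", sQuote(nm))
    }
    v_num
  })
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(species, names(df))
  kind <- ifelse(names(df) %in% bioassay_traits, "bioassay", "alkaloid")
  trait_matrix(vals, kind, genus)
}

#' Default bioactivity thresholds
#'
#' Screening and IC50 rules for the two central-nervous-system bioassays:
#' acetylcholinesterase (AChE) inhibition is screened at 1.0 ug/ml with a
#' 50% inhibition cutoff (inclusive), serotonin-reuptake-transporter (SERT)
#' binding at 5 mg/ml with an 85% cutoff (exclusive, "more than 85%");
#' either assay is scored active only if, in addition, the extract's IC50
#' is below 50 ug/ml.
#' @export
bioassay_rules <- function() {
  list(
    AChE = list(screen_min = 50, screen_strict = FALSE,
                screen_conc = 1.0, screen_conc_unit = "ug/ml", ic50_max = 50),
    SERT = list(screen_min = 85, screen_strict = TRUE,
                screen_conc = 5, screen_conc_unit = "mg/ml", ic50_max = 50)
  )
}

#' Binarize a bioassay screening record
#'
#' Active (1) iff the screening criterion passes and IC50 < 50 ug/ml;
#' inactive (0) if the screen fails or IC50 >= 50; missing (`NA`) if the
#' screening value is absent, or if the screen passed but no IC50 was
#' determined.
#'
#' @param assay `"AChE"` or `"SERT"` (or any assay named in `rules`).
#' @param screening Screening value (% inhibition / % binding), in
#'   \[0, 100\]; `NA` for not determined. Vectorized.
#' @param ic50 IC50 in ug/ml (`NA` if not determined). Vectorized.
#' @param concentration Optional screening concentration; when given it
#'   must equal the rule's stated concentration.
#' @param rules Threshold configuration, see [bioassay_rules()].
#' @return Integer vector of 0/1/`NA`.
#' @export
code_bioactivity <- function(assay, screening, ic50 = NA_real_,
                             concentration = NULL, rules = bioassay_rules()) {
  rule <- rules[[assay]]
  if (is.null(rule)) stop_chemophylo("unknown assay: ", assay)
  if (!is.null(concentration) &&
      any(abs(concentration - rule$screen_conc) > 1e-9)) {
    stop_chemophylo("screening concentration must be ", rule$screen_conc, " ",
                    rule$screen_conc_unit, " for ", assay)
  }
  if (any(!is.na(screening) & (screening < 0 | screening > 100))) {
    stop_chemophylo("screening percentages must be in [0, 100]")
  }
  pass <- if (rule$screen_strict) screening > rule$screen_min else
    screening >= rule$screen_min
  n <- max(length(screening), length(ic50))
  pass <- rep_len(pass, n)
  ic50 <- rep_len(ic50, n)
  out <- rep(NA_integer_, n)
  out[!is.na(pass) & !pass] <- 0L
  hit <- !is.na(pass) & pass & !is.na(ic50)
  out[hit] <- as.integer(ic50[hit] < rule$ic50_max)
  out
}

#' Split traits into informative and excluded sets
#'
#' A trait is kept iff at least two species carry state 1 and at least two
#' carry state 0 among its non-missing entries. This symmetrizes the
#' single-species exclusion used for traits like belladine and cherylline:
#' D is undefined without variation, and a single carrier (or single
#' absence) renders the nulls degenerate.
#'
#' @param x A [trait_matrix()].
#' @return List with `kept` (character vector) and `excluded` (data frame
#'   of trait, n_present, n_absent, n_missing, reason).
#' @export
informative_traits <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  if (ncol(x$values) == 0) stop_chemophylo("empty trait matrix")
  n1 <- colSums(x$values == 1, na.rm = TRUE)
  n0 <- colSums(x$values == 0, na.rm = TRUE)
  nm <- colSums(is.na(x$values))
  keep <- n1 >= 2 & n0 >= 2
  reason <- ifelse(n1 < 2, paste0("state 1 in ", n1, " species"),
                   paste0("state 0 in ", n0, " species"))
  list(
    kept = colnames(x$values)[keep],
    excluded = data.frame(
      trait = colnames(x$values)[!keep],
      n_present = unname(n1[!keep]),
      n_absent = unname(n0[!keep]),
      n_missing = unname(nm[!keep]),
      reason = unname(reason[!keep]),
      stringsAsFactors = FALSE
    )
  )
}

#' Reconcile a trait matrix with a tree
#'
#' Restricts both to their common species and records, per trait, the
#' species with a non-missing value; downstream analyses of a trait run on
#' the tree pruned to exactly those species (species lacking one assay are
#' pruned only from that assay's analysis, not from the others).
#'
#' @param x A [trait_matrix()].
#' @param tree A `"phylo"` tree.
#' @return List of class `"reconciled"`: `matrix` (trait_matrix on common
#'   species), `tree` (pruned to common species), `trait_species` (named
#'   list: trait -> species with data), `dropped` (tips absent from the
#'   matrix, species absent from the tree, and per-trait missing species).
#' @export
reconcile <- function(x, tree) {
  stopifnot(inherits(x, "trait_matrix"))
  tree <- validate_phylogeny(tree)
  common <- intersect(tree$tip.label, rownames(x$values))
  if (length(common) < 4) {
    stop_chemophylo("fewer than 4 species shared between tree and trait table")
  }
  drop_tree <- setdiff(tree$tip.label, common)
  drop_mat <- setdiff(rownames(x$values), common)
  if (length(drop_tree) > 0) {
    warning(length(drop_tree), " tree tip(s) without trait data dropped: ",
            paste(drop_tree, collapse = ", "), call. = FALSE)
  }
  vals <- x$values[common, , drop = FALSE]
  trait_species <- lapply(colnames(vals), function(tr) {
    common[!is.na(vals[, tr])]
  })
  names(trait_species) <- colnames(vals)
  per_trait_missing <- lapply(trait_species, function(sp) setdiff(common, sp))
  structure(list(
    matrix = trait_matrix(vals, x$kind, x$genus),
    tree = prune_to_tips(tree, common),
    trait_species = trait_species,
    dropped = list(tree_tips = drop_tree, matrix_species = drop_mat,
                   per_trait = per_trait_missing)
  ), class = "reconciled")
}
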