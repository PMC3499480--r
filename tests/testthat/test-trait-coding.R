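test_that("load_trait_table reads, classifies and rejects columns", {
  f <- write_temp_csv(c(
    "species,genus,lycorine,crinine,AChE,SERT",
    "Narcissus_poeticus,Narcissus,1,0,1,",
    "Galanthus_nivalis,Galanthus,1,1,0,0",
    "Crinum_bulbispermum,Crinum,0,1,,1"
  ))
  tm <- load_trait_table(f)
  expect_s3_class(tm, "trait_matrix")
  expect_equal(dim(tm$values), c(3, 4))
  expect_equal(unname(tm$kind), c("alkaloid", "alkaloid", "bioassay", "bioassay"))
  expect_true(is.na(tm$values["Narcissus_poeticus", "SERT"]))
  expect_true(is.na(tm$values["Crinum_bulbispermum", "AChE"]))
  expect_equal(tm$genus[["Crinum_bulbispermum"]], "Crinum")

  bad <- write_temp_csv(c("species,lycorine", "s1,2", "s2,0"))
  expect_error(load_trait_table(bad), "non-binary value")
  txt <- write_temp_csv(c("species,lycorine", "s1,yes", "s2,0"))
  expect_error(load_trait_table(txt), "non-binary value")
  dup <- write_temp_csv(c("species,lycorine", "s1,1", "s1,0"))
  expect_error(load_trait_table(dup), "duplicate species")
  unk <- write_temp_csv(c("species,lycorine,mystery", "s1,1,0"))
  expect_error(load_trait_table(unk), "unknown trait column")
  # whitelisting accepts the extra column as an alkaloid type
  tm2 <- load_trait_table(unk, alkaloid_traits = c("lycorine", "mystery"))
  expect_equal(unname(tm2$kind), c("alkaloid", "alkaloid"))
})

test_that("code_bioactivity applies screening and IC50 thresholds", {
  # screen pass at 1.0 ug/ml and IC50 below 50 ug/ml -> active
  expect_equal(code_bioactivity("AChE", 60, ic50 = 12), 1L)
  expect_equal(code_bioactivity("AChE", 30), 0L)                # fails screen
  expect_equal(code_bioactivity("SERT", 90, ic50 = 80), 0L)     # fails IC50
  # AChE cutoff is inclusive ("minimum 50%"), SERT strict ("more than 85%")
  expect_equal(code_bioactivity("AChE", 50, ic50 = 10), 1L)
  expect_equal(code_bioactivity("SERT", 85, ic50 = 10), 0L)
  expect_equal(code_bioactivity("SERT", 85.1, ic50 = 10), 1L)
  # missing screening -> missing; passed screen without IC50 -> missing
  expect_true(is.na(code_bioactivity("AChE", NA)))
  expect_true(is.na(code_bioactivity("AChE", 70)))
  expect_error(code_bioactivity("MAO", 50), "unknown assay")
  expect_error(code_bioactivity("AChE", 120), "0, 100")
  expect_error(code_bioactivity("AChE", 60, concentration = 2), "concentration")
})

test_that("code_bioactivity is monotone in screening and IC50", {
  screens <- seq(0, 100, by = 5)
  ic50s <- c(1, 10, 49, 50, 80, 200)
  for (assay in c("AChE", "SERT")) {
    for (ic in ic50s) {
      codes <- code_bioactivity(assay, screens, ic50 = ic)
      # raising screening % never turns 1 into 0
      expect_true(all(diff(ifelse(is.na(codes), 0L, codes)) >= 0))
    }
    for (sc in screens) {
      codes <- code_bioactivity(assay, sc, ic50 = ic50s)
      # raising IC50 never turns 0 into 1
      expect_true(all(diff(ifelse(is.na(codes), 1L, codes)) <= 0))
    }
  }
})

test_that("informative_traits keeps only traits varying in both states", {
  vals <- cbind(
    common = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    single = c(1, rep(0, 9)),
    absent = rep(0, 10),
    fixed = rep(1, 10),
    nearly = c(1, 1, rep(0, 8))
  )
  rownames(vals) <- paste0("s", 1:10)
  tm <- trait_matrix(vals, "alkaloid")
  info <- informative_traits(tm)
  expect_setequal(info$kept, c("common", "nearly"))
  expect_setequal(info$excluded$trait, c("single", "absent", "fixed"))
  expect_match(info$excluded$reason[info$excluded$trait == "single"],
               "state 1 in 1 species")

  # idempotence: filtering the kept set changes nothing
  tm_kept <- trait_matrix(vals[, info$kept, drop = FALSE], "alkaloid")
  expect_equal(informative_traits(tm_kept)$kept, info$kept)
  expect_equal(nrow(informative_traits(tm_kept)$excluded), 0)
})

test_that("reconcile intersects species and prunes per trait", {
  set.seed(5)
  tree <- simulate_yule_tree(12, seed = 12)
  sp <- tree$tip.label
  vals <- cbind(a = rep(c(0, 1), 6), SERT = rep(c(1, 0), 6))
  rownames(vals) <- sp
  vals[sp[1:3], "SERT"] <- NA
  tm <- trait_matrix(vals, c("alkaloid", "bioassay"))

  rec <- reconcile(tm, tree)
  expect_equal(sort(rec$tree$tip.label), sort(sp))
  expect_setequal(rec$trait_species$a, sp)
  expect_setequal(rec$trait_species$SERT, sp[4:12])
  expect_setequal(rec$dropped$per_trait$SERT, sp[1:3])

  # a tree tip with no matrix row is dropped with a warning
  vals2 <- vals[sp[1:10], , drop = FALSE]
  tm2 <- trait_matrix(vals2, c("alkaloid", "bioassay"))
  expect_warning(rec2 <- reconcile(tm2, tree), "dropped")
  expect_setequal(rec2$tree$tip.label, sp[1:10])
  expect_setequal(rec2$dropped$tree_tips, sp[11:12])

  # identity case: no missing data leaves the tree untouched
  tm3 <- trait_matrix(vals[, "a", drop = FALSE], "alkaloid")
  rec3 <- reconcile(tm3, tree)
  expect_equal(length(rec3$dropped$per_trait$a), 0)
  expect_equal(ape::write.tree(rec3$tree), ape::write.tree(tree))

  small <- trait_matrix(vals[1:3, , drop = FALSE], c("alkaloid", "bioassay"))
  expect_error(suppressWarnings(reconcile(small, tree)), "fewer than 4")
})
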