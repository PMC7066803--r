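# nomenclature systems, translation, inconsistency detection, renaming

test_that("symbol shapes classify into their nomenclature systems", {
  expect_identical(
    name_system(c("gja1", "GJB7", "gjd2b", "gjd2*1", "cx43", "Cx30.3",
                  "CXNK1", "gja9-cx59", "gjb4like", "NN", "")),
    c("greek", "greek", "greek", "greek", "size", "size", "alphabet",
      "mixed", "like", "none", "none"))
})

test_that("translation follows the table in both directions", {
  expect_identical(translate_name("GJA4", "greek_mammal", "size_mammal"),
                   "Cx37")
  expect_identical(translate_name("cx36.7", "size_teleost",
                                  "amended_teleost"), "gjd6")
  expect_setequal(translate_name("Cx39.2", "size_mammal", "amended_teleost"),
                  c("gjd5a", "gjd5b"))
  expect_identical(translate_name("Cx39.2", "size_mammal", "greek_mammal"),
                   "GJD5")
  # round trip on 1:1 rows
  for (sym in c("GJA4", "GJB7", "GJC2", "GJD3")) {
    size <- translate_name(sym, "greek_mammal", "size_mammal")
    expect_identical(translate_name(size[1], "size_mammal", "greek_mammal"),
                     sym)
  }
  expect_error(translate_name("gjq9", "greek_mammal", "size_mammal"),
               "not found")
  expect_error(translate_name("GJA44", "greek_mammal", "size_mammal"),
               "nearest matches")
})

make_name_ds <- function(labels, groups) {
  n <- length(labels)
  cds <- strrep("GCT", 30)
  recs <- data.frame(
    id = paste0("g", seq_len(n)), species = sub("-.*", "", labels),
    raw_label = labels, db_name = sub("^..-", "", labels),
    prediction_status = "predicted", accession = NA_character_,
    cds = cds, protein = strrep("A", 30), pseudogene = FALSE,
    d1_start = 0L, d1_end = 30L, d2_start = 45L, d2_end = 75L,
    locus_id = NA_character_, stringsAsFactors = FALSE)
  ds <- family_dataset(recs)
  list(ds = ds, groups = setNames(groups, recs$id))
}

test_that("each inconsistency class is detected on constructed cases", {
  x <- make_name_ds(
    labels = c("Dr-gjb7", "Ga-cx28.8", "Tn-gjb7-cx25",   # GJB7 group
               "Fr-gjb4like", "Fr-gjb4like",              # two orthogroups
               "Ch-gja6like",                             # in the GJA4 group
               "Dr-cx36.7"),
    groups = c("GJB7", "GJB7", "GJB7", "GJB9", "GJB10", "GJA4", "GJD6"))
  rep <- detect_inconsistencies(x$ds, x$groups)
  kinds <- rep$kind
  expect_true("mixed_systems_in_group" %in% kinds)
  expect_true("different_names_same_orthogroup" %in% kinds)
  expect_true("same_name_different_orthogroups" %in% kinds)
  expect_true("like_name" %in% kinds)
  expect_true("wrong_orthogroup_name" %in% kinds)
  expect_true("nonunique_within_species" %in% kinds)

  wrong <- rep[rep$kind == "wrong_orthogroup_name", ]
  expect_true(any(grepl("g6", wrong$gene_ids)))   # the gja6like-in-GJA4 case

  # deterministic order and a finding-free clean dataset
  rep2 <- detect_inconsistencies(x$ds, x$groups)
  expect_identical(rep, rep2)
  clean <- make_name_ds(c("Dr-gjb7", "Ga-gjb7"), c("GJB7", "GJB7"))
  expect_equal(nrow(detect_inconsistencies(clean$ds, clean$groups)), 0L)
})

test_that("injected naming noise is fully recovered from simulations", {
  sim <- cached_sim(701, n_ancestral = 8L,
                    naming_profile = c(greek = 0.4, size = 0.4, like = 0.15,
                                       unnamed = 0.05),
                    wrong_name_rate = 0.15)
  rep <- detect_inconsistencies(sim$dataset, sim$truth$orthogroups)
  naming <- sim$truth$naming

  # every group truly labelled with both systems must be flagged mixed
  for (og in unique(naming$true_og)) {
    sys <- naming$system[naming$true_og == og & !naming$wrong]
    if (all(c("greek", "size") %in% sys)) {
      hit <- rep[rep$kind == "mixed_systems_in_group", ]
      expect_true(any(grepl(og, hit$orthogroups, fixed = TRUE)),
                  label = paste("mixed systems flagged for", og))
    }
  }
  # every wrong-group Greek name resolves through the table and must be
  # flagged (wrong size-style names are only detectable via collisions)
  flagged <- unlist(strsplit(rep$gene_ids[rep$kind %in%
    c("wrong_orthogroup_name", "same_name_different_orthogroups")], ","))
  for (id in naming$id[naming$wrong & naming$system == "greek"])
    expect_true(id %in% flagged, label = paste("wrong name flagged:", id))
})

test_that("renaming proposals follow the amended-Greek rules", {
  lm2 <- read_locus_matrix(system.file("extdata", "table2_loci.tsv",
                                       package = "famcurate"))
  ogs <- setNames(lm2$orthogroup, lm2$gene_id)
  calls <- classify_all_duplicates(lm2)
  out <- suggest_names(ogs, calls, lm2)
  prop <- out$proposal

  # mammalian-counterpart group, single teleost copy: bare lowercase symbol
  expect_identical(unname(prop[lm2$gene_id[lm2$orthogroup == "gjb7" &
                                             lm2$species == "Dr"]]), "gjb7")
  # cx39.9 maps through the table to gja2, ohnologs suffixed a/b
  cx399 <- prop[lm2$gene_id[lm2$orthogroup == "cx39.9" &
                              lm2$species == "Dr"]]
  expect_true(all(grepl("^gja2", cx399)))
  # tandem triplet numbered .1/.2/.3 by coordinate
  tn <- sort(unname(prop[lm2$gene_id[lm2$orthogroup == "cx30.3" &
                                       lm2$species == "Tn"]]))
  expect_true(all(grepl("^gjb8", tn)))

  # proposals are injective per species, like-free, and Greek-shaped
  for (sp in unique(lm2$species)) {
    p <- prop[lm2$gene_id[lm2$species == sp]]
    p <- p[!is.na(p)]
    expect_false(anyDuplicated(p) > 0)
  }
  expect_false(any(grepl("like", prop)))
  expect_true(all(grepl("^gj[a-e][0-9]+", prop[!is.na(prop)])))
  expect_false(any(prop == "gja7", na.rm = TRUE))
})

test_that("new subfamily integers skip reserved symbols", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "orthogroup\tmammal_greek\tmammal_size\tmammal_alphabet\tamended_teleost\tcommon_teleost_greek\tcommon_teleost_size",
    "GJA1\tGJA1\tCx43\tCXNK1\tgja1a,gja1b\tgja1\tcx43",
    "GJA3\tGJA3\tCx46\tCXNJ1\tgja3a,gja3b\tgja3\tcx48.5",
    "GJA4\tGJA4\tCx37\tCXNH1\tgja4a,gja4b\tgja4\tcx39.4",
    "GJA5\tGJA5\tCx40\tCXNI\tgja5a,gja5b\tgja5\tcx41.8",
    "GJA6\tGJA6\tCx33\tCXNK2\t-\t-\t-"), tf)
  tb <- nomenclature_table(tf)
  lm <- data.frame(orthogroup = "mystery", copy = "A", species = "Dr",
                   gene_id = "Dr-x", seq_name = "1", start = 1,
                   stringsAsFactors = FALSE)
  out <- suggest_names(setNames("mystery", "Dr-x"), list(), lm, table = tb)
  # gja2 free; but with gja1..gja6 occupied the allocator must skip gja7
  expect_identical(unname(out$proposal["Dr-x"]), "gja2")
  tb2 <- tb
  tb2$amended_teleost[1] <- "gja2a,gja2b"
  occupied_all <- suggest_names(
    setNames("mystery", "Dr-x"), list(), lm,
    table = within(tb2, mammal_greek[5] <- "GJA6"), reserved = "gja7")
  expect_false(identical(unname(occupied_all$proposal["Dr-x"]), "gja7"))
})

test_that("cysteine spacing classifies the extracellular-loop motif", {
  expect_identical(motif_class("AAACWWCWWWCAAA"), "other")
  expect_identical(motif_class("AAACWWWWCWWWWWCAAA"), "CX4CX5C")
  expect_identical(motif_class("AAACWWWWWCWWWWWCAAA"), "CX5CX5C")
  expect_identical(motif_class("AAAWWWWWWWWWWWWAAA"), "none")
  expect_identical(motif_class("CC"), "none")   # shorter than 12 residues
})
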