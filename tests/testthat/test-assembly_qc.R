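# expected complement, missing-gene screen, duplicate artifacts, dot plot

table2 <- function() {
  read_locus_matrix(system.file("extdata", "table2_loci.tsv",
                                package = "famcurate"))
}

test_that("expected counts are the cross-species mode, ties flagged towards the maximum", {
  lm2 <- table2()
  exp <- expected_complement(lm2, "Ch")
  expect_equal(exp$expected[exp$orthogroup == "gjb7"], 1L)
  expect_equal(exp$expected[exp$orthogroup == "gjd2*1"], 2L)
  expect_error(expected_complement(lm2[0, ], "Ch"), "empty|at least")
  expect_error(expected_complement(lm2[lm2$species %in% c("Ch", "Dr"), ],
                                   "Ch"), "at least 2")
  # tie -> maximum, low confidence
  toy <- data.frame(orthogroup = "x", copy = "A",
                    species = c("a", "a", "b"), gene_id = c("a1", "a2", "b1"),
                    seq_name = "1", start = 1, stringsAsFactors = FALSE)
  class(toy) <- c("locus_matrix", "data.frame")
  e <- expected_complement(toy, "t")
  expect_equal(e$expected, 2L)
  expect_true(e$low_confidence)
})

test_that("the herring chromosome-level complement shows exactly the three reported losses", {
  lm2 <- table2()
  exp <- expected_complement(lm2, "Ch")
  ch <- lm2[lm2$species == "Ch", ]
  expect_equal(nrow(find_missing(ch, exp, lm2)), 0L)

  drop <- ch$orthogroup == "gjb7" |
    (ch$orthogroup == "gja9" & ch$copy == "B") |
    (ch$orthogroup == "gjb1" & ch$copy == "B")
  rep <- find_missing(ch[!drop, ], exp, lm2)
  expect_equal(nrow(rep), 3L)
  expect_setequal(rep$orthogroup, c("gja9", "gjb1", "gjb7"))
  expect_true(all(rep$expected > rep$observed))
  gjb7 <- rep[rep$orthogroup == "gjb7", ]
  expect_true(all(c("14", "15") %in% strsplit(gjb7$expected_chr, ",")[[1]]))
})

test_that("simulator-injected deletions are recalled in full", {
  hits <- 0L; total <- 0L
  for (seed in 801:805) {
    sim <- cached_sim(seed, n_ancestral = 8L, cds_len = 120L,
                      domains = list(c(0L, 36L), c(60L, 96L)))
    sim2 <- inject_misassembly(sim, "Dr", deletions = 5L, seed = seed)
    lm <- locus_matrix(sim2$dataset, sim$truth$orthogroups)
    exp <- expected_complement(lm, "Dr")
    dr <- lm[lm$species == "Dr", ]
    rep <- find_missing(dr, exp, lm)
    del_ids <- sim2$truth$events$id[sim2$truth$events$type == "deletion"]
    truth <- sim$truth$genes
    for (id in del_ids) {
      og <- truth$orthogroup[truth$id == id]
      pre <- sum(truth$orthogroup == og & truth$species == "Dr")
      expected <- exp$expected[exp$orthogroup == og]
      if (length(expected) && expected == pre) {   # unambiguous expectation
        total <- total + 1L
        if (og %in% rep$orthogroup) hits <- hits + 1L
      }
    }
    # and no finding without a shortfall
    expect_true(all(rep$expected > rep$observed))
  }
  expect_gt(total, 0L)
  expect_equal(hits, total)

  # an intact assembly with no biological loss yields no findings
  clean <- cached_sim(801, n_ancestral = 8L, cds_len = 120L, loss_prob = 0,
                      tandem_rate = 0,
                      domains = list(c(0L, 36L), c(60L, 96L)))
  lm <- locus_matrix(clean$dataset, clean$truth$orthogroups)
  expect_equal(nrow(find_missing(lm[lm$species == "Dr", ],
                                 expected_complement(lm, "Dr"), lm)), 0L)
})

test_that("near-identical duplicate scan flags shared-scaffold copies as artifacts", {
  sim <- cached_sim(806, n_ancestral = 4L)
  sim2 <- inject_misassembly(sim, "Ga", duplications = 1L, dup_copies = 2L,
                             seed = 3)
  rep <- scan_duplicates(sim2$dataset, 0.99)
  expect_equal(nrow(rep), 1L)
  expect_identical(rep$verdict, "likely_artifact")
  expect_equal(length(strsplit(rep$gene_ids, ",")[[1]]), 3L)

  # true ohnolog pairs at ~15% divergence stay below a 0.99 threshold
  rep0 <- scan_duplicates(sim$dataset, 0.99)
  expect_equal(nrow(rep0), 0L)

  # record order does not change the report
  ds_rev <- sim2$dataset
  ds_rev$records <- ds_rev$records[rev(seq_len(nrow(ds_rev$records))), ]
  expect_identical(scan_duplicates(ds_rev, 0.99), rep)
})

test_that("exact-anchor dot plots chain identity and call constructed inversions", {
  sim <- cached_sim(807, n_ancestral = 4L)
  ds <- sim$dataset
  chr <- ds$loci$seq_name[1]
  sp <- ds$records$species[match(ds$loci$locus_id[1], ds$records$locus_id)]
  pre <- emit_chromosome(ds, sp, chr, length = 60000L, seed = 2)

  sub <- substr(pre, 20001, 50000)
  bp <- anchor_dotplot(sub, pre, word_size = 256, gap_threshold = 2000)
  expect_equal(nrow(bp$chains), 1L)
  expect_equal(nrow(bp$events), 0L)
  expect_identical(bp$chains$orientation, "+")

  # middle third reverse-complemented -> one inversion spanning it
  inv <- invert_interval(pre, 20000, 40000)
  bp2 <- anchor_dotplot(pre, inv, word_size = 256, gap_threshold = 2000,
                        expected_window = c(25000, 30000))
  invs <- bp2$events[bp2$events$type == "inversion", ]
  expect_equal(nrow(invs), 1L)
  expect_lt(abs(invs$qpos - 20000), 512)
  expect_lt(abs(invs$qend - 40000), 512)
  expect_true(bp2$flag)
  # an expected window outside the event does not flag
  bp3 <- anchor_dotplot(pre, inv, word_size = 256, gap_threshold = 2000,
                        expected_window = c(50000, 52000))
  expect_false(bp3$flag)

  # query/target swap preserves the event structure
  bp4 <- anchor_dotplot(inv, pre, word_size = 256, gap_threshold = 2000)
  expect_equal(sum(bp4$events$type == "inversion"),
               sum(bp2$events$type == "inversion"))
  expect_equal(nrow(bp4$chains), nrow(bp2$chains))

  # no shared words at all -> indeterminate flag
  set.seed(9)
  other <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
  bp5 <- anchor_dotplot(other, pre, word_size = 256)
  expect_true(is.na(bp5$flag))
})

test_that("a simulated misassembly near a gene flags its expected window", {
  sim <- cached_sim(807, n_ancestral = 4L)
  sim2 <- inject_misassembly(sim, "Ga", inversions = 1L, seed = 8)
  ev <- sim2$truth$events
  ev <- ev[ev$type == "inversion", ][1, ]
  pre <- emit_chromosome(sim$dataset, "Ga", ev$seq_name, length = 130000L,
                         seed = 2)
  iv <- c(ev$start, min(ev$end, nchar(pre)))
  post <- invert_interval(pre, iv[1], iv[2])
  bp <- anchor_dotplot(pre, post, word_size = 256, gap_threshold = 2000,
                       expected_window = iv)
  expect_true(bp$flag)
  expect_gte(sum(bp$events$type == "inversion"), 1L)
})
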