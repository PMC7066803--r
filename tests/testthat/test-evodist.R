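# site filters, percent identity, and distance corrections

test_that("partial deletion keeps exactly the columns meeting the coverage cutoff", {
  gapless <- random_nt_alignment(10, 20, seed = 1)
  expect_identical(unclass(apply_partial_deletion(gapless, site_filter(0.95))),
                   unclass(gapless))

  m <- matrix("A", 20, 10)
  m[1:2, 4] <- "-"               # coverage 0.90 at column 4
  rownames(m) <- paste0("t", 1:20)
  aln <- as_alignment(m, "aa")
  out <- apply_partial_deletion(aln, site_filter(0.95))
  expect_equal(ncol(out), 9)
  # idempotence
  expect_identical(unclass(apply_partial_deletion(out, site_filter(0.95))),
                   unclass(out))

  allgap <- as_alignment(matrix(c("A", "-"), 2, 5,
                                dimnames = list(c("a", "b"), NULL)), "aa")
  expect_error(apply_partial_deletion(allgap, site_filter(1.0)),
               "no sites survive")
})

test_that("codon-position selection is frame-anchored at column 1", {
  m <- matrix(rep(c("A", "C", "G"), 3), 2, 9, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  aln <- as_alignment(m, "nt")
  out <- select_codon_positions(aln, c(1, 2))
  expect_equal(ncol(out), 6)
  expect_identical(unclass(out)[1, ], unclass(aln)[1, c(1, 2, 4, 5, 7, 8)])
  expect_identical(unclass(select_codon_positions(aln, 1:3)), unclass(aln))
  expect_error(select_codon_positions(aln, integer(0)), "non-empty")
  bad <- as_alignment(matrix("A", 2, 8, dimnames = list(c("a", "b"), NULL)),
                      "nt")
  expect_error(select_codon_positions(bad, c(1, 2)), "divisible by 3")
})

test_that("percent identity counts matches over mutually resolved columns", {
  expect_equal(percent_identity("ACTG", "ACTG"), 100.00)
  # comparable columns {1,4}: both match
  expect_equal(percent_identity("AC-G", "A-TG"), 100.00)
  expect_equal(percent_identity("ACTG", "ACTA"), 75.00)
  expect_equal(percent_identity("ACTG", "ACTA"),
               percent_identity("ACTA", "ACTG"))
  expect_true(is.na(percent_identity("--AA", "AA--")))

  aln <- random_nt_alignment(5, 60, seed = 3, gap_prob = 0.1)
  M <- identity_matrix(aln)
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(100, 5))
})

test_that("distance corrections match their closed forms and flag saturation", {
  a <- as_alignment(c(x = strrep("A", 100),
                      y = paste0(strrep("A", 90), strrep("C", 10))),
                    level = "aa")
  expect_equal(unname(compute_distances(a, "p")["x", "y"]), 0.10)
  expect_equal(unname(compute_distances(a, "poisson")["x", "y"]),
               -log(0.9), tolerance = 1e-12)
  same <- as_alignment(c(x = "ACGTACGT", y = "ACGTACGT"), level = "nt")
  expect_equal(unname(compute_distances(same, "jc")["x", "y"]), 0)

  sat <- as_alignment(c(x = strrep("A", 20), y = strrep("C", 20)),
                      level = "nt")
  D <- compute_distances(sat, "jc")
  expect_true(is.na(D["x", "y"]))
  expect_true(attr(D, "saturated")["x", "y"])

  nt <- as_alignment(c(x = strrep("ACGT", 25),
                       y = paste0(strrep("ACGT", 20), strrep("TTTT", 5))),
                     level = "nt")
  p <- unname(compute_distances(nt, "p")["x", "y"])
  expect_equal(unname(compute_distances(nt, "jc")["x", "y"]),
               -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("corrections are monotone in p and reduce to p as p -> 0", {
  ps <- c(0.001, 0.005, 0.01)
  pois <- -log(1 - ps)
  jc <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(pois) > 0) && all(diff(jc) > 0))
  expect_equal(pois, ps, tolerance = 0.05)
  expect_equal(jc, ps, tolerance = 0.05)
  # and on actual alignments at small p
  a <- as_alignment(c(x = strrep("A", 1000),
                      y = paste0(strrep("A", 995), strrep("C", 5))),
                    level = "aa")
  expect_equal(unname(compute_distances(a, "poisson")["x", "y"]), 0.005,
               tolerance = 0.05)
})

test_that("ML distance under the Dayhoff matrix recovers a simulated distance", {
  tr <- ape::read.tree(text = "(x:0.15,y:0.15);")
  set.seed(42)
  dat <- phangorn::simSeq(tr, l = 10000, type = "AA", model = "Dayhoff")
  m <- matrix(toupper(as.character(dat)), 2,
              dimnames = list(c("x", "y"), NULL))
  aln <- as_alignment(m, "aa")
  D <- compute_distances(aln, "dayhoff_ml")
  expect_equal(unname(D["x", "y"]), 0.3, tolerance = 0.02 / 0.3)
  expect_identical(attr(D, "model_tag"), "dayhoff_ml")
  D2 <- compute_distances(aln, "jtt_ml")
  expect_true(is.finite(D2["x", "y"]) && D2["x", "y"] > 0)
})

test_that("distance matrices round-trip through the square TSV format", {
  D <- compute_distances(random_nt_alignment(4, 60, seed = 9), "p")
  path <- tempfile(fileext = ".tsv")
  write_distances(D, path)
  D2 <- read_distances(path)
  expect_equal(unclass(D)[rownames(D2), colnames(D2)], D2,
               tolerance = 1e-12, ignore_attr = TRUE)
})
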