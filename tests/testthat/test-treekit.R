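# neighbor joining, OLS/minimum evolution, parsimony, bootstrap, clans

test_that("three-taxon NJ solves the closed-form star resolution", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(lens["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(lens["C"]), (5 + 6 - 3) / 2)
})

test_that("NJ recovers additive trees exactly (topology and path lengths)", {
  for (s in 1:100) {
    n <- 4 + (s %% 5)
    tr <- random_topology(n, s)
    D <- ape::cophenetic.phylo(tr)
    nj <- build_nj(D)
    expect_equal(phangorn::RF.dist(nj, tr), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ cross-checks against an independent implementation on additive input", {
  tr <- random_topology(7, 99)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(phangorn::RF.dist(build_nj(D), ape::nj(D)), 0)
})

test_that("NJ reports the offending pairs for saturated distances", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- NA
  expect_error(build_nj(D), "a-b")
})

test_that("OLS branch lengths match a generic least-squares oracle", {
  # additive matrix: zero residual, exact lengths
  tr <- random_topology(5, 7)
  D <- ape::cophenetic.phylo(tr)
  fit <- ols_fit(tr, D)
  expect_lt(fit$rss, 1e-16)
  expect_equal(sort(fit$lengths), sort(tr$edge.length), tolerance = 1e-8)

  # non-additive 4-taxon: compare against lm() on an independently built
  # design matrix (path indicators from ape::nodepath)
  M <- random_distances(4, 11)
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  topo <- ape::unroot(topo)
  fit <- ols_fit(topo, M)
  pairs <- t(combn(topo$tip.label, 2))
  X <- matrix(0, nrow(pairs), nrow(topo$edge))
  for (k in seq_len(nrow(pairs))) {
    np <- ape::nodepath(topo, match(pairs[k, 1], topo$tip.label),
                        match(pairs[k, 2], topo$tip.label))
    for (i in seq_len(length(np) - 1)) {
      e <- which(topo$edge[, 1] == np[i] & topo$edge[, 2] == np[i + 1] |
                   topo$edge[, 2] == np[i] & topo$edge[, 1] == np[i + 1])
      X[k, e] <- 1
    }
  }
  y <- M[pairs]
  oracle <- coef(lm(y ~ X - 1))
  expect_equal(unname(fit$tree$edge.length), unname(pmax(oracle, 0)),
               tolerance = 1e-8)

  # star-like distances: internal branch collapses to zero
  S <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(S) <- 0
  sfit <- ols_fit(topo, S)
  internal <- which(topo$edge[, 2] > length(topo$tip.label))
  expect_equal(sfit$tree$edge.length[internal], 0)
})

test_that("minimum-evolution search is idle on additive input and beats/ties NJ", {
  tr <- random_topology(6, 21)
  D <- ape::cophenetic.phylo(tr)
  me <- search_me(D)
  expect_equal(phangorn::RF.dist(me, tr), 0)

  for (s in 1:20) {
    M <- random_distances(6, 4000 + s)
    nj_len <- ols_fit(build_nj(M), M)$tree_length
    me_len <- attr(search_me(M), "tree_length")
    expect_lte(me_len, nj_len + 1e-9)
  }
})

test_that("minimum evolution equals the exhaustive optimum on most small instances", {
  hits <- 0L
  for (s in 1:50) {
    M <- random_distances(6, 1000 + s)
    if (attr(search_me(M), "tree_length") <= exhaustive_me_length(M) + 1e-9)
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("ME recovers the generating topology where NJ errs (frozen instance)", {
  set.seed(352)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 0.5)
  D <- ape::cophenetic.phylo(tr)
  E <- matrix(runif(36, 0, 0.35), 6)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  dimnames(E) <- dimnames(D)
  Dp <- D + E
  expect_gt(phangorn::RF.dist(build_nj(Dp), tr), 0)
  expect_equal(phangorn::RF.dist(search_me(Dp), tr), 0)
})

test_that("Fitch scoring matches textbook counts and brute force", {
  quartet <- ape::unroot(ape::read.tree(text = "((A1,A2),(C1,C2));"))
  col <- as_alignment(matrix(c("A", "A", "C", "C"), 4, 1,
                             dimnames = list(c("A1", "A2", "C1", "C2"), NULL)),
                      "nt")
  expect_equal(fitch_score(quartet, col), 1L)
  crossed <- ape::unroot(ape::read.tree(text = "((A1,C1),(A2,C2));"))
  expect_equal(fitch_score(crossed, col), 2L)

  constant <- as_alignment(matrix("A", 4, 5,
                                  dimnames = list(c("A1", "A2", "C1", "C2"),
                                                  NULL)), "nt")
  expect_equal(fitch_score(quartet, constant), 0L)

  # independent oracle: phangorn's parsimony on random trees/alignments,
  # including gapped columns treated as missing
  for (s in 1:15) {
    set.seed(3000 + s)
    n <- 5 + (s %% 4)
    m <- matrix(sample(c("A", "C", "G", "T", "-"), n * 25, replace = TRUE,
                       prob = c(.23, .23, .23, .23, .08)), n, 25,
                dimnames = list(paste0("t", seq_len(n)), NULL))
    tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
    expect_equal(
      fitch_score(tr, as_alignment(m, "nt")),
      phangorn::parsimony(tr, phangorn::as.phyDat(m, type = "DNA")))
  }
})

test_that("parsimony search never worsens its start and usually finds the optimum", {
  hits <- 0L
  for (s in 1:50) {
    aln <- random_nt_alignment(6, 30, seed = 2000 + s)
    D <- compute_distances(aln, "p")
    start_score <- fitch_score(build_nj(D), aln)
    mp <- search_mp(aln)
    expect_lte(attr(mp, "pscore"), start_score)
    if (attr(mp, "pscore") <= exhaustive_mp_score(aln)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("clan and dichotomy queries implement unrooted sister semantics", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  expect_true(forms_clan(tr, c("a1", "a2")))
  expect_true(forms_dichotomy(tr, c("a1", "a2"), c("b1", "b2")))
  crossed <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_false(forms_dichotomy(crossed, c("a1", "a2"), c("b1", "b2")))
  expect_true(forms_clan(tr, "a1"))                  # leaf edge
  expect_true(forms_dichotomy(tr, "a1", "a2"))
  expect_false(forms_dichotomy(crossed, "a1", "a2"))
  expect_error(forms_clan(tr, "zz"), "unknown leaf")
})

test_that("bootstrap support separates clear clusters and is seed-reproducible", {
  set.seed(5)
  # two tight clusters (within-divergence ~1%, between ~100%) plus noise
  m <- matrix("A", 4, 201, dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  m[c("b1", "b2"), ] <- "C"
  idx <- sample(length(m), 60)
  m[idx] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  aln <- as_alignment(m, "nt")
  cfg <- analysis_config("NJ", "nt12", "p", bootstrap_reps = 100L, seed = 7)
  res <- bootstrap_support(aln, cfg)
  key <- paste(sort(c("b1", "b2")), collapse = "|")
  expect_gte(unname(res$support[key]), 99)

  res2 <- bootstrap_support(aln, cfg)
  expect_identical(res$support, res2$support)

  one <- analysis_config("NJ", "nt12", "p", bootstrap_reps = 1L, seed = 3)
  r1 <- bootstrap_support(aln, one)
  expect_true(all(r1$support %in% c(0, 100)))

  # permutation of input rows leaves supports unchanged
  perm <- as_alignment(unclass(aln)[c(3, 1, 4, 2), ], "nt")
  rp <- bootstrap_support(perm, cfg)
  expect_equal(rp$support[names(res$support)], res$support)
})
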