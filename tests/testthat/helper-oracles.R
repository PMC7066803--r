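# shared fixtures and independent oracles for the tree/search tests

# random unrooted topology with fresh branch lengths
random_topology <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  tr
}

# random symmetric non-additive distance matrix
random_distances <- function(n, seed, lo = 0.2, hi = 1.2) {
  set.seed(seed)
  M <- matrix(runif(n * n, lo, hi), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(letters[seq_len(n)], letters[seq_len(n)])
  M
}

random_nt_alignment <- function(n, L, seed, gap_prob = 0) {
  set.seed(seed)
  states <- c("A", "C", "G", "T")
  prob <- rep((1 - gap_prob) / 4, 4)
  if (gap_prob > 0) { states <- c(states, "-"); prob <- c(prob, gap_prob) }
  m <- matrix(sample(states, n * L, replace = TRUE, prob = prob), n, L,
              dimnames = list(letters[seq_len(n)], NULL))
  as_alignment(m, "nt")
}

# exhaustive minimum-evolution optimum over all topologies (n small)
exhaustive_me_length <- function(D) {
  tips <- rownames(D)
  all_t <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  min(vapply(all_t, function(t) ols_fit(t, D)$tree_length, 1))
}

exhaustive_mp_score <- function(aln) {
  tips <- rownames(aln)
  all_t <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  min(vapply(all_t, function(t) fitch_score(t, aln), 1L))
}

# memoised simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, n_ancestral = 6L, ...) {
  key <- paste(c(seed, n_ancestral, unlist(list(...))), collapse = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_family(
      simulation_config(n_ancestral = n_ancestral, seed = seed, ...))
  .sim_cache[[key]]
}

# the reduced analysis grid used for parameter-recovery experiments
recovery_grid <- function() {
  list(
    analysis_config("NJ", "aa", "poisson", 0, 1),
    analysis_config("NJ", "aa", "dayhoff_ml", 0, 2),
    analysis_config("NJ", "aa", "jtt_ml", 0, 3),
    analysis_config("NJ", "nt12", "p", 0, 4),
    analysis_config("NJ", "nt12", "jc", 0, 5),
    analysis_config("MP", "aa", NULL, 0, 6),
    analysis_config("MP", "nt12", NULL, 0, 7)
  )
}

mammal_codes <- c("Hs", "Md")

reference_groups_of <- function(truth) {
  mam <- truth[truth$species %in% mammal_codes, , drop = FALSE]
  split(mam$id, mam$orthogroup)
}

teleost_ids_of <- function(truth)
  truth$id[!(truth$species %in% mammal_codes)]
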