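# Tree reconstruction and clade queries.  Trees are ape "phylo" objects,
# reasoned about with unrooted semantics throughout: a "clan" is one side of
# an edge, and a dichotomy is a pair of sister clans.

# ---------------------------------------------------------------------------
# Neighbor joining
# ---------------------------------------------------------------------------

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Q-criterion.  Ties in Q are broken by
#' the lexicographically smallest pair of cluster ids (a cluster is labelled
#' by the smallest leaf id it contains), so the result is deterministic.
#' Negative branch lengths are clamped to zero.
#'
#' @param D Symmetric distance matrix with ids as dimnames and finite
#'   entries.
#' @return An unrooted `phylo` tree.
#' @export
build_nj <- function(D) {
  D <- as.matrix(D)
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(D) || any(!is.finite(D))) {
    idx <- which(is.na(D) | !is.finite(D), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    stop("saturated/missing distances for pairs: ",
         paste(paste(ids[idx[, 1L]], ids[idx[, 2L]], sep = "-"),
               collapse = ", "))
  }

  lab <- ids            # newick fragment per active cluster
  key <- ids            # smallest leaf id per cluster (tie-break key)
  act <- seq_len(n)
  Dm <- D
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    k <- key[act]
    pk <- cbind(pmin(k[cand[, 1L]], k[cand[, 2L]]),
                pmax(k[cand[, 1L]], k[cand[, 2L]]))
    ord <- order(pk[, 1L], pk[, 2L])
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    ai <- act[i]; aj <- act[j]
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", lab[ai], max(li, 0),
                      lab[aj], max(lj, 0))
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lab[ai] <- newlab
    key[ai] <- min(key[ai], key[aj])
    act <- c(act[keep], ai)
  }
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  la <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  lb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  lc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 lab[a], max(la, 0), lab[b], max(lb, 0), lab[c3], max(lc, 0))
  tr <- ape::read.tree(text = nwk)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# ---------------------------------------------------------------------------
# OLS branch lengths / minimum evolution
# ---------------------------------------------------------------------------

# tip-set indicator per edge (rows = edges, cols = tips)
edge_tip_sets <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  po <- ape::postorder(phy)
  for (e in po) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  below[phy$edge[, 2L], , drop = FALSE]
}

#' Ordinary-least-squares branch lengths for a fixed topology
#'
#' Fits unweighted OLS branch lengths to a distance matrix on a given
#' topology; negative estimates are clamped to zero after fitting, and the
#' tree length is the sum of the clamped lengths (the minimum-evolution
#' objective).
#'
#' @param phy `phylo` topology spanning the taxa of `D`.
#' @param D Distance matrix.
#' @return List with `tree` (lengths attached), `lengths`, `tree_length`,
#'   `rss` (residual sum of squares of the unclamped fit).
#' @export
ols_fit <- function(phy, D) {
  D <- as.matrix(D)
  tips <- phy$tip.label
  stopifnot(all(tips %in% rownames(D)))
  D <- D[tips, tips]
  nt <- length(tips)
  sets <- edge_tip_sets(phy)                     # edges x tips
  pr <- which(lower.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  d <- D[pr]
  # A[pair, edge] = 1 iff edge lies on the path between the pair
  A <- matrix(0, nrow(pr), nrow(sets))
  for (e in seq_len(nrow(sets))) {
    s <- sets[e, ]
    A[, e] <- as.numeric(xor(s[pr[, 1L]], s[pr[, 2L]]))
  }
  fit <- lm.fit(A, d)
  b <- fit$coefficients
  if (anyNA(b)) {
    warning("singular OLS design; unresolved branch lengths set to 0")
    b[is.na(b)] <- 0
  }
  res <- d - A %*% b
  bl <- pmax(b, 0)
  phy$edge.length <- unname(bl)
  list(tree = phy, lengths = unname(bl), tree_length = sum(bl),
       rss = sum(res^2))
}

nni_neighbors <- function(phy) {
  # deterministic order from phangorn::nni
  trs <- phangorn::nni(phy)
  lapply(trs, function(t) { t$edge.length <- NULL; t })
}

#' Minimum-evolution tree search
#'
#' Hill-climb over nearest-neighbor-interchange moves from a start tree
#' (default the NJ tree), accepting the first move that strictly decreases
#' the OLS tree length, until a local optimum is reached.
#'
#' @param D Distance matrix.
#' @param start Optional starting `phylo` topology (default `build_nj(D)`).
#' @param max_sweeps Safety cap on full NNI sweeps.
#' @return The locally optimal tree with OLS branch lengths, with the tree
#'   length in attribute `tree_length`.
#' @export
search_me <- function(D, start = NULL, max_sweeps = 50L) {
  if (is.null(start)) start <- build_nj(D)
  cur <- ape::unroot(start)
  cur_fit <- ols_fit(cur, D)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (nb in nni_neighbors(cur)) {
      f <- ols_fit(nb, D)
      if (f$tree_length < cur_fit$tree_length - 1e-10) {
        cur <- nb; cur_fit <- f; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  out <- cur_fit$tree
  attr(out, "tree_length") <- cur_fit$tree_length
  out
}

# ---------------------------------------------------------------------------
# Parsimony
# ---------------------------------------------------------------------------

aln_state_masks <- function(aln) {
  m <- unclass(aln)
  states <- setdiff(sort(unique(as.vector(m))), AMBIG)
  if (length(states) > 30L) stop("too many states for bitmask parsimony")
  full <- bitwShiftL(1L, length(states)) - 1L
  code <- setNames(bitwShiftL(1L, seq_along(states) - 1L), states)
  masks <- matrix(full, nrow(m), ncol(m), dimnames = dimnames(m))
  known <- m %in% states
  masks[known] <- code[m[known]]
  masks
}

#' Fitch parsimony score of a topology
#'
#' Small-parsimony substitution count summed over columns; gaps and
#' ambiguities are treated as missing (they never force a change).
#'
#' @param phy `phylo` topology.
#' @param aln Alignment over the tree's tips.
#' @return Integer score.
#' @export
fitch_score <- function(phy, aln) {
  fitch_on_masks(phy, aln_state_masks(aln))
}

# sequential Fitch over a (possibly trifurcating-root) phylo; for up to
# three children the sequential intersection/union count equals the
# minimal (Hartigan) count, so no explicit binary re-rooting is needed
fitch_on_masks <- function(phy, masks) {
  tips <- phy$tip.label
  stopifnot(all(tips %in% rownames(masks)))
  nt <- length(tips)
  nn <- nt + phy$Nnode
  node_mask <- matrix(0L, nn, ncol(masks))
  node_mask[seq_len(nt), ] <- masks[tips, , drop = FALSE]
  seen <- integer(nn)
  score <- 0L
  po <- ape::postorder(phy)
  for (e in po) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    if (seen[p] == 0L) {
      node_mask[p, ] <- node_mask[ch, ]
    } else {
      inter <- bitwAnd(node_mask[p, ], node_mask[ch, ])
      zero <- inter == 0L
      score <- score + sum(zero)
      inter[zero] <- bitwOr(node_mask[p, zero], node_mask[ch, zero])
      node_mask[p, ] <- inter
    }
    seen[p] <- seen[p] + 1L
  }
  score
}

#' Maximum-parsimony tree search
#'
#' NNI hill-climb minimizing the Fitch score, first-improving move in the
#' fixed neighbor order, from a start tree (default: NJ on p-distances).
#' On small taxon sets the NNI landscape is proportionally rugged, so the
#' climb is repeated from seeded random starting topologies and the best
#' local optimum returned; large alignments carry enough signal that the
#' single NJ-start climb is used.
#'
#' @param aln Alignment.
#' @param start Optional starting topology.
#' @param max_sweeps Safety cap on sweeps per climb.
#' @param restarts Extra climbs from random (seeded) topologies; default 4
#'   for <= 12 taxa, 0 otherwise.
#' @param seed Seed for the restart topologies.
#' @return The locally optimal `phylo` (no branch lengths), Fitch score in
#'   attribute `pscore`.
#' @export
search_mp <- function(aln, start = NULL, max_sweeps = 50L,
                      restarts = NULL, seed = 1L) {
  if (is.null(start)) {
    D <- compute_distances(aln, "p")
    D[is.na(D)] <- max(D, na.rm = TRUE) * 1.5 + 0.5
    start <- build_nj(D)
  }
  if (is.null(restarts)) restarts <- if (nrow(aln) <= 12L) 4L else 0L
  masks <- aln_state_masks(aln)
  climb <- function(tree0) {
    cur <- ape::unroot(tree0)
    cur$edge.length <- NULL
    cur_s <- fitch_on_masks(cur, masks)
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (nb in nni_neighbors(cur)) {
        s <- fitch_on_masks(nb, masks)
        if (s < cur_s) { cur <- nb; cur_s <- s; improved <- TRUE; break }
      }
      if (!improved) break
    }
    attr(cur, "pscore") <- cur_s
    cur
  }
  best <- climb(start)
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      t0 <- ape::rtree(nrow(aln), tip.label = sample(rownames(aln)))
      cand <- climb(t0)
      if (attr(cand, "pscore") < attr(best, "pscore")) best <- cand
    }
  }
  best
}

# ---------------------------------------------------------------------------
# Bipartitions, clans, dichotomies
# ---------------------------------------------------------------------------

#' Non-trivial bipartitions of a tree, canonically encoded
#'
#' Each internal edge splits the leaves in two; the encoding is the sorted
#' id list of the side *not* containing the alphabetically smallest leaf,
#' joined with `"|"`.
#'
#' @param phy `phylo`.
#' @return Character vector of canonical bipartition keys.
#' @export
tree_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  sets <- edge_tip_sets(phy)
  keys <- character(0)
  for (e in seq_len(nrow(sets))) {
    s <- tips[sets[e, ]]
    if (length(s) < 2L || length(s) > length(tips) - 2L) next
    if (ref %in% s) s <- setdiff(tips, s)
    keys <- c(keys, paste(sort(s), collapse = "|"))
  }
  unique(keys)
}

clan_key <- function(taxa, tips) {
  ref <- sort(tips)[1L]
  if (ref %in% taxa) taxa <- setdiff(tips, taxa)
  paste(sort(taxa), collapse = "|")
}

#' Is a taxon set a clan of the tree?
#'
#' A clan is one side of some edge of the unrooted tree (the unrooted
#' analogue of monophyly).  Singletons and sets covering all but at most one
#' leaf are trivially clans.
#'
#' @param phy `phylo`.
#' @param taxa Character vector of leaf ids.
#' @return Logical.
#' @export
forms_clan <- function(phy, taxa) {
  tips <- phy$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown))
    stop("unknown leaf: ", paste(unknown, collapse = ", "))
  taxa <- unique(taxa)
  if (length(taxa) <= 1L || length(taxa) >= length(tips) - 1L) return(TRUE)
  clan_key(taxa, tips) %in% tree_bipartitions(phy)
}

#' Are two taxon sets sister clans (a dichotomy)?
#'
#' True iff `setA`, `setB` and their union are each clans, i.e. the two sets
#' are each other's closest relatives in the unrooted tree.
#'
#' @param phy `phylo`.
#' @param setA,setB Disjoint leaf-id sets.
#' @return Logical.
#' @export
forms_dichotomy <- function(phy, setA, setB) {
  if (length(intersect(setA, setB)))
    stop("setA and setB must be disjoint")
  forms_clan(phy, setA) && forms_clan(phy, setB) &&
    forms_clan(phy, union(setA, setB))
}

# ---------------------------------------------------------------------------
# Bootstrap
# ---------------------------------------------------------------------------

#' Bootstrap clade support for one analysis configuration
#'
#' Resamples alignment columns with replacement (seeded), rebuilds the tree
#' per replicate with the configured method, and scores every bipartition of
#' the point tree by the percentage of replicate trees containing it.
#' Replicates whose distance matrix is degenerate are skipped with a warning
#' but still counted in the denominator.
#'
#' @param aln Nucleotide codon alignment (the analysis level and filters are
#'   taken from `cfg`).
#' @param cfg An [analysis_config()] with `bootstrap_reps >= 1`.
#' @return A list of class `analysis_result`: `config`, `tree` (the point
#'   tree), `support` (named percentage vector keyed by canonical
#'   bipartition), `n_reps`, `n_failed`.
#' @export
bootstrap_support <- function(aln, cfg) {
  stopifnot(cfg$bootstrap_reps >= 1L)
  prepared <- prepare_level(aln, cfg)
  point <- infer_tree_prepared(prepared, cfg)
  keys <- tree_bipartitions(point)
  counts <- setNames(numeric(length(keys)), keys)
  all_counts <- list()
  failed <- 0L
  set.seed(cfg$seed)
  L <- ncol(prepared)
  for (r in seq_len(cfg$bootstrap_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_aln <- as_alignment(unclass(prepared)[, idx, drop = FALSE],
                            level = aln_level(prepared))
    tr <- tryCatch(infer_tree_prepared(rep_aln, cfg), error = function(e) NULL)
    if (is.null(tr)) { failed <- failed + 1L; next }
    bp <- tree_bipartitions(tr)
    hit <- keys %in% bp
    counts[hit] <- counts[hit] + 1
    for (k in bp) all_counts[[k]] <- (all_counts[[k]] %||% 0) + 1
  }
  if (failed > 0L)
    warning(failed, " bootstrap replicate(s) failed and were skipped")
  support <- 100 * counts / cfg$bootstrap_reps
  structure(list(config = cfg, tree = point, support = support,
                 replicate_bipartitions =
                   100 * unlist(all_counts) / cfg$bootstrap_reps,
                 n_reps = cfg$bootstrap_reps, n_failed = failed),
            class = "analysis_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
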