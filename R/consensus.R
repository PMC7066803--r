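# The analysis grid (method x level x model) and the consensus
# classification of orthologous groups across analyses.

#' One cell of the analysis grid
#'
#' @param method `"NJ"`, `"ME"` or `"MP"`.
#' @param level `"aa"` (translated conserved domains) or `"nt12"` (codon
#'   positions 1 and 2).
#' @param model Distance model tag (see [compute_distances()]); ignored for
#'   `"MP"`.  `nt12` admits only the nucleotide models `p` and `jc`.
#' @param bootstrap_reps Bootstrap replicates (default 500; 0 = point tree
#'   only).
#' @param seed Integer seed for any resampling.
#' @param filter A [site_filter()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(method = c("NJ", "ME", "MP"),
                            level = c("aa", "nt12"),
                            model = NULL,
                            bootstrap_reps = 500L,
                            seed = 1L,
                            filter = site_filter()) {
  method <- match.arg(method)
  level <- match.arg(level)
  if (method != "MP") {
    if (is.null(model)) stop("distance methods need a model")
    aa_models <- c("p", "poisson", "dayhoff_ml", "jtt_ml")
    nt_models <- c("p", "jc")
    ok <- if (level == "aa") model %in% aa_models else model %in% nt_models
    if (!ok)
      stop("model '", model, "' is not valid at level '", level, "'")
  } else model <- NA_character_
  stopifnot(bootstrap_reps >= 0L)
  structure(list(method = method, level = level, model = model,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), filter = filter),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("analysis_config: %s / %s%s (coverage %.2f, %d bootstrap)\n",
              x$method, x$level,
              if (is.na(x$model)) "" else paste0(" / ", x$model),
              x$filter$coverage_cutoff, x$bootstrap_reps))
  invisible(x)
}

# level conversion + site filtering for one config
prepare_level <- function(aln, cfg) {
  stopifnot(aln_level(aln) == "nt")
  if (cfg$level == "aa") {
    out <- translate_alignment(aln)
  } else {
    out <- select_codon_positions(aln, cfg$filter$codon_positions)
  }
  apply_partial_deletion(out, cfg$filter)
}

# tree inference on an already level-converted, filtered alignment
infer_tree_prepared <- function(prepared, cfg) {
  if (cfg$method == "MP") return(search_mp(prepared))
  D <- compute_distances(prepared, cfg$model)
  if (anyNA(D)) stop("degenerate distance matrix (saturated entries)")
  if (cfg$method == "NJ") build_nj(D) else search_me(D)
}

#' Infer the tree for one analysis configuration
#'
#' @param aln Nucleotide codon alignment of the conserved domains.
#' @param cfg An [analysis_config()].
#' @return An `analysis_result` (with bootstrap support if
#'   `bootstrap_reps > 0`).
#' @export
run_analysis <- function(aln, cfg) {
  if (cfg$bootstrap_reps > 0L) return(bootstrap_support(aln, cfg))
  prepared <- prepare_level(aln, cfg)
  structure(list(config = cfg, tree = infer_tree_prepared(prepared, cfg),
                 support = NULL, n_reps = 0L, n_failed = 0L),
            class = "analysis_result")
}

#' The default 21-analysis grid
#'
#' Neighbor-joining and minimum-evolution at both levels under several
#' substitution models, maximum parsimony at both levels, and a
#' complete-deletion (coverage 1.0) wing — 21 analyses in total.  The
#' conclusions of the pipeline rest on consensus across this grid, not on
#' any single cell.
#'
#' @param bootstrap_reps Bootstrap replicates per cell (default 0: the grid
#'   is used for cross-analysis consensus, with bootstrap run separately
#'   where wanted).
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @return List of 21 [analysis_config()] objects.
#' @export
default_grid <- function(bootstrap_reps = 0L, seed = 1L) {
  partial <- site_filter(0.95)
  complete <- site_filter(1.00)
  cells <- list(
    list("NJ", "aa", "poisson", partial),
    list("NJ", "aa", "dayhoff_ml", partial),
    list("NJ", "aa", "jtt_ml", partial),
    list("NJ", "nt12", "p", partial),
    list("NJ", "nt12", "jc", partial),
    list("ME", "aa", "poisson", partial),
    list("ME", "aa", "dayhoff_ml", partial),
    list("ME", "aa", "jtt_ml", partial),
    list("ME", "nt12", "p", partial),
    list("ME", "nt12", "jc", partial),
    list("MP", "aa", NULL, partial),
    list("MP", "nt12", NULL, partial),
    list("NJ", "aa", "poisson", complete),
    list("NJ", "aa", "dayhoff_ml", complete),
    list("NJ", "aa", "jtt_ml", complete),
    list("NJ", "nt12", "jc", complete),
    list("ME", "aa", "dayhoff_ml", complete),
    list("ME", "aa", "jtt_ml", complete),
    list("ME", "nt12", "jc", complete),
    list("MP", "aa", NULL, complete),
    list("MP", "nt12", NULL, complete)
  )
  lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    analysis_config(method = cl[[1L]], level = cl[[2L]], model = cl[[3L]],
                    bootstrap_reps = bootstrap_reps, seed = seed + i,
                    filter = cl[[4L]])
  })
}

#' Run a grid of analyses
#'
#' Excluded taxa (configured long-branch cases) are dropped from the
#' alignment first.  Per-cell failures are recorded without aborting the
#' grid.
#'
#' @param aln Nucleotide codon alignment.
#' @param configs List of [analysis_config()]s.
#' @param exclude Leaf ids to drop before analysis (e.g.
#'   `dataset$excluded_ids`).
#' @return List of `analysis_result`s; failed cells carry `$error` instead
#'   of `$tree`.
#' @export
run_grid <- function(aln, configs, exclude = character()) {
  stopifnot(length(configs) >= 1L)
  if (length(exclude)) {
    keep <- setdiff(rownames(aln), exclude)
    aln <- as_alignment(unclass(aln)[keep, , drop = FALSE],
                        level = aln_level(aln))
  }
  out <- lapply(configs, function(cfg) {
    tryCatch(run_analysis(aln, cfg), error = function(e)
      structure(list(config = cfg, tree = NULL, support = NULL,
                     error = conditionMessage(e)),
                class = "analysis_result"))
  })
  if (all(vapply(out, function(r) is.null(r$tree), TRUE)))
    stop("all grid cells failed; first error: ", out[[1L]]$error)
  out
}

# ---------------------------------------------------------------------------
# Support tallies
# ---------------------------------------------------------------------------

#' Define a clan or dichotomy query
#'
#' @param name Query label.
#' @param relation `"clan"` or `"dichotomy"`.
#' @param taxa Leaf ids (for clan queries).
#' @param setA,setB Leaf-id sets (for dichotomy queries).
#' @return A list of class `support_query`.
#' @export
support_query <- function(name, relation = c("clan", "dichotomy"),
                          taxa = NULL, setA = NULL, setB = NULL) {
  relation <- match.arg(relation)
  if (relation == "clan") stopifnot(length(taxa) >= 1L)
  else stopifnot(length(setA) >= 1L, length(setB) >= 1L)
  structure(list(name = name, relation = relation, taxa = taxa,
                 setA = setA, setB = setB), class = "support_query")
}

#' Tally how many analyses support each query
#'
#' A query is deemed robust when supported by a strict majority of the
#' analyses that produced a tree (k/n > 0.5): the curation protocol treats
#' "all, or most" agreeing analyses as robust and never endorses a minority
#' call, so 14/21 is robust and 10/20 is not.
#'
#' @param results List of `analysis_result`s (cells with errors are ignored
#'   and do not count towards n).
#' @param queries List of [support_query()]s.
#' @return data.frame with columns `query`, `relation`, `k`, `n`, `robust`.
#' @export
tally <- function(results, queries) {
  trees <- Filter(Negate(is.null), lapply(results, `[[`, "tree"))
  n <- length(trees)
  rows <- lapply(queries, function(q) {
    k <- sum(vapply(trees, function(tr) {
      present <- all(c(q$taxa, q$setA, q$setB) %in% tr$tip.label)
      if (!present) return(FALSE)
      if (q$relation == "clan") forms_clan(tr, q$taxa)
      else forms_dichotomy(tr, q$setA, q$setB)
    }, TRUE))
    data.frame(query = q$name, relation = q$relation, k = k, n = n,
               robust = k / n > 0.5, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a tally table as TSV
#' @param tl Result of [tally()].
#' @param path Output path.
#' @export
write_tally <- function(tl, path) {
  write.table(tl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tl)
}

# ---------------------------------------------------------------------------
# Orthogroup assignment
# ---------------------------------------------------------------------------

#' Assign genes to orthologous groups by cross-analysis majority vote
#'
#' For each tree, a focal (teleost) gene `g` carries a maximal
#' reference-free clan M(g): the largest clan containing `g` but no
#' reference gene.  The gene votes for reference group R when M(g) and R
#' together form a clan — i.e. the gene's teleost context is the sister of
#' that mammalian group, the way group membership is read off a tree — and
#' for the smallest such union when groups are nested.  Analyses whose
#' tree does not resolve the gene's attachment abstain; the final label is
#' the majority (> 0.5) of the cast votes, with a two-vote quorum.  Genes
#' with split votes are reported unassigned.  Genes whose context attaches
#' to no reference
#' group are clustered into teleost-only (novel) groups: two of them share
#' a novel group when they fall in the same reference-free clan in more
#' than half of the trees.
#'
#' @param results List of `analysis_result`s.
#' @param reference_groups Named list: group label -> mammalian gene ids.
#' @param focal_ids The gene ids to classify (e.g. all teleost genes).
#' @return List with `assignment` (named character vector, novel groups
#'   labelled `"novel:<k>"`), `unassigned`, and `votes` (the per-gene vote
#'   tables).
#' @export
assign_orthogroups <- function(results, reference_groups, focal_ids) {
  stopifnot(length(reference_groups) >= 1L,
            all(vapply(reference_groups, length, 1L) >= 1L))
  trees <- Filter(Negate(is.null), lapply(results, `[[`, "tree"))
  n <- length(trees)
  votes <- matrix(NA_character_, length(focal_ids), n,
                  dimnames = list(focal_ids, NULL))
  # per tree: also record reference-free clan membership of each focal gene
  free_clan <- matrix(NA_character_, length(focal_ids), n,
                      dimnames = list(focal_ids, NULL))
  for (t in seq_len(n)) {
    tr <- trees[[t]]
    tips <- tr$tip.label
    present <- intersect(focal_ids, tips)
    sets <- edge_tip_sets(tr)                      # edges x tips (child side)
    sz <- rowSums(sets)
    nt <- length(tips)
    Gm <- vapply(reference_groups,
                 function(ids) as.numeric(tips %in% ids),
                 numeric(length(tips)))            # tips x groups
    Cc <- sets %*% Gm                              # group counts, child side
    totK <- colSums(Gm)
    ref_child <- rowSums(Cc)
    tot_ref <- sum(totK)
    # canonical keys of every clan (side of an edge) in this tree
    side_keys <- unique(unlist(lapply(seq_len(nrow(sets)), function(e)
      clan_key(tips[sets[e, ]], tips))))
    for (g in present) {
      gi <- match(g, tips)
      # M(g): largest clan containing g but no reference gene
      ing <- sets[, gi]
      fsize1 <- ifelse(ing & ref_child == 0, sz, -Inf)
      fsize0 <- ifelse(!ing & (tot_ref - ref_child) == 0, nt - sz, -Inf)
      M <- if (max(fsize1) >= max(fsize0)) tips[sets[which.max(fsize1), ]]
      else tips[!sets[which.max(fsize0), ]]
      free_clan[g, t] <- paste(sort(intersect(M, focal_ids)),
                               collapse = "|")
      # vote: the group whose members form a clan together with M(g)
      cand_size <- vapply(seq_along(reference_groups), function(k) {
        u <- union(M, reference_groups[[k]])
        u <- intersect(u, tips)
        if (length(u) >= nt) return(Inf)
        if (clan_key(u, tips) %in% side_keys) length(u) else Inf
      }, 1)
      if (any(is.finite(cand_size))) {
        best <- which(cand_size == min(cand_size))
        if (length(best) == 1L)
          votes[g, t] <- names(reference_groups)[best]
      } else if (length(M) == 1L) {
        # lone rogue gene: read it off the smallest enclosing clan holding
        # exactly one reference group (it is no teleost-only clade)
        size1 <- ifelse(ing & ref_child > 0, sz, Inf)
        size0 <- ifelse(!ing & (tot_ref - ref_child) > 0, nt - sz, Inf)
        if (is.finite(min(size1, size0))) {
          cnt <- if (min(size1) <= min(size0)) Cc[which.min(size1), ]
          else totK - Cc[which.min(size0), ]
          if (sum(cnt > 0) == 1L)
            votes[g, t] <- names(reference_groups)[which(cnt > 0)]
        }
      }
    }
  }
  assignment <- setNames(rep(NA_character_, length(focal_ids)), focal_ids)
  for (g in focal_ids) {
    v <- votes[g, ]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next      # quorum: abstaining trees do not count
    tab <- table(v)
    top <- names(tab)[which.max(tab)]
    if (max(tab) / length(v) > 0.5) assignment[g] <- top
  }
  unassigned <- names(assignment)[is.na(assignment)]
  # cluster into novel teleost-only groups: only genes that never attached
  # to any reference (split-vote genes stay unassigned)
  zero_vote <- unassigned[rowSums(!is.na(votes[unassigned, , drop = FALSE])) == 0L]
  if (length(zero_vote) > 1L) {
    pairs <- combn(zero_vote, 2L)
    adj <- matrix(FALSE, length(zero_vote), length(zero_vote),
                  dimnames = list(zero_vote, zero_vote))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      same <- sum(!is.na(free_clan[a, ]) & !is.na(free_clan[b, ]) &
                    free_clan[a, ] == free_clan[b, ])
      if (same / n > 0.5) adj[a, b] <- adj[b, a] <- TRUE
    }
    comp <- connected_components(adj)
    for (i in seq_along(comp)) {
      if (length(comp[[i]]) >= 2L)
        assignment[comp[[i]]] <- paste0("novel:", i)
    }
  }
  list(assignment = assignment,
       unassigned = names(assignment)[is.na(assignment)],
       votes = votes)
}

connected_components <- function(adj) {
  nodes <- rownames(adj)
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    stack <- v; comp <- character(0)
    while (length(stack)) {
      u <- stack[1L]; stack <- stack[-1L]
      if (seen[u]) next
      seen[u] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, nodes[adj[u, ]][!seen[nodes[adj[u, ]]]])
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

#' Export an orthogroup assignment as TSV
#' @param asg Result of [assign_orthogroups()].
#' @param path Output path.
#' @export
write_orthogroups <- function(asg, path) {
  df <- data.frame(gene_id = names(asg$assignment),
                   group = unname(asg$assignment),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(asg)
}
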