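# Assembly quality screening: missing expected genes, artifactual
# near-identical duplicates, and exact-match dot-plot breakpoint scanning.

#' Expected gene complement per orthogroup
#'
#' The expected copy count of an orthogroup in a target species/assembly is
#' the mode of its copy counts across the other species or assemblies in
#' the matrix; ties are resolved towards the maximum and flagged
#' low-confidence.
#'
#' @param lm A `locus_matrix` whose `species` column distinguishes the
#'   assemblies being compared.
#' @param target_species The assembly to screen (excluded from the mode).
#' @return data.frame of class `expected_complement` with columns
#'   `orthogroup`, `expected`, `low_confidence`, `provenance`.
#' @export
expected_complement <- function(lm, target_species) {
  others <- setdiff(unique(lm$species), target_species)
  if (length(others) < 2L)
    stop("need at least 2 non-target species/assemblies")
  ogs <- sort(unique(lm$orthogroup))
  if (!length(ogs)) stop("empty locus matrix")
  rows <- lapply(ogs, function(og) {
    cnt <- vapply(others, function(sp)
      sum(lm$orthogroup == og & lm$species == sp), 1L)
    tab <- table(cnt)
    top <- as.integer(names(tab)[tab == max(tab)])
    data.frame(orthogroup = og, expected = max(top),
               low_confidence = length(top) > 1L,
               provenance = paste(others[cnt == max(top)], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("expected_complement", "data.frame")
  out
}

#' Report genes missing from an assembly
#'
#' Compares the observed per-orthogroup copy counts of one assembly against
#' the expected complement; each shortfall is a finding, annotated with the
#' chromosome(s) where the missing gene was expected, read from the synteny
#' matrix (the plurality chromosome of the orthogroup in the corroborating
#' assemblies of the same species if present, else across species).
#'
#' @param assembly_genes data.frame with columns `orthogroup` (one row per
#'   observed gene copy) for the screened assembly.
#' @param expected An [expected_complement()].
#' @param synteny Optional `locus_matrix` used to annotate expected
#'   chromosomes (its `species` column names the corroborating assemblies).
#' @return data.frame of class `missing_gene_report` with columns
#'   `orthogroup`, `expected`, `observed`, `expected_chr`, `corroborating`.
#' @export
find_missing <- function(assembly_genes, expected, synteny = NULL) {
  obs <- table(assembly_genes$orthogroup)
  rows <- list()
  for (i in seq_len(nrow(expected))) {
    og <- expected$orthogroup[i]
    o <- if (og %in% names(obs)) as.integer(obs[[og]]) else 0L
    e <- expected$expected[i]
    if (o >= e) next
    exp_chr <- ""
    corrob <- expected$provenance[i]
    if (!is.null(synteny)) {
      s <- synteny[synteny$orthogroup == og & is_placed(synteny$seq_name), ,
                   drop = FALSE]
      if (nrow(s)) {
        tab <- sort(table(s$seq_name), decreasing = TRUE)
        exp_chr <- paste(names(tab)[seq_len(min(2L, length(tab)))],
                         collapse = ",")
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup = og, expected = e, observed = o,
      expected_chr = exp_chr, corroborating = corrob,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(orthogroup = character(), expected = integer(),
                  observed = integer(), expected_chr = character(),
                  corroborating = character(), stringsAsFactors = FALSE)
  class(out) <- c("missing_gene_report", "data.frame")
  out
}

cds_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    pa <- strsplit(a, "")[[1L]]; pb <- strsplit(b, "")[[1L]]
    return(sum(pa == pb) / length(pa))
  }
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::pid(al) / 100
}

#' Scan for artifactual near-identical duplicates
#'
#' Groups same-species records whose CDS identity reaches the threshold.
#' A group is a likely assembly artifact when its copies share a scaffold,
#' or when another assembly of the same species collapses them to a single
#' locus; otherwise the duplication is reported as plausible biology.
#'
#' @param ds A [family_dataset()].
#' @param identity_threshold Fraction in (0.9, 1]; default 0.99 covers the
#'   "identical" and "nearly identical" cases alike.
#' @param collapsed_elsewhere Optional character vector of orthogroup or
#'   gene ids known to be single-copy in another assembly of the same
#'   species (forces `likely_artifact`).
#' @return data.frame of class `duplicate_artifact_report` with columns
#'   `species`, `gene_ids`, `identity`, `seq_names`, `verdict`.
#' @export
scan_duplicates <- function(ds, identity_threshold = 0.99,
                            collapsed_elsewhere = character()) {
  stopifnot(identity_threshold > 0.9, identity_threshold <= 1)
  rec <- ds$records[order(ds$records$id), , drop = FALSE]
  rows <- list()
  for (sp in sort(unique(rec$species))) {
    sub <- rec[rec$species == sp, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    adj <- matrix(FALSE, n, n, dimnames = list(sub$id, sub$id))
    idm <- matrix(NA_real_, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      pid <- cds_identity(sub$cds[i], sub$cds[j])
      idm[i, j] <- idm[j, i] <- pid
      if (pid >= identity_threshold) adj[i, j] <- adj[j, i] <- TRUE
    }
    if (!any(adj)) next
    comps <- connected_components(adj)
    for (comp in comps) {
      if (length(comp) < 2L) next
      ii <- match(comp, sub$id)
      seqn <- ds$loci$seq_name[match(sub$locus_id[ii], ds$loci$locus_id)]
      seqn[is.na(seqn)] <- "?"
      shared <- any(duplicated(seqn[seqn != "?"]))
      collapsed <- any(comp %in% collapsed_elsewhere)
      verdict <- if (shared || collapsed) "likely_artifact"
      else "plausible_biology"
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, gene_ids = paste(comp, collapse = ","),
        identity = round(min(idm[ii, ii], na.rm = TRUE), 4),
        seq_names = paste(unique(seqn), collapse = ","),
        verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(species = character(), gene_ids = character(),
                  identity = numeric(), seq_names = character(),
                  verdict = character(), stringsAsFactors = FALSE)
  class(out) <- c("duplicate_artifact_report", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Exact-match anchor dot plot
# ---------------------------------------------------------------------------

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exact matches of non-overlapping query words in target (one strand);
# returns 0-based query/target offsets of word-sized anchors
word_anchors <- function(query, target, word_size) {
  starts <- seq(1L, nchar(query) - word_size + 1L, by = word_size)
  words <- substring(query, starts, starts + word_size - 1L)
  keep <- !grepl("[^ACGT]", words)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(words[keep]))
  hits <- Biostrings::matchPDict(dict, Biostrings::DNAString(target))
  qs <- integer(0); ts <- integer(0)
  hkeep <- which(keep)
  for (k in seq_along(hits)) {
    st <- Biostrings::startIndex(hits)[[k]]
    if (is.null(st) || !length(st)) next
    qs <- c(qs, rep(starts[hkeep[k]] - 1L, length(st)))
    ts <- c(ts, st - 1L)
  }
  data.frame(qstart = qs, tstart = ts)
}

merge_run <- function(df, word_size, orientation) {
  # merge word anchors on the same diagonal into maximal runs
  if (!nrow(df)) return(NULL)
  diag <- if (orientation == "+") df$tstart - df$qstart else df$tstart + df$qstart
  out <- list()
  for (d in unique(diag)) {
    sub <- df[diag == d, , drop = FALSE]
    sub <- sub[order(sub$qstart), , drop = FALSE]
    run_start <- 1L
    for (i in seq_len(nrow(sub))) {
      last <- i == nrow(sub)
      if (last || sub$qstart[i + 1L] - sub$qstart[i] > word_size) {
        qs <- sub$qstart[run_start]; qe <- sub$qstart[i] + word_size
        ts0 <- min(sub$tstart[run_start:i])
        out[[length(out) + 1L]] <- data.frame(
          qstart = qs, qend = qe, tstart = ts0,
          tend = ts0 + (qe - qs), orientation = orientation,
          stringsAsFactors = FALSE)
        run_start <- i + 1L
      }
    }
  }
  do.call(rbind, out)
}

#' Exact-match dot plot with breakpoint and inversion calling
#'
#' Finds exact shared substrings of at least `word_size` nucleotides between
#' query and target on both strands (word seeding at `word_size` step,
#' merged into maximal same-diagonal runs), chains collinear runs, and
#' reports breaks (query gaps between adjacent chains exceeding
#' `gap_threshold`) and inversions (chains matching the reverse strand).
#' If an expected gene window is given, events intersecting it set `flag`.
#'
#' @param query_seq,target_seq Nucleotide sequences (character scalars).
#' @param word_size Minimum exact-match length (default 256, >= 16).
#' @param gap_threshold Query gap that constitutes a break (default 10000).
#' @param expected_window Optional `c(start, end)` on the query (0-based
#'   half-open) where a gene is expected.
#' @return List of class `breakpoint_report`: `anchors` (merged runs),
#'   `chains`, `events` (data.frame `type`, `qpos`, `qend`), `flag`
#'   (`TRUE`/`FALSE`, or `NA` when no anchors were found).
#' @export
anchor_dotplot <- function(query_seq, target_seq, word_size = 256L,
                           gap_threshold = 10000L, expected_window = NULL) {
  stopifnot(word_size >= 16L, nchar(query_seq) >= word_size,
            nchar(target_seq) >= word_size)
  query_seq <- toupper(query_seq); target_seq <- toupper(target_seq)
  fwd <- word_anchors(query_seq, target_seq, word_size)
  rc <- word_anchors(query_seq, revcomp(target_seq), word_size)
  if (nrow(rc)) # map reverse-strand hits back to target coordinates
    rc$tstart <- nchar(target_seq) - (rc$tstart + word_size)
  runs <- rbind(
    if (nrow(fwd)) merge_run(fwd, word_size, "+"),
    if (nrow(rc)) {
      rcm <- data.frame(qstart = rc$qstart, tstart = rc$tstart)
      merge_run(rcm, word_size, "-")
    }
  )
  if (is.null(runs) || !nrow(runs))
    return(structure(list(anchors = NULL, chains = NULL,
                          events = data.frame(type = character(),
                                              qpos = integer(),
                                              qend = integer()),
                          flag = NA), class = "breakpoint_report"))
  runs <- runs[order(runs$qstart), , drop = FALSE]
  # chain collinear runs: same orientation and consistent diagonal drift
  chain_id <- integer(nrow(runs))
  cid <- 0L
  for (i in seq_len(nrow(runs))) {
    if (i == 1L) { cid <- 1L; chain_id[i] <- cid; next }
    prev <- runs[i - 1L, ]
    same <- runs$orientation[i] == prev$orientation &&
      runs$qstart[i] - prev$qend <= gap_threshold &&
      abs((runs$tstart[i] - runs$qstart[i]) -
            (prev$tstart - prev$qstart)) <= gap_threshold
    if (!same) cid <- cid + 1L
    chain_id[i] <- cid
  }
  runs$chain <- chain_id
  chains <- do.call(rbind, lapply(split(runs, runs$chain), function(s)
    data.frame(chain = s$chain[1L], qstart = min(s$qstart),
               qend = max(s$qend), tstart = min(s$tstart),
               tend = max(s$tend), orientation = s$orientation[1L],
               n_anchors = nrow(s), stringsAsFactors = FALSE)))
  chains <- chains[order(chains$qstart), , drop = FALSE]
  events <- list()
  if (nrow(chains) > 1L) for (i in 2:nrow(chains)) {
    gap <- chains$qstart[i] - chains$qend[i - 1L]
    if (gap > gap_threshold)
      events[[length(events) + 1L]] <- data.frame(
        type = "break", qpos = chains$qend[i - 1L], qend = chains$qstart[i],
        stringsAsFactors = FALSE)
    if (chains$orientation[i] != chains$orientation[i - 1L])
      events[[length(events) + 1L]] <- data.frame(
        type = "inversion_boundary", qpos = chains$qstart[i],
        qend = chains$qstart[i], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(chains)))
    if (chains$orientation[i] == "-")
      events[[length(events) + 1L]] <- data.frame(
        type = "inversion", qpos = chains$qstart[i], qend = chains$qend[i],
        stringsAsFactors = FALSE)
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(type = character(), qpos = integer(), qend = integer(),
                  stringsAsFactors = FALSE)
  flag <- NA
  if (!is.null(expected_window)) {
    flag <- any(events$qend >= expected_window[1L] &
                  events$qpos <= expected_window[2L])
  }
  structure(list(anchors = runs, chains = chains, events = events,
                 flag = flag), class = "breakpoint_report")
}
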