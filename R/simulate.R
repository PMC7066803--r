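# Gene-family evolution simulator: a teleost + mammal species tree with a
# teleost-base whole-genome duplication, per-lineage gene loss, tandem
# duplication, chromosomal rearrangement, sequence divergence over two
# conserved domains, database-style naming noise, and misassembly
# injection -- all with full ground truth.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' The species tree covers the range of teleost divergence times (in Mya):
#' whole-genome duplication on the teleost stem at 350, eel diverging at
#' 300, the herring/zebrafish ancestor at 250 splitting at 240, the
#' acanthomorphs at 150, stickleback at 100 and the pufferfishes at 70,
#' with a mammal outgroup (teleost-tetrapod split at 430, human-opossum at
#' 160).  Rates are per gene per species-tree branch; sequence divergence
#' is Jukes-Cantor per site, faster outside the two conserved domains.
#'
#' @param n_ancestral Ancestral (pre-duplication) gene count (default 20,
#'   the connexin-family scale).
#' @param n_chromosomes Pre-duplication chromosome count (default 12;
#'   doubled by the duplication, matching teleost karyotype scale).
#' @param loss_prob Per-lineage loss probability of each duplicated copy
#'   (whole-genome-duplication "B" copies and tandem copies), applied once
#'   on each terminal branch; default 0.2, i.e. each species retains ~80%
#'   of its duplicates, the high-retention regime this family shows.
#' @param tandem_rate Per-gene per-branch tandem duplication probability
#'   (default 0.1).
#' @param rearrangement_rate Per-lineage probability that a gene (together
#'   with its tandem co-copies: relocations are segmental) moves to a
#'   random other chromosome (default 0.05, applied on terminal branches).
#' @param domain_rate Substitutions/site/My inside the conserved domains
#'   (default 3e-4: ~0.26 substitutions/site between teleosts and mammals).
#' @param spacer_factor Rate multiplier outside the domains (default 3).
#' @param cds_len CDS length in nt (default 660).
#' @param domains Two 0-based half-open intervals on the CDS (defaults
#'   `c(0, 270)` and `c(330, 630)`: with the 15-nt extensions the
#'   concatenated domains give 200 aligned codons, the scale of the real
#'   conserved-domain alignments).
#' @param chr_length Chromosome length in bp for locus placement and
#'   chromosome emission (default 120000).
#' @param family_radiation_mya Depth (My) of the radiation that produced
#'   the ancestral paralogs from one family ancestor (default 700,
#'   pre-vertebrate): controls inter-orthogroup identity, keeping the whole
#'   family alignable as in a real conserved-domain set.
#' @param naming_profile Fractions of genes labelled with their Greek name,
#'   a size-style name, a "-like" name, or left unnamed (must sum to <= 1;
#'   remainder unnamed).
#' @param wrong_name_rate Probability that a drawn name refers to a
#'   different orthogroup (default 0.05).
#' @param seed Integer seed; every stochastic step derives from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_ancestral = 20L, n_chromosomes = 12L,
                              loss_prob = 0.2, tandem_rate = 0.1,
                              rearrangement_rate = 0.05,
                              domain_rate = 3e-4, spacer_factor = 3,
                              cds_len = 660L,
                              domains = list(c(0L, 270L), c(330L, 630L)),
                              chr_length = 120000L,
                              family_radiation_mya = 700,
                              naming_profile = c(greek = 0.35, size = 0.35,
                                                 like = 0.2, unnamed = 0.1),
                              wrong_name_rate = 0.05,
                              seed = 1L) {
  stopifnot(n_ancestral >= 1L, n_chromosomes >= 1L,
            loss_prob >= 0, loss_prob <= 1,
            tandem_rate >= 0, tandem_rate <= 1,
            rearrangement_rate >= 0, rearrangement_rate <= 1,
            domain_rate >= 0, cds_len %% 3L == 0L,
            sum(naming_profile) <= 1 + 1e-9,
            wrong_name_rate >= 0, wrong_name_rate <= 1)
  if (n_chromosomes < 2L && rearrangement_rate > 0)
    stop("rearrangement needs at least 2 chromosomes")
  structure(list(
    n_ancestral = as.integer(n_ancestral),
    n_chromosomes = as.integer(n_chromosomes),
    loss_prob = loss_prob, tandem_rate = tandem_rate,
    rearrangement_rate = rearrangement_rate,
    domain_rate = domain_rate, spacer_factor = spacer_factor,
    cds_len = as.integer(cds_len), domains = domains,
    chr_length = as.integer(chr_length),
    family_radiation_mya = family_radiation_mya,
    naming_profile = naming_profile, wrong_name_rate = wrong_name_rate,
    wgd_time = 350, seed = as.integer(seed)
  ), class = "simulation_config")
}

# species tree: nested lists; leaves are species codes, internal nodes
# carry the divergence time (Mya) of their children
sim_species_tree <- function() {
  list(time = 430,
       left = list(time = 160, left = "Hs", right = "Md", clade = "mammal"),
       right = list(time = 300, left = "Aj",
                    right = list(time = 250,
                                 left = list(time = 240, left = "Ch",
                                             right = "Dr"),
                                 right = list(time = 150, left = "Gm",
                                              right = list(time = 100,
                                                           left = "Ga",
                                                           right = list(
                                                             time = 70,
                                                             left = "Fr",
                                                             right = "Tn")))),
                    clade = "teleost"))
}

# orthogroup base symbols: Greek nomenclature pool skipping the reserved
# gja7 (historically used for Cx45)
orthogroup_symbols <- function(n) {
  pool <- unlist(lapply(c("a", "b", "c", "d", "e"), function(s)
    paste0("gj", s, setdiff(1:9, if (s == "a") 7L else integer(0)))))
  if (n > length(pool)) pool <- c(pool, paste0("gja", 10:(10 + n)))
  pool[seq_len(n)]
}

random_cds <- function(cds_len) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, cds_len %/% 3L, replace = TRUE), collapse = "")
}

# JC mutation over dt My; seq is a char vector; site_rate a per-site rate
# vector; codons mutated into stops are reverted (purifying-selection proxy)
mutate_seq <- function(seq, site_rate, dt) {
  p <- 0.75 * (1 - exp(-4 / 3 * site_rate * dt))
  hit <- which(runif(length(seq)) < p)
  if (!length(hit)) return(seq)
  old <- seq
  bases <- c("A", "C", "G", "T")
  for (i in hit) seq[i] <- sample(setdiff(bases, seq[i]), 1L)
  cod <- unique((hit - 1L) %/% 3L)
  for (ci in cod) {
    idx <- ci * 3L + 1:3
    if (paste(seq[idx], collapse = "") %in% STOP_CODONS)
      seq[idx] <- old[idx]
  }
  seq
}

site_rate_vector <- function(cfg) {
  r <- rep(cfg$domain_rate * cfg$spacer_factor, cfg$cds_len)
  for (d in cfg$domains) r[(d[1L] + 1L):d[2L]] <- cfg$domain_rate
  r
}

new_gene <- function(og, slot, tandem, chrom, pos, seq) {
  list(og = og, slot = slot, tandem = tandem, chrom = chrom, pos = pos,
       seq = seq)
}

sim_branch <- function(genes, dt, cfg, rates, teleost, terminal = FALSE) {
  # losses hit duplicated copies only (WGD "B" copies and tandem copies),
  # once per terminal lineage
  if (terminal) {
    keep <- vapply(genes, function(g)
      !((g$slot == "B" || g$tandem > 0L) && runif(1L) < cfg$loss_prob), TRUE)
    genes <- genes[keep]
  }
  # tandem duplications
  out <- list()
  for (g in genes) {
    out[[length(out) + 1L]] <- g
    if (runif(1L) < cfg$tandem_rate) {
      existing <- max(0L, g$tandem)
      child <- g
      child$tandem <- existing + 1L
      child$pos <- min(g$pos + 2000L, cfg$chr_length - cfg$cds_len)
      out[[length(out) + 1L]] <- child
    }
  }
  genes <- out
  # rearrangements: segmental moves of a gene plus its tandem co-copies,
  # applied once per terminal lineage
  if (terminal && cfg$rearrangement_rate > 0) {
    nchr_now <- cfg$n_chromosomes * (if (teleost) 2L else 1L)
    blocks <- vapply(genes, function(g) paste(g$og, g$slot), "")
    for (bl in unique(blocks)) {
      if (runif(1L) < cfg$rearrangement_rate) {
        idx <- which(blocks == bl)
        newchr <- sample(setdiff(seq_len(nchr_now),
                                 genes[[idx[1L]]]$chrom), 1L)
        base_pos <- sample.int(cfg$chr_length - cfg$cds_len -
                                 2000L * length(idx), 1L)
        for (k in seq_along(idx)) {
          genes[[idx[k]]]$chrom <- newchr
          genes[[idx[k]]]$pos <- base_pos + 2000L * (k - 1L)
        }
      }
    }
  }
  # sequence divergence
  for (i in seq_along(genes))
    genes[[i]]$seq <- mutate_seq(genes[[i]]$seq, rates, dt)
  genes
}

sim_recurse <- function(node, genes, t_from, cfg, rates, teleost, tips) {
  if (is.character(node)) {
    tips[[node]] <- sim_branch(genes, t_from, cfg, rates, teleost,
                               terminal = TRUE)
    return(tips)
  }
  # branch from t_from down to node$time, then split
  if (teleost && t_from > cfg$wgd_time && node$time < cfg$wgd_time) {
    genes <- sim_branch(genes, t_from - cfg$wgd_time, cfg, rates, teleost)
    dup <- lapply(genes, function(g) {
      g$slot <- "B"
      g$chrom <- g$chrom + cfg$n_chromosomes
      g
    })
    genes <- c(genes, dup)
    genes <- sim_branch(genes, cfg$wgd_time - node$time, cfg, rates, teleost)
  } else {
    genes <- sim_branch(genes, t_from - node$time, cfg, rates, teleost)
  }
  for (side in c("left", "right")) {
    tips <- sim_recurse(node[[side]], genes, node$time, cfg, rates,
                        teleost, tips)
  }
  tips
}

#' Simulate a gene family across the species tree
#'
#' @param cfg A [simulation_config()].
#' @return List with `dataset` (a [family_dataset()]), and `truth`: per-gene
#'   orthogroup and true names, ohnolog pairs, tandem sets, naming-noise
#'   record, and an (initially empty) injected-event table.
#' @export
simulate_family <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  symbols <- orthogroup_symbols(cfg$n_ancestral)
  rates <- site_rate_vector(cfg)
  family_seq <- strsplit(random_cds(cfg$cds_len), "")[[1L]]
  ancestral <- lapply(seq_len(cfg$n_ancestral), function(i)
    new_gene(og = i, slot = "A", tandem = 0L,
             chrom = sample.int(cfg$n_chromosomes, 1L),
             pos = sample.int(cfg$chr_length - cfg$cds_len, 1L),
             seq = mutate_seq(family_seq, rates, cfg$family_radiation_mya)))
  tree <- sim_species_tree()
  tips <- list()
  # root is the bony-vertebrate ancestor; clades are set at the root split
  for (side in c("left", "right")) {
    child <- tree[[side]]
    tips <- sim_recurse(child, ancestral, tree$time, cfg, rates,
                        identical(child$clade, "teleost"), tips)
  }

  sp_meta <- species_table()
  recs <- list(); loci <- list(); truth_rows <- list()
  ohn <- list(); tand <- list()
  acc <- 0L
  for (sp in names(tips)) {
    genes <- tips[[sp]]
    ogs <- vapply(genes, `[[`, 1L, "og")
    slots <- vapply(genes, `[[`, "", "slot")
    for (og in unique(ogs)) {
      idx <- which(ogs == og)
      base <- symbols[og]
      both <- length(unique(slots[idx])) == 2L
      for (slot in unique(slots[idx])) {
        sidx <- idx[slots[idx] == slot]
        pos <- vapply(genes[sidx], `[[`, 1L, "pos")
        ord <- sidx[order(pos)]
        for (k in seq_along(ord)) {
          i <- ord[k]
          acc <- acc + 1L
          nm <- base
          if (both) nm <- paste0(nm, if (slot == "A") "a" else "b")
          if (length(ord) > 1L) nm <- paste0(nm, ".", k)
          genes[[i]]$true_name <- nm
          genes[[i]]$id_acc <- sprintf("XM_%09d", acc)
        }
        if (length(ord) > 1L)
          tand[[length(tand) + 1L]] <- list(
            species = sp, orthogroup = base,
            slot = slot, n = length(ord))
      }
      if (both)
        ohn[[length(ohn) + 1L]] <- list(species = sp, orthogroup = base)
    }
    tips[[sp]] <- genes
  }

  # database-style labels (naming noise)
  labels <- naming_noise(tips, symbols, cfg$naming_profile,
                         cfg$wrong_name_rate)

  li <- 0L
  for (sp in names(tips)) {
    for (g in tips[[sp]]) {
      li <- li + 1L
      locus_id <- paste0("L", li)
      db_tokens <- labels$db_name[labels$species == sp &
                                    labels$accession == g$id_acc]
      raw <- paste(c(sp, if (!nzchar(db_tokens)) "NN",
                     if (nzchar(db_tokens)) db_tokens, g$id_acc),
                   collapse = "-")
      id <- raw
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, species = sp, raw_label = raw,
        db_name = db_tokens, prediction_status =
          if (nzchar(db_tokens)) "predicted" else "NN",
        accession = g$id_acc,
        cds = paste(g$seq, collapse = ""), pseudogene = FALSE,
        protein = NA_character_,
        d1_start = cfg$domains[[1L]][1L], d1_end = cfg$domains[[1L]][2L],
        d2_start = cfg$domains[[2L]][1L], d2_end = cfg$domains[[2L]][2L],
        locus_id = locus_id, stringsAsFactors = FALSE)
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = locus_id, assembly_id = paste0(sp, "_asm1"),
        seq_name = paste0("chr", g$chrom),
        start = as.integer(g$pos), end = as.integer(g$pos + cfg$cds_len),
        strand = "+", stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = id, species = sp, orthogroup = symbols[g$og],
        slot = g$slot, tandem = g$tandem, chrom = g$chrom,
        true_name = g$true_name, accession = g$id_acc,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  records$protein <- vapply(records$cds, translate_cds, "", USE.NAMES = FALSE)
  ds <- family_dataset(records, species = sp_meta,
                       loci = do.call(rbind, loci))
  truth_df <- do.call(rbind, truth_rows)
  labels$id <- truth_df$id[match(paste(labels$species, labels$accession),
                                 paste(truth_df$species, truth_df$accession))]
  list(
    dataset = ds,
    truth = list(
      config = cfg,
      genes = truth_df,
      orthogroups = setNames(truth_df$orthogroup, truth_df$id),
      ohnolog_pairs = ohn, tandem_sets = tand,
      naming = labels,
      events = data.frame(type = character(), species = character(),
                          id = character(), seq_name = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
    )
  )
}

#' Draw database-style labels for simulated genes
#'
#' Each gene's label is drawn from the naming profile: its true Greek
#' symbol, a size-style name shared by the orthogroup, a "-like" name after
#' a related group, or no name; with probability `wrong_name_rate` the
#' Greek/size/like name is taken from a different orthogroup, and the
#' wrong-name assignment is recorded.
#'
#' @param tips Internal per-species gene lists (from [simulate_family()]).
#' @param symbols Orthogroup base symbols.
#' @param profile Named fractions `greek`, `size`, `like`, `unnamed`.
#' @param wrong_name_rate Wrong-orthogroup probability.
#' @return data.frame with `species`, `accession`, `db_name` (possibly
#'   `""`), `system`, `wrong` (logical), `true_og`, `named_og`.
#' @export
naming_noise <- function(tips, symbols, profile, wrong_name_rate) {
  size_name <- function(og) sprintf("cx%.1f", 25 + og * 0.7)
  cats <- c("greek", "size", "like", "unnamed")
  pr <- c(profile[["greek"]], profile[["size"]], profile[["like"]],
          profile[["unnamed"]])
  pr <- c(pr, max(0, 1 - sum(pr)))  # remainder unnamed
  rows <- list()
  for (sp in names(tips)) for (g in tips[[sp]]) {
    cat_i <- sample.int(5L, 1L, prob = pr)
    cat <- c(cats, "unnamed")[cat_i]
    wrong <- FALSE
    named_og <- g$og
    if (cat != "unnamed" && runif(1L) < wrong_name_rate) {
      wrong <- TRUE
      named_og <- sample(setdiff(seq_along(symbols), g$og), 1L)
    }
    nm <- switch(cat,
                 greek = symbols[named_og],
                 size = size_name(named_og),
                 like = paste0(symbols[named_og], "like"),
                 unnamed = "")
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, accession = g$id_acc, db_name = nm,
      system = cat, wrong = wrong, true_og = symbols[g$og],
      named_og = symbols[named_og], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Inject misassemblies into a simulated dataset
#'
#' Deletions remove genes from the assembly view (the truth keeps them);
#' segmental duplications add near-identical copies (default 0.2%
#' divergence) on the same chromosome; inversions flip a chromosomal
#' interval, updating the loci it contains.  All events are appended to
#' `truth$events`.
#'
#' @param sim A `list(dataset, truth)` from [simulate_family()].
#' @param species Species/assembly to corrupt.
#' @param deletions Number of genes to delete (or explicit gene ids).
#' @param duplications Number of genes to duplicate, each gaining
#'   `dup_copies` extra copies.
#' @param dup_copies Extra copies per duplicated gene (default 1).
#' @param inversions Number of gene-containing intervals to invert.
#' @param divergence Per-site divergence of duplicated copies (default
#'   0.002).
#' @param seed Seed for the event draws.
#' @return Updated `list(dataset, truth)`.
#' @export
inject_misassembly <- function(sim, species, deletions = 0L,
                               duplications = 0L, dup_copies = 1L,
                               inversions = 0L, divergence = 0.002,
                               seed = 1L) {
  set.seed(seed)
  ds <- sim$dataset; truth <- sim$truth
  rec <- ds$records
  sp_ids <- rec$id[rec$species == species]
  used <- character(0)
  ev <- function(type, id, seq_name, start, end)
    truth$events[nrow(truth$events) + 1L, ] <<-
    list(type, species, id, seq_name, as.integer(start), as.integer(end))

  if (is.character(deletions)) {
    del <- deletions
  } else if (deletions > 0L) {
    del <- sample(sp_ids, deletions)
  } else del <- character(0)
  for (id in del) {
    lid <- rec$locus_id[rec$id == id]
    lrow <- ds$loci[ds$loci$locus_id == lid, ]
    ev("deletion", id, lrow$seq_name, lrow$start, lrow$end)
  }
  used <- del

  dup_ids <- if (duplications > 0L)
    sample(setdiff(sp_ids, used), duplications) else character(0)
  used <- c(used, dup_ids)
  new_recs <- list(); new_loci <- list()
  for (id in dup_ids) {
    r <- rec[rec$id == id, ]
    lrow <- ds$loci[ds$loci$locus_id == r$locus_id, ]
    for (k in seq_len(dup_copies)) {
      seq <- strsplit(r$cds, "")[[1L]]
      hit <- which(runif(length(seq)) < divergence)
      for (i in hit) seq[i] <- sample(setdiff(c("A", "C", "G", "T"), seq[i]), 1L)
      cds2 <- paste(seq, collapse = "")
      nid <- paste0(id, "_dup", k)
      nlid <- paste0(r$locus_id, "d", k)
      r2 <- r
      r2$id <- r2$raw_label <- nid
      r2$cds <- cds2
      r2$protein <- translate_cds(cds2, pseudogene = TRUE)
      r2$locus_id <- nlid
      l2 <- lrow
      l2$locus_id <- nlid
      l2$start <- lrow$start + k * 5000L
      l2$end <- l2$start + (lrow$end - lrow$start)
      new_recs[[length(new_recs) + 1L]] <- r2
      new_loci[[length(new_loci) + 1L]] <- l2
      ev("segmental_duplication", nid, l2$seq_name, l2$start, l2$end)
      truth$genes <- rbind(truth$genes, data.frame(
        id = nid, species = species,
        orthogroup = truth$genes$orthogroup[truth$genes$id == id],
        slot = "artifact", tandem = 0L,
        chrom = truth$genes$chrom[truth$genes$id == id],
        true_name = NA_character_, accession = NA_character_,
        stringsAsFactors = FALSE))
    }
  }

  rec <- rec[!(rec$id %in% del), , drop = FALSE]
  if (length(new_recs)) rec <- rbind(rec, do.call(rbind, new_recs))
  loci <- ds$loci
  if (length(new_loci)) loci <- rbind(loci, do.call(rbind, new_loci))

  if (inversions > 0L) {
    cand <- rec$id[rec$species == species & !(rec$id %in% used)]
    inv_ids <- sample(cand, min(inversions, length(cand)))
    for (id in inv_ids) {
      lid <- rec$locus_id[rec$id == id]
      lrow <- loci[loci$locus_id == lid, ]
      a <- max(0L, lrow$start - 2000L)
      b <- lrow$end + 4000L
      inside <- loci$seq_name == lrow$seq_name &
        loci$assembly_id == lrow$assembly_id &
        loci$start >= a & loci$end <= b
      s <- loci$start[inside]; e <- loci$end[inside]
      loci$start[inside] <- a + (b - e)
      loci$end[inside] <- a + (b - s)
      loci$strand[inside] <- ifelse(loci$strand[inside] == "+", "-", "+")
      ev("inversion", id, lrow$seq_name, a, b)
    }
  }

  sim$dataset <- family_dataset(rec, species = ds$species, loci = loci,
                                excluded_ids = intersect(ds$excluded_ids,
                                                         rec$id))
  sim$truth <- truth
  sim
}

#' Emit a chromosome sequence for one species
#'
#' Builds the chromosome as seeded random background with each resident
#' gene's CDS written at its locus (reverse-complemented on the minus
#' strand).  The background depends only on `(species, seq_name, seed)`,
#' so pre- and post-misassembly datasets emit comparable sequences.
#'
#' @param ds A [family_dataset()].
#' @param species Species code.
#' @param seq_name Chromosome label (e.g. `"chr3"`).
#' @param length Chromosome length (default: config scale, 120000).
#' @param seed Background seed.
#' @return Character scalar.
#' @export
emit_chromosome <- function(ds, species, seq_name, length = 120000L,
                            seed = 1L) {
  set.seed(seed * 1000L + sum(utf8ToInt(paste0(species, seq_name))))
  chrom <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  rec <- ds$records[ds$records$species == species, , drop = FALSE]
  m <- match(rec$locus_id, ds$loci$locus_id)
  on_chr <- which(!is.na(m) & ds$loci$seq_name[m] == seq_name)
  for (i in on_chr) {
    lrow <- ds$loci[m[i], ]
    if (lrow$start >= length) next
    cds <- rec$cds[i]
    if (lrow$strand == "-") cds <- revcomp(cds)
    span <- lrow$start + seq_len(min(nchar(cds), length - lrow$start))
    chrom[span] <- strsplit(cds, "")[[1L]][seq_along(span)]
  }
  paste(chrom, collapse = "")
}

#' Reverse-complement an interval of a sequence (an inversion)
#'
#' @param seq Character scalar.
#' @param start,end 0-based half-open interval.
#' @return The sequence with the interval reverse-complemented.
#' @export
invert_interval <- function(seq, start, end) {
  stopifnot(start >= 0, end <= nchar(seq), start < end)
  paste0(substr(seq, 1L, start),
         revcomp(substr(seq, start + 1L, end)),
         substr(seq, end + 1L, nchar(seq)))
}

#' Codon alignment of the simulated conserved domains
#'
#' Simulated sequences accumulate substitutions only, so the concatenated
#' (extended) conserved domains of all genes are already positionally
#' homologous: this returns them as a gapless codon alignment ready for
#' [run_grid()].
#'
#' @param ds A simulated [family_dataset()].
#' @param extend Extension triple passed to [extract_conserved_domains()]
#'   (default `c(15, 15, 15)`).
#' @return An nt-level [as_alignment()].
#' @export
domain_alignment <- function(ds, extend = c(15L, 15L, 15L)) {
  seqs <- vapply(seq_len(nrow(ds$records)), function(i) {
    r <- ds$records[i, ]
    extract_conserved_domains(
      r$cds, list(c(r$d1_start, r$d1_end), c(r$d2_start, r$d2_end)),
      extend[1L], extend[2L], extend[3L])
  }, "")
  as_alignment(setNames(seqs, ds$records$id), level = "nt")
}
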