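# Ohnolog vs tandem inference from within-orthogroup copy counts and
# cross-species chromosome co-occurrence.

#' Build a locus matrix from a family dataset and orthogroup map
#'
#' The locus matrix is the long form of a per-orthogroup, per-species
#' chromosome table: one row per gene copy with its chromosome (or
#' scaffold) label and position.  Unplaced copies carry seq_name `"?"`.
#'
#' @param ds A [family_dataset()].
#' @param orthogroups Named character vector: gene id -> orthogroup label.
#' @return data.frame of class `locus_matrix` with columns `orthogroup`,
#'   `species`, `gene_id`, `seq_name`, `start`.
#' @export
locus_matrix <- function(ds, orthogroups) {
  ids <- intersect(ds$records$id, names(orthogroups))
  m <- match(ids, ds$records$id)
  lm <- match(ds$records$locus_id[m], ds$loci$locus_id)
  out <- data.frame(
    orthogroup = unname(orthogroups[ids]),
    copy = NA_character_,
    species = ds$records$species[m],
    gene_id = ids,
    seq_name = ifelse(is.na(lm), "?", ds$loci$seq_name[lm]),
    start = ifelse(is.na(lm), NA_integer_, ds$loci$start[lm]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("locus_matrix", "data.frame")
  out
}

#' Read a wide locus-matrix TSV
#'
#' The wide shape mirrors a per-chromosome ohnology table: columns
#' `orthogroup`, `copy`, then one column per species whose cells hold a
#' chromosome/linkage-group/scaffold label, optionally `label:position`,
#' `"?"` for unplaced, `"-"`/empty for absent.  Slash-separated labels
#' (`2/2/2`) denote tandem multiplets and expand to one row per copy.
#'
#' @param path TSV path.
#' @return A `locus_matrix` data.frame.
#' @export
read_locus_matrix <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  comment.char = "#")
  stopifnot(all(c("orthogroup", "copy") %in% names(w)))
  species <- setdiff(names(w), c("orthogroup", "copy"))
  rows <- list()
  for (i in seq_len(nrow(w))) for (sp in species) {
    cell <- trimws(as.character(w[i, sp]))
    if (is.na(cell) || cell %in% c("", "-", "–")) next
    parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
    for (k in seq_along(parts)) {
      tok <- strsplit(parts[k], ":", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = w$orthogroup[i], copy = as.character(w$copy[i]),
        species = sp,
        gene_id = paste0(sp, "-", w$orthogroup[i], "-", w$copy[i],
                         if (length(parts) > 1L) paste0(".", k) else ""),
        seq_name = tok[1L],
        start = if (length(tok) > 1L) as.integer(tok[2L]) else NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("locus_matrix", "data.frame")
  out
}

is_placed <- function(seq_name) {
  !(seq_name %in% c("?", "", NA)) & !grepl("^sc", seq_name) &
    !grepl("^[0-9]{3,}$", seq_name)
}

#' Conserved co-occurrence groups, anchored on one species
#'
#' For every chromosome of the anchor species, reports the set of
#' orthogroups resident there and, for each other species, the chromosome
#' holding the plurality of those orthogroups together with the deviating
#' members.
#'
#' @param lm A `locus_matrix`.
#' @param anchor_species Species code used as starting point.
#' @return List keyed by anchor chromosome; each element has `seq_name`,
#'   `orthogroups` and `species` (data.frame `species`, `plurality_chr`,
#'   `n_on_plurality`, `deviating`).
#' @export
cooccurrence_groups <- function(lm, anchor_species) {
  stopifnot(anchor_species %in% lm$species)
  a <- lm[lm$species == anchor_species & is_placed(lm$seq_name), , drop = FALSE]
  others <- setdiff(unique(lm$species), anchor_species)
  out <- list()
  for (chr in unique(a$seq_name)) {
    ogs <- unique(a$orthogroup[a$seq_name == chr])
    per <- lapply(others, function(sp) {
      sub <- lm[lm$species == sp & lm$orthogroup %in% ogs &
                  is_placed(lm$seq_name), , drop = FALSE]
      if (!nrow(sub))
        return(data.frame(species = sp, plurality_chr = NA_character_,
                          n_on_plurality = 0L, deviating = "",
                          stringsAsFactors = FALSE))
      tab <- table(sub$seq_name)
      plu <- names(tab)[which.max(tab)]
      on_plu <- unique(sub$orthogroup[sub$seq_name == plu])
      dev <- setdiff(ogs, on_plu)
      data.frame(species = sp, plurality_chr = plu,
                 n_on_plurality = length(on_plu),
                 deviating = paste(dev, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    sp_tab <- if (length(per)) do.call(rbind, per)
    else data.frame(species = character(), plurality_chr = character(),
                    n_on_plurality = integer(), deviating = character(),
                    stringsAsFactors = FALSE)
    out[[chr]] <- list(seq_name = chr, orthogroups = sort(ogs),
                       species = sp_tab)
  }
  out
}

#' Classify a within-species duplicate set as ohnolog / tandem / ambiguous
#'
#' Copies of one orthogroup on the same chromosome (at any distance) are
#' tandem duplicates; copies on different chromosomes are candidate
#' ohnologs, confirmed when the same chromosome pairing is supported by at
#' least one other orthogroup in this species, or when the orthogroup has a
#' two-chromosome duplicate pair in at least two other species.  Unplaced
#' copies never confirm or refute a pairing.
#'
#' @param lm A `locus_matrix`.
#' @param orthogroup Orthogroup label.
#' @param species Species code.
#' @param min_coresident Co-resident orthogroups needed for within-species
#'   confirmation (default 1).
#' @param min_species Other species needed for cross-species confirmation
#'   (default 2).
#' @param copy Optional copy-slot label: restrict the member set to one
#'   ohnolog slot of a wide locus table (e.g. the tandem multiplet within
#'   slot A).
#' @return A list of class `ohnolog_call`: `orthogroup`, `species`,
#'   `member_ids`, `class` (`"ohnolog"`, `"tandem"`, `"ambiguous"`), and
#'   `evidence`; or `NULL` for single-copy groups (no call emitted).
#' @export
classify_duplicates <- function(lm, orthogroup, species,
                                min_coresident = 1L, min_species = 2L,
                                copy = NULL) {
  sub <- lm[lm$orthogroup == orthogroup & lm$species == species, , drop = FALSE]
  if (!is.null(copy)) sub <- sub[!is.na(sub$copy) & sub$copy == copy, , drop = FALSE]
  if (nrow(sub) < 2L) return(NULL)
  call <- function(class, evidence)
    structure(list(orthogroup = orthogroup, species = species,
                   member_ids = sub$gene_id, class = class,
                   evidence = evidence), class = "ohnolog_call")
  placed <- sub[is_placed(sub$seq_name), , drop = FALSE]
  if (nrow(placed) < 2L)
    return(call("ambiguous", list(reason = "unplaced")))
  chrs <- unique(placed$seq_name)
  if (length(chrs) == 1L && nrow(sub) == nrow(placed))
    return(call("tandem", list(seq_name = chrs)))
  if (length(chrs) == 1L)
    return(call("ambiguous", list(reason = "unplaced",
                                  seq_name = chrs)))
  pair <- sort(chrs)[1:2]
  # within-species: other orthogroups whose copies also span this pair
  others <- lm[lm$species == species & lm$orthogroup != orthogroup &
                 is_placed(lm$seq_name), , drop = FALSE]
  co <- vapply(split(others$seq_name, others$orthogroup),
               function(s) all(pair %in% s), TRUE)
  n_co <- sum(co)
  # cross-species: same orthogroup duplicated on two chromosomes elsewhere
  osp <- lm[lm$orthogroup == orthogroup & lm$species != species &
              is_placed(lm$seq_name), , drop = FALSE]
  n_sp <- sum(vapply(split(osp$seq_name, osp$species),
                     function(s) length(unique(s)) >= 2L, TRUE))
  ev <- list(chromosome_pair = pair, coresident_orthogroups = n_co,
             supporting_species = n_sp)
  if (n_co >= min_coresident || n_sp >= min_species)
    call("ohnolog", ev)
  else call("ambiguous", ev)
}

#' All duplicate calls in a locus matrix
#'
#' @param lm A `locus_matrix`.
#' @param ... Passed to [classify_duplicates()].
#' @return List of `ohnolog_call`s (multi-copy orthogroup x species cells
#'   only).
#' @export
classify_all_duplicates <- function(lm, ...) {
  keys <- unique(lm[, c("orthogroup", "species")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    cl <- classify_duplicates(lm, keys$orthogroup[i], keys$species[i], ...)
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  out
}

#' Consistency of ohnolog chromosome pairings
#'
#' For each species and each anchor chromosome carrying duplicated
#' orthogroups, reports the modal partner chromosome, the fraction of
#' two-chromosome duplicate pairs respecting that pairing, and the
#' deviating orthogroups.  Unplaced partners are excluded from both
#' numerator and denominator.
#'
#' @param lm A `locus_matrix`.
#' @return data.frame with columns `species`, `anchor_chr`, `partner_chr`,
#'   `n_pairs`, `n_consistent`, `score`, `deviating`.
#' @export
pairing_consistency <- function(lm) {
  rows <- list()
  for (sp in unique(lm$species)) {
    sub <- lm[lm$species == sp, , drop = FALSE]
    pairs <- list()
    for (og in unique(sub$orthogroup)) {
      s <- sub$seq_name[sub$orthogroup == og]
      s <- unique(s[is_placed(s)])
      if (length(s) >= 2L) {
        s <- sort(s)[1:2]
        pairs[[length(pairs) + 1L]] <- data.frame(
          orthogroup = og, a = s[1L], b = s[2L], stringsAsFactors = FALSE)
      }
    }
    if (!length(pairs)) next
    pdf <- do.call(rbind, pairs)
    for (anchor in unique(c(pdf$a, pdf$b))) {
      hit <- pdf$a == anchor | pdf$b == anchor
      partner <- ifelse(pdf$a[hit] == anchor, pdf$b[hit], pdf$a[hit])
      tab <- table(partner)
      modal <- names(tab)[which.max(tab)]
      dev <- pdf$orthogroup[hit][partner != modal]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, anchor_chr = anchor, partner_chr = modal,
        n_pairs = sum(hit), n_consistent = max(tab),
        score = max(tab) / sum(hit),
        deviating = paste(dev, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(), anchor_chr = character(),
                      partner_chr = character(), n_pairs = integer(),
                      n_consistent = integer(), score = numeric(),
                      deviating = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Export duplicate calls as TSV
#' @param calls List of `ohnolog_call`s.
#' @param path Output path.
#' @export
write_ohnolog_calls <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(cl) data.frame(
    orthogroup = cl$orthogroup, species = cl$species,
    members = paste(cl$member_ids, collapse = ","),
    class = cl$class, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}
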