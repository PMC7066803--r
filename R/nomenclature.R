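# Nomenclature systems, translation, inconsistency detection and
# standardized renaming proposals.

#' Classify the nomenclature system of a gene symbol
#'
#' Systems: `greek` (`gja1`, `GJB7`, `gjd2b`, `gjd2*1`), `size`
#' (`cx43`, `Cx30.3`), `alphabet` (`CXNK1`), `mixed` (Greek and size
#' joined, `gja9-cx59`), `like` (any symbol ending in `like`), `none`
#' (unnamed / `NN`).  Classification is deterministic from the symbol's
#' shape and case-insensitive.
#'
#' @param symbol Character vector of symbols.
#' @return Character vector of system labels.
#' @export
name_system <- function(symbol) {
  s <- tolower(trimws(symbol))
  greek_re <- "^gj[a-e][0-9]+(\\.[0-9]+)?[ab]?(\\*[0-9]+)?$"
  size_re <- "^cx[0-9]+(\\.[0-9]+)?(\\*[0-9]+)?$"
  alpha_re <- "^cxn[a-z][0-9]*$"
  vapply(s, function(x) {
    if (is.na(x) || x %in% c("", "nn", "np", "-")) return("none")
    if (grepl("like$", x)) return("like")
    if (grepl(greek_re, x)) return("greek")
    if (grepl(alpha_re, x)) return("alphabet")
    if (grepl(size_re, x)) return("size")
    toks <- strsplit(x, "-", fixed = TRUE)[[1L]]
    if (length(toks) > 1L) {
      sys <- name_system(toks)
      if ("greek" %in% sys && "size" %in% sys) return("mixed")
    }
    "none"
  }, "", USE.NAMES = FALSE)
}

#' Load the nomenclature translation table
#'
#' The shipped table translates between the mammalian Greek, mammalian
#' size, mammalian alphabetic, and amended teleost Greek systems, and lists
#' the commonly used teleost Greek and size names per orthologous group.
#'
#' @param path Optional path to an alternative TSV with columns
#'   `orthogroup`, `mammal_greek`, `mammal_size`, `mammal_alphabet`,
#'   `amended_teleost`, `common_teleost_greek`, `common_teleost_size`
#'   (multi-valued cells comma-separated, empty = `-`).
#' @return data.frame.
#' @export
nomenclature_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nomenclature_translation.tsv",
                        package = "famcurate", mustWork = TRUE)
  tb <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  amended <- unlist(strsplit(tb$amended_teleost[tb$amended_teleost != "-"], ","))
  if (anyDuplicated(amended))
    stop("amended teleost symbols must be unique")
  tb
}

split_cell <- function(x) {
  if (is.na(x) || x %in% c("", "-")) character(0)
  else trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
}

table_columns <- c(
  greek_mammal = "mammal_greek", size_mammal = "mammal_size",
  alphabet_mammal = "mammal_alphabet", amended_teleost = "amended_teleost",
  greek_teleost = "common_teleost_greek", size_teleost = "common_teleost_size"
)

#' Translate a symbol between nomenclature systems
#'
#' @param symbol Symbol to translate (case-insensitive lookup).
#' @param from,to System names: one of `"greek_mammal"`, `"size_mammal"`,
#'   `"alphabet_mammal"`, `"amended_teleost"`, `"greek_teleost"`,
#'   `"size_teleost"`.
#' @param table A [nomenclature_table()].
#' @return Character vector of target-system symbols for the matched row
#'   (several where the table lists several).
#' @export
translate_name <- function(symbol, from, to, table = nomenclature_table()) {
  from <- match.arg(from, names(table_columns))
  to <- match.arg(to, names(table_columns))
  fcol <- table[[table_columns[[from]]]]
  hit <- which(vapply(fcol, function(cell)
    tolower(symbol) %in% tolower(split_cell(cell)), TRUE))
  if (!length(hit)) {
    all_syms <- unlist(lapply(fcol, split_cell))
    near <- all_syms[agrepl(symbol, all_syms, ignore.case = TRUE,
                            max.distance = 0.25)]
    stop("symbol '", symbol, "' not found in system '", from, "'",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(unique(near), collapse = ", ")))
  }
  out <- unique(unlist(lapply(table[[table_columns[[to]]]][hit], split_cell)))
  if (!length(out))
    stop("no '", to, "' symbol recorded for '", symbol, "'")
  out
}

#' Detect naming inconsistencies in a classified dataset
#'
#' Finds the recurring violation classes: mixed nomenclature systems inside
#' one orthologous group; evident orthologs carrying different names;
#' identical names used for genes in distinct orthogroups; `-like` names;
#' names whose own orthogroup (per the translation table) differs from the
#' gene's assigned orthogroup; and non-unique names within a species.
#' Findings are ordered by orthogroup, then gene id.
#'
#' @param ds A [family_dataset()].
#' @param orthogroups Named character vector: gene id -> orthogroup label.
#' @param table A [nomenclature_table()] (used for `wrong_orthogroup_name`).
#' @return data.frame with columns `kind`, `gene_ids`, `orthogroups`,
#'   `message`.
#' @export
detect_inconsistencies <- function(ds, orthogroups,
                                   table = nomenclature_table()) {
  rec <- ds$records
  rec <- rec[rec$id %in% names(orthogroups), , drop = FALSE]
  rec$group <- unname(orthogroups[rec$id])
  rec$sys <- name_system(rec$db_name)
  rec <- rec[order(rec$group, rec$id), , drop = FALSE]
  f <- list()
  add <- function(kind, ids, groups, msg)
    f[[length(f) + 1L]] <<- data.frame(
      kind = kind, gene_ids = paste(ids, collapse = ","),
      orthogroups = paste(unique(groups), collapse = ","),
      message = msg, stringsAsFactors = FALSE)

  for (g in unique(rec$group)) {
    sub <- rec[rec$group == g, , drop = FALSE]
    named <- sub[sub$sys != "none", , drop = FALSE]
    sys <- setdiff(unique(named$sys), "like")
    if (length(intersect(sys, c("greek", "size"))) > 1L ||
        "mixed" %in% named$sys)
      add("mixed_systems_in_group", named$id, g,
          sprintf("group %s mixes nomenclature systems (%s)", g,
                  paste(sort(unique(named$sys)), collapse = ", ")))
    nm <- tolower(named$db_name)
    if (length(unique(nm)) > 1L)
      add("different_names_same_orthogroup", named$id, g,
          sprintf("orthologs in group %s carry different names: %s", g,
                  paste(sort(unique(named$db_name)), collapse = ", ")))
    likes <- sub[sub$sys == "like", , drop = FALSE]
    if (nrow(likes))
      add("like_name", likes$id, g,
          sprintf("'-like' names in group %s: %s", g,
                  paste(sort(unique(likes$db_name)), collapse = ", ")))
  }

  # identical names across distinct orthogroups
  named <- rec[rec$sys != "none", , drop = FALSE]
  for (nm in sort(unique(tolower(named$db_name)))) {
    sub <- named[tolower(named$db_name) == nm, , drop = FALSE]
    if (length(unique(sub$group)) > 1L)
      add("same_name_different_orthogroups", sub$id, sub$group,
          sprintf("name '%s' used in %d distinct orthogroups", nm,
                  length(unique(sub$group))))
  }

  # name resolves to a different orthogroup than assigned
  for (i in seq_len(nrow(rec))) {
    base <- sub("like$", "", tolower(rec$db_name[i]))
    if (!nzchar(base) || rec$sys[i] == "none") next
    owner <- name_owner_group(base, table)
    if (!is.na(owner) && tolower(owner) != tolower(rec$group[i]))
      add("wrong_orthogroup_name", rec$id[i], c(rec$group[i], owner),
          sprintf("gene %s named after group %s but assigned to %s",
                  rec$id[i], owner, rec$group[i]))
  }

  # duplicate names within one species
  for (sp in sort(unique(named$species))) {
    sub <- named[named$species == sp, , drop = FALSE]
    dup <- unique(tolower(sub$db_name)[duplicated(tolower(sub$db_name))])
    for (nm in sort(dup)) {
      hit <- sub[tolower(sub$db_name) == nm, , drop = FALSE]
      if (length(unique(hit$group)) > 1L)
        add("nonunique_within_species", hit$id, hit$group,
            sprintf("species %s uses name '%s' for %d distinct genes",
                    sp, nm, nrow(hit)))
    }
  }

  if (!length(f))
    return(data.frame(kind = character(), gene_ids = character(),
                      orthogroups = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, f)
}

# which orthogroup (table row) does a bare symbol belong to, if resolvable
name_owner_group <- function(symbol, table) {
  for (col in c("mammal_greek", "amended_teleost", "common_teleost_greek",
                "common_teleost_size", "mammal_size")) {
    hit <- which(vapply(table[[col]], function(cell)
      tolower(symbol) %in% tolower(sub("[ab]$", "", split_cell(cell))) ||
        tolower(symbol) %in% tolower(split_cell(cell)), TRUE))
    if (length(hit) == 1L) return(table$orthogroup[hit])
  }
  NA_character_
}

#' Propose standardized names under the amended Greek rules
#'
#' Proposal rules, in order: a group with a mammalian counterpart takes the
#' mammalian Greek symbol, lowercased; a confirmed ohnolog pair takes
#' `a`/`b` suffixes (`a` goes to the copy on the smaller anchor
#' chromosome label, a deterministic and documented tie-break); a tandem
#' pair takes `.1`/`.2` by ascending coordinate; a teleost-only group takes
#' its amended symbol from the table, or the lowest unoccupied subfamily
#' integer, skipping reserved symbols (`gja7`, historically used for Cx45);
#' `-like` is never proposed.  Proposals are unique within each species.
#'
#' @param orthogroups Named character vector: gene id -> orthogroup label
#'   (mammalian Greek symbols for groups with mammal counterparts,
#'   otherwise any group label resolvable via the table or a novel label).
#' @param ohnolog_calls List of `ohnolog_call`s (see
#'   [classify_all_duplicates()]).
#' @param lm The `locus_matrix` used for the calls (for coordinates and
#'   chromosome order).
#' @param table A [nomenclature_table()].
#' @param reserved Symbols never proposed (default `"gja7"`).
#' @return List with `proposal` (named character vector gene id -> symbol)
#'   and `rationale` (named character vector per orthogroup).
#' @export
suggest_names <- function(orthogroups, ohnolog_calls, lm,
                          table = nomenclature_table(),
                          reserved = "gja7") {
  groups <- unique(unname(orthogroups))
  base <- setNames(character(length(groups)), groups)
  rationale <- setNames(character(length(groups)), groups)
  occupied <- tolower(c(
    unlist(lapply(table$mammal_greek, split_cell)),
    sub("[ab]$", "", unlist(lapply(table$amended_teleost, split_cell)))))
  occupied <- unique(c(occupied, tolower(reserved)))

  for (g in groups) {
    if (grepl("^gj[a-e][0-9]+$", tolower(g)) &&
        any(vapply(table$mammal_greek, function(cell)
          tolower(g) %in% tolower(split_cell(cell)), TRUE))) {
      base[g] <- tolower(g)
      rationale[g] <- "mammalian counterpart: mammalian Greek symbol, lowercased"
      next
    }
    amended <- tryCatch(
      sub("[ab]$", "",
          translate_name(g, "size_teleost", "amended_teleost", table)[1L]),
      error = function(e) tryCatch(
        sub("[ab]$", "",
            translate_name(g, "greek_teleost", "amended_teleost", table)[1L]),
        error = function(e) NA_character_))
    if (!is.na(amended)) {
      base[g] <- tolower(amended)
      rationale[g] <- "teleost-only group: amended symbol from the translation table"
      next
    }
    subfam <- substr(tolower(g), 1L, 3L)
    if (!grepl("^gj[a-e]$", subfam)) subfam <- "gja"
    k <- 1L
    while (paste0(subfam, k) %in% c(occupied, tolower(base))) {
      k <- k + 1L
      if (k > 1000L) stop("exhausted integer space for subfamily ", subfam)
    }
    base[g] <- paste0(subfam, k)
    rationale[g] <-
      sprintf("teleost-only group: lowest unoccupied %s integer (reserved skipped)",
              subfam)
  }

  proposal <- setNames(rep(NA_character_, length(orthogroups)),
                       names(orthogroups))
  calls_by <- list()
  for (cl in ohnolog_calls)
    calls_by[[paste(cl$orthogroup, cl$species, sep = "\r")]] <- cl

  for (sp in unique(lm$species)) {
    for (g in groups) {
      ids <- names(orthogroups)[orthogroups == g]
      ids <- ids[ids %in% lm$gene_id[lm$species == sp]]
      if (!length(ids)) next
      cl <- calls_by[[paste(g, sp, sep = "\r")]]
      if (length(ids) == 1L || is.null(cl)) {
        proposal[ids] <- base[g]
      } else if (cl$class == "ohnolog") {
        chr <- lm$seq_name[match(ids, lm$gene_id)]
        ord <- order(chr_order_key(chr), ids)
        proposal[ids[ord]] <- paste0(base[g], letters[seq_along(ids)])
      } else if (cl$class == "tandem") {
        pos <- lm$start[match(ids, lm$gene_id)]
        ord <- order(pos, ids)
        proposal[ids[ord]] <- paste0(base[g], ".", seq_along(ids))
      } else {
        # ambiguous duplicates: numbered to preserve uniqueness
        ord <- order(ids)
        proposal[ids[ord]] <- paste0(base[g], ".", seq_along(ids))
      }
    }
  }
  # fall back for genes without locus rows
  missing <- is.na(proposal)
  proposal[missing] <- base[orthogroups[names(proposal)[missing]]]
  list(proposal = proposal, rationale = rationale)
}

# numeric-aware chromosome ordering key ("2" < "10" < "chr11" < "X")
chr_order_key <- function(x) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", x)))
  sprintf("%010.1f%s", ifelse(is.na(num), 1e8, num), x)
}

#' Cysteine-spacing class of an extracellular-loop segment
#'
#' Scans the translated second conserved domain for the triple-cysteine
#' motifs `C-x(4)-C-x(5)-C` (the family-wide pattern) and `C-x(5)-C-x(5)-C`
#' (the GJB3 hallmark), reporting the class of the first match.  Any other
#' triple-cysteine spacing (up to 10 residues between cysteines) reports
#' `"other"`; no such triple reports `"none"`.
#'
#' @param protein_segment Character scalar.
#' @return One of `"CX4CX5C"`, `"CX5CX5C"`, `"other"`, `"none"`.
#' @export
motif_class <- function(protein_segment) {
  s <- toupper(protein_segment)
  if (nchar(s) < 12L) return("none")
  m45 <- regexpr("C[^C]{4}C[^C]{5}C", s)
  m55 <- regexpr("C[^C]{5}C[^C]{5}C", s)
  many <- regexpr("C[^C]{0,10}C[^C]{0,10}C", s)
  pos <- c(CX4CX5C = m45[1L], CX5CX5C = m55[1L])
  pos <- pos[pos > 0L]
  if (length(pos)) return(names(pos)[which.min(pos)])
  if (many[1L] > 0L) return("other")
  "none"
}
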