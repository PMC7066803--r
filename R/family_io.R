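#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rbinom setNames lm.fit
#' @importFrom utils read.delim write.table combn head tail
NULL

# ---------------------------------------------------------------------------
# Species metadata
# ---------------------------------------------------------------------------

#' Default species table
#'
#' The teleost and mammalian species used throughout the package, with their
#' two-letter codes, clade and approximate divergence time (million years ago)
#' from the remaining species in their clade.  Teleosts span the range of
#' divergence times in the group, from the early-diverging eels to the
#' late-diverging pufferfishes; human and opossum stand in for the mammals.
#'
#' @return A data.frame with columns `code`, `name`, `clade`,
#'   `divergence_mya`.
#' @export
species_table <- function() {
  data.frame(
    code = c("Aj", "Ch", "Dr", "Gm", "Ga", "Fr", "Tn", "Hs", "Md", "Mm"),
    name = c(
      "Anguilla japonica", "Clupea harengus", "Danio rerio",
      "Gadus morhua", "Gasterosteus aculeatus", "Takifugu rubripes",
      "Tetraodon nigroviridis", "Homo sapiens", "Monodelphis domestica",
      "Mus musculus"
    ),
    clade = c(rep("teleost", 7), rep("mammal", 3)),
    divergence_mya = c(300, 240, 250, 150, 100, 70, 70, 160, 160, 90),
    stringsAsFactors = FALSE
  )
}

ACCESSION_RE <- "^([A-Za-z]{1,4}_[0-9]+(\\.[0-9]+)?|G[0-9]+|ENS[A-Z]*[GT][0-9]+)$"

# ---------------------------------------------------------------------------
# Structured labels
# ---------------------------------------------------------------------------

#' Parse a structured sequence label
#'
#' Labels follow the `<SpeciesCode>-<dbName>-<accession>` convention, e.g.
#' `"Fr-gja9-cx59-XM_003965660"`.  The leading dash-delimited token is the
#' species code, a trailing token matching an accession-like pattern
#' (letters + underscore + digits, or `G` + digits for abbreviated Ensembl
#' gene numbers) is the accession, and everything in between are database
#' name tokens.  The markers `NN` (no name in the database) and `NP` (not
#' predicted by the database) set the prediction status.
#'
#' @param raw Character scalar, the label as read.
#' @param species Character vector of known species codes; defaults to the
#'   codes of [species_table()].
#' @return A list with elements `species`, `names` (character vector of name
#'   tokens, excluding status markers), `accession` (or `NA`), and `status`
#'   (`"predicted"`, `"NN"` or `"NP"`).
#' @examples
#' parse_label("Fr-gja9-cx59-XM_003965660")
#' parse_label("Tn-NP-cx30.3")
#' @export
parse_label <- function(raw, species = species_table()$code) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("empty label")
  toks <- strsplit(raw, "-", fixed = TRUE)[[1L]]
  if (!(toks[1L] %in% species))
    stop(sprintf("unknown species code '%s' in label '%s'", toks[1L], raw))
  sp <- toks[1L]
  toks <- toks[-1L]
  status <- "predicted"
  if (length(toks) && toks[1L] %in% c("NN", "NP")) {
    status <- toks[1L]
    toks <- toks[-1L]
  }
  acc <- NA_character_
  if (length(toks) && grepl(ACCESSION_RE, toks[length(toks)])) {
    acc <- toks[length(toks)]
    toks <- toks[-length(toks)]
  }
  list(species = sp, names = toks, accession = acc, status = status)
}

#' Reassemble a structured label from its parts
#'
#' Inverse of [parse_label()]: `format_label(parse_label(x)) == x` for any
#' valid label.
#'
#' @param parts A list as returned by [parse_label()].
#' @return Character scalar.
#' @export
format_label <- function(parts) {
  toks <- c(
    parts$species,
    if (parts$status %in% c("NN", "NP")) parts$status,
    parts$names,
    if (!is.na(parts$accession)) parts$accession
  )
  paste(toks, collapse = "-")
}

# ---------------------------------------------------------------------------
# Conserved domains
# ---------------------------------------------------------------------------

#' Extract the concatenated conserved domains from a coding sequence
#'
#' The family-wide alignable regions are two conserved domains on the CDS.
#' Following the curation protocol, the first domain can be extended in the
#' 3' direction and the second domain in both the 5' and 3' directions (by
#' 15 nt each by default, reaching into the flanking loop-coding sequence).
#' Extensions that would overrun the CDS are clamped with a warning.
#'
#' @param cds Character scalar, the coding sequence.
#' @param domains A list of two integer vectors `c(start, end)`, 0-based
#'   half-open, ordered and non-overlapping.
#' @param extend_first_3p,extend_second_5p,extend_second_3p Non-negative
#'   extension lengths in nucleotides (defaults 15, 15, 15).
#' @return Character scalar: the concatenation of the (extended) domain
#'   subsequences.
#' @export
extract_conserved_domains <- function(cds, domains,
                                      extend_first_3p = 15L,
                                      extend_second_5p = 15L,
                                      extend_second_3p = 15L) {
  stopifnot(length(domains) == 2L,
            extend_first_3p >= 0, extend_second_5p >= 0, extend_second_3p >= 0)
  n <- nchar(cds)
  d1 <- as.integer(domains[[1L]]); d2 <- as.integer(domains[[2L]])
  if (d1[1L] < 0 || d1[2L] <= d1[1L] || d2[2L] <= d2[1L] || d2[2L] > n)
    stop("domain intervals out of order or outside the CDS")
  if (d1[2L] > d2[1L]) stop("domains overlap")
  e1 <- c(d1[1L], d1[2L] + extend_first_3p)
  e2 <- c(d2[1L] - extend_second_5p, d2[2L] + extend_second_3p)
  clamped <- FALSE
  if (e1[2L] > n) { e1[2L] <- n; clamped <- TRUE }
  if (e2[1L] < 0) { e2[1L] <- 0L; clamped <- TRUE }
  if (e2[2L] > n) { e2[2L] <- n; clamped <- TRUE }
  if (e1[2L] > e2[1L]) { e1[2L] <- e2[1L]; clamped <- TRUE }
  if (clamped)
    warning("domain extension clamped to CDS/domain bounds")
  paste0(substr(cds, e1[1L] + 1L, e1[2L]), substr(cds, e2[1L] + 1L, e2[2L]))
}

# ---------------------------------------------------------------------------
# Translation helper
# ---------------------------------------------------------------------------

#' Translate a coding sequence
#'
#' Standard-code translation.  A terminal stop codon is trimmed before
#' translation; internal stops are an error unless `pseudogene = TRUE`, in
#' which case they are rendered as `*`.
#'
#' @param cds Character scalar (length divisible by 3 after trimming an
#'   incomplete terminal codon).
#' @param pseudogene Allow internal stop codons.
#' @return Character scalar, the protein sequence.
#' @export
translate_cds <- function(cds, pseudogene = FALSE) {
  cds <- toupper(cds)
  cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
  if (!grepl("[^ACGT]", cds)) {
    i <- seq(1L, nchar(cds), 3L)
    aa <- paste(Biostrings::GENETIC_CODE[substring(cds, i, i + 2L)],
                collapse = "")
  } else {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    ))
  }
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", aa) && !pseudogene)
    stop("internal stop codon in CDS (set pseudogene = TRUE to allow)")
  aa
}

# ---------------------------------------------------------------------------
# FamilyDataset
# ---------------------------------------------------------------------------

#' Construct a family dataset
#'
#' Bundles the gene records of one gene family with the species metadata and
#' the locus table, and validates the referential invariants: unique record
#' ids, every record species and locus resolvable, domains inside the CDS,
#' excluded ids a subset of record ids.
#'
#' @param records data.frame with columns `id`, `species`, `raw_label`,
#'   `db_name`, `prediction_status`, `accession`, `cds`, `protein`,
#'   `d1_start`, `d1_end`, `d2_start`, `d2_end` (0-based half-open domain
#'   coordinates), `locus_id`, `pseudogene`.
#' @param species data.frame as in [species_table()].
#' @param loci data.frame with columns `locus_id`, `assembly_id`,
#'   `seq_name`, `start`, `end`, `strand` (0-based half-open, `start < end`,
#'   strand `+`/`-`).
#' @param excluded_ids Record ids excluded from tree analyses (e.g. known
#'   long-branch-attraction cases), set by configuration, never auto-detected.
#' @return An object of class `family_dataset`.
#' @export
family_dataset <- function(records, species = species_table(),
                           loci = NULL, excluded_ids = character()) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id))
    stop("duplicate record ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  bad_sp <- setdiff(records$species, species$code)
  if (length(bad_sp))
    stop("records reference unknown species: ", paste(bad_sp, collapse = ", "))
  if (is.null(loci))
    loci <- data.frame(locus_id = character(), assembly_id = character(),
                       seq_name = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  if (nrow(loci)) {
    if (any(!nzchar(loci$seq_name))) stop("locus with empty seq_name")
    bad <- which(loci$start >= loci$end)
    if (length(bad))
      stop("locus row ", bad[1L], " has end <= start (locus_id ",
           loci$locus_id[bad[1L]], ")")
  }
  have_locus <- !is.na(records$locus_id) & nzchar(records$locus_id)
  bad_loc <- setdiff(records$locus_id[have_locus], loci$locus_id)
  if (length(bad_loc))
    stop("records reference unknown loci: ", paste(bad_loc, collapse = ", "))
  bad_ex <- setdiff(excluded_ids, records$id)
  if (length(bad_ex))
    stop("excluded_ids not in records: ", paste(bad_ex, collapse = ", "))
  n <- nchar(records$cds)
  bad_dom <- which(!(records$d1_start >= 0 & records$d1_start < records$d1_end &
                       records$d1_end <= records$d2_start &
                       records$d2_start < records$d2_end &
                       records$d2_end <= n))
  if (length(bad_dom))
    stop("domain intervals invalid for record(s): ",
         paste(records$id[bad_dom], collapse = ", "))
  structure(
    list(records = records, species = species, loci = loci,
         excluded_ids = excluded_ids),
    class = "family_dataset"
  )
}

#' @export
print.family_dataset <- function(x, ...) {
  cat("family_dataset:", nrow(x$records), "records,",
      length(unique(x$records$species)), "species,",
      nrow(x$loci), "loci")
  if (length(x$excluded_ids))
    cat(",", length(x$excluded_ids), "excluded")
  cat("\n")
  invisible(x)
}

#' Load a family dataset from FASTA + locus TSV + domain definitions
#'
#' The FASTA headers must be structured labels parseable by [parse_label()].
#' The locus TSV must have the header
#' `gene_id assembly seq_name start end strand` with 1-based inclusive
#' coordinates (converted to 0-based half-open internally; reverse-strand
#' genes may be given with start > end and are normalized to start < end
#' with strand `-`).  Domain definitions map each gene id (or `"default"`)
#' to the two conserved-domain intervals.
#'
#' @param fasta_path Path to the CDS FASTA.
#' @param locus_tsv_path Path to the locus table, or `NULL`.
#' @param domain_def Either a path to a two-column TSV
#'   (`gene_id d1_start d1_end d2_start d2_end`, 0-based half-open) or a
#'   named list of `list(d1 = c(s,e), d2 = c(s,e))`; the entry `"default"`
#'   applies to genes without their own entry.
#' @param species data.frame as in [species_table()].
#' @param pseudogene_ids Ids allowed to carry internal stop codons.
#' @return A [family_dataset()].
#' @export
load_dataset <- function(fasta_path, locus_tsv_path = NULL, domain_def,
                         species = species_table(),
                         pseudogene_ids = character()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("FASTA with duplicated id: ", ids[duplicated(ids)][1L])
  cds <- as.character(seqs)

  if (is.character(domain_def)) {
    dd <- read.delim(domain_def, stringsAsFactors = FALSE)
    domain_def <- lapply(seq_len(nrow(dd)), function(i)
      list(d1 = c(dd$d1_start[i], dd$d1_end[i]),
           d2 = c(dd$d2_start[i], dd$d2_end[i])))
    names(domain_def) <- dd$gene_id
  }
  get_dom <- function(id) {
    d <- domain_def[[id]]
    if (is.null(d)) d <- domain_def[["default"]]
    if (is.null(d)) stop("no domain definition for gene ", id)
    d
  }

  parts <- lapply(ids, parse_label, species = species$code)
  recs <- data.frame(
    id = ids,
    species = vapply(parts, `[[`, "", "species"),
    raw_label = ids,
    db_name = vapply(parts, function(p) paste(p$names, collapse = "-"), ""),
    prediction_status = vapply(parts, `[[`, "", "status"),
    accession = vapply(parts, `[[`, "", "accession"),
    cds = unname(cds),
    stringsAsFactors = FALSE
  )
  recs$pseudogene <- recs$id %in% pseudogene_ids
  recs$protein <- mapply(translate_cds, recs$cds, recs$pseudogene,
                         USE.NAMES = FALSE)
  dom <- lapply(ids, get_dom)
  recs$d1_start <- vapply(dom, function(d) as.integer(d$d1[1L]), 1L)
  recs$d1_end <- vapply(dom, function(d) as.integer(d$d1[2L]), 1L)
  recs$d2_start <- vapply(dom, function(d) as.integer(d$d2[1L]), 1L)
  recs$d2_end <- vapply(dom, function(d) as.integer(d$d2[2L]), 1L)

  loci <- NULL
  recs$locus_id <- NA_character_
  if (!is.null(locus_tsv_path)) {
    lt <- read.delim(locus_tsv_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "assembly", "seq_name", "start", "end", "strand")
    if (!all(need %in% names(lt)))
      stop("locus table must have columns: ", paste(need, collapse = " "))
    unknown <- setdiff(lt$gene_id, ids)
    if (length(unknown))
      stop("locus referencing unknown gene: ", paste(unknown, collapse = ", "))
    # normalize reverse-strand start > end, then 1-based incl -> 0-based half-open
    rev <- lt$start > lt$end
    tmp <- lt$start[rev]; lt$start[rev] <- lt$end[rev]; lt$end[rev] <- tmp
    lt$strand[rev] <- "-"
    bad <- which(lt$start == lt$end | lt$start < 1)
    if (length(bad))
      stop("locus table row ", bad[1L], ": invalid coordinates for gene ",
           lt$gene_id[bad[1L]])
    loci <- data.frame(
      locus_id = paste0("L", seq_len(nrow(lt))),
      assembly_id = lt$assembly, seq_name = lt$seq_name,
      start = as.integer(lt$start) - 1L, end = as.integer(lt$end),
      strand = lt$strand, stringsAsFactors = FALSE
    )
    recs$locus_id[match(lt$gene_id, recs$id)] <- loci$locus_id
  }

  family_dataset(recs, species = species, loci = loci)
}

#' Write a family dataset back to FASTA + locus TSV
#'
#' Inverse of [load_dataset()]: sequences as 60-column wrapped FASTA keyed by
#' the structured labels, loci as a TSV with 1-based inclusive coordinates.
#'
#' @param ds A [family_dataset()].
#' @param fasta_path,locus_tsv_path Output paths (`locus_tsv_path` may be
#'   `NULL` to skip).
#' @return `ds`, invisibly.
#' @export
write_dataset <- function(ds, fasta_path, locus_tsv_path = NULL) {
  x <- Biostrings::DNAStringSet(setNames(ds$records$cds, ds$records$id))
  Biostrings::writeXStringSet(x, fasta_path, width = 60L)
  if (!is.null(locus_tsv_path)) {
    m <- match(ds$records$locus_id, ds$loci$locus_id)
    keep <- !is.na(m)
    lt <- data.frame(
      gene_id = ds$records$id[keep],
      assembly = ds$loci$assembly_id[m[keep]],
      seq_name = ds$loci$seq_name[m[keep]],
      start = ds$loci$start[m[keep]] + 1L,
      end = ds$loci$end[m[keep]],
      strand = ds$loci$strand[m[keep]],
      stringsAsFactors = FALSE
    )
    write.table(lt, locus_tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(ds)
}
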