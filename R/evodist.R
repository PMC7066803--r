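# Alignment container, site filters and evolutionary distances.

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap `-`), or a character matrix with one column per site and rownames.
#' @param level `"aa"` or `"nt"`.
#' @return An object of class `fam_alignment`: a character matrix
#'   (taxa x sites) with a `level` attribute.
#' @export
as_alignment <- function(seqs, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must have unique names")
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("all rows must have equal length")
    m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(names(seqs), NULL))
  }
  structure(m, level = level, class = c("fam_alignment", "matrix", "array"))
}

aln_level <- function(aln) attr(aln, "level")

#' Read an aligned FASTA file
#' @param path FASTA path.
#' @param level `"nt"` or `"aa"`.
#' @return A [as_alignment()] object.
#' @export
read_alignment <- function(path, level = c("nt", "aa")) {
  level <- match.arg(level)
  x <- Biostrings::readBStringSet(path)
  as_alignment(setNames(as.character(x), names(x)), level = level)
}

#' Write an alignment to FASTA
#' @param aln Alignment.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  s <- apply(unclass(aln), 1L, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(s, rownames(aln))), path, width = 60L)
  invisible(aln)
}

#' Translate a codon alignment to amino acids
#'
#' Codon columns that are all-gap in a row become a single `-`; codons with
#' any gap or ambiguity translate to `X`.
#'
#' @param aln An nt-level alignment with column count divisible by 3.
#' @return An aa-level alignment.
#' @export
translate_alignment <- function(aln) {
  stopifnot(aln_level(aln) == "nt", ncol(aln) %% 3L == 0L)
  code <- Biostrings::GENETIC_CODE
  m <- unclass(aln)
  i1 <- seq(1L, ncol(m), 3L)
  cod <- matrix(paste0(m[, i1], m[, i1 + 1L], m[, i1 + 2L]), nrow = nrow(m))
  aa <- code[cod]
  aa[cod == "---"] <- "-"
  aa[is.na(aa)] <- "X"
  dim(aa) <- dim(cod)
  rownames(aa) <- rownames(m)
  as_alignment(aa, level = "aa")
}

# ---------------------------------------------------------------------------
# Site filters
# ---------------------------------------------------------------------------

#' Site filter configuration
#'
#' @param coverage_cutoff Fraction in (0, 1]: minimum non-gap coverage for a
#'   column to be retained (default 0.95, i.e. "partial deletion").
#' @param codon_positions Subset of 1:3 retained at nt level (default 1:2;
#'   third positions are commonly saturated at teleost-mammal divergences).
#' @return A list of class `site_filter`.
#' @export
site_filter <- function(coverage_cutoff = 0.95, codon_positions = c(1L, 2L)) {
  stopifnot(coverage_cutoff > 0, coverage_cutoff <= 1,
            all(codon_positions %in% 1:3), length(codon_positions) >= 1L)
  structure(list(coverage_cutoff = coverage_cutoff,
                 codon_positions = sort(unique(as.integer(codon_positions)))),
            class = "site_filter")
}

#' Remove low-coverage alignment columns (partial deletion)
#'
#' Keeps every column whose non-gap fraction is at least the coverage
#' cutoff; column order is preserved, so the operation is idempotent.
#'
#' @param aln Alignment.
#' @param cfg A [site_filter()] (only `coverage_cutoff` is used).
#' @return Filtered alignment.
#' @export
apply_partial_deletion <- function(aln, cfg = site_filter()) {
  stopifnot(nrow(aln) > 0L)
  gap <- unclass(aln) == "-"
  keep <- colMeans(!gap) >= cfg$coverage_cutoff
  if (!any(keep)) stop("no sites survive filtering")
  as_alignment(unclass(aln)[, keep, drop = FALSE], level = aln_level(aln))
}

#' Select codon positions from a nucleotide alignment
#'
#' The reading frame is anchored at column 1 of the alignment.
#'
#' @param aln nt-level alignment whose length is divisible by 3.
#' @param positions Non-empty subset of 1:3.
#' @return Alignment restricted to the chosen codon positions.
#' @export
select_codon_positions <- function(aln, positions = c(1L, 2L)) {
  if (aln_level(aln) != "nt") stop("codon positions require an nt alignment")
  if (length(positions) == 0L) stop("positions must be a non-empty subset of 1:3")
  stopifnot(all(positions %in% 1:3))
  if (ncol(aln) %% 3L != 0L) stop("alignment length not divisible by 3")
  idx <- which(((seq_len(ncol(aln)) - 1L) %% 3L + 1L) %in% positions)
  as_alignment(unclass(aln)[, idx, drop = FALSE], level = "nt")
}

# ---------------------------------------------------------------------------
# Percent identity
# ---------------------------------------------------------------------------

AMBIG <- c("-", "N", "X", "?")

#' Percent identity between two gapped rows
#'
#' 100 x matches / columns where both rows are non-gap and unambiguous,
#' rounded to two decimals (rounding happens only at this reporting surface;
#' [identity_matrix()] keeps full precision available via `digits = NA`).
#'
#' @param a,b Equal-length gapped sequences (character scalars or vectors of
#'   single characters).
#' @param digits Decimal places (default 2; `NA` for no rounding).
#' @return Percentage, or `NA` if no comparable columns exist.
#' @export
percent_identity <- function(a, b, digits = 2L) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !(a %in% AMBIG) & !(b %in% AMBIG)
  if (!any(ok)) return(NA_real_)
  p <- 100 * sum(a[ok] == b[ok]) / sum(ok)
  if (is.na(digits)) p else round(p, digits)
}

#' All-against-all percent identity matrix
#'
#' @param aln Alignment.
#' @param digits Decimal places (default 2).
#' @return Symmetric matrix with a 100.00 diagonal.
#' @export
identity_matrix <- function(aln, digits = 2L) {
  m <- unclass(aln)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- percent_identity(m[i, ], m[j, ], digits = NA)
  }
  if (is.na(digits)) out else round(out, digits)
}

# ---------------------------------------------------------------------------
# Distances
# ---------------------------------------------------------------------------

#' Pairwise evolutionary distances
#'
#' Models: `p` (mismatch fraction over comparable columns), `poisson`
#' (-ln(1-p), aa), `jc` (Jukes-Cantor, nt), and `dayhoff_ml` / `jtt_ml`
#' (maximum-likelihood pairwise distances under the Dayhoff or JTT empirical
#' amino-acid matrices, computed with [phangorn::dist.ml()]).  Columns where
#' either row carries a gap or ambiguity are ignored pairwise.  Entries past
#' the saturation bound of a correction (p >= 0.75 for `jc`, p >= 1 for
#' `poisson`) are returned as `NA` and flagged in the `saturated` attribute.
#'
#' @param aln Alignment of the matching level.
#' @param model One of `"p"`, `"poisson"`, `"jc"`, `"dayhoff_ml"`, `"jtt_ml"`.
#' @return A symmetric distance matrix with zero diagonal, `model_tag`
#'   attribute, and a logical `saturated` attribute.
#' @export
compute_distances <- function(aln,
                              model = c("p", "poisson", "jc",
                                        "dayhoff_ml", "jtt_ml")) {
  model <- match.arg(model)
  lev <- aln_level(aln)
  if (model %in% c("poisson", "dayhoff_ml", "jtt_ml") && lev != "aa")
    stop("model '", model, "' requires an aa alignment")
  if (model == "jc" && lev != "nt")
    stop("model 'jc' requires an nt alignment")
  m <- unclass(aln)
  n <- nrow(m)
  ids <- rownames(m)

  if (model %in% c("dayhoff_ml", "jtt_ml")) {
    pd <- phangorn::as.phyDat(m, type = "AA")
    D <- as.matrix(phangorn::dist.ml(
      pd, model = if (model == "dayhoff_ml") "Dayhoff" else "JTT"))
    D <- D[ids, ids]
    sat <- !is.finite(D); diag(sat) <- FALSE
    D[sat] <- NA_real_
    diag(D) <- 0
    return(structure(D, model_tag = model, saturated = sat))
  }

  # vectorized pairwise p-distance via one-hot products
  alphabet <- setdiff(sort(unique(as.vector(m))), AMBIG)
  okm <- !(m %in% AMBIG)
  dim(okm) <- dim(m)
  okm <- okm * 1
  comp <- okm %*% t(okm)
  match_ct <- matrix(0, n, n)
  for (a in alphabet) {
    xa <- (m == a) * 1
    match_ct <- match_ct + xa %*% t(xa)
  }
  p <- 1 - match_ct / comp
  p[comp == 0] <- NA_real_
  diag(p) <- 0

  D <- p
  if (model == "poisson") {
    ok <- !is.na(p) & p < 1
    D[!ok] <- NA_real_
    D[ok] <- -log(1 - p[ok])
  } else if (model == "jc") {
    ok <- !is.na(p) & p < 0.75
    D[!ok] <- NA_real_
    D[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  }
  sat <- is.na(D) & !is.na(p)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  dimnames(sat) <- dimnames(D)
  structure(D, model_tag = model, saturated = sat)
}

#' Write a distance matrix as square TSV
#' @param D Distance matrix.
#' @param path Output path.
#' @export
write_distances <- function(D, path) {
  df <- data.frame(id = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(D)
}

#' Read a square TSV distance matrix
#' @param path Input path.
#' @return Numeric matrix with ids as dimnames.
#' @export
read_distances <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- df[[1L]]
  storage.mode(D) <- "double"
  D
}
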