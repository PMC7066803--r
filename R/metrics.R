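# Ground-truth evaluation helpers for simulated families: how well the
# pipeline recovers orthogroups, ohnolog pairs and tandem duplicates.

#' Orthogroup-assignment accuracy against simulator truth
#'
#' @param assignment Named vector from [assign_orthogroups()]`$assignment`.
#' @param truth_genes The `truth$genes` table of [simulate_family()].
#' @param focal_ids Gene ids evaluated (unassigned genes count as wrong).
#' @return Fraction correct in `[0, 1]`.
#' @export
orthogroup_accuracy <- function(assignment, truth_genes, focal_ids) {
  lab <- setNames(truth_genes$orthogroup, truth_genes$id)
  got <- assignment[focal_ids]
  mean(!is.na(got) & got == lab[focal_ids])
}

truth_cells <- function(truth_genes) {
  # per (species, orthogroup): surviving slots and per-slot copy numbers
  key <- paste(truth_genes$species, truth_genes$orthogroup, sep = "\r")
  cells <- lapply(split(truth_genes, key), function(s) {
    list(species = s$species[1L], orthogroup = s$orthogroup[1L],
         ohnolog = length(unique(s$slot[s$slot %in% c("A", "B")])) == 2L,
         tandem = any(table(s$slot) >= 2L),
         n = nrow(s))
  })
  cells
}

#' Ohnolog precision/recall/F1 of duplicate classification
#'
#' Truth positives are species-orthogroup cells where both
#' whole-genome-duplication copies survive; predictions are the
#' `"ohnolog"` calls of [classify_all_duplicates()].
#'
#' @param calls List of `ohnolog_call`s.
#' @param truth_genes The `truth$genes` table.
#' @return Named vector `precision`, `recall`, `f1`.
#' @export
ohnolog_metrics <- function(calls, truth_genes) {
  cells <- truth_cells(truth_genes)
  truth_pos <- vapply(cells, function(c) c$ohnolog, TRUE)
  truth_key <- vapply(cells, function(c)
    paste(c$species, c$orthogroup, sep = "\r"), "")
  pred_key <- vapply(calls, function(cl)
    paste(cl$species, cl$orthogroup, sep = "\r"), "")
  pred_ohn <- pred_key[vapply(calls, function(cl)
    cl$class == "ohnolog", TRUE)]
  tp <- sum(pred_ohn %in% truth_key[truth_pos])
  prec <- if (length(pred_ohn)) tp / length(pred_ohn) else NA_real_
  rec <- if (sum(truth_pos)) tp / sum(truth_pos) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(precision = prec, recall = rec, f1 = f1)
}

#' Tandem-classification accuracy on tandem-only cells
#'
#' Evaluated on species-orthogroup cells that carry a tandem multiplet but
#' not a surviving ohnolog pair (cells with both are dominated by the
#' two-chromosome signal and are excluded).
#'
#' @param calls List of `ohnolog_call`s.
#' @param truth_genes The `truth$genes` table.
#' @return Fraction of tandem-only cells classified `"tandem"`, or `NA`
#'   when no such cell exists.
#' @export
tandem_accuracy <- function(calls, truth_genes) {
  cells <- truth_cells(truth_genes)
  tonly <- vapply(cells, function(c) c$tandem && !c$ohnolog, TRUE)
  if (!any(tonly)) return(NA_real_)
  keys <- vapply(cells, function(c)
    paste(c$species, c$orthogroup, sep = "\r"), "")[tonly]
  cls <- setNames(vapply(calls, `[[`, "", "class"),
                  vapply(calls, function(cl)
                    paste(cl$species, cl$orthogroup, sep = "\r"), ""))
  hit <- cls[keys]
  mean(!is.na(hit) & hit == "tandem")
}
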