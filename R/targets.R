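#' Prioritize drug targets among the selected genes
#'
#' Joins the selected, association-ranked genes against a local drug-gene
#' interaction table; genes with at least one interaction are retained and
#' genes belonging to any exclusion set (e.g. "BCR signaling" members, or
#' targets already under clinical study in the disease) are flagged
#' excluded with the set name as the reason. The final priority order
#' among retained, non-excluded genes is the association rank.
#'
#' @param selected_genes character vector of gene symbols in association
#'   rank order (best first).
#' @param interactions data.frame with columns `gene`, `drug`, `source`.
#' @param exclusions a `gene_set_collection` (or named list) of exclusion
#'   sets; may be empty.
#' @return list: `table` (data.frame: gene, rank, drugs, sources,
#'   excluded, reason, priority — NA for excluded genes),
#'   `n_without_interaction` (selected genes absent from the interaction
#'   table).
#' @export
prioritize_targets <- function(selected_genes, interactions,
                               exclusions = list()) {
  need <- c("gene", "drug", "source")
  if (!all(need %in% colnames(interactions))) {
    stop("interaction table must have columns gene, drug, source", call. = FALSE)
  }
  genes_up <- toupper(selected_genes)
  inter_up <- toupper(interactions$gene)
  has_drug <- genes_up %in% inter_up
  kept <- selected_genes[has_drug]
  kept_up <- genes_up[has_drug]
  drugs <- vapply(kept_up, function(g) {
    paste(sort(unique(interactions$drug[inter_up == g])), collapse = ";")
  }, character(1))
  sources <- vapply(kept_up, function(g) {
    paste(sort(unique(interactions$source[inter_up == g])), collapse = ";")
  }, character(1))
  reason <- vapply(kept_up, function(g) {
    hit <- names(exclusions)[vapply(exclusions, function(s) g %in% toupper(s), logical(1))]
    paste(hit, collapse = ";")
  }, character(1))
  excluded <- nzchar(reason)
  tab <- data.frame(gene = kept, rank = which(has_drug),
                    drugs = unname(drugs), sources = unname(sources),
                    excluded = unname(excluded),
                    reason = ifelse(excluded, unname(reason), NA_character_),
                    stringsAsFactors = FALSE)
  tab$priority <- NA_integer_
  tab$priority[!tab$excluded] <- seq_len(sum(!tab$excluded))
  rownames(tab) <- NULL
  list(table = tab, n_without_interaction = sum(!has_drug))
}
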