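#' Read a GMT gene-set collection
#'
#' Each line is `set name<TAB>description<TAB>member...`; members are
#' uppercase-normalized and deduplicated.
#'
#' @param path GMT file.
#' @return named list of class `gene_set_collection`; each element is a
#'   character vector of gene symbols with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT parse error at line %d of %s: fewer than 3 fields", i, path),
           call. = FALSE)
    }
    members <- unique(toupper(parts[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[parts[1]]] <- structure(members, description = parts[2])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute per set).
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric over-representation of a query gene list
#'
#' For each set, with universe size `N`, set size `K` (after intersecting
#' with the universe), query size `n` and overlap `k`, the upper-tail
#' p-value is `P(X >= k)` for `X` hypergeometric, followed by
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of gene symbols (must lie in the
#'   universe; case-normalized).
#' @param collection a `gene_set_collection` (or named list of vectors).
#' @param universe character vector defining the background, typically all
#'   genes measured in at least one QC-passed batch.
#' @return data.frame: `set`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `overlap_genes` (semicolon-separated), ordered by `p`.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(toupper(collection[[nm]])), universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               overlap_genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), c("set", "k", "K", "n", "N", "p", "q", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#' @param p vector of p-values in (0, 1].
#' @return q-values aligned to the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' The nine pathway-annotation categories
#' @export
annotation_categories <- c(
  "BCR signaling", "cytoskeleton regulation", "DNA repair and cell cycle",
  "histone modification", "immune regulation", "metabolism",
  "protein processing", "RNA processing", "signaling protein")

#' Annotate genes with a single pathway category
#'
#' Each gene carries at most one of the nine categories (a gene mapped to
#' two categories is a validation error); genes absent from the map are
#' labeled "unannotated".
#'
#' @param genes character vector of gene symbols.
#' @param category_map data.frame with columns `gene` and `category`.
#' @return list: `table` (gene, category), `counts` (named count per
#'   category present).
#' @export
annotate_categories <- function(genes, category_map) {
  stopifnot(all(c("gene", "category") %in% colnames(category_map)))
  bad_cat <- setdiff(unique(category_map$category), annotation_categories)
  if (length(bad_cat)) {
    stop("unknown annotation categor(ies): ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(category_map$gene[duplicated(category_map$gene)])
  if (length(dup)) {
    stop("gene(s) mapped to more than one category: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  lab <- category_map$category[match(genes, category_map$gene)]
  lab[is.na(lab)] <- "unannotated"
  tab <- data.frame(gene = genes, category = lab, stringsAsFactors = FALSE)
  counts <- table(factor(lab, levels = c(annotation_categories, "unannotated")))
  list(table = tab, counts = counts)
}
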