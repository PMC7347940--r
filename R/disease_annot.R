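# Gene-disease annotation: join the gene catalog against a flattened
# Orphadata-style association table, expanding gene-symbol aliases from
# an NCBI gene_info-style table.

#' Load a gene-disease association table with alias expansion
#'
#' The disease table is a TSV with columns `symbol`, `disorder_id`,
#' `disorder_name`. The alias source is a gene_info-style TSV carrying
#' `Symbol` and `Synonyms` columns (synonyms separated by `|`; `-`
#' denotes none). Matching is performed on uppercased symbols. Canonical
#' symbols always map to themselves; an alias claimed by two different
#' canonical symbols is ambiguous and is dropped with a warning.
#'
#' @param disease_path Path to the disease association TSV.
#' @param gene_info_path Path to the gene_info-style TSV.
#' @return A `gene_disease_table`: list with `associations` (data.table
#'   `symbol`, `disorder_id`, `disorder_name`) and `aliases` (data.table
#'   `alias` -> `symbol`, both uppercased, canonical self-pairs
#'   included).
#' @export
load_gene_disease <- function(disease_path, gene_info_path) {
  dis <- fread(disease_path, sep = "\t", header = TRUE,
               colClasses = "character")
  need <- c("symbol", "disorder_id", "disorder_name")
  if (!all(need %in% names(dis)))
    stop("disease table lacks required column(s): ",
         paste(setdiff(need, names(dis)), collapse = ", "))
  gi <- fread(gene_info_path, sep = "\t", header = TRUE,
              colClasses = "character")
  if (!all(c("Symbol", "Synonyms") %in% names(gi)))
    stop("gene_info table lacks required columns Symbol, Synonyms")
  dis[, symbol := toupper(symbol)]
  canon <- toupper(gi$Symbol)
  alias <- rbindlist(lapply(seq_len(nrow(gi)), function(i) {
    syn <- strsplit(gi$Synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- toupper(syn[nzchar(syn) & syn != "-"])
    if (!length(syn)) return(NULL)
    data.table(alias = syn, symbol = canon[i])
  }))
  self <- data.table(alias = unique(canon), symbol = unique(canon))
  if (is.null(alias) || !nrow(alias)) {
    alias <- self
  } else {
    # canonical symbols win over any synonym claim on the same string
    alias <- alias[!alias %in% canon]
    alias <- unique(alias)
    amb <- alias[, .N, by = alias][N > 1L, alias]
    if (length(amb)) {
      warning("dropping ambiguous alias(es) claimed by multiple genes: ",
              paste(amb, collapse = ", "))
      alias <- alias[!alias %in% amb]
    }
    alias <- rbind(self, alias)
  }
  structure(list(associations = dis[], aliases = alias[]),
            class = "gene_disease_table")
}

#' Look up disorder associations for gene symbols
#'
#' @param table A `gene_disease_table`.
#' @param symbols Character vector of gene symbols (aliases accepted).
#' @return List (one element per input symbol) of disorder_id vectors;
#'   empty when unassociated.
#' @export
lookup_disorders <- function(table, symbols) {
  stopifnot(inherits(table, "gene_disease_table"))
  up <- toupper(symbols)
  canon <- table$aliases$symbol[match(up, table$aliases$alias)]
  canon[is.na(canon)] <- up[is.na(canon)]
  lapply(canon, function(s)
    table$associations[symbol == s, unique(disorder_id)])
}

#' Annotate a gene catalog with disease associations
#'
#' Flags a gene when its symbol, or any alias of it, appears in the
#' association table. The unique flagged-gene counter counts each gene
#' once; per-label tallies allow a gene under several event labels.
#'
#' @param catalog A `gene_catalog` (from [summarize_gene_catalog()]) or
#'   a `data.frame` with a `gene_symbol` column.
#' @param table A `gene_disease_table`.
#' @return The catalog with `disease_associated` and `disorder_ids`
#'   columns added to its gene table (and updated summary counters for
#'   `gene_catalog` input).
#' @export
annotate_catalog <- function(catalog, table) {
  stopifnot(inherits(table, "gene_disease_table"))
  is_cat <- inherits(catalog, "gene_catalog")
  genes <- if (is_cat) copy(catalog$genes) else copy(as.data.table(catalog))
  if (!"gene_symbol" %in% names(genes))
    stop("catalog must carry a gene_symbol column")
  hits <- lookup_disorders(table, genes$gene_symbol)
  genes[, disease_associated := lengths(hits) > 0L]
  genes[, disorder_ids := vapply(hits, paste, "", collapse = ",")]
  if (!is_cat) return(genes[])
  catalog$genes <- genes[]
  flagged <- genes[disease_associated == TRUE, gene_id]
  catalog$summary$n_disease_genes <- length(unique(flagged))
  if (nrow(catalog$events)) {
    ev <- catalog$events
    per_label <- ev[gene_id %in% flagged,
                    .(n_disease_genes = length(unique(gene_id))), by = label]
    catalog$summary$disease_genes_per_label <- per_label[order(label)]
  }
  catalog
}
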