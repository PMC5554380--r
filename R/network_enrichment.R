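#' Seed-plus-first-neighbor subnetwork with degree centrality
#'
#' Induces the subgraph on the seed genes and their direct interactors in
#' the supplied interaction network, then reports each node's degree within
#' that subgraph (the only centrality used downstream: hub genes are the
#' highest-degree nodes). A seed absent from the interaction table is kept
#' as an isolated node with a warning.
#'
#' @param seeds character vector of seed gene symbols.
#' @param interactions an undirected `igraph` graph (see [read_edge_list()]).
#' @return list of class `network_graph`: `graph` (igraph), `nodes`,
#'   `n_nodes`, `n_edges`, `degree` (named, sorted decreasing), `seeds`.
#' @export
first_neighbor_network <- function(seeds, interactions) {
  stopifnot(length(seeds) >= 1, igraph::is_igraph(interactions))
  known <- intersect(seeds, igraph::V(interactions)$name)
  missing <- setdiff(seeds, known)
  if (length(missing))
    warning("seed(s) absent from the interaction table, kept isolated: ",
            paste(missing, collapse = ", "))
  nbrs <- if (length(known))
    unique(unlist(lapply(igraph::ego(interactions, 1, known), names)))
  else character()
  keep <- union(known, nbrs)
  sub <- igraph::induced_subgraph(interactions, keep)
  sub <- igraph::add_vertices(sub, length(missing), name = missing)
  deg <- sort(igraph::degree(sub), decreasing = TRUE)
  structure(list(graph = sub, nodes = igraph::V(sub)$name,
                 n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub),
                 degree = deg, seeds = seeds),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d nodes, %d edges (seeds: %s)\n",
              x$n_nodes, x$n_edges, paste(x$seeds, collapse = ", ")))
  cat("  top degree:", paste(sprintf("%s=%d", names(utils::head(x$degree, 5)),
                                     utils::head(x$degree, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one query hit, tests whether the query gene
#' set is enriched for the term's annotation against the background
#' universe, using the upper-tail hypergeometric probability
#' `P(X >= k)` with `k` query hits, `n` annotated query genes, `K` background
#' genes in the term, and universe size `N`. GeneRatio is `k/n`, BgRatio is
#' `K/N`. p-values are Benjamini-Hochberg adjusted across all emitted terms;
#' significance is conventionally called at BH <= 0.05.
#'
#' @param query character vector of query gene symbols.
#' @param gene_sets named list, term -> genes ([read_gene_sets()]).
#' @param background gene universe; default: all genes in `gene_sets`
#'   (the annotated universe).
#' @return data.frame of class `enrichment_table`: term, description, k, n,
#'   K, N, gene_ratio, bg_ratio, p, p_bh — sorted by adjusted p.
#' @export
enrich <- function(query, gene_sets, background = NULL) {
  if (is.null(background)) background <- unique(unlist(gene_sets))
  if (!length(background)) stop("empty background universe")
  gene_sets <- lapply(gene_sets, intersect, y = background)
  q_ann <- intersect(unique(query), background)
  n <- length(q_ann)
  N <- length(background)
  desc <- attr(gene_sets, "description")
  rows <- lapply(names(gene_sets), function(term) {
    K <- length(gene_sets[[term]])
    k <- length(intersect(q_ann, gene_sets[[term]]))
    if (k < 1) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               description = if (!is.null(desc)) unname(desc[term]) else "",
               k = k, n = n, K = K, N = N,
               gene_ratio = k / n, bg_ratio = K / N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(structure(data.frame(), class = c("enrichment_table", "data.frame")))
  out <- do.call(rbind, rows)
  out$p_bh <- adjust_pvalues(out$p, "BH")
  out <- out[order(out$p_bh, out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Split genes into up/down sets by a strict log2 fold-change threshold
#'
#' Upregulated: `log2FC > threshold`; downregulated: `log2FC < -threshold`;
#' boundary values (exactly +/- threshold) are excluded.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param threshold strict cutoff (default 1).
#' @return list: `up`, `down` (character vectors of gene names).
#' @export
log2fc_filter <- function(log2fc, threshold = 1) {
  stopifnot(all(is.finite(log2fc)))
  list(up = names(log2fc)[log2fc > threshold],
       down = names(log2fc)[log2fc < -threshold])
}
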