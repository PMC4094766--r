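#' Build the tripartite miRNA-mRNA-lncRNA network linked through GO terms
#'
#' GO-term nodes are restricted to terms enriched on BOTH sides of the
#' analysis (the miRNA side, enriched over the pooled miRNA-associated mRNAs,
#' and the lncRNA side, enriched over the pooled neighbor coding genes) at
#' `q_cutoff`. mRNA nodes are the genes contributing to a shared term from
#' either side; miRNA and lncRNA nodes are the selected RNAs whose associated
#' or neighbor genes hit a shared term. Edges are typed: `targets`
#' (miRNA -> mRNA, only between selected miRNAs and their associated down-3/4
#' mRNAs), `neighbor` (lncRNA -> mRNA) and `annotated` (mRNA -> GO term).
#' For every (miRNA, lncRNA) pair, a shared-function score counts the shared
#' enriched terms hit by both the miRNA's associated mRNAs and the lncRNA's
#' neighbor genes (a Jaccard index over the two term sets is reported
#' alongside). Node and edge orderings are deterministic.
#'
#' @param mirna_assoc a [mirna_associated_mrnas()] result.
#' @param neighbor_genes a [neighbor_gene_set()] result.
#' @param enrichment_mirna_side [enrich()] result on the pooled associated
#'   mRNAs.
#' @param enrichment_lnc_side [enrich()] result on the pooled neighbor genes.
#' @param q_cutoff BH q-value at or below which a term counts as enriched
#'   (default 0.05).
#' @return An object of class `crosslink_network` with `nodes`, `edges`,
#'   `scores`, `shared_terms`, per-side enriched term sets and a `summary`
#'   count list.
#' @export
build_crosslink <- function(mirna_assoc, neighbor_genes,
                            enrichment_mirna_side, enrichment_lnc_side,
                            q_cutoff = 0.05) {
  stopifnot(inherits(mirna_assoc, "mirna_assoc"),
            inherits(neighbor_genes, "neighbor_gene_set"),
            inherits(enrichment_mirna_side, "enrichment_result"),
            inherits(enrichment_lnc_side, "enrichment_result"))
  n_pop_m <- attr(enrichment_mirna_side, "population_size")
  n_pop_l <- attr(enrichment_lnc_side, "population_size")
  if (!identical(n_pop_m, n_pop_l))
    stop("build_crosslink: the two enrichment sides were computed on ",
         "different populations (", n_pop_m, " vs ", n_pop_l, " genes)",
         call. = FALSE)

  terms_m <- enrichment_mirna_side$term[enrichment_mirna_side$q <= q_cutoff]
  terms_l <- enrichment_lnc_side$term[enrichment_lnc_side$q <= q_cutoff]
  shared <- sort(intersect(terms_m, terms_l))

  term_genes <- function(res, terms) {
    g <- res$genes[match(terms, res$term)]
    stats::setNames(g, terms)
  }
  genes_m <- term_genes(enrichment_mirna_side, shared)
  genes_l <- term_genes(enrichment_lnc_side, shared)

  # contributing RNAs and mRNAs, per shared term
  mir_sets <- mirna_assoc$per_mirna
  lnc_sets <- neighbor_genes$per_lnc
  mrna_nodes <- sort(unique(c(unlist(genes_m, use.names = FALSE),
                              unlist(genes_l, use.names = FALSE))))
  mirna_nodes <- sort(names(mir_sets)[vapply(mir_sets, function(g)
    any(g %in% mrna_nodes), logical(1))])
  lnc_nodes <- sort(names(lnc_sets)[vapply(lnc_sets, function(g)
    any(g %in% mrna_nodes), logical(1))])

  node_df <- function(ids, type, pattern) {
    data.frame(id = ids, type = rep_len(type, length(ids)),
               stage_pattern = rep_len(pattern, length(ids)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_df(mirna_nodes, "miRNA", "UP34"),
    node_df(lnc_nodes, "lncRNA", "UP34"),
    node_df(mrna_nodes, "mRNA", "DOWN34"),
    node_df(shared, "GO", "")
  )

  edge_df <- function(src, dst, type, pattern) {
    data.frame(source = src, target = dst, edge_type = type,
               stage_pattern = pattern, stringsAsFactors = FALSE)
  }
  edges <- list()
  for (m in mirna_nodes) {
    dst <- sort(intersect(mir_sets[[m]], mrna_nodes))
    if (length(dst)) edges[[paste0("t", m)]] <- edge_df(m, dst, "targets", "UP34")
  }
  for (l in lnc_nodes) {
    dst <- sort(intersect(lnc_sets[[l]], mrna_nodes))
    if (length(dst)) edges[[paste0("n", l)]] <- edge_df(l, dst, "neighbor", "UP34")
  }
  for (tm in shared) {
    dst <- sort(unique(c(genes_m[[tm]], genes_l[[tm]])))
    if (length(dst)) edges[[paste0("a", tm)]] <- edge_df(dst, tm, "annotated",
                                                         "DOWN34")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    edge_df(character(0), character(0), character(0), character(0))
  edges <- unique(edges)
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  # shared-function scores over the shared enriched terms
  mir_terms <- lapply(stats::setNames(mirna_nodes, mirna_nodes), function(m)
    shared[vapply(shared, function(tm)
      any(mir_sets[[m]] %in% genes_m[[tm]]), logical(1))])
  lnc_terms <- lapply(stats::setNames(lnc_nodes, lnc_nodes), function(l)
    shared[vapply(shared, function(tm)
      any(lnc_sets[[l]] %in% genes_l[[tm]]), logical(1))])
  scores <- expand.grid(mirna = mirna_nodes, lnc = lnc_nodes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(scores)) {
    scores$shared_terms <- mapply(function(m, l)
      length(intersect(mir_terms[[m]], lnc_terms[[l]])),
      scores$mirna, scores$lnc)
    scores$jaccard <- mapply(function(m, l) {
      u <- length(union(mir_terms[[m]], lnc_terms[[l]]))
      if (u == 0L) 0 else length(intersect(mir_terms[[m]],
                                           lnc_terms[[l]])) / u
    }, scores$mirna, scores$lnc)
  } else {
    scores$shared_terms <- integer(0)
    scores$jaccard <- numeric(0)
  }
  scores <- scores[order(scores$mirna, scores$lnc), , drop = FALSE]
  rownames(scores) <- NULL

  structure(
    list(nodes = nodes, edges = edges, scores = scores,
         shared_terms = shared,
         terms_mirna_side = sort(terms_m), terms_lnc_side = sort(terms_l),
         q_cutoff = q_cutoff,
         summary = list(n_terms_mirna_side = length(terms_m),
                        n_terms_lnc_side = length(terms_l),
                        n_shared_terms = length(shared),
                        n_mirna = length(mirna_nodes),
                        n_lnc = length(lnc_nodes),
                        n_mrna = length(mrna_nodes),
                        n_edges = nrow(edges))),
    class = "crosslink_network"
  )
}

#' @export
print.crosslink_network <- function(x, ...) {
  s <- x$summary
  cat("Tripartite cross-link network\n")
  cat(sprintf("  enriched terms: %d (miRNA side) / %d (lncRNA side), %d shared\n",
              s$n_terms_mirna_side, s$n_terms_lnc_side, s$n_shared_terms))
  cat(sprintf("  nodes: %d miRNA, %d lncRNA, %d mRNA, %d GO; %d edges\n",
              s$n_mirna, s$n_lnc, s$n_mrna, s$n_shared_terms, s$n_edges))
  invisible(x)
}

#' Export a cross-link network
#'
#' Three interchange formats: a typed edge list TSV, GraphML (via igraph),
#' and a lossless JSON serialization that [import_network_json()] reads back
#' unchanged.
#'
#' @param network a [build_crosslink()] result.
#' @param path output file path.
#' @param format `"tsv"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml", "json")) {
  stopifnot(inherits(network, "crosslink_network"))
  if (length(format) == 1L && !format %in% c("tsv", "graphml", "json"))
    stop("export_network: unknown format '", format, "'", call. = FALSE)
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    payload <- list(nodes = network$nodes, edges = network$edges,
                    scores = network$scores,
                    shared_terms = network$shared_terms,
                    terms_mirna_side = network$terms_mirna_side,
                    terms_lnc_side = network$terms_lnc_side,
                    q_cutoff = network$q_cutoff,
                    summary = network$summary)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cross-link network back from its JSON export
#'
#' @param path JSON file written by [export_network()].
#' @return A `crosslink_network` equal to the exported one.
#' @export
import_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_chr_df <- function(df, cols) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cl in cols) df[[cl]] <- as.character(df[[cl]])
    df
  }
  empty_edges <- data.frame(source = character(0), target = character(0),
                            edge_type = character(0),
                            stage_pattern = character(0),
                            stringsAsFactors = FALSE)
  empty_scores <- data.frame(mirna = character(0), lnc = character(0),
                             shared_terms = integer(0), jaccard = numeric(0),
                             stringsAsFactors = FALSE)
  nodes <- if (length(x$nodes)) as_chr_df(x$nodes, c("id", "type",
                                                     "stage_pattern"))
           else data.frame(id = character(0), type = character(0),
                           stage_pattern = character(0),
                           stringsAsFactors = FALSE)
  edges <- if (length(x$edges)) as_chr_df(x$edges, c("source", "target",
                                                     "edge_type",
                                                     "stage_pattern"))
           else empty_edges
  scores <- if (length(x$scores)) {
    s <- as_chr_df(x$scores, c("mirna", "lnc"))
    s$shared_terms <- as.integer(s$shared_terms)
    s$jaccard <- as.numeric(s$jaccard)
    s
  } else empty_scores
  structure(
    list(nodes = nodes, edges = edges, scores = scores,
         shared_terms = as.character(unlist(x$shared_terms)),
         terms_mirna_side = as.character(unlist(x$terms_mirna_side)),
         terms_lnc_side = as.character(unlist(x$terms_lnc_side)),
         q_cutoff = x$q_cutoff,
         summary = lapply(x$summary, as.integer)),
    class = "crosslink_network"
  )
}
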