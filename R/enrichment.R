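#' Read a GO annotation from GMT or long-form TSV
#'
#' GMT files (term id, description, then gene ids, tab-separated) are parsed
#' with [fgsea::gmtPathways()]; long-form TSV needs a header with columns
#' `term_id` and `gene_id` (and optionally `description`). Memberships are
#' deduplicated per term.
#'
#' @param path file path; format chosen by extension (`.gmt` vs anything
#'   else) unless `format` is given.
#' @param format `"gmt"` or `"tsv"`.
#' @return A `go_annotation`: list with `terms` (named list of gene-id
#'   vectors) and `desc` (named descriptions).
#' @export
read_go_annotation <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    terms <- lapply(fgsea::gmtPathways(path), function(v) sort(unique(v)))
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 2L]
    desc <- stats::setNames(vapply(fields, `[`, "", 2L),
                            vapply(fields, `[`, "", 1L))
    desc <- desc[names(terms)]
  } else {
    df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(df)))
      stop("read_go_annotation: TSV needs columns 'term_id' and 'gene_id'",
           call. = FALSE)
    terms <- lapply(split(df$gene_id, df$term_id), function(v) sort(unique(v)))
    desc <- if ("description" %in% names(df))
      stats::setNames(df$description[!duplicated(df$term_id)],
                      df$term_id[!duplicated(df$term_id)])[names(terms)]
    else stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms, desc = desc), class = "go_annotation")
}

#' Write a GO annotation as GMT and/or long-form TSV
#'
#' @param go a `go_annotation`.
#' @param path output path; format chosen by extension (`.gmt` writes GMT,
#'   otherwise long-form TSV).
#' @return `path`, invisibly.
#' @export
write_go_annotation <- function(go, path) {
  stopifnot(inherits(go, "go_annotation"))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- vapply(names(go$terms), function(tm)
      paste(c(tm, go$desc[[tm]], go$terms[[tm]]), collapse = "\t"), "")
    writeLines(lines, path)
  } else {
    df <- data.frame(term_id = rep(names(go$terms), lengths(go$terms)),
                     gene_id = unlist(go$terms, use.names = FALSE),
                     stringsAsFactors = FALSE)
    df$description <- go$desc[df$term_id]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Local GO-term enrichment (hypergeometric / EASE)
#'
#' For each term with at least `min_overlap` study genes, the upper-tail
#' hypergeometric probability of drawing `k` or more annotated genes in a
#' study set of size `n` from a population of `N` genes of which `K` carry
#' the term:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The EASE score is the same tail computed with the overlap reduced by one
#' (`max(k - 1, 0)`), a deliberately conservative variant popularized by the
#' DAVID service; with `k = 1` it equals 1. Benjamini-Hochberg q-values are
#' computed across the tested terms on the active statistic, and results are
#' sorted by p-value then term id.
#'
#' @param study_set character vector of study gene ids; must be a subset of
#'   `population`.
#' @param annotation a `go_annotation`.
#' @param population character vector of background gene ids (e.g. all
#'   annotated coding genes detected on the array).
#' @param method active statistic: `"ease"` (default) or `"fisher"` (plain
#'   hypergeometric).
#' @param min_overlap minimum study-set overlap for a term to be tested
#'   (default 2).
#' @return A data frame of class `enrichment_result` with columns term,
#'   description, N, K, n, k, p_hyper, ease, p (active statistic), q and a
#'   list-column `genes` of the overlapping gene ids. The population size is
#'   carried in attribute `population_size`.
#' @export
enrich <- function(study_set, annotation, population,
                   method = c("ease", "fisher"), min_overlap = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(annotation, "go_annotation"))
  study_set <- unique(study_set)
  population <- unique(population)
  outside <- setdiff(study_set, population)
  if (length(outside))
    stop("enrich: study genes outside the population: ",
         paste(utils::head(outside, 10L), collapse = ", "),
         if (length(outside) > 10L) ", ..." else "", call. = FALSE)
  N <- length(population)
  n <- length(study_set)

  rows <- lapply(names(annotation$terms), function(tm) {
    members <- intersect(annotation$terms[[tm]], population)
    K <- length(members)
    hits <- intersect(members, study_set)
    k <- length(hits)
    if (k < min_overlap) return(NULL)
    p_hyper <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    ease <- stats::phyper(max(k - 1L, 0L) - 1L, K, N - K, n,
                          lower.tail = FALSE)
    data.frame(term = tm,
               description = unname(annotation$desc[tm]),
               N = N, K = K, n = n, k = k,
               p_hyper = p_hyper, ease = ease,
               genes = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    res <- data.frame(term = character(0), description = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), p_hyper = numeric(0), ease = numeric(0),
                      p = numeric(0), q = numeric(0),
                      genes = I(list()), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
    res$p <- if (method == "ease") res$ease else res$p_hyper
    res$q <- stats::p.adjust(res$p, method = "BH")
    res <- res[order(res$p, res$term), , drop = FALSE]
    res <- res[, c("term", "description", "N", "K", "n", "k",
                   "p_hyper", "ease", "p", "q", "genes")]
    rownames(res) <- NULL
  }
  attr(res, "method") <- method
  attr(res, "population_size") <- N
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GO enrichment (%s statistic): %d terms tested, %d at q <= 0.05\n",
              attr(x, "method"), nrow(x), sum(x$q <= 0.05)))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, c("term", "K", "n", "k", "p", "q")],
                      8L), row.names = FALSE)
  invisible(x)
}

#' Attach source miRNAs and lncRNAs to enriched terms
#'
#' For every enriched term, records which selected miRNAs contributed
#' (their associated mRNAs hit the term) and which selected lncRNAs
#' contributed (their neighbor coding genes hit the term) -- the bookkeeping
#' that lets the tripartite network tie the three RNA classes together
#' through shared functions.
#'
#' @param results an [enrich()] result.
#' @param mirna_assoc optional [mirna_associated_mrnas()] result.
#' @param neighbor_genes optional [neighbor_gene_set()] result.
#' @return `results` with list-columns `mirnas` and `lncs` added.
#' @export
annotate_enrichment_to_sources <- function(results, mirna_assoc = NULL,
                                           neighbor_genes = NULL) {
  stopifnot(inherits(results, "enrichment_result"))
  hit_sources <- function(term_genes, sets) {
    if (is.null(sets)) return(character(0))
    names(sets)[vapply(sets, function(g) length(intersect(g, term_genes)) > 0L,
                       logical(1))]
  }
  mir_sets <- if (!is.null(mirna_assoc)) mirna_assoc$per_mirna else NULL
  lnc_sets <- if (!is.null(neighbor_genes)) neighbor_genes$per_lnc else NULL
  results$mirnas <- I(lapply(results$genes, hit_sources, sets = mir_sets))
  results$lncs <- I(lapply(results$genes, hit_sources, sets = lnc_sets))
  results
}

#' Write enrichment results to TSV
#'
#' @param results an [enrich()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  stopifnot(inherits(results, "enrichment_result"))
  df <- as.data.frame(results)
  for (col in intersect(c("genes", "mirnas", "lncs"), names(df)))
    df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
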