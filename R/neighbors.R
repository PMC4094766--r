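#' Read coding and lncRNA gene loci from BED6
#'
#' Intervals follow the BED convention (0-based, half-open). The biotype of
#' each locus is taken from its name prefix (`LNC`/`LINC` ids are lncRNAs,
#' anything else coding) or, when `biotype_tsv` is given, from a two-column
#' companion table (gene_id, biotype). Degenerate intervals (start >= end)
#' and unknown biotypes are rejected with their line number.
#'
#' @param path BED6 file path.
#' @param biotype_tsv optional TSV with columns `gene_id` and `biotype`
#'   (`coding` or `lncRNA`).
#' @return A `genome_annotation` data frame (gene_id, chrom, start, end,
#'   strand, biotype) sorted by chromosome and start.
#' @export
read_loci <- function(path, biotype_tsv = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    gene_id = if (!is.null(gr$name)) as.character(gr$name)
              else sprintf("locus%05d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("read_loci: degenerate interval (start >= end) at line ", bad[1L],
         " of ", path, call. = FALSE)
  if (is.null(biotype_tsv)) {
    df$biotype <- ifelse(grepl("^(LNC|LINC)", df$gene_id, ignore.case = TRUE),
                         "lncRNA", "coding")
  } else {
    bt <- utils::read.delim(biotype_tsv, header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    df$biotype <- bt$biotype[match(df$gene_id, bt$gene_id)]
    bad <- which(is.na(df$biotype) | !df$biotype %in% c("coding", "lncRNA"))
    if (length(bad))
      stop("read_loci: unknown biotype for gene '", df$gene_id[bad[1L]],
           "' at line ", bad[1L], " of ", path, call. = FALSE)
  }
  as_genome_annotation(df)
}

#' Build a genome annotation from a data frame of loci
#'
#' @param df data frame with columns gene_id, chrom, start, end, strand,
#'   biotype (0-based half-open intervals).
#' @return A validated `genome_annotation`, sorted by chromosome and start.
#' @export
as_genome_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(df)))
    stop("as_genome_annotation: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (any(df$start >= df$end))
    stop("as_genome_annotation: degenerate interval (start >= end)",
         call. = FALSE)
  if (any(df$chrom == "" | is.na(df$chrom)))
    stop("as_genome_annotation: empty chromosome name", call. = FALSE)
  if (!all(df$biotype %in% c("coding", "lncRNA")))
    stop("as_genome_annotation: biotype must be 'coding' or 'lncRNA'",
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("as_genome_annotation: duplicated gene ids", call. = FALSE)
  df <- df[order(df$chrom, df$start, df$gene_id), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Write a genome annotation as BED6
#'
#' @param annotation a `genome_annotation`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  gr$name <- annotation$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Nearest flanking coding genes of each lncRNA
#'
#' Assigns every lncRNA locus its two flanking coding genes: upstream is the
#' coding gene with the largest end coordinate not exceeding the lncRNA
#' start, downstream the coding gene with the smallest start coordinate not
#' below the lncRNA end (distances are interval gaps in bp, ignoring strand).
#' A coding gene overlapping the lncRNA is assigned at distance 0 on the side
#' of its midpoint relative to the lncRNA midpoint. Ties in distance are
#' broken toward the lexicographically smaller gene id. A side with no
#' candidate on the chromosome stays empty (`NA`); lncRNAs on chromosomes
#' without any coding gene get an empty assignment with a warning.
#'
#' The implementation binary-searches sorted per-chromosome coordinate
#' indexes (via [findInterval()]); it is checked against an exhaustive linear
#' scan in the test-suite.
#'
#' @param annotation a `genome_annotation` containing both coding and lncRNA
#'   loci.
#' @param lnc_ids optional character vector restricting the lncRNAs assigned;
#'   default all lncRNA loci in the annotation.
#' @return A data frame of class `neighbor_assignment`: lnc_id, upstream_id,
#'   upstream_distance, downstream_id, downstream_distance.
#' @export
nearest_neighbors <- function(annotation, lnc_ids = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lnc <- annotation[annotation$biotype == "lncRNA", , drop = FALSE]
  if (!is.null(lnc_ids)) lnc <- lnc[lnc$gene_id %in% lnc_ids, , drop = FALSE]
  res <- data.frame(lnc_id = lnc$gene_id,
                    upstream_id = NA_character_, upstream_distance = NA_real_,
                    downstream_id = NA_character_,
                    downstream_distance = NA_real_,
                    stringsAsFactors = FALSE)
  bare_chroms <- character(0)
  for (ch in unique(lnc$chrom)) {
    li <- which(lnc$chrom == ch)
    cod <- annotation[annotation$biotype == "coding" &
                        annotation$chrom == ch, , drop = FALSE]
    if (nrow(cod) == 0L) { bare_chroms <- c(bare_chroms, ch); next }
    # end-sorted index (ties: larger id first, so the last hit is the
    # lexicographic minimum among maximal ends)
    ordu <- order(cod$end, -xtfrm(cod$gene_id))
    end_u <- cod$end[ordu]; id_u <- cod$gene_id[ordu]
    # start-sorted index (ties: smaller id first)
    ordd <- order(cod$start, xtfrm(cod$gene_id))
    start_d <- cod$start[ordd]; id_d <- cod$gene_id[ordd]
    end_d <- cod$end[ordd]
    mid_d <- (start_d + end_d) / 2

    for (i in li) {
      s <- lnc$start[i]; e <- lnc$end[i]; mid <- (s + e) / 2
      up_id <- NA_character_; up_d <- Inf
      dn_id <- NA_character_; dn_d <- Inf
      ui <- findInterval(s, end_u)
      if (ui >= 1L) { up_id <- id_u[ui]; up_d <- s - end_u[ui] }
      p <- findInterval(e - 0.5, start_d)   # number of coding starts < e
      if (p < length(start_d)) { dn_id <- id_d[p + 1L]; dn_d <- start_d[p + 1L] - e }
      if (p >= 1L) {
        ov <- which(end_d[seq_len(p)] > s)  # overlapping coding genes
        for (o in ov) {
          if (mid_d[o] <= mid) {
            if (up_d > 0 || (up_d == 0 && id_d[o] < up_id)) {
              up_id <- id_d[o]; up_d <- 0
            }
          } else {
            if (dn_d > 0 || (dn_d == 0 && id_d[o] < dn_id)) {
              dn_id <- id_d[o]; dn_d <- 0
            }
          }
        }
      }
      res$upstream_id[i] <- up_id
      res$upstream_distance[i] <- if (is.finite(up_d)) up_d else NA_real_
      res$downstream_id[i] <- dn_id
      res$downstream_distance[i] <- if (is.finite(dn_d)) dn_d else NA_real_
    }
  }
  if (length(bare_chroms))
    warning("nearest_neighbors: no coding genes on chromosome(s) ",
            paste(bare_chroms, collapse = ", "),
            "; lncRNAs there get empty assignments")
  class(res) <- c("neighbor_assignment", "data.frame")
  res
}

#' Pool the neighbor coding genes of selected lncRNAs
#'
#' The union of assigned flanking coding genes over the selected lncRNAs --
#' the gene set carried into GO enrichment on the lncRNA side -- together
#' with the number of selected lncRNAs that have at least one neighbor.
#'
#' @param assignments a [nearest_neighbors()] result.
#' @param selected_lncs character vector of lncRNA ids; defaults to all
#'   assigned lncRNAs.
#' @return A list of class `neighbor_gene_set`: `genes` (sorted union),
#'   `n_lnc_with_neighbor`, and `per_lnc` (named list of each lncRNA's
#'   neighbor genes).
#' @export
neighbor_gene_set <- function(assignments, selected_lncs = NULL) {
  stopifnot(inherits(assignments, "neighbor_assignment"))
  a <- assignments
  if (!is.null(selected_lncs))
    a <- a[a$lnc_id %in% selected_lncs, , drop = FALSE]
  per <- lapply(seq_len(nrow(a)), function(i)
    sort(unique(stats::na.omit(c(a$upstream_id[i], a$downstream_id[i])))))
  names(per) <- a$lnc_id
  structure(list(genes = sort(unique(unlist(per, use.names = FALSE))),
                 n_lnc_with_neighbor = sum(lengths(per) > 0L),
                 per_lnc = per),
            class = "neighbor_gene_set")
}

#' @export
print.neighbor_gene_set <- function(x, ...) {
  cat(sprintf("Neighbor gene set: %d coding genes from %d lncRNAs with >=1 neighbor\n",
              length(x$genes), x$n_lnc_with_neighbor))
  invisible(x)
}

#' Write neighbor assignments to TSV
#'
#' @param assignments a [nearest_neighbors()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighbors <- function(assignments, path) {
  stopifnot(inherits(assignments, "neighbor_assignment"))
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
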