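#' Generate all pipeline inputs with planted truth
#'
#' Runs the four synthetic-data generators in sequence -- expression tables,
#' genome annotation, miRNA target map, GO annotation -- threading the
#' planted-truth record through them, and returns everything needed to run
#' and verify the full pipeline. With `noise_log2_sd = 0` every planted
#' fold change is observed exactly and the downstream differential-expression
#' caller recovers the planted sets with sensitivity and specificity 1.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `triome_sim` with elements `config`, `expression`
#'   (named list of three [stage_expression()] tables), `annotation`
#'   (a `genome_annotation`), `target_map`, `go` (a `go_annotation`) and
#'   `truth` (the planted-truth record).
#' @export
#' @examples
#' sim <- simulate_triome(sim_config(n_lnc = 60, n_mrna = 120, n_mirna = 12,
#'                                   planted_up34_lncs = 6,
#'                                   planted_down34_mrnas = 20,
#'                                   targets_per_mirna = 15,
#'                                   genes_per_term = 12, n_go_terms = 8,
#'                                   noise_log2_sd = 0, seed = 11))
#' sim$truth$up34_mirnas
simulate_triome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  expr <- generate_expression(config)
  truth <- expr$truth
  ann <- generate_genome_annotation(config)
  truth$lnc_neighbors <- attr(ann, "planted_neighbors")
  tm <- generate_target_map(config, truth)
  truth$mirna_targets <- unclass(tm)
  go <- generate_go_annotation(config, truth)
  truth$enriched_terms <- attr(go, "planted_terms")
  structure(
    list(config = config, expression = expr$tables, annotation = ann,
         target_map = tm, go = go, truth = truth),
    class = "triome_sim"
  )
}

#' @export
print.triome_sim <- function(x, ...) {
  cat("Synthetic five-stage study\n")
  cat(sprintf("  %d lncRNA / %d miRNA / %d mRNA probes, seed %d\n",
              x$config$n_lnc, x$config$n_mirna, x$config$n_mrna,
              x$config$seed))
  cat(sprintf("  planted up-3/4 miRNAs: %s\n",
              paste(x$truth$up34_mirnas, collapse = ", ")))
  cat(sprintf("  planted down-3/4 mRNAs: %d; up-3/4 lncRNAs: %d\n",
              length(x$truth$down34_mrnas), length(x$truth$up34_lncs)))
  cat(sprintf("  genome: %d loci on %d chromosomes; %d GO terms (%d planted)\n",
              nrow(x$annotation), x$config$n_chromosomes,
              length(x$go$terms), length(x$truth$enriched_terms)))
  invisible(x)
}

# deterministic probe-id universes; a pure function of the config so every
# generator can reconstruct them without sharing state
probe_ids <- function(config) {
  list(
    lncRNA = sprintf("LNC%05d", seq_len(config$n_lnc)),
    miRNA  = sprintf("MIR%04d", seq_len(config$n_mirna)),
    mRNA   = sprintf("MRNA%05d", seq_len(config$n_mrna))
  )
}

# derived sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

# sample() that never falls into the 1:n trap for length-1 numeric vectors
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Generate the three stage-expression tables and the planted-truth record
#'
#' Stage 1 holds log-normal baseline intensities; each disease stage carries a
#' planted set of probes whose signal is the baseline multiplied (up) or
#' divided (down) by `planted_fc`, with multiplicative log2-normal noise
#' applied to every cell afterwards. Planting is restricted to probes whose
#' baseline exceeds `detect_floor * planted_fc`, so planted probes remain
#' detected in every stage even when downregulated. Exactly
#' `planted_up34_mirnas` miRNAs are upregulated in both stages 3 and 4 (any
#' coincidental extras are demoted from the stage-4 set); `planted_up34_lncs`
#' lncRNAs and `planted_down34_mrnas` mRNAs are forced into the corresponding
#' stage-3/4 patterns. A small block of probes per class (a quarter of the
#' per-stage planting budget; none for miRNAs) is upregulated in all four
#' disease stages so the intersection collection is non-empty.
#'
#' @param config a [sim_config()].
#' @return A list with `tables` (named list of three [stage_expression()]
#'   objects) and `truth` (per-class planted sets, co-expressed probes and the
#'   stage-3/4 pattern sets).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 0))
  ids <- probe_ids(config)

  gen_class <- function(class_ids, rna_class) {
    n <- length(class_ids)
    baseline <- pmax(2^stats::rnorm(n, config$baseline_log2_mean,
                                    config$baseline_log2_sd), 1e-6)
    names(baseline) <- class_ids
    eligible <- class_ids[baseline > config$detect_floor * config$planted_fc]
    n_de <- max(1L, round(config$de_fraction_per_stage * n))
    n_persist <- round(n_de / 4)
    persistent <- if (n_persist > 0L)
      sample(eligible, min(n_persist, length(eligible))) else character(0)
    # the all-stage block is downregulated for miRNAs so it cannot collide
    # with the exactly-planted up-in-3/4 guarantee
    persist_up <- rna_class != "miRNA"

    up <- down <- stats::setNames(vector("list", 4L), paste0("stage", 2:5))
    pool <- setdiff(eligible, persistent)
    for (s in .DISEASE_STAGES) {
      nm <- paste0("stage", s)
      n_extra <- min(max(n_de - length(persistent), 0L), length(pool))
      extra <- sample(pool, n_extra)
      dir_up <- sample(c(TRUE, FALSE), n_extra, replace = TRUE)
      up[[nm]] <- sort(c(if (persist_up) persistent, extra[dir_up]))
      down[[nm]] <- sort(c(if (!persist_up) persistent, extra[!dir_up]))
    }

    forced <- character(0)
    if (rna_class == "miRNA" && config$planted_up34_mirnas > 0L) {
      forced <- sort(sample(setdiff(eligible, persistent),
                            config$planted_up34_mirnas))
      for (nm in c("stage3", "stage4")) {
        up[[nm]] <- sort(union(up[[nm]], forced))
        down[[nm]] <- setdiff(down[[nm]], forced)
      }
      # make the planted miRNAs the ONLY ones upregulated in both 3 and 4
      extras <- setdiff(intersect(up$stage3, up$stage4), forced)
      up$stage4 <- setdiff(up$stage4, extras)
    }
    if (rna_class == "lncRNA" && config$planted_up34_lncs > 0L) {
      forced <- sort(sample(setdiff(eligible, persistent),
                            min(config$planted_up34_lncs,
                                length(setdiff(eligible, persistent)))))
      for (nm in c("stage3", "stage4")) {
        up[[nm]] <- sort(union(up[[nm]], forced))
        down[[nm]] <- setdiff(down[[nm]], forced)
      }
    }
    if (rna_class == "mRNA" && config$planted_down34_mrnas > 0L) {
      forced <- sort(sample(setdiff(eligible, persistent),
                            min(config$planted_down34_mrnas,
                                length(setdiff(eligible, persistent)))))
      for (nm in c("stage3", "stage4")) {
        down[[nm]] <- sort(union(down[[nm]], forced))
        up[[nm]] <- setdiff(up[[nm]], forced)
      }
    }

    sig <- matrix(baseline, n, .N_STAGES,
                  dimnames = list(class_ids, .STAGE_COLS))
    for (s in .DISEASE_STAGES) {
      nm <- paste0("stage", s)
      sig[up[[nm]], s] <- sig[up[[nm]], s] * config$planted_fc
      sig[down[[nm]], s] <- sig[down[[nm]], s] / config$planted_fc
    }
    noise <- if (config$noise_log2_sd > 0)
      matrix(2^stats::rnorm(n * .N_STAGES, 0, config$noise_log2_sd),
             n, .N_STAGES) else 1
    x <- sig * noise

    de_by_stage <- lapply(paste0("stage", .DISEASE_STAGES),
                          function(nm) union(up[[nm]], down[[nm]]))
    table <- stage_expression(class_ids, x, rna_class)
    # co-expression is a derived label, not planted signal: record it on the
    # scale the pipeline sees, i.e. after median normalization
    detected <- call_detection(median_normalize(table, config$detect_floor),
                               config$detect_floor)
    list(
      table = table,
      truth = list(
        ids = class_ids,
        up = up, down = down,
        co_expressed = detected$co_expressed,
        union = sort(Reduce(union, de_by_stage)),
        intersection = sort(Reduce(intersect, de_by_stage)),
        forced = forced
      )
    )
  }

  lnc <- gen_class(ids$lncRNA, "lncRNA")
  mir <- gen_class(ids$miRNA, "miRNA")
  mrn <- gen_class(ids$mRNA, "mRNA")

  truth <- list(
    classes = list(lncRNA = lnc$truth, miRNA = mir$truth, mRNA = mrn$truth),
    up34_mirnas = sort(intersect(mir$truth$up$stage3, mir$truth$up$stage4)),
    up34_lncs   = sort(intersect(lnc$truth$up$stage3, lnc$truth$up$stage4)),
    down34_mrnas = sort(intersect(mrn$truth$down$stage3,
                                  mrn$truth$down$stage4))
  )
  stopifnot(all(truth$up34_mirnas %in% mir$truth$up$stage3),
            all(truth$up34_mirnas %in% mir$truth$up$stage4),
            length(truth$up34_mirnas) == config$planted_up34_mirnas)

  list(tables = list(lncRNA = lnc$table, miRNA = mir$table,
                     mRNA = mrn$table),
       truth = truth)
}

#' Generate a synthetic genome annotation with known lncRNA neighbors
#'
#' Places all coding and lncRNA loci on `n_chromosomes` chromosomes as
#' non-degenerate 0-based half-open intervals laid out left to right with
#' random gaps; a configurable fraction of lncRNAs is then shifted to overlap
#' its upstream coding gene to exercise the distance-zero neighbor rule. The
#' true upstream/downstream coding neighbors of every lncRNA (computed by a
#' direct linear scan over the final coordinates) are attached as attribute
#' `"planted_neighbors"`.
#'
#' @param config a [sim_config()].
#' @return A `genome_annotation` data frame (gene_id, chrom, start, end,
#'   strand, biotype) with attribute `planted_neighbors`.
#' @export
generate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1))
  ids <- probe_ids(config)
  gene_id <- c(ids$mRNA, ids$lncRNA)
  biotype <- rep(c("coding", "lncRNA"), c(config$n_mrna, config$n_lnc))
  chrom <- sample(paste0("chr", seq_len(config$n_chromosomes)),
                  length(gene_id), replace = TRUE)

  out <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    on_chrom <- which(chrom == paste0("chr", ci))
    k <- length(on_chrom)
    if (k == 0L) next
    ord <- resample(on_chrom)
    lens <- sample(200:2000, k, replace = TRUE)
    gaps <- sample(100:5000, k, replace = TRUE)
    starts <- cumsum(gaps) + c(0, cumsum(lens)[-k])
    ends <- starts + lens
    if (ends[k] > config$chrom_length)
      stop("generate_genome_annotation: cannot pack ", k, " loci into chr", ci,
           " of length ", config$chrom_length,
           "; increase 'chrom_length' or 'n_chromosomes'", call. = FALSE)
    out[[ci]] <- data.frame(
      gene_id = gene_id[ord], chrom = paste0("chr", ci),
      start = starts, end = ends,
      strand = sample(c("+", "-"), k, replace = TRUE),
      biotype = biotype[ord], stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, out[!vapply(out, is.null, logical(1))])

  # shift a fraction of lncRNAs left so they overlap their upstream coding gene
  n_olap <- round(config$lnc_overlap_fraction * config$n_lnc)
  if (n_olap > 0L) {
    lnc_rows <- which(ann$biotype == "lncRNA")
    candidates <- lnc_rows[vapply(lnc_rows, function(i) {
      any(ann$biotype == "coding" & ann$chrom == ann$chrom[i] &
            ann$end <= ann$start[i])
    }, logical(1))]
    for (i in resample(candidates, min(n_olap, length(candidates)))) {
      cod <- which(ann$biotype == "coding" & ann$chrom == ann$chrom[i] &
                     ann$end <= ann$start[i])
      prev <- cod[which.max(ann$end[cod])]
      len <- ann$end[i] - ann$start[i]
      depth <- min(ceiling(len / 2), ann$end[prev] - ann$start[prev] - 1L)
      ann$start[i] <- ann$end[prev] - depth
      ann$end[i] <- ann$start[i] + len
    }
  }

  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  attr(ann, "planted_neighbors") <- scan_neighbors(ann)
  ann
}

# linear-scan neighbor truth: independent of the indexed implementation in
# nearest_neighbors(); same rules (max end <= start upstream, min start >= end
# downstream, overlap => distance 0 on the side of the coding gene's midpoint,
# ties to the lexicographically smaller id)
scan_neighbors <- function(ann) {
  lnc <- ann[ann$biotype == "lncRNA", , drop = FALSE]
  cod <- ann[ann$biotype == "coding", , drop = FALSE]
  res <- data.frame(lnc_id = lnc$gene_id,
                    upstream_id = NA_character_, upstream_distance = NA_real_,
                    downstream_id = NA_character_,
                    downstream_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lnc))) {
    cc <- cod[cod$chrom == lnc$chrom[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    s <- lnc$start[i]; e <- lnc$end[i]
    pick <- function(idx, d) {
      if (!length(idx)) return(c(NA_character_, NA_real_))
      best <- idx[d[idx] == min(d[idx])]
      best <- best[order(cc$gene_id[best])][1L]
      c(cc$gene_id[best], min(d[idx]))
    }
    d_up <- s - cc$end           # valid where >= 0
    d_dn <- cc$start - e
    olap <- which(cc$start < e & cc$end > s)
    mid_cod <- (cc$start + cc$end) / 2
    up_idx <- c(which(d_up >= 0), olap[mid_cod[olap] <= (s + e) / 2])
    dn_idx <- c(which(d_dn >= 0), olap[mid_cod[olap] > (s + e) / 2])
    d_up[olap] <- 0; d_dn[olap] <- 0
    up <- pick(up_idx, pmax(d_up, 0))
    dn <- pick(dn_idx, pmax(d_dn, 0))
    res$upstream_id[i] <- up[1L]
    res$upstream_distance[i] <- as.numeric(up[2L])
    res$downstream_id[i] <- dn[1L]
    res$downstream_distance[i] <- as.numeric(dn[2L])
  }
  res
}

#' Generate a miRNA -> mRNA target map with planted enrichment
#'
#' Every miRNA receives `targets_per_mirna` distinct target mRNAs. For the
#' planted up-in-stages-3/4 miRNAs, each target is drawn from the planted
#' down-in-stages-3/4 mRNA set with probability
#' `target_enrichment_in_down34` (binomially, so the realized overlap
#' fluctuates around the configured rate) and from the remaining mRNAs
#' otherwise; all other miRNAs draw targets uniformly from the whole mRNA
#' universe.
#'
#' @param config a [sim_config()].
#' @param truth planted-truth record holding `down34_mrnas` (as produced by
#'   [generate_expression()]).
#' @return A `target_map`: named list mapping each miRNA id to a sorted
#'   character vector of target mRNA ids.
#' @export
generate_target_map <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$targets_per_mirna > config$n_mrna)
    stop("generate_target_map: more targets per miRNA than mRNAs", call. = FALSE)
  set.seed(sub_seed(config$seed, 2))
  ids <- probe_ids(config)
  down34 <- intersect(truth$down34_mrnas, ids$mRNA)
  other <- setdiff(ids$mRNA, down34)
  t_per <- config$targets_per_mirna

  map <- lapply(ids$miRNA, function(m) {
    if (m %in% truth$up34_mirnas) {
      k_in <- stats::rbinom(1L, t_per, config$target_enrichment_in_down34)
      k_in <- min(k_in, length(down34))
      k_out <- min(t_per - k_in, length(other))
      sort(c(sample(down34, k_in), sample(other, k_out)))
    } else {
      sort(sample(ids$mRNA, t_per))
    }
  })
  names(map) <- ids$miRNA
  structure(map, class = "target_map")
}

#' Generate a GO annotation with planted enriched terms
#'
#' The first `planted_enriched_terms` terms over-represent both the
#' miRNA-associated mRNAs (targets of the planted up-3/4 miRNAs that are also
#' down-3/4) and the coding neighbor genes of the planted up-3/4 lncRNAs, so
#' downstream enrichment recovers them on both sides of the tripartite
#' analysis; all remaining term memberships are uniform draws from the mRNA
#' universe. With `genes_per_term = 0` the annotation is empty and downstream
#' enrichment has nothing to test.
#'
#' @param config a [sim_config()].
#' @param truth planted-truth record holding `mirna_targets`, `up34_mirnas`,
#'   `down34_mrnas`, `up34_lncs` and `lnc_neighbors`.
#' @return A `go_annotation` (list with `terms`, a named list of gene-id
#'   vectors, and `desc`, named descriptions), with attribute
#'   `planted_terms`.
#' @export
generate_go_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 3))
  ids <- probe_ids(config)
  term_ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  gpt <- config$genes_per_term
  if (gpt == 0L || config$n_go_terms == 0L) {
    go <- structure(list(terms = stats::setNames(list(), character(0)),
                         desc = stats::setNames(character(0), character(0))),
                    class = "go_annotation")
    attr(go, "planted_terms") <- character(0)
    return(go)
  }

  # pools are restricted to co-expressed mRNAs: enrichment planted among
  # genes that are never detected could not be recovered by any analysis
  detected <- truth$classes$mRNA$co_expressed
  assoc <- sort(intersect(unique(unlist(lapply(
    truth$mirna_targets[truth$up34_mirnas],
    intersect, truth$down34_mrnas))), detected))
  nb <- truth$lnc_neighbors
  nb <- nb[nb$lnc_id %in% truth$up34_lncs, , drop = FALSE]
  neighbor_pool <- sort(intersect(unique(stats::na.omit(
    c(nb$upstream_id, nb$downstream_id))), detected))

  n_planted <- config$planted_enriched_terms
  terms <- vector("list", config$n_go_terms)
  for (j in seq_len(config$n_go_terms)) {
    if (j <= n_planted) {
      n_a <- min(ceiling(0.4 * gpt), length(assoc))
      n_b <- min(ceiling(0.4 * gpt), length(neighbor_pool))
      core <- unique(c(sample(assoc, n_a), sample(neighbor_pool, n_b)))
      filler_pool <- setdiff(ids$mRNA, core)
      filler <- sample(filler_pool, min(max(gpt - length(core), 0L),
                                        length(filler_pool)))
      terms[[j]] <- sort(c(core, filler))
    } else {
      terms[[j]] <- sort(sample(ids$mRNA, gpt))
    }
  }
  names(terms) <- term_ids
  go <- structure(
    list(terms = terms,
         desc = stats::setNames(sprintf("synthetic process %03d",
                                        seq_len(config$n_go_terms)),
                                term_ids)),
    class = "go_annotation"
  )
  attr(go, "planted_terms") <- term_ids[seq_len(n_planted)]
  go
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("GO annotation: %d terms, %d distinct genes\n",
              length(x$terms), length(unique(unlist(x$terms)))))
  invisible(x)
}

#' @export
print.target_map <- function(x, ...) {
  n_pairs <- sum(lengths(x))
  cat(sprintf("Target map: %d miRNAs, %d miRNA-mRNA pairs\n",
              length(x), n_pairs))
  invisible(x)
}
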