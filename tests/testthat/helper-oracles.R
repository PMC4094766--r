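# Independent brute-force oracles used to cross-check the implementations.
# Each is written as directly as possible (no shared code with R/).

# exhaustive linear-scan neighbor assignment: for every lncRNA, walk over all
# coding genes on its chromosome and keep the best candidate per side
oracle_neighbors <- function(ann) {
  lnc <- ann[ann$biotype == "lncRNA", , drop = FALSE]
  cod <- ann[ann$biotype == "coding", , drop = FALSE]
  out <- data.frame(lnc_id = lnc$gene_id,
                    upstream_id = NA_character_, upstream_distance = NA_real_,
                    downstream_id = NA_character_,
                    downstream_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lnc))) {
    s <- lnc$start[i]; e <- lnc$end[i]
    best <- list(up = NULL, down = NULL)   # each: c(dist, id)
    for (j in which(cod$chrom == lnc$chrom[i])) {
      gs <- cod$start[j]; ge <- cod$end[j]; id <- cod$gene_id[j]
      if (ge <= s) { side <- "up"; d <- s - ge }
      else if (gs >= e) { side <- "down"; d <- gs - e }
      else {
        d <- 0
        side <- if ((gs + ge) / 2 <= (s + e) / 2) "up" else "down"
      }
      cur <- best[[side]]
      if (is.null(cur) || d < as.numeric(cur[1]) ||
          (d == as.numeric(cur[1]) && id < cur[2]))
        best[[side]] <- c(d, id)
    }
    if (!is.null(best$up)) {
      out$upstream_id[i] <- best$up[2]
      out$upstream_distance[i] <- as.numeric(best$up[1])
    }
    if (!is.null(best$down)) {
      out$downstream_id[i] <- best$down[2]
      out$downstream_distance[i] <- as.numeric(best$down[1])
    }
  }
  out
}

# hypergeometric upper tail by explicit enumeration of all size-n draws from
# a population of N genes of which the first K carry the term
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# naive average-linkage agglomeration returning the cophenetic distance
# matrix; assumes all pairwise merge distances are distinct
oracle_average_linkage_cophenetic <- function(x) {
  n <- nrow(x)
  labs <- rownames(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n * 2 - 1)
  active[(n + 1):(2 * n - 1)] <- FALSE
  dm <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
  dm[1:n, 1:n] <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  nxt <- n
  for (step in seq_len(n - 1)) {
    act <- which(active[seq_len(nxt)])
    best <- c(Inf, NA, NA)
    for (a in act) for (b in act) if (a < b && dm[a, b] < best[1])
      best <- c(dm[a, b], a, b)
    a <- best[2]; b <- best[3]; h <- best[1]
    nxt <- nxt + 1
    clusters[[nxt]] <- c(clusters[[a]], clusters[[b]])
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- h; coph[j, i] <- h
    }
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (cth in act) {
      if (cth == a || cth == b) next
      dm[nxt, cth] <- dm[cth, nxt] <-
        (na * dm[min(a, cth), max(a, cth)] +
           nb * dm[min(b, cth), max(b, cth)]) / (na + nb)
    }
    active[c(a, b)] <- FALSE
    active[nxt] <- TRUE
  }
  coph
}

# small helper: build a stage_expression table from a plain matrix
make_table <- function(x, class = "mRNA", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(nrow(x)))
  triome::stage_expression(ids, x, class)
}

# small zero-noise simulation config used across tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_lnc = 120, n_mrna = 200, n_mirna = 20,
                   planted_up34_lncs = 10, planted_down34_mrnas = 30,
                   targets_per_mirna = 25, n_go_terms = 12,
                   genes_per_term = 20, planted_enriched_terms = 2,
                   noise_log2_sd = 0, seed = 99)
  do.call(triome::sim_config, utils::modifyList(defaults, args))
}
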