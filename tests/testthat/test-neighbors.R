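ann_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]],
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               strand = "+", biotype = r[[5]], stringsAsFactors = FALSE)))
  as_genome_annotation(df)
}

test_that("BED round trip preserves loci and rejects degenerate records", {
  cfg <- tiny_config(n_lnc = 30, n_mrna = 40)
  ann <- generate_genome_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_loci(ann, path)
  back <- read_loci(path)
  expect_equal(as.data.frame(back),
               as.data.frame(ann)[, names(back)], ignore_attr = TRUE)
  # degenerate interval: start == end
  writeLines("chr1\t100\t100\tGENE1\t0\t+", path)
  expect_error(read_loci(path))
})

test_that("flank assignment handles boundaries and containment", {
  # single coding gene left of the lncRNA: upstream only
  a <- ann_df(list("G1", "chr1", 100, 200, "coding"),
              list("LNC1", "chr1", 500, 600, "lncRNA"))
  nb <- nearest_neighbors(a)
  expect_identical(nb$upstream_id, "G1")
  expect_equal(nb$upstream_distance, 300)
  expect_true(is.na(nb$downstream_id))

  # lncRNA at chromosome start: upstream empty
  a <- ann_df(list("LNC1", "chr1", 0, 50, "lncRNA"),
              list("G1", "chr1", 100, 200, "coding"))
  nb <- nearest_neighbors(a)
  expect_true(is.na(nb$upstream_id))
  expect_identical(nb$downstream_id, "G1")
  expect_equal(nb$downstream_distance, 50)

  # coding gene fully containing the lncRNA: distance 0, side of midpoint
  a <- ann_df(list("G1", "chr1", 100, 1000, "coding"),
              list("LNC1", "chr1", 400, 450, "lncRNA"))
  nb <- nearest_neighbors(a)
  expect_true("G1" %in% c(nb$upstream_id, nb$downstream_id))
  hit_side <- if (identical(nb$upstream_id, "G1")) "upstream" else "downstream"
  expect_equal(nb[[paste0(hit_side, "_distance")]], 0)

  # between two exactly flanking coding genes
  a <- ann_df(list("G1", "chr1", 0, 100, "coding"),
              list("LNC1", "chr1", 100, 200, "lncRNA"),
              list("G2", "chr1", 200, 300, "coding"))
  nb <- nearest_neighbors(a)
  expect_identical(nb$upstream_id, "G1")
  expect_identical(nb$downstream_id, "G2")
  expect_equal(nb$upstream_distance, 0)
  expect_equal(nb$downstream_distance, 0)

  # chromosome without coding genes: empty assignment with a warning
  a <- ann_df(list("LNC1", "chr9", 0, 50, "lncRNA"),
              list("G1", "chr1", 100, 200, "coding"))
  expect_warning(nb <- nearest_neighbors(a), "chr9")
  expect_true(is.na(nb$upstream_id) && is.na(nb$downstream_id))
})

test_that("distance ties break toward the lexicographically smaller id", {
  a <- ann_df(list("GB", "chr1", 100, 200, "coding"),
              list("GA", "chr1", 150, 200, "coding"),
              list("LNC1", "chr1", 300, 400, "lncRNA"),
              list("GD", "chr1", 500, 600, "coding"),
              list("GC", "chr1", 500, 650, "coding"))
  nb <- nearest_neighbors(a)
  expect_identical(nb$upstream_id, "GA")
  expect_identical(nb$downstream_id, "GC")
})

test_that("indexed assignment equals the exhaustive linear scan", {
  set.seed(61)
  for (rep in 1:3) {
    n_cod <- 400; n_lnc <- 150
    df <- data.frame(
      gene_id = c(sprintf("G%04d", seq_len(n_cod)),
                  sprintf("LNC%04d", seq_len(n_lnc))),
      chrom = sample(paste0("chr", 1:4), n_cod + n_lnc, replace = TRUE),
      start = sample.int(50000, n_cod + n_lnc, replace = TRUE),
      strand = "+",
      biotype = rep(c("coding", "lncRNA"), c(n_cod, n_lnc)),
      stringsAsFactors = FALSE)
    df$end <- df$start + sample.int(800, n_cod + n_lnc, replace = TRUE)
    ann <- as_genome_annotation(df)
    got <- suppressWarnings(nearest_neighbors(ann))
    want <- oracle_neighbors(as.data.frame(ann))
    got <- got[order(got$lnc_id), ]; want <- want[order(want$lnc_id), ]
    expect_equal(got, want, ignore_attr = TRUE)
    # flank geometry whenever the assignment is a non-overlapping gene
    for (i in seq_len(nrow(got))) {
      lr <- ann[ann$gene_id == got$lnc_id[i], ]
      if (!is.na(got$upstream_id[i]) && got$upstream_distance[i] > 0)
        expect_lte(ann$end[ann$gene_id == got$upstream_id[i]], lr$start)
      if (!is.na(got$downstream_id[i]) && got$downstream_distance[i] > 0)
        expect_gte(ann$start[ann$gene_id == got$downstream_id[i]], lr$end)
    }
  }
})

test_that("neighbor gene sets pool uniquely over selected lncRNAs", {
  a <- ann_df(list("G1", "chr1", 0, 100, "coding"),
              list("LNC1", "chr1", 150, 200, "lncRNA"),
              list("LNC2", "chr1", 250, 300, "lncRNA"),
              list("G2", "chr1", 400, 500, "coding"))
  nb <- nearest_neighbors(a)
  gs <- neighbor_gene_set(nb)
  expect_identical(gs$genes, c("G1", "G2"))   # shared neighbors counted once
  expect_equal(gs$n_lnc_with_neighbor, 2L)
  expect_length(neighbor_gene_set(nb, character(0))$genes, 0L)
})

test_that("synthetic-genome neighbor truth is recovered", {
  cfg <- tiny_config(n_lnc = 60, n_mrna = 100, lnc_overlap_fraction = 0.1)
  ann <- generate_genome_annotation(cfg)
  truth_nb <- attr(ann, "planted_neighbors")
  got <- nearest_neighbors(ann)
  got <- got[order(got$lnc_id), ]
  truth_nb <- truth_nb[order(truth_nb$lnc_id), ]
  expect_equal(as.data.frame(got), truth_nb, ignore_attr = TRUE)
})
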