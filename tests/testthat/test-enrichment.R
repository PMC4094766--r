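go_ann <- function(terms, desc = NULL) {
  if (is.null(desc))
    desc <- stats::setNames(names(terms), names(terms))
  structure(list(terms = terms, desc = desc), class = "go_annotation")
}

test_that("hypergeometric tail matches exhaustive draw enumeration", {
  # the worked instance: N=20 genes, term of 5, study of 6, overlap 4
  pop <- sprintf("g%02d", 1:20)
  ann <- go_ann(list(T1 = pop[1:5]))
  study <- c(pop[1:4], pop[10:11])
  res <- enrich(study, ann, pop, method = "fisher")
  expect_equal(res$p, oracle_hyper_tail(20, 5, 6, 4), tolerance = 1e-12)

  # random instances with N <= 25, enumerated exhaustively
  set.seed(71)
  tried <- 0
  while (tried < 10) {
    N <- sample(10:25, 1); n <- sample(3:6, 1); K <- sample(2:(N - 2), 1)
    if (choose(N, n) > 40000) next
    tried <- tried + 1
    pop <- sprintf("g%02d", seq_len(N))
    study <- sample(pop, n)
    k <- length(intersect(study, pop[1:K]))
    if (k == 0) next
    res <- enrich(study, go_ann(list(T1 = pop[1:K])), pop,
                  method = "fisher", min_overlap = 0L)
    expect_equal(res$p, oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("a study set equal to the population is never enriched", {
  pop <- sprintf("g%02d", 1:20)
  ann <- go_ann(list(T1 = pop[1:5], T2 = pop[3:12]))
  res <- enrich(pop, ann, pop, method = "fisher")
  expect_true(all(res$p == 1))
})

test_that("the EASE score is the tail with the overlap reduced by one", {
  pop <- sprintf("g%02d", 1:30)
  ann <- go_ann(list(T1 = pop[1:6]))
  study <- c(pop[1:3], pop[20:24])
  res <- enrich(study, ann, pop, method = "ease")
  expect_equal(res$ease,
               phyper(1, 6, 24, 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(res$ease, res$p_hyper)    # strictly more conservative here
  # k = 1: EASE equals 1 exactly
  res1 <- enrich(pop[1], ann, pop, method = "ease", min_overlap = 0L)
  expect_equal(res1$ease, 1)
})

test_that("study genes outside the population are an error", {
  pop <- sprintf("g%02d", 1:10)
  ann <- go_ann(list(T1 = pop[1:5]))
  expect_error(enrich(c(pop[1:2], "zz"), ann, pop), "zz")
})

test_that("BH q-values are monotone in the p-value ordering and bounded", {
  set.seed(72)
  pop <- sprintf("g%03d", 1:200)
  terms <- lapply(1:20, function(i) sample(pop, 30))
  names(terms) <- sprintf("T%02d", 1:20)
  res <- enrich(sample(pop, 50), go_ann(terms), pop, method = "fisher")
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$q > 0 & res$q <= 1))
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
})

test_that("term overlaps below min_overlap are not tested", {
  pop <- sprintf("g%02d", 1:30)
  ann <- go_ann(list(T1 = pop[1:5], T2 = pop[28:30]))
  res <- enrich(pop[1:5], ann, pop, min_overlap = 2L)
  expect_identical(res$term, "T1")
})

test_that("a planted all-signal term is overwhelmingly significant", {
  cfg <- tiny_config()
  sim <- simulate_triome(cfg)
  tr <- sim$truth
  assoc <- sort(unique(unlist(lapply(tr$mirna_targets[tr$up34_mirnas],
                                     intersect, tr$down34_mrnas))))
  pop <- sprintf("MRNA%05d", seq_len(cfg$n_mrna))
  ann <- go_ann(list(PLANTED = assoc))
  res <- enrich(assoc, ann, pop, method = "fisher")
  expect_lt(res$p, 1e-10)
})

test_that("enriched terms carry their contributing miRNAs and lncRNAs", {
  pop <- sprintf("g%02d", 1:40)
  ann <- go_ann(list(T1 = pop[1:8], T2 = pop[30:35]))
  study <- pop[c(1:6, 30:32)]
  res <- enrich(study, ann, pop, method = "fisher", min_overlap = 1L)
  assoc <- structure(list(per_mirna = list(m1 = pop[1:3], m2 = pop[30:31]),
                          all = pop[c(1:3, 30:31)], mirnas = c("m1", "m2"),
                          down34_mrnas = study), class = "mirna_assoc")
  nbg <- structure(list(genes = pop[4:6], n_lnc_with_neighbor = 1L,
                        per_lnc = list(L1 = pop[4:6])),
                   class = "neighbor_gene_set")
  out <- annotate_enrichment_to_sources(res, assoc, nbg)
  t1 <- which(out$term == "T1"); t2 <- which(out$term == "T2")
  expect_setequal(out$mirnas[[t1]], "m1")
  expect_setequal(out$lncs[[t1]], "L1")
  expect_setequal(out$mirnas[[t2]], "m2")
  expect_length(out$lncs[[t2]], 0L)   # term hit only by miRNA-side genes
})

test_that("GMT and long-form TSV annotations round trip", {
  terms <- list(`GO:0000001` = c("g1", "g2", "g5"),
                `GO:0000002` = c("g2", "g3"))
  go <- go_ann(terms, desc = c(`GO:0000001` = "process one",
                               `GO:0000002` = "process two"))
  for (ext in c(".gmt", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_go_annotation(go, path)
    back <- read_go_annotation(path)
    expect_identical(back$terms, terms)
    expect_identical(unname(back$desc[names(terms)]),
                     c("process one", "process two"))
  }
})
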