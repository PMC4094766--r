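# minimal hand-built inputs for network tests
mk_assoc <- function(per) {
  structure(list(per_mirna = per,
                 all = sort(unique(unlist(per, use.names = FALSE))),
                 mirnas = sort(names(per)),
                 down34_mrnas = sort(unique(unlist(per, use.names = FALSE)))),
            class = "mirna_assoc")
}
mk_nbg <- function(per) {
  structure(list(genes = sort(unique(unlist(per, use.names = FALSE))),
                 n_lnc_with_neighbor = sum(lengths(per) > 0),
                 per_lnc = per), class = "neighbor_gene_set")
}
mk_enr <- function(terms, qs, genes, pop_size = 100L) {
  res <- data.frame(term = terms, description = terms, N = pop_size,
                    K = 10L, n = 10L, k = lengths(genes),
                    p_hyper = qs, ease = qs, p = qs, q = qs,
                    stringsAsFactors = FALSE)
  res$genes <- I(genes)
  attr(res, "method") <- "fisher"
  attr(res, "population_size") <- pop_size
  class(res) <- c("enrichment_result", "data.frame")
  res
}

test_that("terms enriched on both sides define the network core", {
  assoc <- mk_assoc(list(m1 = c("g1", "g2"), m2 = c("g3")))
  nbg <- mk_nbg(list(L1 = c("g1"), L2 = c("g4")))
  em <- mk_enr(c("T1", "T2"), c(0.01, 0.01),
               list(c("g1", "g2"), c("g3")))
  el <- mk_enr(c("T1", "T3"), c(0.02, 0.01), list(c("g1"), c("g4")))
  net <- build_crosslink(assoc, nbg, em, el)
  expect_identical(net$shared_terms, "T1")
  expect_setequal(net$nodes$id[net$nodes$type == "GO"], "T1")
  expect_setequal(net$nodes$id[net$nodes$type == "mRNA"], c("g1", "g2"))
  expect_setequal(net$nodes$id[net$nodes$type == "miRNA"], "m1")
  expect_setequal(net$nodes$id[net$nodes$type == "lncRNA"], "L1")
  sc <- net$scores
  expect_equal(sc$shared_terms[sc$mirna == "m1" & sc$lnc == "L1"], 1L)
  # every edge endpoint exists and the graph is simple
  expect_true(all(c(net$edges$source, net$edges$target) %in% net$nodes$id))
  expect_false(any(duplicated(net$edges[, c("source", "target")])))
})

test_that("no shared terms means no cross-class connectivity", {
  assoc <- mk_assoc(list(m1 = c("g1")))
  nbg <- mk_nbg(list(L1 = c("g2")))
  em <- mk_enr("T1", 0.01, list("g1"))
  el <- mk_enr("T2", 0.01, list("g2"))
  net <- build_crosslink(assoc, nbg, em, el)
  expect_length(net$shared_terms, 0L)
  expect_equal(nrow(net$edges), 0L)
  expect_length(net$nodes$id[net$nodes$type == "GO"], 0L)
  # disjoint annotation sides: all shared-function scores are zero
  em2 <- mk_enr(c("T1", "T2"), c(0.01, 0.01), list("g1", "g2"))
  el2 <- mk_enr(c("T1", "T2"), c(0.01, 0.01), list("g2", "g1"))
  net2 <- build_crosslink(assoc, nbg, em2, el2)
  expect_true(all(net2$scores$shared_terms <=
                    pmin(length(net2$terms_mirna_side),
                         length(net2$terms_lnc_side))))
})

test_that("mismatched enrichment populations are rejected", {
  assoc <- mk_assoc(list(m1 = "g1"))
  nbg <- mk_nbg(list(L1 = "g1"))
  em <- mk_enr("T1", 0.01, list("g1"), pop_size = 100L)
  el <- mk_enr("T1", 0.01, list("g1"), pop_size = 120L)
  expect_error(build_crosslink(assoc, nbg, em, el), "different populations")
})

test_that("planted shared terms are recovered end to end", {
  cfg <- tiny_config()
  rep <- run_pipeline(triome_config(simulate = list(
    n_lnc = 120, n_mrna = 200, n_mirna = 20, planted_up34_lncs = 10,
    planted_down34_mrnas = 30, targets_per_mirna = 25, n_go_terms = 12,
    genes_per_term = 20, planted_enriched_terms = 2, noise_log2_sd = 0),
    seed = 99))
  expect_identical(rep$network$shared_terms, rep$truth$enriched_terms)
  net <- rep$network
  expect_true(all(rep$truth$up34_mirnas %in%
                    net$nodes$id[net$nodes$type == "miRNA"]))
  expect_true(all(net$nodes$id[net$nodes$type == "lncRNA"] %in%
                    rep$truth$up34_lncs))
  # shared-function scores are bounded by the per-side term counts
  expect_true(all(net$scores$shared_terms <=
                    min(net$summary$n_terms_mirna_side,
                        net$summary$n_terms_lnc_side)))
})

test_that("JSON export round trips losslessly and formats agree on edges", {
  assoc <- mk_assoc(list(m1 = c("g1", "g2"), m2 = c("g2", "g3")))
  nbg <- mk_nbg(list(L1 = c("g1", "g3"), L2 = c("g2")))
  em <- mk_enr(c("T1", "T2"), c(0.001, 0.02),
               list(c("g1", "g2"), c("g2", "g3")))
  el <- mk_enr(c("T1", "T2"), c(0.01, 0.003),
               list(c("g1", "g3"), c("g2")))
  net <- build_crosslink(assoc, nbg, em, el)
  expect_gt(nrow(net$edges), 0L)

  jpath <- withr::local_tempfile(fileext = ".json")
  export_network(net, jpath, "json")
  back <- import_network_json(jpath)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$scores, net$scores)
  expect_identical(back$shared_terms, net$shared_terms)
  expect_equal(back$summary, net$summary, ignore_attr = TRUE)

  tpath <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tpath, "tsv")
  expect_equal(nrow(utils::read.delim(tpath)), nrow(net$edges))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(igraph::vcount(g), nrow(net$nodes))

  expect_error(export_network(net, tpath, "gexf"), "unknown format")

  # an empty network still exports headers-only files
  net0 <- build_crosslink(mk_assoc(list(m1 = "g1")), mk_nbg(list(L1 = "g2")),
                          mk_enr("T1", 0.5, list("g1")),
                          mk_enr("T1", 0.5, list("g2")))
  export_network(net0, tpath, "tsv")
  expect_equal(nrow(utils::read.delim(tpath)), 0L)
  export_network(net0, jpath, "json")
  expect_length(import_network_json(jpath)$shared_terms, 0L)
})

test_that("removing a gene from a side never increases any score", {
  assoc <- mk_assoc(list(m1 = c("g1", "g2")))
  nbg_full <- mk_nbg(list(L1 = c("g1", "g3")))
  nbg_less <- mk_nbg(list(L1 = c("g3")))
  em <- mk_enr(c("T1", "T2"), c(0.001, 0.002),
               list(c("g1", "g2"), c("g2")))
  el <- mk_enr(c("T1", "T2"), c(0.001, 0.002),
               list(c("g1", "g3"), c("g3")))
  s_full <- build_crosslink(assoc, nbg_full, em, el)$scores
  s_less <- build_crosslink(assoc, nbg_less, em, el)$scores
  for (i in seq_len(nrow(s_less)))
    expect_lte(s_less$shared_terms[i], s_full$shared_terms[i])
})
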