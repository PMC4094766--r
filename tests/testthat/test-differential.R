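test_that("fold changes are exact ratios and the 2-fold boundary is inclusive", {
  x <- rbind(c(100, 100, 200, 199, 50),
             c(100, 400, 25, 100, 100),
             c(40,  80,  80,  80,  80))   # stage-1 at/below floor: unreliable
  tab <- make_table(x, ids = c("A", "B", "C"))
  fc <- suppressMessages(compute_fold_changes(tab))
  expect_equal(unname(fc$fc["A", ]), c(1, 2, 1.99, 0.5))
  expect_false(fc$reliable[["C"]])
  de <- build_de_collection(fc, threshold = 2)
  expect_identical(de$up$stage3, "A")       # fc = 2.0 exactly counts
  expect_false("A" %in% de$up$stage4)       # 1.99 does not
  expect_identical(de$down$stage5, "A")     # fc = 0.5 exactly counts
  expect_identical(de$up$stage2, "B")
  expect_identical(de$down$stage3, "B")
  expect_false("C" %in% de$universe)        # unreliable probes excluded
  # a probe identical to stage 1 is never differentially expressed
  same <- make_table(matrix(100, 2, 5), ids = c("X", "Y"))
  de_same <- build_de_collection(compute_fold_changes(same))
  expect_length(de_same$union, 0L)
})

test_that("union and intersection match brute-force enumeration", {
  set.seed(21)
  n <- 1000L
  x <- cbind(stage1 = rep(100, n),
             matrix(100 * 2^runif(4 * n, -2.2, 2.2), n, 4))
  tab <- make_table(x)
  de <- build_de_collection(compute_fold_changes(tab), threshold = 2)
  # brute force: per-probe membership decided directly from the ratios
  ids <- tab$probe_id
  in_stage <- sapply(2:5, function(s) x[, s] / x[, 1] >= 2 |
                       x[, s] / x[, 1] <= 0.5)
  expect_setequal(de$union, ids[rowSums(in_stage) >= 1])
  expect_setequal(de$intersection, ids[rowSums(in_stage) == 4])
  for (s in 2:5) {
    nm <- paste0("stage", s)
    expect_setequal(union(de$up[[nm]], de$down[[nm]]), ids[in_stage[, s - 1]])
    expect_length(intersect(de$up[[nm]], de$down[[nm]]), 0L)
    expect_true(all(de$intersection %in% union(de$up[[nm]], de$down[[nm]])))
    expect_true(all(union(de$up[[nm]], de$down[[nm]]) %in% de$union))
  }
})

test_that("raising the threshold never grows any differential set", {
  set.seed(22)
  x <- cbind(rep(100, 300), matrix(100 * 2^runif(1200, -3, 3), 300, 4))
  fc <- compute_fold_changes(make_table(x))
  prev <- build_de_collection(fc, threshold = 2)
  for (T in c(2.5, 3, 4, 6)) {
    cur <- build_de_collection(fc, threshold = T)
    for (nm in names(cur$up)) {
      expect_true(all(cur$up[[nm]] %in% prev$up[[nm]]))
      expect_true(all(cur$down[[nm]] %in% prev$down[[nm]]))
    }
    expect_true(all(cur$union %in% prev$union))
    expect_true(all(cur$intersection %in% prev$intersection))
    prev <- cur
  }
})

test_that("stage patterns select exactly the constrained probes", {
  x <- rbind(c(100, 100, 400, 400, 100),    # up in 3 and 4
             c(100, 100, 25, 400, 100),     # down 3, up 4
             c(100, 100, 400, 25, 100),     # up 3, down 4
             c(100, 100, 400, 100, 100))    # up in 3 only
  tab <- make_table(x, ids = c("A", "B", "C", "D"))
  de <- build_de_collection(compute_fold_changes(tab))
  expect_identical(select_pattern(de, "UP34"), "A")
  expect_identical(select_pattern(de, "DOWN3_UP4"), "B")
  expect_length(select_pattern(de, "DOWN34"), 0L)
  expect_identical(select_pattern(de, c(stage3 = "up")), c("A", "C", "D"))
  # all-"any" pattern returns the whole universe
  expect_identical(select_pattern(de, c(stage2 = "any", stage3 = "any",
                                        stage4 = "any", stage5 = "any")),
                   c("A", "B", "C", "D"))
  expect_error(select_pattern(de, c(stage1 = "up")), "disease stages")
  expect_error(select_pattern(de, "UP12"), "unknown pattern")
})

test_that("zero-noise synthetic data is recovered exactly by the DE caller", {
  cfg <- tiny_config(planted_fc = 4, noise_log2_sd = 0)
  ex <- generate_expression(cfg)
  for (cls in names(ex$tables)) {
    tr <- ex$truth$classes[[cls]]
    norm <- median_normalize(ex$tables[[cls]], cfg$detect_floor)
    de <- build_de_collection(
      suppressMessages(compute_fold_changes(norm, cfg$detect_floor)),
      threshold = 2)
    expect_identical(de$up, tr$up)
    expect_identical(de$down, tr$down)
    expect_identical(de$union, tr$union)
    expect_identical(de$intersection, tr$intersection)
  }
})

test_that("UP34 selection recovers exactly the planted miRNAs", {
  cfg <- tiny_config(n_mirna = 50, planted_up34_mirnas = 2)
  ex <- generate_expression(cfg)
  norm <- median_normalize(ex$tables$miRNA, cfg$detect_floor)
  de <- build_de_collection(
    suppressMessages(compute_fold_changes(norm, cfg$detect_floor)))
  expect_identical(select_pattern(de, "UP34"), ex$truth$up34_mirnas)
  expect_length(select_pattern(de, "UP34"), 2L)
})
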