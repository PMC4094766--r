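#' Pipeline configuration
#'
#' Either `inputs` (paths to the six input files) or `simulate` (arguments
#' forwarded to [sim_config()]) must be supplied. All thresholds are
#' validated before any stage runs; invalid configurations raise a condition
#' of class `triome_validation_error`.
#'
#' @param inputs named list of file paths: `lncRNA`, `miRNA`, `mRNA`
#'   (expression TSVs), `loci` (BED6), `target_map` (TSV), `go` (GMT or
#'   long-form TSV).
#' @param simulate named list of [sim_config()] arguments; the pipeline then
#'   generates its own inputs with planted truth.
#' @param fc_threshold minimum fold change for a differential call
#'   (default 2).
#' @param intensity_floor floor for the median-normalization factor set
#'   (default 50).
#' @param expressed_floor floor for detection calls and the stage-1
#'   reliability check (default 50).
#' @param min_overlap minimum study overlap for a GO term to be tested
#'   (default 2).
#' @param enrichment_method `"ease"` or `"fisher"`.
#' @param q_cutoff BH q-value cutoff for an enriched term (default 0.05).
#' @param outdir optional directory; when set, every intermediate artifact is
#'   written there.
#' @param seed integer seed used when `simulate` is set.
#' @return A list of class `triome_config`.
#' @export
triome_config <- function(inputs = NULL, simulate = NULL,
                          fc_threshold = 2, intensity_floor = 50,
                          expressed_floor = 50, min_overlap = 2L,
                          enrichment_method = c("ease", "fisher"),
                          q_cutoff = 0.05, outdir = NULL, seed = 1L) {
  enrichment_method <- match.arg(enrichment_method)
  cfg <- structure(
    list(inputs = inputs, simulate = simulate,
         fc_threshold = fc_threshold, intensity_floor = intensity_floor,
         expressed_floor = expressed_floor,
         min_overlap = as.integer(min_overlap),
         enrichment_method = enrichment_method, q_cutoff = q_cutoff,
         outdir = outdir, seed = as.integer(seed)),
    class = "triome_config"
  )
  validate_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [triome_config()]; the `inputs`
#' and `simulate` blocks are passed through as named lists.
#'
#' @param path YAML file path.
#' @return A validated `triome_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(triome_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    validation_error("unknown configuration key(s): ",
                     paste(unknown, collapse = ", "))
  do.call(triome_config, y)
}

validation_error <- function(...) {
  stop(structure(class = c("triome_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

validate_config <- function(cfg) {
  if (is.null(cfg$inputs) == is.null(cfg$simulate))
    validation_error("exactly one of 'inputs' and 'simulate' must be given")
  if (!is.null(cfg$inputs)) {
    need <- c("lncRNA", "miRNA", "mRNA", "loci", "target_map", "go")
    missing_keys <- setdiff(need, names(cfg$inputs))
    if (length(missing_keys))
      validation_error("missing input path(s): ",
                       paste(missing_keys, collapse = ", "))
    for (nm in need)
      if (!file.exists(cfg$inputs[[nm]]))
        validation_error("input file for '", nm, "' does not exist: ",
                         cfg$inputs[[nm]])
  }
  for (nm in c("fc_threshold", "intensity_floor", "expressed_floor"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      validation_error("'", nm, "' must be a positive number")
  if (cfg$fc_threshold <= 1)
    validation_error("'fc_threshold' must exceed 1")
  if (cfg$min_overlap < 0)
    validation_error("'min_overlap' must be non-negative")
  if (cfg$q_cutoff <= 0 || cfg$q_cutoff > 1)
    validation_error("'q_cutoff' must lie in (0, 1]")
  invisible(cfg)
}

#' Run the full integrative pipeline
#'
#' Executes the stage sequence normalize -> detect -> differential
#' expression and set algebra -> stage patterns -> clustering ->
#' miRNA-target integration -> cis neighbors -> GO enrichment (both sides)
#' -> tripartite cross-linking, and returns a report holding every headline
#' count plus the intermediate objects. When `config$outdir` is set, every
#' intermediate artifact is written there; if a stage fails, a `FAILED`
#' marker naming the stage is left in the directory and the error is
#' re-raised with the stage name.
#'
#' The enrichment background population is the set of GO-annotated coding
#' genes detected (expressed in at least one stage) on the mRNA array; both
#' study sets are intersected with it.
#'
#' @param config a [triome_config()], or the path of a YAML file for
#'   [read_pipeline_config()].
#' @return An object of class `triome_report`; element `counts` carries the
#'   machine-readable headline counts, element `truth` the planted truth when
#'   the run was simulated.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "triome_config"))
  validate_config(config)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir))
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- stage("simulate", simulate_triome(do.call(sim_config, sim_args)))
    tables <- sim$expression
    annotation <- sim$annotation
    target_map <- sim$target_map
    go <- sim$go
    truth <- sim$truth
    if (!is.null(outdir)) write_sim_inputs(sim, file.path(outdir, "inputs"))
  } else {
    tables <- stage("read_expression", list(
      lncRNA = read_expression(config$inputs$lncRNA, "lncRNA"),
      miRNA = read_expression(config$inputs$miRNA, "miRNA"),
      mRNA = read_expression(config$inputs$mRNA, "mRNA")))
    annotation <- stage("read_loci", read_loci(config$inputs$loci))
    target_map <- stage("read_target_map",
                        read_target_map(config$inputs$target_map))
    go <- stage("read_go_annotation", read_go_annotation(config$inputs$go))
  }

  normalized <- stage("normalize", lapply(tables, median_normalize,
                                          floor = config$intensity_floor))
  detection <- stage("detect", lapply(normalized, call_detection,
                                      expressed_floor = config$expressed_floor))
  fc <- stage("fold_changes", suppressMessages(
    lapply(normalized, compute_fold_changes,
           reference_floor = config$expressed_floor)))
  de <- stage("de_collections", lapply(names(fc), function(cls)
    build_de_collection(fc[[cls]], threshold = config$fc_threshold,
                        co_expressed = detection[[cls]]$co_expressed)))
  names(de) <- names(fc)

  patterns <- stage("patterns", list(
    up34_mirnas = select_pattern(de$miRNA, "UP34"),
    down34_mrnas = select_pattern(de$mRNA, "DOWN34"),
    up34_lncs = select_pattern(de$lncRNA, "UP34"),
    down3_up4_lncs = select_pattern(de$lncRNA, "DOWN3_UP4")))

  clustering <- stage("clustering", {
    out <- list()
    for (cls in names(de)) {
      for (set_nm in c("union", "intersection")) {
        ids <- de[[cls]][[set_nm]]
        if (length(ids) >= 2L) {
          m <- fc[[cls]]$log2fc[match(ids, fc[[cls]]$probe_id), ,
                                drop = FALSE]
          rownames(m) <- ids
          out[[paste(cls, set_nm, sep = "_")]] <- cluster_profiles(m)
        }
      }
    }
    out
  })

  assoc <- stage("target_integration",
                 mirna_associated_mrnas(target_map, patterns$up34_mirnas,
                                        patterns$down34_mrnas))

  neighbors <- stage("cis_neighbors", nearest_neighbors(annotation))
  nbset <- stage("neighbor_gene_set",
                 neighbor_gene_set(neighbors, patterns$up34_lncs))

  annotated_genes <- sort(unique(unlist(go$terms, use.names = FALSE)))
  population <- intersect(detection$mRNA$expressed_any, annotated_genes)
  enr <- stage("enrichment", list(
    mirna_side = enrich(intersect(assoc$all, population), go, population,
                        method = config$enrichment_method,
                        min_overlap = config$min_overlap),
    lnc_side = enrich(intersect(nbset$genes, population), go, population,
                      method = config$enrichment_method,
                      min_overlap = config$min_overlap)))
  enr$mirna_side <- annotate_enrichment_to_sources(enr$mirna_side, assoc, nbset)
  enr$lnc_side <- annotate_enrichment_to_sources(enr$lnc_side, assoc, nbset)

  network <- stage("crosslink",
                   build_crosslink(assoc, nbset, enr$mirna_side, enr$lnc_side,
                                   q_cutoff = config$q_cutoff))

  counts <- list(
    detection_rate = lapply(detection, `[[`, "detection_rate"),
    co_expressed = lapply(detection, function(d) length(d$co_expressed)),
    de = lapply(de, function(d) list(
      per_stage = stats::setNames(
        lapply(names(d$up), function(nm)
          list(up = length(d$up[[nm]]), down = length(d$down[[nm]]))),
        names(d$up)),
      union = length(d$union), intersection = length(d$intersection),
      selected = length(d$selected))),
    patterns = lapply(patterns, length),
    assoc_per_mirna = lapply(assoc$per_mirna, length),
    assoc_pooled = length(assoc$all),
    lnc_with_neighbors = nbset$n_lnc_with_neighbor,
    enrichment = list(
      mirna_side_tested = nrow(enr$mirna_side),
      mirna_side_enriched = sum(enr$mirna_side$q <= config$q_cutoff),
      lnc_side_tested = nrow(enr$lnc_side),
      lnc_side_enriched = sum(enr$lnc_side$q <= config$q_cutoff),
      shared_terms = length(network$shared_terms)),
    network = network$summary
  )

  report <- structure(
    list(config = config, counts = counts, detection = detection, fc = fc,
         de = de, patterns = patterns, clustering = clustering,
         assoc = assoc, neighbors = neighbors, neighbor_genes = nbset,
         enrichment = enr, network = network, truth = truth),
    class = "triome_report"
  )
  if (!is.null(outdir)) stage("write_artifacts",
                              write_report_artifacts(report, normalized,
                                                     outdir))
  report
}

write_report_artifacts <- function(report, normalized, outdir) {
  for (cls in names(normalized)) {
    write_expression(normalized[[cls]],
                     file.path(outdir, paste0("normalized_", cls, ".tsv")))
    write_detection(report$detection[[cls]],
                    file.path(outdir, paste0("detection_", cls, ".tsv")))
    write_de_calls(report$de[[cls]], report$fc[[cls]],
                   file.path(outdir, paste0("de_calls_", cls, ".tsv")))
    jsonlite::write_json(venn_counts(report$de[[cls]]),
                         file.path(outdir, paste0("venn_", cls, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(report$clustering))
    write_newick(report$clustering[[nm]],
                 file.path(outdir, paste0("cluster_", nm, ".nwk")))
  write_mirna_assoc(report$assoc, file.path(outdir, "mirna_associated.tsv"))
  write_neighbors(report$neighbors, file.path(outdir, "neighbors.tsv"))
  write_enrichment(report$enrichment$mirna_side,
                   file.path(outdir, "enrichment_mirna_side.tsv"))
  write_enrichment(report$enrichment$lnc_side,
                   file.path(outdir, "enrichment_lnc_side.tsv"))
  export_network(report$network, file.path(outdir, "network_edges.tsv"), "tsv")
  export_network(report$network, file.path(outdir, "network.graphml"),
                 "graphml")
  export_network(report$network, file.path(outdir, "network.json"), "json")
  jsonlite::write_json(report$counts, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(file = list.files(outdir, recursive = TRUE),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.triome_report <- function(x, ...) {
  c <- x$counts
  cat("Five-stage integrative pipeline report\n")
  cat(sprintf("  detection rate: lncRNA %.2f%% / miRNA %.2f%% / mRNA %.2f%%\n",
              c$detection_rate$lncRNA, c$detection_rate$miRNA,
              c$detection_rate$mRNA))
  cat(sprintf("  co-expressed in all 5 stages: %d lncRNA / %d miRNA / %d mRNA\n",
              c$co_expressed$lncRNA, c$co_expressed$miRNA,
              c$co_expressed$mRNA))
  cat(sprintf("  selected (co-expressed & DE in every stage): %d / %d / %d\n",
              c$de$lncRNA$selected, c$de$miRNA$selected, c$de$mRNA$selected))
  cat(sprintf("  stage-3/4 patterns: %d up miRNAs, %d down mRNAs, %d up lncRNAs\n",
              c$patterns$up34_mirnas, c$patterns$down34_mrnas,
              c$patterns$up34_lncs))
  cat(sprintf("  miRNA-associated mRNAs (pooled): %d; lncRNAs with neighbors: %d\n",
              c$assoc_pooled, c$lnc_with_neighbors))
  cat(sprintf("  enriched GO terms: %d (miRNA side) / %d (lncRNA side), %d shared\n",
              c$enrichment$mirna_side_enriched, c$enrichment$lnc_side_enriched,
              c$enrichment$shared_terms))
  invisible(x)
}
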