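#' Write all synthetic pipeline inputs to a directory
#'
#' Materializes a [simulate_triome()] result as the plain-text interchange
#' files the pipeline reads: one expression TSV per RNA class, a BED6 locus
#' table, the target-map TSV, the GO annotation in both GMT and long-form
#' TSV, and the planted-truth record as JSON.
#'
#' @param sim a `triome_sim` object.
#' @param outdir output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
write_sim_inputs <- function(sim, outdir) {
  stopifnot(inherits(sim, "triome_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    lncRNA = file.path(outdir, "expression_lncRNA.tsv"),
    miRNA = file.path(outdir, "expression_miRNA.tsv"),
    mRNA = file.path(outdir, "expression_mRNA.tsv"),
    loci = file.path(outdir, "loci.bed"),
    target_map = file.path(outdir, "target_map.tsv"),
    go = file.path(outdir, "go_annotation.gmt"),
    go_tsv = file.path(outdir, "go_annotation.tsv"),
    truth = file.path(outdir, "planted_truth.json")
  )
  for (cls in names(sim$expression))
    write_expression(sim$expression[[cls]], paths[[cls]])
  write_loci(sim$annotation, paths$loci)
  write_target_map(sim$target_map, paths$target_map)
  write_go_annotation(sim$go, paths$go)
  write_go_annotation(sim$go, paths$go_tsv)
  write_truth(sim$truth, paths$truth)
  invisible(paths)
}

#' Write a planted-truth record as JSON
#'
#' @param truth the `truth` element of a `triome_sim`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
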