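#' Read a miRNA -> mRNA target map from TSV
#'
#' Expects two tab-separated columns (mirna_id, mrna_id) with a header row and
#' an optional third column carrying a source tag (e.g. the prediction
#' database the pair came from). Duplicate pairs are stored once; malformed
#' lines (missing or empty fields) are rejected with their line number.
#'
#' @param path file path; an empty file (header only) yields an empty map.
#' @return A `target_map`: named list mapping each miRNA id to a sorted vector
#'   of target mRNA ids, with a `pair_sources` attribute when a source column
#'   is present.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(structure(stats::setNames(list(), character(0)),
                     class = "target_map"))
  if (ncol(df) < 2L)
    stop("read_target_map: '", path, "' must have at least two columns ",
         "(mirna_id, mrna_id)", call. = FALSE)
  bad <- which(is.na(df[[1L]]) | df[[1L]] == "" |
                 is.na(df[[2L]]) | df[[2L]] == "")
  if (length(bad))
    stop("read_target_map: malformed line ", bad[1L] + 1L, " of ", path,
         ": empty miRNA or mRNA id", call. = FALSE)
  key <- paste(df[[1L]], df[[2L]], sep = "\r")
  first <- !duplicated(key)
  df <- df[first, , drop = FALSE]
  map <- lapply(split(df[[2L]], df[[1L]]), function(v) sort(unique(v)))
  map <- map[order(names(map))]
  out <- structure(map, class = "target_map")
  if (ncol(df) >= 3L)
    attr(out, "pair_sources") <- stats::setNames(df[[3L]],
                                                 paste(df[[1L]], df[[2L]]))
  out
}

#' Write a target map to TSV
#'
#' @param map a `target_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  df <- data.frame(mirna_id = rep(names(map), lengths(map)),
                   mrna_id = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect predicted miRNA targets with downregulated mRNAs
#'
#' For each selected miRNA, the associated mRNAs are its predicted targets
#' that are also downregulated in stages 3 and 4 -- the intersection that
#' turns a generic target-prediction export into stage-specific candidate
#' regulation. miRNAs absent from the target map yield empty sets with a
#' warning. Both per-miRNA sets and their pooled union are returned.
#'
#' @param target_map a `target_map` ([read_target_map()] or
#'   [generate_target_map()]).
#' @param mirnas character vector of selected miRNA ids (typically the
#'   up-in-stages-3/4 set).
#' @param down34_mrnas character vector of mRNAs downregulated in stages 3
#'   and 4.
#' @return An object of class `mirna_assoc`: `per_mirna` (named list of
#'   sorted associated-mRNA vectors), `all` (their union), `mirnas` and
#'   `down34_mrnas` as supplied.
#' @export
mirna_associated_mrnas <- function(target_map, mirnas, down34_mrnas) {
  stopifnot(inherits(target_map, "target_map"))
  missing <- setdiff(mirnas, names(target_map))
  if (length(missing))
    warning("mirna_associated_mrnas: no predicted targets for ",
            paste(missing, collapse = ", "), "; returning empty sets")
  per <- lapply(stats::setNames(mirnas, mirnas), function(m) {
    if (m %in% names(target_map))
      sort(intersect(target_map[[m]], down34_mrnas))
    else character(0)
  })
  structure(list(per_mirna = per,
                 all = sort(unique(unlist(per, use.names = FALSE))),
                 mirnas = sort(mirnas),
                 down34_mrnas = sort(down34_mrnas)),
            class = "mirna_assoc")
}

#' @export
print.mirna_assoc <- function(x, ...) {
  cat("miRNA-associated mRNAs (targets intersected with down-3/4 mRNAs):\n")
  for (m in names(x$per_mirna))
    cat(sprintf("  %s: %d associated mRNAs\n", m, length(x$per_mirna[[m]])))
  cat(sprintf("  pooled: %d distinct mRNAs of %d down-3/4\n",
              length(x$all), length(x$down34_mrnas)))
  invisible(x)
}

#' Write associated miRNA-mRNA pairs and a per-miRNA count summary
#'
#' @param assoc a [mirna_associated_mrnas()] result.
#' @param path output TSV path for the pairs; a JSON count summary is written
#'   alongside with extension `.counts.json`.
#' @return `path`, invisibly.
#' @export
write_mirna_assoc <- function(assoc, path) {
  stopifnot(inherits(assoc, "mirna_assoc"))
  df <- data.frame(
    mirna_id = rep(names(assoc$per_mirna), lengths(assoc$per_mirna)),
    mrna_id = unlist(assoc$per_mirna, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- c(lapply(assoc$per_mirna, length),
              list(pooled = length(assoc$all)))
  jsonlite::write_json(counts, paste0(sub("\\.tsv$", "", path), ".counts.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
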