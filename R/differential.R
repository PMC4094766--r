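#' Fold changes of each disease stage against the normal stage
#'
#' With one pooled sample per stage there is no variance estimate, so
#' differential expression is a pure fold-change criterion: for each probe the
#' ratio of its (normalized) intensity in disease stage s (s = 2..5) to its
#' stage-1 intensity. Probes whose stage-1 intensity is at or below
#' `reference_floor` cannot yield a trustworthy ratio; they are flagged
#' unreliable and excluded from differential-expression calling (their count
#' is reported via a message rather than being assigned infinite fold
#' changes).
#'
#' @param table a [stage_expression()] object (normalized).
#' @param reference_floor stage-1 intensity at or below which a probe is
#'   flagged unreliable (default 50).
#' @return An object of class `fc_table`: `probe_id`, `fc` (probes x 4 matrix,
#'   stages 2-5; `NA` where stage 1 is zero), `log2fc`, `reliable` (logical)
#'   and `rna_class`.
#' @export
compute_fold_changes <- function(table, reference_floor = 50) {
  stopifnot(inherits(table, "stage_expr"))
  x <- table$intensities
  ref <- x[, 1L]
  fc <- x[, .DISEASE_STAGES, drop = FALSE] / ifelse(ref > 0, ref, NA_real_)
  colnames(fc) <- paste0("stage", .DISEASE_STAGES)
  reliable <- ref > reference_floor
  n_bad <- sum(!reliable)
  if (n_bad > 0L)
    message("compute_fold_changes: ", n_bad, " ", table$rna_class,
            " probe(s) at or below the stage-1 floor (", reference_floor,
            ") excluded from differential-expression calling")
  structure(list(rna_class = table$rna_class,
                 probe_id = table$probe_id,
                 fc = fc, log2fc = log2(fc),
                 reliable = stats::setNames(reliable, table$probe_id)),
            class = "fc_table")
}

#' @export
print.fc_table <- function(x, ...) {
  cat(sprintf("Fold changes vs stage 1 (%s): %d probes, %d reliable\n",
              x$rna_class, length(x$probe_id), sum(x$reliable)))
  invisible(x)
}

#' Per-stage differential-expression calls and their union / intersection
#'
#' A probe is called upregulated in a disease stage when its fold change
#' against stage 1 is at least `threshold` (inclusive: fc = 2 counts at the
#' default 2-fold minimum difference threshold) and downregulated when the
#' fold change is at most `1/threshold`. Two collections are derived: the
#' union (probes differentially expressed in at least one disease stage) and
#' the intersection (probes differentially expressed in every disease stage).
#' If a co-expressed probe set is supplied, the selected-for-analysis set is
#' the intersection collection restricted to co-expressed probes.
#'
#' @param fc_table a [compute_fold_changes()] result.
#' @param threshold minimum fold change (default 2); must be > 1.
#' @param co_expressed optional character vector of co-expressed probe ids.
#' @return An object of class `de_collection` with per-stage `up` and `down`
#'   sets, `union`, `intersection`, `selected` (intersection restricted to
#'   co-expressed probes, or `NULL`), the probe `universe` (reliable probes)
#'   and per-stage counts.
#' @export
build_de_collection <- function(fc_table, threshold = 2, co_expressed = NULL) {
  stopifnot(inherits(fc_table, "fc_table"))
  if (threshold <= 1)
    stop("build_de_collection: 'threshold' must exceed 1", call. = FALSE)
  keep <- fc_table$reliable & !is.na(fc_table$fc[, 1L])
  fc <- fc_table$fc[keep, , drop = FALSE]
  ids <- fc_table$probe_id[keep]

  stage_nm <- paste0("stage", .DISEASE_STAGES)
  up <- down <- stats::setNames(vector("list", length(stage_nm)), stage_nm)
  for (nm in stage_nm) {
    up[[nm]] <- sort(ids[fc[, nm] >= threshold])
    down[[nm]] <- sort(ids[fc[, nm] <= 1 / threshold])
  }
  de_by_stage <- lapply(stage_nm, function(nm) union(up[[nm]], down[[nm]]))
  de_union <- sort(Reduce(union, de_by_stage))
  de_intersection <- sort(Reduce(intersect, de_by_stage))
  selected <- if (!is.null(co_expressed))
    sort(intersect(de_intersection, co_expressed)) else NULL

  structure(
    list(rna_class = fc_table$rna_class, threshold = threshold,
         up = up, down = down,
         union = de_union, intersection = de_intersection,
         co_expressed = if (is.null(co_expressed)) NULL else sort(co_expressed),
         selected = selected, universe = sort(ids),
         counts = data.frame(
           stage = .DISEASE_STAGES,
           n_up = vapply(up, length, integer(1)),
           n_down = vapply(down, length, integer(1)),
           n_de = vapply(de_by_stage, length, integer(1)),
           row.names = NULL)),
    class = "de_collection"
  )
}

#' @export
print.de_collection <- function(x, ...) {
  cat(sprintf("Differential-expression collection (%s, fold change >= %g):\n",
              x$rna_class, x$threshold))
  print(x$counts, row.names = FALSE)
  cat(sprintf("  union: %d  intersection: %d", length(x$union),
              length(x$intersection)))
  if (!is.null(x$selected))
    cat(sprintf("  selected (co-expressed & intersection): %d",
                length(x$selected)))
  cat("\n")
  invisible(x)
}

# named shorthands for the stage patterns used in the study
.PATTERN_SHORTHANDS <- list(
  UP34 = c(stage3 = "up", stage4 = "up"),
  DOWN34 = c(stage3 = "down", stage4 = "down"),
  DOWN3_UP4 = c(stage3 = "down", stage4 = "up")
)

#' Select probes matching a directional stage pattern
#'
#' A pattern constrains the direction of the differential-expression call in
#' each disease stage to `"up"`, `"down"` or `"any"` (unconstrained). The
#' shorthands `"UP34"` (up in stages 3 and 4), `"DOWN34"` and `"DOWN3_UP4"`
#' (down in stage 3, up in stage 4) name the patterns used to pick out the
#' RNAs of interest in the stage 3 to 4 transition. A pattern with every
#' stage unconstrained returns the whole probe universe of the collection.
#'
#' @param de a [build_de_collection()] result.
#' @param pattern either a shorthand string or a named character vector such
#'   as `c(stage3 = "down", stage4 = "up")`; stages not named are
#'   unconstrained.
#' @return Sorted character vector of probe ids satisfying every constraint.
#' @export
select_pattern <- function(de, pattern) {
  stopifnot(inherits(de, "de_collection"))
  if (is.character(pattern) && length(pattern) == 1L && is.null(names(pattern))) {
    if (!pattern %in% names(.PATTERN_SHORTHANDS))
      stop("select_pattern: unknown pattern shorthand '", pattern,
           "'; use one of ", paste(names(.PATTERN_SHORTHANDS), collapse = ", "),
           " or a named direction vector", call. = FALSE)
    pattern <- .PATTERN_SHORTHANDS[[pattern]]
  }
  valid_stages <- paste0("stage", .DISEASE_STAGES)
  if (is.null(names(pattern)) || !all(names(pattern) %in% valid_stages))
    stop("select_pattern: pattern names must be disease stages (",
         paste(valid_stages, collapse = ", "), ")", call. = FALSE)
  if (!all(pattern %in% c("up", "down", "any")))
    stop("select_pattern: directions must be 'up', 'down' or 'any'",
         call. = FALSE)
  result <- de$universe
  for (nm in names(pattern)) {
    result <- switch(pattern[[nm]],
                     up = intersect(result, de$up[[nm]]),
                     down = intersect(result, de$down[[nm]]),
                     any = result)
  }
  sort(result)
}

#' Write per-stage differential-expression calls to TSV
#'
#' One row per (probe, stage) call with fold change, log2 fold change and
#' direction; membership in the union/intersection collections is written to
#' a companion data frame.
#'
#' @param de a [build_de_collection()] result.
#' @param fc_table the matching [compute_fold_changes()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_calls <- function(de, fc_table, path) {
  stopifnot(inherits(de, "de_collection"), inherits(fc_table, "fc_table"))
  rows <- list()
  for (nm in names(de$up)) {
    for (dir in c("up", "down")) {
      ids <- if (dir == "up") de$up[[nm]] else de$down[[nm]]
      if (!length(ids)) next
      i <- match(ids, fc_table$probe_id)
      rows[[paste(nm, dir)]] <- data.frame(
        probe_id = ids, stage = as.integer(sub("stage", "", nm)),
        fc = fc_table$fc[i, nm], log2fc = fc_table$log2fc[i, nm],
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), stage = integer(0), fc = numeric(0),
               log2fc = numeric(0), direction = character(0))
  out <- out[order(out$stage, out$probe_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Venn counts of the per-stage differential-expression sets
#'
#' The machine-readable analogue of a four-set Venn diagram over the disease
#' stages: per-stage up/down/total counts plus the union and intersection
#' cardinalities, suitable for JSON export.
#'
#' @param de a [build_de_collection()] result.
#' @return A list of counts.
#' @export
venn_counts <- function(de) {
  stopifnot(inherits(de, "de_collection"))
  list(rna_class = de$rna_class, threshold = de$threshold,
       per_stage = de$counts,
       union = length(de$union), intersection = length(de$intersection),
       selected = if (is.null(de$selected)) NA_integer_
                  else length(de$selected))
}
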