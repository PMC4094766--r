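#' Construct a five-stage expression table
#'
#' The central container for probe-level intensities: a probes x 5 matrix with
#' stage 1 the normal reference and stages 2-5 the disease stages. Probe ids
#' must be unique (replicate probes are averaged at read time by
#' [read_expression()]) and intensities non-negative.
#'
#' @param probe_id character vector of unique probe ids.
#' @param intensities numeric matrix (probes x 5) or data frame of
#'   non-negative intensities; columns are taken as stages 1-5 in order.
#' @param rna_class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @param normalized logical; whether the table has been median-normalized.
#' @return An object of class `stage_expr`.
#' @export
stage_expression <- function(probe_id, intensities,
                             rna_class = c("lncRNA", "miRNA", "mRNA"),
                             normalized = FALSE) {
  rna_class <- match.arg(rna_class)
  x <- as.matrix(intensities)
  storage.mode(x) <- "double"
  if (ncol(x) != .N_STAGES)
    stop("stage_expression: expected exactly ", .N_STAGES, " stage columns, got ",
         ncol(x), call. = FALSE)
  if (length(probe_id) != nrow(x))
    stop("stage_expression: probe ids and intensity rows differ in length",
         call. = FALSE)
  if (anyDuplicated(probe_id))
    stop("stage_expression: probe ids must be unique; use read_expression() ",
         "to average replicate probes", call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop("stage_expression: intensities must be non-negative and non-missing",
         call. = FALSE)
  dimnames(x) <- list(probe_id, .STAGE_COLS)
  structure(list(rna_class = rna_class, probe_id = as.character(probe_id),
                 intensities = x, normalized = isTRUE(normalized)),
            class = "stage_expr")
}

#' @export
print.stage_expr <- function(x, ...) {
  cat(sprintf("Five-stage %s expression table: %d probes%s\n",
              x$rna_class, length(x$probe_id),
              if (x$normalized) " (median-normalized)" else ""))
  print(utils::head(x$intensities, 4L))
  if (length(x$probe_id) > 4L) cat("  ...\n")
  invisible(x)
}

#' Read a five-stage expression table from TSV
#'
#' Expects a tab-delimited file with a header row and at least six columns:
#' a probe id followed by the five stage intensities. Replicate probes
#' (duplicated ids) are averaged arithmetically, keeping the row order of
#' first occurrence. Non-numeric or negative intensities are rejected with
#' the offending line number.
#'
#' @param path file path.
#' @param rna_class RNA class label for the table.
#' @return A [stage_expression()] object.
#' @export
read_expression <- function(path, rna_class = c("lncRNA", "miRNA", "mRNA")) {
  rna_class <- match.arg(rna_class)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < .N_STAGES + 1L)
    stop("read_expression: '", path, "' needs a probe-id column plus ",
         .N_STAGES, " stage columns; found ", ncol(df), call. = FALSE)
  stage_cols <- if (all(.STAGE_COLS %in% names(df))) .STAGE_COLS
                else names(df)[2:(.N_STAGES + 1L)]
  probe <- df[[1L]]
  x <- matrix(NA_real_, nrow(df), .N_STAGES)
  for (j in seq_along(stage_cols)) {
    v <- suppressWarnings(as.numeric(df[[stage_cols[j]]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop("read_expression: non-numeric or negative intensity in column '",
           stage_cols[j], "' at line ", bad[1L] + 1L, " of ", path,
           call. = FALSE)
    x[, j] <- v
  }
  # average replicate probes, preserving first-occurrence order
  if (anyDuplicated(probe)) {
    f <- factor(probe, levels = unique(probe))
    x <- rowsum(x, f) / as.vector(table(f))
    probe <- levels(f)
  }
  stage_expression(probe, x, rna_class)
}

#' Write a five-stage expression table to TSV
#'
#' @param table a [stage_expression()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  stopifnot(inherits(table, "stage_expr"))
  df <- data.frame(probe_id = table$probe_id, rna_class = table$rna_class,
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median normalization with an intensity floor
#'
#' The normalization-factor probe set consists of the probes whose intensity
#' exceeds `floor` in all five stages. Each stage column is divided by the
#' median of the factor set in that stage, then rescaled by the grand mean of
#' the five medians so the data keep their original scale (and intensity
#' floors keep their meaning). After normalization the factor-set median is
#' identical in every stage. Multiplying any stage column by a positive
#' constant changes the result by at most one global factor (through the
#' grand mean), so all cross-stage ratios -- and every downstream
#' fold-change call -- are invariant to per-stage scaling.
#'
#' @param table a [stage_expression()] object (not yet normalized).
#' @param floor intensity threshold for membership in the factor set
#'   (default 50).
#' @return A normalized `stage_expr`.
#' @export
median_normalize <- function(table, floor = 50) {
  stopifnot(inherits(table, "stage_expr"))
  if (table$normalized)
    warning("median_normalize: table is already normalized; normalizing again")
  x <- table$intensities
  in_factor <- apply(x > floor, 1L, all)
  if (!any(in_factor))
    stop("median_normalize: no probe exceeds the intensity floor (", floor,
         ") in all five stages; lower the floor", call. = FALSE)
  med <- apply(x[in_factor, , drop = FALSE], 2L, stats::median)
  scaled <- sweep(x, 2L, med, "/") * mean(med)
  out <- stage_expression(table$probe_id, scaled, table$rna_class,
                          normalized = TRUE)
  attr(out, "normalization") <- list(floor = floor, medians = med,
                                     n_factor_probes = sum(in_factor))
  out
}

#' Detection and co-expression calling
#'
#' A probe is called expressed in a stage when its intensity exceeds
#' `expressed_floor`. Two distinct summaries are reported: the detection rate
#' (probes expressed in at least one stage over all probes, as a percentage
#' truncated to two decimals, the convention used in published detection
#' rates) and the co-expressed set (probes expressed in all five stages),
#' which downstream analyses intersect with the differential-expression
#' collections.
#'
#' @param table a [stage_expression()] object (normally after
#'   [median_normalize()]).
#' @param expressed_floor intensity threshold for an expressed call
#'   (default 50).
#' @return An object of class `detection_result` with elements `expressed`
#'   (logical probes x stages matrix), `co_expressed`, `expressed_any`,
#'   `detection_rate` (percent, 2 decimals), `n_probes` and `rna_class`.
#' @export
call_detection <- function(table, expressed_floor = 50) {
  stopifnot(inherits(table, "stage_expr"))
  expressed <- table$intensities > expressed_floor
  any_stage <- rowSums(expressed) > 0L
  all_stage <- rowSums(expressed) == .N_STAGES
  structure(
    list(rna_class = table$rna_class,
         expressed = expressed,
         expressed_any = table$probe_id[any_stage],
         co_expressed = table$probe_id[all_stage],
         n_probes = length(table$probe_id),
         detection_rate = trunc(1e4 * sum(any_stage) / length(any_stage) +
                                  1e-9) / 100,
         expressed_floor = expressed_floor),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("%s detection: %.2f%% (%d/%d expressed in >=1 stage), %d co-expressed in all 5\n",
              x$rna_class, x$detection_rate, length(x$expressed_any),
              x$n_probes, length(x$co_expressed)))
  invisible(x)
}

#' Write a per-probe detection report
#'
#' @param detection a [call_detection()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(detection, path) {
  stopifnot(inherits(detection, "detection_result"))
  df <- data.frame(probe_id = rownames(detection$expressed),
                   rna_class = detection$rna_class,
                   detection$expressed,
                   co_expressed = rownames(detection$expressed) %in%
                     detection$co_expressed,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
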