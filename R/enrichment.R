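#' Normalize sgRNA read counts to ten million per sample
#'
#' Each sample column is scaled so that normalized reads per sgRNA equal
#' the guide's reads divided by the sample's total reads, times 1e7:
#' `n[g,s] = c[g,s] / sum_g c[g,s] * 1e7`. Every normalized column
#' therefore sums to exactly 1e7 (up to floating-point rounding).
#'
#' @param counts Guide-by-sample matrix of non-negative integers
#'   (rownames = guide ids, colnames = sample ids).
#' @return Numeric matrix of the same shape.
#' @details Normalization is undefined for an all-zero sample; such a
#'   column raises an error naming the sample.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero) > 0L) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[zero[1L]]
          else as.character(zero[1L])
    stop("normalization undefined for all-zero sample '", nm, "'",
         call. = FALSE)
  }
  sweep(counts, 2L, totals, "/") * 1e7
}

#' Fold enrichment of treated over untreated normalized reads
#'
#' Fold enrichment for a guide is its normalized reads in the
#' lysenin-treated sample divided by its normalized reads in the
#' untreated control. When the untreated value is 0 the denominator is
#' reformatted to 1 so that the ratio stays finite; the numerator is
#' never reformatted, so a treated value of 0 gives fold enrichment 0.
#'
#' @param treated,untreated Numeric vectors of normalized reads sharing
#'   guide order (and names, if named).
#' @return Numeric vector of fold-enrichment values, >= 0 and finite.
#' @export
fold_enrichment <- function(treated, untreated) {
  if (length(treated) != length(untreated)) {
    stop("treated and untreated columns differ in length", call. = FALSE)
  }
  if (!is.null(names(treated)) && !is.null(names(untreated)) &&
      !identical(names(treated), names(untreated))) {
    stop("treated and untreated columns differ in guide order",
         call. = FALSE)
  }
  denom <- ifelse(untreated == 0, 1, untreated)
  treated / denom
}

#' Per-pool fold-enrichment table
#'
#' Computes fold enrichment for every pool experiment in the screen: one
#' column per pool (A-1, A-2, B-1, B-2, ...), each the treated/untreated
#' ratio of that pool's normalized sample pair.
#'
#' @param normalized Guide-by-sample matrix of normalized reads
#'   (see [normalize_counts()]).
#' @param samples A `sample_sheet` covering the matrix columns; every
#'   pool must have exactly one treated and one untreated sample.
#' @return Guide-by-pool numeric matrix of fold-enrichment values.
#' @export
enrichment_table <- function(normalized, samples) {
  samples <- as_sample_sheet(as.data.frame(samples))
  missing <- setdiff(samples$sample_id, colnames(normalized))
  if (length(missing) > 0L) {
    stop("sample(s) absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pools <- unique(pool_id(samples))
  fe <- matrix(NA_real_, nrow = nrow(normalized), ncol = length(pools),
               dimnames = list(rownames(normalized), pools))
  for (p in pools) {
    rows <- which(pool_id(samples) == p)
    tr <- samples$sample_id[rows][samples$condition[rows] == "treated"]
    un <- samples$sample_id[rows][samples$condition[rows] == "untreated"]
    if (length(tr) != 1L || length(un) != 1L) {
      stop("pool ", p, " must have exactly one treated and one ",
           "untreated sample", call. = FALSE)
    }
    fe[, p] <- fold_enrichment(normalized[, tr], normalized[, un])
  }
  fe
}

#' Call reproducibly enriched sgRNAs
#'
#' A guide is called enriched when its fold enrichment is strictly
#' greater than `threshold` ("more than fivefold", not at-least) in the
#' pool experiments of its own half-library: in every one of them under
#' `replicate_mode = "all"` (the reproducibility requirement, default),
#' or in at least one under `"any"`.
#'
#' @param fe Guide-by-pool fold-enrichment matrix whose column names are
#'   pool labels like `"A-1"` (see [enrichment_table()]).
#' @param library An `sgrna_library` covering the guides in `fe`.
#' @param threshold Strict fold-enrichment cutoff (default 5).
#' @param replicate_mode `"all"` (default) or `"any"`.
#' @return Named logical vector, one element per guide in `fe`.
#' @export
call_enriched_sgrnas <- function(fe, library, threshold = 5,
                                 replicate_mode = c("all", "any")) {
  replicate_mode <- match.arg(replicate_mode)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  library <- as_sgrna_library(as.data.frame(library))
  halves <- library$half_library[match(rownames(fe), library$guide_id)]
  if (anyNA(halves)) {
    stop("guide(s) in the enrichment table are absent from the library",
         call. = FALSE)
  }
  pool_half <- substr(colnames(fe), 1L, 1L)
  hits <- logical(nrow(fe))
  names(hits) <- rownames(fe)
  for (h in unique(halves)) {
    cols <- which(pool_half == h)
    if (length(cols) == 0L) {
      stop("no pool experiment present for half-library ", h,
           call. = FALSE)
    }
    above <- fe[, cols, drop = FALSE] > threshold
    hits[halves == h] <- if (replicate_mode == "all") {
      rowSums(above)[halves == h] == length(cols)
    } else {
      rowSums(above)[halves == h] >= 1L
    }
  }
  hits
}

#' Call candidate genes from enriched sgRNAs
#'
#' A gene is a candidate when it has at least `min_per_half` enriched
#' guides in half-library A *and* in half-library B (the dual-library
#' criterion); genes meeting the bar in exactly one half-library are
#' reported separately as partial.
#'
#' @param sgrna_hits Named logical vector of per-guide enrichment calls
#'   (names = guide ids; see [call_enriched_sgrnas()]).
#' @param library An `sgrna_library` containing every hit guide.
#' @param min_per_half Minimum enriched guides required per half-library
#'   (default 1).
#' @param require_both_halves If `FALSE`, one qualifying half-library is
#'   enough for candidacy and no partial class is reported.
#' @return A `candidate_report` list: `candidate_genes`, `partial_genes`,
#'   `sgrna_hits`, `supporting_guides` (named list of hit guide ids per
#'   listed gene) and `parameters`.
#' @export
call_candidate_genes <- function(sgrna_hits, library, min_per_half = 1L,
                                 require_both_halves = TRUE) {
  if (min_per_half < 1L) stop("min_per_half must be >= 1", call. = FALSE)
  library <- as_sgrna_library(as.data.frame(library))
  idx <- match(names(sgrna_hits), library$guide_id)
  if (anyNA(idx)) {
    stop("hit guide(s) absent from the library: ",
         paste(utils::head(names(sgrna_hits)[is.na(idx)], 3L),
               collapse = ", "), call. = FALSE)
  }
  gene <- library$gene[idx]
  half <- library$half_library[idx]
  genes <- sort(unique(library$gene))
  nA <- table(factor(gene[sgrna_hits & half == "A"], levels = genes))
  nB <- table(factor(gene[sgrna_hits & half == "B"], levels = genes))
  okA <- nA >= min_per_half
  okB <- nB >= min_per_half
  if (require_both_halves) {
    candidate <- genes[okA & okB]
    partial <- genes[xor(okA, okB)]
  } else {
    candidate <- genes[okA | okB]
    partial <- character(0)
  }
  listed <- c(candidate, partial)
  supporting <- lapply(listed, function(g) {
    names(sgrna_hits)[sgrna_hits & gene == g]
  })
  names(supporting) <- listed
  structure(list(
    candidate_genes = candidate,
    partial_genes = partial,
    sgrna_hits = sgrna_hits,
    supporting_guides = supporting,
    parameters = list(min_per_half = as.integer(min_per_half),
                      require_both_halves = require_both_halves)
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Screen candidate report: %d candidate gene(s), %d partial\n",
              length(x$candidate_genes), length(x$partial_genes)))
  cat(sprintf("  enriched sgRNAs: %d of %d\n",
              sum(x$sgrna_hits), length(x$sgrna_hits)))
  p <- x$parameters
  cat(sprintf("  parameters: threshold > %s, replicate_mode = %s, min_per_half = %d\n",
              format(p$threshold %||% NA), p$replicate_mode %||% "all",
              p$min_per_half))
  if (length(x$candidate_genes) > 0L) {
    cat("  candidates:", paste(utils::head(x$candidate_genes, 10L),
                               collapse = ", "))
    if (length(x$candidate_genes) > 10L) cat(", ...")
    cat("\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full enrichment-and-calling stage of the screen
#'
#' Composes [normalize_counts()], [enrichment_table()],
#' [call_enriched_sgrnas()] and [call_candidate_genes()] and stamps the
#' report with the parameters used, so a count table plus a sample
#' sheet yields the screen's candidate genes in one call.
#'
#' @param counts Guide-by-sample integer matrix.
#' @param samples A `sample_sheet` covering the count columns.
#' @param library An `sgrna_library` covering the count rows.
#' @param threshold Strict fold-enrichment cutoff (default 5).
#' @param replicate_mode `"all"` (default) or `"any"`.
#' @param min_per_half Minimum enriched guides per half-library (default 1).
#' @param require_both_halves Dual-library criterion flag (default TRUE).
#' @return List with `report` (a `candidate_report`), `fe` (guide-by-pool
#'   fold-enrichment matrix) and `normalized`.
#' @export
run_screen <- function(counts, samples, library, threshold = 5,
                       replicate_mode = c("all", "any"),
                       min_per_half = 1L, require_both_halves = TRUE) {
  replicate_mode <- match.arg(replicate_mode)
  normalized <- normalize_counts(counts)
  fe <- enrichment_table(normalized, samples)
  hits <- call_enriched_sgrnas(fe, library, threshold = threshold,
                               replicate_mode = replicate_mode)
  report <- call_candidate_genes(hits, library,
                                 min_per_half = min_per_half,
                                 require_both_halves = require_both_halves)
  report$parameters <- c(report$parameters,
                         list(threshold = threshold,
                              replicate_mode = replicate_mode))
  list(report = report, fe = fe, normalized = normalized)
}

#' Export fold-enrichment values in long format for tile heatmaps
#'
#' Writes (or returns) one row per guide and pool experiment for the
#' requested genes -- the layout a tile-heatmap of six guides per gene
#' across the replicate experiments is drawn from.
#'
#' @param fe Guide-by-pool fold-enrichment matrix.
#' @param library An `sgrna_library`.
#' @param genes Character vector of genes to export (subset of the
#'   library's genes).
#' @param path Optional TSV output path.
#' @return Data frame with columns `gene`, `guide_id`, `half_library`,
#'   `experiment`, `fold_enrichment`, guides ordered within gene.
#' @export
export_heatmap_matrix <- function(fe, library, genes, path = NULL) {
  library <- as_sgrna_library(as.data.frame(library))
  unknown <- setdiff(genes, library$gene)
  if (length(unknown) > 0L) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- library[library$gene %in% genes, , drop = FALSE]
  rows <- rows[order(match(rows$gene, genes), rows$guide_id), ,
               drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    data.frame(gene = rows$gene[i], guide_id = rows$guide_id[i],
               half_library = rows$half_library[i],
               experiment = colnames(fe),
               fold_enrichment = fe[rows$guide_id[i], ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene = character(0), guide_id = character(0),
                      half_library = character(0),
                      experiment = character(0),
                      fold_enrichment = numeric(0))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Candidate count on an externally downloaded processed count table
#'
#' Applies the default pipeline (normalize, per-pool fold enrichment,
#' strict >5-fold calling in both replicate experiments, dual
#' half-library gene criterion) to a processed guide-by-sample count
#' table, e.g. the deposited counts of a published screen, and returns
#' the resulting number of candidate genes alongside the report.
#'
#' @param counts_path Count table TSV (see [read_count_table()]).
#' @param samples A `sample_sheet` describing its columns.
#' @param library An `sgrna_library`.
#' @param ... Passed to [run_screen()].
#' @return List with `n_candidates` and `report`.
#' @export
benchmark_candidate_count <- function(counts_path, samples, library, ...) {
  counts <- read_count_table(counts_path)
  res <- run_screen(counts, samples, library, ...)
  list(n_candidates = length(res$report$candidate_genes),
       report = res$report)
}
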