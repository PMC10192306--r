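#' Read an sgRNA library table
#'
#' Loads the guide catalogue of a pooled knockout library from a
#' tab-separated file with columns `gene`, `guide_id`, `spacer` and
#' `half_library`. Spacers are the 20-nt programmable sequences that are
#' counted by the screen; GeCKO-v2-style libraries carry six guides per
#' gene split three/three across half-libraries A and B.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame of class `sgrna_library` with columns
#'   `gene`, `guide_id`, `spacer`, `half_library`.
#' @details Loading fails loudly on malformed rows: a missing column, a
#'   non-ACGT or wrong-length spacer, a duplicated `guide_id`, or a spacer
#'   shared by two guides (the error names both offending guide ids --
#'   ambiguous spacers would silently corrupt counting downstream).
#' @seealso [read_sample_sheet()], [count_guides()]
#' @export
read_sgrna_library <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  as_sgrna_library(df)
}

#' Validate a guide-catalogue data frame
#'
#' @param df Data frame with columns `gene`, `guide_id`, `spacer`,
#'   `half_library`.
#' @return The validated data frame with class `sgrna_library` prepended.
#' @export
as_sgrna_library <- function(df) {
  required <- c("gene", "guide_id", "spacer", "half_library")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sgRNA library format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  df$spacer <- toupper(df$spacer)
  n <- nrow(df)
  if (n == 0L) stop("sgRNA library is empty", call. = FALSE)

  bad_len <- which(nchar(df$spacer) != nchar(df$spacer[1L]) |
                     grepl("[^ACGT]", df$spacer))
  if (length(bad_len) > 0L) {
    stop("sgRNA library spacer error at row(s) ",
         paste(utils::head(bad_len, 5L), collapse = ", "),
         " (guide ", df$guide_id[bad_len[1L]],
         "): spacers must be equal-length uppercase ACGT strings",
         call. = FALSE)
  }
  dup_id <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup_id) > 0L) {
    stop("sgRNA library integrity error: duplicated guide_id ",
         paste(unique(dup_id), collapse = ", "), call. = FALSE)
  }
  dup_sp <- unique(df$spacer[duplicated(df$spacer)])
  if (length(dup_sp) > 0L) {
    offenders <- df$guide_id[df$spacer == dup_sp[1L]]
    stop("sgRNA library integrity error: spacer ", dup_sp[1L],
         " shared by guides ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }
  bad_half <- which(!df$half_library %in% c("A", "B"))
  if (length(bad_half) > 0L) {
    stop("sgRNA library error: half_library must be 'A' or 'B' (row ",
         bad_half[1L], ")", call. = FALSE)
  }
  class(df) <- c("sgrna_library", "data.frame")
  df
}

#' @export
print.sgrna_library <- function(x, ...) {
  cat(sprintf("sgRNA library: %d guides, %d genes, spacer length %d\n",
              nrow(x), length(unique(x$gene)), nchar(x$spacer[1L])))
  cat(sprintf("  half-library A: %d guides; B: %d guides\n",
              sum(x$half_library == "A"), sum(x$half_library == "B")))
  invisible(x)
}

#' Write an sgRNA library table
#'
#' @param library An `sgrna_library` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sgrna_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen sample sheet
#'
#' The sample sheet maps sequencing barcodes to the screen's pools and
#' conditions. A complete lysenin-selection screen has eight samples:
#' half-libraries A and B, each with two independent pools (replicates
#' 1 and 2, i.e. pools A-1, A-2, B-1, B-2), each sequenced in a
#' lysenin-treated and an untreated arm.
#'
#' @param path TSV with columns `sample_id`, `half_library`,
#'   `pool_replicate`, `condition`, `barcode`.
#' @return Validated data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  as_sample_sheet(df)
}

#' Validate a sample sheet
#'
#' @param df Data frame with the sample-sheet columns.
#' @return The validated data frame, class `sample_sheet`.
#' @export
as_sample_sheet <- function(df) {
  required <- c("sample_id", "half_library", "pool_replicate",
                "condition", "barcode")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample sheet format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$half_library <- as.character(df$half_library)
  df$pool_replicate <- as.integer(df$pool_replicate)
  df$condition <- as.character(df$condition)
  df$barcode <- toupper(as.character(df$barcode))
  if (nrow(df) == 0L) stop("sample sheet is empty", call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet error: duplicated sample_id", call. = FALSE)
  }
  if (!all(df$half_library %in% c("A", "B"))) {
    stop("sample sheet error: half_library must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(df$condition %in% c("treated", "untreated"))) {
    stop("sample sheet error: condition must be 'treated' or 'untreated'",
         call. = FALSE)
  }
  key <- paste(df$half_library, df$pool_replicate, df$condition)
  if (anyDuplicated(key)) {
    stop("sample sheet error: (half_library, pool_replicate, condition) ",
         "must be unique", call. = FALSE)
  }
  if (any(nchar(df$barcode) < 4L) || grepl("[^ACGT]", paste(df$barcode, collapse = ""))) {
    stop("sample sheet error: barcodes must be ACGT strings of length >= 4",
         call. = FALSE)
  }
  if (length(unique(nchar(df$barcode))) != 1L) {
    stop("sample sheet error: barcodes must all have the same length",
         call. = FALSE)
  }
  if (anyDuplicated(df$barcode)) {
    stop("sample sheet configuration error: two samples share a barcode",
         call. = FALSE)
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Pool label for each sample ("A-1", "B-2", ...)
#' @param samples A `sample_sheet`.
#' @return Character vector of pool labels, one per row.
#' @export
pool_id <- function(samples) {
  paste(samples$half_library, samples$pool_replicate, sep = "-")
}

#' Read / write a guide-by-sample count table
#'
#' Count tables are TSVs whose first column (`guide_id`) holds guide ids
#' and whose remaining columns are per-sample non-negative integer read
#' counts.
#'
#' @param path TSV path.
#' @return Integer matrix, rows named by guide, columns by sample.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1L] != "guide_id") {
    stop("count table format error: first column must be 'guide_id'",
         call. = FALSE)
  }
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$guide_id)
  if (any(is.na(m)) || any(m < 0L)) {
    stop("count table error: counts must be non-negative integers",
         call. = FALSE)
  }
  m
}

#' @rdname read_count_table
#' @param counts Guide-by-sample integer matrix with dimnames.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Deterministic inline barcode set
#'
#' Generates `n` equal-length DNA barcodes with pairwise Hamming distance
#' of at least `min_dist`, by greedy selection over a fixed enumeration
#' order (no randomness), so the same call always yields the same set.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nt (default 6).
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @return Character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, width = 6L, min_dist = 3L) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), width), stringsAsFactors = FALSE))
  pool <- do.call(paste0, grid)
  chosen <- character(0)
  chosen_mat <- NULL
  pool_mat <- do.call(rbind, strsplit(pool, "", fixed = TRUE))
  for (i in seq_along(pool)) {
    cand <- pool_mat[i, ]
    if (is.null(chosen_mat) ||
        all(rowSums(chosen_mat != matrix(cand, nrow(chosen_mat), width,
                                         byrow = TRUE)) >= min_dist)) {
      chosen <- c(chosen, pool[i])
      chosen_mat <- rbind(chosen_mat, cand)
      if (length(chosen) == n) return(chosen)
    }
  }
  stop("cannot construct ", n, " barcodes of length ", width,
       " with min distance ", min_dist, call. = FALSE)
}
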