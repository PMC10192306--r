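#' Read a FASTQ file into a data frame
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] for 4-line,
#' Phred+33 FASTQ, plain or gzip-compressed.
#'
#' @param path FASTQ path (`.fastq`, `.fq`, optionally `.gz`).
#' @return Data frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(
    read_id = names(dss),
    sequence = as.character(dss),
    quality = as.character(S4Vectors::mcols(dss)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Hamming distance from each of a set of strings to each barcode.
# Works on the unique strings only, so cost is bounded by the barcode
# neighbourhood actually observed, not the number of reads.
barcode_distances <- function(prefixes, barcodes) {
  L <- nchar(barcodes[1L])
  u <- unique(prefixes)
  ok <- nchar(u) == L & !grepl("[^ACGTN]", u)
  d_u <- matrix(L + 1L, nrow = length(u), ncol = length(barcodes))
  if (any(ok)) {
    um <- do.call(rbind, strsplit(u[ok], "", fixed = TRUE))
    for (j in seq_along(barcodes)) {
      bc <- strsplit(barcodes[j], "", fixed = TRUE)[[1L]]
      d_u[ok, j] <- rowSums(um != matrix(bc, nrow(um), L, byrow = TRUE))
    }
  }
  d_u[match(prefixes, u), , drop = FALSE]
}

#' Assign reads to samples by inline barcode
#'
#' Each read carries its sample barcode at a fixed position (by default
#' the first L bases). A read is assigned to the unique sample whose
#' barcode lies within `max_mismatch` Hamming distance of the read's
#' barcode region; reads with no barcode in tolerance, or with a tied
#' best match, are left unassigned -- ties are never broken arbitrarily,
#' preserving count integrity over yield.
#'
#' @param sequences Character vector of read sequences.
#' @param samples A `sample_sheet` (see [read_sample_sheet()]).
#' @param max_mismatch Maximum Hamming distance to accept (default 0).
#' @param barcode_start 1-based position of the barcode (default 1).
#' @return Integer vector, one element per read: the row index of the
#'   assigned sample in `samples`, or `NA` if unassigned. The attribute
#'   `"unassigned"` holds the unassigned count.
#' @export
demultiplex_reads <- function(sequences, samples, max_mismatch = 0L,
                              barcode_start = 1L) {
  samples <- as_sample_sheet(as.data.frame(samples))
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  barcodes <- samples$barcode
  L <- nchar(barcodes[1L])
  prefixes <- substr(sequences, barcode_start, barcode_start + L - 1L)
  d <- barcode_distances(prefixes, barcodes)
  best <- do.call(pmin, as.data.frame(d))
  n_best <- rowSums(d == best)
  assign <- max.col(-d, ties.method = "first")
  assign[best > max_mismatch | n_best > 1L] <- NA_integer_
  structure(assign, unassigned = sum(is.na(assign)))
}

#' Extract the 20-nt spacer from amplicon reads
#'
#' Finds the first exact occurrence of the 5' vector flank downstream of
#' the barcode region and returns the `spacer_length` bases that follow
#' it. When a 3' flank is supplied it must match immediately after the
#' spacer, otherwise the read is rejected. When the 5' flank is absent
#' from a read and `fallback_offset` is given, the spacer is taken at
#' that fixed 1-based offset instead.
#'
#' @param sequences Character vector of read sequences.
#' @param flank5 DNA string expected immediately 5' of the spacer
#'   (may be "" only if `fallback_offset` is given).
#' @param flank3 DNA string expected immediately 3' of the spacer
#'   ("" disables the check).
#' @param spacer_length Spacer length (default 20).
#' @param search_from 1-based position at which the flank search starts
#'   (typically barcode length + 1; default 1).
#' @param fallback_offset Optional fixed 1-based spacer offset used when
#'   `flank5` is not found.
#' @return Character vector of spacers; `NA` where unextractable.
#' @export
extract_spacers <- function(sequences, flank5, flank3 = "",
                            spacer_length = 20L, search_from = 1L,
                            fallback_offset = NULL) {
  if (!nzchar(flank5) && is.null(fallback_offset)) {
    stop("extract_spacers: flank5 must be nonempty or fallback_offset given",
         call. = FALSE)
  }
  n <- length(sequences)
  start <- rep(NA_integer_, n)
  if (nzchar(flank5)) {
    tail_seq <- substr(sequences, search_from, nchar(sequences))
    pos <- regexpr(flank5, tail_seq, fixed = TRUE)
    found <- pos > 0L
    start[found] <- search_from - 1L + pos[found] + nchar(flank5)
  }
  if (!is.null(fallback_offset)) {
    start[is.na(start)] <- as.integer(fallback_offset)
  }
  sp <- rep(NA_character_, n)
  idx <- which(!is.na(start) &
                 start + spacer_length - 1L <= nchar(sequences))
  sp[idx] <- substr(sequences[idx], start[idx],
                    start[idx] + spacer_length - 1L)
  if (nzchar(flank3)) {
    after <- rep(NA_character_, n)
    after[idx] <- substr(sequences[idx], start[idx] + spacer_length,
                         start[idx] + spacer_length + nchar(flank3) - 1L)
    sp[!is.na(sp) & (is.na(after) | after != flank3)] <- NA_character_
  }
  sp
}

# All Hamming-distance-1 variants of the library spacers, as a lookup
# table variant -> guide index; variants reachable from two different
# guides are marked ambiguous (index 0).
spacer_neighbor_table <- function(spacers) {
  L <- nchar(spacers[1L])
  bases <- c("A", "C", "G", "T")
  keys <- character(0)
  vals <- integer(0)
  for (i in seq_len(L)) {
    orig <- substr(spacers, i, i)
    for (b in bases) {
      changed <- orig != b
      if (!any(changed)) next
      v <- paste0(substr(spacers, 1L, i - 1L), b,
                  substr(spacers, i + 1L, L))
      keys <- c(keys, v[changed])
      vals <- c(vals, which(changed))
    }
  }
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  # a duplicated variant key means >= 2 guides at distance 1: ambiguous
  vals[dup] <- 0L
  list(keys = keys, vals = vals)
}

#' Count sgRNA spacers against a library
#'
#' Exact-match counting at `mismatch_tolerance = 0`. At tolerance 1 an
#' observed spacer is counted for a guide iff it matches no library
#' spacer exactly and has exactly one library spacer within Hamming
#' distance 1; spacers at distance 1 from two or more guides are
#' unmapped (never arbitrarily assigned). Wrong-length or `NA` spacers
#' count as unmapped/unextractable.
#'
#' @param spacers Character vector of observed spacers (`NA` allowed).
#' @param library An `sgrna_library`.
#' @param mismatch_tolerance 0 (default) or 1.
#' @return Named integer vector of per-guide counts (names = guide ids),
#'   with attributes `"unmapped"` (non-`NA` spacers that did not map) and
#'   `"unextractable"` (`NA` inputs).
#' @export
count_guides <- function(spacers, library, mismatch_tolerance = 0L) {
  library <- as_sgrna_library(as.data.frame(library))
  if (!mismatch_tolerance %in% c(0L, 1L)) {
    stop("mismatch_tolerance must be 0 or 1", call. = FALSE)
  }
  unextractable <- sum(is.na(spacers))
  obs <- spacers[!is.na(spacers)]
  hit <- match(obs, library$spacer)
  if (mismatch_tolerance == 1L && anyNA(hit)) {
    nb <- spacer_neighbor_table(library$spacer)
    miss <- which(is.na(hit) & nchar(obs) == nchar(library$spacer[1L]))
    j <- match(obs[miss], nb$keys)
    found <- !is.na(j) & nb$vals[ifelse(is.na(j), 1L, j)] > 0L
    hit[miss[found]] <- nb$vals[j[found]]
  }
  counts <- tabulate(hit, nbins = nrow(library))
  names(counts) <- library$guide_id
  structure(as.integer(counts),
            names = library$guide_id,
            unmapped = sum(is.na(hit)),
            unextractable = unextractable)
}

#' FASTQ to count table: demultiplex, extract and count
#'
#' Runs the full read-processing stage of the screen: reads one or more
#' pooled FASTQ files, assigns reads to samples by inline barcode,
#' recovers the spacers, and counts them against the library, producing
#' a guide-by-sample count table plus per-sample QC totals. The
#' conservation identities `total reads = sum(assigned) + unassigned`
#' and, per sample, `assigned = mapped + unmapped + unextractable`
#' hold exactly.
#'
#' @param fastq_paths Character vector of FASTQ paths (pooled reads).
#' @param library An `sgrna_library`.
#' @param samples A `sample_sheet`.
#' @param max_barcode_mismatch Barcode Hamming tolerance (default 0).
#' @param mismatch_tolerance Spacer Hamming tolerance, 0 or 1 (default 0).
#' @param flank5,flank3 Vector flanks around the spacer (see
#'   [extract_spacers()]); defaults match [emit_fastq()].
#' @param spacer_length Spacer length (default 20).
#' @param fallback_offset Optional fixed spacer offset when `flank5`
#'   is absent from a read.
#' @return List with `counts` (guide x sample integer matrix), `qc`
#'   (data frame: sample_id, assigned, mapped, unmapped, unextractable,
#'   plus one `unassigned` total row) and `unassigned` (count).
#' @export
count_screen <- function(fastq_paths, library, samples,
                         max_barcode_mismatch = 0L,
                         mismatch_tolerance = 0L,
                         flank5 = default_flank5(),
                         flank3 = default_flank3(),
                         spacer_length = 20L,
                         fallback_offset = NULL) {
  library <- as_sgrna_library(as.data.frame(library))
  samples <- as_sample_sheet(as.data.frame(samples))
  reads <- do.call(rbind, lapply(fastq_paths, read_fastq))
  assign <- demultiplex_reads(reads$sequence, samples,
                              max_mismatch = max_barcode_mismatch)
  bl <- nchar(samples$barcode[1L])
  counts <- matrix(0L, nrow = nrow(library), ncol = nrow(samples),
                   dimnames = list(library$guide_id, samples$sample_id))
  qc <- data.frame(sample_id = samples$sample_id,
                   assigned = 0L, mapped = 0L, unmapped = 0L,
                   unextractable = 0L, stringsAsFactors = FALSE)
  for (s in seq_len(nrow(samples))) {
    seqs <- reads$sequence[which(assign == s)]
    sp <- extract_spacers(seqs, flank5 = flank5, flank3 = flank3,
                          spacer_length = spacer_length,
                          search_from = bl + 1L,
                          fallback_offset = fallback_offset)
    ct <- count_guides(sp, library, mismatch_tolerance = mismatch_tolerance)
    counts[, s] <- ct
    qc$assigned[s] <- length(seqs)
    qc$mapped[s] <- sum(ct)
    qc$unmapped[s] <- attr(ct, "unmapped")
    qc$unextractable[s] <- attr(ct, "unextractable")
  }
  list(counts = counts, qc = qc,
       unassigned = attr(assign, "unassigned"))
}

#' Default amplicon layout around the spacer
#'
#' Reads are modelled as `barcode + flank5 + spacer + flank3`. The
#' defaults use the U6 cloning overhang `CACCG` upstream and the start
#' of the sgRNA scaffold `GTTT` downstream, a conventional layout for
#' lentiviral sgRNA amplicons; the true amplicon structure of any given
#' screen should be supplied explicitly if it differs.
#'
#' @return A DNA string.
#' @export
default_flank5 <- function() "CACCG"

#' @rdname default_flank5
#' @export
default_flank3 <- function() "GTTT"
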