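# Shared fixtures: tiny deterministic libraries, sample sheets and count
# tables built in code, plus literal-rule oracles kept independent of the
# package's implementation.

toy_library <- function(n_genes = 4L, guides_per_gene = 6L, seed = 42L) {
  simulate_library(n_genes, guides_per_gene, seed = seed)
}

toy_samples <- function() standard_sample_sheet()

# random count table over a library and sample sheet, guaranteed to have
# no all-zero sample column
random_counts <- function(library, samples, max_count = 30L) {
  m <- matrix(sample.int(max_count + 1L, nrow(library) * nrow(samples),
                         replace = TRUE) - 1L,
              nrow = nrow(library),
              dimnames = list(library$guide_id, samples$sample_id))
  zero <- colSums(m) == 0L
  m[1L, zero] <- 1L
  m
}

# Literal-rule oracle: explicit loops over the printed formulas and the
# stated selection rule, no shared code with the package internals.
oracle_screen_calls <- function(counts, samples, library, threshold = 5) {
  norm <- counts
  for (s in seq_len(ncol(counts))) {
    norm[, s] <- counts[, s] / sum(counts[, s]) * 1e7
  }
  pools <- unique(paste(samples$half_library, samples$pool_replicate,
                        sep = "-"))
  fe <- matrix(NA_real_, nrow(counts), length(pools),
               dimnames = list(rownames(counts), pools))
  for (p in pools) {
    parts <- strsplit(p, "-")[[1L]]
    tr <- samples$sample_id[samples$half_library == parts[1L] &
                              samples$pool_replicate == as.integer(parts[2L]) &
                              samples$condition == "treated"]
    un <- samples$sample_id[samples$half_library == parts[1L] &
                              samples$pool_replicate == as.integer(parts[2L]) &
                              samples$condition == "untreated"]
    for (g in seq_len(nrow(counts))) {
      denom <- norm[g, un]
      if (denom == 0) denom <- 1
      fe[g, p] <- norm[g, tr] / denom
    }
  }
  hits <- logical(nrow(counts))
  names(hits) <- rownames(counts)
  for (g in seq_len(nrow(counts))) {
    half <- library$half_library[library$guide_id == rownames(counts)[g]]
    exps <- pools[substr(pools, 1L, 1L) == half]
    ok <- TRUE
    for (p in exps) if (!(fe[g, p] > threshold)) ok <- FALSE
    hits[g] <- ok
  }
  candidates <- character(0)
  partial <- character(0)
  for (gene in sort(unique(library$gene))) {
    gids <- library$guide_id[library$gene == gene]
    inA <- any(hits[gids[library$half_library[match(gids, library$guide_id)] == "A"]])
    inB <- any(hits[gids[library$half_library[match(gids, library$guide_id)] == "B"]])
    if (inA && inB) candidates <- c(candidates, gene)
    else if (inA || inB) partial <- c(partial, gene)
  }
  list(fe = fe, hits = hits, candidates = candidates, partial = partial)
}

# textbook sum-form Pearson correlation, evaluated directly
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# between-class variance of the partition {<= t, > t}; the Otsu
# threshold must attain its maximum over an exhaustive sweep
between_class_variance <- function(image, t) {
  lo <- image <= t
  w0 <- mean(lo)
  if (w0 == 0 || w0 == 1) return(0)
  w0 * (1 - w0) * (mean(image[lo]) - mean(image[!lo]))^2
}

max_between_class_variance <- function(image, n_sweep = 1024L) {
  cand <- seq(min(image), max(image), length.out = n_sweep)
  max(vapply(cand, between_class_variance, numeric(1), image = image))
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}
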