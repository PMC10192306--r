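# Run `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so simulation helpers never perturb user randomness.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic lysenin-selection screen
#'
#' Declares the study design the simulator emulates: a GeCKO-v2-like
#' library (`guides_per_gene` guides per gene split equally between
#' half-libraries A and B), two independent pools per half-library
#' (A-1, A-2, B-1, B-2), `rounds` successive rounds of cytolysin
#' selection on the treated arm, an untreated subcultured control, and
#' multinomial sequencing of each arm at `depth` reads.
#'
#' Selection acts through per-guide survival weights: a cell carrying a
#' guide of efficacy `e` against a true resistance ("hit") gene survives
#' a round with probability `s_base + e * (s_hit - s_base)`; all other
#' cells survive with probability `s_base`. Guide efficacies are drawn
#' once per guide: inactive with probability `prob_inactive`, otherwise
#' Beta(`efficacy_shape1`, `efficacy_shape2`); each hit gene is
#' guaranteed at least `min_active_per_gene` active guides.
#'
#' @param n_genes Number of genes (default 1000).
#' @param guides_per_gene Guides per gene, even (default 6, split 3/3).
#' @param n_hit_genes Number of true resistance genes (default 20).
#' @param s_hit Per-round survival of a fully efficacious hit-gene cell
#'   under treatment, in (0, 1] (default 0.5).
#' @param s_base Per-round survival of any other cell, in (0, 1)
#'   (default 0.02).
#' @param rounds Selection rounds (default 3).
#' @param baseline_sigma Log-scale SD of initial guide abundances
#'   (default 0.5; 0 gives a uniform library).
#' @param depth Reads sequenced per sample (default 1e6).
#' @param prob_inactive Probability a hit-gene guide is inert (default 1/6).
#' @param min_active_per_gene Guaranteed active guides per hit gene
#'   (default 5).
#' @param efficacy_shape1,efficacy_shape2 Beta parameters for active-guide
#'   efficacy (defaults 6 and 1.5; mean 0.8).
#' @param seed Integer seed driving all randomness (default 1).
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 1000L, guides_per_gene = 6L,
                              n_hit_genes = 20L, s_hit = 0.5,
                              s_base = 0.02, rounds = 3L,
                              baseline_sigma = 0.5, depth = 1e6,
                              prob_inactive = 1 / 6,
                              min_active_per_gene = 5L,
                              efficacy_shape1 = 6, efficacy_shape2 = 1.5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_hit_genes = as.integer(n_hit_genes),
              s_hit = s_hit, s_base = s_base, rounds = as.integer(rounds),
              baseline_sigma = baseline_sigma, depth = as.numeric(depth),
              prob_inactive = prob_inactive,
              min_active_per_gene = as.integer(min_active_per_gene),
              efficacy_shape1 = efficacy_shape1,
              efficacy_shape2 = efficacy_shape2,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$guides_per_gene %% 2L != 0L) {
    stop("guides_per_gene must be even (equal A/B split)", call. = FALSE)
  }
  if (cfg$n_hit_genes < 0L || cfg$n_hit_genes > cfg$n_genes) {
    stop("n_hit_genes must be in [0, n_genes]", call. = FALSE)
  }
  if (cfg$s_hit <= 0 || cfg$s_hit > 1) stop("s_hit must be in (0, 1]", call. = FALSE)
  if (cfg$s_base <= 0 || cfg$s_base >= 1) stop("s_base must be in (0, 1)", call. = FALSE)
  if (cfg$s_hit < cfg$s_base) stop("s_hit must be >= s_base", call. = FALSE)
  if (cfg$baseline_sigma < 0) stop("baseline_sigma must be >= 0", call. = FALSE)
  if (cfg$depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (cfg$rounds < 0L) stop("rounds must be >= 0", call. = FALSE)
  if (cfg$min_active_per_gene > cfg$guides_per_gene) {
    stop("min_active_per_gene cannot exceed guides_per_gene", call. = FALSE)
  }
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Simulate a GeCKO-v2-like sgRNA library
#'
#' Builds the guide catalogue the simulator screens: `guides_per_gene`
#' unique random 20-nt spacers per gene, the first half assigned to
#' half-library A and the second to B.
#'
#' @param n_genes Number of genes.
#' @param guides_per_gene Guides per gene (even; default 6).
#' @param spacer_length Spacer length (default 20).
#' @param seed Optional seed (local RNG; default NULL uses current RNG).
#' @return An `sgrna_library` data frame.
#' @export
simulate_library <- function(n_genes, guides_per_gene = 6L,
                             spacer_length = 20L, seed = NULL) {
  with_seed(seed, {
    n <- n_genes * guides_per_gene
    repeat {
      sp <- vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
              collapse = "")
      }, character(1))
      if (!anyDuplicated(sp)) break
    }
    gene <- rep(sprintf("GENE%04d", seq_len(n_genes)),
                each = guides_per_gene)
    within_gene <- rep(seq_len(guides_per_gene), times = n_genes)
    as_sgrna_library(data.frame(
      gene = gene,
      guide_id = paste0(gene, "_sg", within_gene),
      spacer = sp,
      half_library = ifelse(within_gene <= guides_per_gene / 2L, "A", "B"),
      stringsAsFactors = FALSE
    ))
  })
}

#' Standard eight-sample sheet for a two-pool, two-half-library screen
#'
#' @param barcode_width Barcode length in nt (default 6).
#' @return A `sample_sheet` with samples
#'   \{A,B\} x \{1,2\} x \{treated, untreated\}.
#' @export
standard_sample_sheet <- function(barcode_width = 6L) {
  grid <- expand.grid(condition = c("treated", "untreated"),
                      pool_replicate = 1:2, half_library = c("A", "B"),
                      stringsAsFactors = FALSE)
  as_sample_sheet(data.frame(
    sample_id = paste(grid$half_library, grid$pool_replicate,
                      grid$condition, sep = "-"),
    half_library = grid$half_library,
    pool_replicate = grid$pool_replicate,
    condition = grid$condition,
    barcode = make_barcodes(nrow(grid), width = barcode_width),
    stringsAsFactors = FALSE
  ))
}

#' Baseline (pre-selection) guide abundances
#'
#' Library representation before any selection: log-normal relative
#' abundances with log-scale spread `baseline_sigma`, normalized to sum
#' to 1. A spread of 0 gives the uniform library `1/N`.
#'
#' @param n_guides Number of guides.
#' @param baseline_sigma Log-scale SD (>= 0).
#' @param seed Optional local seed.
#' @return Numeric vector summing to 1.
#' @export
simulate_baseline <- function(n_guides, baseline_sigma = 0.5, seed = NULL) {
  if (baseline_sigma < 0) stop("baseline_sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    a <- stats::rlnorm(n_guides, meanlog = 0, sdlog = baseline_sigma)
    a / sum(a)
  })
}

#' Per-guide survival weights under cytolysin treatment
#'
#' @param is_hit_guide Logical vector: does the guide target a true
#'   resistance gene?
#' @param efficacy Per-guide efficacy in [0, 1].
#' @param s_hit,s_base Survival probabilities (see [screen_sim_config()]).
#' @return Numeric vector of per-round survival weights.
#' @export
survival_weights <- function(is_hit_guide, efficacy, s_hit, s_base) {
  ifelse(is_hit_guide, s_base + efficacy * (s_hit - s_base), s_base)
}

#' Apply rounds of selection to an abundance vector
#'
#' Selection is modelled at expectation level: each round multiplies
#' every guide's abundance by its survival weight and renormalizes, so
#' the operation is deterministic; stochasticity enters the simulated
#' screen only at sequencing sampling.
#'
#' @param abundances Numeric vector summing to 1.
#' @param weights Per-guide survival weights (see [survival_weights()]).
#' @param rounds Number of selection rounds.
#' @return Post-selection abundance vector summing to 1.
#' @export
simulate_selection <- function(abundances, weights, rounds = 3L) {
  if (abs(sum(abundances) - 1) > 1e-8) {
    stop("abundances must sum to 1", call. = FALSE)
  }
  a <- abundances
  for (r in seq_len(rounds)) {
    a <- a * weights
    a <- a / sum(a)
  }
  a
}

#' Multinomial sequencing sampling of an abundance vector
#'
#' @param abundances Numeric vector summing to 1.
#' @param depth Total reads to draw (>= 0).
#' @param seed Optional local seed.
#' @return Integer count vector summing to `depth`.
#' @export
sample_counts <- function(abundances, depth, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (depth == 0) return(integer(length(abundances)))
  with_seed(seed, {
    as.integer(stats::rmultinom(1L, size = depth, prob = abundances))
  })
}

#' Simulate a complete eight-sample selection screen
#'
#' Generates a library, draws per-guide efficacies and the hit-gene set
#' once, then simulates each pool independently: an independent
#' log-normal baseline over that half-library's guides, an untreated arm
#' sequenced from the baseline, and a treated arm sequenced after
#' `rounds` rounds of survival selection. Guides of the other
#' half-library receive zero counts in a pool's samples, as in a real
#' half-library screen.
#'
#' @param config A `screen_sim_config`.
#' @param library Optional pre-built `sgrna_library`; by default one is
#'   simulated from the config.
#' @return List of class `screen_sim` with `counts` (guide x 8 samples),
#'   `samples`, `library`, `truth` (list: `hit_genes`, `efficacy`,
#'   `abundances` per pool/arm) and `config`.
#' @export
simulate_screen <- function(config = screen_sim_config(), library = NULL) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    if (is.null(library)) {
      library <- simulate_library(config$n_genes, config$guides_per_gene)
    }
    samples <- standard_sample_sheet()
    genes <- unique(library$gene)
    hit_genes <- if (config$n_hit_genes > 0L) {
      sort(sample(genes, config$n_hit_genes))
    } else character(0)
    is_hit_guide <- library$gene %in% hit_genes

    # guide efficacies: point mass of inert guides + Beta-distributed
    # active guides, with a guaranteed minimum of active guides per hit gene
    n_guides <- nrow(library)
    active <- stats::runif(n_guides) >= config$prob_inactive
    efficacy <- ifelse(active,
                       stats::rbeta(n_guides, config$efficacy_shape1,
                                    config$efficacy_shape2),
                       0)
    for (g in hit_genes) {
      gi <- which(library$gene == g)
      n_active <- sum(efficacy[gi] > 0)
      if (n_active < config$min_active_per_gene) {
        inert <- gi[efficacy[gi] == 0]
        revive <- inert[sample.int(length(inert),
                                   config$min_active_per_gene - n_active)]
        efficacy[revive] <- stats::rbeta(length(revive),
                                         config$efficacy_shape1,
                                         config$efficacy_shape2)
      }
    }
    efficacy[!is_hit_guide] <- 0
    weights <- survival_weights(is_hit_guide, efficacy,
                                config$s_hit, config$s_base)

    counts <- matrix(0L, nrow = n_guides, ncol = nrow(samples),
                     dimnames = list(library$guide_id, samples$sample_id))
    abundances <- list()
    for (p in unique(pool_id(samples))) {
      half <- substr(p, 1L, 1L)
      gi <- which(library$half_library == half)
      base <- simulate_baseline(length(gi), config$baseline_sigma)
      post <- simulate_selection(base, weights[gi], config$rounds)
      rows <- which(pool_id(samples) == p)
      for (s in rows) {
        ab <- if (samples$condition[s] == "treated") post else base
        counts[gi, s] <- sample_counts(ab, config$depth)
        abundances[[samples$sample_id[s]]] <- ab
      }
    }
    structure(list(counts = counts, samples = samples, library = library,
                   truth = list(hit_genes = hit_genes, efficacy = efficacy,
                                abundances = abundances),
                   config = config),
              class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated screen: %d genes x %d guides, %d hit genes, depth %g\n",
    x$config$n_genes, nrow(x$library), length(x$truth$hit_genes),
    x$config$depth))
  invisible(x)
}

#' Write the simulator's ground truth as a TSV
#'
#' @param sim A `screen_sim`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  df <- data.frame(gene = sim$library$gene,
                   guide_id = sim$library$guide_id,
                   is_hit = sim$library$gene %in% sim$truth$hit_genes,
                   efficacy = sim$truth$efficacy,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# substitute bases at i.i.d. error positions; used by emit_fastq
mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  width <- nchar(reads[1L])
  chunk <- 50000L
  out <- reads
  for (start in seq(1L, length(reads), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(reads))
    m <- do.call(rbind, strsplit(out[idx], "", fixed = TRUE))
    hit <- matrix(stats::runif(length(idx) * width) < error_rate,
                  nrow = length(idx))
    n_mut <- sum(hit)
    if (n_mut > 0L) {
      # substitute with one of the three other bases, uniformly
      shift <- sample.int(3L, n_mut, replace = TRUE)
      cur <- match(m[hit], bases)
      m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    out[idx] <- apply(m, 1L, paste, collapse = "")
  }
  out
}

#' Emit synthetic FASTQ reads from a count table
#'
#' For every sample and guide, writes `counts[g, s]` reads laid out as
#' `barcode + flank5 + spacer + flank3`, with i.i.d. per-base
#' substitutions at `error_rate` and a constant Phred+33 quality string.
#' Read ids encode sample and guide for debugging only. At
#' `error_rate = 0` the output round-trips exactly through
#' [count_screen()].
#'
#' @param counts Guide-by-sample integer matrix.
#' @param library An `sgrna_library` covering the count rows.
#' @param samples A `sample_sheet` covering the count columns.
#' @param path Output FASTQ path; a `.gz` suffix gzip-compresses.
#' @param flank5,flank3 Vector flanks (defaults [default_flank5()] and
#'   [default_flank3()]).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Optional local seed (used only when `error_rate > 0`).
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(counts, library, samples, path,
                       flank5 = default_flank5(),
                       flank3 = default_flank3(),
                       error_rate = 0, seed = NULL) {
  library <- as_sgrna_library(as.data.frame(library))
  samples <- as_sample_sheet(as.data.frame(samples))
  unknown <- setdiff(rownames(counts), library$guide_id)
  if (length(unknown) > 0L) {
    stop("unknown guide(s) in counts: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    spacer <- library$spacer[match(rownames(counts), library$guide_id)]
    for (s in seq_len(nrow(samples))) {
      cts <- counts[, samples$sample_id[s]]
      keep <- which(cts > 0L)
      if (length(keep) == 0L) next
      sp <- rep(spacer[keep], cts[keep])
      gid <- rep(rownames(counts)[keep], cts[keep])
      reads <- paste0(samples$barcode[s], flank5, sp, flank3)
      reads <- mutate_reads(reads, error_rate)
      qual <- strrep("I", nchar(reads[1L]))
      ids <- paste0("@", samples$sample_id[s], ":", gid, ":",
                    seq_along(reads))
      writeLines(as.vector(rbind(ids, reads, "+", qual)), con)
    }
  })
  invisible(path)
}
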