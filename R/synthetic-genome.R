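#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. The defaults are the
#' study conditions used throughout the test-suite: Poisson read counts,
#' two libraries per condition, a planted treated-only mean of 60 reads per
#' cryptic exon, and an amplification efficiency of 1 (perfect doubling).
#'
#' @param n_genes number of genes to simulate, one per chromosome.
#' @param exons_per_gene integer range (length 2) of constitutive exons per
#'   gene; must lie within 3..8.
#' @param cryptic_prob probability that a gene carries one intronic cryptic
#'   exon (ignored when explicit planted counts are given).
#' @param n_cryptic_targets,n_cryptic_nontargets optional exact numbers of
#'   planted NMD-target and non-target cryptic exons; when supplied they
#'   override `cryptic_prob`.
#' @param depth expected total valid reads per library.
#' @param n_libraries libraries per condition.
#' @param planted_mean expected treated-library read count for each planted
#'   cryptic exon.
#' @param decoy_fraction fraction of small-RNA reads drawn as random decoys
#'   matching no hairpin.
#' @param ct_sd standard deviation of qPCR Ct noise, in cycles.
#' @param efficiency qPCR amplification efficiency, a fraction in [0.8, 1.1]
#'   (1 = template doubles every cycle).
#' @param seed integer seed; together with the other fields it fully
#'   determines every generator output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L, exons_per_gene = c(3L, 8L),
                       cryptic_prob = 0.3,
                       n_cryptic_targets = NULL, n_cryptic_nontargets = NULL,
                       depth = 1e6, n_libraries = 2L, planted_mean = 60,
                       decoy_fraction = 0.1, ct_sd = 0.2, efficiency = 1.0,
                       seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length(exons_per_gene) != 2L || exons_per_gene[1] > exons_per_gene[2] ||
      exons_per_gene[1] < 3L || exons_per_gene[2] > 8L) {
    stop("exons_per_gene must be an increasing range within 3..8")
  }
  if (cryptic_prob < 0 || cryptic_prob > 1) stop("cryptic_prob must lie in [0, 1]")
  if (depth <= 0) stop("depth must be > 0")
  stopifnot_scalar_count(n_libraries, "n_libraries")
  if (planted_mean <= 0) stop("planted_mean must be > 0")
  if (decoy_fraction < 0 || decoy_fraction > 1) stop("decoy_fraction must lie in [0, 1]")
  if (ct_sd < 0) stop("ct_sd must be >= 0")
  if (efficiency < 0.8 || efficiency > 1.1) stop("efficiency must lie in [0.8, 1.1]")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 cryptic_prob = cryptic_prob,
                 n_cryptic_targets = n_cryptic_targets,
                 n_cryptic_nontargets = n_cryptic_nontargets,
                 depth = depth, n_libraries = as.integer(n_libraries),
                 planted_mean = planted_mean,
                 decoy_fraction = decoy_fraction,
                 ct_sd = ct_sd, efficiency = efficiency,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Build one gene: transcript first (so the CDS is stop-free by construction,
# with the natural stop in the last exon), then lay exons onto a chromosome
# with random introns and optionally plant one cryptic exon in an intron that
# is followed by at least one more internal exon, so any premature stop inside
# the cryptic exon sits >= 60 nt (one internal exon) upstream of the last
# exon-exon junction.
build_gene <- function(gene_id, chrom, exon_range,
                       cryptic_kind = c("none", "target", "nontarget"),
                       force_frameshift_length = FALSE) {
  cryptic_kind <- match.arg(cryptic_kind)
  n_ex <- sample(seq(exon_range[1], exon_range[2]), 1L)
  lens <- c(sample(100:300, 1L),
            if (n_ex > 2L) sample(60:200, n_ex - 2L, replace = TRUE),
            sample(150:300, 1L))
  tx_len <- sum(lens)
  cds_start <- sample(10:50, 1L)
  last_junction <- tx_len - lens[n_ex]

  # natural stop: first in-frame position at/after the last junction, plus a
  # random in-frame offset inside the last exon, leaving a >= 3 nt 3'UTR
  first_inframe <- cds_start + 3L * ceiling((last_junction - cds_start) / 3)
  stop_starts <- seq(first_inframe, tx_len - 6L, by = 3L)
  s <- if (length(stop_starts) > 1L) sample(stop_starts, 1L) else stop_starts[1L]

  n_codons <- (s - cds_start - 3L) / 3
  tx <- paste0(rand_dna(cds_start), "ATG", random_codons(n_codons), "TAA",
               rand_dna(tx_len - s - 3L))
  stopifnot(nchar(tx) == tx_len)

  ends <- cumsum(lens)
  starts_tx <- c(0L, ends[-n_ex])
  exon_seqs <- substring(tx, starts_tx + 1L, ends)

  cryptic_seq <- NULL
  j <- NA_integer_
  if (cryptic_kind != "none") {
    j <- if (n_ex > 3L) sample(seq_len(n_ex - 2L), 1L) else 1L
    pos_c <- ends[j]                       # transcript start of cryptic exon
    p <- (pos_c - cds_start) %% 3L
    if (cryptic_kind == "target") {
      len_c <- sample(50:200, 1L)
      if (force_frameshift_length) while (len_c %% 3L == 0L) len_c <- sample(50:200, 1L)
      r <- (3L - p) %% 3L
      cryptic_seq <- paste0(rand_dna(r), random_codons(2L), "TAA",
                            rand_dna(len_c - r - 9L))
    } else {
      len_c <- 3L * sample(17:66, 1L)      # frame-preserving, 51..198 nt
      if (p == 0L) {
        cryptic_seq <- random_codons(len_c / 3L)
      } else {
        # reuse the original junction codon's halves at both cryptic edges so
        # the codons spanning exon_j|cryptic and cryptic|exon_j+1 are exactly
        # the (non-stop) codon that spanned exon_j|exon_j+1 before insertion
        tail_p <- substring(exon_seqs[j], lens[j] - p + 1L, lens[j])
        head_q <- substring(exon_seqs[j + 1L], 1L, 3L - p)
        cryptic_seq <- paste0(head_q, random_codons(len_c / 3L - 1L), tail_p)
      }
    }
    stopifnot(nchar(cryptic_seq) == len_c)
  }

  intron_lens <- sample(250:500, n_ex - 1L, replace = TRUE)
  introns <- character(n_ex - 1L)
  cryptic_off <- NA_integer_
  for (k in seq_len(n_ex - 1L)) {
    if (!is.na(j) && k == j) {
      len_c <- nchar(cryptic_seq)
      cryptic_off <- sample(10:(intron_lens[k] - len_c - 10L), 1L)
      introns[k] <- paste0(rand_dna(cryptic_off), cryptic_seq,
                           rand_dna(intron_lens[k] - cryptic_off - len_c))
    } else {
      introns[k] <- rand_dna(intron_lens[k])
    }
  }

  flank5 <- 50L
  pieces <- character(2L * n_ex)
  pieces[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_seqs
  pieces[seq(2L, 2L * n_ex - 2L, by = 2L)] <- introns
  pieces[2L * n_ex] <- ""
  chrom_seq <- paste0(rand_dna(flank5), paste(pieces, collapse = ""), rand_dna(50L))

  g_starts <- integer(n_ex)
  pos <- flank5
  for (k in seq_len(n_ex)) {
    g_starts[k] <- pos
    pos <- pos + lens[k]
    if (k < n_ex) pos <- pos + intron_lens[k]
  }

  exons <- data.frame(exon_id = sprintf("%s:E%d", gene_id, seq_len(n_ex)),
                      gene_id = gene_id, chrom = chrom,
                      start = g_starts, end = g_starts + lens,
                      strand = "+", curated = TRUE, cryptic = FALSE,
                      stringsAsFactors = FALSE)
  cryptic_row <- NULL
  if (!is.na(j)) {
    c_start <- g_starts[j] + lens[j] + cryptic_off
    cryptic_row <- data.frame(exon_id = sprintf("%s:C1", gene_id),
                              gene_id = gene_id, chrom = chrom,
                              start = c_start, end = c_start + nchar(cryptic_seq),
                              strand = "+", curated = FALSE, cryptic = TRUE,
                              stringsAsFactors = FALSE)
  }

  # half the genes live on the minus strand: mirror the chromosome
  if (runif(1) < 0.5) {
    L <- nchar(chrom_seq)
    chrom_seq <- revcomp(chrom_seq)
    flip <- function(df) {
      new_start <- L - df$end
      df$end <- L - df$start
      df$start <- new_start
      df$strand <- "-"
      df
    }
    exons <- flip(exons)
    if (!is.null(cryptic_row)) cryptic_row <- flip(cryptic_row)
  }

  model <- list(gene_id = gene_id, chrom = chrom, strand = exons$strand[1L],
                exons = exons[, c("exon_id", "start", "end")],
                cds_start_tx = cds_start, cds_end_tx = s + 3L, tx_len = tx_len)
  class(model) <- "transcript_model"

  list(chrom_seq = chrom_seq, exons = exons, cryptic = cryptic_row, model = model)
}

#' Generate a synthetic genome, gene models and planted truth
#'
#' Each gene receives 3-8 constitutive exons on its own chromosome, a CDS that
#' starts with ATG in the first exon and terminates at a natural stop codon in
#' the last exon, and (for selected genes) one intronic cryptic exon.
#' NMD-target cryptic exons carry a planted in-frame premature stop that lies
#' at least 50 nt upstream of the last exon-exon junction of the inclusion
#' transcript; non-target cryptic exons preserve reading frame and contain no
#' in-frame stop, so translation runs through to the natural stop. Labels are
#' recorded by construction, not by running the classifier.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `annotation` (exon data frame, 0-based half-open
#'   coordinates), `models` (named list of transcript models over constitutive
#'   exons) and `truth` (a `planted_truth` list: `nmd_target_exon_ids`,
#'   `non_target_cryptic_ids`, `treated_only_expression`, `seed`).
#' @export
make_genome_and_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_genes

  if (!is.null(config$n_cryptic_targets) || !is.null(config$n_cryptic_nontargets)) {
    nt <- config$n_cryptic_targets %||% 0L
    nn <- config$n_cryptic_nontargets %||% 0L
    if (nt + nn > n) {
      stop("sizing error: more planted cryptic exons than genes available")
    }
    idx <- sample.int(n, nt + nn)
    kind <- rep("none", n)
    kind[idx[seq_len(nt)]] <- "target"
    if (nn > 0L) kind[idx[nt + seq_len(nn)]] <- "nontarget"
  } else {
    kind <- ifelse(runif(n) < config$cryptic_prob,
                   ifelse(runif(n) < 0.5, "target", "nontarget"), "none")
  }

  first_target <- match("target", kind)
  genome <- character(n)
  anno <- vector("list", n)
  models <- vector("list", n)
  gene_ids <- sprintf("g%04d", seq_len(n))
  chroms <- sprintf("chr_%s", gene_ids)
  for (i in seq_len(n)) {
    g <- build_gene(gene_ids[i], chroms[i], config$exons_per_gene, kind[i],
                    force_frameshift_length = identical(i, first_target))
    genome[i] <- g$chrom_seq
    anno[[i]] <- rbind(g$exons, g$cryptic)
    models[[i]] <- g$model
  }
  names(genome) <- chroms
  names(models) <- gene_ids
  annotation <- do.call(rbind, anno)
  rownames(annotation) <- NULL

  target_ids <- annotation$exon_id[annotation$cryptic &
                                     annotation$gene_id %in% gene_ids[kind == "target"]]
  nontarget_ids <- annotation$exon_id[annotation$cryptic &
                                        annotation$gene_id %in% gene_ids[kind == "nontarget"]]
  planted <- c(target_ids, nontarget_ids)
  truth <- structure(list(
    nmd_target_exon_ids = target_ids,
    non_target_cryptic_ids = nontarget_ids,
    treated_only_expression = stats::setNames(rep(config$planted_mean,
                                                  length(planted)), planted),
    arm_bias = NULL, family_shift = NULL, seed = config$seed
  ), class = "planted_truth")

  list(genome = genome, annotation = annotation, models = models, truth = truth)
}

#' Per-exon count table
#'
#' @param counts integer matrix, exons in rows, libraries in columns.
#' @param total_valid_reads optional named vector of per-library totals;
#'   defaults to the column sums.
#' @return object of class `exon_count_table`.
#' @export
exon_count_table <- function(counts, total_valid_reads = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry exon ids as rownames and library ids as colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  tvr <- total_valid_reads %||% colSums(counts)
  if (any(tvr < 0)) stop("total_valid_reads must be non-negative")
  structure(list(counts = counts, total_valid_reads = tvr),
            class = "exon_count_table")
}

#' Simulate paired control/treated exon count tables
#'
#' Constitutive exons receive Poisson counts around condition-independent
#' means whose relative sizes are gamma-distributed and scale with `depth`.
#' Planted cryptic exons (both NMD targets and non-targets) have zero reads in
#' every control library and Poisson counts at their planted treated-only mean
#' in treated libraries, emulating translation-inhibition-stabilized exons.
#'
#' @param models gene models from [make_genome_and_models()].
#' @param truth the matching `planted_truth`.
#' @param config the [sim_config()] used for generation.
#' @return list with `control` and `treated` [exon_count_table()]s.
#' @export
simulate_exon_counts <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 1L)
  const_ids <- unlist(lapply(models, function(m) m$exons$exon_id), use.names = FALSE)
  w <- rgamma(length(const_ids), shape = 2, rate = 2)
  mu <- config$depth * w / sum(w)
  planted_ids <- names(truth$treated_only_expression)
  nlib <- config$n_libraries

  draw <- function(cond) {
    m <- matrix(0L, nrow = length(const_ids) + length(planted_ids), ncol = nlib,
                dimnames = list(c(const_ids, planted_ids),
                                sprintf("%s_%d", cond, seq_len(nlib))))
    for (l in seq_len(nlib)) {
      m[seq_along(const_ids), l] <- rpois(length(const_ids), mu)
      if (cond == "chx" && length(planted_ids)) {
        m[length(const_ids) + seq_along(planted_ids), l] <-
          rpois(length(planted_ids), truth$treated_only_expression)
      }
    }
    exon_count_table(m)
  }
  list(control = draw("ctrl"), treated = draw("chx"))
}
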