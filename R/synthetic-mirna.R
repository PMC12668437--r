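#' Generate a synthetic hairpin (pre-miRNA) reference
#'
#' Hairpins are 60-90 nt with non-overlapping 5p and 3p mature intervals of
#' 20-23 nt near the two ends. Mature sequences are pairwise distinct and each
#' occurs exactly once across the whole reference, so unique-exact-match
#' counting is well defined; generation retries a bounded number of times and
#' errors if uniqueness cannot be attained.
#'
#' @param n_hairpins number of hairpins (>= 1).
#' @param arm_bias optional numeric vector of 5p sampling weights in [0, 1]
#'   (one per hairpin; the 3p weight is the complement). Defaults to draws
#'   from a U-shaped Beta(0.4, 0.4), emulating the strong strand biases seen
#'   in real small-RNA data.
#' @param families optional character vector of family labels per hairpin.
#' @param seed integer seed.
#' @return object of class `mirna_reference`: `hairpins` (named character),
#'   `mature` (data frame hairpin_id, arm, start, end, sequence; 0-based
#'   half-open intervals), `arm_bias` (matrix with columns w5p, w3p).
#' @export
make_mirna_reference <- function(n_hairpins, arm_bias = NULL, families = NULL,
                                 seed = 1L) {
  stopifnot_scalar_count(n_hairpins, "n_hairpins")
  if (n_hairpins < 1L) stop("n_hairpins must be >= 1")
  withr::local_seed(seed)
  if (is.null(arm_bias)) arm_bias <- stats::rbeta(n_hairpins, 0.4, 0.4)
  if (length(arm_bias) != n_hairpins || any(arm_bias < 0 | arm_bias > 1)) {
    stop("arm_bias must be one 5p weight in [0, 1] per hairpin")
  }

  ids <- sprintf("mir-%03d", seq_len(n_hairpins))
  hairpins <- character(n_hairpins)
  mature <- vector("list", n_hairpins)
  seen <- character(0)
  for (i in seq_len(n_hairpins)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      L <- sample(60:90, 1L)
      seq <- rand_dna(L)
      s5 <- sample(1:5, 1L); l5 <- sample(20:23, 1L)
      e3 <- L - sample(1:5, 1L); l3 <- sample(20:23, 1L)
      m5 <- substring(seq, s5 + 1L, s5 + l5)
      m3 <- substring(seq, e3 - l3 + 1L, e3)
      if (s5 + l5 >= e3 - l3) next
      cand <- c(seen, m5, m3)
      if (anyDuplicated(cand)) next
      all_seqs <- c(hairpins[seq_len(i - 1L)], seq)
      n_occ <- function(m) {
        sum(vapply(gregexpr(m, all_seqs, fixed = TRUE),
                   function(g) if (g[1L] == -1L) 0L else length(g), integer(1L)))
      }
      if (n_occ(m5) != 1L || n_occ(m3) != 1L) next
      if (length(seen) && any(vapply(seen, grepl, logical(1L), x = seq,
                                     fixed = TRUE))) next
      hairpins[i] <- seq
      mature[[i]] <- data.frame(hairpin_id = ids[i], arm = c("5p", "3p"),
                                start = c(s5, e3 - l3), end = c(s5 + l5, e3),
                                sequence = c(m5, m3), stringsAsFactors = FALSE)
      seen <- c(seen, m5, m3)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not generate unique mature sequences after 100 retries")
  }
  names(hairpins) <- ids
  structure(list(hairpins = hairpins,
                 mature = do.call(rbind, mature),
                 arm_bias = cbind(w5p = arm_bias, w3p = 1 - arm_bias),
                 families = families),
            class = "mirna_reference")
}

#' Simulate small-RNA reads from a hairpin reference
#'
#' Non-decoy reads are exact copies of mature-arm sequences: a hairpin is
#' drawn (uniformly or by `hairpin_weights`), then the arm by the reference's
#' 5p/3p bias. Decoy reads are random 20-23-mers verified to match no hairpin
#' substring, exercising the unique-exact-match filter downstream.
#'
#' @param reference a [make_mirna_reference()] object.
#' @param n_reads total reads to emit.
#' @param decoy_fraction fraction of reads drawn as decoys.
#' @param hairpin_weights optional sampling weight per hairpin (relative
#'   expression); defaults to uniform.
#' @param arm_bias optional override of the reference's 5p weights.
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `is_decoy`
#'   (logical vector of the same length).
#' @export
simulate_small_rna_reads <- function(reference, n_reads, decoy_fraction = 0.1,
                                     hairpin_weights = NULL, arm_bias = NULL,
                                     seed = 1L) {
  stopifnot(inherits(reference, "mirna_reference"))
  stopifnot_scalar_count(n_reads, "n_reads")
  withr::local_seed(seed)
  n_hp <- length(reference$hairpins)
  w <- hairpin_weights %||% rep(1, n_hp)
  bias <- arm_bias %||% reference$arm_bias[, "w5p"]
  mat <- reference$mature
  seq5 <- stats::setNames(mat$sequence[mat$arm == "5p"], mat$hairpin_id[mat$arm == "5p"])
  seq3 <- stats::setNames(mat$sequence[mat$arm == "3p"], mat$hairpin_id[mat$arm == "3p"])

  is_decoy <- runif(n_reads) < decoy_fraction
  reads <- character(n_reads)
  if (any(!is_decoy)) {
    idx <- sample.int(n_hp, sum(!is_decoy), replace = TRUE, prob = w)
    arm5 <- runif(length(idx)) < bias[idx]
    hp <- names(reference$hairpins)[idx]
    reads[!is_decoy] <- ifelse(arm5, seq5[hp], seq3[hp])
  }
  for (i in which(is_decoy)) {
    repeat {
      d <- rand_dna(sample(20:23, 1L))
      if (!any(grepl(d, reference$hairpins, fixed = TRUE))) break
    }
    reads[i] <- d
  }
  names(reads) <- sprintf("read_%06d", seq_len(n_reads))
  list(reads = reads, is_decoy = is_decoy)
}

#' Simulate a qPCR plate with a spiked calibrator dilution series
#'
#' Ct values follow `intercept + slope * log10(conc) + N(0, ct_sd)` with
#' `slope = -1 / log10(1 + efficiency)`, i.e. template multiplies by
#' (1 + efficiency) each cycle. Spike wells carry the known dilution
#' concentrations (in triplicate by default, as standards are usually run);
#' sample wells carry the true concentrations to be recovered.
#'
#' @param true_concs named numeric vector of sample concentrations (fM); names
#'   become assay ids and may repeat for replicate wells.
#' @param spike_dilutions numeric vector of known spike concentrations (fM).
#' @param config a [sim_config()] supplying `ct_sd`, `efficiency` and `seed`.
#' @param n_spike_replicates wells per spike dilution.
#' @param intercept Ct at 1 fM, in cycles.
#' @return data frame with columns well, assay_id, is_spike, known_conc_fM, Ct.
#' @export
simulate_qpcr_plate <- function(true_concs, spike_dilutions, config,
                                n_spike_replicates = 3L, intercept = 36) {
  stopifnot(inherits(config, "sim_config"))
  if (any(c(true_concs, spike_dilutions) <= 0)) {
    stop("concentrations must be strictly positive")
  }
  withr::local_seed(config$seed + 2L)
  slope <- -1 / log10(1 + config$efficiency)
  spike_conc <- rep(spike_dilutions, each = n_spike_replicates)
  conc <- c(spike_conc, unname(true_concs))
  is_spike <- c(rep(TRUE, length(spike_conc)), rep(FALSE, length(true_concs)))
  assay <- c(rep("spike", length(spike_conc)),
             names(true_concs) %||% sprintf("sample_%d", seq_along(true_concs)))
  ct <- intercept + slope * log10(conc) + rnorm(length(conc), 0, config$ct_sd)
  data.frame(well = sprintf("W%03d", seq_along(conc)),
             assay_id = assay, is_spike = is_spike,
             known_conc_fM = ifelse(is_spike, conc, NA_real_),
             Ct = ct, stringsAsFactors = FALSE)
}

#' Build a synthetic miRNA-family target-site table
#'
#' Plants a chosen number of target mRNAs with 1-6 seed-match sites of the
#' canonical classes (8mer, 7mer-m8, 7mer-1A); site counts are skewed toward
#' single sites as in genome-wide target predictions.
#'
#' @param n_mrnas total mRNAs in the universe (ids m00001...).
#' @param n_targets number of mRNAs given at least one site.
#' @param family family label for the sites.
#' @param seed integer seed.
#' @return data frame (mrna_id, family, site_type, n_sites), one row per target.
#' @export
make_target_site_table <- function(n_mrnas, n_targets, family = "let-7",
                                   seed = 1L) {
  stopifnot_scalar_count(n_mrnas, "n_mrnas")
  stopifnot_scalar_count(n_targets, "n_targets")
  if (n_targets > n_mrnas) stop("n_targets cannot exceed n_mrnas")
  withr::local_seed(seed)
  ids <- sprintf("m%05d", sort(sample.int(n_mrnas, n_targets)))
  data.frame(mrna_id = ids, family = rep(family, n_targets),
             site_type = sample(c("8mer", "7mer-m8", "7mer-1A"), n_targets,
                                replace = TRUE),
             n_sites = sample(1:6, n_targets, replace = TRUE,
                              prob = c(0.92, 0.05, 0.015, 0.008, 0.004, 0.003)),
             stringsAsFactors = FALSE)
}

#' Simulate an mRNA fold-change table with a family-target shift
#'
#' Non-target mRNAs receive log2 fold changes from N(0, sigma); mRNAs present
#' in the site table receive N(family_shift, sigma), emulating derepression of
#' a miRNA family's targets.
#'
#' @param n_mrnas number of mRNAs (ids m00001...).
#' @param target_site_table data frame as from [make_target_site_table()]
#'   (may be empty: then every mRNA is a non-target).
#' @param family_shift log2 shift applied to targets.
#' @param sigma log2 fold-change standard deviation.
#' @param seed integer seed.
#' @return data frame (mrna_id, log2_fc, fold_change).
#' @export
simulate_target_foldchanges <- function(n_mrnas, target_site_table,
                                        family_shift, sigma = 0.3, seed = 1L) {
  stopifnot_scalar_count(n_mrnas, "n_mrnas")
  withr::local_seed(seed)
  ids <- sprintf("m%05d", seq_len(n_mrnas))
  is_target <- ids %in% target_site_table$mrna_id
  lfc <- rnorm(n_mrnas, ifelse(is_target, family_shift, 0), sigma)
  data.frame(mrna_id = ids, log2_fc = lfc, fold_change = 2^lfc,
             stringsAsFactors = FALSE)
}
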