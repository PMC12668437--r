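#' Proportion with half-up percentage and exact binomial interval
#'
#' @param numerator,denominator counts with 0 <= numerator <= denominator and
#'   denominator > 0.
#' @param conf confidence level for the Clopper-Pearson interval.
#' @return list (numerator, denominator, percent to 1 decimal, ci_lower,
#'   ci_upper as percentages).
#' @export
proportion_summary <- function(numerator, denominator, conf = 0.95) {
  stopifnot_scalar_count(numerator, "numerator")
  stopifnot_scalar_count(denominator, "denominator")
  if (denominator == 0) stop("denominator must be > 0")
  if (numerator > denominator) stop("numerator cannot exceed denominator")
  ci <- binom.test(numerator, denominator, conf.level = conf)$conf.int
  list(numerator = numerator, denominator = denominator,
       percent = round_half_up(100 * numerator / denominator, 1),
       ci_lower = 100 * ci[1L], ci_upper = 100 * ci[2L])
}

#' Fold ratio with an order-of-magnitude approximate form
#'
#' @param a,b quantities with b > 0.
#' @return list (ratio = a/b, approx = the ratio rounded to 1 significant
#'   figure, the "~300-fold" style of reporting).
#' @export
ratio_summary <- function(a, b) {
  if (b <= 0) stop("denominator must be > 0")
  r <- a / b
  list(ratio = r, approx = signif(r, 1))
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    inputs = NULL, # optional: list(gff=, control_counts=, treated_counts=)
    synthetic = list(n_genes = 60L, n_cryptic_targets = 8L,
                     n_cryptic_nontargets = 8L, depth = 1e6, n_libraries = 2L,
                     planted_mean = 60, decoy_fraction = 0.1, ct_sd = 0.2,
                     efficiency = 1.0),
    thresholds = list(min_exclusive_reads = 20L, ptc_min_distance_nt = 50L,
                      sharpness_min = 0.9),
    mirna = list(n_hairpins = 20L, n_family = 6L, family = "let-7-like",
                 n_reads = 20000L, fall_1h = 0.5, recovery_6h = 1.0),
    qpcr = list(spike_dilutions = 10^(2:-2), control_conc_fM = 100,
                fall_1h = 0.2, recovery_6h = 1.0),
    targets = list(n_mrnas = 2000L, n_targets = 100L, family_shift = 0.5,
                   sigma = 0.3)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' @param config a list of overrides, or a path to a YAML file of them;
#'   missing fields take the package defaults.
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full stress-response analysis pipeline
#'
#' Orchestrates every stage against a seeded synthetic data set (or, for the
#' exon screen, against user-supplied GFF3 + count-table inputs): exon-screen
#' funnel, pre-miRNA differential and strand-bias analysis across a
#' 0 h / 1 h / 6 h fall-and-recovery design, spike-in qPCR calibration, and
#' the family target-set fold-change comparison. Artifacts (genome FASTA,
#' GFF3, count tables, FASTQ reads, Ct plate, candidate table and the report
#' JSON) are written to `out_dir` when one is configured.
#'
#' @param config a [run_config()], a list of overrides, or a YAML path.
#' @return list of class `summary_report`.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  seed <- cfg$seed
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # --- exon screen ---------------------------------------------------------
  thr <- screen_thresholds(min_exclusive_reads = cfg$thresholds$min_exclusive_reads,
                           ptc_min_distance_nt = cfg$thresholds$ptc_min_distance_nt,
                           sharpness_min = cfg$thresholds$sharpness_min)
  if (!is.null(cfg$inputs)) {
    ann <- read_annotation_gff3(cfg$inputs$gff)
    genome <- read_genome_fasta(cfg$inputs$genome)
    control <- read_exon_counts(cfg$inputs$control_counts)
    treated <- read_exon_counts(cfg$inputs$treated_counts)
    annotation <- ann$annotation
    models <- ann$models
    truth <- NULL
  } else {
    sc <- sim_config(n_genes = cfg$synthetic$n_genes,
                     n_cryptic_targets = cfg$synthetic$n_cryptic_targets,
                     n_cryptic_nontargets = cfg$synthetic$n_cryptic_nontargets,
                     depth = cfg$synthetic$depth,
                     n_libraries = cfg$synthetic$n_libraries,
                     planted_mean = cfg$synthetic$planted_mean,
                     decoy_fraction = cfg$synthetic$decoy_fraction,
                     ct_sd = cfg$synthetic$ct_sd,
                     efficiency = cfg$synthetic$efficiency, seed = seed)
    gen <- make_genome_and_models(sc)
    genome <- gen$genome
    annotation <- gen$annotation
    models <- gen$models
    truth <- gen$truth
    tabs <- simulate_exon_counts(models, truth, sc)
    control <- tabs$control
    treated <- tabs$treated
    if (!is.null(out)) {
      write_genome_fasta(genome, file.path(out, "genome.fa"))
      write_annotation_gff3(annotation, file.path(out, "annotation.gff3"),
                            models = models)
      write_exon_counts(control, annotation, out, "control")
      write_exon_counts(treated, annotation, out, "treated")
      jsonlite::write_json(unclass(truth), file.path(out, "planted_truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  screen <- screen_pipeline(control, treated, annotation, models, genome, thr)

  # --- miRNA quantification across timepoints ------------------------------
  mc <- cfg$mirna
  ref <- make_mirna_reference(mc$n_hairpins, seed = seed + 10L)
  fam_ids <- names(ref$hairpins)[seq_len(min(mc$n_family, mc$n_hairpins))]
  family_map <- stats::setNames(rep(mc$family, length(fam_ids)), fam_ids)
  base_w <- rep(1, mc$n_hairpins)
  scale_family <- function(f) {
    w <- base_w
    w[seq_along(fam_ids)] <- w[seq_along(fam_ids)] * f
    w
  }
  libs <- list()
  plan <- list(ctrl_0h = 1, iron_1h = mc$fall_1h, iron_6h = mc$recovery_6h)
  for (i in seq_along(plan)) {
    sim <- simulate_small_rna_reads(ref, mc$n_reads,
                                    decoy_fraction = cfg$synthetic$decoy_fraction,
                                    hairpin_weights = scale_family(plan[[i]]),
                                    seed = seed + 20L + i)
    libs[[names(plan)[i]]] <- sim$reads
  }
  mir_counts <- count_hairpin_alignments(libs, ref)
  norm <- normalize_expression(mir_counts, ref)
  diff <- call_differential(norm[, "ctrl_0h"], norm[, "iron_1h"])
  fam_fc <- family_aggregate(
    list(`1h` = list(control = norm[, "ctrl_0h"], treated = norm[, "iron_1h"]),
         `6h` = list(control = norm[, "ctrl_0h"], treated = norm[, "iron_6h"])),
    family_map)
  arms <- count_mature_arms(libs$ctrl_0h, ref)
  bias <- classify_strand_bias(arms)
  if (!is.null(out)) write_small_rna_fastq(libs$ctrl_0h,
                                           file.path(out, "smallrna_ctrl_0h.fastq"))

  # --- spike-in qPCR calibration -------------------------------------------
  qc <- cfg$qpcr
  concs <- c(control = qc$control_conc_fM,
             iron_1h = qc$control_conc_fM * qc$fall_1h,
             iron_6h = qc$control_conc_fM * qc$recovery_6h)
  plate_cfg <- sim_config(ct_sd = cfg$synthetic$ct_sd,
                          efficiency = cfg$synthetic$efficiency,
                          seed = seed + 30L)
  plate <- simulate_qpcr_plate(concs, qc$spike_dilutions, plate_cfg)
  curve <- fit_standard_curve(plate[plate$is_spike, ])
  sample_wells <- plate[!plate$is_spike, ]
  recovered <- stats::setNames(ct_to_concentration(sample_wells$Ct, curve),
                               sample_wells$assay_id)
  qpcr_fc <- fold_change_vs_control(recovered)
  if (!is.null(out)) write_ct_plate(plate, file.path(out, "ct_plate.csv"))

  # --- family target-set comparison ----------------------------------------
  tc <- cfg$targets
  site_tab <- make_target_site_table(tc$n_mrnas, tc$n_targets,
                                     family = mc$family, seed = seed + 40L)
  fc_tab <- simulate_target_foldchanges(tc$n_mrnas, site_tab, tc$family_shift,
                                        sigma = tc$sigma, seed = seed + 41L)
  cats <- categorize_mrnas(fc_tab, site_tab, mc$family)
  cmp <- compare_fold_changes(cats$targets$fold_change,
                              cats$non_targets$fold_change)

  report <- structure(list(
    seed = seed,
    funnel = as.list(screen$funnel),
    candidates = screen$candidates,
    planted_truth_recovered = if (!is.null(truth)) {
      setequal(screen$candidates$exon_id[screen$candidates$nmd_status == "target"],
               truth$nmd_target_exon_ids)
    } else NA,
    differential_mirna = c(diff$summary,
                           list(proportion = proportion_summary(
                             diff$summary$n_differential,
                             diff$summary$n_detected))),
    strand_bias = bias$summary,
    family_fold_changes = fam_fc,
    calibration = list(efficiency = curve$efficiency,
                       slope = curve$slope, r_squared = curve$r_squared,
                       fold_changes = qpcr_fc),
    target_comparison = list(n_targets = cats$site_stats$n_targets,
                             n_total = cats$site_stats$n_total,
                             mean_sites = cats$site_stats$mean_sites,
                             test = cmp$test, statistic = cmp$statistic,
                             p_value = cmp$p_value,
                             medians = as.list(cmp$medians))
  ), class = "summary_report")

  if (!is.null(out)) {
    write.table(screen$candidates, file.path(out, "candidate_exons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  }
  report
}

#' Re-validate every proportion printed in a summary report
#'
#' Checks that each (numerator, denominator, percent) triple in the report is
#' arithmetically consistent under the package's rounding rules.
#'
#' @param report a `summary_report`.
#' @return TRUE invisibly; errors on an inconsistent triple.
#' @export
validate_report <- function(report) {
  p <- report$differential_mirna$proportion
  stopifnot(p$percent == round_half_up(100 * p$numerator / p$denominator, 1))
  sb <- report$strand_bias
  if (sum(sb$n) > 0) {
    stopifnot(all(sb$pct == round_half_up(100 * sb$n / sum(sb$n), 0)))
  }
  invisible(TRUE)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("ecstress summary report (seed ", x$seed, ")\n\n", sep = "")
  cat("Exon funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-26s %s\n", nm, x$funnel[[nm]]))
  d <- x$differential_mirna
  cat(sprintf("\npre-miRNAs: %d detected, %d (%.1f%%) differed by >= 20%%\n",
              d$n_detected, d$n_differential, d$pct_differential))
  cat(sprintf("strand bias: %s\n",
              paste(sprintf("%s %d (%d%%)", x$strand_bias$class,
                            x$strand_bias$n, x$strand_bias$pct), collapse = ", ")))
  cat(sprintf("calibration: efficiency %.3f (R^2 %.4f)\n",
              x$calibration$efficiency, x$calibration$r_squared))
  t <- x$target_comparison
  cat(sprintf("targets: %d of %d mRNAs (mean %.2f sites), %s p = %.3g\n",
              t$n_targets, t$n_total, t$mean_sites, t$test, t$p_value))
  invisible(x)
}
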