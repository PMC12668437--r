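# small two-gene annotation used by the counting tests
tiny_annotation <- function() {
  data.frame(
    exon_id = c("gA:E1", "gA:E2", "gB:E1"),
    gene_id = c("gA", "gA", "gB"),
    chrom = c("c1", "c1", "c2"),
    start = c(100L, 300L, 50L), end = c(200L, 400L, 150L),
    strand = c("+", "+", "-"),
    curated = TRUE, cryptic = FALSE, stringsAsFactors = FALSE)
}

test_that("a read counts toward an exon only on the matching strand", {
  ann <- tiny_annotation()
  aln <- data.frame(read_id = "r1", chrom = "c1", start = 120L, end = 150L,
                    strand = "+", stringsAsFactors = FALSE)
  tab <- count_exon_alignments(aln, ann)
  expect_identical(tab$counts["gA:E1", 1L], 1L)
  aln$strand <- "-"
  tab <- count_exon_alignments(aln, ann)
  expect_identical(tab$counts["gA:E1", 1L], 0L)
})

test_that("counting matches the brute-force overlap oracle on 500 reads", {
  set.seed(42)
  ann <- tiny_annotation()
  aln <- data.frame(
    read_id = sprintf("r%03d", 1:500),
    chrom = sample(c("c1", "c2"), 500, replace = TRUE),
    start = sample(0:450, 500, replace = TRUE),
    strand = sample(c("+", "-"), 500, replace = TRUE),
    stringsAsFactors = FALSE)
  aln$end <- aln$start + sample(20:80, 500, replace = TRUE)
  tab <- count_exon_alignments(aln, ann)
  expect_identical(tab$counts[, 1L], oracle_count_exons(aln, ann))
  expect_identical(unname(tab$total_valid_reads), 500L)
})

test_that("SAM input (spliced and unspliced) counts like the data-frame path", {
  ann <- tiny_annotation()
  sam <- file.path(tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:1000",
    "@SQ\tSN:c2\tLN:1000",
    # r1: plus strand, 30M inside gA:E1 (pos 121 -> 0-based 120)
    paste("r1", 0, "c1", 121, 60, "30M", "*", 0, 0, strrep("A", 30),
          "*", sep = "\t"),
    # r2: spliced junction read: last 10 nt of E1, skips intron, 10 nt of E2
    paste("r2", 0, "c1", 191, 60, "10M100N10M", "*", 0, 0, strrep("A", 20),
          "*", sep = "\t"),
    # r3: minus strand (flag 16) inside gB:E1
    paste("r3", 16, "c2", 61, 60, "25M", "*", 0, 0, strrep("A", 25),
          "*", sep = "\t")),
    sam)
  tab <- count_exon_alignments(sam, ann)
  expect_identical(tab$counts["gA:E1", 1L], 2L)  # r1 + r2
  expect_identical(tab$counts["gA:E2", 1L], 1L)  # r2 via second segment
  expect_identical(tab$counts["gB:E1", 1L], 1L)
  expect_identical(unname(tab$total_valid_reads), 3L)
  # the junction segments end exactly at exon boundaries -> sharp
  expect_equal(boundary_sharpness(sam, ann[1, ]), 1.0)
})

test_that("mismatching chromosomes error and empty input warns", {
  ann <- tiny_annotation()
  bad <- data.frame(read_id = "r1", chrom = "chrX", start = 1L, end = 10L,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(count_exon_alignments(bad, ann), "chromosome")
  empty <- bad[0, ]
  expect_warning(tab <- count_exon_alignments(empty, ann), "no mapped reads")
  expect_true(all(tab$counts == 0))
})

test_that("the exclusive-exon rule is strict at more than 20 reads", {
  mk <- function(v) {
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "l1"))
    exon_count_table(m, total_valid_reads = c(l1 = max(sum(v), 1)))
  }
  ctrl <- mk(c(e1 = 0L, e2 = 0L, e3 = 5L))
  trt <- mk(c(e1 = 25L, e2 = 20L, e3 = 50L))
  res <- find_condition_exclusive_exons(ctrl, trt)
  expect_identical(res$exons, "e1")                 # 25 > 20 retained
  expect_false("e2" %in% res$exons)                 # exactly 20 rejected
  expect_identical(sort(res$exclusive_exons), c("e1", "e2"))
  expect_identical(unname(res$stages["n_condition_exclusive"]), 2L)
  empty <- structure(list(counts = matrix(numeric(0), 0L, 1L,
                                          dimnames = list(character(0), "l1")),
                          total_valid_reads = c(l1 = 1)),
                     class = "exon_count_table")
  expect_error(find_condition_exclusive_exons(empty, trt), "empty")
})

test_that("exclusive detection recovers exactly the planted exons", {
  cfg <- sim_config(n_genes = 100L, n_cryptic_targets = 15L,
                    n_cryptic_nontargets = 0L, depth = 1e6, seed = 11L)
  g <- make_genome_and_models(cfg)
  tabs <- simulate_exon_counts(g$models, g$truth, cfg)
  res <- find_condition_exclusive_exons(tabs$control, tabs$treated)
  expect_setequal(res$exons, g$truth$nmd_target_exon_ids)
})

test_that("novelty filter keeps intronic non-curated exons only", {
  g <- make_genome_and_models(sim_config(n_genes = 20L, n_cryptic_targets = 5L,
                                         n_cryptic_nontargets = 5L, seed = 8L))
  planted <- c(g$truth$nmd_target_exon_ids, g$truth$non_target_cryptic_ids)
  curated <- g$annotation$exon_id[g$annotation$curated][1:10]
  kept <- filter_novel_alternative(c(planted, curated), g$annotation)
  expect_setequal(kept, planted)
  expect_message(filter_novel_alternative("nonexistent:E1", g$annotation),
                 "not present")
})

test_that("PTC classification follows the 50-nt junction rule on hand-built genes", {
  # one plus-strand gene: exons [0,120) [300,420) [600,780); CDS starts at 30
  tx_e1 <- paste0(rand_dna(30), "ATG", random_codons(29))  # 120 nt, frame 0 at end
  tx_e2 <- random_codons(40)                               # 120 nt
  tx_e3 <- paste0(random_codons(20), "TAA", rand_dna(117)) # 180 nt, stop at 60
  intron1 <- rand_dna(180); intron2 <- rand_dna(180)
  chrom <- paste0(tx_e1, intron1, tx_e2, intron2, tx_e3)
  genome <- c(cT = chrom)
  model <- structure(list(
    gene_id = "gT", chrom = "cT", strand = "+",
    exons = data.frame(exon_id = c("gT:E1", "gT:E2", "gT:E3"),
                       start = c(0L, 300L, 600L), end = c(120L, 420L, 780L)),
    cds_start_tx = 30L, cds_end_tx = 120L + 120L + 60L + 3L,
    tx_len = 420L), class = "transcript_model")

  insert <- function(seq) {
    # splice a cryptic exon into intron 1 and return its record
    start <- 150L
    substr(genome[["cT"]], start + 1L, start + nchar(seq)) <<- seq
    data.frame(exon_id = "gT:C1", gene_id = "gT", chrom = "cT",
               start = start, end = start + nchar(seq), strand = "+",
               curated = FALSE, cryptic = TRUE, stringsAsFactors = FALSE)
  }
  # frame-preserving, stop-free cryptic (in frame 0 at the E1|E2 junction)
  cand <- insert(random_codons(20))
  expect_identical(classify_nmd_target(model, cand, genome), "non_target")
  expect_identical(oracle_classify_nmd(model, cand, genome), "non_target")
  # cryptic introducing an immediate in-frame TAA, far above the last junction
  cand <- insert(paste0(random_codons(2), "TAA", rand_dna(51)))
  expect_identical(classify_nmd_target(model, cand, genome), "target")
  expect_identical(oracle_classify_nmd(model, cand, genome), "target")
  # frameshifting cryptic with no stop at all anywhere downstream would be
  # indeterminate; here the natural-frame stop is lost but downstream stops
  # exist, so the call must match the oracle whatever it is
  cand <- insert(rand_dna(52))
  expect_identical(classify_nmd_target(model, cand, genome),
                   oracle_classify_nmd(model, cand, genome))
  # error contracts
  out <- cand; out$start <- 900L; out$end <- 950L
  expect_error(classify_nmd_target(model, out, genome), "outside")
  bad_model <- model; bad_model$cds_start_tx <- 31L
  expect_error(classify_nmd_target(bad_model, cand, genome), "ATG")
})

test_that("classifier equals the translation oracle over random genes", {
  cfg <- sim_config(n_genes = 60L, n_cryptic_targets = 30L,
                    n_cryptic_nontargets = 30L, seed = 13L)
  g <- make_genome_and_models(cfg)
  cryptics <- g$annotation[g$annotation$cryptic, ]
  for (k in seq_len(nrow(cryptics))) {
    row <- cryptics[k, ]
    expect_identical(classify_nmd_target(g$models[[row$gene_id]], row, g$genome),
                     oracle_classify_nmd(g$models[[row$gene_id]], row, g$genome))
  }
})

test_that("boundary sharpness is the contained-read fraction", {
  exon <- data.frame(exon_id = "e", chrom = "c1", start = 100L, end = 200L)
  contained <- data.frame(read_id = sprintf("c%d", 1:50), chrom = "c1",
                          start = 110L, end = 150L, strand = "+")
  expect_equal(boundary_sharpness(contained, exon), 1.0)
  straddle <- data.frame(read_id = sprintf("s%d", 1:5), chrom = "c1",
                         start = 90L, end = 120L, strand = "+")
  expect_equal(boundary_sharpness(rbind(contained[1:5, ], straddle), exon), 0.5)
  none <- data.frame(read_id = "x", chrom = "c1", start = 300L, end = 350L,
                     strand = "+")
  expect_warning(v <- boundary_sharpness(none, exon), "undefined")
  expect_true(is.na(v))
})

test_that("sharpness estimate falls in the binomial interval of the truth", {
  set.seed(17)
  n <- 500L
  sharp <- runif(n) < 0.8
  aln <- data.frame(read_id = sprintf("r%d", 1:n), chrom = "c1",
                    start = ifelse(sharp, 110L, 80L),
                    end = ifelse(sharp, 150L, 130L), strand = "+")
  exon <- data.frame(exon_id = "e", chrom = "c1", start = 100L, end = 200L)
  est <- boundary_sharpness(aln, exon)
  expect_lt(abs(est - 0.8), 1.96 * sqrt(0.8 * 0.2 / n) + 1e-9)
})

test_that("percent-of-adjacent reports per-library percent, mean and SD", {
  p <- percent_of_adjacent(6, 100)
  expect_equal(unname(p$per_library), 6.0)
  expect_equal(percent_of_adjacent(c(7, 7), c(7, 7))$mean, 100)
  expect_message(p <- percent_of_adjacent(c(5, 5, 5), c(100, 0, 100)),
                 "excluding")
  expect_identical(p$n_used, 2L)
  expect_error(percent_of_adjacent(c(1, 1), c(0, 0)), "undefined")

  set.seed(5)
  adj <- rpois(16L, 2000)
  cand <- rpois(16L, 0.05 * adj)
  est <- percent_of_adjacent(cand, adj)
  expect_lt(abs(est$mean - 5), 1)
})

test_that("screen pipeline recovers planted targets ranked above non-targets", {
  cfg <- sim_config(n_genes = 80L, n_cryptic_targets = 8L,
                    n_cryptic_nontargets = 8L, depth = 1e6, seed = 2L)
  g <- make_genome_and_models(cfg)
  tabs <- simulate_exon_counts(g$models, g$truth, cfg)
  res <- screen_pipeline(tabs$control, tabs$treated, g$annotation, g$models,
                         g$genome)
  cand <- res$candidates
  expect_setequal(cand$exon_id[cand$nmd_status == "target"],
                  g$truth$nmd_target_exon_ids)
  expect_setequal(cand$exon_id[1:8], g$truth$nmd_target_exon_ids)
  expect_true(all(cand$nmd_status[1:8] == "target"))
  expect_true(all(cand$nmd_status[9:16] == "non_target"))
  # funnel monotonicity along the candidate-set stages
  f <- res$funnel
  stages <- f[c("n_exons_detected_treated", "n_condition_exclusive",
                "n_above_min_reads", "n_novel_alternative",
                "n_final_candidates", "n_nmd_target")]
  expect_true(all(diff(stages) <= 0))
})

test_that("an all-zero treated table yields an empty candidate list", {
  ann <- tiny_annotation()
  z <- matrix(0L, nrow = 3, ncol = 1, dimnames = list(ann$exon_id, "l1"))
  ctrl <- exon_count_table(z + c(5L, 5L, 5L))
  trt <- exon_count_table(z, total_valid_reads = c(l1 = 1))
  res <- screen_pipeline(ctrl, trt, ann, list(), c(c1 = "", c2 = ""))
  expect_identical(nrow(res$candidates), 0L)
  expect_identical(unname(res$funnel["n_exons_detected_treated"]), 0L)
  expect_identical(unname(res$funnel["n_final_candidates"]), 0L)
})

test_that("counts and classifications are invariant under strand reversal", {
  cfg <- sim_config(n_genes = 15L, n_cryptic_targets = 3L,
                    n_cryptic_nontargets = 3L, seed = 21L)
  g <- make_genome_and_models(cfg)
  set.seed(22)
  idx <- sample(nrow(g$annotation), 200L, replace = TRUE)
  aln <- data.frame(read_id = sprintf("r%03d", 1:200),
                    chrom = g$annotation$chrom[idx],
                    start = pmax(g$annotation$start[idx] - sample(0:30, 200, TRUE), 0),
                    strand = sample(c("+", "-"), 200, TRUE),
                    stringsAsFactors = FALSE)
  aln$end <- aln$start + 30L
  flp <- flip_dataset(g$genome, g$annotation, g$models, aln)

  t1 <- count_exon_alignments(aln, g$annotation)
  t2 <- count_exon_alignments(flp$alignments, flp$annotation)
  expect_identical(t1$counts, t2$counts)

  cryptics <- which(g$annotation$cryptic)
  for (k in cryptics) {
    expect_identical(
      classify_nmd_target(g$models[[g$annotation$gene_id[k]]],
                          g$annotation[k, ], g$genome),
      classify_nmd_target(flp$models[[g$annotation$gene_id[k]]],
                          flp$annotation[k, ], flp$genome))
  }
})
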