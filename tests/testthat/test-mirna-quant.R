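# hand-built two-hairpin reference with a shared 24-nt substring
shared_reference <- function() {
  common <- strrep("ACGT", 6L)
  h1 <- paste0("GGGGG", common, rand_dna(40))
  h2 <- paste0("CCCCC", common, rand_dna(40))
  c(hp1 = h1, hp2 = h2)
}

test_that("hairpin counting requires a unique exact substring match", {
  set.seed(1)
  hp <- shared_reference()
  u1 <- substring(hp[["hp1"]], 1L, 24L)          # unique to hp1
  ambiguous <- strrep("ACGT", 6L)                # in both hairpins
  nohit <- strrep("T", 22L)
  tab <- count_hairpin_alignments(list(l1 = c(u1, u1, ambiguous, nohit)), hp)
  expect_identical(tab$counts["hp1", "l1"], 2L)
  expect_identical(tab$counts["hp2", "l1"], 0L)  # ambiguous discarded for both
  expect_identical(unname(tab$total_valid_reads), 4L)
  expect_error(count_hairpin_alignments(list(l1 = u1), character(0)), "empty")
})

test_that("reads outside the length filter are not valid reads", {
  hp <- c(hp1 = rand_dna(70))
  tab <- count_hairpin_alignments(list(l1 = c(rand_dna(10), rand_dna(40))), hp)
  expect_identical(unname(tab$total_valid_reads), 0L)
})

test_that("normalization follows the reads-per-kilobase-per-million form", {
  hp <- c(hp1 = rand_dna(100))
  tab <- mirna_count_table(matrix(c(10L, 0L), nrow = 1,
                                  dimnames = list("hp1", c("a", "b"))),
                           total_valid_reads = c(a = 1e6, b = 1e6))
  norm <- normalize_expression(tab, hp)
  expect_equal(norm["hp1", "a"], 100.0)
  expect_equal(norm["hp1", "b"], 0.0)
})

test_that("normalization is invariant to library-size rescaling", {
  set.seed(3)
  for (f in c(2, 10, 137.5)) {
    m <- matrix(rpois(40, 50), nrow = 10,
                dimnames = list(sprintf("h%d", 1:10), sprintf("l%d", 1:4)))
    hp <- stats::setNames(vapply(1:10, function(i) rand_dna(sample(60:90, 1)),
                                 character(1)), rownames(m))
    t1 <- mirna_count_table(m, total_valid_reads = colSums(m) + 1000)
    t2 <- mirna_count_table(m * f, total_valid_reads = (colSums(m) + 1000) * f)
    expect_equal(normalize_expression(t1, hp), normalize_expression(t2, hp),
                 tolerance = 1e-12)
  }
})

test_that("the 20% differential boundary is inclusive", {
  calls <- function(C, T) {
    call_differential(c(h = C), c(h = T))$calls$direction
  }
  expect_identical(calls(100, 119), "unchanged")
  expect_identical(calls(100, 120), "higher_in_treated")  # exactly 20%
  expect_identical(calls(100, 80), "higher_in_control")
  expect_identical(calls(100, 81), "unchanged")
  expect_identical(calls(0, 5), "treated_only")
  expect_identical(calls(5, 0), "control_only")
  # one-count epsilon below the boundary at C = 1e5 is never differential
  expect_identical(calls(1e5, 1.2e5), "higher_in_treated")
  expect_identical(calls(1e5, 1.2e5 - 1), "unchanged")
})

test_that("planted scaled hairpins are exactly the differential calls", {
  set.seed(9)
  vals <- stats::setNames(runif(100, 50, 500), sprintf("h%03d", 1:100))
  down <- sample(names(vals), 30L)
  treated <- vals
  treated[down] <- treated[down] * 0.5
  res <- call_differential(vals, treated)
  called <- res$calls$hairpin_id[res$calls$direction == "higher_in_control"]
  expect_setequal(called, down)
  expect_identical(res$summary$n_differential, 30L)
  expect_equal(res$summary$pct_differential, 30.0)
})

test_that("undetected hairpins are excluded from the summary denominator", {
  expect_message(res <- call_differential(c(a = 0, b = 100), c(a = 0, b = 130)),
                 "undetected")
  expect_identical(res$summary$n_detected, 1L)
})

test_that("arm counting is exact-match only and matches the substring oracle", {
  ref <- make_mirna_reference(8L, seed = 5L)
  m5 <- ref$mature$sequence[ref$mature$arm == "5p"][1]
  mut <- m5
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  arms <- count_mature_arms(c(m5, m5, mut), ref)
  expect_identical(arms$count_5p[1], 2L)
  expect_identical(sum(arms$count_3p), 0L)

  sim <- simulate_small_rna_reads(ref, 3000L, seed = 6L)
  arms <- count_mature_arms(sim$reads, ref)
  oracle <- oracle_count_arms(sim$reads, ref$mature)
  expect_identical(c(t(as.matrix(arms[, c("count_5p", "count_3p")]))),
                   oracle)
})

test_that("duplicated mature sequences are flagged unusable", {
  mat <- data.frame(hairpin_id = c("a", "a", "b", "b"),
                    arm = c("5p", "3p", "5p", "3p"),
                    start = 0L, end = 21L,
                    sequence = c("AAACCCGGGTTTAAACCCGGG", "ACGTACGTACGTACGTACGTA",
                                 "AAACCCGGGTTTAAACCCGGG", "TGCATGCATGCATGCATGCAT"),
                    stringsAsFactors = FALSE)
  expect_warning(arms <- count_mature_arms("AAACCCGGGTTTAAACCCGGG", mat),
                 "duplicated")
  expect_true(all(arms$count_5p == 0L))
})

test_that("extreme arm bias yields counts within the binomial interval", {
  ref <- make_mirna_reference(1L, seed = 8L)
  sim <- simulate_small_rna_reads(ref, 10000L, decoy_fraction = 0,
                                  arm_bias = 0.999, seed = 9L)
  arms <- count_mature_arms(sim$reads, ref)
  ci <- binom.test(arms$count_5p, 10000L, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.999 && 0.999 <= ci[2])
})

test_that("strand-bias classes and integer percentages match known category counts", {
  expect_identical(classify_strand_bias(
    data.frame(hairpin_id = "h", count_5p = 10L, count_3p = 0L)
  )$per_hairpin$class, "sole_5p")

  # published category sizes 134 sole-3p / 145 sole-5p / 179 both of 458
  arm <- data.frame(
    hairpin_id = sprintf("h%03d", 1:460),
    count_5p = c(rep(0L, 134), rep(5L, 145), rep(5L, 179), 0L, 0L),
    count_3p = c(rep(5L, 134), rep(0L, 145), rep(5L, 179), 0L, 0L))
  res <- classify_strand_bias(arm)
  expect_identical(res$n_detected, 458L)
  expect_identical(res$summary$pct[res$summary$class == "sole_3p"], 29)
  expect_identical(res$summary$pct[res$summary$class == "sole_5p"], 32)
  expect_identical(res$summary$pct[res$summary$class == "both"], 39)
  # (0,0) hairpins excluded without shrinking the class counts
  expect_identical(sum(res$summary$n), res$n_detected)
})

test_that("class conservation holds on random arm-count tables", {
  set.seed(11)
  for (i in 1:20) {
    arm <- data.frame(hairpin_id = sprintf("h%d", 1:50),
                      count_5p = rpois(50, 0.8), count_3p = rpois(50, 0.8))
    res <- classify_strand_bias(arm)
    expect_identical(sum(res$summary$n), res$n_detected)
    expect_identical(res$n_detected,
                     sum(arm$count_5p > 0 | arm$count_3p > 0))
  }
})

test_that("arm ratio handles sole-arm and degenerate cases", {
  r <- arm_ratio(8058L, 1L)
  expect_equal(r$ratio, 8058)
  expect_false(r$sole_arm)
  expect_equal(arm_ratio(5, 5)$ratio, 1.0)
  sole <- arm_ratio(7L, 0L)
  expect_identical(sole$ratio, Inf)
  expect_true(sole$sole_arm)
  expect_error(arm_ratio(0, 0), "undefined")
})

test_that("family aggregation reports member fold changes per timepoint", {
  fam <- c(h1 = "let7", h2 = "let7")
  base <- c(h1 = 100, h2 = 200, h3 = 50)
  res <- family_aggregate(
    list(`1h` = list(control = base, treated = base * c(0.5, 0.5, 1)),
         `6h` = list(control = base, treated = base)),
    fam)
  expect_identical(nrow(res), 4L)
  expect_equal(res$fold_change[res$timepoint == "1h"], c(0.5, 0.5))
  expect_equal(res$fold_change[res$timepoint == "6h"], c(1.0, 1.0))
  # single-member family behaves like a per-hairpin fold change
  one <- family_aggregate(list(`1h` = list(control = base, treated = base * 2)),
                          c(h3 = "solo"))
  expect_equal(one$fold_change, 2.0)
  # zero control members are excluded with a message
  expect_message(family_aggregate(
    list(`1h` = list(control = c(h1 = 0, h2 = 1), treated = c(h1 = 1, h2 = 1))),
    fam), "zero control")
})
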