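#' Hairpin count table
#' @param counts integer matrix, hairpins in rows, libraries in columns.
#' @param total_valid_reads named per-library totals; defaults to column sums.
#' @return object of class `mirna_count_table`.
#' @export
mirna_count_table <- function(counts, total_valid_reads = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 total_valid_reads = total_valid_reads %||% colSums(counts)),
            class = "mirna_count_table")
}

#' Count small-RNA reads against hairpin (pre-miRNA) sequences
#'
#' A read counts toward a hairpin when it is an exact substring of exactly one
#' hairpin in the reference; reads matching two or more hairpins are discarded
#' as non-unique, and reads matching none are ignored. The total valid reads
#' per library is the number of input reads passing the length filter.
#'
#' @param read_sets named list of per-library read vectors (character), or a
#'   single character vector (treated as one library).
#' @param hairpins named character vector of hairpin sequences, or a
#'   `mirna_reference`.
#' @param min_len,max_len read length filter (nt) defining "valid" reads.
#' @return a `mirna_count_table`: list with `counts` (hairpin x library
#'   matrix) and `total_valid_reads`.
#' @export
count_hairpin_alignments <- function(read_sets, hairpins,
                                     min_len = 18L, max_len = 26L) {
  if (inherits(hairpins, "mirna_reference")) hairpins <- hairpins$hairpins
  if (length(hairpins) == 0L) stop("empty hairpin reference")
  if (!is.list(read_sets)) read_sets <- list(lib1 = read_sets)
  hp_ids <- names(hairpins)
  counts <- matrix(0L, nrow = length(hairpins), ncol = length(read_sets),
                   dimnames = list(hp_ids, names(read_sets)))
  tvr <- stats::setNames(integer(length(read_sets)), names(read_sets))
  for (l in seq_along(read_sets)) {
    reads <- as.character(read_sets[[l]])
    reads <- reads[nchar(reads) >= min_len & nchar(reads) <= max_len]
    tvr[l] <- length(reads)
    if (!length(reads)) next
    tab <- table(reads)
    for (u in names(tab)) {
      hit <- which(vapply(hairpins, grepl, logical(1L), pattern = u, fixed = TRUE))
      if (length(hit) == 1L) counts[hit, l] <- counts[hit, l] + tab[[u]]
    }
  }
  structure(list(counts = counts, total_valid_reads = tvr),
            class = "mirna_count_table")
}

#' Normalize hairpin counts to library size and hairpin length
#'
#' Reads-per-kilobase-per-million convention:
#' `value = count * 1e9 / (total_valid_reads * hairpin_length_nt)`.
#'
#' @param table a `mirna_count_table`.
#' @param hairpins named character vector of hairpin sequences (for lengths),
#'   or a `mirna_reference`.
#' @return numeric matrix of normalized expression values.
#' @export
normalize_expression <- function(table, hairpins) {
  if (inherits(hairpins, "mirna_reference")) hairpins <- hairpins$hairpins
  stopifnot(inherits(table, "mirna_count_table"))
  len <- nchar(hairpins[rownames(table$counts)])
  if (any(is.na(len)) || any(len == 0)) {
    stop("every counted hairpin needs a sequence of non-zero length")
  }
  if (any(table$total_valid_reads <= 0)) {
    stop("total_valid_reads must be > 0 to normalize")
  }
  sweep(table$counts * 1e9 / len, 2L, table$total_valid_reads, "/")
}

#' Call differentially expressed pre-miRNAs by the 20 percent rule
#'
#' With control value C and treated value T: `higher_in_treated` when
#' (T - C)/C >= threshold, `higher_in_control` when (C - T)/C >= threshold,
#' otherwise `unchanged`; `treated_only` when C = 0 < T and `control_only`
#' when T = 0 < C. Hairpins undetected in both conditions are excluded from
#' the denominator of the summary percentage.
#'
#' @param control,treated named numeric vectors of (normalized) expression
#'   over the same hairpins.
#' @param threshold relative-change threshold, default 0.20 ("at least 20%").
#' @return list with `calls` (data frame hairpin_id, control, treated,
#'   direction) and `summary` (n_detected, n_differential, pct_differential,
#'   n_higher_in_control, n_higher_in_treated).
#' @export
call_differential <- function(control, treated, threshold = 0.20) {
  ids <- union(names(control), names(treated))
  if (is.null(ids)) stop("control and treated values must be named by hairpin")
  C <- stats::setNames(numeric(length(ids)), ids)
  C[names(control)] <- control
  T_ <- stats::setNames(numeric(length(ids)), ids)
  T_[names(treated)] <- treated

  dir <- rep(NA_character_, length(ids))
  detected <- C > 0 | T_ > 0
  if (any(!detected)) {
    message(sum(!detected), " hairpin(s) undetected in both conditions excluded")
  }
  dir[C == 0 & T_ > 0] <- "treated_only"
  dir[T_ == 0 & C > 0] <- "control_only"
  open <- detected & C > 0 & T_ > 0
  rel_up <- (T_ - C) / C
  rel_dn <- (C - T_) / C
  dir[open & rel_up >= threshold] <- "higher_in_treated"
  dir[open & rel_dn >= threshold] <- "higher_in_control"
  dir[open & is.na(dir)] <- "unchanged"

  calls <- data.frame(hairpin_id = ids, control = unname(C), treated = unname(T_),
                      direction = dir, stringsAsFactors = FALSE)
  diffd <- dir %in% c("higher_in_treated", "higher_in_control",
                      "treated_only", "control_only")
  n_det <- sum(detected)
  list(calls = calls,
       summary = list(n_detected = n_det,
                      n_differential = sum(diffd),
                      pct_differential = if (n_det) round_half_up(
                        100 * sum(diffd) / n_det, 1) else NA_real_,
                      n_higher_in_control = sum(dir %in% c("higher_in_control",
                                                           "control_only")),
                      n_higher_in_treated = sum(dir %in% c("higher_in_treated",
                                                           "treated_only"))))
}

#' Count unique exact matches to mature 5p/3p arm sequences
#'
#' A read counts toward an arm when it is byte-identical to that arm's mature
#' sequence and that sequence occurs exactly once among all mature sequences
#' of the reference; duplicated mature sequences are flagged unusable and
#' their arms excluded with a warning.
#'
#' @param reads character vector of reads.
#' @param reference a `mirna_reference` (or its `mature` data frame).
#' @return data frame (hairpin_id, count_5p, count_3p).
#' @export
count_mature_arms <- function(reads, reference) {
  mat <- if (inherits(reference, "mirna_reference")) reference$mature else reference
  dup <- mat$sequence %in% mat$sequence[duplicated(mat$sequence)]
  if (any(dup)) {
    warning("excluding ", sum(dup), " arm(s) with duplicated mature sequences")
    mat <- mat[!dup, , drop = FALSE]
  }
  tab <- table(reads)
  hit <- match(mat$sequence, names(tab))
  n <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  hp <- unique(mat$hairpin_id)
  out <- data.frame(hairpin_id = hp, count_5p = 0L, count_3p = 0L,
                    stringsAsFactors = FALSE)
  for (a in c("5p", "3p")) {
    col <- paste0("count_", a)
    rows <- mat$arm == a
    out[[col]][match(mat$hairpin_id[rows], hp)] <- n[rows]
  }
  out
}

#' Classify hairpins by 5p/3p strand bias
#'
#' `sole_5p` when only the 5p arm has unique exact matches, `sole_3p` when
#' only the 3p arm does, `both` when both do; hairpins with no matches on
#' either arm are excluded from the denominator. Category percentages are
#' reported to the nearest integer over detected hairpins.
#'
#' @param arm_counts data frame from [count_mature_arms()].
#' @return list with `per_hairpin` (arm_counts plus `class` column),
#'   `summary` (data frame class, n, pct), `n_detected`.
#' @export
classify_strand_bias <- function(arm_counts) {
  cls <- rep(NA_character_, nrow(arm_counts))
  cls[arm_counts$count_5p > 0 & arm_counts$count_3p == 0] <- "sole_5p"
  cls[arm_counts$count_5p == 0 & arm_counts$count_3p > 0] <- "sole_3p"
  cls[arm_counts$count_5p > 0 & arm_counts$count_3p > 0] <- "both"
  per <- cbind(arm_counts, class = cls, stringsAsFactors = FALSE)
  det <- !is.na(cls)
  n_det <- sum(det)
  levels <- c("sole_5p", "sole_3p", "both")
  nn <- vapply(levels, function(l) sum(cls[det] == l), integer(1L))
  summary <- data.frame(class = levels, n = nn,
                        pct = if (n_det) round_half_up(100 * nn / n_det, 0)
                              else rep(NA_real_, 3L),
                        stringsAsFactors = FALSE)
  list(per_hairpin = per, summary = summary, n_detected = n_det)
}

#' 5p:3p expression fold ratio for one hairpin
#'
#' @param count_5p,count_3p unique exact-match counts.
#' @return list with `ratio` (count_5p / count_3p; `Inf` when the 3p count is
#'   zero) and `sole_arm` flag; no pseudocount is applied.
#' @export
arm_ratio <- function(count_5p, count_3p) {
  if (count_5p == 0 && count_3p == 0) {
    stop("both arm counts are zero: ratio undefined")
  }
  if (count_3p == 0) return(list(ratio = Inf, sole_arm = TRUE))
  list(ratio = count_5p / count_3p, sole_arm = FALSE)
}

#' Per-family fold-change series across timepoints
#'
#' For each timepoint, per-hairpin fold change = treated / control on the
#' normalized scale; family members are reported individually (not averaged),
#' suiting a transient fall-and-recovery contrast across timepoints. Members
#' with a zero control value at a timepoint are excluded with a message.
#'
#' @param timepoints named list; each element a list with `control` and
#'   `treated` named numeric vectors of normalized expression.
#' @param family_map named character vector hairpin_id -> family label.
#' @return data frame (family, hairpin_id, timepoint, fold_change).
#' @export
family_aggregate <- function(timepoints, family_map) {
  out <- list()
  for (tp in names(timepoints)) {
    x <- timepoints[[tp]]
    ids <- intersect(names(x$control), names(x$treated))
    ids <- ids[ids %in% names(family_map)]
    zero <- ids[x$control[ids] == 0]
    if (length(zero)) {
      message("timepoint ", tp, ": excluding ", length(zero),
              " member(s) with zero control value")
    }
    ids <- setdiff(ids, zero)
    if (!length(ids)) next
    out[[tp]] <- data.frame(family = unname(family_map[ids]), hairpin_id = ids,
                            timepoint = tp,
                            fold_change = unname(x$treated[ids] / x$control[ids]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
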