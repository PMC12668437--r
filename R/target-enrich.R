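#' Categorize mRNAs by miRNA-family target sites
#'
#' An mRNA is a target when it carries at least one site (8mer, 7mer-m8 or
#' 7mer-1A) for the family in the site table; all other mRNAs in the
#' fold-change table are non-targets. mRNAs present in the site table but
#' absent from the fold-change table are ignored with a message.
#'
#' @param fold_changes data frame with columns `mrna_id` and `fold_change`
#'   (and optionally `log2_fc`).
#' @param sites target-site table (mrna_id, family, site_type, n_sites).
#' @param family family label to select from the site table.
#' @return list with `targets` and `non_targets` (subsets of `fold_changes`)
#'   and `site_stats` (n_targets, n_total, min/max/mean sites per target).
#' @export
categorize_mrnas <- function(fold_changes, sites, family) {
  fam <- sites[sites$family == family, , drop = FALSE]
  bad <- c("8mer", "7mer-m8", "7mer-1A")
  if (nrow(fam) && !all(fam$site_type %in% bad)) {
    stop("site_type must be one of: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(unique(fam$mrna_id), fold_changes$mrna_id)
  if (length(missing)) {
    message("ignoring ", length(missing),
            " site-table mRNA(s) absent from the fold-change table")
  }
  per_mrna <- tapply(fam$n_sites, fam$mrna_id, sum)
  target_ids <- names(per_mrna)[per_mrna >= 1]
  is_target <- fold_changes$mrna_id %in% target_ids
  n_sites <- per_mrna[fold_changes$mrna_id[is_target]]
  list(targets = fold_changes[is_target, , drop = FALSE],
       non_targets = fold_changes[!is_target, , drop = FALSE],
       site_stats = list(n_targets = sum(is_target),
                         n_total = nrow(fold_changes),
                         min_sites = if (any(is_target)) min(n_sites) else NA,
                         max_sites = if (any(is_target)) max(n_sites) else NA,
                         mean_sites = if (any(is_target)) mean(n_sites) else NA))
}

#' Compare fold-change distributions of targets versus non-targets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the fold changes of the
#' two groups; being a rank test, it is unaffected by whether values are on
#' the ratio or log scale.
#'
#' @param targets_fc,non_targets_fc numeric fold-change vectors (non-empty).
#' @return list of class `group_comparison`: test, statistic (U), p_value,
#'   n (group sizes), medians.
#' @export
compare_fold_changes <- function(targets_fc, non_targets_fc) {
  if (!length(targets_fc) || !length(non_targets_fc)) {
    stop("both groups must be non-empty")
  }
  if (length(unique(c(targets_fc, non_targets_fc))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(structure(list(test = "Mann-Whitney", statistic = NA_real_,
                          p_value = 1,
                          n = c(length(targets_fc), length(non_targets_fc)),
                          medians = c(targets = median(targets_fc),
                                      non_targets = median(non_targets_fc))),
                     class = "group_comparison"))
  }
  w <- suppressWarnings(wilcox.test(targets_fc, non_targets_fc,
                                    alternative = "two.sided"))
  structure(list(test = "Mann-Whitney", statistic = unname(w$statistic),
                 p_value = w$p.value,
                 n = c(length(targets_fc), length(non_targets_fc)),
                 medians = c(targets = median(targets_fc),
                             non_targets = median(non_targets_fc))),
            class = "group_comparison")
}

# Dunn's z statistics on mean ranks after a Kruskal-Wallis omnibus test,
# with the usual tie correction on the pooled ranks.
dunn_kruskal <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  mr <- tapply(r, g, mean)
  nn <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- apply(pairs, 2L, function(p) {
    (mr[p[1L]] - mr[p[2L]]) / sqrt(v * (1 / nn[p[1L]] + 1 / nn[p[2L]]))
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = as.numeric(z),
             p_value = 2 * pnorm(-abs(as.numeric(z))))
}

# Dunn-style pairwise z on within-block rank sums after Friedman's test.
dunn_friedman <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  R <- colSums(t(apply(mat, 1L, rank)))
  se <- sqrt(n * k * (k + 1) / 6)
  pairs <- utils::combn(seq_len(k), 2L)
  z <- apply(pairs, 2L, function(p) (R[p[1L]] - R[p[2L]]) / se)
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = as.numeric(z),
             p_value = 2 * pnorm(-abs(as.numeric(z))))
}

#' Nonparametric multi-group comparison with Dunn's post-hoc tests
#'
#' Unpaired data: Kruskal-Wallis omnibus test followed by Dunn's pairwise
#' mean-rank z tests (tie-corrected). Paired data (equal-length groups with
#' matched ordering, e.g. the same hairpins across timepoints): Friedman
#' omnibus test followed by Dunn-style pairwise tests on within-block rank
#' sums. Pairwise tests are two-sided with Holm adjustment by default.
#'
#' @param groups named list of >= 3 numeric vectors.
#' @param paired whether observations are matched across groups.
#' @param p_adjust multiplicity adjustment for the pairwise p-values
#'   (`"holm"`, `"bonferroni"` or `"none"`).
#' @return list of class `multi_group_result`: `omnibus` (test, statistic,
#'   p_value) and `pairwise` (data frame with group labels, z, p_value,
#'   p_adjusted).
#' @export
multi_group_tests <- function(groups, paired = FALSE,
                              p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) == 2L) {
    stop("two groups supplied: use compare_fold_changes() for a two-group test")
  }
  if (length(groups) < 3L) stop("need >= 3 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (paired) {
    if (length(unique(lengths(groups))) != 1L) {
      stop("paired comparison requires equal group sizes with matched ordering")
    }
    mat <- do.call(cbind, groups)
    om <- friedman.test(mat)
    pw <- dunn_friedman(mat)
    omnibus <- list(test = "Friedman", statistic = unname(om$statistic),
                    p_value = om$p.value)
  } else {
    om <- kruskal.test(groups)
    pw <- dunn_kruskal(groups)
    omnibus <- list(test = "Kruskal-Wallis", statistic = unname(om$statistic),
                    p_value = om$p.value)
  }
  pw$group1 <- names(groups)[pw$group1]
  pw$group2 <- names(groups)[pw$group2]
  pw$p_adjusted <- p.adjust(pw$p_value, method = p_adjust)
  structure(list(omnibus = omnibus, pairwise = pw),
            class = "multi_group_result")
}
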