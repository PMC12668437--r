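#' Thresholds for the exon screening funnel
#'
#' @param min_exclusive_reads treated-library read total a condition-exclusive
#'   exon must strictly exceed (default 20, i.e. "more than 20 reads").
#' @param ptc_min_distance_nt minimum distance, in nucleotides, from a
#'   premature stop codon to the last exon-exon junction for the transcript to
#'   be called an NMD target; must lie in 50..55.
#' @param sharpness_min minimum boundary-sharpness fraction for a candidate to
#'   survive the final stage (only applied when read-level alignments are
#'   available).
#' @param max_control_reads maximum total control reads for an exon to still
#'   count as "observed only in treated" (default 0: strictly absent).
#' @param min_reads_scope apply the `min_exclusive_reads` rule to the summed
#'   treated count (`"summed"`, default) or to every library (`"per_library"`).
#' @return object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_exclusive_reads = 20L,
                              ptc_min_distance_nt = 50L,
                              sharpness_min = 0.9,
                              max_control_reads = 0L,
                              min_reads_scope = c("summed", "per_library")) {
  if (min_exclusive_reads < 0) stop("min_exclusive_reads must be >= 0")
  if (ptc_min_distance_nt < 50 || ptc_min_distance_nt > 55) {
    stop("ptc_min_distance_nt must lie in 50..55")
  }
  if (sharpness_min < 0 || sharpness_min > 1) stop("sharpness_min must lie in [0, 1]")
  structure(list(min_exclusive_reads = min_exclusive_reads,
                 ptc_min_distance_nt = ptc_min_distance_nt,
                 sharpness_min = sharpness_min,
                 max_control_reads = max_control_reads,
                 min_reads_scope = match.arg(min_reads_scope)),
            class = "screen_thresholds")
}

# reference-consuming CIGAR segments, split at N (skipped intron) ops;
# returns 0-based half-open segments relative to the chromosome
cigar_segments <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  segs <- list()
  cur_start <- pos - 1L
  cur <- cur_start
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "D", "=", "X")) {
      cur <- cur + len[k]
    } else if (op[k] == "N") {
      if (cur > cur_start) segs[[length(segs) + 1L]] <- c(cur_start, cur)
      cur_start <- cur + len[k]
      cur <- cur_start
    }
  }
  if (cur > cur_start) segs[[length(segs) + 1L]] <- c(cur_start, cur)
  segs
}

#' Read alignments into a segment data frame
#'
#' Accepts a 6-column BED file (0-based half-open, as BED is defined), a
#' BAM/SAM file (read via Rsamtools; spliced reads are split into exonic
#' segments at N CIGAR operations) or a data frame already in segment form.
#'
#' @param x path or data frame with columns read_id, chrom, start, end, strand.
#' @return data frame of aligned segments (0-based half-open); one read may
#'   span several rows.
#' @export
read_alignments <- function(x) {
  if (is.data.frame(x)) {
    need <- c("read_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(x))) {
      stop("alignment data frame needs columns: ", paste(need, collapse = ", "))
    }
    return(x[, need])
  }
  ext <- tolower(tools::file_ext(x))
  if (ext == "bed") {
    b <- read.table(x, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(b) < 6L) stop("BED input must have 6 columns (strand required)")
    return(data.frame(read_id = as.character(b[[4L]]), chrom = as.character(b[[1L]]),
                      start = b[[2L]], end = b[[3L]], strand = as.character(b[[6L]]),
                      stringsAsFactors = FALSE))
  }
  if (ext == "sam") {
    x <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE, indexDestination = TRUE)
    ext <- "bam"
  }
  if (ext == "bam") {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(x, param = p)[[1L]]
    if (length(b$qname) == 0L) return(data.frame(read_id = character(),
                                                 chrom = character(),
                                                 start = integer(), end = integer(),
                                                 strand = character()))
    segs <- mapply(cigar_segments, b$pos, b$cigar, SIMPLIFY = FALSE)
    n_seg <- lengths(segs)
    flat <- do.call(rbind, unlist(segs, recursive = FALSE))
    return(data.frame(read_id = rep(b$qname, n_seg),
                      chrom = rep(as.character(b$rname), n_seg),
                      start = flat[, 1L], end = flat[, 2L],
                      strand = rep(as.character(b$strand), n_seg),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported alignment input: ", x)
}

#' Count strand-matched read alignments per exon
#'
#' A read increments an exon when any of its aligned segments overlaps the
#' exon interval by at least 1 nt and the read strand equals the gene strand;
#' a read is counted at most once per exon, and a read overlapping two
#' adjacent exons increments both. The total valid reads of the library is the
#' number of distinct aligned reads.
#'
#' @param alignments anything accepted by [read_alignments()].
#' @param annotation exon annotation data frame (0-based half-open) as emitted
#'   by [make_genome_and_models()] or read with [read_annotation_gff3()].
#' @param library_id column name for the resulting single-library table.
#' @return an [exon_count_table()] with one library.
#' @export
count_exon_alignments <- function(alignments, annotation, library_id = "lib1") {
  aln <- read_alignments(alignments)
  if (nrow(aln) == 0L) {
    warning("no mapped reads in input; returning empty count table")
    m <- matrix(0L, nrow = nrow(annotation), ncol = 1L,
                dimnames = list(annotation$exon_id, library_id))
    return(exon_count_table(m, total_valid_reads = stats::setNames(0L, library_id)))
  }
  bad <- setdiff(unique(aln$chrom), unique(annotation$chrom))
  if (length(bad)) {
    stop("alignment chromosomes absent from annotation: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  reads <- GenomicRanges::GRanges(aln$chrom,
                                  IRanges::IRanges(aln$start + 1L, aln$end),
                                  strand = aln$strand)
  exons <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start + 1L,
                                                   annotation$end),
                                  strand = annotation$strand)
  ov <- GenomicRanges::findOverlaps(reads, exons, minoverlap = 1L,
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keep <- aln$strand[qh] == annotation$strand[sh]
  pairs <- unique(data.frame(read = aln$read_id[qh][keep], exon = sh[keep]))
  cnt <- table(factor(pairs$exon, levels = seq_len(nrow(annotation))))
  m <- matrix(as.integer(cnt), ncol = 1L,
              dimnames = list(annotation$exon_id, library_id))
  exon_count_table(m, total_valid_reads = stats::setNames(
    length(unique(aln$read_id)), library_id))
}

#' Find exons observed only in the treated condition
#'
#' Returns exons with at most `max_control_reads` (default zero) reads across
#' every control library and a treated read total strictly greater than
#' `min_exclusive_reads`, together with the funnel stage counts.
#'
#' @param control,treated [exon_count_table()]s over a shared annotation.
#' @param thresholds a [screen_thresholds()].
#' @return list with `exons` (character vector of retained exon ids),
#'   `exclusive_exons` (before the read threshold) and `stages` (named counts).
#' @export
find_condition_exclusive_exons <- function(control, treated,
                                           thresholds = screen_thresholds()) {
  stopifnot(inherits(control, "exon_count_table"),
            inherits(treated, "exon_count_table"))
  if (nrow(control$counts) == 0L || nrow(treated$counts) == 0L ||
      ncol(control$counts) == 0L || ncol(treated$counts) == 0L) {
    stop("empty count table supplied")
  }
  ids <- union(rownames(control$counts), rownames(treated$counts))
  csum <- rowSums(control$counts)[ids]
  csum[is.na(csum)] <- 0
  tmat <- treated$counts[intersect(ids, rownames(treated$counts)), , drop = FALSE]
  tsum <- stats::setNames(numeric(length(ids)), ids)
  tsum[rownames(tmat)] <- rowSums(tmat)
  exclusive <- csum <= thresholds$max_control_reads & tsum > 0
  if (thresholds$min_reads_scope == "per_library") {
    tmin <- stats::setNames(numeric(length(ids)), ids)
    tmin[rownames(tmat)] <- apply(tmat, 1L, min)
    above <- exclusive & tmin > thresholds$min_exclusive_reads
  } else {
    above <- exclusive & tsum > thresholds$min_exclusive_reads
  }
  list(exons = ids[above],
       exclusive_exons = ids[exclusive],
       stages = c(n_exons_detected_control = sum(csum > 0),
                  n_exons_detected_treated = sum(tsum > 0),
                  n_condition_exclusive = sum(exclusive),
                  n_above_min_reads = sum(above)))
}

#' Keep only novel alternative exons
#'
#' Retains candidates absent from the curated transcript set that lie inside
#' an intron of a curated transcript of the same gene (no overlap with any
#' curated exon). Candidates without a host gene in the annotation are
#' excluded with a message.
#'
#' @param exon_ids candidate exon ids.
#' @param annotation exon annotation data frame with `curated` flags.
#' @return character vector of surviving exon ids.
#' @export
filter_novel_alternative <- function(exon_ids, annotation) {
  keep <- character(0)
  rows <- annotation[match(exon_ids, annotation$exon_id), , drop = FALSE]
  for (k in seq_along(exon_ids)) {
    r <- rows[k, ]
    if (is.na(r$exon_id)) {
      message("excluding ", exon_ids[k], ": not present in annotation")
      next
    }
    if (isTRUE(r$curated)) next
    cur <- annotation[annotation$gene_id == r$gene_id & annotation$curated, ,
                      drop = FALSE]
    if (nrow(cur) == 0L) {
      message("excluding ", r$exon_id, ": no curated host transcript")
      next
    }
    inside <- r$start >= min(cur$start) && r$end <= max(cur$end)
    overlaps <- any(r$start < cur$end & r$end > cur$start)
    if (inside && !overlaps) keep <- c(keep, r$exon_id)
  }
  keep
}

# Transcript-sense sequence of an ordered (ascending-coordinate) exon chain.
chain_sequence <- function(chrom_seq, starts, ends, strand) {
  s <- paste(substring(chrom_seq, starts + 1L, ends), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Classify a candidate exon as an NMD target by the 50-nt PTC rule
#'
#' Builds the inclusion transcript (candidate spliced between two constitutive
#' exons), translates in 3-nt steps from the annotated CDS start and locates
#' the first stop codon. The transcript is an NMD target when that stop is
#' premature (upstream of the natural stop) and lies at least
#' `ptc_min_distance_nt` nucleotides upstream of the last exon-exon junction,
#' where a retained exon junction complex would mark the mRNA for decay; a
#' first stop that is the natural stop, or that falls within the last-exon
#' window, yields `non_target`; absence of any stop yields `indeterminate`.
#'
#' @param model a `transcript_model` (constitutive exon chain plus CDS start
#'   in transcript coordinates).
#' @param candidate one-row exon record (annotation row) for the cryptic exon.
#' @param genome named character vector of chromosome sequences.
#' @param thresholds a [screen_thresholds()].
#' @return one of `"target"`, `"non_target"`, `"indeterminate"`.
#' @export
classify_nmd_target <- function(model, candidate, genome,
                                thresholds = screen_thresholds()) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exons
  if (candidate$chrom != model$chrom ||
      candidate$start < min(ex$start) || candidate$end > max(ex$end)) {
    stop("candidate exon lies outside the transcript span of ", model$gene_id)
  }
  if (any(candidate$start < ex$end & candidate$end > ex$start)) {
    stop("candidate exon overlaps a constitutive exon of ", model$gene_id)
  }
  chrom_seq <- genome[[model$chrom]]

  starts <- c(ex$start, candidate$start)
  ends <- c(ex$end, candidate$end)
  o <- order(starts)
  tx <- chain_sequence(chrom_seq, starts[o], ends[o], model$strand)
  lens_asc <- (ends - starts)[o]
  lens_tx <- if (model$strand == "-") rev(lens_asc) else lens_asc
  incl_len <- sum(lens_tx)
  cryptic_len <- candidate$end - candidate$start

  cds_start <- model$cds_start_tx
  if (substring(tx, cds_start + 1L, cds_start + 3L) != "ATG") {
    stop("CDS start of ", model$gene_id, " is not an ATG start codon")
  }
  codon_starts <- seq(cds_start, incl_len - 3L, by = 3L)
  codons <- substring(tx, codon_starts + 1L, codon_starts + 3L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) return("indeterminate")
  stop_end <- codon_starts[hit[1L]] + 3L

  last_junction <- incl_len - lens_tx[length(lens_tx)]
  natural_end <- model$cds_end_tx + cryptic_len
  if (stop_end == natural_end) return("non_target")
  if (stop_end < natural_end &&
      (last_junction - stop_end) >= thresholds$ptc_min_distance_nt) {
    return("target")
  }
  "non_target"
}

#' Fraction of reads with boundaries sharp at an exon
#'
#' A read is "sharp" when every one of its aligned segments that overlaps the
#' exon lies entirely within the exon interval (segments ending exactly at an
#' exon boundary - e.g. at a splice junction edge - therefore qualify); reads
#' whose segments straddle a boundary by one or more nucleotides are not.
#'
#' @param alignments anything accepted by [read_alignments()].
#' @param exon one-row exon record with chrom, start, end.
#' @return fraction in [0, 1], or NA (with a warning) when no read overlaps.
#' @export
boundary_sharpness <- function(alignments, exon) {
  aln <- read_alignments(alignments)
  ov <- aln$chrom == exon$chrom & aln$start < exon$end & aln$end > exon$start
  if (!any(ov)) {
    warning("no reads overlap exon ", exon$exon_id %||% "", "; sharpness undefined")
    return(NA_real_)
  }
  seg <- aln[ov, , drop = FALSE]
  contained <- seg$start >= exon$start & seg$end <= exon$end
  sharp_by_read <- tapply(contained, seg$read_id, all)
  sum(sharp_by_read) / length(sharp_by_read)
}

#' Candidate exon expression as percent of the adjacent exon
#'
#' @param candidate_counts,adjacent_counts per-library read counts (matched
#'   order).
#' @return list with `per_library` percentages, `mean`, `sd` (sample SD),
#'   `n_used`, and indices of libraries excluded for a zero adjacent count.
#' @export
percent_of_adjacent <- function(candidate_counts, adjacent_counts) {
  stopifnot(length(candidate_counts) == length(adjacent_counts))
  excl <- which(adjacent_counts == 0)
  if (length(excl) == length(adjacent_counts)) {
    stop("all adjacent-exon counts are zero: percent-of-adjacent undefined")
  }
  if (length(excl)) {
    message("excluding ", length(excl), " librar",
            if (length(excl) == 1L) "y" else "ies", " with zero adjacent count")
  }
  use <- setdiff(seq_along(adjacent_counts), excl)
  pct <- 100 * candidate_counts[use] / adjacent_counts[use]
  list(per_library = pct, mean = mean(pct),
       sd = if (length(pct) > 1L) sd(pct) else NA_real_,
       n_used = length(use), excluded_libraries = excl)
}

#' Staged screen for treatment-stabilized NMD-target exons
#'
#' Applies, in order: condition-exclusive detection with the read threshold,
#' the novel-alternative filter, PTC/NMD classification, and (when read-level
#' alignments are supplied) the boundary-sharpness filter. Survivors are
#' ranked by NMD status, then sharpness, then treated read total, with ties
#' broken by exon id. The funnel report records the candidate-set size after
#' each stage.
#'
#' @param control,treated [exon_count_table()]s.
#' @param annotation exon annotation data frame.
#' @param models named list of `transcript_model`s (by gene id).
#' @param genome named character vector of chromosome sequences.
#' @param thresholds a [screen_thresholds()].
#' @param alignments optional treated-condition read alignments for the
#'   sharpness stage; when absent, sharpness is reported as NA and the
#'   sharpness filter is skipped.
#' @return list of class `exon_screen_result` with `candidates` (ranked data
#'   frame) and `funnel` (named stage counts).
#' @export
screen_pipeline <- function(control, treated, annotation, models, genome,
                            thresholds = screen_thresholds(),
                            alignments = NULL) {
  excl <- find_condition_exclusive_exons(control, treated, thresholds)
  novel <- filter_novel_alternative(excl$exons, annotation)

  rows <- annotation[match(novel, annotation$exon_id), , drop = FALSE]
  n <- length(novel)
  status <- character(n)
  sharp <- rep(NA_real_, n)
  pct_mean <- rep(NA_real_, n)
  pct_sd <- rep(NA_real_, n)
  t_tot <- numeric(n)
  c_tot <- numeric(n)
  for (k in seq_len(n)) {
    r <- rows[k, ]
    m <- models[[r$gene_id]]
    status[k] <- if (is.null(m)) "indeterminate" else {
      classify_nmd_target(m, r, genome, thresholds)
    }
    if (!is.null(alignments)) {
      sharp[k] <- suppressWarnings(boundary_sharpness(alignments, r))
    }
    t_tot[k] <- sum(treated$counts[r$exon_id, ])
    c_tot[k] <- if (r$exon_id %in% rownames(control$counts)) {
      sum(control$counts[r$exon_id, ])
    } else 0
    cur <- annotation[annotation$gene_id == r$gene_id & annotation$curated, ,
                      drop = FALSE]
    cur <- cur[cur$exon_id %in% rownames(treated$counts), , drop = FALSE]
    if (nrow(cur)) {
      dist <- pmax(cur$start - r$end, r$start - cur$end, 0)
      adj <- cur$exon_id[which.min(dist)]
      pct <- tryCatch(percent_of_adjacent(treated$counts[r$exon_id, ],
                                          treated$counts[adj, ]),
                      error = function(e) NULL)
      if (!is.null(pct)) {
        pct_mean[k] <- pct$mean
        pct_sd[k] <- pct$sd
      }
    }
  }

  cand <- data.frame(exon_id = novel, gene_id = rows$gene_id,
                     chrom = rows$chrom, start = rows$start, end = rows$end,
                     strand = rows$strand, control_total = c_tot,
                     treated_total = t_tot, nmd_status = status,
                     sharpness = sharp, pct_adjacent_mean = pct_mean,
                     pct_adjacent_sd = pct_sd, stringsAsFactors = FALSE)
  if (!is.null(alignments) && nrow(cand)) {
    cand <- cand[!is.na(cand$sharpness) &
                   cand$sharpness >= thresholds$sharpness_min, , drop = FALSE]
  }
  if (nrow(cand)) {
    o <- order(-(cand$nmd_status == "target"),
               -ifelse(is.na(cand$sharpness), -Inf, cand$sharpness),
               -cand$treated_total, cand$exon_id)
    cand <- cand[o, , drop = FALSE]
    rownames(cand) <- NULL
  }

  funnel <- c(excl$stages,
              n_novel_alternative = length(novel),
              n_final_candidates = nrow(cand),
              n_nmd_target = sum(cand$nmd_status == "target"))
  structure(list(candidates = cand, funnel = funnel),
            class = "exon_screen_result")
}

#' @export
print.exon_screen_result <- function(x, ...) {
  cat("Exon screen funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-26s %d\n", nm, x$funnel[[nm]]))
  cat("\nTop candidates:\n")
  print(utils::head(x$candidates, 10L))
  invisible(x)
}
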