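# Independent oracles used to check the implementation by a different route.

# warm up Biostrings S4 dispatch so timing-sensitive tests are not dominated
# by one-time namespace loading
invisible(Biostrings::reverseComplement(Biostrings::DNAString("ACGT")))

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Brute-force translation oracle for the PTC rule: assemble the inclusion
# transcript, translate the CDS with Biostrings::translate, locate the first
# '*' in the protein and measure its distance to the last exon-exon junction.
oracle_classify_nmd <- function(model, candidate, genome, min_dist = 50) {
  ex <- model$exons
  starts <- c(ex$start, candidate$start)
  ends <- c(ex$end, candidate$end)
  o <- order(starts)
  tx <- paste(substring(genome[[model$chrom]], starts[o] + 1, ends[o]),
              collapse = "")
  if (model$strand == "-") tx <- revcomp_chr(tx)
  lens <- (ends - starts)[o]
  if (model$strand == "-") lens <- rev(lens)
  incl_len <- sum(lens)

  cds <- substring(tx, model$cds_start_tx + 1, incl_len)
  cds <- substring(cds, 1, 3 * (nchar(cds) %/% 3))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  stop_aa <- regexpr("*", aa, fixed = TRUE)[1]
  if (stop_aa < 0) return("indeterminate")
  stop_end <- model$cds_start_tx + 3 * stop_aa
  last_junction <- incl_len - lens[length(lens)]
  natural_end <- model$cds_end_tx + (candidate$end - candidate$start)
  if (stop_end == natural_end) return("non_target")
  if (stop_end < natural_end && (last_junction - stop_end) >= min_dist) {
    return("target")
  }
  "non_target"
}

# O(reads x exons) interval-overlap counting oracle (strand-matched, each
# read at most once per exon).
oracle_count_exons <- function(aln, annotation) {
  counts <- stats::setNames(integer(nrow(annotation)), annotation$exon_id)
  for (e in seq_len(nrow(annotation))) {
    seen <- character(0)
    for (r in seq_len(nrow(aln))) {
      if (aln$chrom[r] == annotation$chrom[e] &&
          aln$strand[r] == annotation$strand[e] &&
          aln$start[r] < annotation$end[e] &&
          aln$end[r] > annotation$start[e]) {
        seen <- union(seen, aln$read_id[r])
      }
    }
    counts[e] <- length(seen)
  }
  counts
}

# Brute-force substring scan: unique-exact-match arm counts.
oracle_count_arms <- function(reads, mature) {
  usable <- !(mature$sequence %in% mature$sequence[duplicated(mature$sequence)])
  vapply(seq_len(nrow(mature)), function(i) {
    if (!usable[i]) return(0L)
    sum(reads == mature$sequence[i])
  }, integer(1L))
}

# mirror every chromosome and flip all coordinates/strands; classifications
# and counts must be invariant under this transform
flip_dataset <- function(genome, annotation, models, alignments = NULL) {
  lens <- nchar(genome)
  flipped_genome <- vapply(genome, revcomp_chr, character(1))
  flip_df <- function(df) {
    L <- lens[df$chrom]
    new_start <- L - df$end
    df$end <- L - df$start
    df$start <- new_start
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  annotation <- flip_df(annotation)
  models <- lapply(models, function(m) {
    L <- lens[[m$chrom]]
    new_start <- L - m$exons$end
    m$exons$end <- L - m$exons$start
    m$exons$start <- new_start
    m$strand <- if (m$strand == "+") "-" else "+"
    m
  })
  if (!is.null(alignments)) alignments <- flip_df(alignments)
  list(genome = flipped_genome, annotation = annotation, models = models,
       alignments = alignments)
}
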