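#' Write the synthetic genome as FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# genomic CDS pieces of a transcript model, one row per exon overlapping the CDS
cds_genomic_pieces <- function(model) {
  ex <- model$exons
  lens <- ex$end - ex$start
  offs <- cumsum(c(0L, lens[-length(lens)]))
  out <- list()
  for (k in seq_len(nrow(ex))) {
    a <- max(model$cds_start_tx, offs[k])
    b <- min(model$cds_end_tx, offs[k] + lens[k])
    if (a >= b) next
    if (model$strand == "+") {
      gs <- ex$start[k] + (a - offs[k]); ge <- ex$start[k] + (b - offs[k])
    } else {
      gs <- ex$end[k] - (b - offs[k]); ge <- ex$end[k] - (a - offs[k])
    }
    # GFF3 phase: bases to skip from the piece's 5' end to a codon boundary
    phase <- (3L - ((a - model$cds_start_tx) %% 3L)) %% 3L
    out[[length(out) + 1L]] <- data.frame(gene_id = model$gene_id,
                                          chrom = model$chrom,
                                          start = gs, end = ge,
                                          strand = model$strand,
                                          phase = phase)
  }
  do.call(rbind, out)
}

#' Write annotation (and CDS features) as GFF3
#'
#' Exon features carry `curated=true|false` and `cryptic=true|false`
#' attributes; CDS features are derived from each gene model's CDS span.
#' Coordinates are converted from the package's internal 0-based half-open
#' convention to GFF3's 1-based inclusive one.
#'
#' @param annotation exon data frame from [make_genome_and_models()].
#' @param models named list of transcript models (for CDS rows); optional.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path, models = NULL) {
  ex <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end),
                               strand = annotation$strand)
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    type = "exon", ID = annotation$exon_id, gene_id = annotation$gene_id,
    curated = ifelse(annotation$curated, "true", "false"),
    cryptic = ifelse(annotation$cryptic, "true", "false"),
    phase = NA_integer_)
  feats <- ex
  if (!is.null(models)) {
    cds <- do.call(rbind, lapply(models, cds_genomic_pieces))
    cg <- GenomicRanges::GRanges(cds$chrom,
                                 IRanges::IRanges(cds$start + 1L, cds$end),
                                 strand = cds$strand)
    S4Vectors::mcols(cg) <- S4Vectors::DataFrame(
      type = "CDS", ID = sprintf("cds:%s:%d", cds$gene_id, seq_len(nrow(cds))),
      gene_id = cds$gene_id, curated = NA_character_, cryptic = NA_character_,
      phase = cds$phase)
    feats <- c(ex, cg)
  }
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into the package's exon table and gene models
#'
#' @param path GFF3 file as written by [write_annotation_gff3()] (exon
#'   features with `curated`/`cryptic` attributes, optional CDS features).
#' @return list with `annotation` (0-based half-open exon data frame) and
#'   `models` (named list of `transcript_model`s over curated exons; only
#'   genes with CDS features get a model).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_exon <- as.character(gr$type) == "exon"
  ex <- gr[is_exon]
  annotation <- data.frame(
    exon_id = ex$ID, gene_id = ex$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L, end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    curated = ex$curated == "true", cryptic = ex$cryptic == "true",
    stringsAsFactors = FALSE)

  cds <- gr[as.character(gr$type) == "CDS"]
  models <- list()
  for (g in unique(annotation$gene_id[annotation$curated])) {
    rows <- annotation[annotation$gene_id == g & annotation$curated, ,
                       drop = FALSE]
    strand <- rows$strand[1L]
    o <- order(rows$start, decreasing = (strand == "-"))
    rows <- rows[o, , drop = FALSE]
    gc <- cds[cds$gene_id == g]
    if (length(gc) == 0L) next
    lens <- rows$end - rows$start
    offs <- cumsum(c(0L, lens[-length(lens)]))
    tx_off <- function(pos) { # genomic -> transcript coordinate
      for (k in seq_len(nrow(rows))) {
        if (pos >= rows$start[k] && pos <= rows$end[k]) {
          return(if (strand == "+") offs[k] + (pos - rows$start[k])
                 else offs[k] + (rows$end[k] - pos))
        }
      }
      stop("CDS position outside exons of ", g)
    }
    cs <- GenomicRanges::start(gc) - 1L
    ce <- GenomicRanges::end(gc)
    bounds <- unlist(lapply(seq_along(gc), function(i) {
      sort(c(tx_off(cs[i]), tx_off(ce[i])))
    }))
    m <- list(gene_id = g, chrom = rows$chrom[1L], strand = strand,
              exons = data.frame(exon_id = rows$exon_id, start = rows$start,
                                 end = rows$end, stringsAsFactors = FALSE),
              cds_start_tx = min(bounds), cds_end_tx = max(bounds),
              tx_len = sum(lens))
    class(m) <- "transcript_model"
    models[[g]] <- m
  }
  list(annotation = annotation, models = models)
}

#' Write per-library exon count tables (tab-separated)
#'
#' One file per library with columns exon_id, chrom, start, end, strand,
#' count, and a header comment recording the tool version and the library's
#' total valid reads.
#'
#' @param table an [exon_count_table()].
#' @param annotation exon data frame supplying coordinates.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_exon_counts <- function(table, annotation, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- match(rownames(table$counts), annotation$exon_id)
  paths <- character(ncol(table$counts))
  for (l in seq_len(ncol(table$counts))) {
    lib <- colnames(table$counts)[l]
    paths[l] <- file.path(dir, sprintf("%s_%s.tsv", prefix, lib))
    con <- file(paths[l], "w")
    writeLines(sprintf("# ecstress %s library=%s total_valid_reads=%d",
                       as.character(utils::packageVersion("ecstress")), lib,
                       as.integer(table$total_valid_reads[l])), con)
    df <- data.frame(exon_id = rownames(table$counts),
                     chrom = annotation$chrom[idx], start = annotation$start[idx],
                     end = annotation$end[idx], strand = annotation$strand[idx],
                     count = table$counts[, l])
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read per-library exon count tables back into an [exon_count_table()]
#' @param paths files written by [write_exon_counts()].
#' @return an [exon_count_table()].
#' @export
read_exon_counts <- function(paths) {
  cols <- list()
  tvr <- integer(length(paths))
  libs <- character(length(paths))
  for (i in seq_along(paths)) {
    hdr <- readLines(paths[i], n = 1L)
    libs[i] <- sub(".*library=(\\S+).*", "\\1", hdr)
    tvr[i] <- as.integer(sub(".*total_valid_reads=(\\d+).*", "\\1", hdr))
    df <- read.table(paths[i], sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    cols[[i]] <- stats::setNames(df$count, df$exon_id)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- libs
  exon_count_table(m, total_valid_reads = stats::setNames(tvr, libs))
}

#' Write small-RNA reads as FASTQ
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_small_rna_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    strrep("I", n), character(1L)))
  Biostrings::writeXStringSet(Biostrings::QualityScaledDNAStringSet(x, q),
                              path, format = "fastq")
  invisible(path)
}

#' Read small-RNA reads from FASTA/FASTQ into a character vector
#' @param path reads file (.fasta/.fa or .fastq/.fq).
#' @return named character vector.
#' @export
read_small_rna <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Write / read a qPCR Ct plate as CSV
#' @param plate data frame as from [simulate_qpcr_plate()].
#' @param path CSV file.
#' @return the path (write) or the plate data frame (read).
#' @export
write_ct_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_plate
#' @export
read_ct_plate <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
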