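#' Extract junction, intron-coverage and exon-count evidence from alignments
#'
#' Reduces a spliced alignment file (SAM or BAM; junctions encoded as `N`
#' operations in the CIGAR) to the three evidence tables the event callers
#' consume: per-junction read support, per-intron coverage, and per-gene
#' exonic read counts.  Only primary alignments contribute; a read counts as
#' uniquely aligned when its mapping quality is positive, the convention
#' most spliced aligners use for unambiguous placements.
#'
#' @param alignment_path path to a SAM or BAM file.
#' @param annotation a `splice_annotation`.
#' @param species_id library label carried into the evidence tables.
#' @param min_gap smallest reference gap (bp) treated as a splice junction;
#'   shorter gaps are ignored as indel-like.
#' @return An object of class `splice_evidence`: list with `junctions`
#'   (`contig`, `intron_start`, `intron_end`, `support`, `min_overhang`,
#'   `distinct_positions`, `unique_support`), `intron_coverage` (`gene_id`,
#'   `intron_index`, `covered_bases`, `intron_reads`), `exon_counts`
#'   (`gene_id`, `exon_reads`) and `library` (`species_id`, `total_mapped`,
#'   `uniquely_mapped`).
#' @export
extract_evidence <- function(alignment_path, annotation, species_id,
                             min_gap = 20L) {
  if (!file.exists(alignment_path))
    stop("alignment file not found: ", alignment_path)
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(alignment_path, destination = dest,
                       overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("failed to parse alignment records in ",
                               alignment_path, ": ", conditionMessage(e)))
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  flag <- S4Vectors::mcols(aln)$flag
  primary <- bitwAnd(flag, 256L) == 0L
  aln <- aln[primary]
  if (length(aln) == 0L)
    warning("no mapped primary alignments in ", alignment_path)
  mapq <- S4Vectors::mcols(aln)$mapq
  mapq[is.na(mapq)] <- 0L
  is_unique <- mapq > 0L

  blocks <- GenomicAlignments::grglist(aln)  # aligned blocks split on N gaps

  junctions <- .junction_table(blocks, is_unique, min_gap)
  intron_cov <- .intron_coverage_table(blocks, annotation)
  exon_counts <- .exon_count_table(blocks, is_unique, annotation)

  structure(list(
    junctions = junctions,
    intron_coverage = intron_cov,
    exon_counts = exon_counts,
    library = data.frame(species_id = species_id,
                         total_mapped = length(aln),
                         uniquely_mapped = sum(is_unique),
                         stringsAsFactors = FALSE)),
    class = "splice_evidence")
}

#' @export
print.splice_evidence <- function(x, ...) {
  cat("splice_evidence [", x$library$species_id, "]: ",
      nrow(x$junctions), " junctions, ",
      sum(x$intron_coverage$intron_reads > 0L), " covered introns, ",
      x$library$total_mapped, " mapped reads (",
      x$library$uniquely_mapped, " unique)\n", sep = "")
  invisible(x)
}

.empty_junctions <- function() {
  data.frame(contig = character(), intron_start = integer(),
             intron_end = integer(), support = integer(),
             min_overhang = integer(), distinct_positions = integer(),
             unique_support = integer(), stringsAsFactors = FALSE)
}

.junction_table <- function(blocks, is_unique, min_gap) {
  n_blocks <- S4Vectors::elementNROWS(blocks)
  spliced <- which(n_blocks >= 2L)
  if (length(spliced) == 0L) return(.empty_junctions())
  recs <- lapply(spliced, function(i) {
    b <- blocks[[i]]
    s <- GenomicRanges::start(b); e <- GenomicRanges::end(b)
    k <- length(s)
    gap_s <- e[-k] + 1L
    gap_e <- s[-1L] - 1L
    keep <- (gap_e - gap_s + 1L) >= min_gap
    if (!any(keep)) return(NULL)
    w <- e - s + 1L
    data.frame(contig = as.character(GenomicRanges::seqnames(b))[1L],
               intron_start = gap_s[keep], intron_end = gap_e[keep],
               overhang = pmin(w[-k], w[-1L])[keep],
               read_start = s[1L], unique = is_unique[i],
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) return(.empty_junctions())
  key <- paste(recs$contig, recs$intron_start, recs$intron_end, sep = ":")
  agg <- lapply(split(recs, key), function(d) {
    data.frame(contig = d$contig[1L], intron_start = d$intron_start[1L],
               intron_end = d$intron_end[1L], support = nrow(d),
               min_overhang = min(d$overhang),
               distinct_positions = length(unique(d$read_start)),
               unique_support = sum(d$unique), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$contig, out$intron_start, out$intron_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.intron_coverage_table <- function(blocks, annotation) {
  introns <- annotation$introns
  cov <- data.frame(gene_id = introns$gene_id,
                    intron_index = introns$index,
                    covered_bases = 0L, intron_reads = 0L,
                    intron_bases = 0L, stringsAsFactors = FALSE)
  if (nrow(introns) == 0L) return(cov)
  intron_gr <- GenomicRanges::GRanges(
    introns$contig, IRanges::IRanges(introns$start, introns$end))
  flat <- unlist(blocks, use.names = FALSE)
  if (length(flat) == 0L) return(cov)
  read_of_block <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  hits <- GenomicRanges::findOverlaps(intron_gr, flat)
  if (length(hits) == 0L) return(cov)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  for (j in unique(qi)) {
    bl <- flat[si[qi == j]]
    clipped <- IRanges::restrict(IRanges::ranges(bl),
                                 start = introns$start[j],
                                 end = introns$end[j])
    cov$covered_bases[j] <- sum(IRanges::width(IRanges::reduce(clipped)))
    cov$intron_bases[j] <- sum(IRanges::width(clipped))
    cov$intron_reads[j] <- length(unique(read_of_block[si[qi == j]]))
  }
  cov[order(cov$gene_id, cov$intron_index), , drop = FALSE]
}

.exon_count_table <- function(blocks, is_unique, annotation) {
  exons <- annotation$exons
  genes <- unique(exons$gene_id)
  out <- data.frame(gene_id = sort(genes), exon_reads = 0L,
                    stringsAsFactors = FALSE)
  flat <- unlist(blocks, use.names = FALSE)
  if (length(flat) == 0L || nrow(exons) == 0L) return(out)
  read_of_block <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  keep <- is_unique[read_of_block]
  flat <- flat[keep]
  read_of_block <- read_of_block[keep]
  if (length(flat) == 0L) return(out)
  exon_gr <- GenomicRanges::GRanges(
    exons$contig, IRanges::IRanges(exons$start, exons$end))
  hits <- GenomicRanges::findOverlaps(exon_gr, flat)
  if (length(hits) == 0L) return(out)
  pair <- unique(data.frame(
    gene = exons$gene_id[S4Vectors::queryHits(hits)],
    read = read_of_block[S4Vectors::subjectHits(hits)]))
  tab <- table(pair$gene)
  out$exon_reads <- as.integer(tab[out$gene_id])
  out$exon_reads[is.na(out$exon_reads)] <- 0L
  out
}

#' Load evidence tables from TSV files
#'
#' Alternative ingestion path that bypasses SAM parsing: reads the three
#' evidence tables written by [write_evidence_tables()] (or produced by any
#' external junction counter) and returns the same `splice_evidence` object
#' as [extract_evidence()].  Lines starting with `#` are ignored.
#'
#' @param junction_tsv columns `contig`, `intron_start`, `intron_end`,
#'   `support`, `min_overhang`, `distinct_positions`, `unique_support`.
#' @param intron_tsv columns `gene_id`, `intron_index`, `covered_bases`,
#'   `intron_reads`.
#' @param stats_tsv columns `species_id`, `total_mapped`, `uniquely_mapped`.
#' @param exon_tsv optional; columns `gene_id`, `exon_reads`.
#' @return a `splice_evidence` object.
#' @export
load_evidence_tables <- function(junction_tsv, intron_tsv, stats_tsv,
                                 exon_tsv = NULL) {
  read_checked <- function(path, cols) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(d))
    if (length(missing))
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    d[, cols, drop = FALSE]
  }
  junctions <- read_checked(junction_tsv,
    c("contig", "intron_start", "intron_end", "support", "min_overhang",
      "distinct_positions", "unique_support"))
  intron_cov <- read_checked(intron_tsv,
    c("gene_id", "intron_index", "covered_bases", "intron_reads"))
  extra <- utils::read.table(intron_tsv, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  if ("intron_bases" %in% names(extra))
    intron_cov$intron_bases <- extra$intron_bases
  lib <- read_checked(stats_tsv,
    c("species_id", "total_mapped", "uniquely_mapped"))
  if (nrow(lib) != 1L) stop("library stats table must have exactly one row")
  if (lib$uniquely_mapped > lib$total_mapped)
    stop("library stats invariant violated: uniquely_mapped > total_mapped")
  if (nrow(junctions) &&
      any(junctions$support < junctions$distinct_positions))
    stop("junction invariant violated: support < distinct_positions")
  exon_counts <- if (is.null(exon_tsv)) {
    data.frame(gene_id = character(), exon_reads = integer(),
               stringsAsFactors = FALSE)
  } else read_checked(exon_tsv, c("gene_id", "exon_reads"))
  structure(list(junctions = junctions, intron_coverage = intron_cov,
                 exon_counts = exon_counts, library = lib),
            class = "splice_evidence")
}

#' Write evidence tables to TSV
#'
#' @param evidence a `splice_evidence`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix, typically the species id.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_evidence_tables <- function(evidence, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- evidence$library$species_id
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    junctions = file.path(dir, paste0(prefix, ".junctions.tsv")),
    intron_coverage = file.path(dir, paste0(prefix, ".intron_coverage.tsv")),
    exon_counts = file.path(dir, paste0(prefix, ".exon_counts.tsv")),
    library = file.path(dir, paste0(prefix, ".library.tsv")))
  utils::write.table(evidence$junctions, paths["junctions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(evidence$intron_coverage, paths["intron_coverage"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(evidence$exon_counts, paths["exon_counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(evidence$library, paths["library"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
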