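#' Load a reference genome and gene models
#'
#' Reads a genome FASTA and a GFF3 annotation (gene/mRNA/exon/CDS features
#' with Parent links) and builds the indexed annotation object used by every
#' downstream stage.  Genes carrying more than one mRNA model are reduced to
#' the longest model (largest summed exon length; ties broken by the
#' lexicographically smallest model id), so that every gene contributes a
#' single exon chain, a single set of derived introns and one CDS interval.
#'
#' All coordinates are GFF3-native: 1-based, inclusive at both ends.
#'
#' @param genome_path path to the genome FASTA.
#' @param gff_path path to the GFF3 annotation.
#' @return An object of class `splice_annotation`: a list with components
#'   `genes` (one row per gene: `gene_id`, `contig`, `strand`, `model_id`,
#'   `span_start`, `span_end`, `cds_start`, `cds_end`, `n_exons`,
#'   `exonic_len`), `exons` (per retained model: `gene_id`, `contig`,
#'   `start`, `end`, `rank` in transcription direction), `introns` (gaps
#'   between consecutive exons: `gene_id`, `contig`, `start`, `end`,
#'   `index` in transcription direction, `donor_pos`, `acceptor_pos`) and
#'   `genome` (a [Biostrings::DNAStringSet]).
#' @export
load_annotation <- function(genome_path, gff_path) {
  if (!file.exists(genome_path)) stop("genome FASTA not found: ", genome_path)
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  .check_gff3_syntax(gff_path)
  gff <- rtracklayer::import(gff_path, format = "gff3")

  type <- as.character(gff$type)
  genes_gr <- gff[type == "gene"]
  mrna_gr <- gff[type == "mRNA"]
  exon_gr <- gff[type == "exon"]
  cds_gr <- gff[type == "CDS"]
  if (length(genes_gr) == 0L) stop("no gene features in GFF3: ", gff_path)

  first_parent <- function(gr) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  }
  mrna_parent <- first_parent(mrna_gr)
  exon_parent <- first_parent(exon_gr)
  cds_parent <- first_parent(cds_gr)

  exon_len_by_mrna <- tapply(
    IRanges::width(IRanges::ranges(exon_gr)), exon_parent, sum)

  gene_rows <- vector("list", length(genes_gr))
  exon_rows <- vector("list", length(genes_gr))
  for (i in seq_along(genes_gr)) {
    g <- genes_gr[i]
    gid <- g$ID
    models <- mrna_gr$ID[mrna_parent == gid]
    if (length(models) == 0L) next
    lens <- exon_len_by_mrna[models]
    lens[is.na(lens)] <- 0
    # longest model; ties resolved by smallest model id for determinism
    best <- models[order(-lens, models)][1L]

    ex <- exon_gr[exon_parent == best]
    ex <- ex[order(GenomicRanges::start(ex))]
    if (length(ex) == 0L) stop("model without exons for gene ", gid)
    estart <- GenomicRanges::start(ex)
    eend <- GenomicRanges::end(ex)
    if (any(estart[-1L] <= eend[-length(eend)]))
      stop("overlapping exons in gene ", gid)

    cd <- cds_gr[cds_parent == best]
    if (length(cd) > 0L) {
      cs <- min(GenomicRanges::start(cd))
      ce <- max(GenomicRanges::end(cd))
      covered <- vapply(seq_along(cd), function(k) {
        any(GenomicRanges::start(cd)[k] >= estart &
            GenomicRanges::end(cd)[k] <= eend)
      }, logical(1))
      if (!all(covered))
        stop("CDS outside exon span for gene ", gid)
    } else {
      cs <- NA_integer_
      ce <- NA_integer_
    }
    strand <- as.character(GenomicRanges::strand(g))
    if (!strand %in% c("+", "-")) strand <- "+"
    contig <- as.character(GenomicRanges::seqnames(g))

    n <- length(ex)
    rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    exon_rows[[i]] <- data.frame(
      gene_id = gid, contig = contig, start = estart, end = eend,
      rank = rank, stringsAsFactors = FALSE)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, contig = contig, strand = strand, model_id = best,
      span_start = min(estart), span_end = max(eend),
      cds_start = cs, cds_end = ce,
      n_exons = n, exonic_len = sum(eend - estart + 1L),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, exon_rows)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    strand <- genes$strand[match(ex$gene_id[1L], genes$gene_id)]
    derive_introns(ex, strand)
  }))
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          index = integer(), donor_pos = integer(),
                          acceptor_pos = integer(), stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL

  missing_contigs <- setdiff(unique(genes$contig), names(genome))
  if (length(missing_contigs))
    stop("contigs in GFF3 absent from FASTA: ",
         paste(missing_contigs, collapse = ", "))

  structure(list(genes = genes, exons = exons, introns = introns,
                 genome = genome),
            class = "splice_annotation")
}

# Minimal structural scan so malformed lines are reported with their number.
.check_gff3_syntax <- function(gff_path) {
  lines <- readLines(gff_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                   integer(1))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GFF3 line ", bad, " in ", gff_path,
         ": expected 9 tab-separated fields")
  }
  invisible(TRUE)
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat("splice_annotation:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons,", nrow(x$introns), "introns on",
      length(x$genome), "contig(s)\n")
  invisible(x)
}

#' Derive introns from an exon chain
#'
#' Introns are the gaps between consecutive exons of one gene model.  The
#' donor position is the intron boundary adjacent to the upstream exon in
#' transcription direction (the 5' splice site) and the acceptor the boundary
#' adjacent to the downstream exon, so on the minus strand donor and acceptor
#' are the genomic end and start respectively.
#'
#' @param exons data frame with columns `gene_id`, `contig`, `start`, `end`
#'   for one gene, any row order.
#' @param strand `"+"` or `"-"`.
#' @return data frame `gene_id`, `contig`, `start`, `end`, `index`
#'   (transcription order, 1-based), `donor_pos`, `acceptor_pos`; zero rows
#'   for a single-exon gene.
#' @export
derive_introns <- function(exons, strand) {
  ex <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(ex)
  empty <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), index = integer(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  istart <- ex$end[-n] + 1L
  iend <- ex$start[-1L] - 1L
  if (any(iend < istart)) stop("abutting exons leave no intron in gene ",
                               ex$gene_id[1L])
  idx <- if (strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
  data.frame(
    gene_id = ex$gene_id[1L], contig = ex$contig[1L],
    start = istart, end = iend, index = idx,
    donor_pos = if (strand == "+") istart else iend,
    acceptor_pos = if (strand == "+") iend else istart,
    stringsAsFactors = FALSE)
}

#' Classify an interval by genic region
#'
#' Labels a 1-based inclusive interval relative to a gene's coding region:
#' `CDS` when both ends lie within the CDS bounds, `5UTR`/`3UTR` when both
#' ends lie in the corresponding untranslated span (resolved by strand),
#' `5UTR-CDS`/`CDS-3UTR` when the ends fall in different regions, and
#' `intergenic` when the interval lies outside every gene span (only when
#' `gene_id` is omitted and no gene contains the interval).  An interval
#' spanning the whole CDS is labeled `5UTR-CDS`.  Genes without annotated
#' CDS yield `NA`.
#'
#' @param annotation a `splice_annotation`.
#' @param contig contig id.
#' @param start,end interval bounds, 1-based inclusive.
#' @param gene_id optional gene to classify against; when omitted the first
#'   gene (smallest id) whose span contains the interval midpoint is used.
#' @return a single label string.
#' @export
classify_interval <- function(annotation, contig, start, end,
                              gene_id = NULL) {
  stopifnot(start <= end)
  g <- annotation$genes
  if (is.null(gene_id)) {
    hit <- which(g$contig == contig & g$span_start <= start &
                   g$span_end >= end)
    if (length(hit) == 0L) return("intergenic")
    row <- g[hit[order(g$gene_id[hit])][1L], ]
  } else {
    row <- g[g$gene_id == gene_id, ]
    if (nrow(row) == 0L) stop("unknown gene_id: ", gene_id)
  }
  if (is.na(row$cds_start)) return(NA_character_)
  zone <- function(pos) {
    if (pos < row$cds_start) {
      if (row$strand == "+") "5UTR" else "3UTR"
    } else if (pos > row$cds_end) {
      if (row$strand == "+") "3UTR" else "5UTR"
    } else "CDS"
  }
  # left/right in transcription direction so spanning labels read 5' to 3'
  z1 <- zone(if (row$strand == "+") start else end)
  z2 <- zone(if (row$strand == "+") end else start)
  if (z1 == z2) return(z1)
  if (z1 == "5UTR" && z2 == "3UTR") return("5UTR-CDS")
  if (z1 == "5UTR") "5UTR-CDS" else "CDS-3UTR"
}

#' Write a validated annotation summary
#'
#' @param annotation a `splice_annotation`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_annotation_summary <- function(annotation, path) {
  g <- annotation$genes
  n_introns <- vapply(g$gene_id, function(id)
    sum(annotation$introns$gene_id == id), integer(1))
  cds_len <- ifelse(is.na(g$cds_start), 0L,
                    .cds_exonic_length(annotation, g$gene_id))
  out <- data.frame(gene_id = g$gene_id, n_exons = g$n_exons,
                    n_introns = n_introns, cds_len = cds_len,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# exonic bases within the CDS bounds, vectorised over gene ids
.cds_exonic_length <- function(annotation, gene_ids) {
  vapply(gene_ids, function(id) {
    row <- annotation$genes[annotation$genes$gene_id == id, ]
    if (is.na(row$cds_start)) return(0L)
    ex <- annotation$exons[annotation$exons$gene_id == id, ]
    s <- pmax(ex$start, row$cds_start)
    e <- pmin(ex$end, row$cds_end)
    sum(pmax(0L, e - s + 1L))
  }, integer(1))
}

#' Write gene models back to GFF3
#'
#' Emits one gene/mRNA/exon/CDS block per retained model so a reloaded
#' annotation reproduces the original structure.
#'
#' @param annotation a `splice_annotation`.
#' @param path output GFF3 path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- annotation$genes
  fmt <- function(contig, src, type, s, e, strand, attrs)
    paste(contig, src, type, s, e, ".", strand, ".", attrs, sep = "\t")
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    ex <- annotation$exons[annotation$exons$gene_id == row$gene_id, ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    lines <- c(
      fmt(row$contig, "ecasplice", "gene", row$span_start, row$span_end,
          row$strand, paste0("ID=", row$gene_id)),
      fmt(row$contig, "ecasplice", "mRNA", row$span_start, row$span_end,
          row$strand, paste0("ID=", row$model_id, ";Parent=", row$gene_id)),
      fmt(row$contig, "ecasplice", "exon", ex$start, ex$end, row$strand,
          paste0("ID=", row$model_id, ".exon", seq_len(nrow(ex)),
                 ";Parent=", row$model_id)))
    if (!is.na(row$cds_start)) {
      cs <- pmax(ex$start, row$cds_start)
      ce <- pmin(ex$end, row$cds_end)
      keep <- cs <= ce
      lines <- c(lines,
        fmt(row$contig, "ecasplice", "CDS", cs[keep], ce[keep], row$strand,
            paste0("ID=", row$model_id, ".cds", seq_len(sum(keep)),
                   ";Parent=", row$model_id)))
    }
    writeLines(lines, con)
  }
  invisible(path)
}
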