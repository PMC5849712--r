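#' @title Seeded synthetic genomes with planted AS events
#'
#' @description
#' Generates a toy reference (FASTA + GFF3) of multi-exon protein-coding
#' genes, plants labeled AS events of the five types with a controlled
#' cross-species conservation design, and emits per-species spliced
#' alignments (SAM) plus evidence tables so that every pipeline stage can
#' be exercised against known truth.  The generator carries its own
#' transcript-space bookkeeping and its own translation path
#' (via [Biostrings::translate()]), so the intended PTC/frameshift labels
#' are computed independently of the consequence caller.
#'
#' @name synthetic_data
NULL

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Simulation configuration
#'
#' Defaults emulate a four-species survey against one shared reference:
#' compact plant-like genes (4-8 exons, introns of modest length), an
#' event-type mixture dominated by intron retention, and a conservation
#' design in which most planted signatures are private to one species.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_genes number of genes.
#' @param n_species number of species sharing the reference.
#' @param n_events number of planted event signatures (one per gene;
#'   default 60% of genes).
#' @param exon_count_range,exon_len_range,intron_len_range,utr5_range,utr3_range
#'   structural ranges in bp (inclusive).
#' @param event_rates named type mixture for planted events (normalized).
#' @param conservation_design named fractions of signatures planted in
#'   exactly k species, names `"1"..as.character(n_species)`.
#' @param read_length read length for emitted alignments.
#' @param junction_reads supporting reads emitted per planted or
#'   constitutive junction.
#' @param ir_breadth intron-coverage breadth targeted for planted IR.
#' @param noise_rate noise junctions (designed to fail the filters) per
#'   planted junction event.
#' @param frac_ir_div3 fraction of planted IR events placed on introns
#'   whose length is divisible by 3 (frame-preserving retention).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 50L, n_species = 4L,
                              n_events = NULL,
                              exon_count_range = c(4L, 8L),
                              exon_len_range = c(80L, 300L),
                              intron_len_range = c(60L, 200L),
                              utr5_range = c(20L, 60L),
                              utr3_range = c(20L, 60L),
                              event_rates = c(IR = 0.68, ES = 0.07,
                                              AltD = 0.06, AltA = 0.11,
                                              AltP = 0.08),
                              conservation_design = c("1" = 0.70,
                                                      "2" = 0.15,
                                                      "3" = 0.08,
                                                      "4" = 0.07),
                              read_length = 75L, junction_reads = 3L,
                              ir_breadth = 0.8, noise_rate = 0,
                              frac_ir_div3 = 0.4) {
  stopifnot(n_genes >= 1L, n_species >= 2L,
            all(event_rates >= 0), sum(event_rates) > 0,
            all(conservation_design >= 0), noise_rate >= 0,
            frac_ir_div3 >= 0, frac_ir_div3 <= 1,
            exon_len_range[1L] > utr5_range[2L] + 10L,
            exon_len_range[1L] > utr3_range[2L] + 10L)
  if (is.null(n_events)) n_events <- max(1L, round(0.6 * n_genes))
  if (n_events > n_genes)
    stop("n_events may not exceed n_genes (one event per gene)")
  ks <- as.integer(names(conservation_design))
  if (any(is.na(ks)) || any(ks < 1L) || any(ks > n_species))
    stop("conservation_design names must be 1..n_species")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_species = as.integer(n_species), n_events = as.integer(n_events),
    exon_count_range = exon_count_range, exon_len_range = exon_len_range,
    intron_len_range = intron_len_range, utr5_range = utr5_range,
    utr3_range = utr3_range,
    event_rates = event_rates / sum(event_rates),
    conservation_design = conservation_design / sum(conservation_design),
    read_length = as.integer(read_length),
    junction_reads = as.integer(junction_reads),
    ir_breadth = ir_breadth, noise_rate = noise_rate,
    frac_ir_div3 = frac_ir_div3), class = "sim_config")
}

# map an exonic transcript position to the position within the unspliced
# gene (introns included), all in transcription orientation
.tx_pos <- function(p, exon_cum, intron_cum) {
  k <- findInterval(p - 1L, exon_cum) + 1L  # exon index containing p
  p + if (k >= 2L) intron_cum[k - 1L] else 0L
}

# genomic position of an unspliced-transcript position
.genomic_pos <- function(t, g0, L, strand) {
  if (strand == "+") g0 - 1L + t else g0 + L - t
}

.map_interval <- function(a, b, g0, L, strand) {
  x <- .genomic_pos(a, g0, L, strand)
  y <- .genomic_pos(b, g0, L, strand)
  c(min(x, y), max(x, y))
}

#' Simulate the shared reference genome and annotation
#'
#' Genes are laid out on one contig, alternating strands, separated by
#' random spacers.  Every gene has GT..AG introns on the coding strand, an
#' ATG start, a single in-frame stop terminating the CDS and no internal
#' in-frame stop in the constitutive CDS (codons are drawn from the 61
#' sense codons).  UTRs are confined to the first and last exon, so every
#' intron lies within the CDS.
#'
#' @param config a `sim_config`.
#' @param dir output directory for `ref.fa` and `ref.gff3`.
#' @return invisibly, a `sim_reference` list: `fasta`, `gff3` (paths),
#'   `contig` (sequence string), and `meta` (per-gene transcript-space
#'   bookkeeping used by [plant_events()] and [emit_reads()]).
#' @export
simulate_reference <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  if (config$exon_len_range[1L] < 30L)
    stop("exons shorter than 30 bp cannot carry the codon layout")
  meta <- vector("list", config$n_genes)
  pieces <- character(0)
  offset <- 0L
  gff <- c("##gff-version 3")
  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", gi)
    n_ex <- sample(config$exon_count_range[1L]:config$exon_count_range[2L],
                   1L)
    exon_lens <- sample(config$exon_len_range[1L]:config$exon_len_range[2L],
                        n_ex, replace = TRUE)
    intron_lens <- sample(
      config$intron_len_range[1L]:config$intron_len_range[2L],
      n_ex - 1L, replace = TRUE)
    utr5 <- sample(config$utr5_range[1L]:config$utr5_range[2L], 1L)
    utr3 <- sample(config$utr3_range[1L]:config$utr3_range[2L], 1L)
    tot_ex <- sum(exon_lens)
    cds_len <- tot_ex - utr5 - utr3
    utr3 <- utr3 + cds_len %% 3L          # keep the frame closed
    cds_len <- tot_ex - utr5 - utr3
    stopifnot(cds_len >= 9L)
    cds_seq <- paste0("ATG",
                      paste(sample(.SENSE_CODONS, cds_len / 3L - 2L,
                                   replace = TRUE), collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    exonic_seq <- paste0(.rand_dna(utr5), cds_seq, .rand_dna(utr3))
    intron_seqs <- vapply(intron_lens, function(l)
      paste0("GT", .rand_dna(l - 4L), "AG"), character(1))
    strand <- if (gi %% 2L == 1L) "+" else "-"

    exon_cum <- cumsum(exon_lens)
    intron_cum <- cumsum(intron_lens)
    # unspliced transcript (transcription orientation)
    parts <- character(2L * n_ex - 1L)
    for (k in seq_len(n_ex)) {
      from <- if (k == 1L) 1L else exon_cum[k - 1L] + 1L
      parts[2L * k - 1L] <- substr(exonic_seq, from, exon_cum[k])
      if (k < n_ex) parts[2L * k] <- intron_seqs[k]
    }
    tx_seq <- paste(parts, collapse = "")
    L <- nchar(tx_seq)
    spacer <- .rand_dna(300L)
    g0 <- offset + 300L + 1L
    gseq <- if (strand == "+") tx_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        tx_seq)))
    pieces <- c(pieces, spacer, gseq)
    offset <- offset + 300L + L

    exon_g <- t(vapply(seq_len(n_ex), function(k) {
      a <- .tx_pos(if (k == 1L) 1L else exon_cum[k - 1L] + 1L,
                   exon_cum, intron_cum)
      b <- .tx_pos(exon_cum[k], exon_cum, intron_cum)
      .map_interval(a, b, g0, L, strand)
    }, numeric(2)))
    cds_g <- .map_interval(.tx_pos(utr5 + 1L, exon_cum, intron_cum),
                           .tx_pos(utr5 + cds_len, exon_cum, intron_cum),
                           g0, L, strand)

    mid <- paste0(gid, ".1")
    span <- c(min(exon_g[, 1L]), max(exon_g[, 2L]))
    gff <- c(gff,
      paste("chr1", "sim", "gene", span[1L], span[2L], ".", strand, ".",
            paste0("ID=", gid), sep = "\t"),
      paste("chr1", "sim", "mRNA", span[1L], span[2L], ".", strand, ".",
            paste0("ID=", mid, ";Parent=", gid), sep = "\t"))
    ord <- order(exon_g[, 1L])
    for (k in ord)
      gff <- c(gff, paste("chr1", "sim", "exon", exon_g[k, 1L],
                          exon_g[k, 2L], ".", strand, ".",
                          paste0("ID=", mid, ".e", k, ";Parent=", mid),
                          sep = "\t"))
    for (k in ord) {
      cs <- max(exon_g[k, 1L], cds_g[1L])
      ce <- min(exon_g[k, 2L], cds_g[2L])
      if (cs <= ce)
        gff <- c(gff, paste("chr1", "sim", "CDS", cs, ce, ".", strand,
                            ".", paste0("ID=", mid, ".c", k, ";Parent=",
                                        mid), sep = "\t"))
    }
    meta[[gi]] <- list(gene_id = gid, strand = strand, g0 = g0, L = L,
                       n_ex = n_ex, exon_lens = exon_lens,
                       intron_lens = intron_lens, exon_cum = exon_cum,
                       intron_cum = intron_cum, utr5 = utr5, utr3 = utr3,
                       cds_len = cds_len, exonic_seq = exonic_seq,
                       intron_seqs = intron_seqs, exon_g = exon_g,
                       cds_g = cds_g)
  }
  contig <- paste(pieces, collapse = "")
  fasta <- file.path(dir, "ref.fa")
  gff3 <- file.path(dir, "ref.gff3")
  writeLines(c(">chr1", substring(contig,
                                  seq(1L, nchar(contig), 70L),
                                  pmin(seq(1L, nchar(contig), 70L) + 69L,
                                       nchar(contig)))), fasta)
  writeLines(gff, gff3)
  names(meta) <- vapply(meta, `[[`, character(1), "gene_id")
  invisible(structure(list(fasta = fasta, gff3 = gff3, contig = contig,
                           meta = meta, config = config),
                      class = "sim_reference"))
}

# generator-side translation oracle: first in-frame stop via Biostrings
.oracle_first_stop <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(NA_integer_)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, 3L * n)),
    if.fuzzy.codon = "solve"))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0L) NA_integer_ else as.integer(hit)
}

# apply one planned edit to the exonic (spliced) sequence of a gene and
# return the alternative CDS string -- the generator's own reconstruction
.oracle_alt_cds <- function(m, edit) {
  s <- m$exonic_seq
  alt <- if (edit$op == "insert") {
    paste0(substr(s, 1L, edit$after), edit$seq,
           substr(s, edit$after + 1L, nchar(s)))
  } else {
    paste0(substr(s, 1L, edit$del_start - 1L),
           substr(s, edit$del_end + 1L, nchar(s)))
  }
  delta <- nchar(alt) - nchar(s)
  substr(alt, m$utr5 + 1L, m$utr5 + m$cds_len + delta)
}

#' Plant AS events with a conservation design
#'
#' Draws event types from the configured mixture, places each event in its
#' own gene (so consequence eligibility holds by construction), assigns
#' each signature to a species subset per the conservation design, and
#' computes the intended PTC/frameshift labels by the generator's own
#' transcript reconstruction and [Biostrings::translate()].
#'
#' IR events are placed on introns whose length is divisible by 3 for a
#' configured fraction of events.  AltD/AltA/AltP shifts move a splice
#' site into the flanking exon (removing exonic bases) or into the intron
#' (adding intronic bases), 3-18 bp, never touching the start codon.
#'
#' @param reference a `sim_reference`.
#' @param config the same `sim_config`.
#' @return a `sim_truth` list: `signatures` (planted signature table with
#'   `species` comma-list and intended `delta_len`, `frameshift`, `ptc`),
#'   `events` (per-species event table in caller layout) and `species`
#'   (ids `sp1`, `sp2`, ...).
#' @export
plant_events <- function(reference, config) {
  set.seed(config$seed + 1L)
  meta <- reference$meta
  species <- paste0("sp", seq_len(config$n_species))
  types <- names(config$event_rates)

  n_k <- round(config$n_events * config$conservation_design)
  # keep the total fixed after rounding
  while (sum(n_k) > config$n_events) n_k[which.max(n_k)] <-
    n_k[which.max(n_k)] - 1L
  while (sum(n_k) < config$n_events) n_k[which.min(n_k)] <-
    n_k[which.min(n_k)] + 1L
  k_of_event <- rep(as.integer(names(n_k)), n_k)

  gene_pool <- sample(names(meta))
  sig_rows <- list()
  ev_rows <- list()
  gi <- 0L
  for (e in seq_len(config$n_events)) {
    type <- sample(types, 1L, prob = config$event_rates)
    placed <- FALSE
    for (try in 1:50) {
      gi <- gi + 1L
      if (gi > length(gene_pool))
        stop("gene pool exhausted while planting events; ",
             "reduce n_events or enlarge the genome")
      m <- meta[[gene_pool[gi]]]
      plan <- .plan_event(m, type, config)
      if (!is.null(plan)) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place a ", type, " event")
    alt_cds <- .oracle_alt_cds(m, plan$edit)
    const_cds <- substr(m$exonic_seq, m$utr5 + 1L, m$utr5 + m$cds_len)
    delta <- nchar(alt_cds) - nchar(const_cds)
    fs <- (abs(delta) %% 3L) != 0L
    stop1 <- .oracle_first_stop(alt_cds)
    ptc <- !is.na(stop1) && 3L * stop1 < nchar(alt_cds)
    sp_set <- sort(sample(species, k_of_event[e]))
    sig_rows[[e]] <- data.frame(
      gene_id = m$gene_id, event_type = type, coords = plan$coords,
      obs_start = plan$obs[1L], obs_end = plan$obs[2L],
      ref_start = plan$ref[1L], ref_end = plan$ref[2L],
      event_length = plan$length, region = "CDS",
      species = paste(sp_set, collapse = ","),
      n_species = length(sp_set),
      delta_len = delta, frameshift = fs, ptc = ptc,
      stringsAsFactors = FALSE)
    for (sp in sp_set)
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        species_id = sp, gene_id = m$gene_id, event_type = type,
        coords = plan$coords, obs_start = plan$obs[1L],
        obs_end = plan$obs[2L], ref_start = plan$ref[1L],
        ref_end = plan$ref[2L], event_length = plan$length,
        region = "CDS", stringsAsFactors = FALSE)
  }
  signatures <- do.call(rbind, sig_rows)
  events <- do.call(rbind, ev_rows)
  events <- events[order(events$species_id, events$gene_id,
                         events$event_type), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(signatures = signatures, events = events,
                 species = species), class = "sim_truth")
}

# choose concrete coordinates for one event in one gene; NULL if the gene
# cannot host the requested type
.plan_event <- function(m, type, config) {
  n_ex <- m$n_ex
  g0 <- m$g0; L <- m$L; strand <- m$strand
  intron_tx <- function(k)
    c(m$exon_cum[k] + (if (k >= 2L) m$intron_cum[k - 1L] else 0L) + 1L,
      m$exon_cum[k] + m$intron_cum[k])
  if (type == "IR") {
    want_div3 <- stats::runif(1) < config$frac_ir_div3
    ok <- which((m$intron_lens %% 3L == 0L) == want_div3)
    if (length(ok) == 0L) ok <- seq_len(n_ex - 1L)
    k <- if (length(ok) == 1L) ok else sample(ok, 1L)
    tx <- intron_tx(k)
    gg <- .map_interval(tx[1L], tx[2L], g0, L, strand)
    return(list(coords = paste0(gg[1L], "-", gg[2L]), obs = c(NA, NA),
                ref = gg, length = m$intron_lens[k],
                edit = list(op = "insert", after = m$exon_cum[k],
                            seq = m$intron_seqs[k])))
  }
  if (type == "ES") {
    if (n_ex < 3L) return(NULL)
    k <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
    ex_tx <- c(if (k == 1L) 1L else m$exon_cum[k - 1L] + 1L, m$exon_cum[k])
    ex_g <- m$exon_g[k, ]
    jun_tx <- c(intron_tx(k - 1L)[1L], intron_tx(k)[2L])
    jun_g <- .map_interval(jun_tx[1L], jun_tx[2L], g0, L, strand)
    return(list(coords = paste0(ex_g[1L], "-", ex_g[2L]),
                obs = jun_g, ref = c(NA, NA),
                length = m$exon_lens[k],
                edit = list(op = "delete", del_start = ex_tx[1L],
                            del_end = ex_tx[2L])))
  }
  # Alt events need internal flanking exons so shifts stay inside the CDS
  if (n_ex < 4L) return(NULL)
  k <- if (n_ex == 4L) 2L else sample(2:(n_ex - 2L), 1L)
  ilen <- m$intron_lens[k]
  d <- sample(3:18, 1L)
  into_exon <- stats::runif(1) < 0.5       # TRUE: remove exonic bases
  if (!into_exon && ilen - d < 25L) into_exon <- TRUE
  up_len <- m$exon_lens[k]                 # exon upstream of intron k (tx)
  down_len <- m$exon_lens[k + 1L]
  tx <- intron_tx(k)
  ends <- if (type == "AltD") "donor" else
          if (type == "AltA") "acceptor" else "both"
  shift_one <- function(which_end) {
    # returns c(tx_lo, tx_hi) of the observed intron after shifting one
    # end, plus the exonic edit in transcript space
    if (which_end == "donor") {
      if (into_exon) {
        if (up_len - d < 12L) return(NULL)
        list(lo = tx[1L] - d, hi = tx[2L],
             edit = list(op = "delete",
                         del_start = m$exon_cum[k] - d + 1L,
                         del_end = m$exon_cum[k]))
      } else {
        list(lo = tx[1L] + d, hi = tx[2L],
             edit = list(op = "insert", after = m$exon_cum[k],
                         seq = substr(m$intron_seqs[k], 1L, d)))
      }
    } else {
      if (into_exon) {
        if (down_len - d < 12L) return(NULL)
        list(lo = tx[1L], hi = tx[2L] + d,
             edit = list(op = "delete",
                         del_start = m$exon_cum[k] + 1L,
                         del_end = m$exon_cum[k] + d))
      } else {
        list(lo = tx[1L], hi = tx[2L] - d,
             edit = list(op = "insert", after = m$exon_cum[k],
                         seq = substr(m$intron_seqs[k], ilen - d + 1L,
                                      ilen)))
      }
    }
  }
  if (ends != "both") {
    sh <- shift_one(ends)
    if (is.null(sh)) return(NULL)
    obs_g <- .map_interval(sh$lo, sh$hi, g0, L, strand)
    ref_g <- .map_interval(tx[1L], tx[2L], g0, L, strand)
    return(list(coords = paste0(obs_g[1L], "-", obs_g[2L]), obs = obs_g,
                ref = ref_g, length = d, edit = sh$edit))
  }
  # AltP: shift both ends; use removal on the donor side and an
  # independent shift on the acceptor side, merged into one edit pair is
  # awkward, so keep both shifts exon-ward (two deletions collapse to one
  # contiguous edit only if adjacent; instead do donor exon-ward and
  # acceptor exon-ward, expressed as a single replacement)
  d2 <- sample(3:18, 1L)
  if (up_len - d < 12L || down_len - d2 < 12L) return(NULL)
  obs_tx <- c(tx[1L] - d, tx[2L] + d2)
  obs_g <- .map_interval(obs_tx[1L], obs_tx[2L], g0, L, strand)
  ref_g <- .map_interval(tx[1L], tx[2L], g0, L, strand)
  list(coords = paste0(obs_g[1L], "-", obs_g[2L]), obs = obs_g,
       ref = ref_g, length = d + d2,
       edit = list(op = "delete", del_start = m$exon_cum[k] - d + 1L,
                   del_end = m$exon_cum[k] + d2))
}

#' Emit per-species spliced alignments and evidence tables
#'
#' For every species the emitter writes a SAM file containing: exonic
#' reads for every gene (expression evidence), spliced reads across every
#' annotated (constitutive) junction, junction reads for the species'
#' planted ES/AltD/AltA/AltP events (distinct start positions, overhangs
#' comfortably above the filter minimum), intron-tiling reads achieving the
#' configured coverage breadth for planted IR events, optional noise
#' junctions designed to fail the support filter, and a handful of
#' mapping-quality-zero decoy reads in intergenic spacers so that unique
#' and total mapped counts differ.  Evidence tables (junctions, intron
#' coverage, exon counts, library stats) are computed from the emitter's
#' own read plan and written as TSV beside the SAM.
#'
#' @param reference a `sim_reference`.
#' @param truth a `sim_truth` from [plant_events()].
#' @param config the same `sim_config`.
#' @param dir output directory.
#' @return invisibly, a list per species with elements `sam` and the four
#'   TSV paths.
#' @export
emit_reads <- function(reference, truth, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed + 2L)
  contig <- reference$contig
  clen <- nchar(contig)
  meta <- reference$meta
  rl <- config$read_length
  jr <- config$junction_reads

  # genomic introns per gene, ascending
  gintrons <- lapply(meta, function(m) {
    eg <- m$exon_g[order(m$exon_g[, 1L]), , drop = FALSE]
    if (nrow(eg) < 2L) return(NULL)
    cbind(start = eg[-nrow(eg), 2L] + 1L, end = eg[-1L, 1L] - 1L)
  })

  read_seq <- function(blocks) {
    paste(vapply(seq_len(nrow(blocks)), function(i)
      substr(contig, blocks[i, 1L], blocks[i, 2L]), character(1)),
      collapse = "")
  }
  out <- list()
  for (sp in truth$species) {
    pos <- integer(0); cigar <- character(0); mapq <- integer(0)
    blocks <- list()
    add_junction_reads <- function(js, je, n = jr) {
      gap <- je - js + 1L
      for (r in seq_len(n)) {
        left <- 10L + 2L * (r - 1L)
        right <- 12L
        p <- js - left
        pos <<- c(pos, p); mapq <<- c(mapq, 60L)
        cigar <<- c(cigar, paste0(left, "M", gap, "N", right, "M"))
        blocks[[length(blocks) + 1L]] <<-
          cbind(c(p, je + 1L), c(js - 1L, je + right))
      }
    }
    # expression reads on the first exon of every gene
    for (m in meta) {
      eg <- m$exon_g[order(m$exon_g[, 1L]), , drop = FALSE]
      for (off in c(0L, 3L)) {
        p <- eg[1L, 1L] + off
        w <- min(rl, eg[1L, 2L] - p + 1L)
        pos <- c(pos, p); mapq <- c(mapq, 60L)
        cigar <- c(cigar, paste0(w, "M"))
        blocks[[length(blocks) + 1L]] <- cbind(p, p + w - 1L)
      }
    }
    # constitutive junctions
    for (g in names(meta)) {
      gi <- gintrons[[g]]
      if (is.null(gi)) next
      for (k in seq_len(nrow(gi)))
        add_junction_reads(gi[k, "start"], gi[k, "end"])
    }
    # planted events of this species
    ev <- truth$events[truth$events$species_id == sp, , drop = FALSE]
    n_junction_events <- 0L
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$event_type == "IR") {
        s <- e$ref_start; t <- e$ref_end
        ilen <- t - s + 1L
        w <- min(rl, ilen)
        k_reads <- max(2L, as.integer(ceiling(config$ir_breadth * ilen / w))
                       + 1L)
        # duplicates are kept: short introns still need >= 2 reads
        starts <- as.integer(round(
          seq(s, max(s, t - w + 1L), length.out = k_reads)))
        for (p in starts) {
          pos <- c(pos, p); mapq <- c(mapq, 60L)
          cigar <- c(cigar, paste0(w, "M"))
          blocks[[length(blocks) + 1L]] <- cbind(p, p + w - 1L)
        }
      } else {
        add_junction_reads(e$obs_start, e$obs_end)
        n_junction_events <- n_junction_events + 1L
      }
    }
    # noise junctions: single support, thin overhang -> always filtered
    n_noise <- round(config$noise_rate * max(1L, n_junction_events))
    ann_starts <- unlist(lapply(gintrons, function(x)
      if (is.null(x)) integer(0) else x[, "start"]))
    made <- 0L; guard <- 0L
    while (made < n_noise && guard < 50L * n_noise) {
      guard <- guard + 1L
      g <- sample(names(meta), 1L)
      gi <- gintrons[[g]]
      if (is.null(gi)) next
      k <- sample(nrow(gi), 1L)
      gs <- gi[k, "start"] + 7L
      ge <- gs + 29L
      if (ge > gi[k, "end"] - 6L || gs %in% ann_starts) next
      p <- gs - 5L
      pos <- c(pos, p); mapq <- c(mapq, 60L)
      cigar <- c(cigar, paste0(5L, "M", 30L, "N", 5L, "M"))
      blocks[[length(blocks) + 1L]] <- cbind(c(p, ge + 1L),
                                             c(gs - 1L, ge + 5L))
      made <- made + 1L
    }
    # multi-mapping decoys in the leading intergenic spacer
    for (r in 1:5) {
      p <- 20L + 10L * r
      pos <- c(pos, p); mapq <- c(mapq, 0L)
      cigar <- c(cigar, paste0(min(rl, 60L), "M"))
      blocks[[length(blocks) + 1L]] <- cbind(p, p + min(rl, 60L) - 1L)
    }

    sam_path <- file.path(dir, paste0(sp, ".sam"))
    con <- file(sam_path, "w")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 paste0("@SQ\tSN:chr1\tLN:", clen)), con)
    ord <- order(pos)
    for (i in ord) {
      writeLines(paste(sprintf("%s_r%06d", sp, i), 0L, "chr1", pos[i],
                       mapq[i], cigar[i], "*", 0L, 0L,
                       read_seq(blocks[[i]]), "*", sep = "\t"), con)
    }
    close(con)

    tsvs <- .plan_evidence_tables(sp, pos, cigar, mapq, blocks, meta,
                                  gintrons, dir, config)
    out[[sp]] <- c(list(sam = sam_path), tsvs)
  }
  invisible(out)
}

# evidence tables from the emitter's read plan (generator-side bookkeeping,
# written in the same TSV dialect the loaders expect)
.plan_evidence_tables <- function(sp, pos, cigar, mapq, blocks, meta,
                                  gintrons, dir, config) {
  spliced <- grepl("N", cigar, fixed = TRUE)
  jrec <- list()
  for (i in which(spliced)) {
    b <- blocks[[i]]
    for (k in seq_len(nrow(b) - 1L)) {
      jrec[[length(jrec) + 1L]] <- data.frame(
        js = b[k, 2L] + 1L, je = b[k + 1L, 1L] - 1L,
        overhang = min(b[k, 2L] - b[k, 1L] + 1L,
                       b[k + 1L, 2L] - b[k + 1L, 1L] + 1L),
        start = pos[i], unique = mapq[i] > 0L)
    }
  }
  jrec <- do.call(rbind, jrec)
  jtab <- if (is.null(jrec)) .empty_junctions() else {
    agg <- lapply(split(jrec, paste(jrec$js, jrec$je)), function(d)
      data.frame(contig = "chr1", intron_start = d$js[1L],
                 intron_end = d$je[1L], support = nrow(d),
                 min_overhang = min(d$overhang),
                 distinct_positions = length(unique(d$start)),
                 unique_support = sum(d$unique), stringsAsFactors = FALSE))
    x <- do.call(rbind, agg)
    x <- x[order(x$intron_start, x$intron_end), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  flat_s <- unlist(lapply(blocks, function(b) b[, 1L]))
  flat_e <- unlist(lapply(blocks, function(b) b[, 2L]))
  flat_read <- rep(seq_along(blocks),
                   vapply(blocks, nrow, integer(1)))
  flat <- IRanges::IRanges(flat_s, flat_e)
  cov_rows <- list()
  for (g in names(meta)) {
    gi <- gintrons[[g]]
    if (is.null(gi)) next
    strand <- meta[[g]]$strand
    n_int <- nrow(gi)
    for (k in seq_len(n_int)) {
      idx_tx <- if (strand == "+") k else n_int - k + 1L
      ir <- IRanges::IRanges(gi[k, "start"], gi[k, "end"])
      ov <- IRanges::findOverlaps(ir, flat)
      hits <- S4Vectors::subjectHits(ov)
      if (length(hits)) {
        clipped <- IRanges::restrict(flat[hits], start = gi[k, "start"],
                                     end = gi[k, "end"])
        cb <- sum(IRanges::width(IRanges::reduce(clipped)))
        ib <- sum(IRanges::width(clipped))
        nr <- length(unique(flat_read[hits]))
      } else { cb <- 0L; ib <- 0L; nr <- 0L }
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        gene_id = g, intron_index = idx_tx, covered_bases = cb,
        intron_reads = nr, intron_bases = ib, stringsAsFactors = FALSE)
    }
  }
  cov <- do.call(rbind, cov_rows)
  cov <- cov[order(cov$gene_id, cov$intron_index), , drop = FALSE]
  exon_rows <- lapply(names(meta), function(g) {
    m <- meta[[g]]
    er <- IRanges::IRanges(m$exon_g[, 1L], m$exon_g[, 2L])
    ov <- IRanges::findOverlaps(er, flat)
    hits <- S4Vectors::subjectHits(ov)
    hits <- hits[mapq[flat_read[hits]] > 0L]
    data.frame(gene_id = g,
               exon_reads = length(unique(flat_read[hits])),
               stringsAsFactors = FALSE)
  })
  exon_counts <- do.call(rbind, exon_rows)
  exon_counts <- exon_counts[order(exon_counts$gene_id), , drop = FALSE]
  lib <- data.frame(species_id = sp, total_mapped = length(pos),
                    uniquely_mapped = sum(mapq > 0L),
                    stringsAsFactors = FALSE)
  ev <- structure(list(junctions = jtab, intron_coverage = cov,
                       exon_counts = exon_counts, library = lib),
                  class = "splice_evidence")
  as.list(write_evidence_tables(ev, dir, sp))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_reference()], [plant_events()],
#' [emit_reads()], plus truth tables (`truth_events.tsv`,
#' `truth_consequences.tsv`) and a YAML echo of the configuration.
#'
#' @param config a `sim_config`.
#' @param dir output directory.
#' @return list with `reference`, `truth` and `files` (per-species output
#'   paths).
#' @export
simulate_dataset <- function(config, dir) {
  ref <- simulate_reference(config, dir)
  truth <- plant_events(ref, config)
  files <- emit_reads(ref, truth, config, dir)
  utils::write.table(truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- truth$signatures[, c("gene_id", "event_type", "n_species",
                               "delta_len", "frameshift", "ptc")]
  utils::write.table(cons, file.path(dir, "truth_consequences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config_echo.yaml"))
  list(reference = ref, truth = truth, files = files)
}
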