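#' @title Coding consequences of single-event genes
#'
#' @description
#' For genes that carry exactly one AS event, located in the coding region
#' and not touching the start codon, the alternative transcript is
#' reconstructed from the genome and the event, translated with the
#' standard nuclear code, and scored for a premature termination codon
#' (PTC: any stop strictly upstream of the codon aligned to the
#' constitutive stop) and for a frameshift (inserted/removed length not a
#' multiple of 3).
#'
#' @name consequence_caller
NULL

.parse_coords <- function(coords) {
  parts <- strsplit(coords, ",", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE),
                             as.integer))
  data.frame(start = m[, 1L], end = m[, 2L])
}

# genomic interval of the bases the event adds or removes
.affected_span <- function(event) {
  iv <- .parse_coords(event$coords)
  s <- min(iv$start); e <- max(iv$end)
  if (event$event_type %in% c("AltD", "AltA", "AltP")) {
    s <- min(s, event$ref_start, event$obs_start)
    e <- max(e, event$ref_end, event$obs_end)
  }
  c(start = s, end = e)
}

#' Check consequence-analysis eligibility of a gene
#'
#' A gene qualifies when (1) it carries exactly one AS event signature,
#' (2) that event lies in the coding region, and (3) the event does not
#' affect the start codon.
#'
#' @param gene_id gene to check.
#' @param events event rows of this gene (distinct signatures).
#' @param annotation a `splice_annotation`.
#' @return list with logical `single_event`, `in_cds`,
#'   `start_codon_intact`, `eligible`.
#' @export
check_eligibility <- function(gene_id, events, annotation) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  sigs <- unique(event_signature(events)$signature)
  single <- length(sigs) == 1L
  in_cds <- FALSE
  intact <- TRUE
  if (single && !is.na(g$cds_start)) {
    ev <- events[1L, ]
    in_cds <- identical(ev$region, "CDS")
    start_codon <- if (g$strand == "+") c(g$cds_start, g$cds_start + 2L)
                   else c(g$cds_end - 2L, g$cds_end)
    sp <- .affected_span(ev)
    intact <- sp["end"] < start_codon[1L] || sp["start"] > start_codon[2L]
  }
  eligible <- single && in_cds && intact && !is.na(g$cds_start)
  list(single_event = single, in_cds = in_cds,
       start_codon_intact = intact, eligible = eligible)
}

# modified exonic structure (genomic, ascending) after applying one event
.alt_exon_ranges <- function(exons, event) {
  ir <- IRanges::IRanges(exons$start, exons$end)
  type <- event$event_type
  if (type == "IR") {
    iv <- .parse_coords(event$coords)
    ir <- IRanges::reduce(c(ir, IRanges::IRanges(iv$start, iv$end)))
  } else if (type == "ES") {
    iv <- .parse_coords(event$coords)
    ir <- IRanges::setdiff(ir, IRanges::IRanges(iv$start, iv$end))
  } else {
    # replace the reference intron with the observed one: everything that
    # was exonic stays exonic except the observed intron, and reference
    # intronic bases outside the observed intron become exonic
    ex_new <- IRanges::reduce(c(
      ir, IRanges::IRanges(event$ref_start, event$ref_end)))
    ir <- IRanges::setdiff(ex_new,
                           IRanges::IRanges(event$obs_start, event$obs_end))
  }
  ir
}

.extract_oriented <- function(genome, contig, ranges, lo, hi, strand) {
  clipped <- IRanges::restrict(ranges, start = lo, end = hi)
  clipped <- clipped[IRanges::width(clipped) > 0L]
  seqs <- vapply(seq_along(clipped), function(k)
    as.character(Biostrings::subseq(genome[[contig]],
                                    IRanges::start(clipped)[k],
                                    IRanges::end(clipped)[k])),
    character(1))
  s <- paste(seqs, collapse = "")
  if (strand == "-")
    s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Reconstruct constitutive and alternative coding sequences
#'
#' Applies one event to the gene's exon chain and extracts the coding
#' sequence between the annotated start and stop bounds from the genome:
#' IR inserts the intron sequence, ES removes the skipped exon sequence,
#' AltD/AltA/AltP replace the reference intron by the observed junction.
#' Minus-strand genes are reverse-complemented, so both returned sequences
#' read 5' to 3' and begin with the start codon.
#'
#' @param annotation a `splice_annotation` (with genome).
#' @param event one event row.
#' @return list with character strings `constitutive` and `alt`, and
#'   integer `delta_len` (alt minus constitutive length).
#' @export
build_alt_cds <- function(annotation, event) {
  g <- annotation$genes[annotation$genes$gene_id == event$gene_id, ]
  if (nrow(g) == 0L) stop("unknown gene_id: ", event$gene_id)
  if (is.na(g$cds_start)) stop("gene without CDS: ", event$gene_id)
  sp <- .affected_span(event)
  if (sp["start"] < g$span_start || sp["end"] > g$span_end)
    stop("event interval outside gene span for ", event$gene_id)
  ex <- annotation$exons[annotation$exons$gene_id == event$gene_id, ,
                         drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  const_r <- IRanges::IRanges(ex$start, ex$end)
  alt_r <- .alt_exon_ranges(ex, event)
  const <- .extract_oriented(annotation$genome, g$contig, const_r,
                             g$cds_start, g$cds_end, g$strand)
  alt <- .extract_oriented(annotation$genome, g$contig, alt_r,
                           g$cds_start, g$cds_end, g$strand)
  clipped <- IRanges::restrict(alt_r, start = g$cds_start, end = g$cds_end)
  clipped <- clipped[IRanges::width(clipped) > 0L]
  w <- IRanges::width(clipped)
  if (g$strand == "-") w <- rev(w)
  # transcript coordinate of the 3'-most exon-exon junction in the alt CDS
  last_junction <- if (length(w) >= 2L) sum(w[-length(w)]) else NA_integer_
  list(constitutive = const, alt = alt,
       delta_len = nchar(alt) - nchar(const),
       last_junction_tx = last_junction)
}

# first in-frame stop codon index, scanning from position 1; NA if none
.first_stop_codon <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  n_codons <- nchar(seq) %/% 3L
  for (c_i in seq_len(n_codons)) {
    codon <- substr(seq, 3L * c_i - 2L, 3L * c_i)
    if (codon %in% stops) return(c_i)
  }
  NA_integer_
}

#' Call PTC and frameshift for one alternative transcript
#'
#' Translates the alternative coding sequence in frame from its first base.
#' A PTC is any stop codon ending strictly before the final position of the
#' sequence — i.e. upstream of the codon aligned to the constitutive stop.
#' A frameshift is a length difference that is not a multiple of 3.
#'
#' @param alt_cds alternative coding sequence (starts with ATG).
#' @param constitutive_cds constitutive coding sequence (starts with ATG).
#' @param nmd_distance optional: when given together with
#'   `last_junction_tx`, an additional `ptc_nmd` flag marks stops more than
#'   this many bases upstream of the last exon-exon junction (the classic
#'   50-nt rule of thumb for NMD targeting).
#' @param last_junction_tx transcript coordinate (bases from the start
#'   codon) of the last junction, as returned by [build_alt_cds()].
#' @return list `delta_len`, `frameshift`, `ptc`, `ptc_position` (codon
#'   index of the premature stop, NA when `ptc` is FALSE) and, when the
#'   NMD rule is requested, `ptc_nmd`.
#' @export
call_consequence <- function(alt_cds, constitutive_cds,
                             nmd_distance = NULL,
                             last_junction_tx = NULL) {
  if (substr(constitutive_cds, 1L, 3L) != "ATG" ||
      substr(alt_cds, 1L, 3L) != "ATG")
    stop("coding sequence does not start with ATG; ",
         "gene should have been excluded by eligibility")
  delta <- nchar(alt_cds) - nchar(constitutive_cds)
  frameshift <- (abs(delta) %% 3L) != 0L
  first_stop <- .first_stop_codon(alt_cds)
  ptc <- !is.na(first_stop) && 3L * first_stop < nchar(alt_cds)
  out <- list(delta_len = delta, frameshift = frameshift, ptc = ptc,
              ptc_position = if (ptc) first_stop else NA_integer_)
  if (!is.null(nmd_distance)) {
    out$ptc_nmd <- ptc && !is.na(last_junction_tx) &&
      (last_junction_tx - 3L * first_stop) > nmd_distance
  }
  out
}

#' Consequence calls for all eligible single-event genes
#'
#' Reduces the classified events to distinct signatures, applies the three
#' eligibility criteria per gene, reconstructs the alternative transcript
#' for eligible genes and calls PTC/frameshift.
#'
#' @param classified_events events with `signature` and `conservation`
#'   columns (the `events` component of [classify_events()]).
#' @param annotation a `splice_annotation`.
#' @return data frame with one row per eligible gene: `gene_id`,
#'   `event_type`, `conservation`, `delta_len`, `frameshift`, `ptc`,
#'   `ptc_position`.
#' @export
consequence_calls <- function(classified_events, annotation) {
  ev <- classified_events[!duplicated(classified_events$signature), ,
                          drop = FALSE]
  rows <- list()
  for (gid in unique(ev$gene_id)) {
    gev <- ev[ev$gene_id == gid, , drop = FALSE]
    elig <- check_eligibility(gid, gev, annotation)
    if (!elig$eligible) next
    event <- gev[1L, ]
    seqs <- build_alt_cds(annotation, event)
    call <- call_consequence(seqs$alt, seqs$constitutive)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, event_type = event$event_type,
      conservation = event$conservation,
      delta_len = call$delta_len, frameshift = call$frameshift,
      ptc = call$ptc, ptc_position = call$ptc_position,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), event_type = character(),
                      conservation = character(), delta_len = integer(),
                      frameshift = logical(), ptc = logical(),
                      ptc_position = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contingency tables of PTC and frameshift outcomes
#'
#' Lays out the consequence calls as two tables — PTC and frameshift — with
#' counts and percentages per AS type and per conservation class, plus the
#' per-class totals.  Percentages are count over the type-by-class total,
#' to two decimals.
#'
#' @param calls output of [consequence_calls()].
#' @return list with data frames `ptc` and `frameshift`; columns `class`,
#'   `event_type`, `n_yes`, `pct_yes`, `n_no`, `pct_no`.
#' @export
consequence_tables <- function(calls) {
  types <- c("ES", "IR", "AltD", "AltA", "AltP", "Total")
  classes <- c("ECAS", "non-ECAS")
  one_table <- function(flag_col) {
    rows <- list()
    for (cl in classes) {
      d <- calls[calls$conservation == cl, , drop = FALSE]
      for (t in types) {
        dd <- if (t == "Total") d else d[d$event_type == t, , drop = FALSE]
        yes <- sum(dd[[flag_col]])
        no <- nrow(dd) - yes
        tot <- yes + no
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, event_type = t, n_yes = yes,
          pct_yes = if (tot > 0L) round(100 * yes / tot, 2) else 0,
          n_no = no,
          pct_no = if (tot > 0L) round(100 * no / tot, 2) else 0,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  list(ptc = one_table("ptc"), frameshift = one_table("frameshift"))
}

#' Percentage pair for one contingency cell
#'
#' The arithmetic used in the outcome tables: a yes/no count pair expressed
#' as percentages of their sum, rounded to two decimals.
#'
#' @param n_yes,n_no the two counts.
#' @return named numeric vector `pct_yes`, `pct_no`.
#' @export
outcome_percentages <- function(n_yes, n_no) {
  tot <- n_yes + n_no
  if (tot <= 0L) return(c(pct_yes = 0, pct_no = 0))
  c(pct_yes = round(100 * n_yes / tot, 2),
    pct_no = round(100 * n_no / tot, 2))
}
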