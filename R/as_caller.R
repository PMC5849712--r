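#' @title Alternative-splicing event calling
#'
#' @description
#' Calls the five principal plant AS event types from filtered splice
#' junctions and intron coverage, per species, against one shared
#' annotation:
#'
#' * **IR** (intron retention): an annotated intron with enough
#'   intron-mapped reads and enough coverage across the intron.
#' * **ES** (exon skipping): a junction joining the boundaries of two
#'   non-adjacent annotated exons, excluding the exon(s) in between.
#' * **AltD** / **AltA** (alternative donor / acceptor): a novel junction
#'   whose donor (5' splice site) or acceptor (3' splice site) is shifted
#'   relative to its annotated reference intron while the other end matches.
#' * **AltP** (alternative position): both ends shifted.
#'
#' Event lengths follow the convention: IR — length of the retained
#' intron; ES — summed length of the skipped exon(s); AltD/AltA — bases
#' added or removed at the varying intron end; AltP — sum of the absolute
#' shifts at both ends.
#'
#' @name as_caller
NULL

.empty_events <- function() {
  data.frame(species_id = character(), gene_id = character(),
             event_type = character(), coords = character(),
             obs_start = integer(), obs_end = integer(),
             ref_start = integer(), ref_end = integer(),
             event_length = integer(), region = character(),
             stringsAsFactors = FALSE)
}

.event_row <- function(species_id, gene_id, event_type, coords,
                       obs_start, obs_end, ref_start, ref_end,
                       event_length, region) {
  data.frame(species_id = species_id, gene_id = gene_id,
             event_type = event_type, coords = coords,
             obs_start = obs_start, obs_end = obs_end,
             ref_start = ref_start, ref_end = ref_end,
             event_length = as.integer(event_length), region = region,
             stringsAsFactors = FALSE)
}

#' Call intron-retention events
#'
#' An annotated intron is called retained when it has at least the
#' library-scaled minimum of intron-mapped reads (same scaling as the
#' junction support threshold) and at least `min_breadth` of its positions
#' covered by contiguously aligned read blocks.  Coverage can instead be
#' judged by mean depth (`coverage_mode = "depth"`, using total aligned
#' bases over intron length) if the evidence tables carry the
#' `intron_bases` column.
#'
#' @param evidence a `splice_evidence`.
#' @param annotation a `splice_annotation`.
#' @param policy a `filter_policy` (its support scaling is reused).
#' @param min_breadth minimum covered fraction of the intron (default 0.5).
#' @param coverage_mode `"breadth"` (fraction of positions touched) or
#'   `"depth"` (mean per-base depth).
#' @return event data frame (see [call_events()]).
#' @export
call_ir <- function(evidence, annotation, policy = filter_policy(),
                    min_breadth = 0.5, coverage_mode = c("breadth", "depth")) {
  coverage_mode <- match.arg(coverage_mode)
  cov <- evidence$intron_coverage
  if (nrow(cov) == 0L) return(.empty_events())
  introns <- annotation$introns
  key_ann <- paste(introns$gene_id, introns$index)
  idx <- match(paste(cov$gene_id, cov$intron_index), key_ann)
  if (anyNA(idx))
    stop("coverage row references unknown intron: ",
         paste(cov$gene_id[is.na(idx)][1L], cov$intron_index[is.na(idx)][1L]))
  thr <- support_threshold(policy, evidence$library)
  ilen <- introns$end[idx] - introns$start[idx] + 1L
  frac <- if (coverage_mode == "breadth") {
    cov$covered_bases / ilen
  } else {
    if (is.null(cov$intron_bases))
      stop("coverage_mode='depth' requires an intron_bases column")
    cov$intron_bases / ilen
  }
  called <- which(cov$intron_reads >= thr & frac >= min_breadth)
  if (length(called) == 0L) return(.empty_events())
  rows <- lapply(called, function(k) {
    j <- idx[k]
    region <- classify_interval(annotation, introns$contig[j],
                                introns$start[j], introns$end[j],
                                gene_id = introns$gene_id[j])
    .event_row(evidence$library$species_id, introns$gene_id[j], "IR",
               paste0(introns$start[j], "-", introns$end[j]),
               NA_integer_, NA_integer_,
               introns$start[j], introns$end[j],
               introns$end[j] - introns$start[j] + 1L, region)
  })
  do.call(rbind, rows)
}

# assign each junction to the gene whose span contains its exonic flanks;
# returns NA for intergenic/straddling junctions
.junction_gene <- function(junctions, annotation) {
  g <- annotation$genes
  vapply(seq_len(nrow(junctions)), function(i) {
    fs <- junctions$intron_start[i] - 1L
    fe <- junctions$intron_end[i] + 1L
    hit <- which(g$contig == junctions$contig[i] & g$span_start <= fs &
                   g$span_end >= fe)
    if (length(hit) == 0L) NA_character_ else sort(g$gene_id[hit])[1L]
  }, character(1))
}

#' Call exon-skipping events
#'
#' A passed junction whose start minus one equals the end of annotated exon
#' *i* and whose end plus one equals the start of annotated exon *j* (in
#' genomic order) with *j* >= *i* + 2 skips the exon(s) in between; one
#' event is produced per such junction regardless of how many exons are
#' skipped.
#'
#' @param junctions passed junction table.
#' @param annotation a `splice_annotation`.
#' @param species_id species label for the events.
#' @return event data frame.
#' @export
call_es <- function(junctions, annotation, species_id) {
  if (nrow(junctions) == 0L) return(.empty_events())
  gene_of <- .junction_gene(junctions, annotation)
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    gid <- gene_of[i]
    if (is.na(gid)) next
    ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    js <- junctions$intron_start[i]
    je <- junctions$intron_end[i]
    from <- match(js - 1L, ex$end)
    to <- match(je + 1L, ex$start)
    if (is.na(from) || is.na(to) || to < from + 2L) next
    skipped <- ex[(from + 1L):(to - 1L), , drop = FALSE]
    region <- classify_interval(annotation, junctions$contig[i],
                                min(skipped$start), max(skipped$end),
                                gene_id = gid)
    rows[[length(rows) + 1L]] <- .event_row(
      species_id, gid, "ES",
      paste(paste0(skipped$start, "-", skipped$end), collapse = ","),
      js, je, NA_integer_, NA_integer_,
      sum(skipped$end - skipped$start + 1L), region)
  }
  if (length(rows) == 0L) return(.empty_events())
  do.call(rbind, rows)
}

#' Call alternative donor/acceptor/position events
#'
#' Novel junctions (no exact match to an annotated intron and not an
#' exon-skipping junction) are compared against the annotated intron of
#' their gene with maximal reciprocal overlap (ties broken by smaller total
#' boundary shift).  With the acceptor end matching and the donor end
#' shifted the event is AltD; donor matching, acceptor shifted — AltA; both
#' shifted — AltP.  The strand decides which physical end is the donor.
#' `swap_alt_labels = TRUE` exchanges the AltD/AltA labels for
#' compatibility with tools that use the transposed convention.
#'
#' @param junctions passed junction table.
#' @param annotation a `splice_annotation`.
#' @param species_id species label.
#' @param swap_alt_labels swap the AltD/AltA labels.
#' @return event data frame.
#' @export
call_alt <- function(junctions, annotation, species_id,
                     swap_alt_labels = FALSE) {
  if (nrow(junctions) == 0L) return(.empty_events())
  gene_of <- .junction_gene(junctions, annotation)
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    gid <- gene_of[i]
    if (is.na(gid)) next
    js <- junctions$intron_start[i]
    je <- junctions$intron_end[i]
    introns <- annotation$introns[annotation$introns$gene_id == gid, ,
                                  drop = FALSE]
    if (nrow(introns) == 0L) next
    if (any(introns$start == js & introns$end == je)) next  # constitutive
    ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
    from <- match(js - 1L, ex$end)
    to <- match(je + 1L, ex$start)
    if (!is.na(from) && !is.na(to)) next  # exon-skipping junction
    # reciprocal overlap with each annotated intron
    ov_s <- pmax(js, introns$start)
    ov_e <- pmin(je, introns$end)
    ov <- pmax(0L, ov_e - ov_s + 1L)
    len_obs <- je - js + 1L
    len_ann <- introns$end - introns$start + 1L
    recip <- pmin(ov / len_obs, ov / len_ann)
    if (max(recip) <= 0) {
      message("junction ", junctions$contig[i], ":", js, "-", je,
              " overlaps no annotated intron of ", gid, "; skipped")
      next
    }
    shift_total <- abs(js - introns$start) + abs(je - introns$end)
    best <- order(-recip, shift_total, introns$start)[1L]
    ref <- introns[best, ]
    shift_left <- js - ref$start
    shift_right <- je - ref$end
    strand <- annotation$genes$strand[
      match(gid, annotation$genes$gene_id)]
    # donor is the genomic-left intron end on '+', the right end on '-'
    shift_donor <- if (strand == "+") shift_left else shift_right
    shift_acceptor <- if (strand == "+") shift_right else shift_left
    if (shift_donor != 0L && shift_acceptor == 0L) {
      type <- "AltD"; len <- abs(shift_donor)
    } else if (shift_donor == 0L && shift_acceptor != 0L) {
      type <- "AltA"; len <- abs(shift_acceptor)
    } else {
      type <- "AltP"; len <- abs(shift_donor) + abs(shift_acceptor)
    }
    if (swap_alt_labels && type %in% c("AltD", "AltA"))
      type <- if (type == "AltD") "AltA" else "AltD"
    region <- classify_interval(annotation, junctions$contig[i],
                                js - 1L, je + 1L, gene_id = gid)
    rows[[length(rows) + 1L]] <- .event_row(
      species_id, gid, type, paste0(js, "-", je),
      js, je, ref$start, ref$end, len, region)
  }
  if (length(rows) == 0L) return(.empty_events())
  do.call(rbind, rows)
}

#' Call all AS event types for one species
#'
#' Filters the junction evidence with the supplied policy, then calls IR,
#' ES and the alternative donor/acceptor/position events.
#'
#' @param evidence a `splice_evidence`.
#' @param annotation a `splice_annotation`.
#' @param policy a `filter_policy`.
#' @param min_breadth,coverage_mode IR thresholds, see [call_ir()].
#' @param swap_alt_labels see [call_alt()].
#' @return data frame of events, one row per event, with columns
#'   `species_id`, `gene_id`, `event_type`, `coords` (affected 1-based
#'   inclusive interval(s)), `obs_start`/`obs_end` (observed junction),
#'   `ref_start`/`ref_end` (annotated reference intron), `event_length`,
#'   `region`.
#' @export
call_events <- function(evidence, annotation, policy = filter_policy(),
                        min_breadth = 0.5,
                        coverage_mode = c("breadth", "depth"),
                        swap_alt_labels = FALSE) {
  coverage_mode <- match.arg(coverage_mode)
  passed <- filter_junctions(evidence$junctions, policy,
                             evidence$library)$passed
  sp <- evidence$library$species_id
  out <- rbind(
    call_ir(evidence, annotation, policy, min_breadth, coverage_mode),
    call_es(passed, annotation, sp),
    call_alt(passed, annotation, sp, swap_alt_labels))
  out <- out[order(out$gene_id, out$event_type, out$coords), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize called events
#'
#' @param events event data frame, possibly several species combined.
#' @param expressed_genes optional named list (per species) or vector of
#'   expressed gene ids used for the incidence denominator.
#' @return list with `type_distribution` (per species: count and percentage
#'   per type) and `gene_incidence` (per species: genes with >= 1 event and,
#'   when `expressed_genes` is given, the proportion of expressed genes).
#' @export
summarize_as <- function(events, expressed_genes = NULL) {
  types <- c("ES", "IR", "AltD", "AltA", "AltP")
  if (nrow(events) == 0L) {
    return(list(
      type_distribution = data.frame(
        species_id = character(), event_type = character(),
        n = integer(), percent = numeric(), stringsAsFactors = FALSE),
      gene_incidence = data.frame(
        species_id = character(), n_as_genes = integer(),
        n_expressed = integer(), proportion = numeric(),
        stringsAsFactors = FALSE)))
  }
  dist_rows <- lapply(split(events, events$species_id), function(d) {
    n <- vapply(types, function(t) sum(d$event_type == t), integer(1))
    data.frame(species_id = d$species_id[1L], event_type = types, n = n,
               percent = round(100 * n / sum(n), 2),
               stringsAsFactors = FALSE)
  })
  inc_rows <- lapply(split(events, events$species_id), function(d) {
    sp <- d$species_id[1L]
    expressed <- if (is.null(expressed_genes)) NA_integer_ else {
      eg <- if (is.list(expressed_genes)) expressed_genes[[sp]]
            else expressed_genes
      length(unique(eg))
    }
    n_as <- length(unique(d$gene_id))
    data.frame(species_id = sp, n_as_genes = n_as,
               n_expressed = expressed,
               proportion = if (is.na(expressed) || expressed == 0L)
                 NA_real_ else n_as / expressed,
               stringsAsFactors = FALSE)
  })
  list(type_distribution = do.call(rbind, dist_rows),
       gene_incidence = do.call(rbind, inc_rows))
}
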