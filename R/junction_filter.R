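#' Splice-junction reliability policy
#'
#' The three filters applied to candidate splice junctions before any event
#' is called: minimum read support scaled per ten million mapped reads,
#' minimum aligned overhang on both sides of the junction, and a minimum
#' number of supporting reads with a non-repetitive match position.  The
#' last rule is interpreted strictly: at least `min_distinct_nonrepetitive`
#' supporting reads must be uniquely aligned AND the supporting reads must
#' start at that many distinct genomic coordinates.
#'
#' @param min_support_per_10M required supporting reads per ten million
#'   totally mapped reads (also the absolute floor for small libraries).
#' @param min_overhang minimum aligned bases flanking the junction on both
#'   sides, over all supporting reads.
#' @param min_distinct_nonrepetitive minimum uniquely aligned supporting
#'   reads and minimum distinct read start positions.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_support_per_10M = 2L, min_overhang = 8L,
                          min_distinct_nonrepetitive = 2L) {
  stopifnot(min_support_per_10M >= 1L, min_overhang >= 1L,
            min_distinct_nonrepetitive >= 1L)
  structure(list(min_support_per_10M = as.integer(min_support_per_10M),
                 min_overhang = as.integer(min_overhang),
                 min_distinct_nonrepetitive =
                   as.integer(min_distinct_nonrepetitive)),
            class = "filter_policy")
}

#' Library-scaled support threshold
#'
#' Scales the per-ten-million support requirement to the library size:
#' `max(min_support_per_10M, ceiling(min_support_per_10M * total_mapped /
#' 1e7))`.  The ceiling keeps the threshold integral and monotone in library
#' size; the floor keeps the stated absolute minimum for libraries smaller
#' than ten million reads.
#'
#' @param policy a `filter_policy`.
#' @param library one-row data frame with column `total_mapped` (the
#'   `library` component of a `splice_evidence`).
#' @return integer threshold.
#' @export
support_threshold <- function(policy, library) {
  total <- library$total_mapped
  if (length(total) != 1L || is.na(total) || total <= 0)
    stop("library has no mapped reads; support threshold undefined")
  max(policy$min_support_per_10M,
      as.integer(ceiling(policy$min_support_per_10M * total / 1e7)))
}

#' Filter candidate splice junctions
#'
#' A junction passes when all four conditions hold: support at or above the
#' library-scaled threshold, minimum overhang at or above the policy value,
#' distinct start positions at or above the non-repetitive minimum, and
#' uniquely aligned support at or above the same minimum.  Rejected
#' junctions carry the first failed criterion (checked in that order) in a
#' `reason` column.
#'
#' @param junctions junction table (see [extract_evidence()]).
#' @param policy a `filter_policy`.
#' @param library library stats (one-row data frame with `total_mapped`).
#' @return list with data frames `passed` and `rejected` (the latter with a
#'   `reason` column), a disjoint partition of the input rows.
#' @export
filter_junctions <- function(junctions, policy = filter_policy(),
                             library) {
  thr <- support_threshold(policy, library)
  if (nrow(junctions) == 0L) {
    return(list(passed = junctions,
                rejected = cbind(junctions,
                                 data.frame(reason = character()))))
  }
  reason <- rep(NA_character_, nrow(junctions))
  reason[is.na(reason) & junctions$support < thr] <- "support"
  reason[is.na(reason) & junctions$min_overhang < policy$min_overhang] <-
    "overhang"
  reason[is.na(reason) &
           junctions$distinct_positions <
             policy$min_distinct_nonrepetitive] <- "distinct_positions"
  reason[is.na(reason) &
           junctions$unique_support <
             policy$min_distinct_nonrepetitive] <- "unique_support"
  passed <- junctions[is.na(reason), , drop = FALSE]
  rejected <- junctions[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(passed) <- NULL
  rownames(rejected) <- NULL
  list(passed = passed, rejected = rejected)
}

#' Classify retained junctions by genomic context
#'
#' Each passed junction is labeled by the genic region of the interval it
#' spans: junctions inside a gene get the CDS/UTR label of
#' [classify_interval()] applied to the junction's exonic flanks (one base
#' on each side of the spanned gap), junctions outside every gene span are
#' intergenic.
#'
#' @param junctions passed junction table.
#' @param annotation a `splice_annotation`.
#' @return list with `junctions` (input plus `region` and `gene_id`
#'   columns) and `summary` (counts per region label).
#' @export
classify_junctions <- function(junctions, annotation) {
  n <- nrow(junctions)
  region <- character(n)
  gene <- rep(NA_character_, n)
  g <- annotation$genes
  for (i in seq_len(n)) {
    # flanking exonic bases, so a junction touching a CDS edge is labeled
    # by the exon ends it joins rather than the intronic gap itself
    fs <- junctions$intron_start[i] - 1L
    fe <- junctions$intron_end[i] + 1L
    hit <- which(g$contig == junctions$contig[i] & g$span_start <= fs &
                   g$span_end >= fe)
    if (length(hit) == 0L) {
      region[i] <- "intergenic"
    } else {
      gid <- sort(g$gene_id[hit])[1L]
      gene[i] <- gid
      region[i] <- classify_interval(annotation, junctions$contig[i],
                                     fs, fe, gene_id = gid)
    }
  }
  out <- junctions
  out$gene_id <- gene
  out$region <- region
  levels_order <- c("CDS", "5UTR", "3UTR", "5UTR-CDS", "CDS-3UTR",
                    "intergenic")
  counts <- vapply(levels_order, function(l)
    sum(!is.na(region) & region == l), integer(1))
  summary <- data.frame(region = levels_order, n_junctions = counts,
                        proportion = if (n > 0) counts / n else 0,
                        stringsAsFactors = FALSE)
  list(junctions = out, summary = summary)
}
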