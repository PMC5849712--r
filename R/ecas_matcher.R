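#' Event signatures for cross-species matching
#'
#' Two events are the same signature — and hence candidates for an
#' evolutionarily conserved AS (ECAS) call — when they are the same type in
#' the same gene and affect the same coordinates on the shared reference:
#' IR, the same retained intron; ES, the same skipped exon(s); AltD, AltA
#' and AltP, the same annotated reference intron with the shifted splice
#' site(s) at the same position.  All species are mapped to one reference,
#' so orthology reduces to gene-id identity.
#'
#' @param events event data frame (any number of species).
#' @param tolerance maximum boundary difference (bp) for the shifted splice
#'   sites of AltD/AltA/AltP events to be merged into one signature;
#'   default 0 (exact position match).
#' @return the events with a `signature` character column appended.
#' @export
event_signature <- function(events, tolerance = 0L) {
  if (nrow(events) == 0L) {
    events$signature <- character(0)
    return(events)
  }
  alt <- events$event_type %in% c("AltD", "AltA", "AltP")
  sig <- ifelse(alt,
    paste(events$gene_id, events$event_type,
          paste0(events$ref_start, "-", events$ref_end),
          paste0(events$obs_start, "-", events$obs_end), sep = "|"),
    paste(events$gene_id, events$event_type, events$coords, sep = "|"))
  if (tolerance > 0L && any(alt)) {
    # cluster alt events on the same reference intron whose shifted
    # boundaries agree within the tolerance; representative = first in
    # coordinate order, so the merge is deterministic
    idx <- which(alt)
    key <- paste(events$gene_id[idx], events$event_type[idx],
                 events$ref_start[idx], events$ref_end[idx], sep = "|")
    for (k in unique(key)) {
      grp <- idx[key == k]
      grp <- grp[order(events$obs_start[grp], events$obs_end[grp])]
      reps <- integer(0)
      for (i in grp) {
        matched <- FALSE
        for (r in reps) {
          if (abs(events$obs_start[i] - events$obs_start[r]) <= tolerance &&
              abs(events$obs_end[i] - events$obs_end[r]) <= tolerance) {
            sig[i] <- sig[r]
            matched <- TRUE
            break
          }
        }
        if (!matched) reps <- c(reps, i)
      }
    }
  }
  events$signature <- sig
  events
}

#' Group events into signature records across species
#'
#' @param events event data frame covering all species (all called against
#'   the same annotation).
#' @param tolerance see [event_signature()].
#' @return data frame of class `ecas_records`, one row per distinct
#'   signature: `signature`, `gene_id`, `event_type`, `species` (comma
#'   separated, sorted), `n_species`, `ecas` (TRUE when observed in >= 2
#'   species), ordered by signature.
#' @export
build_signatures <- function(events, tolerance = 0L) {
  ev <- event_signature(events, tolerance)
  recs <- lapply(split(ev, ev$signature), function(d) {
    sp <- sort(unique(d$species_id))
    data.frame(signature = d$signature[1L], gene_id = d$gene_id[1L],
               event_type = d$event_type[1L],
               species = paste(sp, collapse = ","),
               n_species = length(sp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(signature = character(), gene_id = character(),
                      event_type = character(), species = character(),
                      n_species = integer(), stringsAsFactors = FALSE)
  out$ecas <- out$n_species >= 2L
  out <- out[order(out$signature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ecas_records", "data.frame")
  out
}

#' Pairwise ECAS sharing proportion
#'
#' The proportion of shared events between two species, normalized by the
#' union of their event sets: `shared / (n_a + n_b - shared)`, expressed as
#' a percentage.
#'
#' @param n_a,n_b event counts in the two species.
#' @param shared events common to both.
#' @return percentage (0-100).
#' @export
sharing_proportion <- function(n_a, n_b, shared) {
  stopifnot(shared <= n_a, shared <= n_b)
  100 * shared / (n_a + n_b - shared)
}

#' Sharing statistics over species subsets
#'
#' For every subset of 2, 3, ... up to all analyzed species, counts the
#' signatures present in every member of the subset and reports the
#' proportion relative to the union of the members' event sets.  Also
#' reports the exact-membership (upset-style) counts and the overall ECAS
#' tally.
#'
#' @param records output of [build_signatures()].
#' @param species character vector of all analyzed species (defaults to the
#'   species observed in `records`).
#' @return list with `subsets` (columns `species`, `k`, `shared`, `union`,
#'   `percent`), `exact_membership` (signature counts per exact species
#'   set), `n_ecas` (signatures in >= 2 species), `n_ecas_genes` (distinct
#'   genes among them).
#' @export
sharing_stats <- function(records, species = NULL) {
  sets <- strsplit(records$species, ",", fixed = TRUE)
  if (is.null(species))
    species <- sort(unique(unlist(sets)))
  if (length(species) < 2L) stop("need at least two species")
  rows <- list()
  for (k in 2:length(species)) {
    combos <- utils::combn(species, k, simplify = FALSE)
    for (cc in combos) {
      in_all <- vapply(sets, function(s) all(cc %in% s), logical(1))
      in_any <- vapply(sets, function(s) any(cc %in% s), logical(1))
      shared <- sum(in_all)
      un <- sum(in_any)
      rows[[length(rows) + 1L]] <- data.frame(
        species = paste(cc, collapse = ","), k = k, shared = shared,
        union = un,
        percent = if (un > 0L) round(100 * shared / un, 2) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  subsets <- do.call(rbind, rows)
  exact <- as.data.frame(table(records$species),
                         stringsAsFactors = FALSE)
  names(exact) <- c("species", "n_signatures")
  exact <- exact[order(exact$species), , drop = FALSE]
  rownames(exact) <- NULL
  ecas <- records[records$ecas, , drop = FALSE]
  list(subsets = subsets, exact_membership = exact,
       n_ecas = nrow(ecas),
       n_ecas_genes = length(unique(ecas$gene_id)))
}

#' Label every event ECAS or non-ECAS
#'
#' An event is ECAS when its signature was observed in at least two
#' species; otherwise non-ECAS.  A gene with at least one ECAS signature is
#' an ECAS gene.
#'
#' @param events event data frame for all species.
#' @param records output of [build_signatures()] on the same events.
#' @param tolerance the tolerance used to build `records`.
#' @return list with `events` (input plus `signature`, `n_species` and
#'   `conservation` in `{"ECAS","non-ECAS"}`) and `ecas_genes` (character
#'   vector).
#' @export
classify_events <- function(events, records, tolerance = 0L) {
  ev <- event_signature(events, tolerance)
  idx <- match(ev$signature, records$signature)
  if (anyNA(idx) && nrow(ev) > 0L)
    stop("events contain signatures absent from records; ",
         "rebuild records from the same event set")
  ev$n_species <- records$n_species[idx]
  ev$conservation <- ifelse(records$ecas[idx], "ECAS", "non-ECAS")
  list(events = ev,
       ecas_genes = sort(unique(records$gene_id[records$ecas])))
}
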