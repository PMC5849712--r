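#' Pipeline configuration
#'
#' Builds the configuration driving [run_stage()] / [run_pipeline()], from
#' a YAML file and/or direct arguments (arguments win over the file).
#' Fields: `genome`, `gff`, `alignments` (named species -> SAM/BAM path),
#' `out_dir`, `seed`, filter policy (`min_support_per_10M`, `min_overhang`,
#' `min_distinct_nonrepetitive`), IR thresholds (`ir_min_breadth`,
#' `coverage_mode`), `swap_alt_labels`, `ecas_tolerance`, `n_bins`, and a
#' `simulate` sub-list passed to [simulation_config()] for the simulate
#' stage.
#'
#' @param yaml_path optional YAML file.
#' @param ... direct overrides of any field.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(genome = NULL, gff = NULL, alignments = NULL,
              out_dir = "ecasplice_out", seed = 1L,
              min_support_per_10M = 2L, min_overhang = 8L,
              min_distinct_nonrepetitive = 2L,
              ir_min_breadth = 0.5, coverage_mode = "breadth",
              swap_alt_labels = FALSE, ecas_tolerance = 0L,
              n_bins = 10L, simulate = list())
  if (!is.null(yaml_path)) {
    from_file <- yaml::read_yaml(yaml_path)
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}

.stage_header <- function(stage, config) {
  paste0("# ecasplice ",
         as.character(utils::packageVersion("ecasplice")),
         " stage=", stage, " config=", .config_hash(config))
}

.write_stage_tsv <- function(df, path, stage, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stage_header(stage, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.require_upstream <- function(path, needed_stage) {
  if (!all(file.exists(path)))
    stop("missing upstream output ", paste(path[!file.exists(path)],
                                           collapse = ", "),
         "; run the '", needed_stage, "' stage first")
}

.stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.policy_from_config <- function(config) {
  filter_policy(config$min_support_per_10M, config$min_overhang,
                config$min_distinct_nonrepetitive)
}

.species_of <- function(config) {
  if (!is.null(config$alignments)) return(names(config$alignments))
  sim_dir <- file.path(config$out_dir, "simulate")
  sams <- list.files(sim_dir, pattern = "\\.sam$")
  if (length(sams) == 0L)
    stop("no alignments configured and no simulated data; ",
         "run the 'simulate' stage first")
  sub("\\.sam$", "", sams)
}

.load_annotation_from_config <- function(config) {
  genome <- config$genome
  gff <- config$gff
  if (is.null(genome) || is.null(gff)) {
    sim_dir <- file.path(config$out_dir, "simulate")
    genome <- file.path(sim_dir, "ref.fa")
    gff <- file.path(sim_dir, "ref.gff3")
    .require_upstream(c(genome, gff), "simulate")
  }
  load_annotation(genome, gff)
}

.load_species_evidence <- function(config, sp) {
  d <- file.path(config$out_dir, "evidence")
  paths <- file.path(d, paste0(sp, c(".junctions.tsv",
                                     ".intron_coverage.tsv",
                                     ".library.tsv", ".exon_counts.tsv")))
  .require_upstream(paths, "evidence")
  load_evidence_tables(paths[1L], paths[2L], paths[3L], paths[4L])
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic reference + reads), `evidence` (SAM ->
#' evidence tables), `filter` (junction filtering + context summary),
#' `call` (AS events per species), `express` (RPKM + trend tables),
#' `conserve` (cross-species signatures and sharing), `consequence`
#' (PTC/frameshift tables), `stats` (length and position comparisons),
#' `all` (everything in order).  Each stage writes TSV outputs under
#' `out_dir/<stage>/`, headed by a comment line with the package version,
#' the stage name and a hash of the configuration.
#'
#' @param stage stage name.
#' @param config a `pipeline_config`.
#' @return invisibly, the stage's primary output paths.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "evidence", "filter", "call",
                              "express", "conserve", "consequence",
                              "stats", "all"))
  if (stage == "all") {
    stages <- c(if (is.null(config$alignments)) "simulate", "evidence",
                "filter", "call", "express", "conserve", "consequence",
                "stats")
    return(invisible(lapply(stages, run_stage, config = config)))
  }
  switch(stage,
    simulate = {
      d <- .stage_dir(config, "simulate")
      sim_args <- config$simulate
      sim_args$seed <- config$seed
      sc <- do.call(simulation_config, sim_args)
      res <- simulate_dataset(sc, d)
      invisible(c(res$reference$fasta, res$reference$gff3))
    },
    evidence = {
      d <- .stage_dir(config, "evidence")
      ann <- .load_annotation_from_config(config)
      alns <- config$alignments
      if (is.null(alns)) {
        sim_dir <- file.path(config$out_dir, "simulate")
        sp <- .species_of(config)
        alns <- stats::setNames(file.path(sim_dir, paste0(sp, ".sam")), sp)
      }
      paths <- lapply(names(alns), function(sp) {
        ev <- extract_evidence(alns[[sp]], ann, sp)
        write_evidence_tables(ev, d, sp)
      })
      invisible(unlist(paths))
    },
    filter = {
      d <- .stage_dir(config, "filter")
      ann <- .load_annotation_from_config(config)
      policy <- .policy_from_config(config)
      out <- character(0)
      for (sp in .species_of(config)) {
        ev <- .load_species_evidence(config, sp)
        fl <- filter_junctions(ev$junctions, policy, ev$library)
        cl <- classify_junctions(fl$passed, ann)
        p1 <- file.path(d, paste0(sp, ".junctions_passed.tsv"))
        .write_stage_tsv(cl$junctions, p1, "filter", config)
        .write_stage_tsv(fl$rejected,
                         file.path(d, paste0(sp, ".junctions_rejected.tsv")),
                         "filter", config)
        .write_stage_tsv(cl$summary,
                         file.path(d,
                                   paste0(sp, ".junction_context_summary.tsv")),
                         "filter", config)
        out <- c(out, p1)
      }
      invisible(out)
    },
    call = {
      d <- .stage_dir(config, "call")
      ann <- .load_annotation_from_config(config)
      policy <- .policy_from_config(config)
      all_events <- list()
      for (sp in .species_of(config)) {
        passed_path <- file.path(config$out_dir, "filter",
                                 paste0(sp, ".junctions_passed.tsv"))
        .require_upstream(passed_path, "filter")
        passed <- utils::read.table(passed_path, header = TRUE, sep = "\t",
                                    comment.char = "#",
                                    stringsAsFactors = FALSE)
        ev <- .load_species_evidence(config, sp)
        events <- rbind(
          call_ir(ev, ann, policy, config$ir_min_breadth,
                  config$coverage_mode),
          call_es(passed, ann, sp),
          call_alt(passed, ann, sp, config$swap_alt_labels))
        events <- events[order(events$gene_id, events$event_type,
                               events$coords), , drop = FALSE]
        .write_stage_tsv(events,
                         file.path(d, paste0("events_", sp, ".tsv")),
                         "call", config)
        all_events[[sp]] <- events
      }
      combined <- do.call(rbind, all_events)
      rownames(combined) <- NULL
      summ <- summarize_as(combined)
      .write_stage_tsv(summ$type_distribution,
                       file.path(d, "as_summary.tsv"), "call", config)
      invisible(file.path(d, paste0("events_", .species_of(config),
                                    ".tsv")))
    },
    express = {
      d <- .stage_dir(config, "express")
      ann <- .load_annotation_from_config(config)
      out <- character(0)
      for (sp in .species_of(config)) {
        ev <- .load_species_evidence(config, sp)
        expr <- compute_rpkm(ev, ann)
        p <- file.path(d, paste0("expression_", sp, ".tsv"))
        .write_stage_tsv(expr, p, "express", config)
        events_path <- file.path(config$out_dir, "call",
                                 paste0("events_", sp, ".tsv"))
        .require_upstream(events_path, "call")
        events <- utils::read.table(events_path, header = TRUE, sep = "\t",
                                    comment.char = "#",
                                    stringsAsFactors = FALSE)
        for (feat in c("rpkm", "intron_number")) {
          tr <- tryCatch(
            trend_vs_feature(events, ann, feat, expression = expr,
                             event_type = if (feat == "intron_number") "IR",
                             n_bins = config$n_bins),
            error = function(e) NULL)
          if (!is.null(tr)) {
            tab <- tr$bins
            tab$slope <- tr$slope
            tab$r_squared <- tr$r_squared
            tab$p_value <- tr$p_value
            .write_stage_tsv(tab,
                             file.path(d, paste0("trend_", feat, "_", sp,
                                                 ".tsv")),
                             "express", config)
          }
        }
        out <- c(out, p)
      }
      invisible(out)
    },
    conserve = {
      d <- .stage_dir(config, "conserve")
      events <- .read_all_events(config)
      recs <- build_signatures(events, config$ecas_tolerance)
      stats <- sharing_stats(recs, .species_of(config))
      .write_stage_tsv(as.data.frame(recs),
                       file.path(d, "ecas_events.tsv"), "conserve", config)
      .write_stage_tsv(stats$subsets,
                       file.path(d, "sharing_matrix.tsv"), "conserve",
                       config)
      .write_stage_tsv(stats$exact_membership,
                       file.path(d, "upset_counts.tsv"), "conserve",
                       config)
      invisible(file.path(d, "ecas_events.tsv"))
    },
    consequence = {
      d <- .stage_dir(config, "consequence")
      ann <- .load_annotation_from_config(config)
      events <- .read_all_events(config)
      recs <- build_signatures(events, config$ecas_tolerance)
      cls <- classify_events(events, recs, config$ecas_tolerance)
      calls <- consequence_calls(cls$events, ann)
      tabs <- consequence_tables(calls)
      .write_stage_tsv(calls, file.path(d, "consequences.tsv"),
                       "consequence", config)
      .write_stage_tsv(tabs$ptc, file.path(d, "ptc_table.tsv"),
                       "consequence", config)
      .write_stage_tsv(tabs$frameshift,
                       file.path(d, "frameshift_table.tsv"),
                       "consequence", config)
      invisible(file.path(d, "consequences.tsv"))
    },
    stats = {
      d <- .stage_dir(config, "stats")
      events <- .read_all_events(config)
      recs <- build_signatures(events, config$ecas_tolerance)
      cls <- classify_events(events, recs, config$ecas_tolerance)
      sig_events <- cls$events[!duplicated(cls$events$signature), ,
                               drop = FALSE]
      ls <- length_summary(sig_events)
      pc <- position_comparison(sig_events)
      .write_stage_tsv(ls, file.path(d, "length_summary.tsv"), "stats",
                       config)
      .write_stage_tsv(pc$shares, file.path(d, "position_summary.tsv"),
                       "stats", config)
      .write_stage_tsv(pc$tests, file.path(d, "tests.tsv"), "stats",
                       config)
      invisible(file.path(d, "length_summary.tsv"))
    })
}

.read_all_events <- function(config) {
  sp <- .species_of(config)
  paths <- file.path(config$out_dir, "call", paste0("events_", sp, ".tsv"))
  .require_upstream(paths, "call")
  events <- do.call(rbind, lapply(paths, utils::read.table, header = TRUE,
                                  sep = "\t", comment.char = "#",
                                  stringsAsFactors = FALSE))
  rownames(events) <- NULL
  events
}

#' Run the whole pipeline
#'
#' Equivalent to `run_stage("all", config)`.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(config) {
  run_stage("all", config)
}
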