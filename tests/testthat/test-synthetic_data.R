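test_that("equal seeds give byte-identical output, distinct seeds differ", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  cfg <- simulation_config(seed = 5L, n_genes = 8L)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "ref.fa")),
                   readLines(file.path(d2, "ref.fa")))
  expect_identical(readLines(file.path(d1, "sp1.sam")),
                   readLines(file.path(d2, "sp1.sam")))
  expect_identical(readLines(file.path(d1, "truth_events.tsv")),
                   readLines(file.path(d2, "truth_events.tsv")))
  simulate_dataset(simulation_config(seed = 6L, n_genes = 8L), d3)
  expect_false(identical(readLines(file.path(d1, "ref.fa")),
                         readLines(file.path(d3, "ref.fa"))))
})

test_that("simulated genes have canonical splice sites and clean ORFs", {
  fx <- shared_sim()
  ref <- fx$sim$reference
  for (m in ref$meta) {
    # GT..AG on the coding strand by construction
    expect_true(all(startsWith(m$intron_seqs, "GT")))
    expect_true(all(endsWith(m$intron_seqs, "AG")))
    # and on the genome after strand mapping
    ann <- fx$annotation
    it <- ann$introns[ann$introns$gene_id == m$gene_id, ][1, ]
    gseq <- as.character(Biostrings::subseq(ann$genome[["chr1"]],
                                            it$start, it$end))
    if (m$strand == "-")
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
    expect_identical(substr(gseq, 1, 2), "GT")
    expect_identical(substr(gseq, nchar(gseq) - 1, nchar(gseq)), "AG")
    # constitutive CDS: ATG start, terminal stop, no internal stop
    cds <- substr(m$exonic_seq, m$utr5 + 1, m$utr5 + m$cds_len)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("the conservation design fixes how many species share events", {
  cfg <- simulation_config(seed = 9L, n_genes = 40L, n_events = 20L,
                           conservation_design = c("1" = 0.5, "4" = 0.5))
  dir <- file.path(tempdir(), "consv")
  ref <- simulate_reference(cfg, dir)
  truth <- plant_events(ref, cfg)
  expect_identical(sum(truth$signatures$n_species == 4L), 10L)
  expect_identical(sum(truth$signatures$n_species == 1L), 10L)
  expect_identical(nrow(truth$signatures), 20L)
  # every 4-species signature appears in all four per-species sets
  quad <- truth$signatures[truth$signatures$n_species == 4L, ]
  for (i in seq_len(nrow(quad))) {
    hits <- truth$events[truth$events$gene_id == quad$gene_id[i], ]
    expect_setequal(hits$species_id, truth$species)
  }
})

test_that("a zero rate removes the type from the truth", {
  cfg <- simulation_config(seed = 3L, n_genes = 20L,
                           event_rates = c(IR = 1, ES = 0, AltD = 0,
                                           AltA = 0, AltP = 0))
  dir <- file.path(tempdir(), "ironly")
  ref <- simulate_reference(cfg, dir)
  truth <- plant_events(ref, cfg)
  expect_true(all(truth$signatures$event_type == "IR"))
})

test_that("planted intron-retention frame mix follows frac_ir_div3", {
  cfg <- simulation_config(seed = 13L, n_genes = 60L, n_events = 60L,
                           event_rates = c(IR = 1, ES = 0, AltD = 0,
                                           AltA = 0, AltP = 0),
                           frac_ir_div3 = 1)
  dir <- file.path(tempdir(), "div3")
  ref <- simulate_reference(cfg, dir)
  truth <- plant_events(ref, cfg)
  # frame-preserving wherever the gene offers a divisible intron (a
  # minority of genes have none, and fall back to any intron)
  expect_gt(mean(truth$signatures$event_length %% 3L == 0L), 0.7)
  expect_true(all(truth$signatures$frameshift ==
                    (truth$signatures$event_length %% 3L != 0L)))
  cfg0 <- simulation_config(seed = 13L, n_genes = 60L, n_events = 60L,
                            event_rates = c(IR = 1, ES = 0, AltD = 0,
                                            AltA = 0, AltP = 0),
                            frac_ir_div3 = 0)
  ref0 <- simulate_reference(cfg0, file.path(tempdir(), "div0"))
  truth0 <- plant_events(ref0, cfg0)
  expect_lt(mean(truth0$signatures$event_length %% 3L == 0L), 0.3)
})

test_that("planted events are realizable and labeled consistently", {
  fx <- shared_sim()
  truth <- fx$sim$truth$signatures
  ann <- fx$annotation
  # both outcomes occur under the default mixture
  expect_true(any(truth$ptc))
  expect_true(any(!truth$ptc))
  # every planted interval lies inside its gene span, in the CDS
  g <- ann$genes[match(truth$gene_id, ann$genes$gene_id), ]
  lo <- vapply(strsplit(truth$coords, "[-,]"), function(x)
    min(as.integer(x)), numeric(1))
  hi <- vapply(strsplit(truth$coords, "[-,]"), function(x)
    max(as.integer(x)), numeric(1))
  expect_true(all(lo >= g$span_start & hi <= g$span_end))
  expect_true(all(truth$region == "CDS"))
  expect_true(all(truth$event_length >= 1L))
  # frameshift label is consistent with the recorded length change
  expect_identical(truth$frameshift, (abs(truth$delta_len) %% 3L) != 0L)
})
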