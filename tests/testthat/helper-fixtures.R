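# Shared fixtures, built once per test run and cached in this environment.
.fixture_env <- new.env(parent = emptyenv())

# Two-gene toy reference with hand-chosen coordinates:
#   GA ('+'): exons 1-100, 201-300, 401-500; CDS 31-470
#   GB ('-'): exons 601-700, 801-900;        CDS 631-870
# Sequence is fixed-seed random; coordinates are what the tests assert on.
toy_reference <- function() {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  dir <- file.path(tempdir(), "ecasplice-toy")
  dir.create(dir, showWarnings = FALSE)
  set.seed(42)
  contig <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", contig), fasta)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t500\t.\t+\t.\tID=GA",
    "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=GA.1;Parent=GA",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tID=GA.1.e1;Parent=GA.1",
    "chr1\tt\texon\t201\t300\t.\t+\t.\tID=GA.1.e2;Parent=GA.1",
    "chr1\tt\texon\t401\t500\t.\t+\t.\tID=GA.1.e3;Parent=GA.1",
    "chr1\tt\tCDS\t31\t100\t.\t+\t.\tID=GA.1.c1;Parent=GA.1",
    "chr1\tt\tCDS\t201\t300\t.\t+\t.\tID=GA.1.c2;Parent=GA.1",
    "chr1\tt\tCDS\t401\t470\t.\t+\t.\tID=GA.1.c3;Parent=GA.1",
    "chr1\tt\tgene\t601\t900\t.\t-\t.\tID=GB",
    "chr1\tt\tmRNA\t601\t900\t.\t-\t.\tID=GB.1;Parent=GB",
    "chr1\tt\texon\t601\t700\t.\t-\t.\tID=GB.1.e1;Parent=GB.1",
    "chr1\tt\texon\t801\t900\t.\t-\t.\tID=GB.1.e2;Parent=GB.1",
    "chr1\tt\tCDS\t631\t700\t.\t-\t.\tID=GB.1.c1;Parent=GB.1",
    "chr1\tt\tCDS\t801\t870\t.\t-\t.\tID=GB.1.c2;Parent=GB.1"), gff)
  .fixture_env$toy <- list(fasta = fasta, gff = gff,
                           annotation = load_annotation(fasta, gff))
  .fixture_env$toy
}

# A small simulated four-species dataset shared by several test files.
shared_sim <- function() {
  if (!is.null(.fixture_env$sim)) return(.fixture_env$sim)
  dir <- file.path(tempdir(), "ecasplice-sim")
  cfg <- simulation_config(seed = 11L, n_genes = 40L)
  sim <- simulate_dataset(cfg, dir)
  ann <- load_annotation(sim$reference$fasta, sim$reference$gff3)
  .fixture_env$sim <- list(sim = sim, annotation = ann, config = cfg,
                           dir = dir)
  .fixture_env$sim
}

# Event rows in the caller's column layout, for tests that construct
# events directly.
make_event <- function(species_id, gene_id, event_type, coords,
                       obs_start = NA_integer_, obs_end = NA_integer_,
                       ref_start = NA_integer_, ref_end = NA_integer_,
                       event_length = 1L, region = "CDS") {
  data.frame(species_id = species_id, gene_id = gene_id,
             event_type = event_type, coords = coords,
             obs_start = obs_start, obs_end = obs_end,
             ref_start = ref_start, ref_end = ref_end,
             event_length = as.integer(event_length), region = region,
             stringsAsFactors = FALSE)
}

# Minimal SAM writer for hand-constructed alignment tests.
write_sam <- function(path, records, contig = "chr1", contig_len = 1000L) {
  lines <- c("@HD\tVN:1.6",
             paste0("@SQ\tSN:", contig, "\tLN:", contig_len))
  for (i in seq_along(records)) {
    r <- records[[i]]
    seq_field <- if (is.null(r$seq)) {
      w <- sum(as.integer(
        regmatches(r$cigar,
                   gregexpr("[0-9]+(?=[MI=X])", r$cigar, perl = TRUE))[[1]]))
      paste(rep("A", w), collapse = "")
    } else r$seq
    lines <- c(lines, paste(
      if (is.null(r$qname)) paste0("r", i) else r$qname,
      if (is.null(r$flag)) 0L else r$flag,
      contig, r$pos,
      if (is.null(r$mapq)) 60L else r$mapq,
      r$cigar, "*", 0L, 0L, seq_field, "*", sep = "\t"))
  }
  writeLines(lines, path)
  path
}
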