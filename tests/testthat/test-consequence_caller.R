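# Single-gene toy: exon ATGGGG, intron GTATAAAAG (9 bp), exon CCCTAA.
# The retained intron carries an in-frame TAA at codon 4.
cons_toy <- function(strand = "+") {
  dir <- tempdir()
  tx <- "ATGGGGGTATAAAAGCCCTAA"
  contig <- if (strand == "+") tx else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  fa <- file.path(dir, paste0("cons", strand, ".fa"))
  writeLines(c(">cc", contig), fa)
  gff <- file.path(dir, paste0("cons", strand, ".gff3"))
  writeLines(c("##gff-version 3",
    paste0("cc\tt\tgene\t1\t21\t.\t", strand, "\t.\tID=GT1"),
    paste0("cc\tt\tmRNA\t1\t21\t.\t", strand, "\t.\tID=GT1.1;Parent=GT1"),
    paste0("cc\tt\texon\t1\t6\t.\t", strand, "\t.\tID=e1;Parent=GT1.1"),
    paste0("cc\tt\texon\t16\t21\t.\t", strand, "\t.\tID=e2;Parent=GT1.1"),
    paste0("cc\tt\tCDS\t1\t6\t.\t", strand, "\t.\tID=c1;Parent=GT1.1"),
    paste0("cc\tt\tCDS\t16\t21\t.\t", strand, "\t.\tID=c2;Parent=GT1.1")),
    gff)
  load_annotation(fa, gff)
}

ir_toy_event <- function() {
  e <- make_event("spX", "GT1", "IR", "7-15", ref_start = 7L,
                  ref_end = 15L, event_length = 9L)
  e$contig <- NULL
  e
}

test_that("intron retention concatenates the intron into the CDS", {
  ann <- cons_toy("+")
  seqs <- build_alt_cds(ann, ir_toy_event())
  expect_identical(seqs$constitutive, "ATGGGGCCCTAA")
  expect_identical(seqs$alt, "ATGGGGGTATAAAAGCCCTAA")
  expect_identical(seqs$delta_len, 9L)
  call <- call_consequence(seqs$alt, seqs$constitutive)
  expect_true(call$ptc)
  expect_identical(call$ptc_position, 4L)   # TAA at codon 4
  expect_false(call$frameshift)             # delta 9
})

test_that("minus-strand genes give the same protein-level outcome", {
  ann <- cons_toy("-")
  seqs <- build_alt_cds(ann, ir_toy_event())
  expect_identical(seqs$constitutive, "ATGGGGCCCTAA")
  expect_identical(seqs$alt, "ATGGGGGTATAAAAGCCCTAA")
  call <- call_consequence(seqs$alt, seqs$constitutive)
  expect_true(call$ptc)
  expect_identical(call$ptc_position, 4L)
})

test_that("exon skipping shortens the CDS; terminal stop is not a PTC", {
  dir <- tempdir()
  # exons ATGGGG / CCGCTA / CCCTAA with 7 bp introns
  contig <- "ATGGGGGTCCCAGCCGCTAGTCCCAGCCCTAA"
  fa <- file.path(dir, "es.fa"); writeLines(c(">ce", contig), fa)
  gff <- file.path(dir, "es.gff3")
  writeLines(c("##gff-version 3",
    "ce\tt\tgene\t1\t32\t.\t+\t.\tID=GE1",
    "ce\tt\tmRNA\t1\t32\t.\t+\t.\tID=GE1.1;Parent=GE1",
    "ce\tt\texon\t1\t6\t.\t+\t.\tID=e1;Parent=GE1.1",
    "ce\tt\texon\t14\t19\t.\t+\t.\tID=e2;Parent=GE1.1",
    "ce\tt\texon\t27\t32\t.\t+\t.\tID=e3;Parent=GE1.1",
    "ce\tt\tCDS\t1\t6\t.\t+\t.\tID=c1;Parent=GE1.1",
    "ce\tt\tCDS\t14\t19\t.\t+\t.\tID=c2;Parent=GE1.1",
    "ce\tt\tCDS\t27\t32\t.\t+\t.\tID=c3;Parent=GE1.1"), gff)
  ann <- load_annotation(fa, gff)
  ev <- make_event("spX", "GE1", "ES", "14-19", obs_start = 7L,
                   obs_end = 26L, event_length = 6L)
  seqs <- build_alt_cds(ann, ev)
  expect_identical(seqs$constitutive, "ATGGGGCCGCTACCCTAA")
  expect_identical(seqs$alt, "ATGGGGCCCTAA")
  expect_identical(seqs$delta_len, -6L)
  call <- call_consequence(seqs$alt, seqs$constitutive)
  expect_false(call$ptc)        # the stop is the terminal codon
  expect_false(call$frameshift) # 6 is a multiple of 3
  # identity: no event applied
  same <- call_consequence(seqs$constitutive, seqs$constitutive)
  expect_false(same$ptc); expect_false(same$frameshift)
})

test_that("eligibility applies the three criteria", {
  ann <- cons_toy("+")
  one <- ir_toy_event()
  ok <- check_eligibility("GT1", one, ann)
  expect_true(ok$eligible)
  # two events in the gene
  two <- rbind(one, make_event("spX", "GT1", "AltD", "8-15",
                               obs_start = 8L, obs_end = 15L,
                               ref_start = 7L, ref_end = 15L))
  expect_false(check_eligibility("GT1", two, ann)$single_event)
  # event outside the coding region
  utr <- one; utr$region <- "3UTR"
  expect_false(check_eligibility("GT1", utr, ann)$in_cds)
  # event overlapping the start codon
  hit_start <- make_event("spX", "GT1", "ES", "1-6", obs_start = 1L,
                          obs_end = 6L, region = "CDS")
  expect_false(check_eligibility("GT1", hit_start,
                                 ann)$start_codon_intact)
})

test_that("frameshift is a pure function of the length change", {
  fx <- shared_sim()
  truth <- fx$sim$truth$signatures
  expect_identical(truth$frameshift, (abs(truth$delta_len) %% 3L) != 0L)
  # and the caller agrees on every planted gene
  cls <- classify_events(fx$sim$truth$events,
                         build_signatures(fx$sim$truth$events))
  calls <- consequence_calls(cls$events, fx$annotation)
  m <- match(calls$gene_id, truth$gene_id)
  expect_identical(calls$frameshift, (abs(calls$delta_len) %% 3L) != 0L)
  expect_identical(calls$delta_len, truth$delta_len[m])
})

test_that("PTC calls match the generator's independent translation oracle", {
  fx <- shared_sim()
  truth <- fx$sim$truth$signatures
  cls <- classify_events(fx$sim$truth$events,
                         build_signatures(fx$sim$truth$events))
  calls <- consequence_calls(cls$events, fx$annotation)
  expect_identical(nrow(calls), nrow(truth))  # all planted genes eligible
  m <- match(calls$gene_id, truth$gene_id)
  expect_identical(calls$ptc, truth$ptc[m])
  expect_identical(calls$frameshift, truth$frameshift[m])
})

test_that("outcome tables print two-decimal percentages that sum to 100", {
  calls <- data.frame(
    gene_id = sprintf("g%03d", 1:40),
    event_type = rep(c("IR", "ES"), each = 20),
    conservation = rep(c("ECAS", "non-ECAS"), 20),
    delta_len = 3L, frameshift = rep(c(TRUE, FALSE), c(15, 25)),
    ptc = rep(c(TRUE, FALSE), c(30, 10)), ptc_position = 1L,
    stringsAsFactors = FALSE)
  tabs <- consequence_tables(calls)
  nonzero <- tabs$ptc$n_yes + tabs$ptc$n_no > 0
  expect_true(all(abs(tabs$ptc$pct_yes[nonzero] +
                        tabs$ptc$pct_no[nonzero] - 100) <= 0.01))
  expect_equal(outcome_percentages(158, 43),
               c(pct_yes = 78.61, pct_no = 21.39))
  expect_equal(outcome_percentages(0, 0), c(pct_yes = 0, pct_no = 0))
})

test_that("the optional NMD-distance rule flags only distal stops", {
  ann <- cons_toy("+")
  seqs <- build_alt_cds(ann, ir_toy_event())
  # retained intron removes the junction: no junction downstream
  call <- call_consequence(seqs$alt, seqs$constitutive,
                           nmd_distance = 50L,
                           last_junction_tx = seqs$last_junction_tx)
  expect_true(call$ptc)
  expect_false(isTRUE(call$ptc_nmd))
})
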