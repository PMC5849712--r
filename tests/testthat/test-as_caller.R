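lib10 <- data.frame(species_id = "spX", total_mapped = 1e7,
                    uniquely_mapped = 9e6)

evidence_with <- function(junctions = NULL, coverage = NULL) {
  structure(list(
    junctions = if (is.null(junctions)) data.frame() else junctions,
    intron_coverage = if (is.null(coverage)) {
      data.frame(gene_id = character(), intron_index = integer(),
                 covered_bases = integer(), intron_reads = integer())
    } else coverage,
    exon_counts = data.frame(gene_id = character(),
                             exon_reads = integer()),
    library = lib10), class = "splice_evidence")
}

jrow <- function(start, end) {
  data.frame(contig = "chr1", intron_start = start, intron_end = end,
             support = 3L, min_overhang = 10L, distinct_positions = 2L,
             unique_support = 3L, stringsAsFactors = FALSE)
}

test_that("intron retention needs both read support and breadth", {
  ann <- toy_reference()$annotation
  cov <- function(cb, nr) data.frame(gene_id = "GA", intron_index = 1L,
                                     covered_bases = cb, intron_reads = nr)
  # GA intron 1 is 100 bp: 50/100 covered with 2 reads -> called
  ev <- call_ir(evidence_with(coverage = cov(50L, 2L)), ann)
  expect_identical(ev$event_type, "IR")
  expect_identical(ev$event_length, 100L)
  expect_identical(ev$region, "CDS")
  expect_identical(ev$coords, "101-200")
  # breadth 49% fails no matter the read count
  expect_identical(
    nrow(call_ir(evidence_with(coverage = cov(49L, 10L)), ann)), 0L)
  # support of 1 read fails at 10M mapped
  expect_identical(
    nrow(call_ir(evidence_with(coverage = cov(100L, 1L)), ann)), 0L)
  # unknown intron reference is an error
  expect_error(
    call_ir(evidence_with(coverage = data.frame(
      gene_id = "GA", intron_index = 9L, covered_bases = 10L,
      intron_reads = 2L)), ann), "unknown intron")
})

test_that("exon skipping joins non-adjacent annotated exon boundaries", {
  ann <- toy_reference()$annotation
  # junction 101-400 joins exon1/exon3 of GA, skipping exon2 (100 bp)
  es <- call_es(jrow(101L, 400L), ann, "spX")
  expect_identical(es$event_type, "ES")
  expect_identical(es$coords, "201-300")
  expect_identical(es$event_length, 100L)
  # annotated (constitutive) junction produces nothing
  expect_identical(nrow(call_es(jrow(101L, 200L), ann, "spX")), 0L)
  expect_identical(nrow(call_alt(jrow(101L, 200L), ann, "spX")), 0L)
})

test_that("multi-exon skips match a brute-force exon-pair enumeration", {
  # five-exon gene, junctions probing all boundary pairs
  dir <- tempdir()
  fa <- file.path(dir, "five.fa")
  set.seed(5)
  writeLines(c(">c5", paste(sample(c("A", "C", "G", "T"), 1000,
                                   replace = TRUE), collapse = "")), fa)
  gff <- file.path(dir, "five.gff3")
  ex_s <- c(1L, 201L, 401L, 601L, 801L)
  ex_e <- c(100L, 300L, 500L, 700L, 900L)
  writeLines(c("##gff-version 3",
    "c5\tt\tgene\t1\t900\t.\t+\t.\tID=GC",
    "c5\tt\tmRNA\t1\t900\t.\t+\t.\tID=GC.1;Parent=GC",
    paste0("c5\tt\texon\t", ex_s, "\t", ex_e,
           "\t.\t+\t.\tID=e", 1:5, ";Parent=GC.1"),
    "c5\tt\tCDS\t31\t100\t.\t+\t.\tID=c1;Parent=GC.1",
    "c5\tt\tCDS\t201\t300\t.\t+\t.\tID=c2;Parent=GC.1",
    "c5\tt\tCDS\t401\t500\t.\t+\t.\tID=c3;Parent=GC.1",
    "c5\tt\tCDS\t601\t700\t.\t+\t.\tID=c4;Parent=GC.1",
    "c5\tt\tCDS\t801\t870\t.\t+\t.\tID=c5;Parent=GC.1"), gff)
  ann <- load_annotation(fa, gff)
  # independent oracle: enumerate every exon pair (i, j), j >= i + 2
  oracle <- list()
  for (i in 1:5) for (j in 1:5) if (j >= i + 2) {
    oracle[[length(oracle) + 1L]] <- data.frame(
      js = ex_e[i] + 1L, je = ex_s[j] - 1L,
      skipped = paste(paste0(ex_s[(i + 1):(j - 1)], "-",
                             ex_e[(i + 1):(j - 1)]), collapse = ","),
      len = sum(ex_e[(i + 1):(j - 1)] - ex_s[(i + 1):(j - 1)] + 1L))
  }
  oracle <- do.call(rbind, oracle)
  jx <- do.call(rbind, lapply(seq_len(nrow(oracle)), function(k)
    jrow(oracle$js[k], oracle$je[k])))
  jx$contig <- "c5"
  es <- call_es(jx, ann, "spX")
  expect_identical(nrow(es), nrow(oracle))
  m <- match(paste(es$obs_start, es$obs_end),
             paste(oracle$js, oracle$je))
  expect_false(anyNA(m))
  expect_identical(es$coords, oracle$skipped[m])
  expect_identical(es$event_length, as.integer(oracle$len[m]))
  # a junction from exon1 to exon4 skips two exons as ONE event
  one <- call_es({j <- jrow(101L, 600L); j$contig <- "c5"; j}, ann, "spX")
  expect_identical(nrow(one), 1L)
  expect_identical(one$event_length, 200L)
})

test_that("alternative donor/acceptor/position shifts are measured in bp", {
  ann <- toy_reference()$annotation
  # '+' gene GA, annotated intron 101-200
  altd <- call_alt(jrow(109L, 200L), ann, "spX")
  expect_identical(altd$event_type, "AltD")
  expect_identical(altd$event_length, 8L)
  expect_identical(altd$ref_start, 101L)
  alta <- call_alt(jrow(101L, 212L), ann, "spX")
  expect_identical(alta$event_type, "AltA")
  expect_identical(alta$event_length, 12L)
  altp <- call_alt(jrow(95L, 205L), ann, "spX")
  expect_identical(altp$event_type, "AltP")
  expect_identical(altp$event_length, 11L)   # 6 + 5
})

test_that("AltD and AltA swap under strand reversal of the same shift", {
  ann <- toy_reference()$annotation
  # same physical change (genomic-left boundary moved): AltD on '+' GA,
  # AltA on '-' GB
  plus <- call_alt(jrow(109L, 200L), ann, "spX")
  minus <- call_alt(jrow(709L, 800L), ann, "spX")
  expect_identical(plus$event_type, "AltD")
  expect_identical(minus$event_type, "AltA")
  expect_identical(minus$event_length, 8L)
  # label swap flag transposes the convention
  swapped <- call_alt(jrow(109L, 200L), ann, "spX",
                      swap_alt_labels = TRUE)
  expect_identical(swapped$event_type, "AltA")
})

test_that("called events stay inside their gene and types partition", {
  fx <- shared_sim()
  ann <- fx$annotation
  ev <- extract_evidence(fx$sim$files$sp2$sam, ann, "sp2")
  events <- call_events(ev, ann)
  g <- ann$genes[match(events$gene_id, ann$genes$gene_id), ]
  lo <- vapply(strsplit(events$coords, "[-,]"), function(x)
    min(as.integer(x)), numeric(1))
  hi <- vapply(strsplit(events$coords, "[-,]"), function(x)
    max(as.integer(x)), numeric(1))
  expect_true(all(lo >= g$span_start & hi <= g$span_end))
  expect_false(any(events$region == "intergenic"))
  s <- summarize_as(events)
  expect_equal(sum(s$type_distribution$n), nrow(events))
  expect_equal(sum(s$type_distribution$percent), 100, tolerance = 0.02)
})

test_that("type shares follow the planted mixture and empty input is safe", {
  ev <- rbind(
    do.call(rbind, replicate(63, make_event("s1", "g1", "IR", "1-10"),
                             simplify = FALSE)),
    do.call(rbind, replicate(37, make_event("s1", "g2", "ES", "2-20"),
                             simplify = FALSE)))
  s <- summarize_as(ev)
  expect_equal(s$type_distribution$percent[
    s$type_distribution$event_type == "IR"], 63)
  empty <- summarize_as(ev[0, ])
  expect_identical(nrow(empty$type_distribution), 0L)
})
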