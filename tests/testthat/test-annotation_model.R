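test_that("loading derives introns and validates gene structure", {
  toy <- toy_reference()
  ann <- toy$annotation
  expect_s3_class(ann, "splice_annotation")
  # n exons -> n-1 introns
  expect_identical(sum(ann$exons$gene_id == "GA"), 3L)
  expect_identical(sum(ann$introns$gene_id == "GA"), 2L)
  ia <- ann$introns[ann$introns$gene_id == "GA", ]
  expect_equal(ia$start, c(101L, 301L))
  expect_equal(ia$end, c(200L, 400L))
  # '+' strand: donor at genomic start of the intron
  expect_equal(ia$donor_pos, ia$start)
  # '-' strand gene: donor/acceptor mirrored
  ib <- ann$introns[ann$introns$gene_id == "GB", ]
  expect_equal(ib$donor_pos, 800L)
  expect_equal(ib$acceptor_pos, 701L)
  # exon + intron lengths tile the gene span
  for (gid in ann$genes$gene_id) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    ex <- ann$exons[ann$exons$gene_id == gid, ]
    it <- ann$introns[ann$introns$gene_id == gid, ]
    expect_equal(sum(ex$end - ex$start + 1L) +
                   sum(it$end - it$start + 1L),
                 g$span_end - g$span_start + 1L)
  }
})

test_that("the longest model is retained, ties broken by model id", {
  dir <- tempdir()
  fa <- file.path(dir, "two_models.fa")
  writeLines(c(">c1", paste(rep("ACGT", 300), collapse = "")), fa)
  gff <- file.path(dir, "two_models.gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tgene\t1\t1000\t.\t+\t.\tID=G1",
    "c1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=G1.b;Parent=G1",
    "c1\tt\texon\t1\t300\t.\t+\t.\tID=e1;Parent=G1.b",
    "c1\tt\tCDS\t1\t300\t.\t+\t.\tID=c1a;Parent=G1.b",
    "c1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=G1.a;Parent=G1",
    "c1\tt\texon\t1\t200\t.\t+\t.\tID=e2;Parent=G1.a",
    "c1\tt\texon\t551\t800\t.\t+\t.\tID=e3;Parent=G1.a",
    "c1\tt\tCDS\t1\t200\t.\t+\t.\tID=c1b;Parent=G1.a"), gff)
  ann <- load_annotation(fa, gff)
  # 450 exonic bp beats 300
  expect_identical(ann$genes$model_id, "G1.a")
  expect_identical(ann$genes$exonic_len, 450L)
  # equal-length tie: lexicographically smallest model id wins
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tgene\t1\t1000\t.\t+\t.\tID=G1",
    "c1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=G1.b;Parent=G1",
    "c1\tt\texon\t1\t300\t.\t+\t.\tID=e1;Parent=G1.b",
    "c1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=G1.a;Parent=G1",
    "c1\tt\texon\t101\t400\t.\t+\t.\tID=e2;Parent=G1.a"), gff)
  ann2 <- load_annotation(fa, gff)
  expect_identical(ann2$genes$model_id, "G1.a")
})

test_that("structural errors are reported with context", {
  dir <- tempdir()
  fa <- file.path(dir, "bad.fa")
  writeLines(c(">c1", paste(rep("ACGT", 300), collapse = "")), fa)
  gff <- file.path(dir, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tt\tgene\t1\t400\t.\t+\t.\tID=G1",
    "c1\tt\tmRNA\t1\t400\t.\t+\t.\tID=G1.1;Parent=G1",
    "c1\tt\texon\t1\t200\t.\t+\t.\tID=e1;Parent=G1.1",
    "c1\tt\tCDS\t250\t350\t.\t+\t.\tID=c1;Parent=G1.1"), gff)
  expect_error(load_annotation(fa, gff), "CDS outside exon span.*G1")
  writeLines(c("##gff-version 3",
               "c1\tt\tgene\t1\t400",
               "c1\tt\tmRNA\t1\t400\t.\t+\t.\tID=G1.1;Parent=G1"), gff)
  expect_error(load_annotation(fa, gff), "line 2")
})

test_that("derive_introns handles strand and gene size", {
  plus <- derive_introns(
    data.frame(gene_id = "g", contig = "c", start = c(1L, 201L),
               end = c(100L, 300L)), "+")
  expect_equal(plus$start, 101L)
  expect_equal(plus$end, 200L)
  expect_equal(plus$donor_pos, 101L)
  expect_equal(plus$acceptor_pos, 200L)
  minus <- derive_introns(
    data.frame(gene_id = "g", contig = "c", start = c(201L, 1L),
               end = c(300L, 100L)), "-")
  expect_equal(minus$donor_pos, 200L)
  expect_equal(minus$acceptor_pos, 101L)
  four <- derive_introns(
    data.frame(gene_id = "g", contig = "c",
               start = c(1L, 201L, 401L, 601L),
               end = c(100L, 300L, 500L, 700L)), "+")
  expect_identical(nrow(four), 3L)
  single <- derive_introns(
    data.frame(gene_id = "g", contig = "c", start = 1L, end = 100L), "+")
  expect_identical(nrow(single), 0L)
})

test_that("classify_interval is exhaustive and strand-aware", {
  ann <- toy_reference()$annotation
  # GA '+': CDS 31-470
  expect_identical(classify_interval(ann, "chr1", 210, 260,
                                     gene_id = "GA"), "CDS")
  expect_identical(classify_interval(ann, "chr1", 5, 20,
                                     gene_id = "GA"), "5UTR")
  expect_identical(classify_interval(ann, "chr1", 480, 495,
                                     gene_id = "GA"), "3UTR")
  expect_identical(classify_interval(ann, "chr1", 20, 60,
                                     gene_id = "GA"), "5UTR-CDS")
  expect_identical(classify_interval(ann, "chr1", 450, 490,
                                     gene_id = "GA"), "CDS-3UTR")
  # GB '-': CDS 631-870; genomic-right of the CDS is the 5' side
  expect_identical(classify_interval(ann, "chr1", 880, 895,
                                     gene_id = "GB"), "5UTR")
  expect_identical(classify_interval(ann, "chr1", 610, 625,
                                     gene_id = "GB"), "3UTR")
  expect_identical(classify_interval(ann, "chr1", 860, 880,
                                     gene_id = "GB"), "5UTR-CDS")
  # outside every gene
  expect_identical(classify_interval(ann, "chr1", 950, 990), "intergenic")
  # exhaustiveness over random intervals
  set.seed(1)
  labels <- replicate(200, {
    s <- sample(1:990, 1); e <- s + sample(0:9, 1)
    classify_interval(ann, "chr1", s, e)
  })
  expect_true(all(labels %in% c("CDS", "5UTR", "3UTR", "5UTR-CDS",
                                "CDS-3UTR", "intergenic")))
})

test_that("GFF3 round-trip preserves the gene models", {
  toy <- toy_reference()
  ann <- toy$annotation
  out <- file.path(tempdir(), "roundtrip.gff3")
  write_gff3(ann, out)
  ann2 <- load_annotation(toy$fasta, out)
  expect_equal(ann$genes, ann2$genes)
  expect_equal(ann$exons, ann2$exons)
  expect_equal(ann$introns, ann2$introns)
})

test_that("annotation summary reports exon/intron/CDS sizes", {
  ann <- toy_reference()$annotation
  out <- file.path(tempdir(), "summary.tsv")
  write_annotation_summary(ann, out)
  s <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(s$n_exons[s$gene_id == "GA"], 3L)
  expect_equal(s$n_introns[s$gene_id == "GA"], 2L)
  # CDS 31-470 minus the two introns = 70 + 100 + 70
  expect_equal(s$cds_len[s$gene_id == "GA"], 240L)
})
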