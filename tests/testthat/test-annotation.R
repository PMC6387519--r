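write_gff <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

gene_line <- function(seq, type, s, e, strand, attrs) {
  paste(seq, "test", type, s, e, ".", strand, ".", attrs, sep = "\t")
}

test_that("feature index derives introns, TSS and merged exons", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 1001, 3000, "+", "ID=g1"),
    gene_line("chr1", "exon", 1001, 1200, "+", "ID=g1.e1;Parent=g1"),
    gene_line("chr1", "exon", 1801, 2000, "+", "ID=g1.e2;Parent=g1")))
  idx <- build_feature_index(gff)
  introns <- as.data.frame(idx$introns)
  expect_equal(introns$start, c(1201, 2001))
  expect_equal(introns$end, c(1800, 3000))
  expect_equal(idx$tss$pos, 1000)   # 0-based TSS
  expect_equal(idx$tss$strand, "+")
})

test_that("minus-strand genes place the TSS at the right edge", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 501, 900, "-", "ID=g1"),
    gene_line("chr1", "exon", 501, 900, "-", "ID=g1.e1;Parent=g1")))
  idx <- build_feature_index(gff)
  expect_equal(idx$tss$pos, 899)
  expect_equal(idx$tss$strand, "-")
})

test_that("overlapping isoform exons are merged before intron derivation", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 1, 1000, "+", "ID=g1"),
    gene_line("chr1", "exon", 1, 300, "+", "ID=e1;Parent=t1"),
    gene_line("chr1", "exon", 200, 450, "+", "ID=e2;Parent=t2"),
    gene_line("chr1", "exon", 800, 1000, "+", "ID=e3;Parent=t1")))
  idx <- build_feature_index(gff)
  ex <- as.data.frame(idx$exons)
  expect_equal(ex$start, c(1, 800))
  expect_equal(ex$end, c(450, 1000))
  introns <- as.data.frame(idx$introns)
  expect_equal(introns$start, 451)
  expect_equal(introns$end, 799)
})

test_that("genes without exon children become single-exon genes", {
  gff <- write_gff(gene_line("chr1", "gene", 101, 400, "+", "ID=g1"))
  expect_message(idx <- build_feature_index(gff), "single-exon")
  ex <- as.data.frame(idx$exons)
  expect_equal(c(ex$start, ex$end), c(101, 400))
  expect_equal(length(idx$introns), 0)
})

test_that("exons outside gene spans are clipped with a warning", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 101, 400, "+", "ID=g1"),
    gene_line("chr1", "exon", 51, 200, "+", "ID=e1;Parent=g1")))
  expect_warning(idx <- build_feature_index(gff), "clipped")
  ex <- as.data.frame(idx$exons)
  expect_equal(min(ex$start), 101)
})

test_that("region assignment follows exon > intron > intergenic precedence", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 1001, 3000, "+", "ID=g1"),
    gene_line("chr1", "exon", 1001, 1200, "+", "ID=g1.e1;Parent=g1"),
    gene_line("chr1", "exon", 1801, 2000, "+", "ID=g1.e2;Parent=g1")))
  idx <- build_feature_index(gff)
  rec <- tibble::tibble(
    seq_id = "chr1",
    start = c(1050L, 1194L, 1300L, 5000L),
    end = c(1062L, 1206L, 1312L, 5012L),
    repeat_class = "AC", actual_motif = "AC", k = 2L,
    length_bp = 12L, units = 6L)
  ann <- annotate_records(rec, idx)
  expect_equal(ann$region, c("exon", "exon", "intron", "intergenic"))
  expect_equal(ann$exon_overlap_pct[1], 100)
  # junction SSR: bases 1194..1199 exonic (exon ends at 0-based 1200) = 6/12
  expect_equal(ann$exon_overlap_pct[2], 50)
  expect_true(is.na(ann$exon_overlap_pct[3]))
  # SSR overlapping the TSS has distance 0
  tss0 <- annotate_records(tibble::tibble(
    seq_id = "chr1", start = 995L, end = 1007L, repeat_class = "AC",
    actual_motif = "AC", k = 2L, length_bp = 12L, units = 6L), idx)
  expect_equal(tss0$tss_distance, 0)
})

test_that("a planted intergenic repeat reports its exact TSS distance", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 25001, 27000, "+", "ID=g1"),
    gene_line("chr1", "exon", 25001, 27000, "+", "ID=g1.e1;Parent=g1")))
  idx <- build_feature_index(gff)
  # SSR [1489, 1501): last base 1500; TSS at 0-based 25000 -> 23500 bp away
  rec <- tibble::tibble(
    seq_id = "chr1", start = 1489L, end = 1501L, repeat_class = "AAAT",
    actual_motif = "AAAT", k = 4L, length_bp = 12L, units = 3L)
  ann <- annotate_records(rec, idx)
  expect_equal(ann$region, "intergenic")
  expect_equal(ann$tss_distance, 23500)
})

test_that("every SSR gets exactly one region and fractions partition", {
  set.seed(61)
  gm <- random_gene_models(40000, n_genes = 4)
  sp <- synthetic_genome_spec(
    "orgA", genome_length = 40000, seed = 55,
    planted_repeats = tibble::tibble(
      motif = rep(c("AC", "AAG", "AGAT", "A", "AACGTC"), 6),
      units = rep(c(8, 5, 4, 13, 3), 6)),
    gene_models = gm)
  g <- generate_genome(sp)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(g$gff, gff)
  rec <- scan_sequence(g$sequence, seq_id = "orgA_chr1")
  ann <- annotate_records(rec, build_feature_index(gff))
  expect_true(all(ann$region %in% c("exon", "intron", "intergenic")))
  expect_equal(nrow(ann), nrow(rec))
  comp <- region_composition(ann)
  sums <- tapply(comp$pct, comp$region, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  overall_bases <- sum(comp$bases[comp$region == "overall"])
  expect_equal(overall_bases, sum(ann$length_bp))
})

test_that("SSRs planted wholly inside exons all show complete exon overlap", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 1001, 2000, "+", "ID=g1"),
    gene_line("chr1", "exon", 1001, 2000, "+", "ID=g1.e1;Parent=g1")))
  idx <- build_feature_index(gff)
  rec <- tibble::tibble(
    seq_id = "chr1", start = seq(1000L, 1900L, by = 100L),
    repeat_class = "AC", actual_motif = "AC", k = 2L,
    length_bp = 12L, units = 6L) |>
    dplyr::mutate(end = start + 12L, .after = "start")
  ann <- annotate_records(rec, idx)
  expect_true(all(ann$region == "exon"))
  expect_true(all(ann$exon_overlap_pct == 100))
})

test_that("constructed motif-size mixture gives exact composition", {
  rec <- tibble::tibble(
    seq_id = "chr1", start = c(0L, 100L), end = c(60L, 140L),
    repeat_class = c("AAG", "AACGTC"), actual_motif = c("AAG", "AACGTC"),
    k = c(3L, 6L), length_bp = c(60L, 40L), units = c(20L, 6L),
    region = "exon", exon_overlap_pct = 100, tss_distance = 10)
  comp <- region_composition(rec)
  exon <- comp[comp$region == "exon", ]
  expect_equal(exon$pct[exon$k == 3], 60)
  expect_equal(exon$pct[exon$k == 6], 40)
  expect_equal(sum(exon$pct), 100)
})

test_that("paired test machinery detects a systematic exon deficit", {
  set.seed(71)
  detected <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    genomic <- stats::rbeta(10, 20, 60)          # per-organism proportions
    exonic <- genomic * 0.8 * stats::rlnorm(10, 0, 0.08)
    p <- ssr_t_test(exonic, genomic, paired = TRUE)$p.value
    if (!is.na(p) && p < 0.05 && mean(exonic) < mean(genomic)) {
      detected <- detected + 1
    }
  }
  expect_gt(detected / n_sim, 0.9)
})

test_that("unknown sequences are intergenic with warning or error on request", {
  gff <- write_gff(c(
    gene_line("chr1", "gene", 1, 100, "+", "ID=g1"),
    gene_line("chr1", "exon", 1, 100, "+", "ID=e;Parent=g1")))
  idx <- build_feature_index(gff)
  rec <- tibble::tibble(seq_id = "chrZ", start = 0L, end = 12L,
                        repeat_class = "AC", actual_motif = "AC", k = 2L,
                        length_bp = 12L, units = 6L)
  expect_warning(ann <- annotate_records(rec, idx), "intergenic")
  expect_equal(ann$region, "intergenic")
  expect_error(annotate_records(rec, idx, unknown_seq = "error"), "absent")
})
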