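reg_full <- load_registry("GRCh37")
site_a <- reg_full$sites[1, ]
snv <- reg_full$variants[1, ]
del <- reg_full$variants[2, ]

test_that("allele support pools reads mapped at either paralog locus", {
  recs <- c(
    covering_reads(10, site_a$smn1_position, site_a$smn1_allele, "smn1loc"),
    covering_reads(42, site_a$smn2_position, site_a$smn2_allele, "smn2ref"),
    covering_reads(5, site_a$smn2_position, site_a$smn1_allele, "mismap"))
  # sort by position (SMN2 locus < SMN1 locus on chr5)
  bam <- make_bam(recs[order(as.integer(sub(".*\t0\t5\t(\\d+)\t.*", "\\1",
                                            recs)))])
  dd <- count_discriminating_site(bam, site_a)
  expect_identical(dd, c(d1 = 15L, d2 = 42L))
})

test_that("reads carrying neither allele, N or low quality count in neither", {
  p <- site_a$smn1_position
  recs <- c(
    covering_reads(3, p, "N", "nn"),
    covering_reads(4, p, site_a$smn1_allele, "lowq", qual_char = "#"),
    covering_reads(2, p, "T", "other"))   # site-a alleles are A/G
  bam <- make_bam(recs)
  expect_identical(count_discriminating_site(bam, site_a),
                   c(d1 = 0L, d2 = 0L))
  # and an empty pileup is simply zero
  far <- make_bam(covering_reads(5, p + 100000L, "A", "far"))
  expect_identical(count_discriminating_site(far, site_a),
                   c(d1 = 0L, d2 = 0L))
})

test_that("overlapping mates are counted once, higher base quality wins", {
  p <- site_a$smn1_position
  start <- p - 50L
  mate1 <- sam_record("frag1", start, strrep(site_a$smn1_allele, 100L),
                      flag = 99L, qual = strrep("5", 100L))   # Q20, allele A
  mate2 <- sam_record("frag1", start, strrep(site_a$smn2_allele, 100L),
                      flag = 147L, qual = strrep("F", 100L))  # Q37, allele G
  bam <- make_bam(c(mate1, mate2))
  expect_identical(count_discriminating_site(bam, site_a),
                   c(d1 = 0L, d2 = 1L))
  # reversing the qualities flips the verdict
  mate1b <- sam_record("frag1", start, strrep(site_a$smn1_allele, 100L),
                       flag = 99L, qual = strrep("F", 100L))
  mate2b <- sam_record("frag1", start, strrep(site_a$smn2_allele, 100L),
                       flag = 147L, qual = strrep("5", 100L))
  bam2 <- make_bam(c(mate1b, mate2b))
  expect_identical(count_discriminating_site(bam2, site_a),
                   c(d1 = 1L, d2 = 0L))
})

test_that("flag filters drop duplicates/secondary but keep MAPQ 0", {
  p <- site_a$smn1_position
  recs <- c(
    covering_reads(6, p, site_a$smn1_allele, "keep", mapq = 0L),
    covering_reads(3, p, site_a$smn1_allele, "dup", flag = 1024L),
    covering_reads(2, p, site_a$smn1_allele, "sec", flag = 256L),
    covering_reads(2, p, site_a$smn1_allele, "supp", flag = 2048L),
    covering_reads(1, p, site_a$smn1_allele, "qcfail", flag = 512L))
  bam <- make_bam(recs)
  expect_identical(count_discriminating_site(bam, site_a),
                   c(d1 = 6L, d2 = 0L))
  lenient <- sma_read_filters(drop_duplicates = FALSE)
  expect_identical(count_discriminating_site(bam, site_a, lenient),
                   c(d1 = 9L, d2 = 0L))
})

test_that("mean gene depth averages per-base depth incl. zero positions", {
  iv <- data.frame(chromosome = "5", start = 1001, end = 1200,
                   gene_symbol = "X", role = "control")
  # uniform 10x
  bam <- make_bam(vapply(1:10, function(i) {
    sam_record(sprintf("u_%02d", i), 1001L, strrep("A", 200L))
  }, character(1)))
  expect_equal(mean_gene_depth(bam, iv), 10)
  # left half 10x, right half 20x -> mean 15
  recs <- c(vapply(1:10, function(i)
    sam_record(sprintf("l_%02d", i), 1001L, strrep("A", 100L)),
    character(1)),
    vapply(1:20, function(i)
      sam_record(sprintf("r_%02d", i), 1101L, strrep("A", 100L)),
      character(1)))
  bam <- make_bam(recs)
  expect_equal(mean_gene_depth(bam, iv), 15)
  # no reads at all -> zero
  empty <- make_bam(character(0))
  expect_equal(mean_gene_depth(empty, iv), 0)
})

test_that("mean depth matches a brute-force per-position oracle", {
  set.seed(401)
  iv <- data.frame(chromosome = "5", start = 5001, end = 5400)
  n <- 60L
  starts <- sample(4800:5400, n, replace = TRUE)
  lens <- sample(c(80L, 120L, 151L), n, replace = TRUE)
  recs <- vapply(seq_len(n), function(i) {
    sam_record(sprintf("o_%03d", i), starts[i], strrep("A", lens[i]))
  }, character(1))
  bam <- make_bam(recs[order(starts)])
  oracle <- mean(vapply(iv$start:iv$end, function(p) {
    sum(starts <= p & starts + lens - 1L >= p)
  }, numeric(1)))
  expect_equal(mean_gene_depth(bam, iv), oracle, tolerance = 1e-12)
})

test_that("SNV duplication variant counts alt-carrying spanning reads", {
  recs <- c(covering_reads(32, snv$start, snv$ref_allele, "ref"),
            covering_reads(8, snv$start, snv$alt_allele, "alt"))
  bam <- make_bam(recs)
  expect_identical(screen_duplication_variant(bam, snv),
                   c(supporting = 8L, covering = 40L))
})

test_that("2-bp deletion needs an alignment deleting both bases", {
  start <- del$start - 50L   # 50M before the deletion
  with_del <- vapply(1:6, function(i) {
    sam_record(sprintf("del_%02d", i), start, strrep("A", 100L),
               cigar = "50M2D50M")
  }, character(1))
  partial <- vapply(1:4, function(i) {   # deletes only the first base
    sam_record(sprintf("part_%02d", i), start, strrep("A", 100L),
               cigar = "50M1D50M")
  }, character(1))
  plain <- covering_reads(10, del$start, "A", "plain")  # same start
  bam <- make_bam(c(plain, with_del, partial))
  res <- screen_duplication_variant(bam, del)
  expect_identical(res[["supporting"]], 6L)
  expect_identical(res[["covering"]], 20L)
  # absence of the event
  bam2 <- make_bam(plain)
  expect_identical(screen_duplication_variant(bam2, del),
                   c(supporting = 0L, covering = 10L))
})

test_that("input contract errors are explicit", {
  reg <- test_registry()
  cram <- tempfile(fileext = ".cram")
  writeLines("x", cram)
  expect_error(collect_sample_counts(cram, reg),
               "reference FASTA is required")
  bam <- make_bam(covering_reads(2, site_a$smn1_position, "A", "idx"))
  file.remove(paste0(bam, ".bai"))
  expect_error(collect_sample_counts(bam, reg), "no index")
  bam2 <- make_bam(covering_reads(2, 500L, "A", "ctg", chrom = "1"),
                   contigs = c("1" = 249250621), name = "noctg")
  expect_error(count_discriminating_site(bam2, site_a),
               "not present in alignment header")
  expect_error(collect_sample_counts(tempfile(fileext = ".bam"), reg,
                                     sample_id = "gone"),
               "gone.*not found")
})

test_that("header-only alignments give all-zero counts", {
  reg <- test_registry()
  chroms <- unique(reg$genes$chromosome)
  bam <- make_bam(character(0),
                  contigs = stats::setNames(rep(2.5e8, length(chroms)),
                                            chroms),
                  name = "headeronly")
  cc <- collect_sample_counts(bam, reg)
  expect_true(all(cc$d1 == 0L) && all(cc$d2 == 0L))
  expect_equal(cc$smn1_mean_depth, 0)
  expect_true(all(cc$control_mean_depth == 0))
  expect_true(all(cc$dup_variant_support$covering == 0L))
})

test_that("extraction is deterministic and additive under file merging", {
  reg <- test_registry()
  dir <- withr::local_tempdir()
  g1 <- generate_sample(synthetic_sample_spec("m1", 2, 2, seed = 21),
                        reg, dir = dir)
  g2 <- generate_sample(synthetic_sample_spec("m2", 1, 2, seed = 22),
                        reg, dir = dir)
  c1 <- collect_sample_counts(g1$bam, reg)
  expect_identical(c1, collect_sample_counts(g1$bam, reg))
  c2 <- collect_sample_counts(g2$bam, reg)
  merged <- Rsamtools::mergeBam(c(g1$bam, g2$bam),
                                file.path(dir, "merged.bam"),
                                indexDestination = TRUE)
  cm <- collect_sample_counts(merged, reg)
  expect_identical(cm$d1, c1$d1 + c2$d1)
  expect_identical(cm$d2, c1$d2 + c2$d2)
  expect_equal(cm$smn1_mean_depth, c1$smn1_mean_depth + c2$smn1_mean_depth)
  expect_equal(cm$control_mean_depth,
               c1$control_mean_depth + c2$control_mean_depth)
  expect_identical(cm$dup_variant_support$covering,
                   c1$dup_variant_support$covering +
                     c2$dup_variant_support$covering)
  # d1 + d2 never exceeds the reads covering the two paralog positions
  expect_true(all(cm$d1 + cm$d2 <=
                    c1$d1 + c1$d2 + c2$d1 + c2$d2 + 0L))
})
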