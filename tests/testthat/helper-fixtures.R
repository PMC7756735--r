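# Shared fixture builders.  All alignment fixtures are generated in code at
# test time; nothing binary ships with the package.

# Truncated registry used by synthetic-data tests: small intervals keep
# fixtures fast while every statistic (built from *mean* depths) is
# interval-length invariant.
test_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- truncate_registry(load_registry("GRCh37"))
    reg
  }
})

# One SAM record with sensible defaults (150 bp not required; seq sets rl).
sam_record <- function(qname, pos, seq, chrom = "5", flag = 0L, mapq = 60L,
                       cigar = NULL, qual = NULL) {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, chrom, pos, mapq, cigar, seq, qual)
}

# Write records (already coordinate-sorted per contig) to an indexed BAM.
make_bam <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame()),
                     contigs = c("5" = 180915260), name = "fixture") {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(c(header, records), sam)
  Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                   indexDestination = TRUE)
}

# Reads of length `len` of one repeated base covering `pos` at its centre.
covering_reads <- function(n, position, base, prefix, len = 100L,
                           chrom = "5", mapq = 0L, qual_char = "F",
                           flag = 0L) {
  if (n == 0L) return(character(0))
  start <- position - len %/% 2L
  vapply(seq_len(n), function(i) {
    sam_record(sprintf("%s_%03d", prefix, i), start, strrep(base, len),
               chrom = chrom, mapq = mapq, flag = flag,
               qual = strrep(qual_char, len))
  }, character(1))
}

table3 <- data.frame(
  id = 1:7,
  pi_a = c(0.26, 0.29, 0.22, 0.32, 0.28, 0.30, 0.40),
  pi_b = c(0.19, 0.22, 0.22, 0.26, 0.26, 0.26, 0.32),
  pi_c = c(0.24, 0.29, 0.21, 0.23, 0.22, 0.25, 0.30),
  d1_a = c(13, 17, 15, 27, 25, 23, 23),
  d1_b = c(8, 14, 15, 18, 24, 22, 19),
  d1_c = c(11, 21, 13, 13, 20, 19, 18),
  d2_a = c(23, 46, 42, 42, 72, 65, 30),
  d2_b = c(23, 54, 41, 39, 78, 74, 36),
  d2_c = c(22, 57, 38, 33, 79, 68, 37),
  theta = c(0.741, 1.101, 0.842, 0.837, 1.109, 1.148, 0.936),
  cn = c("1:2", "1:3", "1:2", "1:2", "1:3", "1:3", "inconclusive"),
  stringsAsFactors = FALSE
)

# Hand-built per-sample counts object (for statistics tests that need no
# alignment file).
fake_counts <- function(sample_id, smn1_depth, smn2_depth, control_depth,
                        d1 = c(a = 30L, b = 30L, c = 30L),
                        d2 = c(a = 30L, b = 30L, c = 30L),
                        dup = NULL) {
  controls <- load_registry()$genes
  controls <- controls$gene_symbol[controls$role == "control"]
  if (length(control_depth) == 1L) control_depth <- rep(control_depth, 20L)
  control_depth <- stats::setNames(control_depth, controls)
  if (is.null(dup)) {
    dup <- data.frame(hgvs_label = c("g.27134T>G", "g.27706_27707delAT"),
                      supporting = c(0L, 0L), covering = c(30L, 30L),
                      stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, d1 = d1, d2 = d2,
                 smn1_mean_depth = smn1_depth,
                 smn2_mean_depth = smn2_depth,
                 control_mean_depth = control_depth,
                 dup_variant_support = dup),
            class = "smn_sample_counts")
}
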