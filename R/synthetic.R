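# GRCh37 primary-contig lengths for SAM headers (coordinates stay authentic
# even though fixture reads are confined to registry intervals).
GRCH37_CONTIG_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
)

#' Specification of one synthetic sample
#'
#' Describes the genotype and sequencing parameters used to emit a
#' synthetic aligned sample over the SMN locus and the control genes.
#' Defaults emulate a 30x short-read genome: each gene copy contributes
#' 15x (a diploid control gene therefore 30x), 150 bp single-end reads and
#' a small per-base error rate.
#'
#' @param sample_id Sample identifier (also the read-name prefix).
#' @param smn1_copies,smn2_copies Non-negative integer copy numbers.
#' @param silent_carrier_haplotype If \code{TRUE}, every SMN1-derived read
#'   carries the two duplication-associated polymorphisms (g.27134T>G and
#'   g.27706_27707delAT).
#' @param mean_depth_per_copy Depth contributed by each SMN gene copy
#'   (15 means a 2:2 sample totals 60x across the two loci).
#' @param read_length Read length in bp (>= 50).
#' @param base_error_rate Per-base substitution error probability.
#' @param control_depth Mean depth over each control gene.
#' @param mismap_fraction Fraction of SMN-origin reads placed at the
#'   \emph{other} paralog's locus (default 0.5, emulating the heavy
#'   cross-mapping between the near-identical genes).
#' @param seed Integer seed; the emitted file is a pure function of the
#'   spec (same spec, same bytes).
#' @return A list of class \code{smn_synthetic_spec}.
#' @export
synthetic_sample_spec <- function(sample_id, smn1_copies = 2L,
                                  smn2_copies = 2L,
                                  silent_carrier_haplotype = FALSE,
                                  mean_depth_per_copy = 15,
                                  read_length = 150L,
                                  base_error_rate = 0.002,
                                  control_depth = 30,
                                  mismap_fraction = 0.5,
                                  seed = 1L) {
  stopifnot(is.character(sample_id), nzchar(sample_id),
            smn1_copies >= 0L, smn2_copies >= 0L,
            mean_depth_per_copy > 0, control_depth > 0,
            read_length >= 50L,
            base_error_rate >= 0, base_error_rate < 1,
            mismap_fraction >= 0, mismap_fraction <= 1)
  structure(list(sample_id = sample_id,
                 smn1_copies = as.integer(smn1_copies),
                 smn2_copies = as.integer(smn2_copies),
                 silent_carrier_haplotype = isTRUE(silent_carrier_haplotype),
                 mean_depth_per_copy = mean_depth_per_copy,
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 control_depth = control_depth,
                 mismap_fraction = mismap_fraction,
                 seed = as.integer(seed)),
            class = "smn_synthetic_spec")
}

# Deterministic reference-like background base at each position.
background_base <- function(pos) {
  c("A", "C", "G", "T")[(pos %% 4L) + 1L]
}

# Tiling start positions giving ~`depth` mean coverage over [s, e] with
# reads of length rl: evenly spaced starts across [s - rl + 1, e].
tiling_starts <- function(s, e, rl, depth) {
  as.integer(round(seq(s - rl + 1, e, by = rl / depth)))
}

# Deterministic selection of ~fraction*n indices, spread evenly.
spread_select <- function(n, fraction) {
  sel <- logical(n)
  if (fraction >= 1) return(!sel | TRUE)
  if (fraction == 0.5) return(seq_len(n) %% 2L == 0L)
  k <- round(fraction * n)
  if (k > 0L) sel[unique(as.integer(round(seq(1, n, length.out = k))))] <- TRUE
  sel
}

#' Generate one synthetic aligned sample
#'
#' Emits a coordinate-sorted, indexed BAM whose header declares full
#' GRCh37 contig lengths.  Reads tile every registry gene interval on a
#' deterministic grid; SMN-origin reads carry their paralog's
#' discriminating alleles at sites a, b, c (and, for duplication
#' haplotypes, the two silent-carrier polymorphisms), and a
#' \code{mismap_fraction} of them is placed at the other paralog's locus
#' (deterministically interleaved, so the split is exact).  Seeded
#' randomness enters only through per-base sequencing errors.  The
#' returned \code{truth} is the generator's own bookkeeping over the
#' emitted read set (computed \emph{after} error application), as an
#' \code{smn_sample_counts}, so extraction can be checked field by field.
#'
#' @param spec A [synthetic_sample_spec()].
#' @param registry An \code{smn_registry}; for compact fixtures pass a
#'   [truncate_registry()] result.  The SMN1 and SMN2 intervals must be
#'   exact offset copies (true of the packaged registry).
#' @param dir Output directory.
#' @param contig_style \code{"plain"} writes GRCh37-style names ("5"),
#'   \code{"chr"} writes UCSC-style ("chr5").
#' @return List with \code{bam} (path), \code{truth}
#'   (\code{smn_sample_counts}) and \code{n_reads}.
#' @export
generate_sample <- function(spec, registry, dir = tempdir(),
                            contig_style = c("plain", "chr")) {
  stopifnot(inherits(spec, "smn_synthetic_spec"),
            inherits(registry, "smn_registry"))
  contig_style <- match.arg(contig_style)
  rl <- spec$read_length
  plain_off <- 0:(rl - 1L)

  genes <- registry$genes
  sites <- registry$sites
  variants <- registry$variants
  smn1 <- genes[genes$gene_symbol == "SMN1", ]
  smn2 <- genes[genes$gene_symbol == "SMN2", ]
  offset <- sites$smn1_position[1] - sites$smn2_position[1]
  if (smn1$start - smn2$start != offset || smn1$end - smn2$end != offset) {
    stop("registry SMN1/SMN2 intervals are not exact offset copies; ",
         "the generator requires the packaged interval layout",
         call. = FALSE)
  }
  snv <- variants[variants$variant_class == "SNV", ]
  del <- variants[variants$variant_class == "deletion", ]

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  cname <- function(chrom) {
    if (contig_style == "chr") paste0("chr", chrom) else chrom
  }
  overlap_len <- function(a1, a2, b1, b2) {
    pmax(0, pmin(a2, b2) - pmax(a1, b1) + 1)
  }
  qual_str <- strrep("F", rl)  # Phred 37 everywhere

  truth_d1 <- truth_d2 <- stats::setNames(integer(3), sites$label)
  truth_depth <- stats::setNames(numeric(nrow(genes)), genes$gene_symbol)
  snv_sup <- snv_cov <- del_sup <- del_cov <- 0L
  smn_lines <- character(0)
  n_reads <- 0L

  ## --- SMN reads, built in the SMN1 coordinate frame -------------------
  n_copies <- spec$smn1_copies + spec$smn2_copies
  if (n_copies > 0L) {
    starts1 <- tiling_starts(smn1$start, smn1$end, rl,
                             spec$mean_depth_per_copy)
    frame_pos <- rep(starts1, n_copies)
    origin <- rep(c(rep("SMN1", spec$smn1_copies),
                    rep("SMN2", spec$smn2_copies)), each = length(starts1))
    n <- length(frame_pos)
    mismap <- spread_select(n, spec$mismap_fraction)
    is_del <- spec$silent_carrier_haplotype & origin == "SMN1" &
      frame_pos <= del$start - 1L & frame_pos >= del$start - rl + 1L

    # frame positions covered by each read's query bases (deletion reads
    # skip the two deleted bases and span two extra reference positions)
    posm <- matrix(0L, n, rl)
    for (i in seq_len(n)) {
      p <- frame_pos[i]
      if (is_del[i]) {
        a <- del$start - p
        posm[i, ] <- p + c(seq_len(a) - 1L, (a + 2L):(rl + 1L))
      } else {
        posm[i, ] <- p + plain_off
      }
    }
    seqm <- matrix(background_base(posm), n, rl)
    for (j in seq_len(3)) {           # discriminating alleles by origin
      hit <- posm == sites$smn1_position[j]
      allele <- ifelse(origin == "SMN1", sites$smn1_allele[j],
                       sites$smn2_allele[j])
      seqm[hit] <- allele[row(posm)[hit]]
    }
    hit <- posm == snv$start          # duplication SNV / its ref base
    snv_base <- ifelse(spec$silent_carrier_haplotype & origin == "SMN1",
                       snv$alt_allele, snv$ref_allele)
    seqm[hit] <- snv_base[row(posm)[hit]]
    for (dpos in seq(del$start, del$end)) {   # ref AT on non-deleted reads
      hit <- posm == dpos
      seqm[hit] <- substr(del$ref_allele, dpos - del$start + 1L,
                          dpos - del$start + 1L)
    }
    if (spec$base_error_rate > 0) {   # seeded sequencing errors
      err <- which(stats::runif(n * rl) < spec$base_error_rate)
      if (length(err)) {
        subs <- c("A", "C", "G", "T")
        cur <- match(seqm[err], subs)
        seqm[err] <- subs[((cur - 1L +
                              sample(1:3, length(err), replace = TRUE)) %% 4L) + 1L]
      }
    }

    # bookkeeping: allele support at the sites is pooled over both loci,
    # so the mismap shift is irrelevant and frame coordinates suffice
    for (j in seq_len(3)) {
      sp <- sites$smn1_position[j]
      cov_i <- which(rowSums(posm == sp) > 0L)
      if (length(cov_i)) {
        col <- max.col(posm[cov_i, , drop = FALSE] == sp, "first")
        b <- seqm[cbind(cov_i, col)]
        truth_d1[j] <- sum(b == sites$smn1_allele[j])
        truth_d2[j] <- sum(b == sites$smn2_allele[j])
      }
    }
    shift <- ifelse(xor(origin == "SMN2", mismap), -offset, 0L)
    mapped_pos <- frame_pos + shift
    at_smn1 <- shift == 0L
    ref_end_frame <- frame_pos + rl - 1L + 2L * is_del

    in_interval <- function(rows) {
      sum(vapply(rows, function(i) {
        sum(posm[i, ] >= smn1$start & posm[i, ] <= smn1$end)
      }, numeric(1)))
    }
    truth_depth["SMN1"] <- in_interval(which(at_smn1)) /
      (smn1$end - smn1$start + 1)
    truth_depth["SMN2"] <- in_interval(which(!at_smn1)) /
      (smn2$end - smn2$start + 1)

    # duplication-variant screen truth (SMN1 locus, spanning fragments)
    spans_snv <- at_smn1 & frame_pos <= snv$start & ref_end_frame >= snv$end
    snv_cov <- sum(spans_snv)
    carries_alt <- logical(n)
    hit <- posm == snv$start
    carries_alt[unique(row(posm)[hit & seqm == snv$alt_allele])] <- TRUE
    snv_sup <- sum(spans_snv & carries_alt)
    spans_del <- at_smn1 & (is_del | (frame_pos <= del$start &
                                        ref_end_frame >= del$end))
    del_cov <- sum(spans_del)
    del_sup <- sum(is_del & at_smn1)

    cigar <- ifelse(is_del,
                    sprintf("%dM2D%dM", del$start - frame_pos,
                            rl - (del$start - frame_pos)),
                    sprintf("%dM", rl))
    seqs <- do.call(paste0, as.data.frame(seqm, stringsAsFactors = FALSE))
    qn <- sprintf("%s_smn_%06d", spec$sample_id, seq_len(n))
    smn_lines <- sprintf("%s\t0\t%s\t%d\t0\t%s\t*\t0\t0\t%s\t%s",
                         qn, cname(smn1$chromosome), mapped_pos, cigar,
                         seqs, qual_str)
    n_reads <- n
  }

  ## --- control-gene reads ----------------------------------------------
  ctrl <- genes[genes$role == "control", , drop = FALSE]
  ctrl_lines <- vector("list", nrow(ctrl))
  for (i in seq_len(nrow(ctrl))) {
    g <- ctrl[i, ]
    starts <- tiling_starts(g$start, g$end, rl, spec$control_depth)
    m <- length(starts)
    seqs <- vapply(starts, function(s) {
      paste(background_base(s + plain_off), collapse = "")
    }, character(1))
    qn <- sprintf("%s_%s_%06d", spec$sample_id, g$gene_symbol, seq_len(m))
    ctrl_lines[[i]] <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                               qn, cname(g$chromosome), starts, rl, seqs,
                               qual_str)
    truth_depth[g$gene_symbol] <-
      sum(overlap_len(starts, starts + rl - 1L, g$start, g$end)) /
      (g$end - g$start + 1)
    n_reads <- n_reads + m
  }

  ## --- assemble a sorted SAM and convert -------------------------------
  chroms <- unique(genes$chromosome)
  chroms <- chroms[order(match(chroms, names(GRCH37_CONTIG_LENGTHS)))]
  lens <- GRCH37_CONTIG_LENGTHS[chroms]
  lens[is.na(lens)] <- 3e8
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", cname(chroms), as.integer(lens)))
  body <- c(smn_lines, unlist(ctrl_lines))
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    rn <- vapply(fields, `[`, character(1), 3L)
    ps <- as.integer(vapply(fields, `[`, character(1), 4L))
    body <- body[order(match(rn, cname(chroms)), ps)]
  }
  sam <- file.path(dir, paste0(spec$sample_id, ".sam"))
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, spec$sample_id),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)

  truth <- structure(list(
    sample_id = spec$sample_id,
    d1 = truth_d1, d2 = truth_d2,
    smn1_mean_depth = truth_depth[["SMN1"]],
    smn2_mean_depth = truth_depth[["SMN2"]],
    control_mean_depth = truth_depth[ctrl$gene_symbol],
    dup_variant_support = data.frame(
      hgvs_label = variants$hgvs_label,
      supporting = ifelse(variants$variant_class == "SNV",
                          snv_sup, del_sup),
      covering = ifelse(variants$variant_class == "SNV",
                        snv_cov, del_cov),
      stringsAsFactors = FALSE)
  ), class = "smn_sample_counts")

  list(bam = bam, truth = truth, n_reads = n_reads)
}

#' Generate an indexed batch of synthetic samples
#'
#' Per-sample seeds are derived deterministically from \code{base_seed}
#' (\code{base_seed + 1000 * index}) unless \code{base_seed} is
#' \code{NULL}, in which case each spec's own seed is used; the truth
#' table is serialized alongside the BAMs as a TSV.
#'
#' @param specs List of [synthetic_sample_spec()] objects with unique
#'   sample ids.
#' @param registry An \code{smn_registry}.
#' @param dir Output directory (created if needed).
#' @param base_seed Optional integer master seed for the batch.
#' @return List with \code{bams} (named paths), \code{truth} (named list
#'   of \code{smn_sample_counts}) and \code{truth_tsv} (path).
#' @export
generate_batch <- function(specs, registry, dir = tempdir(),
                           base_seed = NULL) {
  if (length(specs) == 0L) stop("empty batch specification", call. = FALSE)
  ids <- vapply(specs, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!is.null(base_seed)) sp$seed <- as.integer(base_seed + 1000L * i)
    out[[i]] <- generate_sample(sp, registry, dir = dir)
  }
  truth <- lapply(out, `[[`, "truth")
  names(truth) <- ids
  tt <- do.call(rbind, lapply(truth, function(tr) {
    data.frame(sample_id = tr$sample_id,
               d1_a = tr$d1[["a"]], d1_b = tr$d1[["b"]], d1_c = tr$d1[["c"]],
               d2_a = tr$d2[["a"]], d2_b = tr$d2[["b"]], d2_c = tr$d2[["c"]],
               smn1_mean_depth = tr$smn1_mean_depth,
               smn2_mean_depth = tr$smn2_mean_depth,
               stringsAsFactors = FALSE)
  }))
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(tt, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bams = stats::setNames(vapply(out, `[[`, character(1), "bam"), ids),
       truth = truth, truth_tsv = truth_tsv)
}
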