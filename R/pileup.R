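#' Read-filter settings for pileup counting
#'
#' Defaults follow carrier-screening practice at a segmental duplication:
#' duplicate-flagged, secondary, supplementary, QC-fail and unmapped records
#' are excluded, but there is deliberately \emph{no} mapping-quality filter
#' (near-identical paralogs legitimately produce MAPQ-0 multi-mappers, and
#' discarding them would destroy the allele signal).  Base calls at
#' discriminating/variant positions must reach \code{min_base_quality}.
#'
#' @param min_base_quality Minimum Phred base quality for an allele call to
#'   count (default 13).
#' @param min_mapq Minimum mapping quality (default 0, i.e. keep
#'   multi-mappers).
#' @param drop_duplicates,drop_secondary,drop_supplementary,drop_qcfail
#'   Logical; exclude reads with the corresponding SAM flag.
#' @return A list of class \code{sma_read_filters}.
#' @export
sma_read_filters <- function(min_base_quality = 13L, min_mapq = 0L,
                             drop_duplicates = TRUE, drop_secondary = TRUE,
                             drop_supplementary = TRUE, drop_qcfail = TRUE) {
  stopifnot(min_base_quality >= 0L, min_mapq >= 0L)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapq = as.integer(min_mapq),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_supplementary = isTRUE(drop_supplementary),
                 drop_qcfail = isTRUE(drop_qcfail)),
            class = "sma_read_filters")
}

# Open an alignment file as a BamFile, checking format and index.  CRAM is
# accepted only with a reference FASTA and is converted through the system
# samtools, since Rsamtools reads BAM natively.
open_alignment <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "cram") {
    if (is.null(reference)) {
      stop("a reference FASTA is required to read CRAM file '", path, "'",
           call. = FALSE)
    }
    if (!file.exists(reference)) {
      stop("reference FASTA not found: ", reference, call. = FALSE)
    }
    samtools <- Sys.which("samtools")
    if (!nzchar(samtools)) {
      stop("CRAM input requires the 'samtools' executable on PATH",
           call. = FALSE)
    }
    bam <- tempfile(fileext = ".bam")
    status <- system2(samtools, c("view", "-b", "-T", shQuote(reference),
                                  "-o", shQuote(bam), shQuote(path)))
    if (status != 0L) stop("samtools failed to convert CRAM: ", path,
                           call. = FALSE)
    Rsamtools::indexBam(bam)
    path <- bam
  } else if (ext != "bam") {
    stop("unsupported alignment format '", ext, "' for ", path,
         " (BAM or CRAM expected)", call. = FALSE)
  }
  idx <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path),
           paste0(path, ".csi"))
  if (!any(file.exists(idx))) {
    stop("no index (.bai/.csi) found for alignment file: ", path,
         call. = FALSE)
  }
  Rsamtools::BamFile(path)
}

scan_flag <- function(filters) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (filters$drop_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filters$drop_supplementary) FALSE else NA,
    isDuplicate = if (filters$drop_duplicates) FALSE else NA,
    isNotPassingQualityControls = if (filters$drop_qcfail) FALSE else NA
  )
}

# Param construction is S4-heavy and identical for every sample of a
# batch, so built ScanBamParam objects are memoized per (header, ranges,
# filters, fields).
.param_cache <- new.env(parent = emptyenv())

# One multi-range query: fetch passing reads for every row of `ranges`
# (chromosome, start, end) in a single scanBam call, returning one plain
# list (fields of `what`, mapq-filtered) per range, in input order.
# seq/qual conversion is costly, so callers request only the fields they
# read.
scan_ranges <- function(bf, ranges, filters,
                        what = c("qname", "pos", "mapq", "cigar",
                                 "seq", "qual")) {
  contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  contig <- vapply(ranges$chromosome, resolve_contig, character(1),
                   header_contigs = contigs)
  ckey <- paste(c(contig, ranges$start, ranges$end, what,
                  unlist(filters)), collapse = "|")
  param <- .param_cache[[ckey]]
  if (is.null(param)) {
    param <- Rsamtools::ScanBamParam(
      flag = scan_flag(filters),
      what = unique(c(what, "mapq")),
      which = GenomicRanges::GRanges(contig,
                                     IRanges::IRanges(ranges$start,
                                                      ranges$end)))
    .param_cache[[ckey]] <- param
  }
  res <- Rsamtools::scanBam(bf, param = param)
  # scanBam groups ranges by seqname; restore input order by name
  key <- paste0(contig, ":", ranges$start, "-", ranges$end)
  stopifnot(!anyDuplicated(key), all(key %in% names(res)))
  res <- res[key]
  lapply(res, function(r) {
    keep <- !is.na(r$pos) & (is.na(r$mapq) | r$mapq >= filters$min_mapq)
    if ("cigar" %in% names(r)) keep <- keep & !is.na(r$cigar)
    out <- list(n = sum(keep))
    for (f in what) {
      v <- r[[f]]
      if (f %in% c("seq", "qual")) v <- as.character(v)
      out[[f]] <- v[keep]
    }
    out
  })
}

# Per-read base call at one reference position over a read list.  Returns
# base (NA when the position falls in a deletion/refskip, is soft-clipped
# or lies outside the alignment) and its Phred quality.
read_base_at <- function(reads, position) {
  n <- reads$n
  base <- rep(NA_character_, n)
  qual <- rep(NA_integer_, n)
  if (n == 0L) return(list(base = base, qual = qual))
  simple <- grepl("^[0-9]+M$", reads$cigar)  # fast path: ungapped reads
  if (any(simple)) {
    off <- position - reads$pos[simple]
    ok <- off >= 0L &
      off < as.integer(sub("M", "", reads$cigar[simple], fixed = TRUE))
    idx <- which(simple)[ok]
    o <- off[ok] + 1L
    base[idx] <- substr(reads$seq[idx], o, o)
    qual[idx] <- vapply(seq_along(idx), function(i) {
      utf8ToInt(substr(reads$qual[idx[i]], o[i], o[i])) - 33L
    }, integer(1))
  }
  for (i in which(!simple)) {
    ops <- GenomicAlignments::explodeCigarOps(reads$cigar[i])[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[i])[[1L]]
    rpos <- reads$pos[i]
    qpos <- 1L
    for (j in seq_along(ops)) {
      o <- ops[j]; l <- lens[j]
      if (o == "M" || o == "=" || o == "X") {
        if (position >= rpos && position < rpos + l) {
          k <- qpos + (position - rpos)
          base[i] <- substr(reads$seq[i], k, k)
          qual[i] <- utf8ToInt(substr(reads$qual[i], k, k)) - 33L
          break
        }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (o == "D" || o == "N") {
        if (position >= rpos && position < rpos + l) break  # deleted/skipped
        rpos <- rpos + l
      } else if (o == "I" || o == "S") {
        qpos <- qpos + l
      }                                   # H, P consume nothing
      if (rpos > position) break
    }
  }
  list(base = base, qual = qual)
}

# Fragment-level allele calls at one position: one entry per fragment
# (qname); when both mates cover the position the higher-base-quality call
# is kept, so a fragment is counted once.
fragment_base_at <- function(reads, position, min_base_quality) {
  calls <- read_base_at(reads, position)
  ok <- which(!is.na(calls$base) & calls$base != "N" &
                calls$qual >= min_base_quality)
  if (length(ok) == 0L) {
    return(list(qname = character(), base = character()))
  }
  ord <- ok[order(reads$qname[ok], -calls$qual[ok])]
  first <- ord[!duplicated(reads$qname[ord])]
  list(qname = reads$qname[first], base = calls$base[first])
}

# --- range-free cores (take pre-fetched read lists) ----------------------

site_counts_core <- function(reads_smn1, reads_smn2, site, min_base_quality) {
  b1 <- fragment_base_at(reads_smn1, site$smn1_position, min_base_quality)
  b2 <- fragment_base_at(reads_smn2, site$smn2_position, min_base_quality)
  # a fragment observed at both loci (e.g. mates split across paralogs)
  # still counts once
  qn <- c(b1$qname, b2$qname)
  bb <- c(b1$base, b2$base)[!duplicated(qn)]
  c(d1 = sum(bb == site$smn1_allele), d2 = sum(bb == site$smn2_allele))
}

mean_depth_core <- function(reads, start, end) {
  width <- end - start + 1
  if (reads$n == 0L) return(0)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  total <- 0
  if (any(simple)) {
    w <- as.integer(sub("M", "", reads$cigar[simple], fixed = TRUE))
    lo <- pmax(reads$pos[simple], start)
    hi <- pmin(reads$pos[simple] + w - 1L, end)
    total <- sum(pmax(0, hi - lo + 1))
  }
  if (!all(simple)) {
    rngs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      reads$cigar[!simple], pos = reads$pos[!simple],
      ops = c("M", "=", "X"))
    ir <- unlist(rngs, use.names = FALSE)
    lo <- pmax(IRanges::start(ir), start)
    hi <- pmin(IRanges::end(ir), end)
    total <- total + sum(pmax(0, hi - lo + 1))
  }
  total / width
}

variant_core <- function(reads, variant, min_base_quality) {
  if (reads$n == 0L) return(c(supporting = 0L, covering = 0L))
  ref_end <- reads$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar) - 1L
  spans <- reads$pos <= variant$start & ref_end >= variant$end
  covering <- length(unique(reads$qname[spans]))
  if (variant$variant_class == "SNV") {
    sub <- lapply(reads[c("qname", "pos", "cigar", "seq", "qual")],
                  `[`, spans)
    sub$n <- sum(spans)
    calls <- fragment_base_at(sub, variant$start, min_base_quality)
    supporting <- sum(calls$base == variant$alt_allele)
  } else {
    del <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      reads$cigar, pos = reads$pos, ops = "D")
    hit <- vapply(seq_len(reads$n), function(i) {
      r <- del[[i]]
      spans[i] && any(IRanges::start(r) <= variant$start &
                        IRanges::end(r) >= variant$end)
    }, logical(1))
    supporting <- length(unique(reads$qname[hit]))
  }
  c(supporting = as.integer(supporting), covering = as.integer(covering))
}

# -------------------------------------------------------------------------

#' Count paralog-discriminating allele support at one site
#'
#' Reads covering \emph{either} the SMN1 or the analogous SMN2 coordinate
#' are pooled: mismapping between the near-identical paralogs makes the
#' mapped locus uninformative, so only the base a read carries assigns it
#' to a paralog.  \code{d1} counts fragments carrying the SMN1 allele,
#' \code{d2} those carrying the SMN2 allele; fragments carrying neither
#' base (or a deletion, refskip, N, or sub-threshold base quality) count
#' in neither.  When both mates of a pair cover a position the
#' higher-base-quality call is used, so a fragment is counted once.
#'
#' @param alignment Path to an indexed BAM (or CRAM, see \code{reference}),
#'   or an open \code{BamFile}.
#' @param site One row of \code{registry$sites}.
#' @param filters A [sma_read_filters()] object.
#' @param reference Optional reference FASTA (required for CRAM).
#' @return Named integer vector \code{c(d1 = , d2 = )}.
#' @export
count_discriminating_site <- function(alignment, site,
                                      filters = sma_read_filters(),
                                      reference = NULL) {
  bf <- if (inherits(alignment, "BamFile")) alignment else
    open_alignment(alignment, reference)
  rr <- scan_ranges(bf, data.frame(
    chromosome = rep(site$chromosome, 2L),
    start = c(site$smn1_position, site$smn2_position),
    end = c(site$smn1_position, site$smn2_position)), filters)
  site_counts_core(rr[[1L]], rr[[2L]], site, filters$min_base_quality)
}

#' Mean depth of coverage over a gene interval
#'
#' Arithmetic mean of per-base aligned depth (passing reads; aligned
#' M/=/X bases, so deletions do not add depth) across every position of
#' the closed interval; zero-depth positions contribute zero.
#'
#' @inheritParams count_discriminating_site
#' @param interval One row of \code{registry$genes}.
#' @return A non-negative number.
#' @export
mean_gene_depth <- function(alignment, interval,
                            filters = sma_read_filters(),
                            reference = NULL) {
  bf <- if (inherits(alignment, "BamFile")) alignment else
    open_alignment(alignment, reference)
  rr <- scan_ranges(bf, data.frame(chromosome = interval$chromosome,
                                   start = interval$start,
                                   end = interval$end), filters,
                    what = c("pos", "cigar"))
  mean_depth_core(rr[[1L]], interval$start, interval$end)
}

#' Screen an SMN1-duplication polymorphism
#'
#' For the SNV, supporting fragments carry the alternate base at the
#' position; for the 2-bp deletion, a fragment supports only if its
#' alignment records a deletion spanning \emph{both} deleted bases
#' (partial overlap does not count).  Covering fragments are all passing
#' fragments whose alignment spans the whole variant locus.
#'
#' @inheritParams count_discriminating_site
#' @param variant One row of \code{registry$variants}.
#' @return Named integer vector \code{c(supporting = , covering = )}.
#' @export
screen_duplication_variant <- function(alignment, variant,
                                       filters = sma_read_filters(),
                                       reference = NULL) {
  bf <- if (inherits(alignment, "BamFile")) alignment else
    open_alignment(alignment, reference)
  rr <- scan_ranges(bf, data.frame(chromosome = variant$chromosome,
                                   start = variant$start,
                                   end = variant$end), filters)
  variant_core(rr[[1L]], variant, filters$min_base_quality)
}

#' Extract all per-sample raw measurements from one alignment file
#'
#' Composes [count_discriminating_site()], [mean_gene_depth()] and
#' [screen_duplication_variant()] over every registry entry, using two
#' multi-range index queries per file (allele-bearing positions with
#' sequences, gene intervals without).
#'
#' @inheritParams count_discriminating_site
#' @param registry An \code{smn_registry} from [load_registry()].
#' @param sample_id Sample identifier; defaults to the file basename
#'   without extension.
#' @return An object of class \code{smn_sample_counts}: a list with
#'   \code{sample_id}, named vectors \code{d1} and \code{d2} (sites a, b,
#'   c), \code{smn1_mean_depth}, \code{smn2_mean_depth}, named vector
#'   \code{control_mean_depth}, and data frame \code{dup_variant_support}
#'   (hgvs_label, supporting, covering).
#' @export
collect_sample_counts <- function(alignment, registry,
                                  filters = sma_read_filters(),
                                  reference = NULL, sample_id = NULL) {
  stopifnot(inherits(registry, "smn_registry"))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bam|cram)$", "", basename(alignment),
                     ignore.case = TRUE)
  }
  tryCatch({
    bf <- open_alignment(alignment, reference)
    sites <- registry$sites
    genes <- registry$genes
    variants <- registry$variants

    allele_ranges <- rbind(
      data.frame(chromosome = rep(sites$chromosome, 2L),
                 start = c(sites$smn1_position, sites$smn2_position),
                 end = c(sites$smn1_position, sites$smn2_position)),
      data.frame(chromosome = variants$chromosome, start = variants$start,
                 end = variants$end))
    ra <- scan_ranges(bf, allele_ranges, filters)
    rg <- scan_ranges(bf, data.frame(chromosome = genes$chromosome,
                                     start = genes$start, end = genes$end),
                      filters, what = c("pos", "cigar"))

    d1 <- d2 <- stats::setNames(integer(3), sites$label)
    for (j in seq_len(3)) {
      dd <- site_counts_core(ra[[j]], ra[[3L + j]], sites[j, ],
                             filters$min_base_quality)
      d1[j] <- dd[["d1"]]; d2[j] <- dd[["d2"]]
    }
    depth <- stats::setNames(numeric(nrow(genes)), genes$gene_symbol)
    for (k in seq_len(nrow(genes))) {
      depth[k] <- mean_depth_core(rg[[k]], genes$start[k], genes$end[k])
    }
    sup <- cov <- integer(nrow(variants))
    for (k in seq_len(nrow(variants))) {
      sc <- variant_core(ra[[6L + k]], variants[k, ],
                         filters$min_base_quality)
      sup[k] <- sc[["supporting"]]; cov[k] <- sc[["covering"]]
    }
    structure(list(
      sample_id = sample_id,
      d1 = d1, d2 = d2,
      smn1_mean_depth = depth[["SMN1"]],
      smn2_mean_depth = depth[["SMN2"]],
      control_mean_depth = depth[genes$role == "control"],
      dup_variant_support = data.frame(hgvs_label = variants$hgvs_label,
                                       supporting = sup, covering = cov,
                                       stringsAsFactors = FALSE)
    ), class = "smn_sample_counts")
  }, error = function(e) {
    stop("sample '", sample_id, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname collect_sample_counts
#' @param x,... An \code{smn_sample_counts} and ignored arguments.
#' @export
print.smn_sample_counts <- function(x, ...) {
  cat("sample", x$sample_id, "\n")
  cat("  D1 (SMN1 allele):", paste(names(x$d1), x$d1, sep = "=",
                                   collapse = " "), "\n")
  cat("  D2 (SMN2 allele):", paste(names(x$d2), x$d2, sep = "=",
                                   collapse = " "), "\n")
  cat(sprintf("  mean depth SMN1 %.2f, SMN2 %.2f, controls %.2f (median)\n",
              x$smn1_mean_depth, x$smn2_mean_depth,
              stats::median(x$control_mean_depth)))
  v <- x$dup_variant_support
  cat("  duplication variants:",
      paste(sprintf("%s %d/%d", v$hgvs_label, v$supporting, v$covering),
            collapse = "; "), "\n")
  invisible(x)
}
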