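#' Load the packaged SMN locus registry
#'
#' The registry bundles every genomic coordinate the method touches on
#' GRCh37: the three paralog-discriminating positions between \emph{SMN1}
#' and \emph{SMN2} (labelled \code{a}, \code{b}, \code{c}), the \emph{SMN1}
#' and \emph{SMN2} gene intervals plus the 20 control-gene intervals used
#' for depth normalization, and the two \emph{SMN1}-duplication-associated
#' polymorphisms (g.27134T>G and g.27706_27707delAT) used to tag silent
#' (2+0) carriers.
#'
#' Coordinates are stored 1-based inclusive.  Gene intervals are RefSeq
#' GRCh37 transcript spans; the source annotation is recorded in the header
#' of the packaged TSV (\code{system.file("extdata", "grch37_registry.tsv",
#' package = "smnscreen")}), which is parseable independently of this
#' package.
#'
#' @param build Genome build tag. Only \code{"GRCh37"} is bundled.
#' @param path Path to a registry TSV. Defaults to the packaged table;
#'   overriding it is intended for tests and for scaled-down fixture
#'   registries (see [truncate_registry()]).
#'
#' @return An object of class \code{smn_registry}: a list with data frames
#'   \code{sites} (label, chromosome, smn1_position, smn2_position,
#'   smn1_allele, smn2_allele), \code{genes} (gene_symbol, chromosome,
#'   start, end, role) and \code{variants} (hgvs_label, chromosome, start,
#'   end, variant_class, ref_allele, alt_allele).
#'
#' @examples
#' reg <- load_registry("GRCh37")
#' reg$sites
#' subset(reg$genes, role == "target")
#' @export
load_registry <- function(build = "GRCh37", path = NULL) {
  if (!identical(build, "GRCh37")) {
    stop("unsupported genome build '", build,
         "': only GRCh37 is bundled with this package", call. = FALSE)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "grch37_registry.tsv",
                        package = "smnscreen", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  num <- function(x) as.numeric(x)

  s <- raw[raw$record_type == "site", , drop = FALSE]
  sites <- data.frame(
    label = s$label,
    chromosome = s$chromosome,
    smn1_position = num(s$start),
    smn2_position = num(s$paired_position),
    smn1_allele = s$allele_smn1,
    smn2_allele = s$allele_smn2,
    stringsAsFactors = FALSE
  )
  g <- raw[raw$record_type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_symbol = g$label,
    chromosome = g$chromosome,
    start = num(g$start),
    end = num(g$end),
    role = g$role,
    stringsAsFactors = FALSE
  )
  v <- raw[raw$record_type == "variant", , drop = FALSE]
  variants <- data.frame(
    hgvs_label = v$label,
    chromosome = v$chromosome,
    start = num(v$start),
    end = num(v$end),
    variant_class = v$variant_class,
    ref_allele = v$allele_smn1,
    alt_allele = ifelse(v$alt_allele == "NA" | is.na(v$alt_allele),
                        "", v$alt_allele),
    stringsAsFactors = FALSE
  )
  reg <- structure(
    list(build = build, sites = sites, genes = genes, variants = variants),
    class = "smn_registry"
  )
  validate_registry(reg)
  reg
}

#' @rdname load_registry
#' @param x,... An \code{smn_registry} and ignored further arguments.
#' @export
print.smn_registry <- function(x, ...) {
  cat("SMN locus registry (", x$build, ")\n", sep = "")
  cat("  discriminating sites: ",
      paste(x$sites$label, collapse = ", "), "\n", sep = "")
  cat("  genes: ", sum(x$genes$role == "target"), " target, ",
      sum(x$genes$role == "control"), " control\n", sep = "")
  cat("  duplication variants: ",
      paste(x$variants$hgvs_label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Internal consistency checks; stops on a malformed registry.
validate_registry <- function(reg) {
  sites <- reg$sites; genes <- reg$genes; variants <- reg$variants
  stopifnot(
    nrow(sites) == 3L,
    identical(sort(sites$label), c("a", "b", "c")),
    all(sites$smn1_allele != sites$smn2_allele),
    all(nchar(sites$smn1_allele) == 1L),
    all(nchar(sites$smn2_allele) == 1L),
    nrow(genes[genes$role == "control", ]) == 20L,
    nrow(genes[genes$role == "target", ]) == 2L,
    all(c("SMN1", "SMN2") %in% genes$gene_symbol[genes$role == "target"]),
    all(genes$start < genes$end),
    nrow(variants) == 2L
  )
  smn1 <- genes[genes$gene_symbol == "SMN1", ]
  smn2 <- genes[genes$gene_symbol == "SMN2", ]
  stopifnot(
    smn1$chromosome == "5", smn2$chromosome == "5",
    all(sites$smn1_position >= smn1$start & sites$smn1_position <= smn1$end),
    all(sites$smn2_position >= smn2$start & sites$smn2_position <= smn2$end)
  )
  invisible(reg)
}

#' Shrink registry intervals for compact fixtures
#'
#' Returns a registry whose gene intervals are truncated: each control gene
#' keeps only its first \code{control_width} bases, and the \emph{SMN1} /
#' \emph{SMN2} intervals are reduced to a window that still contains all
#' three discriminating sites and both duplication variants (padded by
#' \code{smn_pad} bases on each side).  All batch statistics are
#' interval-length invariant (they are built from \emph{mean} depths), so a
#' truncated registry changes fixture size, not results.  Intended for
#' synthetic-data work; the packaged full-length registry remains the
#' contract for real alignments.
#'
#' @param registry An \code{smn_registry}.
#' @param control_width Width (bp) kept per control gene.
#' @param smn_pad Padding (bp) around the discriminating-site/variant window
#'   on each SMN gene.
#' @return A valid \code{smn_registry} with smaller intervals.
#' @export
truncate_registry <- function(registry, control_width = 400L, smn_pad = 150L) {
  stopifnot(inherits(registry, "smn_registry"),
            control_width >= 50L, smn_pad >= 0L)
  genes <- registry$genes
  ctrl <- genes$role == "control"
  genes$end[ctrl] <- pmin(genes$end[ctrl], genes$start[ctrl] + control_width - 1)

  sites <- registry$sites
  variants <- registry$variants
  lo1 <- min(sites$smn1_position, variants$start) - smn_pad
  hi1 <- max(sites$smn1_position, variants$end) + smn_pad
  offset <- sites$smn1_position[1] - sites$smn2_position[1]
  i1 <- which(genes$gene_symbol == "SMN1")
  i2 <- which(genes$gene_symbol == "SMN2")
  genes$start[i1] <- max(genes$start[i1], lo1)
  genes$end[i1] <- min(genes$end[i1], hi1)
  genes$start[i2] <- max(genes$start[i2], lo1 - offset)
  genes$end[i2] <- min(genes$end[i2], hi1 - offset)

  out <- registry
  out$genes <- genes
  validate_registry(out)
  out
}

# Resolve the contig name actually used by an alignment header: registries
# store bare GRCh37 names ("5") but headers may declare "chr5".
resolve_contig <- function(chromosome, header_contigs) {
  cands <- unique(c(chromosome, paste0("chr", chromosome),
                    sub("^chr", "", chromosome)))
  hit <- cands[cands %in% header_contigs]
  if (length(hit) == 0L) {
    stop("contig '", chromosome, "' (or alias) not present in alignment ",
         "header; available: ",
         paste(utils::head(header_contigs, 5), collapse = ", "),
         if (length(header_contigs) > 5) ", ...", call. = FALSE)
  }
  hit[[1L]]
}
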