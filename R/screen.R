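#' Screen a batch of alignment files for SMA carrier status
#'
#' The main entry point: extracts raw counts from every alignment
#' (optionally in parallel), performs the joint batch normalization, and
#' classifies each sample.  The batch is the estimation unit — scale
#' factors are relative to batch column means — so a batch should contain
#' mostly copy-number-normal samples; a warning is emitted when more than
#' 20\% of samples are flagged as carriers, since the normalization
#' anchor (batch average of about four total SMN copies) is then suspect.
#'
#' Extraction runs per sample and may run concurrently
#' (\code{ncpus > 1}); normalization and classification always run after
#' all extractions, and results are identical whatever the worker count.
#' In lenient mode (default) a failing sample is reported and excluded;
#' \code{strict = TRUE} aborts on the first failure.
#'
#' @param alignments Character vector of BAM/CRAM paths.
#' @param sample_ids Optional identifiers (default: file basenames
#'   without extension).
#' @param registry An \code{smn_registry} ([load_registry()] by default).
#' @param config A [sma_config()].
#' @param filters A [sma_read_filters()].
#' @param reference Reference FASTA (required for CRAM input).
#' @param ncpus Number of extraction workers (>= 1).
#' @param strict Abort on the first failing sample instead of skipping it.
#' @return Object of class \code{sma_screen}: list with \code{calls}
#'   (per-sample \code{smn_sample_call}s), \code{batch}
#'   (\code{smn_batch_stats}), \code{counts}, \code{errors} (named
#'   character vector for skipped samples) and \code{config}.
#' @examples
#' \dontrun{
#' reg <- load_registry("GRCh37")
#' res <- sma_screen(c("s1.bam", "s2.bam"), registry = reg)
#' summary(res)
#' write_sma_report(res, "report.tsv")
#' }
#' @export
sma_screen <- function(alignments, sample_ids = NULL,
                       registry = load_registry("GRCh37"),
                       config = sma_config(),
                       filters = sma_read_filters(),
                       reference = NULL, ncpus = 1L, strict = FALSE) {
  stopifnot(length(alignments) >= 1L, ncpus >= 1L)
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.(bam|cram)$", "", basename(alignments),
                      ignore.case = TRUE)
  }
  stopifnot(length(sample_ids) == length(alignments))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  extract_one <- function(i) {
    tryCatch(
      list(ok = TRUE,
           counts = collect_sample_counts(alignments[i], registry,
                                          filters = filters,
                                          reference = reference,
                                          sample_id = sample_ids[i])),
      error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- if (ncpus > 1L) {
    parallel::mclapply(seq_along(alignments), extract_one,
                       mc.cores = ncpus, mc.preschedule = TRUE)
  } else {
    lapply(seq_along(alignments), extract_one)
  }
  message(sprintf("extracted %d sample(s) in %.1fs", length(res),
                  proc.time()[["elapsed"]] - t0))
  ok <- vapply(res, `[[`, logical(1), "ok")
  errors <- vapply(res[!ok], `[[`, character(1), "message")
  names(errors) <- sample_ids[!ok]
  for (e in errors) message("ERROR: ", e)
  if (strict && any(!ok)) {
    stop("extraction failed in strict mode: ", errors[[1L]], call. = FALSE)
  }
  if (!any(ok)) stop("no valid samples in batch", call. = FALSE)

  counts <- lapply(res[ok], `[[`, "counts")
  batch <- compute_batch(counts, registry)
  calls <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    calls[[i]] <- classify_sample(counts[[i]], batch$theta[[i]],
                                  batch$pi[i, ], batch$raw_ratio[i, ],
                                  config)
  }
  names(calls) <- batch$sample_ids
  carrier_frac <- mean(vapply(calls, function(x)
    isTRUE(x$likely_carrier), logical(1)))
  if (carrier_frac > 0.2) {
    warning(sprintf(
      "%.0f%% of the batch is flagged as carrier; batch normalization ",
      100 * carrier_frac),
      "assumes an average total SMN copy number of ~4 and is likely ",
      "biased — interpret scale factors with caution", call. = FALSE)
  }
  structure(list(calls = calls, batch = batch, counts = counts,
                 errors = errors, config = config),
            class = "sma_screen")
}

#' @rdname sma_screen
#' @param x,object,... An \code{sma_screen} object and ignored arguments.
#' @export
print.sma_screen <- function(x, ...) {
  n <- length(x$calls)
  carriers <- sum(vapply(x$calls, function(cl) isTRUE(cl$likely_carrier),
                         logical(1)))
  silent <- sum(vapply(x$calls, `[[`, logical(1), "silent_carrier_flag"))
  cat("SMA carrier screen:", n, "sample(s);",
      carriers, "likely carrier(s);", silent, "silent-carrier flag(s)\n")
  if (length(x$errors)) {
    cat("skipped (extraction failed):",
        paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname sma_screen
#' @export
summary.sma_screen <- function(object, ...) {
  df <- as.data.frame(object)
  print(df[, c("id", "scale_factor", "pi_a", "pi_b", "pi_c",
               "CN_estimate", "likely_carrier", "silent_carrier")],
        row.names = FALSE, digits = 3)
  invisible(df)
}

#' Flatten screen results into the report table
#'
#' One row per sample in input order, with scaled proportions, raw
#' allele-support coverages, the scale factor, the copy-number estimate
#' and the duplication-variant screen.
#'
#' @param x An \code{sma_screen}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data.frame.
#' @export
as.data.frame.sma_screen <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- lapply(x$calls, function(cl) {
    cc <- x$counts[[match(cl$sample_id, vapply(x$counts, `[[`,
                                               character(1), "sample_id"))]]
    v <- cl$dup_variant_status
    data.frame(id = cl$sample_id,
               pi_a = cl$pi[["a"]], pi_b = cl$pi[["b"]], pi_c = cl$pi[["c"]],
               cov_SMN1_a = cc$d1[["a"]], cov_SMN1_b = cc$d1[["b"]],
               cov_SMN1_c = cc$d1[["c"]],
               cov_SMN2_a = cc$d2[["a"]], cov_SMN2_b = cc$d2[["b"]],
               cov_SMN2_c = cc$d2[["c"]],
               scale_factor = cl$theta,
               CN_estimate = cl$genotype_estimate,
               likely_carrier = cl$likely_carrier,
               silent_carrier = cl$silent_carrier_flag,
               dup_27134_support = v$supporting[1], dup_27134_covering = v$covering[1],
               dup_27706_support = v$supporting[2], dup_27706_covering = v$covering[2],
               notes = paste(cl$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-sample TSV report
#'
#' Scaled proportions and scale factors are printed to three decimals
#' (one more than the historical two-decimal display, whose
#' truncation-versus-rounding convention is ambiguous); raw counts stay
#' integers.
#'
#' @param x An \code{sma_screen}.
#' @param path Output TSV path.
#' @return Invisibly, the formatted data.frame.
#' @export
write_sma_report <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("pi_a", "pi_b", "pi_c", "scale_factor")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.3f", df[[col]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(df)
}

#' Command-line driver
#'
#' Thin argument-parsing layer over [sma_screen()] used by the installed
#' \code{inst/scripts/smn_screen.R} entry point; exposed as a function so
#' it can be called (and tested) in-process.
#'
#' @param argv Character vector of command-line arguments (positional
#'   alignment paths and options; see \code{--help}).
#' @return Invisibly, the exit status (0 on success).
#' @export
sma_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--manifest", type = "character", default = NULL,
                          help = "TSV with columns: alignment path [, sample id]"),
    optparse::make_option("--output", type = "character", default = "smn_screen.tsv",
                          help = "output report path [default %default]"),
    optparse::make_option("--reference", type = "character", default = NULL,
                          help = "reference FASTA (required for CRAM)"),
    optparse::make_option("--ncpus", type = "integer", default = 1L,
                          help = "extraction workers [default %default]"),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML classification-settings file"),
    optparse::make_option("--strict", action = "store_true", default = FALSE,
                          help = "abort on the first failing sample"),
    optparse::make_option("--version", action = "store_true", default = FALSE,
                          help = "print version and exit")
  )
  parser <- optparse::OptionParser(
    usage = "usage: smn_screen.R [options] alignment.bam [alignment2.bam ...]",
    option_list = spec)
  parsed <- optparse::parse_args(parser, args = argv,
                                 positional_arguments = TRUE)
  opts <- parsed$options
  if (opts$version) {
    cat("smnscreen", as.character(utils::packageVersion("smnscreen")), "\n")
    return(invisible(0L))
  }
  paths <- parsed$args
  ids <- NULL
  if (!is.null(opts$manifest)) {
    man <- utils::read.delim(opts$manifest, header = FALSE,
                             stringsAsFactors = FALSE)
    paths <- c(paths, man[[1L]])
    if (ncol(man) >= 2L) {
      ids <- c(sub("\\.(bam|cram)$", "",
                   basename(parsed$args), ignore.case = TRUE), man[[2L]])
    }
  }
  if (length(paths) == 0L) {
    optparse::print_help(parser)
    stop("no alignment files given", call. = FALSE)
  }
  config <- if (!is.null(opts$config)) read_sma_config(opts$config)
            else sma_config()
  res <- sma_screen(paths, sample_ids = ids, config = config,
                    reference = opts$reference, ncpus = opts$ncpus,
                    strict = opts$strict)
  write_sma_report(res, opts$output)
  message("report written to ", opts$output)
  invisible(0L)
}
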