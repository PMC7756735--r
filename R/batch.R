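#' Relative SMN coverage against each control gene
#'
#' For one sample, entry \eqn{k} is \eqn{Z_k = (c_1 + c_2) / H_k}: combined
#' mean SMN1 + SMN2 depth over the mean depth of control gene \eqn{k}.
#' Because the numerator sums both paralogs, \eqn{Z} tracks \emph{total}
#' SMN copy number and is insensitive to mismapping between them.
#'
#' @param counts An \code{smn_sample_counts} from [collect_sample_counts()].
#' @param control_order Character vector giving the control-gene order of
#'   the returned vector (defaults to the order stored in \code{counts}).
#' @return Named positive numeric vector of length K = 20.
#' @export
relative_coverage <- function(counts, control_order = NULL) {
  h <- counts$control_mean_depth
  if (!is.null(control_order)) {
    stopifnot(all(control_order %in% names(h)))
    h <- h[control_order]
  }
  if (any(h <= 0)) {
    stop("sample '", counts$sample_id, "': zero mean coverage on control ",
         "gene(s) ", paste(names(h)[h <= 0], collapse = ", "),
         "; exclude or re-sequence the sample (coverage is never imputed)",
         call. = FALSE)
  }
  (counts$smn1_mean_depth + counts$smn2_mean_depth) / h
}

#' Batch scale factors from the relative-coverage matrix
#'
#' Column means \eqn{\bar Z_k = \sum_i Z_{ki} / N} anchor each control gene
#' to the batch, and the per-sample scale factor is the mean normalized
#' relative coverage \eqn{\hat\theta_i = (\sum_k Z_{ki}/\bar Z_k)/K}.
#' \eqn{\hat\theta} is proportional to total SMN copy number when the batch
#' average total is (as in the general population) about four copies.
#' By construction \code{mean(theta) == 1}.
#'
#' @param z N x K matrix of positive relative coverages (rows = samples).
#' @return List with \code{z_bar} (length K) and \code{theta} (length N,
#'   named by rownames of \code{z}).
#' @export
scale_factors <- function(z) {
  z <- as.matrix(z)
  if (!is.numeric(z) || nrow(z) < 1L) {
    stop("z must be a numeric matrix with at least one row", call. = FALSE)
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("relative-coverage matrix must be strictly positive and finite",
         call. = FALSE)
  }
  z_bar <- colMeans(z)
  theta <- rowMeans(sweep(z, 2L, z_bar, "/"))
  list(z_bar = z_bar, theta = theta)
}

#' Scaled SMN1 read proportion at a discriminating site
#'
#' \eqn{\pi = \hat\theta \cdot D_1 / (D_1 + D_2)}: the raw SMN1 allele
#' fraction rescaled by the sample's total-copy-number factor, so that a
#' 2:2 genotype sits near 0.5 and a single-SMN1 carrier falls below 1/3.
#' With no covering reads the value is undefined and \code{NA} is returned
#' (never zero): downstream classification reports such samples
#' inconclusive rather than mistaking absence of data for absence of
#' allele.
#'
#' @param theta Positive scale factor \eqn{\hat\theta} of the sample.
#' @param d1,d2 Non-negative allele-support counts for the SMN1 and SMN2
#'   alleles.
#' @return A non-negative number, or \code{NA_real_} when d1 + d2 == 0.
#' @examples
#' scaled_proportion(0.842, 15, 42)  # ~0.22, a carrier-range value
#' @export
scaled_proportion <- function(theta, d1, d2) {
  stopifnot(is.numeric(theta), theta > 0)
  if (d1 < 0 || d2 < 0) stop("allele counts must be non-negative",
                             call. = FALSE)
  if (d1 + d2 == 0) return(NA_real_)
  theta * d1 / (d1 + d2)
}

#' Joint batch normalization over a set of samples
#'
#' Builds the N x K relative-coverage matrix from per-sample counts, the
#' batch column means and scale factors, and the N x 3 matrix of scaled
#' SMN1 proportions at sites a, b, c.  The batch is the estimation unit:
#' every sample's scale factor is relative to the same column means, so
#' results are identical whatever order samples are supplied in (rows
#' simply follow input order).
#'
#' @param all_counts List of \code{smn_sample_counts}.
#' @param registry An \code{smn_registry} (fixes control-gene order).
#' @return Object of class \code{smn_batch_stats}: list with
#'   \code{sample_ids}, \code{z} (N x K), \code{z_bar}, \code{theta},
#'   \code{pi} (N x 3, columns a, b, c; \code{NA} where undefined) and
#'   \code{raw_ratio} (N x 3 matrix of D1/D2, \code{NA} where D2 = 0).
#' @export
compute_batch <- function(all_counts, registry) {
  stopifnot(inherits(registry, "smn_registry"), length(all_counts) >= 1L)
  ids <- vapply(all_counts, function(x) x$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  controls <- registry$genes$gene_symbol[registry$genes$role == "control"]
  z <- t(vapply(all_counts, relative_coverage, numeric(length(controls)),
                control_order = controls))
  rownames(z) <- ids
  colnames(z) <- controls
  sf <- scale_factors(z)

  labels <- registry$sites$label
  pi_mat <- raw_ratio <- matrix(NA_real_, length(ids), 3,
                                dimnames = list(ids, labels))
  for (i in seq_along(all_counts)) {
    cc <- all_counts[[i]]
    for (j in seq_along(labels)) {
      d1 <- cc$d1[[labels[j]]]; d2 <- cc$d2[[labels[j]]]
      pi_mat[i, j] <- scaled_proportion(sf$theta[i], d1, d2)
      raw_ratio[i, j] <- if (d2 > 0) d1 / d2 else NA_real_
    }
  }
  structure(list(sample_ids = ids, z = z, z_bar = sf$z_bar,
                 theta = sf$theta, pi = pi_mat, raw_ratio = raw_ratio),
            class = "smn_batch_stats")
}

#' @rdname compute_batch
#' @param x,... An \code{smn_batch_stats} and ignored arguments.
#' @export
print.smn_batch_stats <- function(x, ...) {
  cat("SMN batch statistics: N =", length(x$sample_ids),
      "samples, K =", ncol(x$z), "control genes\n")
  df <- data.frame(theta = round(x$theta, 3), round(x$pi, 3))
  names(df)[-1] <- paste0("pi_", colnames(x$pi))
  print(utils::head(df, 10))
  if (length(x$sample_ids) > 10) cat("...", length(x$sample_ids) - 10,
                                     "more samples\n")
  invisible(x)
}
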