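#' Classification settings
#'
#' Tunable thresholds for carrier flagging, genotype estimation and
#' silent-carrier detection.  The genotype centroids encode the expected
#' joint behaviour of the scale factor and the raw SMN1/SMN2 allele ratio:
#' a 1:3 carrier keeps four total SMN copies (\eqn{\hat\theta \sim 1}) but
#' only one of four SMN1-like alleles at each site (ratio ~ 1/3); 1:2 gives
#' \eqn{\hat\theta \sim 0.75}, ratio ~ 1/2; 1:1 gives
#' \eqn{\hat\theta \sim 0.5}, ratio ~ 1.
#'
#' @param carrier_pi_threshold Flag a sample as likely carrier when the
#'   scaled SMN1 proportion falls below this at any site (default 1/3).
#' @param theta_centroids,ratio_centroids Named numeric vectors (names
#'   \code{"1:1"}, \code{"1:2"}, \code{"1:3"}) of expected scale factors
#'   and raw allele ratios per carrier genotype.
#' @param theta_tolerance,ratio_tolerance Maximum distance from a centroid
#'   component for a match (defaults 0.15).
#' @param silent_theta_targets Expected scale factors for duplication
#'   haplotypes (0.75 for 2:1, 0.5 for 2:0).
#' @param silent_pi_target Expected scaled proportion for a 2+\emph{n}
#'   duplication carrier (1/2).
#' @param silent_theta_tolerance,silent_pi_tolerance Matching tolerances
#'   for the silent-carrier rule (defaults 0.12).
#' @param variant_min_support,variant_min_fraction Minimum supporting reads
#'   (default 3) and supporting fraction of covering reads (default 0.08)
#'   for a duplication polymorphism to be called present.
#' @return A list of class \code{sma_config}.
#' @export
sma_config <- function(carrier_pi_threshold = 1 / 3,
                       theta_centroids = c("1:1" = 0.5, "1:2" = 0.75,
                                           "1:3" = 1.0),
                       ratio_centroids = c("1:1" = 1.0, "1:2" = 0.5,
                                           "1:3" = 1 / 3),
                       theta_tolerance = 0.15,
                       ratio_tolerance = 0.15,
                       silent_theta_targets = c(0.75, 0.5),
                       silent_pi_target = 0.5,
                       silent_theta_tolerance = 0.12,
                       silent_pi_tolerance = 0.12,
                       variant_min_support = 3L,
                       variant_min_fraction = 0.08) {
  genos <- c("1:1", "1:2", "1:3")
  stopifnot(carrier_pi_threshold > 0,
            identical(sort(names(theta_centroids)), genos),
            identical(sort(names(ratio_centroids)), genos),
            theta_tolerance > 0, ratio_tolerance > 0,
            silent_theta_tolerance > 0, silent_pi_tolerance > 0,
            variant_min_support >= 0, variant_min_fraction >= 0)
  structure(list(carrier_pi_threshold = carrier_pi_threshold,
                 theta_centroids = theta_centroids[genos],
                 ratio_centroids = ratio_centroids[genos],
                 theta_tolerance = theta_tolerance,
                 ratio_tolerance = ratio_tolerance,
                 silent_theta_targets = silent_theta_targets,
                 silent_pi_target = silent_pi_target,
                 silent_theta_tolerance = silent_theta_tolerance,
                 silent_pi_tolerance = silent_pi_tolerance,
                 variant_min_support = as.integer(variant_min_support),
                 variant_min_fraction = variant_min_fraction),
            class = "sma_config")
}

#' Read classification settings from a key-value (YAML) file
#'
#' Keys missing from the file keep their [sma_config()] defaults; centroid
#' maps may be given as named lists.
#'
#' @param path Path to a YAML file of \code{key: value} pairs.
#' @return A \code{sma_config}.
#' @export
read_sma_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- formals(sma_config)
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(sma_config, vals)
}

#' Likely-carrier rule
#'
#' A sample is flagged as a likely SMA carrier when its scaled SMN1
#' proportion is below the threshold (default 1/3) at \emph{any} of the
#' three discriminating sites.  The any-site reading matters: a carrier
#' can sit above 1/3 at one noisy site while two sites are clearly low.
#'
#' @param pi Numeric vector of the three scaled proportions (a, b, c);
#'   must be defined (handle missing values upstream).
#' @param config A [sma_config()].
#' @return Logical.
#' @export
call_carrier <- function(pi, config = sma_config()) {
  stopifnot(length(pi) == 3L, !anyNA(pi))
  any(pi < config$carrier_pi_threshold)
}

#' Absolute SMN1:SMN2 genotype estimation for a likely carrier
#'
#' The median raw allele ratio D1/D2 across the three sites selects
#' candidate genotypes (those whose ratio centroid lies within
#' \code{ratio_tolerance}); among candidates the one whose expected scale
#' factor is closest to the observed \eqn{\hat\theta} wins, provided it is
#' within \code{theta_tolerance}.  When the ratios match no centroid, or
#' the \eqn{\hat\theta} check fails for every ratio-compatible genotype
#' (i.e. the two signals vote for different genotypes), the estimate is
#' \code{"inconclusive"}.  The median (not the mean) of the three ratios
#' is used, for robustness to one noisy site.
#'
#' @param theta Scale factor \eqn{\hat\theta} of the sample.
#' @param raw_ratios Numeric vector of the three D1/D2 ratios (a, b, c);
#'   \code{NA} entries (D2 = 0) are dropped from the median.
#' @param config A [sma_config()].
#' @return One of \code{"1:1"}, \code{"1:2"}, \code{"1:3"},
#'   \code{"inconclusive"}.
#' @export
estimate_genotype <- function(theta, raw_ratios, config = sma_config()) {
  stopifnot(length(raw_ratios) == 3L)
  r <- stats::median(raw_ratios, na.rm = TRUE)
  if (!is.finite(r)) return("inconclusive")
  cand <- names(config$ratio_centroids)[
    abs(config$ratio_centroids - r) <= config$ratio_tolerance]
  if (length(cand) == 0L) return("inconclusive")
  dtheta <- abs(config$theta_centroids[cand] - theta)
  best <- cand[which.min(dtheta)]
  if (min(dtheta) > config$theta_tolerance) return("inconclusive")
  best
}

#' Silent-carrier (2+0 / 2+1) detection
#'
#' A duplication haplotype carrying two SMN1 copies in cis is invisible to
#' plain copy counting; it is tagged by two polymorphisms (g.27134T>G and
#' g.27706_27707delAT).  The flag is raised only when \emph{both} variants
#' are present (enough supporting reads and supporting fraction), the
#' scale factor is near 0.75 (2:1) or 0.5 (2:0), and every scaled SMN1
#' proportion is near 1/2.
#'
#' @param counts An \code{smn_sample_counts} (for the variant screen).
#' @param theta Scale factor of the sample.
#' @param pi Numeric vector of the three scaled proportions (may contain
#'   \code{NA}; any missing value prevents the flag).
#' @param config A [sma_config()].
#' @return List with \code{flag} (logical) and \code{notes} (character
#'   vector recording which conditions matched or failed).
#' @export
detect_silent_carrier <- function(counts, theta, pi, config = sma_config()) {
  v <- counts$dup_variant_support
  notes <- character()
  present <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (v$covering[i] == 0L) {
      notes <- c(notes, paste0(v$hgvs_label[i],
                               " unassessable (no covering reads)"))
      present[i] <- FALSE
    } else {
      present[i] <- v$supporting[i] >= config$variant_min_support &&
        v$supporting[i] / v$covering[i] >= config$variant_min_fraction
      notes <- c(notes, sprintf("%s %s (%d/%d)", v$hgvs_label[i],
                                if (present[i]) "present" else "absent",
                                v$supporting[i], v$covering[i]))
    }
  }
  if (!all(present)) {
    return(list(flag = FALSE, notes = notes))
  }
  theta_ok <- any(abs(config$silent_theta_targets - theta) <=
                    config$silent_theta_tolerance)
  if (!theta_ok) {
    notes <- c(notes, sprintf(
      "theta %.3f inconsistent with 2+0/2+1 (expected ~%s)", theta,
      paste(config$silent_theta_targets, collapse = " or ")))
  }
  pi_ok <- !anyNA(pi) && all(abs(pi - config$silent_pi_target) <=
                               config$silent_pi_tolerance)
  if (!pi_ok) {
    notes <- c(notes, "scaled proportions not all near 1/2")
  }
  list(flag = theta_ok && pi_ok, notes = notes)
}

#' Classify one sample from its counts and batch statistics
#'
#' Composes the likely-carrier rule, genotype estimation and
#' silent-carrier detection.  Samples that are not flagged still report
#' their scale factor, scaled proportions and variant screen ("screened
#' and reported"); samples with an undefined scaled proportion are
#' reported inconclusive, never silently classified.
#'
#' @param counts An \code{smn_sample_counts}.
#' @param theta Scale factor of this sample from [compute_batch()].
#' @param pi Numeric vector of the three scaled proportions for this
#'   sample (may contain \code{NA}).
#' @param raw_ratios Numeric vector of the three D1/D2 ratios.
#' @param config A [sma_config()].
#' @return Object of class \code{smn_sample_call}: list with
#'   \code{sample_id}, \code{theta}, \code{pi}, \code{raw_ratios},
#'   \code{likely_carrier}, \code{genotype_estimate} (\code{"1:1"},
#'   \code{"1:2"}, \code{"1:3"}, \code{"inconclusive"} or
#'   \code{"not-carrier"}), \code{silent_carrier_flag},
#'   \code{dup_variant_status} and \code{notes}.
#' @export
classify_sample <- function(counts, theta, pi, raw_ratios,
                            config = sma_config()) {
  notes <- character()
  if (anyNA(pi)) {
    likely <- NA
    genotype <- "inconclusive"
    notes <- c(notes, paste0(
      "undefined scaled proportion at site(s) ",
      paste(names(pi)[is.na(pi)], collapse = ", "),
      " (no covering reads); sample inconclusive"))
  } else {
    likely <- call_carrier(pi, config)
    genotype <- if (likely) estimate_genotype(theta, raw_ratios, config)
                else "not-carrier"
    if (all(pi < 0.05)) {
      notes <- c(notes, paste0(
        "all scaled proportions near zero: possible absence of SMN1 ",
        "(SMA-affected pattern, not a validated call)"))
    }
  }
  silent <- detect_silent_carrier(counts, theta, pi, config)
  v <- counts$dup_variant_support
  v$present <- v$covering > 0L &
    v$supporting >= config$variant_min_support &
    v$supporting / pmax(v$covering, 1L) >= config$variant_min_fraction
  structure(list(sample_id = counts$sample_id,
                 theta = theta, pi = pi, raw_ratios = raw_ratios,
                 likely_carrier = likely,
                 genotype_estimate = genotype,
                 silent_carrier_flag = silent$flag,
                 dup_variant_status = v,
                 notes = c(notes, silent$notes)),
            class = "smn_sample_call")
}

#' @rdname classify_sample
#' @param x,... An \code{smn_sample_call} and ignored arguments.
#' @export
print.smn_sample_call <- function(x, ...) {
  cat("sample", x$sample_id, "\n")
  cat(sprintf("  theta %.3f; pi %s\n", x$theta,
              paste(names(x$pi), sprintf("%.3f", x$pi), sep = "=",
                    collapse = " ")))
  cat("  likely carrier:", x$likely_carrier,
      " genotype:", x$genotype_estimate,
      " silent-carrier flag:", x$silent_carrier_flag, "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
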