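# Preprocessing chain: blank-peak removal and QC drift correction on the
# full injection set, sample filtering, isomer deduplication, log2 +
# quantile normalization, half-minimum imputation.

#' Keep study samples with a known tissue
#'
#' Drops blanks, QCs and any study sample without location information.
#'
#' @param d a `met_dataset`
#' @return the filtered `met_dataset`
#' @export
filter_samples <- function(d) {
  keep <- d$samples$role == "study" & d$samples$tissue != "none"
  if (!any(keep)) stop("no study samples with a known tissue remain")
  subset_samples(d, which(keep))
}

#' Remove blank-dominant peaks
#'
#' A metabolite is removed when its median study intensity fails to exceed
#' `ratio_threshold` times its median blank intensity. Metabolites absent
#' from the blanks (all missing or zero) are always kept. With no blank
#' samples present the dataset is returned unchanged with a warning.
#'
#' @param d a raw-scale `met_dataset` still containing blank samples
#' @param ratio_threshold positive fold-over-blank requirement (default 3)
#' @return list: `dataset` (peaks removed) and `removed` (metabolite ids)
#' @export
remove_blank_peaks <- function(d, ratio_threshold = 3) {
  stopifnot(ratio_threshold > 0)
  blank <- d$samples$role == "blank"
  if (!any(blank)) {
    warning("no blank samples present; blank-peak removal skipped")
    return(list(dataset = d, removed = character(0)))
  }
  study <- d$samples$role == "study" & d$samples$tissue != "none"
  med_blank <- apply(d$abundance[blank, , drop = FALSE], 2, stats::median,
                     na.rm = TRUE)
  med_study <- apply(d$abundance[study, , drop = FALSE], 2, stats::median,
                     na.rm = TRUE)
  absent <- is.na(med_blank) | med_blank == 0
  drop <- !absent & !is.na(med_study) & med_study < ratio_threshold * med_blank
  removed <- d$metabolites$metabolite_id[drop]
  list(dataset = subset_metabolites(d, which(!drop)), removed = removed)
}

#' Correct linear instrument drift using QC injections
#'
#' Per metabolite, log2 QC intensity is regressed on injection order and
#' every sample's intensity is divided by the fitted trend at its own
#' injection order, rescaled so the mean QC level is preserved
#' (`raw * 2^(-b * (order - mean QC order))`). After correction the QC
#' trend of a drift-only metabolite is flat. Metabolites with fewer than
#' three usable QC values are left uncorrected; with fewer than three QC
#' samples overall the dataset is returned unchanged with a warning.
#'
#' @param d a raw-scale `met_dataset` containing QC samples with injection
#'   orders
#' @return the corrected `met_dataset` (attribute `n_uncorrected` counts
#'   metabolites left untouched)
#' @export
qc_drift_correct <- function(d) {
  stopifnot(d$scale == "raw")
  qc <- which(d$samples$role == "QC")
  if (length(qc) < 3) {
    warning("fewer than 3 QC samples; drift correction skipped")
    attr(d, "n_uncorrected") <- n_metabolites(d)
    return(d)
  }
  ord <- d$samples$injection_order
  x <- d$abundance
  n_uncorrected <- 0L
  for (j in seq_len(ncol(x))) {
    v <- x[qc, j]
    ok <- !is.na(v) & v > 0
    if (sum(ok) < 3 || stats::var(ord[qc][ok]) == 0) {
      n_uncorrected <- n_uncorrected + 1L
      next
    }
    y <- log2(v[ok]); o <- ord[qc][ok]
    b <- stats::cov(o, y) / stats::var(o)
    x[, j] <- x[, j] * 2^(-b * (ord - mean(o)))
  }
  out <- met_dataset(x, d$samples, d$metabolites, scale = "raw")
  attr(out, "n_uncorrected") <- n_uncorrected
  out
}

#' Drop unnamed peaks and collapse isomer groups
#'
#' Unnamed metabolites are discarded. Within each isomer group the member
#' with the largest inter-quartile range of log2 intensity across study
#' samples is kept; exact ties keep the member earliest in input order.
#' Values of retained metabolites are never altered.
#'
#' @param d a raw-scale `met_dataset` (study samples only or mixed; the IQR
#'   is computed over study samples)
#' @return the deduplicated `met_dataset`, with attributes
#'   `n_unnamed_dropped` and `n_isomer_collapsed`.
#' @export
dedup_isomers <- function(d) {
  stopifnot(d$scale == "raw")
  named <- d$metabolites$name != ""
  n_unnamed <- sum(!named)
  study <- d$samples$role == "study" & d$samples$tissue != "none"
  keep <- named
  grp <- d$metabolites$isomer_group
  collapsed <- 0L
  for (g in unique(grp[named & grp != ""])) {
    members <- which(named & grp == g)
    if (length(members) < 2) next
    iqrs <- vapply(members, function(j) {
      v <- d$abundance[study, j]
      v <- v[!is.na(v) & v > 0]
      if (length(v) < 2) return(-Inf)
      stats::IQR(log2(v))
    }, numeric(1))
    best <- members[which.max(iqrs)]  # which.max takes the first on ties
    keep[setdiff(members, best)] <- FALSE
    collapsed <- collapsed + length(members) - 1L
  }
  out <- subset_metabolites(d, which(keep))
  attr(out, "n_unnamed_dropped") <- n_unnamed
  attr(out, "n_isomer_collapsed") <- collapsed
  out
}

#' Log2-transform and quantile-normalize across samples
#'
#' Intensities are log2-transformed and every sample's value distribution
#' is mapped onto the common reference (the mean of sorted values across
#' samples), preserving within-sample ranks with ties averaged. Missing
#' values stay missing; samples with missing values are normalized against
#' an interpolated reference. Zero intensities cannot be log-transformed
#' and are converted to missing with a warning.
#'
#' @param d a raw-scale `met_dataset`
#' @return a `log2_normalized`-scale `met_dataset`
#' @export
log2_quantile_normalize <- function(d) {
  stopifnot(d$scale == "raw")
  x <- d$abundance
  if (any(x == 0, na.rm = TRUE)) {
    warning("zero intensities set to missing before log2 transform")
    x[x == 0] <- NA_real_
  }
  n_present <- rowSums(!is.na(x))
  if (any(n_present < 2)) {
    stop("sample(s) with fewer than 2 present values: ",
         paste(rownames(x)[n_present < 2], collapse = ", "))
  }
  lx <- log2(x)
  norm <- t(limma::normalizeQuantiles(t(lx), ties = TRUE))
  dimnames(norm) <- dimnames(x)
  met_dataset(norm, d$samples, d$metabolites, scale = "log2_normalized")
}

#' Impute missing values with half the minimum observed value
#'
#' Each missing cell receives half of the metabolite's minimum observed
#' intensity times `(1 + u)`, `u ~ Uniform(0, noise_scale)`. On log2-scale
#' matrices the rule is applied on the intensity scale, i.e.
#' `min_obs - 1 + log2(1 + u)`. For `noise_scale < 1` imputed values are
#' strictly below the metabolite's observed minimum. Deterministic under
#' `seed`.
#'
#' @param d a `met_dataset` (any scale)
#' @param noise_scale upper bound of the uniform noise fraction
#'   (default 0.1)
#' @param seed integer RNG seed
#' @return the imputed `met_dataset` with attribute `n_imputed`
#' @export
impute_half_min <- function(d, noise_scale = 0.1, seed = 1L) {
  stopifnot(noise_scale >= 0)
  x <- d$abundance
  miss <- is.na(x)
  if (!any(miss)) {
    attr(d, "n_imputed") <- 0L
    return(d)
  }
  full <- colSums(!miss) == 0
  if (any(full)) {
    stop("metabolite(s) fully missing: ",
         paste(colnames(x)[full], collapse = ", "))
  }
  set.seed(seed)
  on_log2 <- d$scale %in% c("log2", "log2_normalized")
  for (j in which(colSums(miss) > 0)) {
    mj <- which(miss[, j])
    m <- min(x[, j], na.rm = TRUE)
    u <- stats::runif(length(mj), 0, noise_scale)
    x[mj, j] <- if (on_log2) m - 1 + log2(1 + u) else 0.5 * m * (1 + u)
  }
  out <- met_dataset(x, d$samples, d$metabolites, scale = d$scale)
  attr(out, "n_imputed") <- sum(miss)
  out
}

#' Run the full preprocessing chain
#'
#' Blank-peak removal and QC drift correction are applied while blanks and
#' QCs are still in the matrix, then samples are filtered to located study
#' samples, isomers deduplicated, the matrix log2-transformed and
#' quantile-normalized, and remaining missing values imputed.
#'
#' @param d a raw-scale `met_dataset` as produced by [generate_dataset()]
#'   or [read_dataset()]
#' @param blank_ratio fold-over-blank threshold for [remove_blank_peaks()]
#' @param noise_scale imputation noise fraction for [impute_half_min()]
#' @param seed RNG seed for imputation noise
#' @return list: `dataset` (analysis-ready, `log2_normalized`) and
#'   `report`, a one-row data.frame with columns `n_samples_in`,
#'   `n_samples_out`, `n_metabolites_in`, `n_metabolites_out`,
#'   `n_blank_removed`, `n_unnamed_dropped`, `n_isomer_collapsed`,
#'   `n_imputed_cells`. Counts reconcile exactly:
#'   `in - removed - dropped - collapsed = out`.
#' @export
preprocess <- function(d, blank_ratio = 3, noise_scale = 0.1, seed = 1L) {
  n_samples_in <- n_samples(d)
  n_met_in <- n_metabolites(d)
  br <- remove_blank_peaks(d, blank_ratio)
  dc <- qc_drift_correct(br$dataset)
  fs <- filter_samples(dc)
  dd <- dedup_isomers(fs)
  qn <- log2_quantile_normalize(dd)
  im <- impute_half_min(qn, noise_scale = noise_scale, seed = seed)
  report <- data.frame(
    n_samples_in = n_samples_in,
    n_samples_out = n_samples(im),
    n_metabolites_in = n_met_in,
    n_metabolites_out = n_metabolites(im),
    n_blank_removed = length(br$removed),
    n_unnamed_dropped = attr(dd, "n_unnamed_dropped"),
    n_isomer_collapsed = attr(dd, "n_isomer_collapsed"),
    n_imputed_cells = attr(im, "n_imputed"))
  list(dataset = im, report = report)
}
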