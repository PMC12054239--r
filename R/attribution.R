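# Correlation-contrast source attribution. For a metabolite panel, the
# Pearson correlation between the panel abundance vectors of a fetal GI
# sample and a decidua sample measures coupling to the maternal
# compartment; the GI/meconium correlation measures coupling to local
# luminal production. Panels whose decidua/GI correlations exceed their
# meconium/GI correlations behave like maternally transmitted compounds;
# the reverse pattern indicates local production.

#' Enumerate cross-tissue sample pairs
#'
#' @param d a `met_dataset` (study samples)
#' @param tissue_a,tissue_b tissue supergroups
#' @param mode `all_pairs` (every sample of A against every sample of B,
#'   including cross-subject pairs), `subject_matched` (same subject only)
#'   or `age_matched` (both subjects at gestational age `age`).
#' @param age gestational age in weeks for `age_matched` mode (default 23)
#' @return data.frame: `sample_a`, `sample_b`, `tissue_a`, `tissue_b`
#'   (fine tissues), `subject_a`, `subject_b`, `same_subject`.
#' @export
enumerate_cross_tissue_pairs <- function(d, tissue_a, tissue_b,
                                         mode = c("all_pairs",
                                                  "subject_matched",
                                                  "age_matched"),
                                         age = 23) {
  mode <- match.arg(mode)
  ia <- .supergroup_rows(d, tissue_a)
  ib <- .supergroup_rows(d, tissue_b)
  if (!length(ia) || !length(ib)) {
    stop("empty tissue group: ", if (!length(ia)) tissue_a else tissue_b)
  }
  g <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
  s <- d$samples
  pairs <- data.frame(sample_a = s$sample_id[g$a], sample_b = s$sample_id[g$b],
                      tissue_a = s$tissue[g$a], tissue_b = s$tissue[g$b],
                      subject_a = s$subject_id[g$a],
                      subject_b = s$subject_id[g$b],
                      stringsAsFactors = FALSE)
  pairs$same_subject <- pairs$subject_a == pairs$subject_b
  if (mode == "subject_matched") {
    pairs <- pairs[pairs$same_subject, , drop = FALSE]
  } else if (mode == "age_matched") {
    keep <- s$gestational_age[g$a] == age & s$gestational_age[g$b] == age
    pairs <- pairs[keep, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Profile correlation between two samples over a metabolite panel
#'
#' @param d a log2-scale `met_dataset`
#' @param sample_a,sample_b sample ids
#' @param panel character vector of metabolite ids (at least 3 with values
#'   present in both samples)
#' @param method `pearson` (default) or `spearman`
#' @return the correlation of the two panel abundance vectors
#' @export
panel_profile_correlation <- function(d, sample_a, sample_b, panel,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(d$scale %in% c("log2", "log2_normalized"))
  i <- match(sample_a, d$samples$sample_id)
  j <- match(sample_b, d$samples$sample_id)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  cols <- match(panel, d$metabolites$metabolite_id)
  if (anyNA(cols)) stop("panel contains unknown metabolite ids")
  va <- d$abundance[i, cols]
  vb <- d$abundance[j, cols]
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3) stop("fewer than 3 panel metabolites present in both samples")
  va <- va[ok]; vb <- vb[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: zero variance in a panel vector")
  }
  stats::cor(va, vb, method = method)
}

#' Pairwise tissue correlation matrix for one subject
#'
#' For a subject sampled in several tissues, the symmetric matrix of panel
#' profile correlations between its tissues (unit diagonal; replicate
#' samples of a tissue are averaged).
#'
#' @param d a log2-scale `met_dataset`
#' @param subject subject id with at least two sampled tissues
#' @param panel metabolite ids
#' @param method correlation type
#' @return tissue x tissue symmetric numeric matrix
#' @export
subject_correlation_matrix <- function(d, subject, panel,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rows <- which(d$samples$subject_id == subject & d$samples$role == "study" &
                  d$samples$tissue != "none")
  tissues <- unique(d$samples$tissue[rows])
  if (length(tissues) < 2) stop("subject ", subject,
                                " has fewer than 2 sampled tissues")
  m <- diag(1, length(tissues))
  dimnames(m) <- list(tissues, tissues)
  for (a in seq_along(tissues)) {
    for (b in seq_along(tissues)) {
      if (b <= a) next
      sa <- d$samples$sample_id[rows][d$samples$tissue[rows] == tissues[a]]
      sb <- d$samples$sample_id[rows][d$samples$tissue[rows] == tissues[b]]
      rho <- mean(vapply(sa, function(u) {
        mean(vapply(sb, function(v) {
          panel_profile_correlation(d, u, v, panel, method)
        }, numeric(1)))
      }, numeric(1)))
      m[a, b] <- m[b, a] <- rho
    }
  }
  m
}

#' Contrast two correlation samples into an origin verdict
#'
#' Welch two-sample t-test between the decidua/GI and meconium/GI
#' correlation samples of one panel. The panel is labelled `maternal` when
#' the decidua/GI correlations are significantly higher, `local` when the
#' meconium/GI correlations are, and `indeterminate` otherwise.
#'
#' @param rho_dec_gi,rho_mec_gi numeric vectors of pair correlations (at
#'   least 2 each)
#' @param alpha significance level (default 0.05)
#' @param panel optional panel name carried into the result
#' @return one-row data.frame: `panel`, `n_dec_gi`, `n_mec_gi`,
#'   `mean_rho_dec_gi`, `mean_rho_mec_gi`, `t_statistic`, `p_value`,
#'   `label`.
#' @export
contrast_correlation_classes <- function(rho_dec_gi, rho_mec_gi,
                                         alpha = 0.05, panel = NA_character_) {
  rho_dec_gi <- rho_dec_gi[!is.na(rho_dec_gi)]
  rho_mec_gi <- rho_mec_gi[!is.na(rho_mec_gi)]
  if (length(rho_dec_gi) < 2 || length(rho_mec_gi) < 2) {
    stop("each correlation set needs at least 2 values")
  }
  tt <- tryCatch(stats::t.test(rho_dec_gi, rho_mec_gi),
                 error = function(e) NULL)
  if (is.null(tt)) {  # both sets essentially constant
    t_stat <- 0
    p <- 1
  } else {
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  ma <- mean(rho_dec_gi); mb <- mean(rho_mec_gi)
  label <- if (p < alpha && ma > mb) "maternal" else
    if (p < alpha && ma < mb) "local" else "indeterminate"
  data.frame(panel = panel, n_dec_gi = length(rho_dec_gi),
             n_mec_gi = length(rho_mec_gi), mean_rho_dec_gi = ma,
             mean_rho_mec_gi = mb, t_statistic = t_stat, p_value = p,
             label = label, stringsAsFactors = FALSE)
}

#' Attribute metabolite panels to a maternal or local origin
#'
#' For each panel, computes the decidua/GI and GI/meconium pair
#' correlations under the requested pairing mode and contrasts them with
#' [contrast_correlation_classes()]. Pairs whose correlation is undefined
#' (constant panel vector) are dropped with a warning; a panel left with
#' fewer than two correlations on a side is reported `indeterminate`.
#'
#' @param d a preprocessed (log2-scale) `met_dataset`
#' @param panels panel names to attribute
#' @param mode pairing mode, see [enumerate_cross_tissue_pairs()]
#' @param method correlation type
#' @param alpha significance level
#' @param age gestational age for `age_matched` mode
#' @return data.frame with one row per panel (columns of
#'   [contrast_correlation_classes()] plus `mode`); attribute
#'   `pair_correlations` holds the long per-pair table for plotting.
#' @export
attribute_all_panels <- function(d, panels = c("microbial", "xenobiotic",
                                               "fetal_derived"),
                                 mode = "all_pairs",
                                 method = "pearson", alpha = 0.05, age = 23) {
  pair_dec <- enumerate_cross_tissue_pairs(d, "decidua", "GI", mode, age)
  pair_mec <- enumerate_cross_tissue_pairs(d, "GI", "meconium", mode, age)
  res <- list(); long <- list()
  for (panel in panels) {
    ids <- panel_ids(d, panel)
    if (!length(ids)) {
      warning("panel ", panel, " is empty; skipped")
      next
    }
    rho_of <- function(pairs, contrast) {
      if (!nrow(pairs)) return(numeric(0))
      rho <- vapply(seq_len(nrow(pairs)), function(k) {
        tryCatch(panel_profile_correlation(d, pairs$sample_a[k],
                                           pairs$sample_b[k], ids, method),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (anyNA(rho)) warning(sum(is.na(rho)), " pair(s) with undefined ",
                              panel, " correlation dropped")
      long[[length(long) + 1L]] <<- data.frame(
        panel = panel, contrast = contrast, pairs, rho = rho,
        stringsAsFactors = FALSE)
      rho[!is.na(rho)]
    }
    rho_dec <- rho_of(pair_dec, "decidua_GI")
    rho_mec <- rho_of(pair_mec, "GI_meconium")
    row <- if (length(rho_dec) < 2 || length(rho_mec) < 2) {
      warning("panel ", panel, " has too few defined correlations; ",
              "indeterminate")
      data.frame(panel = panel, n_dec_gi = length(rho_dec),
                 n_mec_gi = length(rho_mec),
                 mean_rho_dec_gi = if (length(rho_dec)) mean(rho_dec) else NA,
                 mean_rho_mec_gi = if (length(rho_mec)) mean(rho_mec) else NA,
                 t_statistic = NA_real_, p_value = NA_real_,
                 label = "indeterminate", stringsAsFactors = FALSE)
    } else {
      contrast_correlation_classes(rho_dec, rho_mec, alpha, panel)
    }
    row$mode <- mode
    res[[length(res) + 1L]] <- row
  }
  out <- do.call(rbind, res)
  attr(out, "pair_correlations") <- do.call(rbind, long)
  out
}
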