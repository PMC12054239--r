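# Two-group moderated differential abundance: pooled-variance group
# contrast, empirical-Bayes variance shrinkage (moment estimation of the
# scaled inverse-chi-square prior on log variances), moderated t,
# Benjamini-Hochberg q-values and volcano classification.

#' Samples belonging to a tissue supergroup
#' @param d a `met_dataset`
#' @param group supergroup (`decidua`, `GI`, `meconium`, `PV`)
#' @return integer sample indices
#' @keywords internal
.supergroup_rows <- function(d, group) {
  stopifnot(group %in% SUPERGROUPS)
  sg <- tissue_supergroup(d$samples$tissue)
  which(d$samples$role == "study" & !is.na(sg) & sg == group)
}

#' Per-metabolite two-group contrast
#'
#' For each metabolite, the log2 fold change `mean(A) - mean(B)`, the
#' pooled within-group variance and the residual degrees of freedom
#' `n_a + n_b - 2`. Input must be log2-scale and imputed (no missing
#' values in the contrasted samples).
#'
#' @param d a `log2`/`log2_normalized`-scale `met_dataset`
#' @param group_a,group_b tissue supergroups; fold changes are
#'   `group_a - group_b`
#' @return data.frame: `metabolite_id`, `log_fc`, `s2`, `df`, `n_a`, `n_b`
#' @export
fit_group_contrast <- function(d, group_a, group_b) {
  stopifnot(d$scale %in% c("log2", "log2_normalized"))
  ia <- .supergroup_rows(d, group_a)
  ib <- .supergroup_rows(d, group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples (", group_a, ": ", length(ia),
         ", ", group_b, ": ", length(ib), ")")
  }
  xa <- d$abundance[ia, , drop = FALSE]
  xb <- d$abundance[ib, , drop = FALSE]
  if (anyNA(xa) || anyNA(xb)) stop("contrast requires an imputed matrix")
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var)
  vb <- apply(xb, 2, stats::var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  data.frame(metabolite_id = d$metabolites$metabolite_id,
             log_fc = unname(ma - mb), s2 = unname(s2),
             df = na + nb - 2, n_a = na, n_b = nb,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate the variance-shrinkage prior
#'
#' Fits the scaled inverse-chi-square prior (`d0` degrees of freedom, scale
#' `s0_sq`) for per-metabolite sample variances by matching the first two
#' moments of `log(s2)` to the implied scaled-F distribution: the excess
#' variance of `log(s2)` beyond the chi-square sampling contribution
#' identifies `d0` through the trigamma function. When the moment equation
#' has no positive solution (no excess heterogeneity) the prior degenerates
#' to `d0 = Inf`; if all variances are exactly equal, `s0_sq` is that
#' common value.
#'
#' @param s2 vector of sample variances (at least 10)
#' @param df residual degrees of freedom (scalar or per-metabolite)
#' @return list with elements `d0` and `s0_sq`
#' @export
estimate_prior <- function(s2, df) {
  if (length(s2) < 10) stop("prior estimation needs at least 10 metabolites")
  if (length(df) == 1) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 10) stop("too few positive finite variances")
  z <- log(s2[ok])
  if (stats::var(z) == 0) {
    return(list(d0 = Inf, s0_sq = s2[ok][1]))
  }
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistic
#'
#' Shrinks each metabolite's variance toward the prior,
#' `s2_tilde = (d0*s0_sq + df*s2) / (d0 + df)`, and tests the log fold
#' change with `t = log_fc / sqrt(s2_tilde * (1/n_a + 1/n_b))` on
#' `d0 + df` degrees of freedom (normal in the `d0 = Inf` limit). `d0 = 0`
#' recovers the ordinary pooled t-statistic.
#'
#' @param log_fc,s2,df vectors from [fit_group_contrast()]
#' @param prior list with `d0`, `s0_sq` from [estimate_prior()]
#' @param n_a,n_b group sizes
#' @return data.frame with columns `t_mod`, `p` (two-sided; floored at
#'   1e-300 when the shrunken variance vanishes)
#' @export
moderated_t <- function(log_fc, s2, df, prior, n_a, n_b) {
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  stopifnot(d0 >= 0, s0_sq > 0)
  n <- max(length(log_fc), length(s2), length(df))
  log_fc <- rep_len(log_fc, n)
  s2 <- rep_len(s2, n)
  df <- rep_len(df, n)
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se > 0, log_fc / se, sign(log_fc) * Inf)
  t_mod[se == 0 & log_fc == 0] <- 0
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmax(p, 1e-300)
  p[t_mod == 0] <- 1
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min over {j: p_j >= p_i} of
#' m * p_j / rank_j`, capped at 1. Preserves the ordering of p-values.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return vector of q-values
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Volcano classification at fixed thresholds
#'
#' `up_in_a` iff `log_fc > fc_threshold` and `q < q_threshold`; `up_in_b`
#' iff `log_fc < -fc_threshold` and `q < q_threshold`; otherwise `ns`.
#' Inequalities are strict, so a fold change exactly at the threshold is
#' not significant.
#'
#' @param log_fc,q vectors
#' @param fc_threshold absolute log2 fold-change threshold (default 2.5)
#' @param q_threshold q-value threshold (default 0.05)
#' @return character vector in `{"up_in_a", "up_in_b", "ns"}`
#' @export
classify_volcano <- function(log_fc, q, fc_threshold = 2.5,
                             q_threshold = 0.05) {
  out <- rep("ns", length(log_fc))
  out[log_fc > fc_threshold & q < q_threshold] <- "up_in_a"
  out[log_fc < -fc_threshold & q < q_threshold] <- "up_in_b"
  out
}

#' Moderated differential abundance between two tissue supergroups
#'
#' Runs the full chain [fit_group_contrast()], [estimate_prior()],
#' [moderated_t()], [bh_adjust()], [classify_volcano()].
#'
#' @inheritParams fit_group_contrast
#' @inheritParams classify_volcano
#' @return data.frame (one row per metabolite): `metabolite_id`, `name`,
#'   `group_a`, `group_b`, `log_fc`, `s2`, `df`, `t_mod`, `p`, `q`,
#'   `volcano_class`.
#' @export
run_differential <- function(d, group_a, group_b, fc_threshold = 2.5,
                             q_threshold = 0.05) {
  fit <- fit_group_contrast(d, group_a, group_b)
  prior <- estimate_prior(fit$s2, fit$df)
  mt <- moderated_t(fit$log_fc, fit$s2, fit$df, prior, fit$n_a[1], fit$n_b[1])
  q <- bh_adjust(mt$p)
  data.frame(metabolite_id = fit$metabolite_id,
             name = d$metabolites$name,
             group_a = group_a, group_b = group_b,
             log_fc = fit$log_fc, s2 = fit$s2, df = fit$df,
             t_mod = mt$t_mod, p = mt$p, q = q,
             volcano_class = classify_volcano(fit$log_fc, q, fc_threshold,
                                              q_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
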