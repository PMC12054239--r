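# Per-metabolite four-group tissue comparison: one-way ANOVA, Tukey HSD
# post hoc, gestational-age-adjusted re-test and tissue-pattern calls.

#' One-way ANOVA over per-group value vectors
#'
#' @param group_values named list of numeric vectors, one per group (at
#'   least 2 groups with at least 2 values each)
#' @return list: `F`, `p`, `degenerate` (TRUE when all values are
#'   identical, reported as `F = 0`, `p = 1`)
#' @export
one_way_anova <- function(group_values) {
  stopifnot(length(group_values) >= 2,
            all(vapply(group_values, length, integer(1)) >= 2))
  y <- unlist(group_values, use.names = FALSE)
  g <- factor(rep(seq_along(group_values),
                  vapply(group_values, length, integer(1))))
  if (stats::var(y) == 0) {
    return(list(F = 0, p = 1, degenerate = TRUE))
  }
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1], degenerate = FALSE)
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' @inheritParams one_way_anova
#' @return named numeric vector of Tukey-adjusted p-values, names
#'   `"B-A"` for each group pair; all 1 when the data are degenerate.
#' @export
tukey_posthoc <- function(group_values) {
  stopifnot(length(group_values) >= 2,
            all(vapply(group_values, length, integer(1)) >= 2))
  if (is.null(names(group_values))) {
    names(group_values) <- paste0("g", seq_along(group_values))
  }
  y <- unlist(group_values, use.names = FALSE)
  g <- factor(rep(names(group_values),
                  vapply(group_values, length, integer(1))),
              levels = names(group_values))
  pair_names <- utils::combn(names(group_values), 2,
                             function(x) paste(x[2], x[1], sep = "-"))
  if (stats::var(y) == 0) {
    return(stats::setNames(rep(1, length(pair_names)), pair_names))
  }
  hsd <- stats::TukeyHSD(stats::aov(y ~ g))$g
  p <- hsd[, "p adj"]
  p[is.na(p)] <- 1
  p
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise t-tests on the pooled ANOVA mean square (all groups), with
#' Bonferroni correction over the group pairs. Alternative to
#' [tukey_posthoc()].
#'
#' @inheritParams one_way_anova
#' @return named numeric vector of adjusted p-values, names `"B-A"`
#' @export
bonferroni_posthoc <- function(group_values) {
  stopifnot(length(group_values) >= 2,
            all(vapply(group_values, length, integer(1)) >= 2))
  if (is.null(names(group_values))) {
    names(group_values) <- paste0("g", seq_along(group_values))
  }
  y <- unlist(group_values, use.names = FALSE)
  k <- length(group_values)
  df_w <- length(y) - k
  pair_names <- utils::combn(names(group_values), 2,
                             function(x) paste(x[2], x[1], sep = "-"))
  if (stats::var(y) == 0) {
    return(stats::setNames(rep(1, length(pair_names)), pair_names))
  }
  mse <- sum(vapply(group_values, function(v) sum((v - mean(v))^2),
                    numeric(1))) / df_w
  pairs <- utils::combn(names(group_values), 2, simplify = FALSE)
  p <- vapply(pairs, function(pr) {
    a <- group_values[[pr[1]]]; b <- group_values[[pr[2]]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    if (se == 0) return(if (mean(a) == mean(b)) 1 else 0)
    2 * stats::pt(-abs((mean(a) - mean(b)) / se), df_w)
  }, numeric(1))
  stats::setNames(pmin(1, p * length(pairs)), pair_names)
}

#' Group effect adjusted for gestational age
#'
#' Nested-model F-test comparing `abundance ~ age` against
#' `abundance ~ age + group`, i.e. the tissue effect with gestational age
#' as a confounder.
#'
#' @param values numeric abundance vector
#' @param ages gestational ages (weeks), no missing values
#' @param groups group membership (factor or character)
#' @return p-value for the group effect controlling age (1 when the data
#'   are degenerate)
#' @export
age_adjusted_group_test <- function(values, ages, groups) {
  stopifnot(length(values) == length(ages), length(values) == length(groups))
  if (anyNA(ages)) stop("ages required for all samples")
  g <- factor(groups)
  if (stats::var(values) == 0) return(1)
  fit0 <- stats::lm(values ~ ages)
  fit1 <- stats::lm(values ~ ages + g)
  if (fit1$df.residual <= 0) {
    stop("collinear design: no residual degrees of freedom")
  }
  a <- stats::anova(fit0, fit1)
  p <- a[["Pr(>F)"]][2]
  if (is.na(p)) 1 else p
}

#' Classify a metabolite's tissue abundance pattern
#'
#' `no_difference` when the ANOVA q-value is not below `alpha`;
#' `enriched_<group>` when one group has the highest mean and all of its
#' pairwise post hoc comparisons are significant; otherwise `mixed`.
#'
#' @param group_means named numeric vector of group means
#' @param posthoc named vector of adjusted pairwise p-values (`"B-A"`
#'   names, as from [tukey_posthoc()])
#' @param q ANOVA q-value for this metabolite
#' @param alpha significance level (default 0.05)
#' @return character pattern label
#' @export
classify_tissue_pattern <- function(group_means, posthoc, q, alpha = 0.05) {
  if (!(q < alpha)) return("no_difference")
  top <- names(group_means)[which.max(group_means)]
  involves_top <- vapply(strsplit(names(posthoc), "-", fixed = TRUE),
                         function(x) top %in% x, logical(1))
  if (sum(involves_top) == length(group_means) - 1 &&
      all(posthoc[involves_top] < alpha)) {
    paste0("enriched_", top)
  } else {
    "mixed"
  }
}

#' Tissue-enrichment ANOVA for a metabolite panel
#'
#' For every metabolite of `panel`, a one-way ANOVA of abundance across
#' the four tissue supergroups, Tukey HSD post hoc p-values for the six
#' group pairs, BH q-values across the panel, an optional
#' gestational-age-adjusted group test, and a tissue-pattern call.
#'
#' @param d a preprocessed (log2-scale, imputed) `met_dataset`
#' @param panel panel name (default `microbial`)
#' @param adjust_age also compute the age-adjusted group p-value
#' @param posthoc `"tukey"` (default) or `"bonferroni"`
#' @param alpha significance level for pattern calls
#' @return data.frame: `metabolite_id`, `name`, `F`, `p`, `q`,
#'   `age_adjusted_p` (if requested), `pattern`, plus one `p_<A>_<B>`
#'   column per group pair.
#' @export
run_tissue_anova <- function(d, panel = "microbial", adjust_age = TRUE,
                             posthoc = c("tukey", "bonferroni"),
                             alpha = 0.05) {
  posthoc_fun <- switch(match.arg(posthoc), tukey = tukey_posthoc,
                        bonferroni = bonferroni_posthoc)
  ids <- panel_ids(d, panel)
  if (!length(ids)) stop("panel ", panel, " is empty")
  sg <- tissue_supergroup(d$samples$tissue)
  keep <- d$samples$role == "study" & !is.na(sg)
  groups <- present <- unique(sg[keep])
  rows <- lapply(stats::setNames(groups, groups),
                 function(g) which(keep & sg == g))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    j <- match(ids[k], d$metabolites$metabolite_id)
    gv <- lapply(rows, function(r) d$abundance[r, j])
    aov1 <- one_way_anova(gv)
    ph <- posthoc_fun(gv)
    means <- vapply(gv, mean, numeric(1))
    row <- data.frame(metabolite_id = ids[k],
                      name = d$metabolites$name[j],
                      F = aov1$F, p = aov1$p,
                      stringsAsFactors = FALSE)
    for (nm in names(ph)) {
      row[[paste0("p_", gsub("-", "_", nm))]] <- ph[[nm]]
    }
    if (adjust_age) {
      r_all <- unlist(rows, use.names = FALSE)
      row$age_adjusted_p <- age_adjusted_group_test(
        d$abundance[r_all, j], d$samples$gestational_age[r_all],
        sg[r_all])
    }
    attr(row, "means") <- means
    attr(row, "posthoc") <- ph
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res$pattern <- vapply(seq_along(out), function(k) {
    classify_tissue_pattern(attr(out[[k]], "means"),
                            attr(out[[k]], "posthoc"), res$q[k], alpha)
  }, character(1))
  rownames(res) <- NULL
  res
}
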