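# Per-tissue, per-metabolite linear association of log2 abundance with
# gestational age. Within the fetal GI tract a significant negative trend
# for a microbial metabolite points to a maternal-circulation origin (the
# compound washes out as gestation advances), a significant positive trend
# to increasing local fetal synthesis.

#' Linear gestational-age trend for one metabolite
#'
#' Ordinary least squares of abundance on age; the Pearson correlation
#' coefficient `r` equals the standardized slope for this simple
#' regression, and `r^2` is the regression's coefficient of determination.
#'
#' @param values abundance vector (log2 scale)
#' @param ages gestational ages in weeks (at least 3 samples, at least 2
#'   distinct ages)
#' @return list: `slope` (log2 units/week), `r`, `p` (two-sided test of
#'   zero slope), `degenerate` (TRUE for a zero-variance response, reported
#'   as `slope = 0`, `r = 0`, `p = 1`)
#' @export
fit_age_trend <- function(values, ages) {
  ok <- !is.na(values) & !is.na(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 3) stop("age trend needs at least 3 samples")
  if (length(unique(ages)) < 2) stop("all ages equal; trend undefined")
  if (stats::var(values) == 0) {
    return(list(slope = 0, r = 0, p = 1, degenerate = TRUE))
  }
  fit <- stats::lm(values ~ ages)
  sm <- summary(fit)$coefficients
  list(slope = unname(fit$coefficients[2]),
       r = stats::cor(values, ages),
       p = unname(sm[2, 4]),
       degenerate = FALSE)
}

#' BH-adjust age-trend rows within one tissue
#'
#' @param rows data.frame of age-trend rows sharing a single `tissue`
#' @return the rows with a `q` column added
#' @export
adjust_within_tissue <- function(rows) {
  if (length(unique(rows$tissue)) > 1) {
    stop("rows from more than one tissue; adjust each tissue separately")
  }
  rows$q <- bh_adjust(rows$p)
  rows
}

#' Interpret a GI age trend as an origin hint
#'
#' Defined for the fetal GI tract only: a microbial-class metabolite with a
#' significant negative trend is flagged `maternal_circulation`; any
#' metabolite with a significant positive trend is flagged
#' `fetal_synthesis`; everything else (including all non-GI tissues) is
#' `none`.
#'
#' @param slope,q fitted slope and q-value
#' @param is_microbial does the metabolite belong to the microbial panel
#' @param tissue tissue supergroup of the fit
#' @param alpha significance level (default 0.05)
#' @return one of `"maternal_circulation"`, `"fetal_synthesis"`, `"none"`
#' @export
interpret_origin_from_trend <- function(slope, q, is_microbial, tissue,
                                        alpha = 0.05) {
  if (tissue != "GI") return("none")
  if (q < alpha && slope < 0 && is_microbial) return("maternal_circulation")
  if (q < alpha && slope > 0) return("fetal_synthesis")
  "none"
}

#' Gestational-age trend table across tissues
#'
#' Fits [fit_age_trend()] for every metabolite of the requested panels in
#' every tissue supergroup, BH-adjusts within each tissue, and annotates
#' GI rows with an origin hint.
#'
#' @param d a preprocessed (log2-scale, imputed) `met_dataset`
#' @param tissues tissue supergroups to analyse
#' @param panels panel names whose union is analysed (default: the bile
#'   acid and SCFA panels)
#' @param alpha significance level for origin hints
#' @return data.frame: `metabolite_id`, `name`, `tissue`, `slope`, `r`,
#'   `p`, `q`, `origin_hint`.
#' @export
run_age_trends <- function(d, tissues = SUPERGROUPS,
                           panels = c("primary_BA", "secondary_BA", "SCFA"),
                           alpha = 0.05) {
  ids <- unique(unlist(lapply(panels, function(p) panel_ids(d, p))))
  if (!length(ids)) stop("no metabolites in requested panels")
  microbial <- ids %in% panel_ids(d, "microbial")
  sg <- tissue_supergroup(d$samples$tissue)
  out <- list()
  for (tis in tissues) {
    rows <- which(d$samples$role == "study" & !is.na(sg) & sg == tis)
    if (length(rows) < 3) next
    ages <- d$samples$gestational_age[rows]
    tab <- do.call(rbind, lapply(seq_along(ids), function(k) {
      j <- match(ids[k], d$metabolites$metabolite_id)
      ft <- fit_age_trend(d$abundance[rows, j], ages)
      data.frame(metabolite_id = ids[k], name = d$metabolites$name[j],
                 tissue = tis, slope = ft$slope, r = ft$r, p = ft$p,
                 stringsAsFactors = FALSE)
    }))
    tab <- adjust_within_tissue(tab)
    tab$origin_hint <- vapply(seq_len(nrow(tab)), function(k) {
      interpret_origin_from_trend(tab$slope[k], tab$q[k], microbial[k],
                                  tis, alpha)
    }, character(1))
    out[[tis]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
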