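#' @keywords internal
"_PACKAGE"

# Fine tissue codes used throughout; "none" marks samples without a recorded
# location (blanks, QCs and the occasional unannotated study sample).
TISSUES <- c("decidua", "SI", "LI", "SI_mec", "LI_mec", "PV")
TISSUE_LEVELS <- c(TISSUES, "none")
SUPERGROUPS <- c("decidua", "GI", "meconium", "PV")
SAMPLE_ROLES <- c("study", "blank", "QC")
PANEL_LEVELS <- c("microbial", "xenobiotic", "fetal_derived", "primary_BA",
                  "secondary_BA", "SCFA", "aromatic", "other")

.SUPERGROUP_MAP <- c(decidua = "decidua", SI = "GI", LI = "GI",
                     SI_mec = "meconium", LI_mec = "meconium", PV = "PV")

#' Map fine tissue codes to tissue supergroups
#'
#' Small and large intestine collapse to `GI`; their meconium counterparts
#' collapse to `meconium`; decidua and placental villi map to themselves.
#' `"none"` (blanks, QCs, unlocated samples) maps to `NA`.
#'
#' @param tissue character vector of fine tissue codes
#'   (`decidua`, `SI`, `LI`, `SI_mec`, `LI_mec`, `PV`, `none`).
#' @return character vector of supergroups (`decidua`, `GI`, `meconium`,
#'   `PV`), `NA` for `none`.
#' @export
#' @examples
#' tissue_supergroup(c("SI", "LI_mec", "decidua", "none"))
tissue_supergroup <- function(tissue) {
  bad <- !tissue %in% TISSUE_LEVELS
  if (any(bad)) {
    stop("unknown tissue code(s): ", paste(unique(tissue[bad]), collapse = ", "))
  }
  out <- unname(.SUPERGROUP_MAP[tissue])
  out[tissue == "none"] <- NA_character_
  out
}

#' Construct a metabolomics dataset
#'
#' Bundles an abundance matrix (samples in rows, metabolites in columns)
#' with its sample metadata and metabolite annotation. Row names of
#' `abundance` must equal `samples$sample_id` and column names
#' `metabolites$metabolite_id`, in order.
#'
#' @param abundance numeric matrix, samples x metabolites. `NA` encodes a
#'   missing measurement; zero is a real measurement.
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `tissue`, `gestational_age`, `role`, `injection_order`.
#' @param metabolites data.frame with columns `metabolite_id`, `name`,
#'   `annotation_level`, `isomer_group`, `panel` (semicolon-separated panel
#'   tokens, e.g. `"microbial;secondary_BA"`).
#' @param scale one of `"raw"`, `"log2"`, `"log2_normalized"`.
#' @return an object of class `met_dataset`.
#' @export
met_dataset <- function(abundance, samples, metabolites, scale = "raw") {
  scale <- match.arg(scale, c("raw", "log2", "log2_normalized"))
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  req_s <- c("sample_id", "subject_id", "tissue", "gestational_age", "role",
             "injection_order")
  req_m <- c("metabolite_id", "name", "annotation_level", "isomer_group",
             "panel")
  miss <- setdiff(req_s, names(samples))
  if (length(miss)) stop("samples table lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(req_m, names(metabolites))
  if (length(miss)) stop("metabolites table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(abundance) != nrow(samples)) {
    stop("abundance has ", nrow(abundance), " rows but samples table has ",
         nrow(samples))
  }
  if (ncol(abundance) != nrow(metabolites)) {
    stop("abundance has ", ncol(abundance),
         " columns but metabolite table has ", nrow(metabolites))
  }
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- samples$sample_id
  }
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- metabolites$metabolite_id
  }
  if (!identical(rownames(abundance), as.character(samples$sample_id))) {
    stop("abundance row names do not match samples$sample_id (alignment error)")
  }
  if (!identical(colnames(abundance), as.character(metabolites$metabolite_id))) {
    stop("abundance column names do not match metabolites$metabolite_id ",
         "(alignment error)")
  }
  structure(list(abundance = abundance, samples = samples,
                 metabolites = metabolites, scale = scale),
            class = "met_dataset")
}

#' @export
print.met_dataset <- function(x, ...) {
  role <- table(factor(x$samples$role, levels = SAMPLE_ROLES))
  cat("met_dataset: ", nrow(x$abundance), " samples x ", ncol(x$abundance),
      " metabolites [scale: ", x$scale, "]\n", sep = "")
  cat("  roles: ", paste(names(role), role, sep = "=", collapse = ", "), "\n",
      sep = "")
  tis <- table(factor(x$samples$tissue[x$samples$role == "study"],
                      levels = TISSUE_LEVELS))
  tis <- tis[tis > 0]
  if (length(tis)) {
    cat("  study tissues: ", paste(names(tis), tis, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples / metabolites
#' @param d a `met_dataset`
#' @return integer count
#' @export
n_samples <- function(d) nrow(d$abundance)

#' @rdname n_samples
#' @export
n_metabolites <- function(d) ncol(d$abundance)

#' Subset a dataset by samples or metabolites
#'
#' @param d a `met_dataset`
#' @param keep logical/integer index or character vector of ids
#' @return the subset `met_dataset`
#' @export
subset_samples <- function(d, keep) {
  if (is.character(keep)) keep <- match(keep, d$samples$sample_id)
  met_dataset(d$abundance[keep, , drop = FALSE],
              d$samples[keep, , drop = FALSE],
              d$metabolites, scale = d$scale)
}

#' @rdname subset_samples
#' @export
subset_metabolites <- function(d, keep) {
  if (is.character(keep)) keep <- match(keep, d$metabolites$metabolite_id)
  met_dataset(d$abundance[, keep, drop = FALSE],
              d$samples,
              d$metabolites[keep, , drop = FALSE], scale = d$scale)
}

#' Metabolite ids belonging to an annotation panel
#'
#' Panels are stored as semicolon-separated tokens in the `panel` column so
#' that a metabolite can belong to several (secondary bile acids are also
#' microbial, for example).
#'
#' @param d a `met_dataset`
#' @param panel single panel token, e.g. `"microbial"`.
#' @return character vector of metabolite ids
#' @export
panel_ids <- function(d, panel) {
  toks <- strsplit(d$metabolites$panel, ";", fixed = TRUE)
  hit <- vapply(toks, function(x) panel %in% x, logical(1))
  d$metabolites$metabolite_id[hit]
}

#' Validate a dataset against its invariants
#'
#' Invariant violations are reported, never thrown: study samples must have
#' a known tissue and a gestational age, blanks/QCs must have tissue
#' `none`, injection orders must be unique, ids must be unique, raw
#' intensities must be non-negative, annotation levels must be 1-4.
#'
#' @param d a `met_dataset`
#' @return data.frame with columns `check`, `id`, `message`; zero rows iff
#'   the dataset is consistent.
#' @export
validate_dataset <- function(d) {
  viol <- list()
  add <- function(check, id, message) {
    viol[[length(viol) + 1L]] <<- data.frame(check = check, id = id,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  s <- d$samples
  m <- d$metabolites

  dup <- unique(s$sample_id[duplicated(s$sample_id)])
  for (id in dup) add("duplicate_sample_id", id, "sample_id occurs more than once")
  dup <- unique(m$metabolite_id[duplicated(m$metabolite_id)])
  for (id in dup) add("duplicate_metabolite_id", id,
                      "metabolite_id occurs more than once")

  bad <- !s$tissue %in% TISSUE_LEVELS
  for (id in s$sample_id[bad]) add("unknown_tissue", id, "tissue not recognised")
  bad <- !s$role %in% SAMPLE_ROLES
  for (id in s$sample_id[bad]) add("unknown_role", id, "role not recognised")

  study <- s$role == "study"
  bad <- study & s$tissue == "none"
  for (id in s$sample_id[bad]) add("study_without_tissue", id,
                                   "study sample has tissue 'none'")
  bad <- study & (is.na(s$gestational_age) |
                    (s$tissue != "none" &
                       (s$gestational_age < 14 | s$gestational_age > 23)))
  for (id in s$sample_id[bad]) add("study_age", id,
                                   "study sample lacks a gestational age in 14-23 weeks")
  bad <- !study & s$tissue != "none"
  for (id in s$sample_id[bad]) add("control_with_tissue", id,
                                   "blank/QC sample has a tissue assignment")
  bad <- is.na(s$injection_order) | s$injection_order < 1
  for (id in s$sample_id[bad]) add("injection_order", id,
                                   "injection order missing or non-positive")
  dup <- unique(s$injection_order[duplicated(s$injection_order) &
                                    !is.na(s$injection_order)])
  for (o in dup) add("injection_order_duplicated", as.character(o),
                     "injection order used by more than one sample")

  bad <- !m$annotation_level %in% 1:4
  for (id in m$metabolite_id[bad]) add("annotation_level", id,
                                       "annotation level outside 1-4")
  if (d$scale == "raw") {
    neg <- which(d$abundance < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      for (i in seq_len(min(nrow(neg), 20))) {
        add("negative_raw_value",
            paste(rownames(d$abundance)[neg[i, 1]],
                  colnames(d$abundance)[neg[i, 2]], sep = "/"),
            "raw intensity is negative")
      }
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Read a dataset from its three tables
#'
#' Expects UTF-8 delimited text with header rows. The abundance table has
#' samples as rows (first column the sample id) and metabolites as columns;
#' `transposed = TRUE` accepts the metabolites-as-rows orientation. Empty
#' cells and `NA` are missing values; zero is a real measurement.
#'
#' @param abundance_path,samples_path,annotation_path file paths
#' @param sep field separator, tab by default (`","` for CSV)
#' @param transposed abundance table is metabolites x samples
#' @return a validated `met_dataset` (raw scale unless a `scale` attribute
#'   column is present in the samples table; the scale written by
#'   [write_dataset()] is restored).
#' @export
read_dataset <- function(abundance_path, samples_path, annotation_path,
                         sep = "\t", transposed = FALSE) {
  ab <- utils::read.table(abundance_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  ids <- ab[[1]]
  raw <- ab[, -1, drop = FALSE]
  vals <- suppressWarnings(
    vapply(raw, function(col) as.numeric(ifelse(col == "", NA, col)),
           numeric(nrow(raw))))
  if (nrow(raw) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(raw)))
  bad <- which(is.na(vals) & !(raw == "" | is.na(raw) | toupper(as.matrix(raw)) == "NA"),
               arr.ind = TRUE)
  if (length(bad)) {
    stop("non-numeric abundance cell at row ", bad[1, 1] , " (", ids[bad[1, 1]],
         "), column ", bad[1, 2], " (", colnames(vals)[bad[1, 2]], ")")
  }
  rownames(vals) <- ids
  if (transposed) vals <- t(vals)

  samples <- utils::read.table(samples_path, header = TRUE, sep = sep,
                               check.names = FALSE, stringsAsFactors = FALSE,
                               quote = "\"", comment.char = "")
  metab <- utils::read.table(annotation_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "\"", comment.char = "")
  metab$name[is.na(metab$name)] <- ""
  metab$isomer_group[is.na(metab$isomer_group)] <- ""
  metab$annotation_level <- as.integer(metab$annotation_level)
  samples$gestational_age <- as.numeric(samples$gestational_age)
  samples$injection_order <- as.integer(samples$injection_order)

  if (!setequal(rownames(vals), samples$sample_id)) {
    missing_ab <- setdiff(samples$sample_id, rownames(vals))
    missing_md <- setdiff(rownames(vals), samples$sample_id)
    stop("sample ids do not align between abundance and metadata tables",
         if (length(missing_ab)) paste0("; absent from abundance: ",
                                        paste(missing_ab, collapse = ", ")),
         if (length(missing_md)) paste0("; absent from metadata: ",
                                        paste(missing_md, collapse = ", ")))
  }
  if (!setequal(colnames(vals), metab$metabolite_id)) {
    stop("metabolite ids do not align between abundance and annotation tables")
  }
  vals <- vals[as.character(samples$sample_id),
               as.character(metab$metabolite_id), drop = FALSE]
  scale <- if (!is.null(samples$.scale)) {
    sc <- unique(samples$.scale)
    samples$.scale <- NULL
    sc[1]
  } else "raw"
  met_dataset(vals, samples, metab, scale = scale)
}

#' Write a dataset as three delimited tables
#'
#' Writes `abundance.tsv` (samples as rows), `samples.tsv` and
#' `metabolites.tsv` under `dir`. The matrix scale is carried in a
#' `.scale` column of the samples table so that [read_dataset()] restores
#' it. Round-trips the value matrix to better than 1e-9.
#'
#' @param d a `met_dataset`
#' @param dir output directory (created if absent)
#' @param sep field separator
#' @return invisibly, the three file paths
#' @export
write_dataset <- function(d, dir, sep = "\t") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("abundance.tsv", "samples.tsv", "metabolites.tsv"))
  vals <- matrix(sprintf("%.17g", d$abundance), nrow = nrow(d$abundance),
                 dimnames = dimnames(d$abundance))
  vals[is.na(d$abundance)] <- ""
  ab <- data.frame(sample_id = rownames(d$abundance), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ab, paths[1], sep = sep, quote = FALSE, row.names = FALSE)
  s <- d$samples
  s$.scale <- d$scale
  utils::write.table(s, paths[2], sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(d$metabolites, paths[3], sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
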