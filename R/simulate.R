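# Synthetic cohort generator. The latent model, per metabolite m of a given
# origin class, sample i in fine tissue t (supergroup g) of subject s:
#
#   x_{m,i} = lambda_{c,g} * mu_m + tau_{c,g} * z_{m,t,s}
#             + gamma_{m,g} * (age_s - mean age) + eps_{m,i}
#
# with mu_m ~ N(0, sigma_profile^2) the latent source profile shared across
# tissues, z ~ N(0,1) a per-subject, per-tissue distortion, and
# eps ~ N(0, sigma_noise^2) measurement noise. Maternal-transmitted classes
# attenuate the maternal profile most strongly along the meconium path;
# fetal (locally produced) classes mirror this with the decidua decoupled.
# Raw intensities are 2^(x + intensity_base); instrument drift adds
# qc_drift_slope * injection_order log2 units to every injection.

.SEC_BA <- c("Deoxycholic acid", "Glycodeoxycholic acid", "Lithocholic acid",
             "Sulfolithocholic acid", "Taurodeoxycholic acid")
.SCFA <- c("Propionic acid", "Butyric acid", "Isovaleric acid")
.AROMATIC <- c("Phenyllactic acid", "4-Hydroxyphenyllactic acid",
               "Indolelactic acid")
.PRIM_BA <- c("Muricholic acid", "1beta-Hydroxycholic acid",
              "3a,7a,12b-Trihydroxy-5b-cholanic acid", "Glycocholic acid",
              "Taurocholic acid", "Cholic acid", "7-Sulfocholic acid",
              "Taurochenodeoxycholic acid", "Chenodeoxycholic acid")

#' Default per-class attenuation and distortion parameters
#'
#' For each simulated origin class, `lambda` attenuates the latent source
#' profile per tissue supergroup and `tau` is the per-subject distortion sd
#' (log2 units). Maternal-transmitted metabolites keep most of their
#' profile in decidua and PV and lose it along the meconium path; locally
#' produced (fetal) metabolites mirror this with the decidua decoupled;
#' xenobiotics are maternal with an even weaker meconium path; steady-state
#' metabolites are uniform; null metabolites carry no shared profile.
#'
#' @return named list of classes, each `list(lambda = ..., tau = ...)` with
#'   one entry per supergroup.
#' @export
default_class_params <- function() {
  sg <- SUPERGROUPS
  mk <- function(lambda, tau) {
    list(lambda = stats::setNames(lambda, sg), tau = stats::setNames(tau, sg))
  }
  list(
    maternal     = mk(c(1.0, 0.6, 0.3, 0.8), c(0.1, 0.4, 1.2, 0.3)),
    xenobiotic   = mk(c(1.0, 0.6, 0.2, 0.8), c(0.1, 0.4, 1.2, 0.3)),
    local        = mk(c(0.3, 0.6, 1.0, 0.6), c(1.2, 0.4, 0.1, 0.6)),
    steady_state = mk(c(1.0, 1.0, 1.0, 1.0), c(0.3, 0.3, 0.3, 0.3)),
    null         = mk(c(0.0, 0.0, 0.0, 0.0), c(1.0, 1.0, 1.0, 1.0))
  )
}

#' Default planted gestational-age slopes
#'
#' Two secondary bile acids and one short-chain fatty acid decline with
#' gestational age in the fetal GI tract (the maternal-circulation
#' signature) and three primary bile acids increase (local fetal
#' synthesis); all other metabolite/tissue combinations have zero slope.
#'
#' @return data.frame with columns `name`, `supergroup`, `slope`
#'   (log2 units per week).
#' @export
default_age_slopes <- function() {
  data.frame(
    name = c("Deoxycholic acid", "Glycodeoxycholic acid", "Propionic acid",
             "Muricholic acid", "1beta-Hydroxycholic acid",
             "3a,7a,12b-Trihydroxy-5b-cholanic acid"),
    supergroup = "GI",
    slope = c(-0.3, -0.3, -0.3, 0.3, 0.3, 0.3),
    stringsAsFactors = FALSE)
}

#' Default cohort sample frame
#'
#' A fixed allocation of 49 study samples to 24 subjects (gestational ages
#' 14-23 weeks) reproducing the cohort's printed structure: 8 decidua,
#' 8 SI, 3 LI, 11 SI meconium, 8 LI meconium and 11 PV samples; one subject
#' (S16) carries all six tissues; at 23 weeks there are 4 decidua, 3 GI and
#' 7 meconium samples, giving 12 decidua/GI and 21 GI/meconium age-matched
#' pairs, and 88 decidua/GI and 209 GI/meconium pairs over all samples.
#'
#' @return data.frame with columns `subject_id`, `tissue`, `gestational_age`.
#' @export
default_sample_frame <- function() {
  spec <- list(
    S01 = list(14, c("decidua", "SI", "SI_mec")),
    S02 = list(15, c("decidua", "SI", "LI_mec")),
    S03 = list(16, c("decidua", "SI", "SI_mec")),
    S04 = list(18, c("decidua", "SI", "LI_mec")),
    S05 = list(19, c("SI", "SI_mec")),
    S06 = list(20, c("SI", "SI_mec")),
    S07 = list(21, c("LI", "PV")),
    S08 = list(22, c("LI", "LI_mec", "PV")),
    S09 = list(17, c("SI_mec", "PV")),
    S10 = list(18, c("SI_mec", "LI_mec")),
    S11 = list(20, "PV"),
    S12 = list(14, "PV"),
    S13 = list(15, "PV"),
    S14 = list(16, "PV"),
    S15 = list(18, "PV"),
    S16 = list(23, c("decidua", "SI", "LI", "SI_mec", "LI_mec", "PV")),
    S17 = list(23, c("decidua", "SI_mec")),
    S18 = list(23, c("decidua", "LI_mec")),
    S19 = list(23, c("decidua", "PV")),
    S20 = list(23, c("SI", "SI_mec", "LI_mec")),
    S21 = list(23, "SI_mec"),
    S22 = list(19, "PV"),
    S23 = list(20, "LI_mec"),
    S24 = list(21, "SI_mec"))
  do.call(rbind, lapply(names(spec), function(s) {
    data.frame(subject_id = s, tissue = spec[[s]][[2]],
               gestational_age = spec[[s]][[1]], stringsAsFactors = FALSE)
  }))
}

#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic cohort. Defaults
#' emulate the study conditions: 24 subjects, 49 study samples in the fixed
#' [default_sample_frame()], panels of 41 microbial, 47 xenobiotic,
#' 9 primary-bile-acid and 8 fetal-derived metabolites plus steady-state and
#' null filler, 7 blanks, 8 QCs and one study sample without location
#' information (65 columns in the raw matrix).
#'
#' @param sample_frame data.frame of study samples (`subject_id`, `tissue`,
#'   `gestational_age`).
#' @param n_subjects expected number of subjects; must match the frame.
#' @param panel_sizes named counts for the `microbial`, `xenobiotic`,
#'   `fetal_derived`, `primary_BA`, `steady_state` and `null` panels. The
#'   microbial panel must be at least 11 (it embeds 5 named secondary bile
#'   acids, 3 SCFAs and 3 aromatic lactic acids).
#' @param sigma_profile sd of the latent per-metabolite source profile
#'   (log2 units).
#' @param class_params per-class attenuation/distortion, see
#'   [default_class_params()].
#' @param sigma_noise per-measurement sd (log2 units).
#' @param age_slopes data.frame (`name`, `supergroup`, `slope`) of planted
#'   gestational-age trends; `NULL` for none.
#' @param missing_rate expected fraction of left-censored (below detection
#'   limit) study/QC cells per metabolite; censoring removes the lowest
#'   intensities, matching the assumption behind half-minimum imputation.
#' @param n_blanks,n_qc counts of blank and pooled-QC injections.
#' @param include_unlocated add one study sample with tissue `none`.
#' @param qc_drift_slope instrument drift, log2 units per injection.
#' @param n_isomer_duplicates number of named metabolites duplicated as
#'   isomeric peaks.
#' @param n_unnamed number of unannotated (empty-name) peaks.
#' @param n_contaminants number of blank-dominant contaminant peaks.
#' @param intensity_base global log2 intensity offset for raw peaks.
#' @param seed default RNG seed used by [generate_dataset()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sample_frame = default_sample_frame(),
                       n_subjects = length(unique(sample_frame$subject_id)),
                       panel_sizes = c(microbial = 41, xenobiotic = 47,
                                       fetal_derived = 8, primary_BA = 9,
                                       steady_state = 30, null = 150),
                       sigma_profile = 1.5,
                       class_params = default_class_params(),
                       sigma_noise = 0.3,
                       age_slopes = default_age_slopes(),
                       missing_rate = 0.05,
                       n_blanks = 7, n_qc = 8,
                       include_unlocated = TRUE,
                       qc_drift_slope = 0.02,
                       n_isomer_duplicates = 10,
                       n_unnamed = 20,
                       n_contaminants = 15,
                       intensity_base = 15,
                       seed = 1L) {
  stopifnot(all(c("subject_id", "tissue", "gestational_age") %in%
                  names(sample_frame)))
  if (!all(sample_frame$tissue %in% TISSUES)) {
    stop("sample_frame contains unknown tissue codes")
  }
  if (n_subjects != length(unique(sample_frame$subject_id))) {
    stop("tissue plan incompatible with n_subjects: frame has ",
         length(unique(sample_frame$subject_id)), " subjects")
  }
  req <- c("microbial", "xenobiotic", "fetal_derived", "primary_BA",
           "steady_state", "null")
  if (!all(req %in% names(panel_sizes))) {
    stop("panel_sizes must name: ", paste(req, collapse = ", "))
  }
  if (panel_sizes[["microbial"]] < 11) {
    stop("microbial panel must hold at least the 11 named compounds")
  }
  if (any(panel_sizes < 0)) stop("panel sizes must be non-negative")
  for (cl in class_params) {
    if (any(cl$lambda < 0 | cl$lambda > 1)) {
      stop("attenuations (lambda) must lie in [0, 1]")
    }
    if (any(cl$tau < 0)) stop("distortion sds (tau) must be non-negative")
  }
  if (sigma_profile < 0 || sigma_noise < 0 || missing_rate < 0 ||
      missing_rate >= 1) {
    stop("sds must be non-negative and missing_rate in [0, 1)")
  }
  structure(list(sample_frame = sample_frame, n_subjects = n_subjects,
                 panel_sizes = panel_sizes, sigma_profile = sigma_profile,
                 class_params = class_params, sigma_noise = sigma_noise,
                 age_slopes = age_slopes, missing_rate = missing_rate,
                 n_blanks = n_blanks, n_qc = n_qc,
                 include_unlocated = include_unlocated,
                 qc_drift_slope = qc_drift_slope,
                 n_isomer_duplicates = n_isomer_duplicates,
                 n_unnamed = n_unnamed, n_contaminants = n_contaminants,
                 intensity_base = intensity_base, seed = seed),
            class = "sim_config")
}

# metabolite annotation skeleton (before isomer duplication)
.build_metabolite_table <- function(config) {
  ps <- config$panel_sizes
  n_generic_microbial <- ps[["microbial"]] - 11L
  row <- function(name, level, panel, class) {
    data.frame(name = name, annotation_level = level, panel = panel,
               sim_class = class, is_contaminant = FALSE,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row(.SEC_BA, 1L, "microbial;secondary_BA", "maternal"),
    row(.SCFA, 1L, "microbial;SCFA", "maternal"),
    row(.AROMATIC, 1L, "microbial;aromatic", "maternal"),
    if (n_generic_microbial > 0)
      row(sprintf("Microbial metabolite %02d", seq_len(n_generic_microbial)),
          2L, "microbial", "maternal"),
    if (ps[["xenobiotic"]] > 0)
      row(sprintf("Xenobiotic %02d", seq_len(ps[["xenobiotic"]])), 2L,
          "xenobiotic", "xenobiotic"),
    if (ps[["primary_BA"]] > 0)
      row(.PRIM_BA[seq_len(ps[["primary_BA"]])], 1L, "primary_BA", "local"),
    if (ps[["fetal_derived"]] > 0)
      row(sprintf("Fetal metabolite %02d", seq_len(ps[["fetal_derived"]])),
          2L, "fetal_derived", "local"),
    if (ps[["steady_state"]] > 0)
      row(sprintf("Endogenous metabolite %02d", seq_len(ps[["steady_state"]])),
          2L, "other", "steady_state"),
    if (ps[["null"]] > 0)
      row(sprintf("Unassigned metabolite %03d", seq_len(ps[["null"]])), 3L,
          "other", "null"))
  if (config$n_contaminants > 0) {
    cont <- row(sprintf("Background contaminant %02d",
                        seq_len(config$n_contaminants)), 3L, "other", "null")
    cont$is_contaminant <- TRUE
    tab <- rbind(tab, cont)
  }
  if (config$n_unnamed > 0) {
    tab <- rbind(tab, row(rep("", config$n_unnamed), 4L, "other", "null"))
  }
  tab$metabolite_id <- sprintf("M%04d", seq_len(nrow(tab)))
  tab$isomer_group <- ""
  tab[, c("metabolite_id", "name", "annotation_level", "isomer_group",
          "panel", "sim_class", "is_contaminant")]
}

# injection sequence: blank+QC lead-in, a blank/QC pair after every ten
# study injections, spares appended at the end of the run
.build_sample_table <- function(config) {
  frame <- config$sample_frame
  study <- data.frame(
    sample_id = paste(frame$subject_id, frame$tissue, sep = "_"),
    subject_id = frame$subject_id, tissue = frame$tissue,
    gestational_age = frame$gestational_age, role = "study",
    stringsAsFactors = FALSE)
  if (config$include_unlocated) {
    study <- rbind(study, data.frame(
      sample_id = "UNK_none", subject_id = "UNK", tissue = "none",
      gestational_age = 20, role = "study", stringsAsFactors = FALSE))
  }
  ctrl <- function(role, n, prefix) {
    if (n <= 0) return(NULL)
    data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
               subject_id = "pool", tissue = "none", gestational_age = NA_real_,
               role = role, stringsAsFactors = FALSE)
  }
  blanks <- ctrl("blank", config$n_blanks, "BLK")
  qcs <- ctrl("QC", config$n_qc, "QC")

  seq_ids <- character(0)
  bi <- qi <- 1L
  take <- function(pool, i) if (i <= nrow(pool)) pool$sample_id[i] else NULL
  si <- 1L
  while (si <= nrow(study)) {
    b <- take(blanks, bi); q <- take(qcs, qi)
    seq_ids <- c(seq_ids, b, q)
    bi <- bi + !is.null(b); qi <- qi + !is.null(q)
    hi <- min(si + 9L, nrow(study))
    seq_ids <- c(seq_ids, study$sample_id[si:hi])
    si <- hi + 1L
  }
  if (!is.null(blanks) && bi <= nrow(blanks)) {
    seq_ids <- c(seq_ids, blanks$sample_id[bi:nrow(blanks)])
  }
  if (!is.null(qcs) && qi <= nrow(qcs)) {
    seq_ids <- c(seq_ids, qcs$sample_id[qi:nrow(qcs)])
  }
  samp <- rbind(study, blanks, qcs)
  samp$injection_order <- match(samp$sample_id, seq_ids)
  samp
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws a raw-scale abundance matrix under the latent maternal/local/
#' steady-state model (see the package vignette), including blanks with low
#' background, blank-dominant contaminant peaks, pooled QC injections,
#' linear (log2) instrument drift over the injection sequence, isomeric
#' duplicate peaks, unnamed peaks and left-censored missing cells. Identical
#' seeds give identical output.
#'
#' @param config a [sim_config()]
#' @param seed integer RNG seed (defaults to `config$seed`)
#' @return list with elements `dataset` (a raw-scale `met_dataset`) and
#'   `ground_truth` (list: `metabolites` with per-metabolite origin label,
#'   latent profile and contaminant/duplicate flags; `age_slopes`;
#'   `expected_correlations`, the analytic panel correlations per
#'   supergroup pair from [expected_profile_correlation()]).
#' @export
generate_dataset <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  met <- .build_metabolite_table(config)
  samp <- .build_sample_table(config)
  n_base <- nrow(met)
  study <- samp[samp$role == "study" & samp$tissue != "none", ]
  sg <- tissue_supergroup(study$tissue)
  age_center <- mean(study$gestational_age)

  mu <- stats::rnorm(n_base, 0, config$sigma_profile)

  # per-(tissue, subject) standard-normal distortions, scaled by class tau
  ts_key <- paste(study$tissue, study$subject_id, sep = "/")
  uts <- unique(ts_key)
  z <- matrix(stats::rnorm(n_base * length(uts)), nrow = n_base,
              dimnames = list(NULL, uts))

  cls <- met$sim_class
  lam_by_sg <- vapply(SUPERGROUPS, function(g) {
    per_class <- vapply(config$class_params, function(cp) cp$lambda[[g]],
                        numeric(1))
    unname(per_class[cls])
  }, numeric(n_base))
  tau_by_sg <- vapply(SUPERGROUPS, function(g) {
    per_class <- vapply(config$class_params, function(cp) cp$tau[[g]],
                        numeric(1))
    unname(per_class[cls])
  }, numeric(n_base))
  # planted age slopes, matched by metabolite name within a supergroup
  slope_of <- function(g) {
    s <- numeric(n_base)
    if (!is.null(config$age_slopes)) {
      as_ <- config$age_slopes[config$age_slopes$supergroup == g, ]
      s[match(as_$name, met$name)] <- as_$slope
    }
    s
  }
  slopes_by_sg <- lapply(stats::setNames(SUPERGROUPS, SUPERGROUPS), slope_of)

  x_study <- matrix(NA_real_, nrow = nrow(study), ncol = n_base)
  for (i in seq_len(nrow(study))) {
    g <- sg[i]
    x_study[i, ] <- lam_by_sg[, g] * mu + tau_by_sg[, g] * z[, ts_key[i]] +
      slopes_by_sg[[g]] * (study$gestational_age[i] - age_center) +
      stats::rnorm(n_base, 0, config$sigma_noise)
  }
  # contaminants: depleted in tissue, dominant in blanks
  contam <- met$is_contaminant
  if (any(contam)) {
    x_study[, contam] <- matrix(
      stats::rnorm(nrow(study) * sum(contam), -2, 0.5), nrow = nrow(study))
  }
  rownames(x_study) <- study$sample_id

  rows <- list(x_study)
  unk <- samp$sample_id[samp$role == "study" & samp$tissue == "none"]
  if (length(unk)) {
    x_unk <- matrix(mu + stats::rnorm(n_base, 0, 0.5), nrow = 1,
                    dimnames = list(unk, NULL))
    x_unk[, contam] <- stats::rnorm(sum(contam), -2, 0.5)
    rows <- c(rows, list(x_unk))
  }
  blk_ids <- samp$sample_id[samp$role == "blank"]
  if (length(blk_ids)) {
    x_blk <- matrix(stats::rnorm(length(blk_ids) * n_base, -8, 0.5),
                    nrow = length(blk_ids), dimnames = list(blk_ids, NULL))
    x_blk[, contam] <- matrix(stats::rnorm(length(blk_ids) * sum(contam),
                                           2, 0.5), nrow = length(blk_ids))
    rows <- c(rows, list(x_blk))
  }
  qc_ids <- samp$sample_id[samp$role == "QC"]
  if (length(qc_ids)) {
    pool <- colMeans(x_study)
    x_qc <- matrix(rep(pool, each = length(qc_ids)), nrow = length(qc_ids),
                   dimnames = list(qc_ids, NULL)) +
      matrix(stats::rnorm(length(qc_ids) * n_base, 0, 0.1),
             nrow = length(qc_ids))
    rows <- c(rows, list(x_qc))
  }
  x <- do.call(rbind, rows)
  x <- x[samp$sample_id, , drop = FALSE]

  # isomeric duplicate peaks: a copy with extra peak-picking noise
  n_dup <- config$n_isomer_duplicates
  truth_dup <- data.frame(metabolite_id = character(),
                          duplicate_of = character(),
                          stringsAsFactors = FALSE)
  if (n_dup > 0) {
    cand <- which(met$name != "" & !met$is_contaminant)
    dup_idx <- sort(sample(cand, min(n_dup, length(cand))))
    x_dup <- x[, dup_idx, drop = FALSE] +
      matrix(stats::rnorm(nrow(x) * length(dup_idx), 0, 0.3), nrow = nrow(x))
    dup_met <- met[dup_idx, ]
    dup_met$metabolite_id <- paste0(met$metabolite_id[dup_idx], "i")
    grp <- paste0("iso_", met$metabolite_id[dup_idx])
    met$isomer_group[dup_idx] <- grp
    dup_met$isomer_group <- grp
    truth_dup <- data.frame(metabolite_id = dup_met$metabolite_id,
                            duplicate_of = met$metabolite_id[dup_idx],
                            stringsAsFactors = FALSE)
    met <- rbind(met, dup_met)
    x <- cbind(x, x_dup)
  }
  colnames(x) <- met$metabolite_id

  # instrument drift over the injection sequence, then raw intensities
  drift <- config$qc_drift_slope * samp$injection_order[match(rownames(x),
                                                              samp$sample_id)]
  raw <- 2^(sweep(x, 1, drift, "+") + config$intensity_base)

  # left-censored missingness on study and QC injections: the lowest cells
  # of each metabolite drop out (detection-limit censoring), at an expected
  # per-metabolite rate of missing_rate; every metabolite keeps at least
  # one observed study value and three QC values
  if (config$missing_rate > 0) {
    roles <- samp$role[match(rownames(raw), samp$sample_id)]
    maskable <- which(roles != "blank")
    n_qc_rows <- sum(roles == "QC")
    for (j in seq_len(ncol(raw))) {
      k <- stats::rbinom(1, length(maskable), config$missing_rate)
      k <- min(k, length(maskable) - max(2, n_qc_rows - 3 + 1))
      if (k <= 0) next
      lowest <- maskable[order(raw[maskable, j])][seq_len(k)]
      raw[lowest, j] <- NA_real_
      # restore guarantees if censoring stripped a required row class
      if (all(is.na(raw[rownames(raw) %in% study$sample_id, j]))) {
        ridx <- which(rownames(raw) %in% study$sample_id)
        raw[ridx[1], j] <- 2^(x[ridx[1], j] + drift[ridx[1]] +
                                config$intensity_base)
      }
      qidx <- which(roles == "QC")
      if (length(qidx) >= 3 && sum(!is.na(raw[qidx, j])) < 3) {
        need <- qidx[is.na(raw[qidx, j])]
        need <- need[seq_len(3 - sum(!is.na(raw[qidx, j])))]
        raw[need, j] <- 2^(x[need, j] + drift[need] + config$intensity_base)
      }
    }
  }

  dataset <- met_dataset(raw, samp,
                         met[, c("metabolite_id", "name", "annotation_level",
                                 "isomer_group", "panel")],
                         scale = "raw")

  origin <- c(maternal = "maternal", xenobiotic = "maternal",
              local = "local", steady_state = "steady_state",
              null = "null")[met$sim_class]
  truth_met <- data.frame(metabolite_id = met$metabolite_id,
                          origin = unname(origin),
                          sim_class = met$sim_class,
                          mu = c(mu, mu[match(truth_dup$duplicate_of,
                                              met$metabolite_id[seq_len(n_base)])]),
                          is_contaminant = met$is_contaminant,
                          stringsAsFactors = FALSE)
  truth_met$duplicate_of <- truth_dup$duplicate_of[
    match(truth_met$metabolite_id, truth_dup$metabolite_id)]

  expected <- .expected_correlation_table(config)
  ground_truth <- list(metabolites = truth_met,
                       age_slopes = config$age_slopes,
                       expected_correlations = expected)
  list(dataset = dataset, ground_truth = ground_truth)
}

.expected_correlation_table <- function(config) {
  pairs <- utils::combn(SUPERGROUPS, 2)
  cls_of_panel <- c(microbial = "maternal", xenobiotic = "xenobiotic",
                    fetal_derived = "local")
  out <- list()
  for (panel in names(cls_of_panel)) {
    cp <- config$class_params[[cls_of_panel[[panel]]]]
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      rho <- tryCatch(
        expected_profile_correlation(config$sigma_profile,
                                     cp$lambda[[a]], cp$lambda[[b]],
                                     cp$tau[[a]], cp$tau[[b]],
                                     config$sigma_noise),
        error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(panel = panel, tissue_a = a,
                                            tissue_b = b, rho = rho,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Analytic large-panel correlation between two samples sharing a profile
#'
#' For two samples that observe the same latent metabolite profile `mu`
#' (sd `sigma_profile`) through attenuations `lambda_a`, `lambda_b` with
#' distortion sds `tau_a`, `tau_b` and measurement noise `sigma_noise`, the
#' Pearson correlation of their panel vectors converges (panel size to
#' infinity) to
#' `lambda_a*lambda_b*sigma^2 / sqrt((lambda_a^2 sigma^2 + tau_a^2 + noise^2)
#' (lambda_b^2 sigma^2 + tau_b^2 + noise^2))`.
#'
#' @param sigma_profile sd of the shared latent profile
#' @param lambda_a,lambda_b attenuations in `[0, 1]`
#' @param tau_a,tau_b distortion sds
#' @param sigma_noise measurement noise sd
#' @return the limiting Pearson correlation
#' @export
expected_profile_correlation <- function(sigma_profile, lambda_a, lambda_b,
                                         tau_a, tau_b, sigma_noise) {
  stopifnot(sigma_profile >= 0, tau_a >= 0, tau_b >= 0, sigma_noise >= 0)
  s2 <- sigma_profile^2
  var_a <- lambda_a^2 * s2 + tau_a^2 + sigma_noise^2
  var_b <- lambda_b^2 * s2 + tau_b^2 + sigma_noise^2
  if (var_a <= 0 || var_b <= 0) {
    stop("undefined correlation: a sample with zero total variance")
  }
  lambda_a * lambda_b * s2 / sqrt(var_a * var_b)
}

#' Write a simulation (dataset tables plus ground truth) to a directory
#'
#' @param sim result of [generate_dataset()]
#' @param dir output directory
#' @return invisibly, the written file paths
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_dataset(sim$dataset, dir)
  gt <- file.path(dir, "ground_truth.tsv")
  utils::write.table(sim$ground_truth$metabolites, gt, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ec <- file.path(dir, "expected_correlations.tsv")
  utils::write.table(sim$ground_truth$expected_correlations, ec, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, gt, ec))
}

#' Simulate a two-group log2 dataset with planted differential effects
#'
#' Per-metabolite variances are drawn from a scaled inverse-chi-square prior
#' (`s0_sq * d0 / chisq(d0)`) and the first `n_effect` metabolites carry an
#' `effect` log2-unit shift in group A (GI) relative to group B (decidua).
#' Used for sensitivity/FDR characterisation of the differential stage.
#'
#' @param n_metabolites total metabolites
#' @param n_effect number with a planted shift
#' @param effect shift in log2 units
#' @param n_a,n_b group sizes (group A samples are `SI`, group B `decidua`)
#' @param d0,s0_sq variance prior (degrees of freedom, scale)
#' @param seed RNG seed
#' @return list: `dataset` (log2-normalized-scale `met_dataset`) and
#'   `is_effect` logical vector of planted truth.
#' @export
simulate_two_group <- function(n_metabolites = 2000, n_effect = 100,
                               effect = 4, n_a = 11, n_b = 8,
                               d0 = 4, s0_sq = 0.25, seed = 1L) {
  set.seed(seed)
  s2 <- s0_sq * d0 / stats::rchisq(n_metabolites, df = d0)
  n <- n_a + n_b
  x <- matrix(stats::rnorm(n * n_metabolites, 0,
                           rep(sqrt(s2), each = n)), nrow = n)
  is_effect <- seq_len(n_metabolites) <= n_effect
  x[seq_len(n_a), is_effect] <- x[seq_len(n_a), is_effect] + effect
  ids <- sprintf("M%04d", seq_len(n_metabolites))
  colnames(x) <- ids
  samples <- data.frame(
    sample_id = sprintf("X%02d", seq_len(n)),
    subject_id = sprintf("P%02d", seq_len(n)),
    tissue = rep(c("SI", "decidua"), c(n_a, n_b)),
    gestational_age = 18, role = "study",
    injection_order = seq_len(n), stringsAsFactors = FALSE)
  rownames(x) <- samples$sample_id
  metab <- data.frame(metabolite_id = ids, name = ids, annotation_level = 2L,
                      isomer_group = "", panel = "other",
                      stringsAsFactors = FALSE)
  list(dataset = met_dataset(x, samples, metab, scale = "log2_normalized"),
       is_effect = is_effect)
}
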