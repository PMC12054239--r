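# Shared fixtures, built in code.

# tiny hand-written dataset: 3 samples x 2 metabolites
toy_dataset <- function(values = matrix(c(1, 2, 3, 10, 20, 30), nrow = 3),
                        scale = "raw") {
  samples <- data.frame(
    sample_id = c("A", "B", "C"),
    subject_id = c("s1", "s1", "s2"),
    tissue = c("decidua", "SI", "SI"),
    gestational_age = c(20, 20, 21),
    role = "study",
    injection_order = 1:3,
    stringsAsFactors = FALSE)
  metab <- data.frame(
    metabolite_id = c("m1", "m2"),
    name = c("Metabolite one", "Metabolite two"),
    annotation_level = c(1L, 2L),
    isomer_group = "",
    panel = c("microbial", "other"),
    stringsAsFactors = FALSE)
  dimnames(values) <- list(samples$sample_id, metab$metabolite_id)
  met_dataset(values, samples, metab, scale = scale)
}

# dataset with explicit per-sample values for a named tissue layout;
# rows of `values` follow the order of `tissue`
layout_dataset <- function(tissue, values, subject = NULL, age = NULL,
                           role = NULL, scale = "log2_normalized",
                           panel = NULL, names_ = NULL) {
  n <- length(tissue)
  if (is.null(subject)) subject <- sprintf("s%02d", seq_len(n))
  if (is.null(age)) age <- rep(20, n)
  if (is.null(role)) role <- ifelse(tissue == "none", "blank", "study")
  samples <- data.frame(
    sample_id = sprintf("smp%02d", seq_len(n)),
    subject_id = subject, tissue = tissue, gestational_age = age,
    role = role, injection_order = seq_len(n), stringsAsFactors = FALSE)
  samples$gestational_age[samples$role != "study"] <- NA
  m <- ncol(values)
  if (is.null(panel)) panel <- rep("other", m)
  if (is.null(names_)) names_ <- sprintf("Compound %02d", seq_len(m))
  metab <- data.frame(
    metabolite_id = sprintf("m%03d", seq_len(m)),
    name = names_, annotation_level = 2L, isomer_group = "",
    panel = panel, stringsAsFactors = FALSE)
  dimnames(values) <- list(samples$sample_id, metab$metabolite_id)
  met_dataset(values, samples, metab, scale = scale)
}

# small fast generator config for unit tests; dots override the defaults
fast_config <- function(...) {
  args <- list(panel_sizes = c(microbial = 11, xenobiotic = 8,
                               fetal_derived = 8, primary_BA = 9,
                               steady_state = 5, null = 20),
               n_isomer_duplicates = 3, n_unnamed = 4, n_contaminants = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# generator config with equal decidua/meconium distortion paths and no
# planted age trends: the no-difference null for calibration checks
null_attribution_config <- function(...) {
  cp <- default_class_params()
  for (cl in c("maternal", "xenobiotic", "local")) {
    cp[[cl]]$lambda[c("decidua", "meconium")] <- 0.65
    cp[[cl]]$tau[c("decidua", "meconium")] <- 0.4
  }
  sim_config(class_params = cp, age_slopes = NULL, ...)
}
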