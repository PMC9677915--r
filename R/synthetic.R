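## Synthetic cohort generator. Emulates the statistical structure the
## analysis assumes: negative-binomial bulk counts over a block-correlated
## log2 latent layer, a tumor vs non-tumor contrast with planted
## differentially expressed "matrisome" genes, two tumor ECM subtypes with a
## planted survival hazard ratio, and a premalignant cohort whose
## progressive lesions drift toward the tumor profile.

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set consumed by
#' [simulateBulkCohort()] and [simulatePremalignantCohort()]. Identical
#' config + seed yields identical output; the root seed spawns fixed
#' substreams per generation stage (gene template, expression noise,
#' survival, censoring, library sizes, premalignant cohort) so adding a
#' stage never perturbs earlier draws.
#'
#' @param n_tumor,n_non_tumor sample counts per tissue class.
#' @param n_genes_total total genes simulated (named G0001, ...).
#' @param n_matrisome leading genes flagged as matrisome in the truth table
#'   (first half core matrisome, second half matrisome-associated).
#' @param n_signature planted risk-signature genes (half shifted up, half
#'   down in tumors).
#' @param block_spec list of \code{c(size, rho)} pairs: correlated gene
#'   blocks with equicorrelation \code{rho} in [0, 1). The first block is
#'   the ECM program additionally shifted in ECM-High tumors.
#' @param effect_size_sd_units per-gene mean shift of planted genes in
#'   tumors, in latent-SD (= log2 SD) units.
#' @param matreotype_fraction fraction of tumors assigned ECM-High.
#' @param planted_log_hr log hazard ratio of ECM-High vs ECM-Low.
#' @param baseline_hazard exponential event hazard per month for ECM-Low.
#' @param censor_rate target random-censoring fraction in (0, 1).
#' @param horizon_months administrative censoring horizon.
#' @param nb_dispersion negative-binomial dispersion: variance
#'   \code{mu + nb_dispersion * mu^2}.
#' @param library_size_range range of per-sample library size factors.
#' @param seed integer root seed.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_tumor = 240L, n_non_tumor = 40L,
                            n_genes_total = 2000L, n_matrisome = 300L,
                            n_signature = 20L,
                            block_spec = list(c(40, 0.7), c(30, 0.5), c(20, 0.3)),
                            effect_size_sd_units = 1,
                            matreotype_fraction = 0.5,
                            planted_log_hr = log(2),
                            baseline_hazard = 0.02,
                            censor_rate = 0.2,
                            horizon_months = 240,
                            nb_dispersion = 0.2,
                            library_size_range = c(0.7, 1.3),
                            seed = 1L) {
  cfg <- list(
    n_tumor = as.integer(n_tumor), n_non_tumor = as.integer(n_non_tumor),
    n_genes_total = as.integer(n_genes_total),
    n_matrisome = as.integer(n_matrisome),
    n_signature = as.integer(n_signature),
    block_spec = lapply(block_spec, as.numeric),
    effect_size_sd_units = as.numeric(effect_size_sd_units),
    matreotype_fraction = as.numeric(matreotype_fraction),
    planted_log_hr = as.numeric(planted_log_hr),
    baseline_hazard = as.numeric(baseline_hazard),
    censor_rate = as.numeric(censor_rate),
    horizon_months = as.numeric(horizon_months),
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_range = as.numeric(library_size_range),
    seed = as.integer(seed))
  counts <- c(cfg$n_tumor, cfg$n_non_tumor, cfg$n_genes_total,
              cfg$n_matrisome, cfg$n_signature)
  if (any(counts <= 0L))
    stop("config error: all counts must be positive")
  rhos <- vapply(cfg$block_spec, `[`, numeric(1), 2L)
  sizes <- vapply(cfg$block_spec, `[`, numeric(1), 1L)
  if (any(rhos < 0 | rhos >= 1))
    stop("config error: block correlations must lie in [0, 1)")
  if (any(sizes < 2))
    stop("config error: correlated blocks need >= 2 genes")
  core <- floor(cfg$n_matrisome / 2)
  if (sum(sizes) + cfg$n_signature > core)
    stop("config error: blocks plus signature genes must fit inside the ",
         "core-matrisome region (", core, " genes)")
  if (cfg$n_matrisome > cfg$n_genes_total)
    stop("config error: n_matrisome exceeds n_genes_total")
  if (cfg$matreotype_fraction <= 0 || cfg$matreotype_fraction >= 1)
    stop("config error: matreotype_fraction must lie in (0, 1)")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("config error: censor_rate must lie in [0, 1)")
  if (cfg$baseline_hazard <= 0)
    stop("config error: baseline_hazard must be positive")
  if (cfg$nb_dispersion < 0)
    stop("config error: nb_dispersion must be non-negative")
  if (length(cfg$library_size_range) != 2L ||
      cfg$library_size_range[1] <= 0 ||
      diff(cfg$library_size_range) < 0)
    stop("config error: library_size_range must be an increasing positive pair")
  class(cfg) <- "SyntheticConfig"
  cfg
}

.stageSeeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(2147483646L, 6L),
           c("template", "expression", "survival", "censoring",
             "library", "premalignant"))
}

## Deterministic gene layout: names, baseline means, block membership and
## the per-gene latent tumor shift (SD units), drawn from its own substream.
.geneTemplate <- function(cfg) {
  seeds <- .stageSeeds(cfg$seed)
  set.seed(seeds[["template"]])
  n <- cfg$n_genes_total
  genes <- sprintf(paste0("G%0", max(4L, nchar(n)), "d"), seq_len(n))
  baseline <- runif(n, 3, 8)
  block <- integer(n)
  rho <- numeric(n)
  at <- 1L
  for (b in seq_along(cfg$block_spec)) {
    s <- as.integer(cfg$block_spec[[b]][1])
    block[at:(at + s - 1L)] <- b
    rho[at:(at + s - 1L)] <- cfg$block_spec[[b]][2]
    at <- at + s
  }
  role <- rep("none", n)
  sig <- at:(at + cfg$n_signature - 1L)
  nUp <- ceiling(cfg$n_signature / 2)
  role[sig[seq_len(nUp)]] <- "sig_up"
  role[sig[-seq_len(nUp)]] <- "sig_dn"
  role[block == 1L] <- "ecm_program"
  shift <- numeric(n)
  shift[role == "sig_up"] <- cfg$effect_size_sd_units
  shift[role == "sig_dn"] <- -cfg$effect_size_sd_units
  alias <- rep(NA_character_, n)
  alias[role == "sig_up"] <- sprintf("SIG_UP_%02d", seq_len(sum(role == "sig_up")))
  alias[role == "sig_dn"] <- sprintf("SIG_DN_%02d", seq_len(sum(role == "sig_dn")))
  core <- floor(cfg$n_matrisome / 2)
  division <- rep(NA_character_, n)
  division[seq_len(core)] <- "core_matrisome"
  if (cfg$n_matrisome > core)
    division[(core + 1L):cfg$n_matrisome] <- "matrisome_associated"
  coreCats <- c("collagens", "proteoglycans", "ECM_glycoproteins")
  assocCats <- c("ECM_affiliated", "ECM_regulators", "secreted_factors")
  category <- rep(NA_character_, n)
  category[seq_len(core)] <- rep_len(coreCats, core)
  if (cfg$n_matrisome > core)
    category[(core + 1L):cfg$n_matrisome] <-
      rep_len(assocCats, cfg$n_matrisome - core)
  data.frame(gene = genes, baseline_log2 = baseline, block = block,
             rho = rho, role = role, tumor_shift_sd = shift, alias = alias,
             division = division, category = category,
             stringsAsFactors = FALSE)
}

## Equicorrelated latent draw: sqrt(rho) * shared + sqrt(1-rho) * own is an
## exact draw from the compound-symmetric N(0, R) with R_ij = rho.
.latentNoise <- function(template, nSamples) {
  n <- nrow(template)
  z <- matrix(rnorm(n * nSamples), n, nSamples)
  for (b in unique(template$block[template$block > 0L])) {
    idx <- which(template$block == b)
    rho <- template$rho[idx[1]]
    shared <- rnorm(nSamples)  # one factor per sample, shared by the block
    z[idx, ] <- sweep(sqrt(1 - rho) * z[idx, , drop = FALSE],
                      2, sqrt(rho) * shared, `+`)
  }
  z
}

#' Simulate a bulk tumor/non-tumor cohort with survival
#'
#' Draws a latent per-gene log2 expression layer (block-structured Gaussian
#' noise around uniform baselines), shifts planted signature genes in
#' tumors (half up, half down) and the ECM-program block additionally in
#' ECM-High tumors, then draws negative-binomial counts around
#' \code{2^latent} scaled by per-sample library factors. Tumor survival
#' times are exponential with the hazard multiplied by
#' \code{exp(planted_log_hr)} for ECM-High; censoring combines a random
#' exponential component calibrated to \code{censor_rate} with an
#' administrative horizon.
#'
#' @param cfg a [syntheticConfig()] object.
#' @return List with elements \code{se} (counts
#'   \code{SummarizedExperiment} with clinical \code{colData}),
#'   \code{metadata} (clinical data.frame), \code{survival} (tumor survival
#'   table), \code{truth_genes} and \code{truth_samples} (planted-truth
#'   records) and \code{config}.
#' @export
simulateBulkCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  seeds <- .stageSeeds(cfg$seed)
  template <- .geneTemplate(cfg)
  nT <- cfg$n_tumor; nN <- cfg$n_non_tumor
  nS <- nT + nN
  ids <- c(sprintf("T%03d", seq_len(nT)), sprintf("N%03d", seq_len(nN)))
  tissue <- rep(c("tumor", "non_tumor"), c(nT, nN))

  nHigh <- round(cfg$matreotype_fraction * nT)
  matreotype <- c(rep(c("ECM_High", "ECM_Low"), c(nHigh, nT - nHigh)),
                  rep("Non_Tumor", nN))

  set.seed(seeds[["expression"]])
  latent <- template$baseline_log2 + .latentNoise(template, nS)
  isTumor <- tissue == "tumor"
  latent[, isTumor] <- latent[, isTumor] + template$tumor_shift_sd
  isHigh <- matreotype == "ECM_High"
  ecm <- template$role == "ecm_program"
  latent[ecm, isHigh] <- latent[ecm, isHigh] + cfg$effect_size_sd_units

  set.seed(seeds[["library"]])
  sf <- runif(nS, cfg$library_size_range[1], cfg$library_size_range[2])
  mu <- sweep(2^latent, 2, sf, `*`)
  counts <- matrix(
    if (cfg$nb_dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else rpois(length(mu), lambda = mu),
    nrow(mu), ncol(mu))
  dimnames(counts) <- list(template$gene, ids)

  set.seed(seeds[["survival"]])
  age <- round(rnorm(nS, 68, 8))
  stage <- ifelse(isTumor, sample(c("I", "II", "III", "IV"), nS,
                                  replace = TRUE,
                                  prob = c(0.35, 0.3, 0.25, 0.1)), NA)
  sex <- sample(c("male", "female"), nS, replace = TRUE)
  smoking <- sample(c("current", "former", "never"), nS, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
  hazard <- cfg$baseline_hazard *
    exp(cfg$planted_log_hr * as.numeric(matreotype == "ECM_High"))
  eventTime <- ifelse(isTumor, rexp(nS, rate = hazard), NA)

  set.seed(seeds[["censoring"]])
  f <- cfg$matreotype_fraction
  meanHazard <- cfg$baseline_hazard *
    ((1 - f) + f * exp(cfg$planted_log_hr))
  censTime <- if (cfg$censor_rate > 0)
    rexp(nS, rate = meanHazard * cfg$censor_rate / (1 - cfg$censor_rate))
  else rep(Inf, nS)
  censTime <- pmin(censTime, cfg$horizon_months)
  time <- pmin(eventTime, censTime)
  event <- as.numeric(eventTime <= censTime)

  metadata <- data.frame(
    sample_id = ids, tissue_class = tissue,
    time_months = ifelse(isTumor, time, NA),
    event = ifelse(isTumor, event, NA),
    age_years = age, stage = stage, sex = sex, smoking_status = smoking,
    cohort = "synthetic_bulk", stringsAsFactors = FALSE)
  rownames(metadata) <- ids
  se <- ExpressionMatrix(counts, unit = "counts", colData = metadata)

  truthSamples <- data.frame(
    sample = ids, tissue_class = tissue, matreotype = matreotype,
    size_factor = sf, stringsAsFactors = FALSE)
  survTab <- metadata[isTumor, c("sample_id", "time_months", "event",
                                 "age_years", "stage")]
  list(se = se, metadata = metadata, survival = survTab,
       truth_genes = template, truth_samples = truthSamples, config = cfg)
}

#' Simulate a premalignant lesion cohort
#'
#' Generates progressive and regressive pre-invasive lesions from the
#' non-tumor expression profile of the same gene template as
#' [simulateBulkCohort()]. Progressive lesions have the supplied risk genes
#' shifted toward the tumor profile by \code{shift_fraction} of each gene's
#' planted tumor effect; regressive lesions stay at the non-tumor profile.
#'
#' @param cfg a [syntheticConfig()] object.
#' @param risk_genes character vector of genes to shift (must exist in the
#'   generated gene universe and be non-empty).
#' @param shift_fraction fraction in [0, 1] of the tumor effect applied to
#'   progressive lesions.
#' @param n_per_group lesions per outcome group.
#' @return List with \code{se} (counts \code{SummarizedExperiment}),
#'   \code{labels} (named character: progressive/regressive),
#'   \code{truth_genes} and \code{config}.
#' @export
simulatePremalignantCohort <- function(cfg, risk_genes, shift_fraction = 1,
                                       n_per_group = 30L) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (length(risk_genes) == 0L)
    stop("config error: risk_genes must be non-empty")
  template <- .geneTemplate(cfg)
  missing <- setdiff(risk_genes, template$gene)
  if (length(missing))
    stop("config error: risk_genes not in the generated gene universe: ",
         paste(missing, collapse = ", "))
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("config error: shift_fraction must lie in [0, 1]")
  seeds <- .stageSeeds(cfg$seed)
  n_per_group <- as.integer(n_per_group)
  nS <- 2L * n_per_group
  ids <- c(sprintf("P%03d", seq_len(n_per_group)),
           sprintf("R%03d", seq_len(n_per_group)))
  labels <- setNames(rep(c("progressive", "regressive"), each = n_per_group),
                     ids)

  set.seed(seeds[["premalignant"]])
  latent <- template$baseline_log2 + .latentNoise(template, nS)
  idx <- match(risk_genes, template$gene)
  prog <- labels == "progressive"
  latent[idx, prog] <- latent[idx, prog] +
    shift_fraction * template$tumor_shift_sd[idx]
  sf <- runif(nS, cfg$library_size_range[1], cfg$library_size_range[2])
  mu <- sweep(2^latent, 2, sf, `*`)
  counts <- matrix(
    if (cfg$nb_dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else rpois(length(mu), lambda = mu),
    nrow(mu), ncol(mu))
  dimnames(counts) <- list(template$gene, ids)
  md <- data.frame(sample_id = ids, tissue_class = "non_tumor",
                   lesion_outcome = unname(labels),
                   cohort = "synthetic_premalignant",
                   stringsAsFactors = FALSE)
  rownames(md) <- ids
  se <- ExpressionMatrix(counts, unit = "counts", colData = md)
  list(se = se, labels = labels, truth_genes = template, config = cfg)
}

#' Write the synthetic-cohort truth and data tables
#'
#' Writes the standard expression/clinical TSVs plus \code{truth.tsv}
#' (per-gene planted roles) and \code{truth_samples.tsv} (per-sample
#' matreotype and library factor) into a directory.
#'
#' @param cohort result of [simulateBulkCohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSyntheticCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(cohort$se, file.path(dir, "counts.tsv"))
  write.table(cohort$metadata, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth_genes, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth_samples, file.path(dir, "truth_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
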