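# Synthetic expression data with planted ground truth.
#
# The generator exists so that every downstream stage (preprocessing,
# differential expression, differential co-expression) can be verified
# against known truth without any external data.  Co-expressed modules use a
# single-latent-factor model per module per condition, which makes the
# expected within-module pairwise correlation exactly equal to the requested
# rho -- a closed form the tests lean on.

#' Specify a planted co-expression module
#'
#' A module is a set of genes sharing one latent factor per condition; under
#' the factor model `x = mu + sd * (sqrt(rho) * F + sqrt(1 - rho) * eps)`
#' every within-module gene pair has correlation `rho` in expectation.
#'
#' @param size Number of genes (>= 3; a group needs at least three pairwise
#'   correlations for a t-statistic).
#' @param rho_EA,rho_NEA Target pairwise correlation within the module in
#'   each condition, in `[0, 1)`.
#' @return A `ModuleSpec` list.
#' @export
module_spec <- function(size, rho_EA, rho_NEA) {
  if (!is_count(size, min = 3L)) stopf("module `size` must be an integer >= 3")
  for (r in c(rho_EA, rho_NEA)) {
    if (!is_number(r) || r < 0 || r >= 1) stopf("rho values must lie in [0, 1)")
  }
  structure(list(size = as.integer(size), rho_EA = rho_EA, rho_NEA = rho_NEA),
            class = "ModuleSpec")
}

#' Configure the expression simulator
#'
#' Defaults mirror the study design the package targets: two groups of 20
#' samples, a desired fold change of 2 (log2 fold change 1) and a per-gene
#' standard deviation of 0.7.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition (default 20).
#' @param de_fraction Fraction of genes carrying a planted differential
#'   expression effect (default 0).
#' @param de_log2fc Planted log2 fold change added to the EA group (default 1).
#' @param gene_sd Per-gene residual standard deviation on the log2 scale
#'   (default 0.7).
#' @param modules List of [module_spec()] objects; module gene sets are
#'   assigned to disjoint blocks of genes.
#' @param covariate_effects Named numeric vector of linear covariate effects
#'   (names among `age`, `sex`, `bmi`, `ocs`) applied to every gene.
#' @param seed Integer seed; identical configurations are bitwise
#'   reproducible.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes, n_per_group = 20L, de_fraction = 0,
                       de_log2fc = 1.0, gene_sd = 0.7, modules = list(),
                       covariate_effects = NULL, seed = 1L) {
  if (!is_count(n_genes)) stopf("`n_genes` must be a positive integer")
  if (!is_count(n_per_group, min = 2L)) stopf("`n_per_group` must be >= 2")
  if (!is_number(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    stopf("`de_fraction` must lie in [0, 1]")
  }
  if (!is_number(gene_sd) || gene_sd <= 0) stopf("`gene_sd` must be > 0")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "ModuleSpec")) stopf("`modules` must be module_spec() objects")
    m
  })
  total_module <- sum(vapply(modules, `[[`, integer(1), "size"))
  if (total_module > n_genes) stopf("module genes (%d) exceed n_genes (%d)",
                                    total_module, n_genes)
  if (!is.null(covariate_effects)) {
    if (is.null(names(covariate_effects)) ||
        !all(names(covariate_effects) %in% c("age", "sex", "bmi", "ocs"))) {
      stopf("`covariate_effects` names must be among age, sex, bmi, ocs")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 gene_sd = gene_sd, modules = modules,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a two-condition expression dataset with planted truth
#'
#' Generates a log2-scale genes x samples matrix for two conditions (EA and
#' NEA).  Module genes follow the single-factor model described in
#' [module_spec()]; differential-expression genes receive `de_log2fc` added
#' to the EA samples; covariate effects enter linearly.  Module blocks are
#' assigned first (disjoint), then DE genes are drawn from the remaining
#' genes so the two kinds of planted signal never overlap.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (an [expression_dataset()] on the
#'   log2 scale) and `truth` (list: `de_genes` named vector of true effects,
#'   `module_membership` named integer vector mapping gene id to module
#'   index, `baseline` per-gene means, `config`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  local_seed(config$seed, {
    n <- config$n_per_group
    n_genes <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    sample_ids <- c(sprintf("EA%02d", seq_len(n)), sprintf("NEA%02d", seq_len(n)))
    condition <- factor(rep(c("EA", "NEA"), each = n), levels = c("EA", "NEA"))

    samples <- data.frame(
      condition = condition,
      age = round(stats::runif(2L * n, 20, 70), 1),
      sex = stats::rbinom(2L * n, 1L, 0.5),
      bmi = round(stats::rlnorm(2L * n, log(26), 0.15), 1),
      ocs = stats::rbinom(2L * n, 1L, 0.2),
      row.names = sample_ids
    )

    baseline <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    names(baseline) <- gene_ids

    # module assignment: consecutive disjoint blocks from the start
    module_membership <- integer(0)
    offset <- 0L
    for (k in seq_along(config$modules)) {
      sz <- config$modules[[k]]$size
      idx <- offset + seq_len(sz)
      mm <- rep.int(k, sz)
      names(mm) <- gene_ids[idx]
      module_membership <- c(module_membership, mm)
      offset <- offset + sz
    }

    free_genes <- gene_ids[!(gene_ids %in% names(module_membership))]
    n_de <- round(config$de_fraction * n_genes)
    if (n_de > length(free_genes)) {
      stopf("de_fraction requests %d DE genes but only %d non-module genes exist",
            n_de, length(free_genes))
    }
    de_ids <- sort(sample(free_genes, n_de))
    de_genes <- rep.int(config$de_log2fc, n_de)
    names(de_genes) <- de_ids

    x <- matrix(stats::rnorm(n_genes * 2L * n), nrow = n_genes,
                dimnames = list(gene_ids, sample_ids))

    for (k in seq_along(config$modules)) {
      m <- config$modules[[k]]
      idx <- which(module_membership == k)
      g <- match(names(module_membership)[idx], gene_ids)
      for (cond in c("EA", "NEA")) {
        rho <- if (cond == "EA") m$rho_EA else m$rho_NEA
        cols <- which(condition == cond)
        f <- stats::rnorm(length(cols))
        x[g, cols] <- sqrt(rho) * matrix(f, length(g), length(cols), byrow = TRUE) +
          sqrt(1 - rho) * x[g, cols]
      }
    }

    x <- baseline + config$gene_sd * x
    if (n_de > 0L) {
      x[de_ids, condition == "EA"] <- x[de_ids, condition == "EA"] + config$de_log2fc
    }
    if (!is.null(config$covariate_effects)) {
      for (nm in names(config$covariate_effects)) {
        shift <- config$covariate_effects[[nm]] * samples[[nm]]
        x <- x + matrix(shift, n_genes, 2L * n, byrow = TRUE)
      }
    }

    list(dataset = expression_dataset(x, samples, scale = "log2"),
         truth = list(de_genes = de_genes,
                      module_membership = module_membership,
                      baseline = baseline,
                      config = config))
  })
}

#' Simulate a clinical/biomarker table
#'
#' Produces a per-sample table obeying the phenotype definition used
#' throughout the package: EA (eosinophilic asthma) samples have at least 1%
#' eosinophils in bronchoalveolar lavage, NEA samples less than 1%.  Blood
#' eosinophil counts are drawn log-normally with EA median 480 cells/uL and
#' NEA median 140 cells/uL, mimicking the published group medians; BAL and
#' blood counts share a latent severity factor so the two are positively
#' correlated.
#'
#' @param n_per_group Samples per condition.
#' @param seed Integer seed.
#' @return A data frame with columns `sample`, `condition`, `age`, `sex`,
#'   `bmi`, `oral_steroid`, `bal_eos_pct`, `blood_eos`, `il5`, `rbm_um`.
#' @export
simulate_clinical_table <- function(n_per_group = 20L, seed = 1L) {
  if (!is_count(n_per_group)) stopf("`n_per_group` must be a positive integer")
  local_seed(seed, {
    n <- as.integer(n_per_group)
    condition <- factor(rep(c("EA", "NEA"), each = n), levels = c("EA", "NEA"))
    severity <- stats::rnorm(2L * n)
    bal <- ifelse(condition == "EA",
                  1 + stats::rlnorm(2L * n, log(4) + 0.4 * severity, 0.6),
                  stats::runif(2L * n, 0, 0.99))
    blood_median <- ifelse(condition == "EA", 480, 140)
    blood <- round(stats::rlnorm(2L * n, log(blood_median) + 0.3 * severity, 0.45))
    data.frame(
      sample = c(sprintf("EA%02d", seq_len(n)), sprintf("NEA%02d", seq_len(n))),
      condition = condition,
      age = round(stats::runif(2L * n, 20, 70), 1),
      sex = stats::rbinom(2L * n, 1L, 0.5),
      bmi = round(stats::rlnorm(2L * n, log(26), 0.15), 1),
      oral_steroid = stats::rbinom(2L * n, 1L, ifelse(condition == "EA", 0.25, 0.1)),
      bal_eos_pct = round(bal, 2),
      blood_eos = blood,
      il5 = round(stats::rlnorm(2L * n, log(ifelse(condition == "EA", 3, 1.5)), 0.5), 2),
      rbm_um = round(stats::rlnorm(2L * n, log(ifelse(condition == "EA", 7, 5.5)), 0.2), 2),
      stringsAsFactors = FALSE
    )
  })
}
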