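# Synthetic factorial studies, human-style cohorts and gene-set collections
# with recorded planted truth.  These stand in for the deposited mouse lung
# RNA-Seq, the newborn blood cohort and curated pathway databases, and carry
# the statistical structure the downstream modules are designed to recover.

GENOTYPES <- c("XXF", "XXM", "XYF", "XYM")

genotype_chromosomal <- function(genotype) {
  c(XXF = "XX", XXM = "XX", XYF = "XY", XYM = "XY")[genotype]
}

genotype_gonadal <- function(genotype) {
  c(XXF = "F", XXM = "M", XYF = "F", XYM = "M")[genotype]
}

#' Simulation configuration
#'
#' Describes the gene universe and noise model for a Four Core Genotypes
#' (FCG) factorial RNA-Seq simulation: a 2x2x2 design of chromosomal sex
#' (XX/XY) by gonadal sex (F/M, via the autosomal Sry transgene) by treatment
#' (room air RA vs. hyperoxia O2), observed at one or more timepoints.
#'
#' Counts are simulated on a CPM-like scale without gene lengths: length
#' normalization cancels from every within-gene contrast downstream, so
#' FPKM-style scaling is deliberately omitted.
#'
#' @param n_genes number of genes in the universe.
#' @param n_per_group biological replicates per design cell (the study design
#'   this emulates used 3 per group).
#' @param timepoints character vector of timepoint labels.
#' @param frac_x,frac_y fraction of genes assigned to the X and Y chromosome;
#'   the remainder are autosomal.
#' @param baseline_log2_mean_range interval for per-gene baseline log2 mean
#'   expression, drawn uniformly.
#' @param dispersion_log_mean,dispersion_log_sd meanlog and sdlog of the
#'   lognormal distribution of the per-gene negative binomial dispersion
#'   \eqn{\phi} (variance \eqn{m + \phi m^2}); defaults put the median
#'   dispersion at 0.1, typical for bulk RNA-Seq.
#' @param library_size_log_sd sd of per-sample log2 library size factors.
#' @param seed root seed; identical configuration and seed give
#'   byte-identical simulated objects.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_per_group = 3L,
                       timepoints = c("P5", "P21"),
                       frac_x = 0.08,
                       frac_y = 0.02,
                       baseline_log2_mean_range = c(3, 10),
                       dispersion_log_mean = log(0.1),
                       dispersion_log_sd = 0.5,
                       library_size_log_sd = 0.1,
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_per_group <- assert_count(n_per_group, "n_per_group")
  if (frac_x < 0 || frac_y < 0 || frac_x + frac_y >= 1) {
    stop("`frac_x` and `frac_y` must be non-negative with frac_x + frac_y < 1",
         call. = FALSE)
  }
  if (length(baseline_log2_mean_range) != 2L ||
      diff(baseline_log2_mean_range) < 0) {
    stop("`baseline_log2_mean_range` must be an increasing interval",
         call. = FALSE)
  }
  stopifnot(length(timepoints) >= 1L, !anyDuplicated(timepoints))
  structure(list(
    n_genes = n_genes,
    n_per_group = n_per_group,
    timepoints = as.character(timepoints),
    frac_x = frac_x,
    frac_y = frac_y,
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    dispersion_log_mean = dispersion_log_mean,
    dispersion_log_sd = dispersion_log_sd,
    library_size_log_sd = library_size_log_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Gene universe and chromosome annotation implied by a configuration
#'
#' Gene identifiers are deterministic (`gene0001`, ...).  The last
#' `frac_y` fraction of genes is assigned to Y, the preceding `frac_x`
#' fraction to X, the rest to autosomes, so the annotation depends only on
#' the configuration and not on the RNG.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `chromosome` (`A`, `X`, `Y`).
#' @export
gene_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  n_y <- round(n * config$frac_y)
  n_x <- round(n * config$frac_x)
  chrom <- rep("A", n)
  if (n_x > 0) chrom[seq.int(n - n_y - n_x + 1L, n - n_y)] <- "X"
  if (n_y > 0) chrom[seq.int(n - n_y + 1L, n)] <- "Y"
  data.frame(gene_id = ids, chromosome = chrom, stringsAsFactors = FALSE)
}

#' Planted effects for the factorial simulator
#'
#' Defines which genes carry which generative effects, so every downstream
#' recovery property can be checked against known truth:
#'
#' * `core_response`: a treatment main effect of magnitude `core_lfc` in all
#'   genotypes, half up- and half downregulated.
#' * `xx_protective`: a chromosomal-sex-by-treatment interaction -- the
#'   hyperoxia effect has magnitude `interaction_lfc_xy` in XY genotypes but
#'   is attenuated to `interaction_lfc_xx` in XX genotypes, emulating the
#'   protective female sex-chromosome complement.
#' * `gonadal_modulated`: a gonadal-sex-by-treatment interaction (full effect
#'   in gonadal males, attenuated in gonadal females).  The default set is
#'   smaller than the chromosomal interaction set because the modelled
#'   biology found gonadal-hormone effects on the hyperoxia response to be
#'   minor relative to sex-chromosome-complement effects.
#' * `x_escapees`: X genes escaping X-inactivation, with baseline expression
#'   +0.585 log2 (a 1.5-fold double dose) in XX samples.
#' * `y_only`: Y genes expressed in XY samples only.
#' * markers: an Xist-like gene (XX samples only), an Sry-like autosomal
#'   transgene (gonadal males only) and a Uty-like Y gene (XY only), the
#'   genotyping sanity checks of the FCG design.
#'
#' Gene membership is assigned deterministically from the front of each
#' chromosome block; all planted sets are pairwise disjoint.
#'
#' @param config a [sim_config()].
#' @param n_core,n_interaction,n_gonadal,n_escapee,n_y_only set sizes.
#' @param core_lfc treatment |log2 fold change| for core genes.
#' @param interaction_lfc_xy,interaction_lfc_xx treatment effect magnitude in
#'   XY vs. XX samples for `xx_protective` genes.
#' @param gonadal_lfc_m,gonadal_lfc_f same for gonadal male vs. female.
#' @param escapee_shift baseline log2 shift of X-escapees in XX samples.
#' @return object of class `planted_effects`.
#' @export
planted_effects <- function(config,
                            n_core = 150L,
                            n_interaction = 100L,
                            n_gonadal = 60L,
                            n_escapee = 20L,
                            n_y_only = 20L,
                            core_lfc = 2,
                            interaction_lfc_xy = 2,
                            interaction_lfc_xx = 0.5,
                            gonadal_lfc_m = 2,
                            gonadal_lfc_f = 0.5,
                            escapee_shift = 0.585) {
  stopifnot(inherits(config, "sim_config"))
  ann <- gene_universe(config)
  auto <- ann$gene_id[ann$chromosome == "A"]
  xg <- ann$gene_id[ann$chromosome == "X"]
  yg <- ann$gene_id[ann$chromosome == "Y"]
  if (length(auto) < n_core + n_interaction + n_gonadal + 1L) {
    stop("not enough autosomal genes for the requested planted sets",
         call. = FALSE)
  }
  if (length(xg) < n_escapee + 1L || length(yg) < n_y_only + 1L) {
    stop("not enough X or Y genes for the requested planted sets",
         call. = FALSE)
  }
  take <- function(pool, from, n) pool[seq.int(from, length.out = n)]
  core <- take(auto, 1L, n_core)
  inter <- take(auto, n_core + 1L, n_interaction)
  gon <- take(auto, n_core + n_interaction + 1L, n_gonadal)
  esc <- take(xg, 1L, n_escapee)
  yonly <- take(yg, 1L, n_y_only)
  half_dirs <- function(genes) {
    # first half up, second half down; deterministic
    d <- rep(c(1, -1), c(ceiling(length(genes) / 2), floor(length(genes) / 2)))
    stats::setNames(d, genes)
  }
  eff <- structure(list(
    core_response = half_dirs(core),
    core_lfc = core_lfc,
    xx_protective = half_dirs(inter),
    interaction_lfc_xy = interaction_lfc_xy,
    interaction_lfc_xx = interaction_lfc_xx,
    gonadal_modulated = half_dirs(gon),
    gonadal_lfc_m = gonadal_lfc_m,
    gonadal_lfc_f = gonadal_lfc_f,
    x_escapees = esc,
    escapee_shift = escapee_shift,
    y_only = yonly,
    marker_genes = c(
      xist_like = xg[length(xg)],
      sry_like = auto[length(auto)],
      uty_like = yg[length(yg)]
    )
  ), class = "planted_effects")
  validate_planted_effects(eff, ann)
  eff
}

#' Planted effects with set sizes scaled to the gene universe
#'
#' Convenience wrapper used by the pipeline: returns [planted_effects()]
#' with the default set sizes (tuned for a 2000-gene universe) scaled
#' proportionally when the configured universe is smaller, so that reduced
#' test worlds remain valid.
#'
#' @param config a [sim_config()].
#' @param ... overrides passed to [planted_effects()].
#' @return a `planted_effects` object.
#' @export
scaled_effects <- function(config, ...) {
  f <- min(1, config$n_genes / 2000)
  args <- list(config = config,
               n_core = max(10L, round(150 * f)),
               n_interaction = max(8L, round(100 * f)),
               n_gonadal = max(6L, round(60 * f)),
               n_escapee = max(2L, round(20 * f)),
               n_y_only = max(2L, round(20 * f)))
  user <- list(...)
  args[names(user)] <- user
  do.call(planted_effects, args)
}

validate_planted_effects <- function(effects, annotation) {
  sets <- list(
    core_response = names(effects$core_response),
    xx_protective = names(effects$xx_protective),
    gonadal_modulated = names(effects$gonadal_modulated),
    x_escapees = effects$x_escapees,
    y_only = effects$y_only,
    marker_genes = unname(effects$marker_genes)
  )
  nm <- names(sets)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0L) {
        stop(sprintf("planted sets overlap: '%s' and '%s' share genes %s",
                     nm[i], nm[j],
                     paste(intersect(sets[[i]], sets[[j]]), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  missing <- setdiff(unlist(sets), annotation$gene_id)
  if (length(missing)) {
    stop("planted genes outside the gene universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  if (any(chrom[effects$x_escapees] != "X")) {
    stop("x_escapees must all lie on the X chromosome", call. = FALSE)
  }
  if (any(chrom[effects$y_only] != "Y")) {
    stop("y_only genes must all lie on the Y chromosome", call. = FALSE)
  }
  invisible(effects)
}

# Build the sample sheet for one simulated study.
build_design <- function(config) {
  design <- expand.grid(
    replicate = seq_len(config$n_per_group),
    treatment = c("RA", "O2"),
    genotype = GENOTYPES,
    timepoint = config$timepoints,
    stringsAsFactors = FALSE
  )
  design$chromosomal_sex <- unname(genotype_chromosomal(design$genotype))
  design$gonadal_sex <- unname(genotype_gonadal(design$genotype))
  design$sample_id <- sprintf("%s_%s_%s_r%d", design$genotype,
                              design$treatment, design$timepoint,
                              design$replicate)
  design[, c("sample_id", "genotype", "chromosomal_sex", "gonadal_sex",
             "treatment", "timepoint")]
}

#' Simulate a factorial FCG count study
#'
#' Draws a gene-by-sample count matrix from a negative binomial model with
#' per-sample mean \eqn{s_j 2^{\eta_{gj}}} where \eqn{\eta_{gj}} is the gene
#' baseline plus the planted effect terms active for sample j's factors, and
#' variance \eqn{m + \phi_g m^2}.  Y-only genes (and the Xist-like and
#' Sry-like markers in their off strata) get mean 0.01 rather than exactly
#' zero to avoid degenerate all-zero rows.
#'
#' @param config a [sim_config()].
#' @param effects a [planted_effects()] over the same gene universe.
#' @return object of class `factorial_study`: list with `counts` (integer
#'   matrix, genes x samples), `design` (sample sheet), `gene_annotation`,
#'   and `truth` (the planted effects).
#' @export
simulate_murine_counts <- function(config, effects = planted_effects(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "planted_effects"))
  ann <- gene_universe(config)
  validate_planted_effects(effects, ann)
  design <- build_design(config)
  n_g <- config$n_genes
  n_s <- nrow(design)
  genes <- ann$gene_id

  with_seed(child_seed(config$seed, 11L), {
    baseline <- stats::runif(n_g, config$baseline_log2_mean_range[1],
                             config$baseline_log2_mean_range[2])
    names(baseline) <- genes
    phi <- stats::rlnorm(n_g, config$dispersion_log_mean,
                         config$dispersion_log_sd)
    size_fac <- 2^stats::rnorm(n_s, 0, config$library_size_log_sd)

    # fixed, recognisable baselines for the genotyping markers
    mk <- effects$marker_genes
    baseline[mk["xist_like"]] <- 8
    baseline[mk["sry_like"]] <- 6
    baseline[mk["uty_like"]] <- 6
    baseline[effects$y_only] <- 6

    is_o2 <- design$treatment == "O2"
    is_xx <- design$chromosomal_sex == "XX"
    is_gm <- design$gonadal_sex == "M"

    eta <- matrix(baseline, n_g, n_s, dimnames = list(genes, design$sample_id))
    add_treat <- function(eta, dirs, lfc_vec) {
      # lfc_vec: per-sample magnitude, applied under O2 only
      eta[names(dirs), ] <- eta[names(dirs), , drop = FALSE] +
        outer(unname(dirs), ifelse(is_o2, lfc_vec, 0))
      eta
    }
    eta <- add_treat(eta, effects$core_response,
                     rep(effects$core_lfc, n_s))
    eta <- add_treat(eta, effects$xx_protective,
                     ifelse(is_xx, effects$interaction_lfc_xx,
                            effects$interaction_lfc_xy))
    eta <- add_treat(eta, effects$gonadal_modulated,
                     ifelse(is_gm, effects$gonadal_lfc_m,
                            effects$gonadal_lfc_f))
    if (length(effects$x_escapees)) {
      eta[effects$x_escapees, is_xx] <-
        eta[effects$x_escapees, is_xx, drop = FALSE] + effects$escapee_shift
    }

    mu <- sweep(2^eta, 2, size_fac, `*`)
    # strata where sex-specific genes are silenced
    mu[effects$y_only, is_xx] <- 0.01
    mu[mk["uty_like"], is_xx] <- 0.01
    mu[mk["xist_like"], !is_xx] <- 0.01
    mu[mk["sry_like"], !is_gm] <- 0.01

    counts <- matrix(
      stats::rnbinom(n_g * n_s, mu = as.vector(mu), size = rep(1 / phi, n_s)),
      n_g, n_s, dimnames = list(genes, design$sample_id)
    )
    structure(list(
      counts = counts,
      design = design,
      gene_annotation = ann,
      truth = effects
    ), class = "factorial_study")
  })
}

#' Simulate a human-style cohort with a planted signature association
#'
#' Each subject carries a latent disease severity \eqn{u_j \sim N(0,1)}.
#' BPD (bronchopulmonary dysplasia) grade is obtained by fixed thresholds on
#' u at (0, 0.7, 1.3) for mild/moderate/severe -- chosen to give a realistic
#' skew toward milder grades; gestational age and birth weight decrease with
#' u plus noise; oxygen requirement at 28 days is the indicator u > 0.2 with
#' a small flip probability.  Expression of signature genes in the targeted
#' sex stratum is \eqn{-\lambda u \cdot \mathrm{dir}(g)} plus unit noise, so
#' the signature's summed Z-score anticorrelates with severity there;
#' everything else is pure noise.
#'
#' @param config a [sim_config()] supplying the gene universe and root seed.
#' @param protect_signature a [signature()] whose activity is planted.
#' @param loading planted effect size \eqn{\lambda}.
#' @param sex_specific if TRUE the association is planted in the female
#'   stratum only; if FALSE, in all subjects.
#' @param n_per_sex subjects per sex.
#' @param seed overrides the configuration seed.
#' @return object of class `cohort`: list with `expression` (genes x
#'   subjects), `clinical` (data.frame) and `truth`.
#' @export
simulate_cohort <- function(config, protect_signature, loading = 2,
                            sex_specific = TRUE, n_per_sex = 60L,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(protect_signature, "fcg_signature"))
  if (!is.finite(loading)) stop("`loading` must be finite", call. = FALSE)
  assert_flag(sex_specific, "sex_specific")
  n_per_sex <- assert_count(n_per_sex, "n_per_sex")
  sig_genes <- c(protect_signature$up, protect_signature$down)
  if (length(sig_genes) == 0L) {
    stop("`protect_signature` is empty", call. = FALSE)
  }
  ann <- gene_universe(config)
  missing <- setdiff(sig_genes, ann$gene_id)
  if (length(missing)) {
    stop("signature genes outside the cohort gene universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seed <- seed %||% child_seed(config$seed, 23L)

  with_seed(seed, {
    n <- 2L * n_per_sex
    sex <- rep(c("F", "M"), each = n_per_sex)
    subject_id <- sprintf("subj%03d", seq_len(n))
    u <- stats::rnorm(n)
    bpd_levels <- c("none", "mild", "moderate", "severe")
    bpd <- cut(u, breaks = c(-Inf, 0, 0.7, 1.3, Inf), labels = bpd_levels)
    gestational_age <- round(27 - 1.5 * u + stats::rnorm(n, 0, 1), 1)
    birth_weight <- round(1000 - 200 * u + stats::rnorm(n, 0, 100))
    flip <- stats::runif(n) < 0.05
    o2 <- ifelse(xor(u > 0.2, flip), "yes", "no")
    clinical <- data.frame(
      subject_id = subject_id, sex = sex,
      gestational_age = gestational_age, birth_weight = birth_weight,
      bpd_status = factor(bpd, levels = bpd_levels, ordered = TRUE),
      o2_at_28d = o2, stringsAsFactors = FALSE
    )
    expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                   dimnames = list(ann$gene_id, subject_id))
    target <- if (sex_specific) sex == "F" else rep(TRUE, n)
    dirs <- c(stats::setNames(rep(1, length(protect_signature$up)),
                              protect_signature$up),
              stats::setNames(rep(-1, length(protect_signature$down)),
                              protect_signature$down))
    expr[names(dirs), target] <- expr[names(dirs), target, drop = FALSE] +
      outer(unname(dirs), u[target]) * (-loading)
    structure(list(
      expression = expr,
      clinical = clinical,
      truth = list(u = stats::setNames(u, subject_id), loading = loading,
                   targeted_sex = if (sex_specific) "F" else "all",
                   signature = protect_signature$name)
    ), class = "cohort")
  })
}

#' Simulate a gene-set collection with known enriched sets
#'
#' A fraction of sets is composed entirely of planted core-response
#' upregulated genes (flagged `enriched` in the recorded truth); the
#' remainder are uniform random draws from the gene universe.
#'
#' @param config a [sim_config()].
#' @param effects a [planted_effects()].
#' @param n_sets total number of sets.
#' @param set_size_range inclusive size interval for random sets.
#' @param n_enriched how many truth-enriched sets to plant.
#' @param seed overrides the configuration seed.
#' @return a named list of character vectors of class `gene_set_collection`
#'   with attribute `truth` (logical vector, per-set enriched flag).
#' @export
simulate_gene_sets <- function(config, effects, n_sets = 50L,
                               set_size_range = c(10L, 100L),
                               n_enriched = 5L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "planted_effects"))
  n_sets <- assert_count(n_sets, "n_sets")
  n_enriched <- assert_count(n_enriched, "n_enriched", positive = FALSE)
  if (n_enriched > n_sets) stop("`n_enriched` exceeds `n_sets`", call. = FALSE)
  if (max(set_size_range) > config$n_genes) {
    stop("set sizes exceed the gene universe", call. = FALSE)
  }
  ann <- gene_universe(config)
  core_up <- names(effects$core_response)[effects$core_response > 0]
  seed <- seed %||% child_seed(config$seed, 37L)

  with_seed(seed, {
    sets <- vector("list", n_sets)
    enriched <- logical(n_sets)
    for (i in seq_len(n_sets)) {
      size <- sample(seq.int(set_size_range[1], set_size_range[2]), 1L)
      if (i <= n_enriched) {
        size <- min(size, length(core_up))
        sets[[i]] <- sort(sample(core_up, size))
        enriched[i] <- TRUE
      } else {
        sets[[i]] <- sort(sample(ann$gene_id, size))
      }
    }
    names(sets) <- sprintf("%s%03d", ifelse(enriched, "PLANTED_SET_", "SET_"),
                           seq_len(n_sets))
    structure(sets, truth = stats::setNames(enriched, names(sets)),
              class = "gene_set_collection")
  })
}

#' @export
print.factorial_study <- function(x, ...) {
  cat(sprintf("<factorial_study> %d genes x %d samples; timepoints: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$timepoint), collapse = ", ")))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d genes x %d subjects (%s)\n",
              nrow(x$expression), ncol(x$expression),
              paste(sprintf("%s: %d", names(table(x$clinical$sex)),
                            table(x$clinical$sex)), collapse = ", ")))
  invisible(x)
}
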