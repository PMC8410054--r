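# Normalization, variance-moderated two-group testing, and directional
# signature calling for the per-genotype hyperoxia contrasts and the
# intergenotype contrasts, with X/Y chromosome stratification.

#' Median-of-ratios size factors
#'
#' For each sample j, \eqn{s_j} is the median over eligible genes of
#' \eqn{K_{gj} / \mathrm{geomean}_{j'}(K_{gj'})}, where eligible genes have
#' positive counts in every sample.  When no gene is eligible the function
#' falls back to library-size ratios (column sum over the geometric mean of
#' column sums) with a warning.
#'
#' @param counts non-negative count matrix, genes in rows.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (any(eligible)) {
    logk <- log(counts[eligible, , drop = FALSE])
    ref <- rowMeans(logk)                      # log geometric mean per gene
    s <- apply(exp(logk - ref), 2, stats::median)
  } else {
    warning("no gene with positive counts in all samples; ",
            "falling back to library-size ratios", call. = FALSE)
    libs <- colSums(counts)
    if (any(libs == 0)) stop("sample with zero total counts", call. = FALSE)
    s <- libs / exp(mean(log(libs)))
  }
  stats::setNames(s, colnames(counts))
}

#' Log2 normalization with pseudocount
#'
#' value = log2(K / s + 1); the pseudocount keeps zero counts at exactly 0.
#'
#' @param counts non-negative count matrix.
#' @param s size factors from [size_factors()].
#' @return object of class `normalized_expression`: list with `log2` matrix
#'   and `size_factors`.
#' @export
log_normalize <- function(counts, s = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(s) != ncol(counts) || any(s <= 0)) {
    stop("`s` must hold one positive size factor per sample", call. = FALSE)
  }
  structure(list(
    log2 = log2(sweep(counts, 2, s, `/`) + 1),
    size_factors = s
  ), class = "normalized_expression")
}

#' Inverse of the trigamma function
#'
#' Newton iteration on the monotone decreasing trigamma, used when fitting
#' the variance prior by log-variance moment matching.
#'
#' @param y positive value.
#' @return x with trigamma(x) = y.
#' @keywords internal
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' Empirical variance prior from per-gene sample variances
#'
#' Assumes \eqn{s_g^2 \sim s_0^2 F(df, d_0)} and estimates \eqn{(d_0,
#' s_0^2)} by matching the mean and variance of \eqn{\log s_g^2}: the
#' spread of log variances in excess of the chi-square sampling spread
#' (trigamma(df/2)) identifies d0, and the location identifies s0.  Returns
#' `d0 = Inf` (complete shrinkage to s0) when the observed spread does not
#' exceed sampling noise.  Zero variances are excluded from the fit.
#'
#' @param s2 per-gene pooled variances.
#' @param df residual degrees of freedom of each s2.
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L) {
    return(list(d0 = Inf, s0_sq = if (length(z)) exp(z) else mean(s2)))
  }
  e_z <- mean(z)
  v_z <- stats::var(z)
  excess <- v_z - trigamma(df / 2)
  bias_df <- digamma(df / 2) - log(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_z - bias_df)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_z - bias_df + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Variance-moderated two-group test
#'
#' Classical pooled two-sample t with variance moderation: the per-gene
#' pooled variance \eqn{s_g^2} (df = nA + nB - 2) is shrunk toward a prior
#' variance \eqn{s_0^2} with prior weight `d0`,
#' \deqn{\tilde s^2 = (d_0 s_0^2 + df\, s_g^2) / (d_0 + df),}
#' \eqn{\tilde t = (\bar m_B - \bar m_A) / (\tilde s \sqrt{1/n_A + 1/n_B})}
#' referred to a t distribution on \eqn{d_0 + df} degrees of freedom.  With
#' `d0 = 0` this is exactly the classical pooled t-test.
#'
#' With numeric `d0` (default 4) the prior variance is the across-gene
#' arithmetic mean of \eqn{s_g^2}.  With `d0 = "empirical"` both the prior
#' weight and the prior variance are estimated from the observed variance
#' distribution via [fit_variance_prior()]; the empirical prior has
#' substantially better power on heteroskedastic count data because the
#' arithmetic mean over-states the typical variance whenever the variance
#' distribution is right-skewed.
#'
#' @param expr a `normalized_expression` or a numeric matrix of log2 values.
#' @param group_a,group_b disjoint character vectors of sample (column)
#'   names, each of size >= 2.
#' @param d0 prior degrees of freedom for variance moderation (>= 0), or
#'   the string "empirical".
#' @return a `deg_table` data.frame: gene, mean_a, mean_b, log2fc
#'   (mean_b - mean_a), t (moderated), df (d0 + residual df), p, q (BH).
#' @export
moderated_two_group_test <- function(expr, group_a, group_b, d0 = 4) {
  m <- if (inherits(expr, "normalized_expression")) expr$log2 else as.matrix(expr)
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "),
         call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop("samples not in expression matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  empirical <- identical(d0, "empirical")
  if (!empirical && (!is.numeric(d0) || d0 < 0)) {
    stop("`d0` must be non-negative or \"empirical\"", call. = FALSE)
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  df <- na + nb - 2L
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  s2 <- (ss_a + ss_b) / df
  if (all(s2 == 0)) {
    warning("zero within-group variance for every gene; ",
            "test defined through the variance prior only", call. = FALSE)
  }
  if (empirical) {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    s0_sq <- mean(s2)
  }
  s2_mod <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 > 0) {
    (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    s2
  }
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  lfc <- mean_b - mean_a
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_mod <- d0 + df
  p <- 2 * stats::pt(abs(t_stat), df = df_mod, lower.tail = FALSE)
  out <- data.frame(
    gene = rownames(m), mean_a = mean_a, mean_b = mean_b,
    log2fc = lfc, t = t_stat, df = df_mod, p = p, q = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; equivalent to
#' `p.adjust(method = "BH")` but kept explicit because the q <= threshold
#' rule defines signature membership throughout the pipeline.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / seq.int(n, 1) * p[o]))[ro]
  q
}

#' Construct a directional signature
#'
#' @param name label for the contrast (e.g. "XXF_O2_vs_RA_P5").
#' @param up,down character vectors of up/down gene identifiers; must be
#'   disjoint.
#' @param fdr_max,lfc_min thresholds that produced the membership.
#' @return object of class `fcg_signature`.
#' @export
fcg_signature <- function(name, up, down, fdr_max = NA_real_,
                          lfc_min = NA_real_) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets overlap: ",
         paste(intersect(up, down), collapse = ", "), call. = FALSE)
  }
  structure(list(name = as.character(name), up = up, down = down,
                 fdr_max = fdr_max, lfc_min = lfc_min),
            class = "fcg_signature")
}

#' @export
print.fcg_signature <- function(x, ...) {
  cat(sprintf("<signature> %s: %d up, %d down\n", x$name, length(x$up),
              length(x$down)))
  invisible(x)
}

#' Call a directional DEG signature from a test table
#'
#' up = genes with q <= fdr_max and log2FC >= lfc_min; down symmetric.
#' Ties at the thresholds are included.
#'
#' @param table a `deg_table`.
#' @param fdr_max FDR threshold.
#' @param lfc_min minimum |log2 fold change|.
#' @param name signature label.
#' @return an [fcg_signature()].
#' @export
call_degs <- function(table, fdr_max = 0.05, lfc_min = 1.0, name = "contrast") {
  stopifnot(is.data.frame(table), all(c("gene", "log2fc", "q") %in% names(table)))
  if (fdr_max <= 0 || lfc_min <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  sig <- table$q <= fdr_max
  fcg_signature(name,
                up = table$gene[sig & table$log2fc >= lfc_min],
                down = table$gene[sig & table$log2fc <= -lfc_min],
                fdr_max = fdr_max, lfc_min = lfc_min)
}

# Keep genes with at least `min_count` in at least `min_samples` samples.
filter_low_counts <- function(counts, min_count = 5L, min_samples = 2L) {
  counts[rowSums(counts >= min_count) >= min_samples, , drop = FALSE]
}

run_contrast <- function(study, samples_a, samples_b, name,
                         fdr_max, lfc_min, d0, min_count, min_samples) {
  sub <- study$counts[, c(samples_a, samples_b), drop = FALSE]
  sub <- filter_low_counts(sub, min_count, min_samples)
  norm <- log_normalize(sub)
  tab <- moderated_two_group_test(norm, samples_a, samples_b, d0 = d0)
  list(table = tab,
       signature = call_degs(tab, fdr_max, lfc_min, name = name))
}

select_samples <- function(design, genotype = NULL, treatment = NULL,
                           timepoint = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) keep <- keep & design$genotype == genotype
  if (!is.null(treatment)) keep <- keep & design$treatment == treatment
  if (!is.null(timepoint)) keep <- keep & design$timepoint == timepoint
  design$sample_id[keep]
}

#' Per-genotype hyperoxia contrasts
#'
#' For each of the four FCG genotypes at one timepoint, normalizes the
#' genotype's samples, tests O2 vs. RA (log2FC = O2 - RA) and calls the
#' directional signature.  Signature names encode genotype and timepoint,
#' e.g. "XXF_O2_vs_RA_P5".
#'
#' @param study a `factorial_study` (or equivalent list with `counts`,
#'   `design`).
#' @param timepoint timepoint label present in the design.
#' @param fdr_max,lfc_min signature thresholds.
#' @param d0 variance-moderation prior df.
#' @param min_count,min_samples low-count filter: keep genes with >=
#'   `min_count` reads in >= `min_samples` samples of the contrast.
#' @return named list of four elements (one per genotype), each with
#'   `table` (deg_table) and `signature`.
#' @export
hyperoxia_contrasts <- function(study, timepoint, fdr_max = 0.05,
                                lfc_min = 1.0, d0 = "empirical", min_count = 5L,
                                min_samples = 2L) {
  design <- study$design
  out <- list()
  for (g in GENOTYPES) {
    ra <- select_samples(design, genotype = g, treatment = "RA",
                         timepoint = timepoint)
    o2 <- select_samples(design, genotype = g, treatment = "O2",
                         timepoint = timepoint)
    if (length(ra) < 2L || length(o2) < 2L) {
      stop(sprintf("empty or underpowered design cell: genotype %s, timepoint %s (%d RA, %d O2 samples)",
                   g, timepoint, length(ra), length(o2)), call. = FALSE)
    }
    out[[g]] <- run_contrast(study, ra, o2,
                             name = sprintf("%s_O2_vs_RA_%s", g, timepoint),
                             fdr_max, lfc_min, d0, min_count, min_samples)
  }
  out
}

#' Pairwise intergenotype contrasts within one condition
#'
#' Six genotype-pair comparisons (log2FC = second genotype minus first)
#' among samples sharing one treatment and timepoint.
#'
#' @inheritParams hyperoxia_contrasts
#' @param condition "RA" or "O2".
#' @return named list of six contrast results.
#' @export
intergenotype_contrasts <- function(study, condition = c("RA", "O2"),
                                    timepoint, fdr_max = 0.05, lfc_min = 1.0,
                                    d0 = "empirical", min_count = 5L,
                                    min_samples = 2L) {
  condition <- match.arg(condition)
  design <- study$design
  pairs <- utils::combn(GENOTYPES, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    if (identical(g1, g2)) stop("self-contrast is not allowed", call. = FALSE)
    s1 <- select_samples(design, genotype = g1, treatment = condition,
                         timepoint = timepoint)
    s2 <- select_samples(design, genotype = g2, treatment = condition,
                         timepoint = timepoint)
    if (length(s1) < 2L || length(s2) < 2L) {
      stop(sprintf("empty design cell for %s or %s in %s at %s",
                   g1, g2, condition, timepoint), call. = FALSE)
    }
    nm <- sprintf("%s_vs_%s_%s_%s", g2, g1, condition, timepoint)
    out[[nm]] <- run_contrast(study, s1, s2, name = nm,
                              fdr_max, lfc_min, d0, min_count, min_samples)
  }
  out
}

#' Tally a signature by direction and chromosome
#'
#' @param sig an [fcg_signature()].
#' @param annotation data.frame with `gene_id` and `chromosome` in
#'   \{A, X, Y\}.
#' @return 2 x 3 integer matrix (rows up/down, columns A/X/Y).
#' @export
chromosome_tally <- function(sig, annotation) {
  stopifnot(inherits(sig, "fcg_signature"))
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  genes <- c(sig$up, sig$down)
  unann <- genes[!genes %in% names(chrom)]
  if (length(unann)) {
    stop("unannotated signature genes: ", paste(unann, collapse = ", "),
         call. = FALSE)
  }
  lv <- c("A", "X", "Y")
  tab <- rbind(
    up = table(factor(chrom[sig$up], levels = lv)),
    down = table(factor(chrom[sig$down], levels = lv))
  )
  storage.mode(tab) <- "integer"
  tab
}
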