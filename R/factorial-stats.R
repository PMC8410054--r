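# Phenotype-table statistics: three-way ANOVA with all interactions
# (Type III sums of squares, sum-to-zero coding) and Sidak-adjusted
# pairwise comparisons on the pooled residual error.

anova_terms <- c("treatment", "chromosomal_sex", "gonadal_sex",
                 "treatment:chromosomal_sex", "treatment:gonadal_sex",
                 "chromosomal_sex:gonadal_sex",
                 "treatment:chromosomal_sex:gonadal_sex")

# Sum-to-zero coded design columns for a 2x2x2 factorial with all
# interactions.  Each term contributes one column (+1 for the first level).
factorial_design_matrix <- function(factors) {
  code <- function(f) {
    lv <- sort(unique(as.character(f)))
    if (length(lv) != 2L) {
      stop("each factor must have exactly 2 observed levels, got: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
    ifelse(as.character(f) == lv[1], 1, -1)
  }
  t_ <- code(factors$treatment)
  c_ <- code(factors$chromosomal_sex)
  g_ <- code(factors$gonadal_sex)
  cbind(`(Intercept)` = 1, treatment = t_, chromosomal_sex = c_,
        gonadal_sex = g_, `treatment:chromosomal_sex` = t_ * c_,
        `treatment:gonadal_sex` = t_ * g_,
        `chromosomal_sex:gonadal_sex` = c_ * g_,
        `treatment:chromosomal_sex:gonadal_sex` = t_ * c_ * g_)
}

rss_fit <- function(x, y) {
  fit <- stats::lm.fit(x, y)
  sum(fit$residuals^2)
}

#' Three-way factorial ANOVA with Type III sums of squares
#'
#' Fits the full 2x2x2 model (treatment, chromosomal sex, gonadal sex, all
#' two-way interactions and the three-way interaction) under sum-to-zero
#' effect coding.  Each term's sum of squares is the increase in residual
#' sum of squares when that term alone is dropped from the full model
#' (Type III), which reduces to the classical balanced formulas when cell
#' sizes are equal and remains well defined for the unbalanced n = 5-6
#' designs typical of lung morphometry.
#'
#' @param values numeric vector of per-animal measurements.
#' @param factors data.frame with columns `treatment`, `chromosomal_sex`,
#'   `gonadal_sex`, each with exactly two observed levels.
#' @return data.frame of class `anova_table`: term, ss, df, f, p, plus a
#'   residual row; attribute `ss_total` holds the total sum of squares.
#' @export
three_way_anova <- function(values, factors) {
  values <- as.numeric(values)
  stopifnot(is.data.frame(factors),
            all(c("treatment", "chromosomal_sex", "gonadal_sex") %in%
                  names(factors)))
  if (length(values) != nrow(factors)) {
    stop("values and factors differ in length", call. = FALSE)
  }
  cells <- table(factors$treatment, factors$chromosomal_sex,
                 factors$gonadal_sex)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: treatment=%s, chromosomal_sex=%s, gonadal_sex=%s",
                 dimnames(cells)[[1]][idx[1]], dimnames(cells)[[2]][idx[2]],
                 dimnames(cells)[[3]][idx[3]]), call. = FALSE)
  }
  x <- factorial_design_matrix(factors)
  n <- length(values)
  rss_full <- rss_fit(x, values)
  df_res <- n - ncol(x)
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)
  ms_res <- rss_full / df_res
  ss <- vapply(anova_terms, function(term) {
    rss_fit(x[, colnames(x) != term, drop = FALSE], values) - rss_full
  }, numeric(1))
  ss <- pmax(ss, 0)
  f <- ss / ms_res
  p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
  out <- data.frame(
    term = c(anova_terms, "residual"),
    ss = c(ss, rss_full),
    df = c(rep(1L, length(anova_terms)), df_res),
    f = c(f, NA_real_),
    p = c(p, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "ss_total") <- sum((values - mean(values))^2)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Sidak multiple-comparison adjustment
#'
#' adjusted p = 1 - (1 - p)^m, clipped to 1.
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m number of comparisons in the family (>= 1).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  m <- assert_count(m, "m")
  pmin(1, 1 - (1 - p)^m)
}

#' Pairwise post hoc comparisons on the pooled residual error
#'
#' Two-sample comparisons between named groups using the pooled residual
#' variance of the one-way cell-means fit (identical to the full factorial
#' residual when the groups are the design cells), with Sidak adjustment
#' over the requested family.
#'
#' @param values numeric vector of measurements.
#' @param groups group label per measurement.
#' @param comparisons list of length-2 character vectors naming group pairs.
#' @return data.frame of class `posthoc_table`: group_1, group_2, diff
#'   (group_2 - group_1), t, p_raw, p_adjusted, m.
#' @export
pairwise_posthoc <- function(values, groups, comparisons) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), is.list(comparisons),
            length(comparisons) >= 1L)
  lv <- unique(groups)
  for (cmp in comparisons) {
    bad <- setdiff(cmp, lv)
    if (length(bad)) {
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(cmp) != 2L) stop("each comparison must name 2 groups",
                                call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  rss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_res <- length(values) - length(lv)
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)
  ms_res <- rss / df_res
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    g1 <- cmp[1]; g2 <- cmp[2]
    diff <- unname(means[g2] - means[g1])
    se <- sqrt(ms_res * (1 / ns[g1] + 1 / ns[g2]))
    t_stat <- if (se > 0) diff / se else ifelse(diff == 0, 0,
                                                sign(diff) * Inf)
    p_raw <- if (is.infinite(t_stat)) 0 else
      2 * stats::pt(abs(t_stat), df_res, lower.tail = FALSE)
    data.frame(group_1 = g1, group_2 = g2, diff = diff, t = unname(t_stat),
               p_raw = unname(p_raw),
               p_adjusted = unname(sidak_adjust(p_raw, m)), m = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_table", "data.frame")
  out
}
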