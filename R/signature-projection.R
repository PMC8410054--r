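# Projection of murine signatures onto an external expression cohort via
# summed Z-scores, intersignature correlation, UPGMA clustering with Newick
# export, and sex-stratified clinical association.

#' Gene-wise Z-score matrix for a cohort
#'
#' Standardizes each gene across all cohort subjects (n - 1 denominator):
#' \eqn{z_{gj} = (x_{gj} - \bar x_g)/\mathrm{sd}_g}.  Z-scores are computed
#' over the whole cohort before any sex stratification; stratification
#' happens at the association step.  Zero-variance genes cannot be
#' standardized and are excluded with a message.
#'
#' @param cohort a `cohort` object or a numeric genes-x-subjects matrix.
#' @return numeric matrix of Z-scores with the retained genes.
#' @export
zscore_matrix <- function(cohort) {
  x <- if (inherits(cohort, "cohort")) cohort$expression else as.matrix(cohort)
  if (ncol(x) < 3L) stop("need at least 3 subjects", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance gene(s) excluded from Z-scoring")
  }
  (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
}

#' Summed Z-score of a signature per subject
#'
#' \deqn{Z_j(S) = \sum_{g \in up} z_{gj} - \sum_{g \in down} z_{gj}.}
#' Signature genes absent from the cohort (or dropped as zero-variance) are
#' ignored; the attribute `coverage` reports the fraction found.  With
#' `normalize = TRUE` the sum is divided by the number of contributing
#' genes; downstream Pearson analyses are invariant to this rescaling.
#' `mode = "separate"` returns a two-row matrix scoring the up and down
#' sets independently instead of subtracting.
#'
#' @param z Z-score matrix from [zscore_matrix()].
#' @param sig an [fcg_signature()].
#' @param normalize divide by the number of contributing genes.
#' @param mode "subtract" (default) or "separate".
#' @return named numeric vector of per-subject scores (or a 2-row matrix in
#'   separate mode) with attribute `coverage`.
#' @export
summed_zscore <- function(z, sig, normalize = FALSE,
                          mode = c("subtract", "separate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sig, "fcg_signature"))
  assert_flag(normalize, "normalize")
  up <- intersect(sig$up, rownames(z))
  down <- intersect(sig$down, rownames(z))
  n_sig <- length(sig$up) + length(sig$down)
  n_found <- length(up) + length(down)
  if (n_found == 0L) {
    stop(sprintf("signature '%s' has zero coverage in the cohort", sig$name),
         call. = FALSE)
  }
  coverage <- n_found / n_sig
  if (coverage < 0.5) {
    warning(sprintf("signature '%s': coverage %.2f below 0.5", sig$name,
                    coverage), call. = FALSE)
  }
  sum_rows <- function(genes) {
    if (length(genes) == 0L) return(stats::setNames(rep(0, ncol(z)), colnames(z)))
    colSums(z[genes, , drop = FALSE])
  }
  if (mode == "subtract") {
    score <- sum_rows(up) - sum_rows(down)
    if (normalize) score <- score / n_found
  } else {
    score <- rbind(up = sum_rows(up), down = sum_rows(down))
    if (normalize) {
      score <- score / pmax(c(length(up), length(down)), 1L)
    }
  }
  attr(score, "coverage") <- coverage
  score
}

#' Score a collection of signatures over a cohort
#'
#' @param z Z-score matrix from [zscore_matrix()].
#' @param signatures list of [fcg_signature()] objects.
#' @param normalize passed to [summed_zscore()].
#' @return object of class `score_matrix`: signatures x subjects numeric
#'   matrix with attribute `coverage` (per-signature fraction found).
#'   Zero-coverage signatures are dropped with a warning.
#' @export
score_all <- function(z, signatures, normalize = FALSE) {
  stopifnot(is.list(signatures), length(signatures) > 0L)
  rows <- list(); cov <- numeric(0)
  for (sig in signatures) {
    res <- tryCatch(summed_zscore(z, sig, normalize = normalize),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("signature '%s' excluded: zero cohort coverage",
                      sig$name), call. = FALSE)
      next
    }
    rows[[sig$name]] <- as.numeric(res)
    cov[sig$name] <- attr(res, "coverage")
  }
  if (length(rows) == 0L) stop("no signature had cohort coverage", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- colnames(z)
  structure(m, coverage = cov, class = c("score_matrix", class(m)))
}

#' Pearson correlation between signature score profiles
#'
#' @param scores a `score_matrix` (signatures x subjects).
#' @return symmetric correlation matrix with unit diagonal; a constant score
#'   row yields NA entries (flagged with a warning), never zero.
#' @export
intersignature_correlation <- function(scores) {
  if (nrow(scores) < 2L) stop("need at least 2 signatures", call. = FALSE)
  if (ncol(scores) < 3L) stop("need at least 3 subjects", call. = FALSE)
  const <- apply(scores, 1, stats::sd) == 0
  if (any(const)) {
    warning("constant score row(s): ",
            paste(rownames(scores)[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(scores)))
  diag(r) <- 1
  r
}

#' Average-linkage (UPGMA) clustering on correlation distance
#'
#' Distance is 1 - Pearson r: from a symmetric correlation matrix directly
#' (`input = "correlation"`), or between the rows of a responses x pathways
#' NES matrix (`input = "nes"`).  Merges use unweighted average linkage with
#' deterministic tie-breaking by lexicographic label order, so results are
#' reproducible regardless of input ordering.
#'
#' @param x correlation matrix or NES matrix.
#' @param input "correlation" or "nes".
#' @return object of class `linkage_tree`: list with `merge`, `height`,
#'   `labels`, `order` (an `hclust`-compatible encoding) and `newick`
#'   string with ultrametric branch lengths.
#' @export
cluster_responses <- function(x, input = c("correlation", "nes")) {
  input <- match.arg(input)
  x <- as.matrix(x)
  if (input == "correlation") {
    if (nrow(x) != ncol(x) || any(abs(x - t(x)) > 1e-8)) {
      stop("correlation input must be a square symmetric matrix",
           call. = FALSE)
    }
    d <- 1 - x
    labels <- rownames(x) %||% paste0("item", seq_len(nrow(x)))
  } else {
    if (nrow(x) < 2L) stop("need at least 2 responses", call. = FALSE)
    d <- 1 - suppressWarnings(stats::cor(t(x)))
    d[is.na(d)] <- 2  # constant rows: maximally distant
    labels <- rownames(x) %||% paste0("item", seq_len(nrow(x)))
  }
  diag(d) <- 0
  upgma(d, labels)
}

# UPGMA with lexicographic tie-breaking.  Clusters are identified by their
# lexicographically smallest leaf label; among equal-distance pairs the pair
# whose sorted (label_i, label_j) comes first lexicographically merges first.
upgma <- function(d, labels) {
  n <- nrow(d)
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  dimnames(d) <- list(labels, labels)
  # active clusters: list of leaf index vectors; id = -leaf or +merge row
  active <- as.list(seq_len(n))
  ids <- -seq_len(n)
  tags <- labels                      # smallest member label per cluster
  heights <- rep(0, n)                # current height of each active cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  newick <- sprintf("%s", labels)
  dm <- d
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        key <- sort(c(tags[i], tags[j]))
        cand <- list(dist = dm[i, j], key = key, i = i, j = j)
        if (is.null(best) || cand$dist < best$dist - 1e-12 ||
            (abs(cand$dist - best$dist) <= 1e-12 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j; h <- best$dist
    ni <- length(active[[i]]); nj <- length(active[[j]])
    # hclust merge encoding
    merge[step, ] <- sort(c(ids[[i]], ids[[j]]))
    height[step] <- h
    bl_i <- h / 2 - heights[i] / 2
    bl_j <- h / 2 - heights[j] / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], max(bl_i, 0),
                   newick[j], max(bl_j, 0))
    # unweighted average linkage update
    newd <- numeric(k)
    for (m in seq_len(k)) {
      if (m != i && m != j) {
        newd[m] <- (ni * dm[i, m] + nj * dm[j, m]) / (ni + nj)
      }
    }
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    ids <- c(ids[keep], step)
    tags <- c(tags[keep], min(tags[c(i, j)]))
    heights <- c(heights[keep], h)
    newick <- c(newick[keep], nwk)
  }
  # leaf order via recursive traversal of the merge matrix
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  ord <- if (n > 1) leaf_order(n - 1L) else 1L
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, newick = paste0(newick[length(newick)], ";")),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves; max height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Convert a linkage tree to an hclust object
#'
#' @param tree a `linkage_tree`.
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  structure(list(merge = tree$merge, height = tree$height, order = tree$order,
                 labels = tree$labels, method = "average",
                 call = match.call(), dist.method = "1 - pearson"),
            class = "hclust")
}

#' Merge height at which two leaves first join
#'
#' @param tree a `linkage_tree`.
#' @param a,b leaf labels.
#' @return the height of the smallest cluster containing both.
#' @export
cophenetic_height <- function(tree, a, b) {
  stopifnot(inherits(tree, "linkage_tree"))
  ia <- match(a, tree$labels); ib <- match(b, tree$labels)
  if (is.na(ia) || is.na(ib)) stop("unknown leaf label", call. = FALSE)
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(tree$merge[node, 1]), members(tree$merge[node, 2]))
  }
  for (step in seq_along(tree$height)) {
    mm <- members(step)
    if (ia %in% mm && ib %in% mm) return(tree$height[step])
  }
  stop("leaves never merge; malformed tree", call. = FALSE)
}

encode_clinical <- function(clinical) {
  bpd_levels <- c("none", "mild", "moderate", "severe")
  data.frame(
    gestational_age = as.numeric(clinical$gestational_age),
    birth_weight = as.numeric(clinical$birth_weight),
    bpd_status = as.numeric(factor(as.character(clinical$bpd_status),
                                   levels = bpd_levels)) - 1,
    o2_at_28d = as.numeric(clinical$o2_at_28d == "yes")
  )
}

#' Sex-stratified association of signature scores with clinical variables
#'
#' Pearson correlation (two-sided) of each signature's summed Z-score with
#' each of four clinical variables -- gestational age (weeks), birth weight
#' (grams), BPD status encoded ordinally 0/1/2/3 (none/mild/moderate/severe)
#' and oxygen at 28 days encoded 0/1 -- within each sex stratum and overall.
#' Strata smaller than 3 subjects are reported as missing.
#'
#' @param scores a `score_matrix` whose columns match `clinical` rows.
#' @param clinical data.frame with columns `sex`, `gestational_age`,
#'   `birth_weight`, `bpd_status`, `o2_at_28d`.
#' @param stratify_by_sex add per-sex strata alongside "all".
#' @return data.frame with columns signature, variable, stratum, r, p, n.
#' @export
clinical_association <- function(scores, clinical, stratify_by_sex = TRUE) {
  assert_flag(stratify_by_sex, "stratify_by_sex")
  if (ncol(scores) != nrow(clinical)) {
    stop("score columns and clinical rows differ in length", call. = FALSE)
  }
  if (any(is.na(clinical$sex))) stop("missing sex in clinical table",
                                     call. = FALSE)
  enc <- encode_clinical(clinical)
  strata <- list(all = rep(TRUE, nrow(clinical)))
  if (stratify_by_sex) {
    for (s in sort(unique(clinical$sex))) {
      strata[[s]] <- clinical$sex == s
    }
  }
  out <- list()
  for (sig in rownames(scores)) {
    for (v in names(enc)) {
      for (st in names(strata)) {
        idx <- strata[[st]]
        n <- sum(idx)
        if (n < 3L || stats::sd(enc[idx, v]) == 0 ||
            stats::sd(scores[sig, idx]) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            signature = sig, variable = v, stratum = st,
            r = NA_real_, p = NA_real_, n = n, stringsAsFactors = FALSE)
          next
        }
        ct <- stats::cor.test(scores[sig, idx], enc[idx, v],
                              method = "pearson")
        out[[length(out) + 1L]] <- data.frame(
          signature = sig, variable = v, stratum = st,
          r = unname(ct$estimate), p = ct$p.value, n = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
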