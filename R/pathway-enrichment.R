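# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov enrichment
# score, gene-sampling permutation NES and FDR, NES matrices masked at the
# significance threshold, pathway overlap, and the discordant-pathway rule
# for the cross-species comparison.

#' Build a ranked list from a differential expression table
#'
#' Genes are ordered by decreasing moderated t statistic; ties are broken
#' lexicographically on the gene identifier so the ranking is deterministic.
#'
#' @param table a `deg_table` (needs columns `gene` and `t`), or any
#'   data.frame with those columns.
#' @return object of class `ranked_list`: list with `genes` (ordered) and
#'   `metric` (same order).
#' @export
rank_from_contrast <- function(table) {
  stopifnot(is.data.frame(table), all(c("gene", "t") %in% names(table)))
  if (anyDuplicated(table$gene)) {
    stop("duplicate gene identifiers in ranking input: ",
         paste(unique(table$gene[duplicated(table$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$t))) {
    stop("ranking metric must be finite for all genes", call. = FALSE)
  }
  o <- order(-table$t, table$gene)
  structure(list(genes = table$gene[o], metric = table$t[o]),
            class = "ranked_list")
}

#' Weighted KS enrichment score
#'
#' The canonical GSEA running sum: walking down the ranked list, hits add
#' \eqn{|r_g|^p / N_R} (with \eqn{N_R = \sum_{g \in S} |r_g|^p}) and misses
#' subtract \eqn{1/(N - N_H)}; the enrichment score is the running-sum value
#' of maximum absolute deviation from zero, signed.  `weight = 0` gives the
#' classical (unweighted) KS statistic.  If every hit has zero metric the
#' hit increments degrade gracefully to the unweighted \eqn{1/N_H}.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of gene identifiers.
#' @param weight the exponent p (default 1).
#' @return list with `es` and `running` (the full running sum).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$genes %in% gene_set
  n <- length(ranked$genes)
  n_h <- sum(hit)
  if (n_h == 0L || n_h == n) {
    stop("gene set must be a non-empty proper subset of the ranked universe",
         call. = FALSE)
  }
  w <- abs(ranked$metric)^weight
  n_r <- sum(w[hit])
  inc <- if (n_r > 0) w * hit / n_r else hit / n_h
  dec <- (!hit) / (n - n_h)
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# ES from sorted hit positions and their weights; O(N_H) per evaluation.
# Candidate extrema occur at each hit position (after adding the hit) and
# just before each hit (all-miss stretch minima).
es_from_positions <- function(pos, w, n) {
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  n_h <- length(pos)
  n_r <- sum(w)
  cw <- if (n_r > 0) cumsum(w) / n_r else seq_len(n_h) / n_h
  miss_unit <- 1 / (n - n_h)
  k <- seq_len(n_h)
  at_hit <- cw - (pos - k) * miss_unit          # value just after hit k
  before_hit <- c(0, cw[-n_h]) - ((pos - 1) - (k - 1)) * miss_unit
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Preranked GSEA with gene-sampling permutations
#'
#' For each gene set (after intersecting with the ranked universe and
#' filtering to sizes within `size_range`), the null distribution of the
#' enrichment score is obtained from `n_perm` random gene sets of matching
#' size.  Phenotype permutation is degenerate at n = 3 per group, so the
#' gene-sampling null standard for preranked GSEA is used.
#'
#' NES = ES / mean(|null ES| of the same sign); the nominal p-value is
#' \eqn{(1 + \#\{ \mathrm{same sign}, |ES_{null}| \ge |ES|\}) /
#' (1 + \#\mathrm{same-sign\ nulls})}.  FDR q compares the observed NES to
#' the pooled normalized null: q(NES*) is the fraction of same-sign null NES
#' at least as extreme, divided by the fraction of same-sign observed NES at
#' least as extreme, clipped to [0, 1].
#'
#' @param ranked a `ranked_list`.
#' @param collection named list of gene sets (e.g. `gene_set_collection`).
#' @param n_perm number of permutations.
#' @param weight ES exponent p.
#' @param size_range inclusive set-size filter after universe intersection.
#' @param seed RNG seed (results are identical for identical seeds).
#' @return data.frame of class `enrichment_result`: set, size, es, nes, p,
#'   q, leading_edge (comma-separated).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000L, weight = 1,
                           size_range = c(5L, 500L), seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"))
  n_perm <- assert_count(n_perm, "n_perm")
  universe <- ranked$genes
  n <- length(universe)
  sets <- lapply(collection, function(s) intersect(s, universe))
  sizes <- lengths(sets)
  keep <- sizes >= size_range[1] & sizes <= size_range[2] & sizes < n
  if (!any(keep)) stop("no gene set survives the size filter", call. = FALSE)
  sets <- sets[keep]
  sizes <- sizes[keep]
  w_all <- abs(ranked$metric)^weight

  with_seed(seed, {
    obs <- vapply(sets, function(s) enrichment_score(ranked, s, weight)$es,
                  numeric(1))
    uniq_sizes <- sort(unique(sizes))
    null_by_size <- list()
    for (sz in uniq_sizes) {
      es_null <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        pos <- sample.int(n, sz)
        es_null[b] <- es_from_positions(pos, w_all[pos], n)
      }
      null_by_size[[as.character(sz)]] <- es_null
    }
    nes <- numeric(length(sets)); p <- numeric(length(sets))
    null_nes_pool <- list()
    for (i in seq_along(sets)) {
      es_null <- null_by_size[[as.character(sizes[i])]]
      same <- es_null[sign(es_null) == sign(obs[i]) | obs[i] == 0]
      if (obs[i] == 0) same <- es_null
      denom <- mean(abs(same))
      nes[i] <- if (length(same) && denom > 0) obs[i] / denom else 0
      p[i] <- (1 + sum(abs(same) >= abs(obs[i]))) / (1 + length(same))
    }
    # pooled normalized null: each null ES scaled by its size-class same-sign
    # mean, pooled over the observed sets' size classes
    pooled <- unlist(lapply(seq_along(sets), function(i) {
      es_null <- null_by_size[[as.character(sizes[i])]]
      pos_mean <- mean(abs(es_null[es_null >= 0]))
      neg_mean <- mean(abs(es_null[es_null < 0]))
      ifelse(es_null >= 0,
             if (is.finite(pos_mean) && pos_mean > 0) es_null / pos_mean else 0,
             if (is.finite(neg_mean) && neg_mean > 0) es_null / neg_mean else 0)
    }), use.names = FALSE)
    q <- vapply(seq_along(sets), function(i) {
      if (nes[i] == 0) return(1)
      sgn <- sign(nes[i])
      null_same <- pooled[sign(pooled) == sgn]
      obs_same <- nes[sign(nes) == sgn]
      num <- if (length(null_same)) {
        mean(abs(null_same) >= abs(nes[i]))
      } else 0
      den <- mean(abs(obs_same) >= abs(nes[i]))
      min(1, if (den > 0) num / den else 1)
    }, numeric(1))
    leading <- vapply(seq_along(sets), function(i) {
      r <- enrichment_score(ranked, sets[[i]], weight)$running
      peak <- which.max(abs(r))
      hits <- ranked$genes %in% sets[[i]]
      le <- if (r[peak] >= 0) {
        ranked$genes[seq_len(peak)][hits[seq_len(peak)]]
      } else {
        ranked$genes[seq.int(peak, n)][hits[seq.int(peak, n)]]
      }
      paste(le, collapse = ",")
    }, character(1))
    out <- data.frame(
      set = names(sets), size = as.integer(sizes), es = obs, nes = nes,
      p = p, q = q, leading_edge = leading,
      row.names = NULL, stringsAsFactors = FALSE
    )
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

#' NES matrix masked at an FDR threshold
#'
#' Builds a responses x gene-sets matrix holding the NES where q < fdr_max
#' and exactly zero elsewhere, over the union of all sets tested.
#'
#' @param results named list of `enrichment_result` data.frames, one per
#'   transcriptomic response.
#' @param fdr_max significance threshold (default 0.25).
#' @return numeric matrix, rows = responses, columns = gene sets.
#' @export
nes_matrix <- function(results, fdr_max = 0.25) {
  stopifnot(is.list(results), length(results) >= 1L)
  all_sets <- sort(unique(unlist(lapply(results, function(r) r$set))))
  m <- matrix(0, length(results), length(all_sets),
              dimnames = list(names(results), all_sets))
  for (nm in names(results)) {
    r <- results[[nm]]
    sig <- r$q < fdr_max
    m[nm, r$set[sig]] <- r$nes[sig]
  }
  m
}

#' Overlap of enriched-pathway label sets
#'
#' Same convention as [overlap_percentage()]: Jaccard percentage by default.
#'
#' @param set_a,set_b character vectors of pathway labels.
#' @param denominator "union" or "smaller".
#' @return list with `n_intersection`, `n_union`, `percent`.
#' @export
pathway_overlap <- function(set_a, set_b,
                            denominator = c("union", "smaller")) {
  denominator <- match.arg(denominator)
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_int <- length(intersect(set_a, set_b))
  n_union <- length(union(set_a, set_b))
  denom <- if (denominator == "union") n_union else min(length(set_a),
                                                        length(set_b))
  list(n_intersection = n_int, n_union = n_union,
       percent = if (denom == 0) 0 else 100 * n_int / denom)
}

#' Pathways induced in the human cohort but suppressed in feminized mice
#'
#' Selects pathways that are significantly induced (NES > 0, q < fdr_max)
#' in the human response AND significantly suppressed (NES < 0, q <
#' fdr_max) in each of the three feminized murine responses (XXF, XXM, XYF)
#' AND, in XYM, either significantly induced or not significant at all.
#'
#' @param human,xxf,xxm,xyf,xym `enrichment_result` data.frames over a
#'   shared pathway universe.
#' @param fdr_max significance threshold (default 0.25).
#' @return character vector of selected pathway names.
#' @export
discordant_pathways <- function(human, xxf, xxm, xyf, xym, fdr_max = 0.25) {
  tab <- function(r) {
    stats::setNames(lapply(seq_len(nrow(r)), function(i) {
      list(nes = r$nes[i], sig = r$q[i] < fdr_max)
    }), r$set)
  }
  th <- tab(human); t_xxf <- tab(xxf); t_xxm <- tab(xxm)
  t_xyf <- tab(xyf); t_xym <- tab(xym)
  common <- Reduce(intersect, list(names(th), names(t_xxf), names(t_xxm),
                                   names(t_xyf), names(t_xym)))
  sel <- vapply(common, function(s) {
    hu <- th[[s]]
    fem <- list(t_xxf[[s]], t_xxm[[s]], t_xyf[[s]])
    ym <- t_xym[[s]]
    hu$sig && hu$nes > 0 &&
      all(vapply(fem, function(f) f$sig && f$nes < 0, logical(1))) &&
      ((ym$sig && ym$nes > 0) || !ym$sig)
  }, logical(1))
  common[sel]
}
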