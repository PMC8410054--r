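# Directional set algebra over the four genotype hyperoxia responses:
# the gonadal/chromosomal region decomposition, overlap percentages and
# direction fractions.

# A signature as a named direction vector: +1 up, -1 down.
signature_directions <- function(sig) {
  stopifnot(inherits(sig, "fcg_signature"))
  c(stats::setNames(rep(1, length(sig$up)), sig$up),
    stats::setNames(rep(-1, length(sig$down)), sig$down))
}

direction_set <- function(dirs) {
  # data.frame gene/direction, sorted by gene for stable output
  if (length(dirs) == 0L) {
    return(data.frame(gene = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(gene = names(dirs), direction = ifelse(dirs > 0, "up", "down"),
                  stringsAsFactors = FALSE)
  d[order(d$gene), , drop = FALSE]
}

#' Four-way directional decomposition of genotype hyperoxia responses
#'
#' Partitions the four genotype signatures into the shared-response regions
#' of the factorial design:
#'
#' * region E -- genes responding, with concordant direction, in all four
#'   genotypes (the core hyperoxia response);
#' * region A -- gonadal female response: XXF and XYF, minus E;
#' * region B -- gonadal male response: XXM and XYM, minus E;
#' * region C -- chromosomal female response: XXF and XXM, minus E;
#' * region D -- chromosomal male response: XYF and XYM, minus E.
#'
#' Membership is directional: a gene counts as shared only when its up/down
#' direction agrees in every signature of the intersection.  Genes present
#' in an intersection with conflicting directions are not shared responses;
#' they are tracked in the `discordant` side list.
#'
#' @param sig_xxf,sig_xxm,sig_xyf,sig_xym the four genotype signatures
#'   ([fcg_signature()] objects).  Passing the identical object for two
#'   genotypes is rejected.
#' @return object of class `venn_decomposition`: list with `regions` (named
#'   list A--E of data.frames gene/direction), `counts` (region x up/down
#'   integer matrix), `discordant` (genes excluded from some intersection by
#'   direction conflict) and `signatures` (the input names).
#' @export
decompose_signatures <- function(sig_xxf, sig_xxm, sig_xyf, sig_xym) {
  sigs <- list(XXF = sig_xxf, XXM = sig_xxm, XYF = sig_xyf, XYM = sig_xym)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (identical(sigs[[i]], sigs[[j]])) {
        stop(sprintf("the same signature object was passed for %s and %s",
                     names(sigs)[i], names(sigs)[j]), call. = FALSE)
      }
    }
  }
  dirs <- lapply(sigs, signature_directions)

  concordant <- function(members) {
    # genes present with the same direction in every listed genotype
    common <- Reduce(intersect, lapply(dirs[members], names))
    if (length(common) == 0L) {
      return(list(dirs = stats::setNames(numeric(0), character(0)),
                  discordant = character(0)))
    }
    mat <- vapply(dirs[members], function(d) d[common], numeric(length(common)))
    if (length(common) == 1L) mat <- matrix(mat, nrow = 1)
    agree <- apply(mat, 1, function(r) all(r == r[1]))
    list(dirs = stats::setNames(mat[, 1][agree], common[agree]),
         discordant = common[!agree])
  }

  e <- concordant(c("XXF", "XXM", "XYF", "XYM"))
  pair_regions <- list(
    A = c("XXF", "XYF"),  # gonadal female
    B = c("XXM", "XYM"),  # gonadal male
    C = c("XXF", "XXM"),  # chromosomal female
    D = c("XYF", "XYM")   # chromosomal male
  )
  regions <- list()
  discordant <- e$discordant
  for (r in names(pair_regions)) {
    cc <- concordant(pair_regions[[r]])
    keep <- setdiff(names(cc$dirs), names(e$dirs))
    regions[[r]] <- direction_set(cc$dirs[keep])
    discordant <- union(discordant, cc$discordant)
  }
  regions$E <- direction_set(e$dirs)
  counts <- t(vapply(regions[c("A", "B", "C", "D", "E")], function(d) {
    c(up = sum(d$direction == "up"), down = sum(d$direction == "down"))
  }, integer(2)))
  structure(list(
    regions = regions[c("A", "B", "C", "D", "E")],
    counts = counts,
    discordant = sort(discordant),
    signatures = vapply(sigs, function(s) s$name, character(1))
  ), class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat("<venn_decomposition>\n")
  print(x$counts)
  if (length(x$discordant)) {
    cat(sprintf("%d direction-discordant shared genes tracked separately\n",
                length(x$discordant)))
  }
  invisible(x)
}

#' Percentage overlap between two directional signatures
#'
#' Directional Jaccard by default: 100 * |intersection| / |union| over
#' (gene, direction) pairs, 0 when both signatures are empty.  The
#' alternative denominator is the smaller signature.
#'
#' @param sig_a,sig_b [fcg_signature()] objects.
#' @param denominator "union" (Jaccard, default) or "smaller".
#' @return percentage in [0, 100].
#' @export
overlap_percentage <- function(sig_a, sig_b,
                               denominator = c("union", "smaller")) {
  denominator <- match.arg(denominator)
  da <- signature_directions(sig_a)
  db <- signature_directions(sig_b)
  common <- intersect(names(da), names(db))
  n_int <- sum(da[common] == db[common])
  n_a <- length(da); n_b <- length(db)
  denom <- if (denominator == "union") {
    n_a + n_b - n_int
  } else {
    min(n_a, n_b)
  }
  if (denom == 0) return(0)
  100 * n_int / denom
}

#' Up/down percentage composition of a region
#'
#' @param region a data.frame with a `direction` column ("up"/"down"), as
#'   stored in a `venn_decomposition`, or an [fcg_signature()].
#' @return named numeric vector `c(up = , down = )` in percent; (0, 0) for
#'   an empty region.
#' @export
direction_fraction <- function(region) {
  if (inherits(region, "fcg_signature")) {
    region <- direction_set(signature_directions(region))
  }
  n <- nrow(region)
  if (n == 0L) return(c(up = 0, down = 0))
  c(up = 100 * sum(region$direction == "up") / n,
    down = 100 * sum(region$direction == "down") / n)
}
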