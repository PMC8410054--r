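# Plain-text interchange: counts/sample-sheet/annotation TSV, GMT gene-set
# collections, cohort clinical CSV, Newick trees.  Writers and readers are
# exact inverses on valid input.

#' Read a gene x sample count matrix from TSV
#'
#' Expects genes in rows with the first column holding gene identifiers and
#' the header holding sample identifiers.  Non-integer or negative entries
#' are rejected with the offending location.
#'
#' @param path TSV file.
#' @return integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_tsv
#' @param counts matrix to write.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as name, description, then
#' gene identifiers.  Malformed lines (fewer than 3 fields) are reported
#' with their line number.
#'
#' @param path GMT file.
#' @return named list of character vectors with attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                   i), call. = FALSE)
    }
    sets[[parts[1]]] <- parts[-(1:2)]
    desc[parts[1]] <- parts[2]
  }
  structure(sets, description = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(collection, "description") %||%
    stats::setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", collection[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort clinical table from CSV
#'
#' Requires columns subject_id, sex, gestational_age, birth_weight,
#' bpd_status, o2_at_28d; bpd_status is coerced to an ordered factor
#' none < mild < moderate < severe.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "gestational_age", "birth_weight",
            "bpd_status", "o2_at_28d")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("clinical table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lv <- c("none", "mild", "moderate", "severe")
  bad <- setdiff(unique(df$bpd_status), lv)
  if (length(bad)) {
    stop("unknown bpd_status values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$bpd_status <- factor(df$bpd_status, levels = lv, ordered = TRUE)
  df
}

#' @rdname read_clinical_csv
#' @param clinical data.frame to write.
#' @export
write_clinical_csv <- function(clinical, path) {
  out <- clinical
  out$bpd_status <- as.character(out$bpd_status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample sheet TSV
#' @param path TSV file.
#' @return data.frame with sample_id, genotype, chromosomal_sex,
#'   gonadal_sex, treatment, timepoint.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "chromosomal_sex", "gonadal_sex",
            "treatment", "timepoint")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_sample_sheet
#' @param design data.frame to write.
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a linkage tree as Newick
#'
#' @param tree a `linkage_tree` from [cluster_responses()].
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' Write a signature as a two-column TSV (gene, direction)
#' @param sig an [fcg_signature()].
#' @param path output file.
#' @export
write_signature_tsv <- function(sig, path) {
  d <- rbind(
    data.frame(gene = sig$up, direction = rep("up", length(sig$up))),
    data.frame(gene = sig$down, direction = rep("down", length(sig$down)))
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
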