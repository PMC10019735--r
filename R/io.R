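# Readers/writers for the external formats the pipeline touches: GMT gene
# sets, per-omics feature x sample TSV matrices, miRNA-target and
# methylation-probe annotation tables, sample labels and survival tables.

#' Construct an omics matrix
#'
#' A light container for one omics layer: a dense numeric feature x sample
#' matrix with a declared omics kind. Methylation layers must hold beta
#' values in \[0, 1\].
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param kind one of `"mrna"`, `"mirna"`, `"methylation"`, `"other"`.
#' @return an object of class `omics_matrix` with elements `values` and
#'   `kind`.
#' @export
omics_matrix <- function(values, kind = c("mrna", "mirna", "methylation", "other")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("omics matrix needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature ids in omics matrix")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids in omics matrix")
  if (any(!is.finite(values)))
    stopf("omics matrix contains missing or non-finite values")
  if (kind == "methylation" && (min(values) < 0 || max(values) > 1))
    stopf("methylation beta values must lie in [0, 1]; found value outside range")
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> kind=%s, %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' One pathway per line: id, description, then member genes, tab-separated.
#' Duplicate genes within a line are collapsed; duplicate pathway ids are an
#' error.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_set_collection`: a list with `pathways`
#'   (named list of character gene vectors) and `description` (named
#'   character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pathways <- vector("list", length(lines))
  descr <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stopf("malformed GMT line %d: expected >= 3 tab-separated fields", i)
    ids[i] <- fields[1]
    descr[i] <- fields[2]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stopf("GMT line %d (%s) has no member genes", i, ids[i])
    pathways[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stopf("duplicate pathway id in GMT: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pathways) <- ids
  names(descr) <- ids
  gene_set_collection(pathways, descr)
}

#' Construct a gene-set collection
#'
#' @param pathways named list of character vectors of member genes.
#' @param description optional named character vector of descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(pathways, description = NULL) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stopf("pathways must be a uniquely named list")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0L)) stopf("every pathway must be non-empty")
  if (is.null(description)) {
    description <- setNames(rep("", length(pathways)), names(pathways))
  } else description <- description[names(pathways)]
  structure(list(pathways = pathways, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$pathways)
  cat(sprintf("<gene_set_collection> %d pathways, %d-%d genes each\n",
              length(sz), min(sz), max(sz)))
  invisible(x)
}

#' Write a gene-set collection to a GMT file
#'
#' @param gene_sets a `gene_set_collection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  lines <- vapply(names(gene_sets$pathways), function(id) {
    paste(c(id, gene_sets$description[[id]], gene_sets$pathways[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an omics matrix from TSV
#'
#' Expects a header of sample ids and a first column of feature ids.
#'
#' @param path path to the TSV file.
#' @param kind omics kind, see [omics_matrix()].
#' @param missing_policy `"error"` (default) rejects missing/non-numeric
#'   cells; `"zero_fill"` replaces them with 0, mirroring the convention that
#'   genes without supporting features carry zero signal.
#' @return an `omics_matrix`.
#' @export
read_omics_matrix <- function(path, kind = c("mrna", "mirna", "methylation", "other"),
                              missing_policy = c("error", "zero_fill")) {
  kind <- match.arg(kind)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stopf("omics matrix file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stopf("omics matrix needs a feature column and >= 1 sample column")
  feats <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(feats, colnames(vals))))
  bad <- !is.finite(num)
  if (any(bad)) {
    if (missing_policy == "error")
      stopf("non-numeric or missing cell(s) in %s (e.g. feature '%s'); use missing_policy='zero_fill' to zero them",
            path, feats[which(rowSums(bad) > 0)[1]])
    num[bad] <- 0
  }
  omics_matrix(num, kind)
}

#' Read a feature-to-gene map
#'
#' Two flavours: `"mirna_target"` expects a two-column TSV (feature, gene);
#' `"probe_promoter"` expects a BED-like TSV with columns probe, chrom, pos,
#' gene, tss, strand (header optional, detected from the first line).
#'
#' @param path path to the TSV file.
#' @param kind `"mirna_target"` or `"probe_promoter"`.
#' @return an object of class `feature_gene_map`: for miRNA a named list of
#'   target-gene character vectors; for probes a data frame with one row per
#'   (probe, gene) pair and the positional columns.
#' @export
read_feature_map <- function(path, kind = c("mirna_target", "probe_promoter")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("feature map file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("feature|probe|gene|mirna", tolower(first))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (kind == "mirna_target") {
    if (ncol(tab) < 2L) stopf("miRNA target map needs two columns (feature, gene)")
    feat <- tab[[1]]; gene <- tab[[2]]
    keep <- !duplicated(paste(feat, gene, sep = "\r"))
    entries <- split(gene[keep], feat[keep])
    entries <- lapply(entries, unique)
    structure(list(kind = kind, entries = entries), class = "feature_gene_map")
  } else {
    if (ncol(tab) < 6L)
      stopf("probe annotation needs columns: probe, chrom, pos, gene, tss, strand")
    df <- data.frame(probe = tab[[1]], chrom = tab[[2]],
                     pos = suppressWarnings(as.integer(tab[[3]])),
                     gene = tab[[4]],
                     tss = suppressWarnings(as.integer(tab[[5]])),
                     strand = tab[[6]], stringsAsFactors = FALSE)
    if (any(is.na(df$pos)) || any(is.na(df$tss)))
      stopf("probe annotation has non-integer pos/tss values")
    if (any(!df$strand %in% c("+", "-")))
      stopf("probe annotation has missing or invalid strand (must be '+' or '-')")
    df <- df[!duplicated(df), , drop = FALSE]
    structure(list(kind = kind, entries = df), class = "feature_gene_map")
  }
}

#' @export
print.feature_gene_map <- function(x, ...) {
  n <- if (is.data.frame(x$entries)) nrow(x$entries) else length(x$entries)
  cat(sprintf("<feature_gene_map> kind=%s, %d entries\n", x$kind, n))
  invisible(x)
}

#' Write a labelled numeric table to TSV
#'
#' Writes with row identifiers in the first column and full numeric
#' precision, so a read-back reproduces the values to better than 1e-12.
#'
#' @param x matrix or data frame with row and (unique) column names.
#' @param path output path.
#' @param id_col name for the first (row id) column.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(x, path, id_col = "id") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stopf("table has no column identifiers")
  if (anyDuplicated(colnames(x))) stopf("duplicate column ids in table")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  if (nrow(x) > 0L) {
    body <- apply(x, 2, function(col)
      if (is.numeric(col)) format(col, digits = 17, trim = TRUE, scientific = NA)
      else as.character(col))
    body <- matrix(body, nrow = nrow(x))
    writeLines(paste(rownames(x), apply(body, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a TSV matrix written by [write_matrix()]
#'
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read sample annotations (group labels and/or survival)
#'
#' @param labels_path optional TSV with columns sample, group.
#' @param survival_path optional TSV with columns sample, time, event.
#' @return an object of class `sample_annotations` with elements `labels`
#'   (named character vector or NULL) and `survival` (data frame with
#'   rownames = sample ids, columns time/event, or NULL).
#' @export
read_sample_annotations <- function(labels_path = NULL, survival_path = NULL) {
  labels <- NULL
  surv <- NULL
  if (!is.null(labels_path)) {
    tab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stopf("labels file needs columns sample, group")
    labels <- setNames(tab[[2]], tab[[1]])
  }
  if (!is.null(survival_path)) {
    tab <- utils::read.delim(survival_path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (ncol(tab) < 3L) stopf("survival file needs columns sample, time, event")
    surv <- data.frame(time = as.numeric(tab[[2]]),
                       event = as.integer(tab[[3]]),
                       row.names = as.character(tab[[1]]))
    if (any(surv$time < 0) || any(is.na(surv$time)))
      stopf("survival times must be nonnegative")
    if (any(!surv$event %in% c(0L, 1L)))
      stopf("survival events must be 0/1")
  }
  sample_annotations(labels, surv)
}

#' Construct sample annotations in memory
#'
#' @param labels named character vector mapping sample id to group, or NULL.
#' @param survival data frame with rownames = sample ids and columns
#'   `time` (nonnegative) and `event` (0/1), or NULL.
#' @return an object of class `sample_annotations`.
#' @export
sample_annotations <- function(labels = NULL, survival = NULL) {
  if (!is.null(labels)) {
    if (is.null(names(labels))) stopf("labels must be named by sample id")
    labels <- setNames(as.character(labels), names(labels))
  }
  if (!is.null(survival)) {
    stopifnot(is.data.frame(survival), all(c("time", "event") %in% names(survival)))
    if (any(survival$time < 0)) stopf("survival times must be nonnegative")
    if (any(!survival$event %in% c(0, 1))) stopf("survival events must be 0/1")
  }
  structure(list(labels = labels, survival = survival),
            class = "sample_annotations")
}
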