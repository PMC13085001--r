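#' Construct and validate a count matrix with sample metadata
#'
#' The central container for bulk RNA-seq experiments: an integer gene-by-
#' sample count matrix plus a per-sample metadata table describing cohort,
#' rearing condition and pharmacological treatment. All downstream operations
#' accept either this container or a bare matrix.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_meta `data.frame` with columns `sample_id`, `cohort`,
#'   `condition` (`"control"` or `"ELS"`) and `treatment` (`"vehicle"` or
#'   `"RU486"`); every column of `counts` must appear in `sample_id`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta` (rows ordered to match the count columns).
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene rownames and sample colnames", call. = FALSE)
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) {
    stop("duplicate gene_id in counts: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in counts", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts))[1L]
    stop(sprintf(
      "counts must be non-negative integers; first offending value %s at index %d",
      format(counts[bad]), bad
    ), call. = FALSE)
  }
  required <- c("sample_id", "cohort", "condition", "treatment")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols)) {
    stop(
      "sample_meta lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  absent <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(absent)) {
    stop(
      "sample(s) missing from metadata: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  bad_cond <- setdiff(unique(sample_meta$condition), c("control", "ELS"))
  if (length(bad_cond)) {
    stop("condition must be 'control' or 'ELS'; got: ",
      paste(bad_cond, collapse = ", "),
      call. = FALSE
    )
  }
  bad_trt <- setdiff(unique(sample_meta$treatment), c("vehicle", "RU486"))
  if (length(bad_trt)) {
    stop("treatment must be 'vehicle' or 'RU486'; got: ",
      paste(bad_trt, collapse = ", "),
      call. = FALSE
    )
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
    drop = FALSE
  ]
  rownames(sample_meta) <- NULL
  storage.mode(counts) <- "double"
  structure(list(counts = counts, sample_meta = sample_meta),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%d cohort(s))\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$sample_meta$cohort))
  ))
  grp <- table(x$sample_meta$condition, x$sample_meta$treatment)
  print(grp)
  invisible(x)
}

# accept a count_matrix or a bare matrix everywhere
.counts_of <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else if (is.matrix(x)) x else {
    stop("expected a count_matrix or a numeric matrix", call. = FALSE)
  }
}

#' Read a count matrix (TSV or MatrixMarket) with its sample metadata
#'
#' TSV input is a header line `gene_id<TAB>sample...` followed by one row per
#' gene. MatrixMarket input (`*.mtx`) carries gene and sample ids in sidecar
#' files `<path>.rows` and `<path>.cols` (one id per line). Non-integer or
#' negative entries, duplicate gene ids, and samples absent from the metadata
#' are rejected rather than coerced.
#'
#' @param path Count file (`.tsv`/`.txt` or `.mtx`).
#' @param meta_path Sample metadata TSV with columns `sample_id`, `cohort`,
#'   `condition`, `treatment`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  meta <- read.delim(meta_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("MatrixMarket input requires sidecar files ", rows_file, " and ",
        cols_file,
        call. = FALSE
      )
    }
    rownames(m) <- readLines(rows_file)
    colnames(m) <- readLines(cols_file)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1L] != "gene_id") {
      stop("count TSV must have 'gene_id' as its first column", call. = FALSE)
    }
    ids <- tab$gene_id
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      stop("duplicate gene_id in ", path, ": ", paste(dup, collapse = ", "),
        call. = FALSE
      )
    }
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("counts must be numeric", call. = FALSE)
    rownames(m) <- ids
  }
  count_matrix(m, meta)
}

#' Write a count matrix and its sample metadata as TSV
#'
#' @param x A [count_matrix()].
#' @param path Output counts TSV (first column `gene_id`).
#' @param meta_path Output metadata TSV.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if (!is.null(meta_path)) {
    write.table(x$sample_meta, meta_path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  invisible(x)
}

#' Write a count matrix in MatrixMarket format with id sidecars
#'
#' @inheritParams write_counts
#' @param path Output `.mtx` file; gene and sample ids go to `<path>.rows`
#'   and `<path>.cols`.
#' @export
write_counts_mtx <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
  writeLines(rownames(x$counts), paste0(path, ".rows"))
  writeLines(colnames(x$counts), paste0(path, ".cols"))
  invisible(x)
}

#' Extract per-gene genomic lengths from a GTF annotation
#'
#' Gene length is the genomic span of the annotated gene feature,
#' `end - start + 1` in the GTF's 1-based inclusive coordinates (the
#' convention used when lengths are pulled from Ensembl gene records).
#' Merged-exon ("union exon") length is deliberately not computed here; if
#' exon-level lengths are wanted, sum exon widths upstream and supply them via
#' [read_gene_lengths()].
#'
#' @param path GTF file (Ensembl dialect).
#' @param feature Feature type to use, default `"gene"`.
#' @return `data.frame` with columns `gene_id` and `length_bp`.
#' @export
gene_lengths_from_gtf <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == feature]
  if (!length(gr)) {
    warning("no '", feature, "' features found in ", path,
      "; returning an empty annotation",
      call. = FALSE
    )
    return(data.frame(gene_id = character(), length_bp = integer()))
  }
  ids <- as.character(gr$gene_id)
  widths <- as.integer(GenomicRanges::width(gr))
  ann <- unique(data.frame(
    gene_id = ids, length_bp = widths,
    stringsAsFactors = FALSE
  ))
  conflict <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(conflict)) {
    stop("conflicting spans for gene_id(s): ",
      paste(conflict, collapse = ", "),
      call. = FALSE
    )
  }
  rownames(ann) <- NULL
  ann
}

#' Read / write a two-column gene length table
#'
#' @param path TSV with header `gene_id<TAB>length_bp`.
#' @return `data.frame` with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(ann))) {
    stop("gene length table needs columns gene_id and length_bp", call. = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in length table", call. = FALSE)
  if (any(ann$length_bp < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  ann
}

#' @rdname read_gene_lengths
#' @param ann Annotation `data.frame` to write.
#' @export
write_gene_lengths <- function(ann, path) {
  write.table(ann[, c("gene_id", "length_bp")], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(ann)
}

#' Read a gene-set collection from a GMT file
#'
#' Each tab-separated line is `set name`, `description`, then one or more
#' member gene ids. Lines with fewer than three fields are a parse error
#' reported with their line number.
#'
#' @param path GMT file.
#' @return Named list of character vectors (class `gene_set_collection`),
#'   with per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf(
      "GMT parse error: line %d has fewer than 3 tab-separated fields",
      short[1L]
    ), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set names in GMT: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", "),
      call. = FALSE
    )
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  structure(sets,
    description = setNames(vapply(fields, `[[`, "", 2L), nm),
    class = "gene_set_collection"
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors; optional per-set descriptions
#'   in `attr(sets, "description")`.
#' @param path Output GMT file.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

.de_numeric_cols <- c("base_mean", "log2fc", "se", "pvalue", "padj")

#' Read / write a differential-expression result table
#'
#' The interchange schema for DE results, whether produced by
#' [nb_wald_test()] or by an external caller (e.g. a DESeq2 run): columns
#' `gene_id`, `log2fc`, `pvalue`, `padj` (required) and `base_mean`, `se`
#' (optional). Probabilities outside \[0, 1\] are rejected. Numeric columns are
#' written with 17 significant digits so a round trip reproduces the values
#' exactly.
#'
#' @param path DE table TSV.
#' @return `data.frame` with a `significant` column derived from
#'   `padj < alpha`.
#' @param alpha FDR threshold used to flag significance on read, default 0.05.
#' @export
read_de_table <- function(path, alpha = 0.05) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "pvalue", "padj")
  missing_cols <- setdiff(required, names(de))
  if (length(missing_cols)) {
    stop("DE table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_id in DE table", call. = FALSE)
  .assert_probabilities(de$pvalue, "pvalue")
  .assert_probabilities(de$padj, "padj")
  de$significant <- !is.na(de$padj) & de$padj < alpha
  de
}

#' @rdname read_de_table
#' @param de DE `data.frame` to write.
#' @export
write_de_table <- function(de, path) {
  out <- de[, intersect(c("gene_id", .de_numeric_cols), names(de)), drop = FALSE]
  for (cl in intersect(.de_numeric_cols, names(out))) {
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(de)
}
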