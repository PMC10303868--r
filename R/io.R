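#' Read a GMT gene-set file
#'
#' Parses the Broad GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are
#' deduplicated within each set (first occurrence kept) and trailing empty
#' fields are dropped.
#'
#' @param path Path to a GMT file (UTF-8, tab-separated).
#' @param source_label Optional label recording where the collection came
#'   from; defaults to the file name.
#' @return A `gene_set_collection`: a list with elements `sets` (named list
#'   of character vectors of gene symbols), `description` (named character
#'   vector) and `source_label`.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tTP53\tMYC", tf)
#' gsc <- read_gmt(tf)
#' gsc$sets$S1
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop_ps("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_ps("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descs <- character(length(fields))
  names <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[!(seq_along(f) > 2 & !nzchar(f))]  # drop empty gene fields
    if (length(f) < 3) {
      stop_ps(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    }
    names[i] <- f[1]
    descs[i] <- f[2]
    genes <- f[-(1:2)]
    sets[[i]] <- genes[!duplicated(genes)]
  }
  dup <- names[duplicated(names)]
  if (length(dup) > 0) {
    stop_ps("duplicate gene-set name(s) in GMT: ",
            paste(unique(dup), collapse = ", "))
  }
  names(sets) <- names
  names(descs) <- names
  new_gene_set_collection(sets, descs, source_label)
}

new_gene_set_collection <- function(sets, description = NULL,
                                    source_label = "user") {
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description,
                 source_label = source_label),
            class = "gene_set_collection")
}

#' Construct a gene-set collection from a named list
#'
#' @param sets Named list of character vectors of gene symbols; duplicates
#'   within a set are removed (first occurrence kept).
#' @param description Optional named character vector of descriptions.
#' @param source_label Free-text provenance label.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL,
                                source_label = "user") {
  if (is.null(names(sets)) || anyNA(names(sets)) || any(!nzchar(names(sets)))) {
    stop_ps("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) stop_ps("gene-set names must be unique")
  if (any(lengths(sets) == 0)) stop_ps("gene sets must be non-empty")
  sets <- lapply(sets, function(g) as.character(g[!duplicated(g)]))
  new_gene_set_collection(sets, description, source_label)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (source: %s)\n",
              length(x$sets), x$source_label))
  cat(sprintf("  set sizes: %d-%d genes\n",
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]] %||% "", gsc$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene expression matrix from tab-delimited text
#'
#' Expects a header row of sample IDs; the first column holds gene symbols.
#' Values are used as supplied (linear or log scale). Duplicate gene symbols
#' are collapsed by keeping the row with the highest mean expression; the
#' number of collapsed rows is reported via `message()`.
#'
#' @param path Path to a TSV file, genes in rows, samples in columns.
#' @return Numeric matrix with gene symbols as row names and sample IDs as
#'   column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) stop_ps("expression file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) stop_ps("duplicate sample IDs in expression header")
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    vals[[j]] <- as_numeric_strict(vals[[j]],
                                   sprintf("expression column %s", dQuote(sample_ids[j])))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(mat, na.rm = TRUE)
    ord <- order(-means)  # keep highest-mean row for each duplicated symbol
    keep <- ord[!duplicated(genes[ord])]
    n_dropped <- nrow(mat) - length(keep)
    mat <- mat[sort(keep), , drop = FALSE]
    message(sprintf("read_expression: collapsed %d duplicate gene row(s), keeping highest mean",
                    n_dropped))
  }
  mat
}

#' Write an expression matrix as tab-delimited text
#'
#' @param mat Numeric matrix, gene symbols as row names.
#' @param path Output path.
#' @param gene_col Name for the first (gene symbol) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical meta table
#'
#' One row per sample. The first column is taken as the sample ID. Rows with
#' missing survival time or event indicator are dropped with a message. The
#' event column must be codable as 0 (censored) / 1 (event).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param time_col Name of the survival-time column.
#' @param event_col Name of the event-indicator column.
#' @return A data frame with columns `sample_id`, `time`, `event`, plus all
#'   remaining columns as covariates.
#' @export
read_clinical <- function(path, time_col = "time", event_col = "event") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  for (col in c(time_col, event_col)) {
    if (!col %in% colnames(df)) {
      stop_ps(sprintf("column %s not found; available columns: %s",
                      dQuote(col), paste(colnames(df), collapse = ", ")))
    }
  }
  sample_id <- as.character(df[[1]])
  if (anyDuplicated(sample_id)) stop_ps("duplicate sample IDs in clinical table")
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  event_raw <- trimws(as.character(df[[event_col]]))
  event <- ifelse(event_raw %in% c("1", "TRUE"), 1,
                  ifelse(event_raw %in% c("0", "FALSE"), 0, NA_real_))
  bad_event <- !is.na(event_raw) & nzchar(event_raw) & is.na(event)
  if (any(bad_event)) {
    stop_ps(sprintf("event column %s contains non-binary value %s",
                    dQuote(event_col), dQuote(event_raw[which(bad_event)[1]])))
  }
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep)) {
    message(sprintf("read_clinical: dropped %d row(s) with missing time or event",
                    sum(!keep)))
  }
  if (any(time[keep] < 0)) stop_ps("negative survival times are not allowed")
  covars <- df[keep, setdiff(colnames(df), c(colnames(df)[1], time_col, event_col)),
               drop = FALSE]
  out <- data.frame(sample_id = sample_id[keep], time = time[keep],
                    event = event[keep], stringsAsFactors = FALSE)
  cbind(out, covars)
}

#' Assemble an aligned cohort from expression and clinical data
#'
#' Both components are subset and reordered to the lexicographically sorted
#' intersection of their sample IDs, so downstream results do not depend on
#' input file order. Counts of dropped samples are reported via `message()`.
#'
#' @param expr Numeric expression matrix (genes x samples) with sample IDs
#'   as column names, e.g. from [read_expression()].
#' @param clin Clinical data frame with a `sample_id` column, e.g. from
#'   [read_clinical()].
#' @return A `cohort`: list with elements `expression` (matrix) and
#'   `clinical` (data frame) over an identical ordered sample set.
#' @export
build_cohort <- function(expr, clin) {
  if (!"sample_id" %in% colnames(clin)) stop_ps("clinical table lacks a sample_id column")
  shared <- sort(intersect(colnames(expr), clin$sample_id))
  if (length(shared) < 2) {
    stop_ps(sprintf("only %d shared sample(s) between expression and clinical data; need >= 2",
                    length(shared)))
  }
  d_expr <- ncol(expr) - length(shared)
  d_clin <- nrow(clin) - length(shared)
  if (d_expr > 0 || d_clin > 0) {
    message(sprintf("build_cohort: dropped %d expression-only and %d clinical-only sample(s)",
                    d_expr, d_clin))
  }
  clin <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  structure(list(expression = expr[, shared, drop = FALSE], clinical = clin),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d genes x %d samples, %d events / %d samples\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event), nrow(x$clinical)))
  invisible(x)
}

#' Filter a cohort by a clinical covariate
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param column Name of a clinical column to filter on.
#' @param allowed Vector of values to keep.
#' @return The filtered `cohort`.
#' @export
filter_samples <- function(cohort, column, allowed) {
  stopifnot(inherits(cohort, "cohort"))
  if (!column %in% colnames(cohort$clinical)) {
    stop_ps(sprintf("column %s not in clinical table; available: %s",
                    dQuote(column),
                    paste(colnames(cohort$clinical), collapse = ", ")))
  }
  keep <- cohort$clinical[[column]] %in% allowed
  if (sum(keep) < 2) {
    stop_ps(sprintf("filtering %s to {%s} leaves %d sample(s); need >= 2",
                    dQuote(column), paste(allowed, collapse = ", "), sum(keep)))
  }
  cohort$clinical <- cohort$clinical[keep, , drop = FALSE]
  rownames(cohort$clinical) <- NULL
  cohort$expression <- cohort$expression[, cohort$clinical$sample_id, drop = FALSE]
  cohort
}

#' Read a two-column ranked gene list (symbol, hazard ratio)
#'
#' The list is sorted by descending ranking value. Duplicate symbols keep
#' the first occurrence with a warning. A header line is detected by a
#' non-numeric second field on the first line.
#'
#' @param path Path to a two-column tab-delimited file.
#' @return A `ranked_gene_list`: data frame with columns `gene` and `value`,
#'   sorted by decreasing `value`.
#' @export
read_ranked_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_ps("ranked list file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop_ps(sprintf("ranked list line %d has fewer than 2 fields",
                    which(lengths(fields) < 2)[1]))
  }
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  start <- if (is.na(first_val)) 2L else 1L  # header detection
  if (start > length(lines)) stop_ps("ranked list has a header but no data rows")
  genes <- vapply(fields[start:length(fields)], `[`, character(1), 1)
  vals_chr <- vapply(fields[start:length(fields)], `[`, character(1), 2)
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    stop_ps(sprintf("non-numeric ranking value %s on line %d",
                    dQuote(vals_chr[which(is.na(vals))[1]]),
                    which(is.na(vals))[1] + start - 1L))
  }
  if (anyDuplicated(genes)) {
    warn_ps(sprintf("ranked list: %d duplicate symbol(s), keeping first occurrence",
                    sum(duplicated(genes))))
    keep <- !duplicated(genes)
    genes <- genes[keep]
    vals <- vals[keep]
  }
  ranked_gene_list(genes, vals)
}

#' Construct a ranked gene list
#'
#' @param genes Character vector of unique gene symbols.
#' @param values Numeric ranking values (e.g. hazard ratios).
#' @return A `ranked_gene_list` data frame sorted by decreasing value;
#'   genes with tied values keep their input order (stable sort), so a
#'   ranking written by [hr_ranking()] round-trips unchanged.
#' @export
ranked_gene_list <- function(genes, values) {
  stopifnot(length(genes) == length(values))
  if (anyDuplicated(genes)) stop_ps("ranked list symbols must be unique")
  ord <- order(-values)
  structure(data.frame(gene = as.character(genes)[ord], value = values[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' Write a ranked gene list as two-column TSV
#'
#' @param ranked A `ranked_gene_list`.
#' @param path Output path.
#' @param header Write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path, header = TRUE) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

screen_table_columns <- c("feature", "kind", "hazard_ratio", "ci_low",
                          "ci_high", "wald_p", "lr_statistic", "lr_p",
                          "bh_adjusted_p", "n", "n_events")

#' Write a screening result table as TSV
#'
#' Emits the fixed column order `feature, kind, hazard_ratio, ci_low,
#' ci_high, wald_p, lr_statistic, lr_p, bh_adjusted_p, n, n_events`,
#' preceded by `#`-prefixed metadata comment lines.
#'
#' @param table A `screen_table` from [screen_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(table, path) {
  meta <- attr(table, "metadata")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (nm in names(meta)) {
      val <- meta[[nm]]
      if (length(val) > 0 && !is.list(val)) {
        writeLines(sprintf("# %s: %s", nm, paste(val, collapse = ",")), con)
      }
    }
  }
  df <- as.data.frame(table)[, screen_table_columns, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screening result table written by [write_screen_table()]
#'
#' @param path Path to the TSV file.
#' @return A `screen_table` data frame.
#' @export
read_screen_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(screen_table_columns, colnames(df))
  if (length(missing) > 0) {
    stop_ps("screen table missing column(s): ", paste(missing, collapse = ", "))
  }
  structure(df, class = c("screen_table", "data.frame"))
}
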