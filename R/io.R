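# Readers and writers for the pipeline's plain-text dialects (UTF-8,
# header row, '.' decimal): cell tables and spine surveys as CSV, bin
# profiles and expression matrices as TSV, gene sets as GMT, structured
# results as JSON.  Plus genotype blinding/unblinding.

require_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
}

check_nonempty <- function(df, path) {
  if (!nrow(df)) stop("'", path, "' contains no data rows")
}

#' Read a per-cell laminar position table (CSV)
#'
#' Expects columns `cell_id`, `depth_fraction`, `slice_id`, `animal_id`,
#' `genotype`; depth fractions must lie in `[0, 1]` and cell ids must be
#' unique within a slice.  Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV file.
#' @return a `cell_position_table` data frame.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("cell_id", "depth_fraction", "slice_id", "animal_id",
                        "genotype"), path)
  check_nonempty(df, path)
  bad <- which(!is.finite(df$depth_fraction) |
                 df$depth_fraction < 0 | df$depth_fraction > 1)
  if (length(bad)) {
    stop("'", path, "': depth_fraction outside [0, 1] at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  dup <- duplicated(df[c("slice_id", "cell_id")])
  if (any(dup)) {
    stop("'", path, "': duplicate cell_id within a slice at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  }
  class(df) <- c("cell_position_table", "data.frame")
  df
}

#' @rdname read_cell_table
#' @param x table to write.
#' @export
write_cell_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Duplicate members within a line are removed with a
#' warning counting them.
#'
#' @param path GMT file.
#' @return list of [gene_set()] objects, named by set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("'", path, "' contains no gene sets")
  n_dup <- 0L
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("'", path, "': GMT line with fewer than 3 fields: ",
           substr(l, 1, 50))
    }
    members <- normalize_gene_ids(parts[-(1:2)])
    n_dup <<- n_dup + (length(members) - length(unique(members)))
    gene_set(parts[1], members)
  })
  if (n_dup > 0L) {
    warning("'", path, "': removed ", n_dup, " duplicate member(s)")
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' @rdname read_gmt
#' @param sets list of [gene_set()] objects.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(sets[[i]]$name, descriptions[i], sets[[i]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-column gene list (TSV)
#'
#' @param path file with one gene id per line (an optional `gene` header is
#'   skipped).
#' @param name name for the resulting set.
#' @return a [gene_set()].
#' @export
read_dex_list <- function(path, name = "dex") {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) && tolower(x[1]) %in% c("gene", "gene_id", "symbol")) x <- x[-1]
  if (!length(x)) stop("'", path, "' contains no gene identifiers")
  gene_set(name, x)
}

#' Read/write a gene expression matrix (TSV, genes x samples)
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("'", path, "' needs a gene column plus sample columns")
  check_nonempty(df, path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("'", path, "': non-numeric expression values")
  if (any(is.na(m))) stop("'", path, "': missing expression values")
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression
#' @param x matrix to write.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write spine-count surveys (CSV)
#'
#' @param path CSV with columns `segment_id`, `animal_id`, `genotype`,
#'   `n_day0`, `n_gained`, `n_lost`, `interval_days`.
#' @return a `spine_survey` data frame.
#' @export
read_spines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("segment_id", "animal_id", "genotype", "n_day0",
                        "n_gained", "n_lost", "interval_days"), path)
  check_nonempty(df, path)
  bad <- which(df$n_day0 < 0 | df$n_gained < 0 | df$n_lost < 0 |
                 df$n_lost > df$n_day0)
  if (length(bad)) {
    stop("'", path, "': invalid spine counts at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  class(df) <- c("spine_survey", "data.frame")
  df
}

#' @rdname read_spines
#' @param x table to write.
#' @export
write_spines <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write per-slice bin-profile tables (TSV)
#'
#' @param path TSV with columns `slice_id`, `genotype`, `bin_01` ...,
#'   `n_cells` (one row per slice), the layout produced by
#'   [bin_profiles()].
#' @return a `bin_profile_table` data frame.
#' @export
read_bin_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("slice_id", "genotype", "n_cells"), path)
  if (!length(grep("^bin_\\d+$", names(df)))) {
    stop("'", path, "' has no bin_XX columns")
  }
  check_nonempty(df, path)
  class(df) <- c("bin_profile_table", "data.frame")
  df
}

#' @rdname read_bin_profiles
#' @param x table to write.
#' @export
write_bin_profiles <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Blind and unblind genotype labels
#'
#' Replaces genotype labels with random codes so that downstream
#' quantification can be done blind to group, and restores them exactly
#' from the key.
#'
#' @param table data frame with a `genotype` column.
#' @param seed seed for the code assignment (same seed, same coding).
#' @return `blind_labels()`: list with `table` (codes in place of
#'   genotypes) and `key` (data frame `code`, `genotype`).
#'   `unblind_labels()`: the restored table.
#' @export
blind_labels <- function(table, seed = NULL) {
  if (!"genotype" %in% names(table)) stop("table has no 'genotype' column")
  gts <- sort(unique(table$genotype))
  codes <- with_seed(seed, {
    sprintf("GRP%04d", sample.int(9999L, length(gts)))
  })
  key <- data.frame(code = codes, genotype = gts, stringsAsFactors = FALSE)
  blinded <- table
  blinded$genotype <- key$code[match(table$genotype, key$genotype)]
  list(table = blinded, key = key)
}

#' @rdname blind_labels
#' @param key the key returned by `blind_labels()`.
#' @export
unblind_labels <- function(table, key) {
  if (!"genotype" %in% names(table)) stop("table has no 'genotype' column")
  idx <- match(table$genotype, key$code)
  if (any(is.na(idx))) {
    stop("table contains code(s) absent from the key: ",
         paste(unique(table$genotype[is.na(idx)]), collapse = ", "))
  }
  out <- table
  out$genotype <- key$genotype[idx]
  out
}

#' Write a structured result as JSON
#'
#' @param x list or data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
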