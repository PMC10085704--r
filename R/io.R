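# TSV / GMT / JSON input-output.

#' Read a wide protein-intensity table
#'
#' Reads a DIA-NN / MaxQuant "proteinGroups"-style TSV (one row per protein
#' group, one numeric column per sample). Raw zeros and non-finite entries
#' encode "not quantified" and are converted to `NA` on import so they can
#' never leak into log2 statistics.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param design A [sample_design()]; every design sample id must be a column
#'   of the file.
#' @param id_column Name of the protein-group id column (default
#'   `"protein_id"`).
#' @param gene_column Optional name of a gene-symbol column.
#' @param transform `"log2"` to log2-transform positive values on import, or
#'   `"none"` to keep values as stored.
#' @param scale Scale tag of the stored values when `transform = "none"`.
#' @return An [intensity_matrix()] on the log2 scale if `transform="log2"`.
#' @export
read_intensity_matrix <- function(path, design, id_column = "protein_id",
                                  gene_column = NULL,
                                  transform = c("none", "log2"),
                                  scale = c("log2", "linear")) {
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!id_column %in% names(tab))
    stop_("id column '%s' not found in %s", id_column, path)
  ids <- as.character(tab[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_("duplicate protein ids in %s: %s", path,
          paste(utils::head(dup, 10), collapse = ", "))
  miss <- setdiff(design$sample_id, names(tab))
  if (length(miss))
    stop_("design samples missing from %s: %s", path,
          paste(miss, collapse = ", "))
  vals <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[!is.finite(vals) | vals == 0] <- NA_real_
  if (transform == "log2") {
    if (any(vals <= 0, na.rm = TRUE))
      stop_("negative values cannot be log2-transformed")
    vals <- log2(vals)
    scale <- "log2"
  }
  rownames(vals) <- ids
  gn <- if (!is.null(gene_column)) {
    if (!gene_column %in% names(tab))
      stop_("gene column '%s' not found in %s", gene_column, path)
    as.character(tab[[gene_column]])
  }
  intensity_matrix(vals, gene_names = gn, scale = scale)
}

# render numeric columns at 17 significant digits so doubles survive a
# write/read round trip bit-exactly (as.character keeps only 15)
format_full_precision <- function(df, na = "") {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      out <- sprintf("%.17g", df[[j]])
      out[is.na(df[[j]])] <- na
      df[[j]] <- out
    }
  }
  df
}

#' Write an intensity matrix as TSV
#'
#' @param mat An `intensity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly. Missing cells are written as empty fields.
#' @export
write_intensity_matrix <- function(mat, path) {
  df <- data.frame(protein_id = protein_ids(mat), stringsAsFactors = FALSE)
  if (!is.null(mat$gene_names)) df$gene_name <- mat$gene_names
  df <- cbind(df, as.data.frame(mat$values, check.names = FALSE))
  utils::write.table(format_full_precision(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample-design TSV
#'
#' @param path TSV with columns sample_id, fraction, condition, replicate.
#' @return A `sample_design`.
#' @export
read_sample_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fraction", "condition", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_("design file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  sample_design(tab$sample_id, tab$fraction, tab$condition, tab$replicate)
}

#' @rdname read_sample_design
#' @param design A `sample_design` to write.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' One term per line: `term_id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate term ids are merged by unioning their members (with a warning).
#'
#' @param path Path to a GMT file.
#' @param namespace Identifier namespace of the members (`"gene"` default).
#' @return An [annotation_set()].
#' @export
read_annotation_gmt <- function(path, namespace = "gene") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_("malformed GMT line %d in %s: need term, description, >=1 member", i, path)
    id <- parts[[1]]
    members <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (!length(members))
      stop_("GMT line %d in %s has an empty member list", i, path)
    if (!is.null(terms[[id]])) {
      warn_("duplicate GMT term '%s'; members unioned", id)
      members <- union(terms[[id]]$members, members)
    }
    terms[[id]] <- list(name = parts[[2]], members = members)
  }
  annotation_set(terms, namespace = namespace)
}

#' Write a results table as TSV with a provenance header
#'
#' Writes any result data frame (differential results, enrichment tables,
#' stoichiometry tables, QC reports) as a TSV preceded by `#`-prefixed
#' comment lines recording the package version and the parameters used.
#'
#' @param result A data frame or an object with an `as.data.frame` method
#'   (e.g. a `differential_result`).
#' @param path Output path.
#' @param params Optional named list of parameters to record in the header.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path, params = NULL, seed = NULL) {
  df <- as.data.frame(result)
  hdr <- c(
    sprintf("# chromatome %s | written %s",
            as.character(utils::packageVersion("chromatome")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(seed)) sprintf("# seed = %s", format(seed)),
    if (length(params)) sprintf("# %s = %s", names(params),
                                vapply(params, function(p)
                                  paste(format(p), collapse = ","), ""))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format_full_precision(df, na = "NA"), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path Path to the TSV.
#' @return A data frame (header comments skipped).
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
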