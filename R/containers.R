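# Core containers: IntensityMatrix, SampleDesign, AnnotationSet.

#' Fraction vocabulary
#'
#' Fraction labels understood by the pipeline: the six subcellular fractions
#' of a chromatin-purification gradient (whole-cell lysate, cytoplasm,
#' nuclei, chromatin after washes 1-3), plus `chromatome` for a single
#' chromatin layer in two-layer designs, `proteome` for matched whole
#' proteomes, and `pulldown`/`igg` for ChIP-MS experiments.
#'
#' @export
FRACTION_LEVELS <- c(
  "whole_cell", "cytoplasm", "nuclei",
  "chromatome_w1", "chromatome_w2", "chromatome_w3",
  "chromatome", "proteome", "pulldown", "igg"
)

#' The six gradient fractions of a fractionation experiment
#' @export
GRADIENT_FRACTIONS <- FRACTION_LEVELS[1:6]

#' Construct a protein-by-sample intensity matrix
#'
#' The central container of the pipeline: a numeric matrix of protein-group
#' intensities (rows = protein groups, columns = samples) with a scale tag
#' distinguishing linear from log2 storage. Missing quantifications are `NA`;
#' raw zeros must be converted to `NA` before construction (see
#' [read_intensity_matrix()]).
#'
#' @param values Numeric matrix with unique, non-empty rownames (protein ids)
#'   and colnames (sample ids).
#' @param gene_names Optional character vector of gene symbols, one per row.
#' @param scale Either `"log2"` or `"linear"`.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, gene_names = NULL,
                             scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_("`values` must be a numeric matrix")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop_("`values` must carry protein ids as rownames and sample ids as colnames")
  dup <- unique(pid[duplicated(pid)])
  if (length(dup))
    stop_("duplicate protein ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  if (anyDuplicated(sid))
    stop_("duplicate sample ids: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!is.null(gene_names) && length(gene_names) != nrow(values))
    stop_("`gene_names` must have one entry per protein")
  structure(
    list(values = values, gene_names = gene_names, scale = scale),
    class = "intensity_matrix"
  )
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Protein and sample identifiers of an intensity matrix
#' @param x An `intensity_matrix`.
#' @return Character vector of ids.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname protein_ids
#' @export
sample_ids <- function(x) colnames(x$values)

assert_log2 <- function(x, what = "this operation") {
  if (!inherits(x, "intensity_matrix"))
    stop_("expected an intensity_matrix")
  if (x$scale != "log2")
    stop_("%s requires log2-scale intensities (got '%s'); transform on import",
          what, x$scale)
  invisible(x)
}

#' Subset an intensity matrix
#'
#' @param x An `intensity_matrix`.
#' @param i Row (protein) index, id vector or logical mask.
#' @param j Column (sample) index, id vector or logical mask.
#' @param ... Ignored.
#' @return An `intensity_matrix` over the selected proteins and samples.
#' @export
`[.intensity_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  gi <- if (is.null(x$gene_names)) NULL else {
    idx <- seq_len(nrow(x$values)); names(idx) <- rownames(x$values)
    x$gene_names[idx[i]]
  }
  intensity_matrix(x$values[i, j, drop = FALSE], gene_names = gi,
                   scale = x$scale)
}

#' Construct a sample-design table
#'
#' Declares, for every sample column, which fraction it belongs to, which
#' biological condition it was measured in, and its replicate index. Tests
#' group samples by (fraction, condition); replicate indices within each
#' group must be consecutive from 1.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param fraction One of [FRACTION_LEVELS] per sample.
#' @param condition Free condition label per sample (e.g. `"naive"`).
#' @param replicate Positive integer replicate index per sample.
#' @return A `sample_design` data frame.
#' @export
sample_design <- function(sample_id, fraction, condition, replicate) {
  d <- data.frame(sample_id = as.character(sample_id),
                  fraction = as.character(fraction),
                  condition = as.character(condition),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id))
    stop_("duplicate sample ids in design: %s",
          paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(d$fraction), FRACTION_LEVELS)
  if (length(bad))
    stop_("unknown fraction label(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(FRACTION_LEVELS, collapse = ", "))
  if (any(d$replicate < 1L) || anyNA(d$replicate))
    stop_("replicate indices must be positive integers")
  for (g in split(d, paste(d$fraction, d$condition, sep = "|"))) {
    if (!identical(sort(g$replicate), seq_len(nrow(g))))
      stop_("replicates in group (%s, %s) must be consecutive from 1",
            g$fraction[1], g$condition[1])
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Sample ids matching a fraction/condition selection
#'
#' @param design A `sample_design`.
#' @param fraction,condition Optional labels to filter on (`NULL` = any).
#' @return Character vector of matching sample ids, in design order.
#' @export
design_samples <- function(design, fraction = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(fraction)) keep <- keep & design$fraction %in% fraction
  if (!is.null(condition)) keep <- keep & design$condition %in% condition
  design$sample_id[keep]
}

# design rows for the samples of `mat`, in column order; errors on mismatch
align_design <- function(mat, design) {
  sid <- sample_ids(mat)
  miss <- setdiff(sid, design$sample_id)
  if (length(miss))
    stop_("samples absent from design: %s", paste(miss, collapse = ", "))
  design[match(sid, design$sample_id), , drop = FALSE]
}

# (fraction, condition) group key per design row
group_key <- function(design) paste(design$fraction, design$condition, sep = "|")

#' Group means of an intensity matrix
#'
#' Mean log2 intensity per protein over the replicates of each
#' (fraction, condition) group, ignoring missing values.
#'
#' @param mat An `intensity_matrix`.
#' @param design A `sample_design` covering the matrix columns.
#' @param by Grouping: `"fraction_condition"`, `"fraction"` or `"condition"`.
#' @return Numeric matrix proteins x groups.
#' @export
group_means <- function(mat, design,
                        by = c("fraction_condition", "fraction", "condition")) {
  by <- match.arg(by)
  d <- align_design(mat, design)
  key <- switch(by,
                fraction_condition = group_key(d),
                fraction = d$fraction,
                condition = d$condition)
  groups <- unique(key)
  out <- vapply(groups, function(g) {
    rowMeans(mat$values[, key == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat$values)))
  out[is.nan(out)] <- NA_real_
  out
}

#' Construct an annotation set
#'
#' @param terms Named list; each element a list with `name` (description) and
#'   `members` (non-empty character vector of identifiers).
#' @param namespace Identifier namespace of the members, `"gene"` or
#'   `"protein"`; used when matching against protein groups.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(terms, namespace = c("gene", "protein")) {
  namespace <- match.arg(namespace)
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop_("terms must be uniquely named by term id")
  for (id in names(terms)) {
    if (!length(terms[[id]]$members))
      stop_("term '%s' has an empty member list", id)
  }
  structure(list(terms = terms, namespace = namespace),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$members), integer(1))
  cat(sprintf("<annotation_set> %d terms (%s ids), member counts %d-%d\n",
              length(x$terms), x$namespace,
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

# Map protein-group labels to annotation namespace: first id of the group,
# case-insensitive (groups are ';'-separated).
first_gene <- function(x) toupper(sub(";.*$", "", x))
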