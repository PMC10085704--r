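# Fisher's exact annotation enrichment against the identified background,
# and strict-valid-value annotation counts.

# exact hypergeometric p for a 2x2 table: k of n foreground proteins in a
# term of size K within a background of N.
# one-sided ("over"): upper tail including k; two-sided: sum of all table
# probabilities not exceeding the observed one (standard exact convention).
hyper_p <- function(k, K, n, N, alternative = c("two.sided", "over")) {
  alternative <- match.arg(alternative)
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  dens <- stats::dhyper(lo:hi, K, N - K, n)
  if (alternative == "over") {
    sum(dens[(lo:hi) >= k])
  } else {
    obs <- stats::dhyper(k, K, N - K, n)
    sum(dens[dens <= obs * (1 + 1e-7)])
  }
}

#' Fisher's exact annotation enrichment
#'
#' Tests each annotation term for over-/under-representation of a foreground
#' protein set against the background of all identified proteins, using the
#' exact hypergeometric distribution of the 2x2 table (in/out of term x
#' in/out of foreground, within the background). P values are
#' Benjamini-Hochberg adjusted across all tested terms; terms with fewer
#' than `min_term_size` members inside the background are skipped.
#'
#' Protein-group identifiers are mapped to the annotation namespace by
#' taking the first id of each group, case-insensitively.
#'
#' @param foreground Character vector of protein ids (must be a subset of
#'   `background`).
#' @param background Character vector of all identified protein ids.
#' @param annotations An [annotation_set()].
#' @param min_term_size Minimum term size within the background (default 3).
#' @param alternative `"two.sided"` (default) or `"over"` for one-sided
#'   over-representation.
#' @return An `enrichment_result` data frame: per term the counts, odds
#'   ratio, enrichment factor, `p`, BH `q` and direction.
#' @export
fisher_enrichment <- function(foreground, background, annotations,
                              min_term_size = 3,
                              alternative = c("two.sided", "over")) {
  alternative <- match.arg(alternative)
  if (!length(foreground)) stop_("empty foreground")
  bad <- setdiff(foreground, background)
  if (length(bad))
    stop_("foreground not a subset of the background (%d offending ids, e.g. %s)",
          length(bad), paste(utils::head(bad, 3), collapse = ", "))
  bg <- unique(first_gene(background))
  fg <- unique(first_gene(foreground))
  N <- length(bg); n <- length(fg)
  rows <- lapply(names(annotations$terms), function(id) {
    members <- unique(toupper(annotations$terms[[id]]$members))
    term_bg <- intersect(members, bg)
    K <- length(term_bg)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(term_bg, fg))
    p <- hyper_p(k, K, n, N, alternative)
    ef <- (k / n) / (K / N)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(term_id = id, term_name = annotations$terms[[id]]$name,
               n_fg_term = k, n_bg_term = K, n_fg = n, n_bg = N,
               odds_ratio = or, enrichment_factor = ef, p = p,
               direction = if (ef >= 1) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(0), term_name = character(0),
                      n_fg_term = integer(0), n_bg_term = integer(0),
                      n_fg = integer(0), n_bg = integer(0),
                      odds_ratio = numeric(0), enrichment_factor = numeric(0),
                      p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Strict-valid-value annotation counts
#'
#' Counts, per annotation term, the proteins of a replicate group that are
#' fully observed (by default all replicates quantified — the stricter
#' "3 of 3 valid values" rule used for GO-category counting) and annotated
#' to the term.
#'
#' @param mat A log2 [intensity_matrix()].
#' @param design A [sample_design()].
#' @param annotations An [annotation_set()].
#' @param fraction,condition Select the replicate group to count in
#'   (`NULL` = all samples as one group).
#' @param min_valid Required valid values; `NULL` (default) means every
#'   replicate of the group must be observed.
#' @return Data frame with `term_id`, `term_name`, `n_proteins`.
#' @export
annotation_counts <- function(mat, design, annotations, fraction = NULL,
                              condition = NULL, min_valid = NULL) {
  d <- align_design(mat, design)
  sids <- design_samples(d, fraction = fraction, condition = condition)
  if (!length(sids)) stop_("no samples match the requested group")
  need <- min_valid %||% length(sids)
  if (need > length(sids))
    stop_("group has %d replicates but %d valid values are required",
          length(sids), need)
  nv <- rowSums(!is.na(mat$values[, sids, drop = FALSE]))
  present <- unique(first_gene(protein_ids(mat)[nv >= need]))
  counts <- vapply(names(annotations$terms), function(id) {
    length(intersect(unique(toupper(annotations$terms[[id]]$members)), present))
  }, integer(1))
  data.frame(term_id = names(annotations$terms),
             term_name = vapply(annotations$terms, function(t) t$name, ""),
             n_proteins = unname(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
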