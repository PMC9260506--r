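#' Clonotype count table for tetramer-sorted fractions
#'
#' @param n_pos,n_neg Named integer vectors of per-clonotype cell counts in
#'   the tetramer-positive and tetramer-negative fractions (names are
#'   clonotype ids; absent clonotypes count 0).
#' @return A `clonotype_count_table`: data.frame `rows` (`clonotype_id`,
#'   `n_pos`, `n_neg`) plus totals `N_pos`, `N_neg`.
#' @export
clonotype_count_table <- function(n_pos, n_neg) {
  ids <- union(names(n_pos), names(n_neg))
  if (length(ids) == 0) stop("empty count table")
  get <- function(x) {
    v <- x[ids]; v[is.na(v)] <- 0L
    as.integer(v)
  }
  rows <- data.frame(clonotype_id = ids, n_pos = get(n_pos),
                     n_neg = get(n_neg), stringsAsFactors = FALSE)
  if (any(rows$n_pos < 0 | rows$n_neg < 0)) stop("counts must be >= 0")
  structure(list(rows = rows, N_pos = sum(rows$n_pos),
                 N_neg = sum(rows$n_neg)),
            class = "clonotype_count_table")
}

#' @export
print.clonotype_count_table <- function(x, ...) {
  cat(sprintf("Clonotype counts: %d clonotypes, %d tetramer+ / %d tetramer- cells\n",
              nrow(x$rows), x$N_pos, x$N_neg))
  invisible(x)
}

#' Read / write clonotype fraction counts as CSV
#' @param path CSV with columns `clonotype_id`, `n_pos`, `n_neg`.
#' @return `read_count_table` returns a `clonotype_count_table`.
#' @export
read_count_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  clonotype_count_table(setNames(x$n_pos, x$clonotype_id),
                        setNames(x$n_neg, x$clonotype_id))
}

#' @param table A `clonotype_count_table` to write.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  write.csv(table$rows, path, row.names = FALSE)
  invisible(path)
}

#' Per-fraction clonotype frequencies
#'
#' @param table A `clonotype_count_table`.
#' @return data.frame `clonotype_id`, `freq_pos`, `freq_neg`; each column of
#'   frequencies sums to 1.
#' @export
fraction_frequencies <- function(table) {
  if (table$N_pos == 0 || table$N_neg == 0)
    stop("both fractions must contain cells")
  data.frame(clonotype_id = table$rows$clonotype_id,
             freq_pos = table$rows$n_pos / table$N_pos,
             freq_neg = table$rows$n_neg / table$N_neg,
             stringsAsFactors = FALSE)
}

#' Select clonal lineages enriched in the tetramer-positive fraction
#'
#' A lineage passes when it comprises at least `min_cells` cells in the
#' tetramer-positive fraction and its tetramer-positive frequency is at least
#' `min_fold` times its (pseudocount-adjusted) tetramer-negative frequency:
#' `(n_pos/N_pos) / ((n_neg + pseudocount)/(N_neg + pseudocount)) >= min_fold`.
#' The pseudocount keeps lineages absent from the negative fraction finite;
#' the unadjusted fold (`Inf` when `n_neg == 0`) is also reported.
#'
#' @param table A `clonotype_count_table`.
#' @param min_cells Minimum tetramer-positive cell count (default 3).
#' @param min_fold Minimum frequency fold enrichment (default 5).
#' @param pseudocount Additive pseudocount on the negative fraction
#'   (default 1; 0 reproduces the raw rule).
#' @return data.frame of passing lineages: `clonotype_id`, `n_pos`,
#'   `freq_pos`, `freq_neg_adjusted`, `fold`, `fold_raw`, sorted by `fold`
#'   descending.
#' @export
select_enriched <- function(table, min_cells = 3, min_fold = 5,
                            pseudocount = 1) {
  stopifnot(min_cells >= 1, min_fold > 0, pseudocount >= 0)
  r <- table$rows
  freq_pos <- r$n_pos / table$N_pos
  freq_neg_adj <- (r$n_neg + pseudocount) / (table$N_neg + pseudocount)
  fold <- freq_pos / freq_neg_adj
  fold_raw <- freq_pos / (r$n_neg / table$N_neg)
  pass <- r$n_pos >= min_cells & fold >= min_fold
  out <- data.frame(clonotype_id = r$clonotype_id, n_pos = r$n_pos,
                    freq_pos = freq_pos, freq_neg_adjusted = freq_neg_adj,
                    fold = fold, fold_raw = fold_raw,
                    stringsAsFactors = FALSE)[pass, , drop = FALSE]
  out <- out[order(-out$fold, out$clonotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Share of enriched lineages satisfying a property
#'
#' @param enriched data.frame from [select_enriched()] (non-empty).
#' @param predicate Logical vector parallel to `enriched`, or a function of
#'   the enriched data.frame returning one.
#' @return List `k`, `n`, `fraction`.
#' @export
motif_share <- function(enriched, predicate) {
  if (nrow(enriched) == 0) stop("no enriched lineages")
  p <- if (is.function(predicate)) predicate(enriched) else predicate
  stopifnot(is.logical(p), length(p) == nrow(enriched))
  list(k = sum(p), n = nrow(enriched), fraction = sum(p) / nrow(enriched))
}

#' Simulate tetramer-positive / tetramer-negative sorting of a repertoire
#'
#' Tetramer capture samples clonotypes into the positive fraction with weight
#' `freq * capture_p` for antigen-specific clonotypes and `freq * leak_p`
#' otherwise (renormalised); the negative fraction uses the complementary
#' weights `freq * (1 - capture_p)` / `freq * (1 - leak_p)`.
#'
#' @param freqs Named numeric vector of clonotype frequencies (sums to 1).
#' @param specific Character vector of antigen-specific clonotype ids.
#' @param capture_p,leak_p Capture probabilities for specific and
#'   non-specific clonotypes; `0 <= leak_p < capture_p <= 1`.
#' @param n_pos,n_neg Cells sorted into each fraction.
#' @param seed Integer seed.
#' @return A `clonotype_count_table` with attribute `specific`.
#' @export
simulate_tetramer_fractions <- function(freqs, specific, capture_p = 0.9,
                                        leak_p = 0.01, n_pos = 2000,
                                        n_neg = 2000, seed = 1) {
  if (length(freqs) == 0) stop("empty clonotype frequencies")
  stopifnot(abs(sum(freqs) - 1) < 1e-8, leak_p >= 0, leak_p < capture_p,
            capture_p <= 1)
  is_spec <- names(freqs) %in% specific
  w_pos <- freqs * ifelse(is_spec, capture_p, leak_p)
  w_neg <- freqs * ifelse(is_spec, 1 - capture_p, 1 - leak_p)
  with_seed(seed, {
    pos <- as.integer(rmultinom(1, n_pos, w_pos / sum(w_pos)))
    neg <- as.integer(rmultinom(1, n_neg, w_neg / sum(w_neg)))
  })
  out <- clonotype_count_table(setNames(pos, names(freqs)),
                               setNames(neg, names(freqs)))
  attr(out, "specific") <- specific
  out
}
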