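#' Count CDR3 sequences containing a motif
#'
#' Exact contiguous substring matching; each sequence counts once however
#' many times the motif occurs within it.
#'
#' @param cdr3_list Character vector of CDR3 amino-acid sequences.
#' @param motif Uppercase amino-acid motif (e.g. `"PPG"`).
#' @return A `motif_count` list: `motif`, `n_matching`, `n_total`,
#'   `matching_ids` (indices, or names when `cdr3_list` is named).
#' @export
count_motif <- function(cdr3_list, motif) {
  stopifnot(nchar(motif) > 0, !grepl("[^A-Z*]", motif))
  hit <- grepl(motif, cdr3_list, fixed = TRUE)
  ids <- if (!is.null(names(cdr3_list))) names(cdr3_list)[hit] else which(hit)
  structure(list(motif = motif, n_matching = sum(hit),
                 n_total = length(cdr3_list), matching_ids = ids),
            class = "motif_count")
}

#' @export
print.motif_count <- function(x, ...) {
  cat(sprintf("Motif %s: %d of %d sequences\n", x$motif, x$n_matching,
              x$n_total))
  invisible(x)
}

#' Group clonotypes sharing an identical CDR3 on one chain
#'
#' @param clonotypes A `clonotype_table`.
#' @param chain `"alpha"` or `"beta"`.
#' @return data.frame with one row per group: `cdr3_aa`, `n_clonotypes`,
#'   `clonotype_ids` (comma-joined), sorted by group size descending then
#'   CDR3.
#' @export
group_shared_cdr3 <- function(clonotypes, chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  cdr3 <- if (chain == "alpha") clonotypes$cdr3_alpha_aa
          else clonotypes$cdr3_beta_aa
  ids <- if ("clonotype_id" %in% names(clonotypes)) clonotypes$clonotype_id
         else as.character(seq_len(nrow(clonotypes)))
  grp <- split(ids, cdr3)
  out <- data.frame(cdr3_aa = names(grp), n_clonotypes = lengths(grp),
                    clonotype_ids = vapply(grp, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clonotypes, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene segment usage table
#'
#' Counts gene usage over clonotypes, weighted by clone (`by_clone`) or by
#' member cells (`by_cell`). Gene labels are compared after stripping allele
#' suffixes; family variants such as TRAV10 and TRAV10D remain distinct.
#'
#' @param clonotypes A `clonotype_table`.
#' @param segment_kind One of `"TRAV"`, `"TRAJ"`, `"TRBV"`, `"TRBD"`,
#'   `"TRBJ"`.
#' @param weight `"by_clone"` or `"by_cell"`.
#' @return A `usage_table` list: `segment_kind`, `weight`, `counts`,
#'   `fractions` (both named numeric vectors, descending).
#' @export
gene_usage <- function(clonotypes,
                       segment_kind = c("TRAV", "TRAJ", "TRBV", "TRBD", "TRBJ"),
                       weight = c("by_clone", "by_cell")) {
  segment_kind <- match.arg(segment_kind)
  weight <- match.arg(weight)
  col <- switch(segment_kind, TRAV = "v_alpha", TRAJ = "j_alpha",
                TRBV = "v_beta", TRBD = "d_beta", TRBJ = "j_beta")
  genes <- sub("\\*.*$", "", clonotypes[[col]])
  w <- if (weight == "by_cell") clonotypes$size else rep(1L, nrow(clonotypes))
  counts <- tapply(w, genes, sum)
  counts <- sort(counts, decreasing = TRUE)
  structure(list(segment_kind = segment_kind, weight = weight,
                 counts = counts, fractions = counts / sum(counts)),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("%s usage (%s):\n", x$segment_kind, x$weight))
  print(data.frame(gene = names(x$counts), count = as.integer(x$counts),
                   fraction = round(as.numeric(x$fractions), 4)))
  invisible(x)
}

#' Convergent-recombination index
#'
#' For each amino-acid CDR3, the number of distinct nucleotide rearrangements
#' observed encoding it. Values above 1 indicate convergent recombination.
#'
#' @param cdr3_aa,cdr3_nt Parallel character vectors; every `cdr3_nt` must
#'   translate to its `cdr3_aa`.
#' @return Named integer vector (names = amino-acid CDR3s), descending.
#' @export
convergence_index <- function(cdr3_aa, cdr3_nt) {
  stopifnot(length(cdr3_aa) == length(cdr3_nt))
  tr <- translate_nt(cdr3_nt)
  bad <- which(tr != cdr3_aa)
  if (length(bad))
    stop("record ", bad[1], ": nucleotide CDR3 translates to '", tr[bad[1]],
         "', not '", cdr3_aa[bad[1]], "'")
  out <- vapply(split(cdr3_nt, cdr3_aa), function(x) length(unique(x)), 0L)
  sort(out, decreasing = TRUE)
}
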