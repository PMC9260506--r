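#' Degenerate codon table
#'
#' Full enumeration of a degenerate codon scheme with translations under the
#' standard genetic code. NNK (N = A/C/G/T, K = G/T) yields 32 codons
#' covering all 20 amino acids with a single stop (TAG); NNS (S = C/G) is
#' its complement-third-base twin; NNN is the full 64-codon set.
#'
#' @param codon_scheme `"NNK"`, `"NNS"` or `"NNN"`.
#' @return data.frame with columns `codon`, `aa` (`"*"` for stop).
#' @export
codon_table <- function(codon_scheme = c("NNK", "NNS", "NNN")) {
  codon_scheme <- match.arg(codon_scheme)
  third <- switch(codon_scheme, NNK = c("G", "T"), NNS = c("C", "G"),
                  NNN = c("A", "C", "G", "T"))
  n <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = third, b2 = n, b1 = n, stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$b1, grid$b2, grid$b3))
  data.frame(codon = codons, aa = unname(GENETIC_CODE_DNA[codons]),
             stringsAsFactors = FALSE)
}

#' Design a saturation-mutagenesis peptide library
#'
#' Diversifies the chosen template positions with a degenerate codon (NNK by
#' default, as used for the XSPXFXXL p15E library) and fixes the remaining
#' positions to specific codons. The design yields the template string
#' (template with `X` at diversified positions) and the degenerate oligo.
#'
#' @param template_peptide Template amino-acid sequence (e.g. `"KSPWFTTL"`).
#' @param diversified_positions Integer vector of 1-based positions to
#'   randomize.
#' @param codon_scheme Degenerate codon for diversified positions.
#' @param fixed_codons Named codon per amino acid for fixed positions
#'   (defaults to common mouse codons).
#' @return A `library_design` list: `template_peptide`,
#'   `diversified_positions`, `codon_scheme`, `fixed_codons` (by position),
#'   `template_string`, `oligo`.
#' @export
design_library <- function(template_peptide, diversified_positions = integer(0),
                           codon_scheme = c("NNK", "NNS", "NNN"),
                           fixed_codons = DEFAULT_FIXED_CODONS) {
  codon_scheme <- match.arg(codon_scheme)
  L <- nchar(template_peptide)
  pos <- sort(unique(as.integer(diversified_positions)))
  if (length(pos) && (min(pos) < 1 || max(pos) > L))
    stop("diversified positions must lie within 1..", L)
  res <- strsplit(template_peptide, "")[[1]]
  tmpl <- res
  tmpl[pos] <- "X"
  codons <- character(L)
  for (p in seq_len(L)) {
    codons[p] <- if (p %in% pos) codon_scheme
                 else {
                   if (!res[p] %in% names(fixed_codons))
                     stop("no fixed codon for residue ", res[p])
                   fixed_codons[[res[p]]]
                 }
  }
  structure(list(template_peptide = template_peptide,
                 diversified_positions = pos,
                 codon_scheme = codon_scheme,
                 fixed_codons = setNames(codons[setdiff(seq_len(L), pos)],
                                         setdiff(seq_len(L), pos)),
                 template_string = paste(tmpl, collapse = ""),
                 oligo = paste(codons, collapse = "")),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("Library %s (%s at %s)\noligo: %s\n", x$template_string,
              x$codon_scheme,
              paste(x$diversified_positions, collapse = ","), x$oligo))
  invisible(x)
}

#' Read / write a library design as JSON
#' @param path JSON path.
#' @return `read_library_design` returns a `library_design`.
#' @export
read_library_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_library(x$template_peptide, x$diversified_positions, x$codon_scheme)
}

#' @param design A `library_design` to write.
#' @rdname read_library_design
#' @export
write_library_design <- function(design, path) {
  jsonlite::write_json(design[c("template_peptide", "diversified_positions",
                                "codon_scheme")], path, auto_unbox = TRUE)
  invisible(path)
}

#' Theoretical diversity of a library design
#'
#' @param design A `library_design`.
#' @return List `nt_variants` (|codon set|^k), `stop_free_peptides`
#'   (|amino acids|^k), `stop_containing_fraction`
#'   (1 - ((codons - stops)/codons)^k), for k diversified positions.
#' @export
diversity <- function(design) {
  tab <- codon_table(design$codon_scheme)
  k <- length(design$diversified_positions)
  nc <- nrow(tab)
  nstop <- sum(tab$aa == "*")
  naa <- length(unique(tab$aa[tab$aa != "*"]))
  list(nt_variants = nc^k, stop_free_peptides = naa^k,
       stop_containing_fraction = 1 - ((nc - nstop) / nc)^k)
}

#' Merge overlapping paired-end reads
#'
#' Read 2 is reverse-complemented, then the best suffix(R1)/prefix(R2')
#' overlap of at least `min_overlap` bases with mismatch fraction at most
#' `max_mismatch_frac` is taken (best = most matching bases; an exact tie is
#' `"ambiguous"`, no qualifying overlap is `"no_overlap"`). Disagreeing
#' overlap bases resolve to the higher-quality base, ties to read 1.
#'
#' @param r1,r2 Character vectors of read sequences (`r2` as sequenced).
#' @param q1,q2 Optional Phred+33 quality strings.
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return data.frame with columns `merged` (`NA` on failure), `status`
#'   (`"merged"`, `"no_overlap"`, `"ambiguous"`), `overlap`.
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 10,
                        max_mismatch_frac = 0.25) {
  stopifnot(length(r1) == length(r2))
  r2rc <- revcomp(r2)
  q2rc <- if (is.null(q2)) rep("", length(r2))
          else vapply(strsplit(q2, ""), function(x)
            paste(rev(x), collapse = ""), "")
  if (is.null(q1)) q1 <- rep("", length(r1))
  out <- lapply(seq_along(r1), function(i)
    cpp_merge_pair(r1[i], r2rc[i], q1[i], q2rc[i], min_overlap,
                   max_mismatch_frac))
  data.frame(merged = vapply(out, function(x)
               if (is.na(x$merged)) NA_character_ else x$merged, ""),
             status = vapply(out, `[[`, "", "status"),
             overlap = vapply(out, function(x)
               if (is.na(x$overlap)) NA_integer_ else x$overlap, 0L),
             stringsAsFactors = FALSE)
}

#' Extract the peptide-coding region between two flanking anchors
#'
#' Finds the unique best Hamming match of each anchor (within `max_mm`
#' substitutions) and returns the region strictly between them. When
#' `expected_length` is given, regions of any other length are rejected.
#'
#' @param merged Character vector of merged reads.
#' @param flank_5,flank_3 Nucleotide anchor sequences.
#' @param max_mm Per-anchor mismatch tolerance (default 1).
#' @param expected_length Required insert length (e.g. `3 * nchar(template)`),
#'   or `NULL` to skip the check.
#' @return data.frame with columns `insert` (`NA` on rejection) and `status`
#'   (`"ok"`, `"no_anchor"`, `"length"`).
#' @export
extract_region <- function(merged, flank_5, flank_3, max_mm = 1,
                           expected_length = NULL) {
  stopifnot(nchar(flank_5) > 0, nchar(flank_3) > 0)
  n <- length(merged)
  insert <- rep(NA_character_, n)
  status <- rep("no_anchor", n)
  for (i in seq_len(n)) {
    p5 <- cpp_find_anchor(merged[i], flank_5, max_mm)
    p3 <- cpp_find_anchor(merged[i], flank_3, max_mm)
    if (p5 <= 0 || p3 <= 0) next
    from <- p5 + nchar(flank_5)
    to <- p3 - 1L
    if (to < from) next
    region <- substr(merged[i], from, to)
    if (!is.null(expected_length) && nchar(region) != expected_length) {
      status[i] <- "length"
      next
    }
    insert[i] <- region
    status[i] <- "ok"
  }
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

#' Translate library inserts and filter against the design
#'
#' Accepts an insert iff it is the right length, contains no stop codon, and
#' every non-diversified position translates to the template residue.
#'
#' @param nt Character vector of inserts (`3 * nchar(template)` each).
#' @param design A `library_design`.
#' @return data.frame with columns `peptide` (`NA` on rejection) and `status`
#'   (`"ok"`, `"length"`, `"stop"`, `"template_mismatch"`).
#' @export
translate_filter <- function(nt, design) {
  L <- nchar(design$template_peptide)
  tmpl <- strsplit(design$template_peptide, "")[[1]]
  fixed <- setdiff(seq_len(L), design$diversified_positions)
  pep <- translate_nt(nt)
  status <- rep("ok", length(nt))
  status[nchar(nt) != 3 * L] <- "length"
  has_stop <- status == "ok" & grepl("*", pep, fixed = TRUE)
  status[has_stop] <- "stop"
  if (length(fixed)) {
    check <- status == "ok"
    for (p in fixed) {
      bad <- check & substr(pep, p, p) != tmpl[p]
      status[bad] <- "template_mismatch"
      check <- check & !bad
    }
  }
  pep[status != "ok"] <- NA_character_
  data.frame(peptide = pep, status = status, stringsAsFactors = FALSE)
}

#' Tally accepted peptides into a count table
#'
#' Exact-identity counts; optionally, singleton peptides within one amino-acid
#' substitution of a peptide at least `absorb_ratio` times more abundant are
#' absorbed into it.
#'
#' @param peptides Character vector of accepted peptides (uniform length).
#' @param round_index Selection round the reads came from (0 = preselection).
#' @param tcr_label Label of the selecting TCR campaign.
#' @param absorb_singletons Absorb 1-mismatch singletons (default `FALSE`).
#' @param absorb_ratio Minimum neighbour/singleton count ratio (default 10).
#' @return A `peptide_counts` data.frame (`peptide`, `count`, descending)
#'   with attributes `round_index`, `tcr_label`, `depth`.
#' @export
tally_peptides <- function(peptides, round_index = 0L, tcr_label = "",
                           absorb_singletons = FALSE, absorb_ratio = 10) {
  if (length(peptides) == 0)
    return(peptide_counts(character(0), integer(0), round_index, tcr_label))
  tab <- table(peptides)
  pep <- names(tab)
  cnt <- as.integer(tab)
  if (absorb_singletons && length(pep) > 1 && any(cnt == 1)) {
    d <- cpp_hamming_matrix(pep)
    for (i in which(cnt == 1)) {
      cand <- which(d[i, ] == 1 & cnt >= absorb_ratio)
      if (length(cand)) {
        k <- cand[order(-cnt[cand], pep[cand])][1]
        cnt[k] <- cnt[k] + 1L
        cnt[i] <- 0L
      }
    }
    keep <- cnt > 0
    pep <- pep[keep]; cnt <- cnt[keep]
  }
  ord <- order(-cnt, pep)
  peptide_counts(pep[ord], cnt[ord], round_index, tcr_label)
}

peptide_counts <- function(peptide, count, round_index = 0L, tcr_label = "") {
  out <- data.frame(peptide = peptide, count = as.integer(count),
                    stringsAsFactors = FALSE)
  structure(out, round_index = as.integer(round_index),
            tcr_label = tcr_label, depth = sum(out$count),
            class = c("peptide_counts", "data.frame"))
}

#' Read / write per-round peptide count tables as CSV
#'
#' The CSV holds columns `round`, `peptide`, `count`; reading returns one
#' `peptide_counts` per round, in round order.
#'
#' @param path CSV path.
#' @param tcr_label Campaign label attached on read.
#' @return `read_peptide_counts` returns a list of `peptide_counts`.
#' @export
read_peptide_counts <- function(path, tcr_label = "") {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("round", "peptide", "count") %in% names(x)))
  lapply(sort(unique(x$round)), function(r) {
    xi <- x[x$round == r, ]
    ord <- order(-xi$count, xi$peptide)
    peptide_counts(xi$peptide[ord], xi$count[ord], r, tcr_label)
  })
}

#' @param tables List of `peptide_counts` to write.
#' @rdname read_peptide_counts
#' @export
write_peptide_counts <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(t)
    data.frame(round = attr(t, "round_index"), peptide = t$peptide,
               count = t$count, stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read-count-weighted positional amino-acid preference matrix
#'
#' For each peptide position, the read-count-weighted frequency of every
#' amino acid: `weight(p, a) = sum(count[peptides with a at p]) / depth`.
#' Each position's weights sum to 1. This is the quantity the selection
#' heat maps display.
#'
#' @param table A `peptide_counts`.
#' @param design A `library_design` (fixes the expected peptide length).
#' @return A `preference_matrix`: numeric matrix, rows = positions
#'   (1..L), columns = the 20 amino acids.
#' @export
preference_matrix <- function(table, design) {
  if (nrow(table) == 0) stop("empty peptide count table")
  L <- nchar(design$template_peptide)
  stopifnot(all(nchar(table$peptide) == L))
  depth <- sum(table$count)
  m <- matrix(0, nrow = L, ncol = length(AA_ALPHABET20),
              dimnames = list(position = seq_len(L), aa = AA_ALPHABET20))
  for (p in seq_len(L)) {
    w <- tapply(table$count, substr(table$peptide, p, p), sum)
    m[p, names(w)] <- w / depth
  }
  structure(m, class = c("preference_matrix", "matrix"),
            round_index = attr(table, "round_index"))
}

#' Pooled preference matrix across selection rounds
#'
#' Pools read counts over all rounds before weighting; the per-round variant
#' ([preference_matrix()]) is usually what selection heat maps show, but the
#' pooled form summarises a whole campaign in one matrix.
#'
#' @param tables List of `peptide_counts` tables.
#' @param design A `library_design`.
#' @return A `preference_matrix`.
#' @export
pooled_preference_matrix <- function(tables, design) {
  all_pep <- unlist(lapply(tables, `[[`, "peptide"))
  all_cnt <- unlist(lapply(tables, `[[`, "count"))
  agg <- tapply(all_cnt, all_pep, sum)
  preference_matrix(peptide_counts(names(agg), as.integer(agg), NA_integer_),
                    design)
}

#' Plot a preference matrix as a heat map
#'
#' @param x A `preference_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.preference_matrix <- function(x, ...) {
  m <- unclass(x)
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                  xlab = "peptide position", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(nrow(m)))
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  invisible(x)
}

#' Per-peptide enrichment trajectories across selection rounds
#'
#' Frequencies use a pseudocount over the union of peptides observed in any
#' round: `freq_t(p) = (count_t(p) + pc) / (depth_t + pc * |union|)`;
#' `fold_t = freq_t / freq_{t-1}` and the cumulative fold is
#' `freq_last / freq_first`.
#'
#' @param tables List of `peptide_counts`, one per round, in round order
#'   (>= 2 rounds).
#' @param pseudocount Additive pseudocount (default 1).
#' @return An `enrichment_trajectory`: data.frame with `peptide`, per-round
#'   `freq_<r>` and `fold_<r>` columns, `final_freq`, `cumulative_fold`.
#' @export
enrichment_trajectory <- function(tables, pseudocount = 1) {
  if (length(tables) < 2) stop("need at least 2 selection rounds")
  peps <- sort(unique(unlist(lapply(tables, `[[`, "peptide"))))
  counts <- vapply(tables, function(t) {
    v <- setNames(t$count, t$peptide)[peps]
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(length(peps)))
  if (length(peps) == 1) counts <- matrix(counts, nrow = 1)
  depths <- colSums(counts)
  freqs <- sweep(counts + pseudocount, 2,
                 depths + pseudocount * length(peps), "/")
  folds <- freqs[, -1, drop = FALSE] / freqs[, -ncol(freqs), drop = FALSE]
  rounds <- vapply(tables, function(t) attr(t, "round_index"), 0L)
  out <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  for (j in seq_along(rounds)) out[[paste0("freq_", rounds[j])]] <- freqs[, j]
  for (j in seq_len(ncol(folds))) out[[paste0("fold_", rounds[j + 1])]] <- folds[, j]
  out$final_freq <- freqs[, ncol(freqs)]
  out$cumulative_fold <- freqs[, ncol(freqs)] / freqs[, 1]
  structure(out, rounds = rounds,
            class = c("enrichment_trajectory", "data.frame"))
}

#' Rank mimotope candidates from their enrichment trajectories
#'
#' Sorted by cumulative fold enrichment (descending), ties by final-round
#' frequency (descending), then peptide lexicographically.
#'
#' @param trajectories An `enrichment_trajectory`.
#' @return data.frame of `mimotope_candidate` rows: `rank`, `peptide`,
#'   `final_round_frequency`, `cumulative_fold_enrichment` plus the per-round
#'   frequency columns.
#' @export
rank_mimotopes <- function(trajectories) {
  ord <- order(-trajectories$cumulative_fold, -trajectories$final_freq,
               trajectories$peptide)
  out <- trajectories[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", "peptide", "final_freq", "cumulative_fold",
                 grep("^freq_", names(out), value = TRUE))]
  names(out)[3:4] <- c("final_round_frequency", "cumulative_fold_enrichment")
  out
}
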