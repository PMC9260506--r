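#' Demultiplex merged amplicon reads to wells
#'
#' Each read is assigned to exactly one well or to the unassigned bin.
#' Assignment requires, in every barcode field, a unique best-matching barcode
#' within `scheme$max_mismatch` substitutions; ties at the best distance make
#' the read `"ambiguous"`, distances above the tolerance make it
#' `"no_match"`, and reads shorter than the barcode prefix are
#' `"too_short"`.
#'
#' @param reads Character vector of merged reads (barcode prefix first).
#' @param scheme A [barcode_scheme()].
#' @return A `demux_result`: data.frame `assignments` with one row per read
#'   (columns `group`, `plate`, `row`, `column`, `well_id`, `assigned`,
#'   `reason`, `insert` = read with the barcode prefix stripped).
#' @export
demultiplex <- function(reads, scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  n <- length(reads)
  width <- scheme_prefix_width(scheme)
  too_short <- nchar(reads) < width
  labels <- list()
  reason <- rep(NA_character_, n)
  reason[too_short] <- "too_short"
  offset <- 0L
  for (f in scheme$layout) {
    bcs <- scheme$fields[[f]]
    w <- nchar(bcs[1])
    sub <- substr(reads, offset + 1L, offset + w)
    d <- vapply(bcs, function(b) cpp_hamming(sub, rep(b, n)), integer(n))
    if (n == 1) d <- matrix(d, nrow = 1)
    best <- apply(d, 1, min)
    n_best <- rowSums(d == best)
    pick <- max.col(-d, ties.method = "first")
    lab <- names(bcs)[pick]
    ok <- best <= scheme$max_mismatch & n_best == 1 & !too_short
    lab[!ok] <- NA_character_
    miss <- is.na(reason) & !ok
    reason[miss & n_best > 1 & best <= scheme$max_mismatch] <- "ambiguous"
    reason[miss & is.na(reason) & best > scheme$max_mismatch] <- "no_match"
    labels[[f]] <- lab
    offset <- offset + w
  }
  a <- data.frame(labels[c("group", "plate", "row", "column")],
                  stringsAsFactors = FALSE)
  a$assigned <- stats::complete.cases(a)
  a$reason <- ifelse(a$assigned, NA_character_, reason)
  a$well_id <- ifelse(a$assigned,
                      paste(a$group, a$plate, a$row, a$column, sep = "|"),
                      NA_character_)
  a$insert <- substr(reads, width + 1L, nchar(reads))
  a$insert[!a$assigned] <- NA_character_
  structure(list(assignments = a, scheme = scheme), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("Demultiplexed %d reads: %d assigned to %d wells, %d unassigned\n",
              nrow(a), sum(a$assigned), length(unique(stats::na.omit(a$well_id))),
              sum(!a$assigned)))
  if (any(!a$assigned))
    print(table(reason = a$reason[!a$assigned]))
  invisible(x)
}

#' Segregate reads into alpha and beta chains by constant-region alignment
#'
#' Locally aligns the TRAC and TRBC reference subsequences against each read
#' (match +1, mismatch -1, gap -2). A read is called for the chain whose
#' constant-region score both exceeds `min_frac * nchar(ref)` and exceeds the
#' other chain's score by at least `margin`; otherwise `"unknown"`.
#'
#' @param reads Character vector of reads (barcodes stripped).
#' @param constant_refs Named character vector `c(TRAC = ..., TRBC = ...)`,
#'   or a `germline_reference` from which the constant regions are taken.
#' @param min_frac Minimum score as a fraction of the reference length.
#' @param margin Required score margin between the two chains.
#' @return Character vector in `c("alpha", "beta", "unknown")`.
#' @export
assign_chain <- function(reads, constant_refs, min_frac = 0.6, margin = 5) {
  if (inherits(constant_refs, "germline_reference")) {
    cc <- constant_refs[constant_refs$kind == "C", ]
    constant_refs <- setNames(cc$nt, ifelse(cc$locus == "TRA", "TRAC", "TRBC"))
  }
  stopifnot(all(c("TRAC", "TRBC") %in% names(constant_refs)))
  score <- function(ref) local_align_scores(ref, reads)
  sa <- score(constant_refs[["TRAC"]])
  sb <- score(constant_refs[["TRBC"]])
  ta <- min_frac * nchar(constant_refs[["TRAC"]])
  tb <- min_frac * nchar(constant_refs[["TRBC"]])
  out <- rep("unknown", length(reads))
  out[sa >= ta & sa - sb >= margin] <- "alpha"
  out[sb >= tb & sb - sa >= margin] <- "beta"
  out
}

# Local alignment scores of one pattern against many subjects
# (match +1 / mismatch -1 / gap -2 per gapped position).
local_align_scores <- function(pattern, subjects) {
  ok <- !is.na(subjects) & nchar(subjects) > 0
  out <- rep(-Inf, length(subjects))
  if (!any(ok)) return(out)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  out[ok] <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rep(pattern, sum(ok))),
    subject = Biostrings::DNAStringSet(subjects[ok]),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
  out
}

#' Collapse reads of one well and chain into consensus sequences
#'
#' Unique sequences are tallied; a sequence is absorbed into a higher-count
#' sequence when it lies within `max_mm` substitutions and the higher count is
#' at least `ratio_threshold` times its own. Absorption proceeds from the
#' rarest sequence upward against current (post-absorption) counts; the
#' absorber is the highest-count qualifying neighbour, ties broken
#' lexicographically. Length-discordant sequences are collapsed within their
#' own length class. Survivors are returned sorted by support (descending),
#' ties lexicographic.
#'
#' @param reads Character vector of reads.
#' @param ratio_threshold Minimum count ratio (absorber / absorbed).
#' @param max_mm Maximum substitutions for absorption.
#' @return data.frame with columns `consensus`, `support`.
#' @export
collapse_reads <- function(reads, ratio_threshold = 5, max_mm = 2) {
  if (length(reads) == 0)
    return(data.frame(consensus = character(0), support = integer(0)))
  tab <- table(reads)
  seqs <- names(tab)
  counts <- as.integer(tab)
  out_seq <- character(0); out_cnt <- integer(0)
  for (len in unique(nchar(seqs))) {
    in_class <- nchar(seqs) == len
    s <- seqs[in_class]; cnt <- counts[in_class]
    if (length(s) > 1) {
      d <- cpp_hamming_matrix(s)
      # visit rarest first (ties lexicographic) against live counts
      ord <- order(cnt, s)
      alive <- rep(TRUE, length(s))
      for (i in ord) {
        cand <- which(alive & d[i, ] >= 0 & d[i, ] <= max_mm &
                        cnt >= ratio_threshold * cnt[i])
        cand <- setdiff(cand, i)
        if (length(cand)) {
          k <- cand[order(-cnt[cand], s[cand])][1]
          cnt[k] <- cnt[k] + cnt[i]
          cnt[i] <- 0L
          alive[i] <- FALSE
        }
      }
      s <- s[alive]; cnt <- cnt[alive]
    }
    out_seq <- c(out_seq, s); out_cnt <- c(out_cnt, cnt)
  }
  ord <- order(-out_cnt, out_seq)
  data.frame(consensus = out_seq[ord], support = out_cnt[ord],
             stringsAsFactors = FALSE)
}

#' Annotate a rearranged chain sequence with V/J (and D) calls and CDR3
#'
#' Best-scoring local alignment of every germline segment of the right locus
#' against the read (match +1, mismatch -1, gap -2); ties are broken by
#' segment name, lexicographically. The CDR3 is then extracted from the
#' conserved cysteine codon (mapped through the V alignment) through the J
#' anchor codon (mapped through the J alignment), inclusive, and translated
#' in the V reading frame.
#'
#' @param nt Rearranged chain nucleotide sequence (one string).
#' @param ref A `germline_reference`.
#' @param chain `"alpha"` or `"beta"`.
#' @param min_score_v,min_score_j,min_score_d Minimum local alignment scores;
#'   below these the read is unannotatable (V/J) or the D call is dropped.
#' @return A `chain_annotation` list: `chain`, `v_call`, `j_call`, `d_call`,
#'   `v_score`, `j_score`, `cdr3_nt`, `cdr3_aa`, `productive`, and 1-based
#'   `cdr3_start`/`cdr3_end` read coordinates.
#' @export
annotate_vj <- function(nt, ref, chain = c("alpha", "beta"),
                        min_score_v = 20, min_score_j = 12,
                        min_score_d = 8) {
  chain <- match.arg(chain)
  locus <- if (chain == "alpha") "TRA" else "TRB"
  vs <- ref[ref$locus == locus & ref$kind == "V", ]
  js <- ref[ref$locus == locus & ref$kind == "J", ]
  if (nrow(vs) == 0 || nrow(js) == 0)
    stop("reference lacks V or J segments for locus ", locus)

  best_v <- best_segment(vs, nt)
  best_j <- best_segment(js, nt)
  if (best_v$score < min_score_v || best_j$score < min_score_j) {
    cond <- structure(
      class = c("mimoseq_unannotatable", "error", "condition"),
      list(message = sprintf(
        "unannotatable %s read (best V %s score %.0f, best J %s score %.0f)",
        chain, best_v$name, best_v$score, best_j$name, best_j$score),
        call = sys.call(-1)))
    stop(cond)
  }

  d_call <- NA_character_
  if (chain == "beta") {
    ds <- ref[ref$locus == locus & ref$kind == "D", ]
    if (nrow(ds) > 0) {
      best_d <- best_segment(ds, nt)
      if (best_d$score >= min_score_d) d_call <- best_d$name
    }
  }

  seg_v <- germline_segment(ref, best_v$name)
  seg_j <- germline_segment(ref, best_j$name)
  cdr3 <- extract_cdr3(nt, best_v$aln, best_j$aln,
                       seg_v$conserved_cys_offset, seg_j$j_anchor_offset)
  structure(list(chain = chain, v_call = best_v$name, j_call = best_j$name,
                 d_call = d_call, v_score = best_v$score,
                 j_score = best_j$score, cdr3_nt = cdr3$cdr3_nt,
                 cdr3_aa = cdr3$cdr3_aa, productive = cdr3$productive,
                 cdr3_start = cdr3$start, cdr3_end = cdr3$end),
            class = "chain_annotation")
}

#' @export
print.chain_annotation <- function(x, ...) {
  cat(sprintf("%s chain: %s / %s%s | CDR3 %s (%s)%s\n", x$chain, x$v_call,
              x$j_call, if (!is.na(x$d_call)) paste0(" / ", x$d_call) else "",
              x$cdr3_aa, x$cdr3_nt,
              if (x$productive) "" else " [non-productive]"))
  invisible(x)
}

# Best-scoring segment of a set against a read; ties by score broken
# lexicographically by name. Returns name, score and the alignment.
best_segment <- function(segs, nt) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  alns <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(segs$nt),
    subject = Biostrings::DNAString(nt),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  scores <- Biostrings::score(alns)
  ord <- order(-scores, segs$name)
  i <- ord[1]
  list(name = segs$name[i], score = scores[i], aln = alns[i])
}

# Map a 1-based pattern position to the subject coordinate through a local
# pairwise alignment; NA when the position is outside the aligned range or
# falls in a subject gap.
map_pattern_to_subject <- function(aln, ppos) {
  p0 <- BiocGenerics::start(Biostrings::pattern(aln))
  p1 <- BiocGenerics::end(Biostrings::pattern(aln))
  s0 <- BiocGenerics::start(Biostrings::subject(aln))
  if (ppos < p0 || ppos > p1) return(NA_integer_)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- p0 - 1L; si <- s0 - 1L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") pi <- pi + 1L
    if (sa[k] != "-") si <- si + 1L
    if (pi == ppos && pa[k] != "-") {
      if (sa[k] == "-") return(NA_integer_)
      return(si)
    }
  }
  NA_integer_
}

#' Extract the CDR3 from aligned V and J segments
#'
#' The CDR3 spans the conserved V cysteine codon (included) through the J
#' anchor codon (included), translated in the V reading frame. Coordinates
#' are 0-based half-open internally and reported 1-based inclusive. A frame
#' break, internal stop or unmappable anchor clears the `productive` flag;
#' the amino-acid sequence is still reported when translatable.
#'
#' @param nt Read sequence.
#' @param v_aln,j_aln `PairwiseAlignments` of the V and J germline segments
#'   against `nt` (as produced inside [annotate_vj()]).
#' @param cys_offset 1-based start of the conserved cysteine codon in the V
#'   germline sequence.
#' @param anchor_offset 1-based start of the anchor codon in the J germline
#'   sequence.
#' @return List with `cdr3_nt`, `cdr3_aa`, `productive`, `start`, `end`
#'   (1-based inclusive read coordinates).
#' @export
extract_cdr3 <- function(nt, v_aln, j_aln, cys_offset, anchor_offset) {
  cys_start <- map_pattern_to_subject(v_aln, cys_offset)
  if (is.na(cys_start)) {
    # fall back to the germline codon upstream of the cysteine
    up <- map_pattern_to_subject(v_aln, cys_offset - 3L)
    if (!is.na(up)) cys_start <- up + 3L
  }
  # The anchor codon is junction-proximal and may be absorbed into the
  # junction by alignment wobble (e.g. ...FF junctions); the G-x-G block
  # right after it is germline-stable, so locate the anchor through it.
  gxg <- map_pattern_to_subject(j_aln, anchor_offset + 3L)
  anchor_start <- if (!is.na(gxg) && gxg > 3L) gxg - 3L
                  else map_pattern_to_subject(j_aln, anchor_offset)
  if (is.na(cys_start))
    stop("V alignment does not cover the conserved cysteine codon")
  if (is.na(anchor_start))
    stop("J alignment does not cover the anchor codon")
  end <- min(anchor_start + 2L, nchar(nt))
  cdr3_nt <- substr(nt, cys_start, end)
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- translate_nt(substr(cdr3_nt, 1L,
                                 3L * (nchar(cdr3_nt) %/% 3L)))
  productive <- in_frame && !grepl("*", cdr3_aa, fixed = TRUE) &&
    nchar(cdr3_aa) > 0 && substr(cdr3_aa, 1, 1) == "C"
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive,
       start = cys_start, end = end)
}

#' Resolve the chain content of one well into a cell record
#'
#' Exactly one alpha and one beta consensus give status `"paired"`; a missing
#' chain gives `"alpha_only"`/`"beta_only"` (or `"empty"`); when a chain has
#' several consensuses the dominant one is retained if its support is at
#' least `dominance_threshold` times the runner-up's, otherwise the well is a
#' `"multiplet"`.
#'
#' @param alpha,beta data.frames from [collapse_reads()] (columns
#'   `consensus`, `support`), one per chain.
#' @param dominance_threshold Support ratio required to rescue a multi-
#'   consensus chain.
#' @return List with `status` and the chosen `alpha`/`beta` consensus rows
#'   (or `NULL`).
#' @export
pair_well <- function(alpha, beta, dominance_threshold = 5) {
  pick <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(list(seq = NULL, multi = FALSE))
    if (nrow(tab) == 1) return(list(seq = tab[1, ], multi = FALSE))
    ord <- order(-tab$support, tab$consensus)
    top <- tab[ord[1], ]; second <- tab[ord[2], ]
    if (top$support >= dominance_threshold * second$support)
      list(seq = top, multi = FALSE)
    else list(seq = NULL, multi = TRUE)
  }
  a <- pick(alpha); b <- pick(beta)
  status <- if (a$multi || b$multi) "multiplet"
  else if (!is.null(a$seq) && !is.null(b$seq)) "paired"
  else if (!is.null(a$seq)) "alpha_only"
  else if (!is.null(b$seq)) "beta_only"
  else "empty"
  list(status = status, alpha = a$seq, beta = b$seq)
}

#' Group paired cells into clonal lineages
#'
#' Cells with identical paired CDR3 sequences and V/J usage are members of
#' one clonal lineage. Grouping is on amino-acid CDR3s by default
#' (`level = "aa"`), or on nucleotide CDR3s (`level = "nt"`); gene names are
#' compared after stripping allele suffixes (`*01` etc.). Output is sorted by
#' clone size (descending), ties by key, and carries the nucleotide CDR3s of
#' the first member cell for contamination screening.
#'
#' @param cells data.frame with one row per cell: columns `well_id`,
#'   `sample`, `status`, `alpha_cdr3_aa`, `alpha_cdr3_nt`, `alpha_v`,
#'   `alpha_j`, `beta_cdr3_aa`, `beta_cdr3_nt`, `beta_v`, `beta_j` and
#'   optionally `beta_d`. Only rows with `status == "paired"` are used.
#' @param level Clone definition level, `"aa"` or `"nt"`.
#' @return data.frame of class `clonotype_table`: `clonotype_id`,
#'   `cdr3_alpha_aa`, `cdr3_beta_aa`, `v_alpha`, `j_alpha`, `v_beta`,
#'   `j_beta`, `d_beta`, `size`, `sample`, `cdr3_alpha_nt`, `cdr3_beta_nt`,
#'   `member_wells` (comma-joined).
#' @export
call_clonotypes <- function(cells, level = c("aa", "nt")) {
  level <- match.arg(level)
  cells <- cells[cells$status == "paired", , drop = FALSE]
  if (nrow(cells) == 0)
    return(structure(data.frame(), class = c("clonotype_table", "data.frame")))
  strip <- function(g) sub("\\*.*$", "", g)
  cdr3a <- if (level == "aa") cells$alpha_cdr3_aa else cells$alpha_cdr3_nt
  cdr3b <- if (level == "aa") cells$beta_cdr3_aa else cells$beta_cdr3_nt
  key <- paste(cdr3a, strip(cells$alpha_v), strip(cells$alpha_j),
               cdr3b, strip(cells$beta_v), strip(cells$beta_j), sep = "|")
  first <- !duplicated(key)
  sizes <- as.integer(table(key)[key[first]])
  out <- data.frame(
    key = key[first],
    cdr3_alpha_aa = cells$alpha_cdr3_aa[first],
    cdr3_beta_aa = cells$beta_cdr3_aa[first],
    v_alpha = strip(cells$alpha_v[first]), j_alpha = strip(cells$alpha_j[first]),
    v_beta = strip(cells$beta_v[first]), j_beta = strip(cells$beta_j[first]),
    d_beta = if ("beta_d" %in% names(cells)) cells$beta_d[first]
             else NA_character_,
    size = sizes,
    sample = vapply(split(cells$sample, key), function(s)
      paste(sort(unique(s)), collapse = ","), character(1))[key[first]],
    cdr3_alpha_nt = cells$alpha_cdr3_nt[first],
    cdr3_beta_nt = cells$beta_cdr3_nt[first],
    member_wells = vapply(split(as.character(cells$well_id), key),
                          function(w) paste(sort(w), collapse = ","),
                          character(1))[key[first]],
    stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$key), , drop = FALSE]
  out$clonotype_id <- sprintf("CT%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out$key <- NULL
  out <- out[, c("clonotype_id", setdiff(names(out), "clonotype_id"))]
  structure(out, class = c("clonotype_table", "data.frame"))
}

#' Flag clonotypes matching known contaminant sequences
#'
#' A clonotype is flagged when either chain's nucleotide CDR3 exactly matches
#' a blacklist sequence (e.g. from earlier sequencing runs) or a sequence
#' observed in intentionally empty wells. Matching is exact; near-matches are
#' not flagged.
#'
#' @param clonotypes A `clonotype_table`.
#' @param blacklist_nt,empty_well_seqs Character vectors of nucleotide
#'   sequences.
#' @return Logical vector, one flag per clonotype.
#' @export
flag_contaminants <- function(clonotypes, blacklist_nt = character(0),
                              empty_well_seqs = character(0)) {
  bad <- unique(c(blacklist_nt, empty_well_seqs))
  clonotypes$cdr3_alpha_nt %in% bad | clonotypes$cdr3_beta_nt %in% bad
}

#' Clonality summary of a repertoire
#'
#' @param clonotypes A `clonotype_table` (or data.frame with a `size`
#'   column).
#' @param k Number of top clones for the cumulative fraction.
#' @return A `clonality_summary`: `total_cells`, data.frame `fractions`
#'   (clone sizes and per-clone fraction of cells, descending), and
#'   `top_k_cumulative`.
#' @export
clonality <- function(clonotypes, k = 3) {
  stopifnot(k >= 1)
  if (nrow(clonotypes) == 0) stop("no clonotypes: clonality is undefined")
  sizes <- sort(clonotypes$size, decreasing = TRUE)
  total <- sum(sizes)
  frac <- sizes / total
  structure(list(
    total_cells = total,
    fractions = data.frame(rank = seq_along(sizes), size = sizes,
                           fraction = frac),
    k = as.integer(k),
    top_k_cumulative = sum(frac[seq_len(min(k, length(frac)))])),
    class = "clonality_summary")
}

#' @export
print.clonality_summary <- function(x, ...) {
  cat(sprintf("%d cells in %d clonotypes; top-%d clones hold %.1f%% of cells\n",
              x$total_cells, nrow(x$fractions), x$k,
              100 * x$top_k_cumulative))
  invisible(x)
}
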