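#' Planted truth for a single-cell TCR plate
#'
#' Lays out one sorted cell per well and records the exact alpha and beta
#' amplicon each well should yield, so downstream demultiplexing, pairing and
#' clonotype calling can be scored against the plant. By default the plate is
#' seeded with the published p15E-reactive clone table (`aip_clone_table()`),
#' each clone occupying clone-size many wells; alternatively a number of
#' random clonotypes is planted with geometric-ish expansion.
#'
#' @param ref A `germline_reference`.
#' @param scheme A `barcode_scheme` providing well coordinates.
#' @param clones Optional data.frame like [aip_clone_table()] (columns
#'   `clone_name`, `clone_size`, `mouse`, `cdr3a`, `trav`, `traj`, `cdr3b`,
#'   `trbv`, `trbj`). When `NULL`, `n_clonotypes` random clonotypes are drawn.
#' @param n_clonotypes Number of random clonotypes when `clones` is `NULL`.
#' @param n_wells Number of wells to fill (default all 96; the clone table is
#'   truncated or recycled-by-expansion to fit).
#' @param error_rate Per-base substitution probability carried into
#'   [simulate_tcr_plate()].
#' @param indel_rate Per-base indel probability (default 0; nested-PCR
#'   amplicons are substitution-dominated and indel-bearing reads are
#'   expected to fall out as filter rejects).
#' @param depth Reads per chain per well.
#' @param seed Integer seed.
#' @return A `plate_truth` object: data.frame `wells` (group, plate, row,
#'   column, clonotype_id, alpha_nt, beta_nt, alpha/beta CDR3 and gene
#'   metadata) plus `error_rate`, `depth`, `seed`.
#' @export
plate_truth <- function(ref, scheme = default_barcode_scheme(), clones = NULL,
                        n_clonotypes = 10, n_wells = 96,
                        error_rate = 0.01, indel_rate = 0, depth = 50,
                        seed = 1) {
  stopifnot(error_rate >= 0, error_rate < 0.25, indel_rate >= 0,
            indel_rate < 0.25, depth >= 1)
  with_seed(seed, {
    if (is.null(clones)) clones <- random_clone_table(ref, n_clonotypes)
    # expand clones into one row per cell, truncated to the plate
    idx <- rep(seq_len(nrow(clones)), clones$clone_size)
    if (length(idx) > n_wells) idx <- idx[seq_len(n_wells)]
    cells <- clones[idx, , drop = FALSE]

    rows <- names(scheme$fields$row)
    cols <- names(scheme$fields$column)
    coords <- expand.grid(row = rows, column = cols,
                          stringsAsFactors = FALSE)
    if (nrow(coords) < length(idx))
      stop("scheme provides fewer wells than cells planted")
    coords <- coords[seq_along(idx), , drop = FALSE]

    wells <- data.frame(
      group = names(scheme$fields$group)[1],
      plate = names(scheme$fields$plate)[1],
      row = coords$row, column = coords$column,
      clonotype_id = cells$clone_name,
      sample = cells$mouse,
      cdr3a = cells$cdr3a, va = paste0("TRAV", cells$trav), ja = "TRAJ7",
      cdr3b = cells$cdr3b, vb = paste0("TRBV", cells$trbv),
      jb = paste0("TRBJ", cells$trbj),
      stringsAsFactors = FALSE)
    # clone tables may already carry full gene names
    wells$va <- sub("^TRAVTRAV", "TRAV", wells$va)
    wells$vb <- sub("^TRBVTRBV", "TRBV", wells$vb)
    wells$jb <- sub("^TRBJTRBJ", "TRBJ", wells$jb)
    if ("traj" %in% names(cells))
      wells$ja <- sub("^TRAJTRAJ", "TRAJ", paste0("TRAJ", cells$traj))

    amp <- function(cdr3, v, j) mapply(build_chain_amplicon, cdr3, v, j,
                                       MoreArgs = list(ref = ref),
                                       USE.NAMES = FALSE)
    # one nucleotide rearrangement per clonotype (clonal progeny share it)
    ua <- !duplicated(wells$clonotype_id)
    key <- match(wells$clonotype_id, wells$clonotype_id[ua])
    wells$alpha_nt <- amp(wells$cdr3a[ua], wells$va[ua], wells$ja[ua])[key]
    wells$beta_nt <- amp(wells$cdr3b[ua], wells$vb[ua], wells$jb[ua])[key]

    structure(list(wells = wells, scheme = scheme, ref = ref,
                   error_rate = error_rate, indel_rate = indel_rate,
                   depth = as.integer(depth), seed = seed),
              class = "plate_truth")
  })
}

random_clone_table <- function(ref, n_clonotypes) {
  travs <- ref$name[ref$locus == "TRA" & ref$kind == "V"]
  trbvs <- ref$name[ref$locus == "TRB" & ref$kind == "V"]
  trajs <- ref$name[ref$locus == "TRA" & ref$kind == "J"]
  trbjs <- ref$name[ref$locus == "TRB" & ref$kind == "J"]
  anchor_of <- function(j) {
    s <- germline_segment(ref, j)
    translate_nt(substr(s$nt, s$j_anchor_offset, s$j_anchor_offset + 2L))
  }
  mk <- function(i) {
    va <- sample(travs, 1); ja <- sample(trajs, 1)
    vb <- sample(trbvs, 1); jb <- sample(trbjs, 1)
    cdr3a <- paste0("CA", paste(sample(AA_ALPHABET20, sample(5:8, 1),
                                       replace = TRUE), collapse = ""),
                    anchor_of(ja))
    cdr3b <- paste0("CASS", paste(sample(AA_ALPHABET20, sample(4:7, 1),
                                         replace = TRUE), collapse = ""),
                    anchor_of(jb))
    data.frame(clone_name = sprintf("SYN%02d", i), clone_size = 0L,
               mouse = "sim", cdr3a = cdr3a, trav = va, traj = ja,
               cdr3b = cdr3b, trbv = vb, trbj = jb, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_clonotypes), mk))
  # geometric-flavoured clone sizes: a few expanded clones, many singletons
  out$clone_size <- sort(pmax(1L, stats::rgeom(n_clonotypes, prob = 0.15)),
                         decreasing = TRUE)
  # names already carry the full locus prefix; strip the re-prefix later
  out$trav <- sub("^TRAV", "", out$trav)
  out$traj <- sub("^TRAJ", "", out$traj)
  out$trbv <- sub("^TRBV", "", out$trbv)
  out$trbj <- sub("^TRBJ", "", out$trbj)
  out
}

#' Simulate barcoded paired-end reads from a planted plate
#'
#' Each well emits `depth` read pairs per chain. The full-length amplicon is
#' the four barcode fields (per the scheme layout) followed by the chain
#' rearrangement and constant region; i.i.d. per-base substitution noise at
#' `error_rate` is applied, then read 1 takes the first `read_len` bases and
#' read 2 the reverse complement of the last `read_len` bases (reads overlap
#' whenever the amplicon is shorter than `2 * read_len`). Qualities are
#' constant Q30. Deterministic for a fixed truth seed.
#'
#' @param truth A `plate_truth`.
#' @param scheme A `barcode_scheme`; defaults to the scheme in `truth`.
#' @param read_len Read length (default 150).
#' @return A `plate_reads` object: data.frame `reads` with columns `id`,
#'   `r1`, `r2`, `q1`, `q2` and hidden provenance columns `.well`, `.chain`
#'   used only for scoring, plus the `truth`.
#' @export
simulate_tcr_plate <- function(truth, scheme = truth$scheme, read_len = 150) {
  stopifnot(inherits(truth, "plate_truth"))
  with_seed(truth$seed + 7L, {
    w <- truth$wells
    prefixes <- vapply(seq_len(nrow(w)), function(i)
      well_prefix(scheme, w[i, c("group", "plate", "column", "row")]),
      character(1))
    amps <- c(paste0(prefixes, w$alpha_nt), paste0(prefixes, w$beta_nt))
    chains <- rep(c("alpha", "beta"), each = nrow(w))
    wells_ix <- rep(seq_len(nrow(w)), 2)

    n_reads <- truth$depth
    amp_rep <- rep(amps, each = n_reads)
    noisy <- add_substitutions(amp_rep, truth$error_rate)
    if (!is.null(truth$indel_rate) && truth$indel_rate > 0)
      noisy <- add_indels(noisy, truth$indel_rate)
    len <- nchar(noisy)
    r1 <- substr(noisy, 1L, pmin(read_len, len))
    r2 <- revcomp(substr(noisy, pmax(1L, len - read_len + 1L), len))
    q30 <- function(s) strrep("?", nchar(s))
    reads <- data.frame(
      id = sprintf("read%06d", seq_along(noisy)),
      r1 = r1, r2 = r2, q1 = q30(r1), q2 = q30(r2),
      .well = rep(wells_ix, each = n_reads),
      .chain = rep(chains, each = n_reads),
      stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, read_len = read_len),
              class = "plate_reads")
  })
}

# i.i.d. indels at rate p: at each affected position a coin decides between
# deleting the base and inserting a random base before it.
add_indels <- function(seqs, p) {
  n_mut <- rbinom(length(seqs), nchar(seqs), p)
  todo <- which(n_mut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sort(sample.int(length(s), n_mut[i]), decreasing = TRUE)
    for (j in pos) {
      if (runif(1) < 0.5) s <- s[-j]
      else s <- append(s, sample(bases, 1), after = j - 1)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# i.i.d. substitutions at rate p; substituted bases move to a different base.
add_substitutions <- function(seqs, p) {
  if (p == 0) return(seqs)
  n_mut <- rbinom(length(seqs), nchar(seqs), p)
  todo <- which(n_mut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(s), n_mut[i])
    for (j in pos) s[j] <- sample(setdiff(bases, s[j]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write simulated plate reads as paired FASTQ files
#'
#' @param plate A `plate_reads` object.
#' @param r1_path,r2_path Output FASTQ paths (uncompressed).
#' @return Invisibly, the two paths.
#' @export
write_plate_fastq <- function(plate, r1_path, r2_path) {
  write_fastq(plate$reads$id, plate$reads$r1, plate$reads$q1, r1_path)
  write_fastq(plate$reads$id, plate$reads$r2, plate$reads$q2, r2_path)
  invisible(c(r1_path, r2_path))
}

write_fastq <- function(id, seq, qual, path) {
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub(" .*", "", names(x)), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
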