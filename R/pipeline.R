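#' Process demultiplexed plate reads into per-well cell records
#'
#' Runs the single-cell amplicon pipeline over merged reads: demultiplexing
#' to wells, constant-region chain segregation, per-well/per-chain read
#' collapse, dominant-consensus pairing, and V/J + CDR3 annotation of the
#' paired consensuses.
#'
#' @param merged Character vector of merged reads (barcode prefixes intact).
#' @param scheme A [barcode_scheme()].
#' @param ref A `germline_reference`.
#' @param sample Sample label stamped on every cell.
#' @param ratio_threshold,max_mm Collapse parameters ([collapse_reads()]).
#' @param dominance_threshold Multiplet-rescue ratio ([pair_well()]).
#' @param min_score_v,min_score_j Annotation score floors ([annotate_vj()]).
#' @return List: `cells` (one row per occupied well; the
#'   [call_clonotypes()] input format plus support columns), `demux`
#'   (the `demux_result`), `chain_calls` (per-read chain labels).
#' @export
process_plate_reads <- function(merged, scheme, ref, sample = "sample1",
                                ratio_threshold = 5, max_mm = 2,
                                dominance_threshold = 5,
                                min_score_v = 20, min_score_j = 12) {
  dm <- demultiplex(merged, scheme)
  a <- dm$assignments
  ok <- a$assigned
  chain <- rep(NA_character_, nrow(a))
  chain[ok] <- assign_chain(a$insert[ok], ref)

  wells <- unique(a$well_id[ok])
  ann_cache <- new.env(parent = emptyenv())
  annotate_cached <- function(nt, ch) {
    key <- paste0(ch, ":", nt)
    if (!is.null(ann_cache[[key]])) return(ann_cache[[key]])
    val <- tryCatch(annotate_vj(nt, ref, ch, min_score_v = min_score_v,
                                min_score_j = min_score_j),
                    mimoseq_unannotatable = function(e) NULL)
    ann_cache[[key]] <- if (is.null(val)) list(NULL) else val
    ann_cache[[key]]
  }

  rows <- lapply(wells, function(w) {
    in_well <- ok & a$well_id == w
    cons <- lapply(c(alpha = "alpha", beta = "beta"), function(ch)
      collapse_reads(a$insert[in_well & chain == ch],
                     ratio_threshold = ratio_threshold, max_mm = max_mm))
    pw <- pair_well(cons$alpha, cons$beta,
                    dominance_threshold = dominance_threshold)
    out <- data.frame(
      well_id = w, sample = sample, status = pw$status,
      alpha_cdr3_aa = NA_character_, alpha_cdr3_nt = NA_character_,
      alpha_v = NA_character_, alpha_j = NA_character_,
      alpha_productive = NA, alpha_support = NA_integer_,
      beta_cdr3_aa = NA_character_, beta_cdr3_nt = NA_character_,
      beta_v = NA_character_, beta_j = NA_character_,
      beta_d = NA_character_, beta_productive = NA,
      beta_support = NA_integer_, stringsAsFactors = FALSE)
    fill <- function(out, chosen, ch) {
      if (is.null(chosen)) return(out)
      ann <- annotate_cached(chosen$consensus, ch)
      if (is.null(ann[[1]]) && !inherits(ann, "chain_annotation")) {
        # unannotatable consensus: treat the chain as absent
        out$status <- if (out$status == "paired")
          if (ch == "alpha") "beta_only" else "alpha_only"
        else "empty"
        return(out)
      }
      p <- if (ch == "alpha") "alpha" else "beta"
      out[[paste0(p, "_cdr3_aa")]] <- ann$cdr3_aa
      out[[paste0(p, "_cdr3_nt")]] <- ann$cdr3_nt
      out[[paste0(p, "_v")]] <- ann$v_call
      out[[paste0(p, "_j")]] <- ann$j_call
      out[[paste0(p, "_productive")]] <- ann$productive
      out[[paste0(p, "_support")]] <- chosen$support
      if (ch == "beta") out$beta_d <- ann$d_call
      out
    }
    out <- fill(out, pw$alpha, "alpha")
    out <- fill(out, pw$beta, "beta")
    out
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, demux = dm, chain_calls = chain)
}

#' Write cell records as an AIRR-style rearrangement TSV
#'
#' One row per annotated chain with the standard columns `cell_id`, `locus`,
#' `v_call`, `d_call`, `j_call`, `junction`, `junction_aa`, `productive`,
#' `consensus_count`.
#'
#' @param cells The `cells` data.frame from [process_plate_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_airr_tsv <- function(cells, path) {
  one <- function(p, locus) {
    has <- !is.na(cells[[paste0(p, "_cdr3_nt")]])
    data.frame(cell_id = cells$well_id[has], locus = locus,
               v_call = cells[[paste0(p, "_v")]][has],
               d_call = if (p == "beta") cells$beta_d[has] else NA_character_,
               j_call = cells[[paste0(p, "_j")]][has],
               junction = cells[[paste0(p, "_cdr3_nt")]][has],
               junction_aa = cells[[paste0(p, "_cdr3_aa")]][has],
               productive = cells[[paste0(p, "_productive")]][has],
               consensus_count = cells[[paste0(p, "_support")]][has],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("alpha", "TRA"), one("beta", "TRB"))
  out <- out[order(out$cell_id, out$locus), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' A serializable bag of stage parameters with defaults for every threshold;
#' written/read as JSON so a run can be reproduced exactly.
#'
#' @param ... Named fields overriding the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sample = "sample1",
    merge = list(min_overlap = 10L, max_mismatch_frac = 0.25),
    demux = list(max_mismatch = 1L),
    collapse = list(ratio_threshold = 5, max_mm = 2L),
    dominance_threshold = 5,
    annotate = list(min_score_v = 20, min_score_j = 12),
    clone_level = "aa",
    clonality_k = 3L,
    motifs = c("PPG", "LELGG", "SWT"),
    enrich = list(min_cells = 3L, min_fold = 5, pseudocount = 1),
    display = list(pseudocount = 1, max_mm = 1L),
    log_level = "info")
  override <- list(...)
  cfg <- utils::modifyList(defaults, override)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON path.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @param config A `run_config` to write.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Machine-readable record of a run: package version, seed, parameters and a
# parameter fingerprint. Deliberately excludes wall-clock time so reruns of
# one config are byte-identical.
write_manifest <- function(config, stage, outputs, path) {
  manifest <- list(
    stage = stage,
    package = "mimoseq",
    version = as.character(utils::packageVersion("mimoseq")),
    seed = config$seed,
    parameters = unclass(config),
    parameter_hash = fnv1a(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA)),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("%s input not found: %s", what,
                 if (is.null(path)) "<missing>" else path), call. = FALSE)
  path
}

#' Run the full repertoire stage
#'
#' Chains read merging, demultiplexing, chain segregation, collapse, pairing,
#' annotation, clonotype calling, clonality and motif reports, writing all
#' stage outputs plus a machine-readable run manifest under `out_dir`.
#'
#' @param config A `run_config` (or path to one as JSON) with fields `r1`,
#'   `r2` (paired FASTQ paths), `scheme` (JSON path or `barcode_scheme`),
#'   `germline` (FASTA path or `germline_reference`) and `out_dir`.
#' @return Invisibly, a list with `cells`, `clonotypes`, `clonality`,
#'   `motifs` and the output paths.
#' @export
run_repertoire <- function(config) {
  if (is.character(config)) config <- read_run_config(check_input(config, "config"))
  r1 <- read_fastq(check_input(config$r1, "R1 FASTQ"))
  r2 <- read_fastq(check_input(config$r2, "R2 FASTQ"))
  scheme <- if (inherits(config$scheme, "barcode_scheme")) config$scheme
            else read_barcode_scheme(check_input(config$scheme, "barcode scheme"))
  ref <- if (inherits(config$germline, "germline_reference")) config$germline
         else read_germline_fasta(check_input(config$germline, "germline"))
  if (nrow(r1) != nrow(r2)) stop("R1/R2 read counts differ")

  merged <- merge_pairs(r1$seq, r2$seq, r1$qual, r2$qual,
                        min_overlap = config$merge$min_overlap,
                        max_mismatch_frac = config$merge$max_mismatch_frac)
  keep <- merged$status == "merged"
  res <- process_plate_reads(
    merged$merged[keep], scheme, ref, sample = config$sample,
    ratio_threshold = config$collapse$ratio_threshold,
    max_mm = config$collapse$max_mm,
    dominance_threshold = config$dominance_threshold,
    min_score_v = config$annotate$min_score_v,
    min_score_j = config$annotate$min_score_j)

  clonotypes <- call_clonotypes(res$cells, level = config$clone_level)
  clon <- clonality(clonotypes, k = config$clonality_k)
  motifs <- do.call(rbind, lapply(config$motifs, function(m) {
    mc <- count_motif(clonotypes$cdr3_beta_aa, m)
    data.frame(motif = m, n_matching = mc$n_matching, n_total = mc$n_total)
  }))

  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    airr = file.path(out_dir, "rearrangements.tsv"),
    clonotypes = file.path(out_dir, "clonotypes.tsv"),
    clonality = file.path(out_dir, "clonality.csv"),
    motifs = file.path(out_dir, "motifs.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_airr_tsv(res$cells, paths$airr)
  write.table(as.data.frame(clonotypes), paths$clonotypes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(clon$fractions, paths$clonality, row.names = FALSE)
  write.csv(motifs, paths$motifs, row.names = FALSE)
  write_manifest(config, "repertoire", paths[names(paths) != "manifest"],
                 paths$manifest)
  invisible(list(cells = res$cells, clonotypes = clonotypes,
                 clonality = clon, motifs = motifs, paths = paths))
}

#' Run the display-selection analysis stage
#'
#' From per-round peptide count tables (CSV) or per-round merged/paired
#' FASTQ, computes per-round count tables, per-round preference matrices,
#' enrichment trajectories and the ranked mimotope candidates.
#'
#' @param config A `run_config` (or JSON path) with fields `design` (JSON
#'   path or `library_design`), `out_dir`, and either `counts` (CSV path with
#'   columns round,peptide,count) or `rounds` (list of per-round FASTQ pairs
#'   `list(r1=, r2=)`) plus `flank_5`/`flank_3` anchors.
#' @return Invisibly, a list with `tables`, `preferences`, `trajectory`,
#'   `candidates` and output paths.
#' @export
run_display <- function(config) {
  if (is.character(config)) config <- read_run_config(check_input(config, "config"))
  design <- if (inherits(config$design, "library_design")) config$design
            else read_library_design(check_input(config$design, "design"))

  if (!is.null(config$counts)) {
    tables <- read_peptide_counts(check_input(config$counts, "count table"),
                                  tcr_label = config$sample)
  } else if (!is.null(config$rounds)) {
    tables <- lapply(seq_along(config$rounds), function(i) {
      rd <- config$rounds[[i]]
      r1 <- read_fastq(check_input(rd$r1, sprintf("round %d R1", i - 1)))
      r2 <- read_fastq(check_input(rd$r2, sprintf("round %d R2", i - 1)))
      merged <- merge_pairs(r1$seq, r2$seq, r1$qual, r2$qual,
                            min_overlap = config$merge$min_overlap,
                            max_mismatch_frac = config$merge$max_mismatch_frac)
      reg <- extract_region(merged$merged[merged$status == "merged"],
                            config$flank_5, config$flank_3,
                            max_mm = config$display$max_mm,
                            expected_length = 3L * nchar(design$template_peptide))
      pep <- translate_filter(reg$insert[reg$status == "ok"], design)
      accepted <- pep$peptide[pep$status == "ok"]
      if (length(accepted) == 0)
        stop("round ", i - 1, ": no accepted reads")
      tally_peptides(accepted, round_index = i - 1L,
                     tcr_label = config$sample)
    })
  } else stop("config must provide either counts or rounds")

  empty <- vapply(tables, nrow, 0L) == 0
  if (any(empty))
    stop("round ", attr(tables[[which(empty)[1]]], "round_index"),
         ": no accepted reads")

  prefs <- lapply(tables, preference_matrix, design = design)
  traj <- enrichment_trajectory(tables, pseudocount = config$display$pseudocount)
  candidates <- rank_mimotopes(traj)

  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(out_dir, "peptide_counts.csv"),
                candidates = file.path(out_dir, "candidates.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_peptide_counts(tables, paths$counts)
  for (t in seq_along(prefs)) {
    r <- attr(tables[[t]], "round_index")
    p <- file.path(out_dir, sprintf("preference_round%d.csv", r))
    write.csv(as.data.frame(unclass(prefs[[t]])), p)
    paths[[sprintf("preference_round%d", r)]] <- p
  }
  write.csv(candidates, paths$candidates, row.names = FALSE)
  write_manifest(config, "display", paths[names(paths) != "manifest"],
                 paths$manifest)
  invisible(list(tables = tables, preferences = prefs, trajectory = traj,
                 candidates = candidates, paths = paths))
}
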