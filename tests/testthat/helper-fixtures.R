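# Shared fixtures, built in code at load time (fast, deterministic).

fx_ref <- generate_germline_reference(4, seed = 1)
fx_scheme <- default_barcode_scheme()
fx_clones <- aip_clone_table()

# A tiny two-field-sized scheme for demultiplexing edge cases.
fx_tiny_scheme <- barcode_scheme(
  group = c(g1 = "AAAAAA", g2 = "CCCCCC"),
  plate = c(p1 = "GGGGGG", p2 = "TTTTTT"),
  column = c(c1 = "ACACAC", c2 = "GTGTGT", c3 = "AGAGAG"),
  row = c(rA = "ACGTAC", rB = "ACGTCA"),
  max_mismatch = 1)

# Brute-force reference implementation of the frequency-ratio absorption rule
# (kept independent of collapse_reads).
brute_collapse <- function(reads, ratio_threshold, max_mm) {
  if (length(reads) == 0)
    return(data.frame(consensus = character(0), support = integer(0)))
  out <- data.frame()
  for (len in unique(nchar(reads))) {
    tab <- table(reads[nchar(reads) == len])
    seqs <- names(tab)
    cnt <- as.integer(tab)
    hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    repeat {
      move <- NULL
      ord <- order(cnt, seqs)
      for (i in ord) {
        ks <- Filter(function(k) k != i && hd(seqs[i], seqs[k]) <= max_mm &&
                       cnt[k] >= ratio_threshold * cnt[i],
                     seq_along(seqs))
        if (length(ks)) {
          ks <- ks[order(-cnt[ks], seqs[ks])]
          move <- c(i, ks[1])
          break
        }
      }
      if (is.null(move)) break
      cnt[move[2]] <- cnt[move[2]] + cnt[move[1]]
      seqs <- seqs[-move[1]]
      cnt <- cnt[-move[1]]
    }
    out <- rbind(out, data.frame(consensus = seqs, support = cnt,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(-out$support, out$consensus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force evaluation of the two-threshold enrichment rule.
brute_enriched_ids <- function(table, min_cells, min_fold, pseudocount) {
  r <- table$rows
  pass <- character(0)
  for (i in seq_len(nrow(r))) {
    fp <- r$n_pos[i] / table$N_pos
    fn <- (r$n_neg[i] + pseudocount) / (table$N_neg + pseudocount)
    if (r$n_pos[i] >= min_cells && fp / fn >= min_fold)
      pass <- c(pass, r$clonotype_id[i])
  }
  sort(pass)
}

# Score recovered cells against a planted plate truth; returns the fraction
# of planted wells whose paired chains match the plant exactly.
score_plate_recovery <- function(truth, cells) {
  w <- truth$wells
  w$well_id <- paste(w$group, w$plate, w$row, w$column, sep = "|")
  m <- merge(w, cells, by = "well_id")
  ok <- m$status == "paired" &
    m$alpha_cdr3_aa == m$cdr3a & m$beta_cdr3_aa == m$cdr3b &
    m$alpha_v == m$va & m$alpha_j == m$ja &
    m$beta_v == m$vb & m$beta_j == m$jb
  sum(ok, na.rm = TRUE) / nrow(w)
}
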