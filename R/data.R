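#' Published p15E-reactive clone table
#'
#' The table of strikingly similar paired TCR sequences recovered by
#' single-cell sorting of activated tumor-infiltrating CD8+ T cells from
#' B16F10 melanomas (treated with the AIP combination therapy, or untreated):
#' 14 clonal lineages sharing two near-identical TRAJ7-derived CDR3-alpha
#' sequences, with clone sizes, mouse of origin, CDR3s and V/D/J gene usage.
#' Ships with the package as plain TSV; used as the default plant for plate
#' simulations and as the reference fixture for the clonotype analytics.
#'
#' @return data.frame with columns `clone_name`, `clone_size`, `mouse`,
#'   `cdr3a`, `trav`, `traj`, `cdr3b`, `trbv`, `trbd`, `trbj`.
#' @export
aip_clone_table <- function() {
  path <- system.file("extdata", "aip_clone_table.tsv", package = "mimoseq",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    clone_name = "character", clone_size = "integer", mouse = "character",
    cdr3a = "character", trav = "character", traj = "character",
    cdr3b = "character", trbv = "character", trbd = "character",
    trbj = "character"))
}

#' Expand a clone table into one row per cell
#'
#' Repeats each clone row `clone_size` times and shapes the result as the
#' paired-cell input of [call_clonotypes()] (synthetic well ids; nucleotide
#' CDR3s reverse-translated with fixed codons, i.e. one rearrangement per
#' clone).
#'
#' @param clones data.frame like [aip_clone_table()].
#' @return data.frame of paired cell records.
#' @export
expand_clones_to_cells <- function(clones) {
  idx <- rep(seq_len(nrow(clones)), clones$clone_size)
  cl <- clones[idx, , drop = FALSE]
  data.frame(
    well_id = sprintf("w%03d", seq_along(idx)),
    sample = cl$mouse,
    status = "paired",
    alpha_cdr3_aa = cl$cdr3a,
    alpha_cdr3_nt = vapply(cl$cdr3a, reverse_translate, "", USE.NAMES = FALSE),
    alpha_v = paste0("TRAV", cl$trav),
    alpha_j = paste0("TRAJ", cl$traj),
    beta_cdr3_aa = cl$cdr3b,
    beta_cdr3_nt = vapply(cl$cdr3b, reverse_translate, "", USE.NAMES = FALSE),
    beta_v = paste0("TRBV", cl$trbv),
    beta_j = paste0("TRBJ", cl$trbj),
    beta_d = paste0("TRBD", cl$trbd),
    stringsAsFactors = FALSE)
}
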