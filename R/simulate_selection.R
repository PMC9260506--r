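#' Planted truth for a yeast display selection campaign
#'
#' Defines the peptide space of a library design together with a planted
#' binding-energy landscape. By default the energy of a peptide is
#' `penalty * (number of diversified positions differing from the planted
#' binder)`, with the template peptide itself as the binder -- an additive
#' landscape whose per-position optimum mirrors selections that converge to
#' wild-type contact residues.
#'
#' @param design A `library_design` (the diversified space is enumerated, so
#'   at most 5 diversified positions are supported).
#' @param binder Planted best-binding peptide (defaults to the template).
#' @param penalty Energy penalty per mismatched diversified position
#'   (unitless; default 2).
#' @param energies Optional named numeric vector (peptide -> energy)
#'   overriding the additive default; must cover the full stop-free space.
#' @param stringency Selection stringency (multiplies energies; default 1).
#' @param depth_per_round Reads sequenced per round (default 1e5).
#' @param n_rounds Number of selection rounds after the preselection pool
#'   (default 3).
#' @param seed Integer seed.
#' @return A `selection_truth` object.
#' @export
selection_truth <- function(design, binder = design$template_peptide,
                            penalty = 2, energies = NULL, stringency = 1,
                            depth_per_round = 1e5, n_rounds = 3, seed = 1) {
  stopifnot(inherits(design, "library_design"), depth_per_round > 0,
            n_rounds >= 1, stringency >= 0)
  k <- length(design$diversified_positions)
  if (k > 5) stop("enumerating more than 5 diversified positions is not supported")
  space <- enumerate_library_peptides(design)
  if (is.null(energies)) {
    stopifnot(nchar(binder) == nchar(design$template_peptide))
    div <- design$diversified_positions
    mm <- rep(0L, length(space$peptide))
    for (p in div)
      mm <- mm + (substr(space$peptide, p, p) != substr(binder, p, p))
    energies <- setNames(penalty * mm, space$peptide)
  } else {
    missing <- setdiff(space$peptide, names(energies))
    if (length(missing))
      stop("energies must cover the full peptide space (",
           length(missing), " peptides missing)")
    energies <- energies[space$peptide]
  }
  structure(list(design = design, binder = binder,
                 peptides = space$peptide, f0 = space$f0,
                 energies = energies, stringency = stringency,
                 depth_per_round = as.integer(depth_per_round),
                 n_rounds = as.integer(n_rounds), seed = seed),
            class = "selection_truth")
}

# Enumerate the stop-free peptide space of a design along with round-0
# frequencies proportional to the number of degenerate codons per residue.
enumerate_library_peptides <- function(design) {
  tab <- codon_table(design$codon_scheme)
  tab <- tab[tab$aa != "*", ]
  mult <- table(tab$aa)
  div <- design$diversified_positions
  tmpl <- strsplit(design$template_peptide, "")[[1]]
  if (length(div) == 0)
    return(list(peptide = design$template_peptide, f0 = 1))
  aas <- sort(unique(tab$aa))
  grid <- do.call(expand.grid,
                  c(rep(list(aas), length(div)), stringsAsFactors = FALSE))
  pep <- matrix(rep(tmpl, each = nrow(grid)), nrow = nrow(grid))
  w <- rep(1, nrow(grid))
  for (j in seq_along(div)) {
    pep[, div[j]] <- grid[[j]]
    w <- w * as.numeric(mult[grid[[j]]])
  }
  list(peptide = apply(pep, 1, paste, collapse = ""), f0 = w / sum(w))
}

#' Simulate a multi-round yeast display selection campaign
#'
#' The preselection pool (round 0) holds the design's stop-free peptides at
#' frequencies proportional to their degenerate-codon multiplicity. Each
#' selection round reweights the pool by the Boltzmann factor
#' `exp(-stringency * energy)` and renormalises:
#' `f_t ∝ f_{t-1} * exp(-stringency * energy)`. Deep sequencing of each round
#' draws `depth_per_round` reads multinomially from the round's pool, so
#' expected counts follow the count-resampling recursion
#' `E[count_t] ∝ count_{t-1} * exp(-stringency * energy)` while rare strong
#' binders are not irrecoverably lost to finite round-0 sampling. Zero-count
#' peptides are dropped from each table.
#'
#' @param truth A `selection_truth`.
#' @return List of `peptide_counts` tables (rounds 0..n_rounds), with
#'   `truth` attached as an attribute.
#' @export
simulate_selection_campaign <- function(truth) {
  stopifnot(inherits(truth, "selection_truth"))
  with_seed(truth$seed, {
    f <- truth$f0
    boltz <- exp(-truth$stringency * truth$energies)
    tables <- vector("list", truth$n_rounds + 1L)
    for (t in 0:truth$n_rounds) {
      if (t > 0) {
        f <- f * boltz
        f <- f / sum(f)
      }
      counts <- as.integer(rmultinom(1, truth$depth_per_round, f))
      keep <- counts > 0
      ord <- order(-counts[keep], truth$peptides[keep])
      tables[[t + 1L]] <- peptide_counts(truth$peptides[keep][ord],
                                         counts[keep][ord], t,
                                         tcr_label = "sim")
    }
    attr(tables, "truth") <- truth
    tables
  })
}

#' Simulate a steady-state one-site binding curve
#'
#' Responses follow `R(C) = rmax * C / (kd + C)` with additive Gaussian
#' noise.
#'
#' @param kd Dissociation constant (uM).
#' @param rmax Maximal response (response units).
#' @param concs Analyte concentrations (uM), e.g. a two-fold dilution series
#'   spanning 0.35-266 uM.
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed.
#' @return A `binding_curve` data.frame (`concentration`, `response`) with
#'   attribute `truth = c(kd, rmax)`.
#' @export
simulate_binding_curve <- function(kd, rmax, concs = 0.35 * 2^(0:9),
                                   noise_sd = 0, seed = 1) {
  if (kd <= 0 || rmax <= 0) stop("kd and rmax must be positive")
  stopifnot(length(concs) > 0, all(concs > 0))
  resp <- rmax * concs / (kd + concs)
  if (noise_sd > 0) resp <- resp + with_seed(seed, rnorm(length(concs), 0, noise_sd))
  structure(data.frame(concentration = concs, response = resp),
            truth = c(kd = kd, rmax = rmax),
            class = c("binding_curve", "data.frame"))
}

#' Simulate a thermal melt (differential scanning fluorimetry) curve
#'
#' Fluorescence follows the two-state sigmoid
#' `f_low + (f_high - f_low) / (1 + exp((tm - T)/width))` with additive
#' Gaussian noise.
#'
#' @param tm Melting midpoint (deg C).
#' @param width Transition width (deg C, > 0).
#' @param f_low,f_high Baseline and plateau fluorescence (a.u.).
#' @param temps Temperature grid (deg C, strictly increasing; default
#'   20..95 at 1 deg, the instrument's scan range).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed Integer seed.
#' @return A `melt_curve` data.frame (`temperature`, `fluorescence`) with
#'   attribute `truth = c(tm, width)`.
#' @export
simulate_melt_curve <- function(tm, width, f_low = 0, f_high = 100,
                                temps = 20:95, noise_sd = 0, seed = 1) {
  stopifnot(width > 0, all(diff(temps) > 0))
  fl <- f_low + (f_high - f_low) / (1 + exp((tm - temps) / width))
  if (noise_sd > 0) fl <- fl + with_seed(seed, rnorm(length(temps), 0, noise_sd))
  structure(data.frame(temperature = temps, fluorescence = fl),
            truth = c(tm = tm, width = width),
            class = c("melt_curve", "data.frame"))
}
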