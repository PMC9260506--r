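fx_design <- design_library("KSPWFTTL", c(1, 4, 6, 7), "NNK")

test_that("NNK library design reproduces the XSPXFXXL template", {
  expect_identical(fx_design$template_string, "XSPXFXXL")
  expect_equal(nchar(fx_design$oligo), 24)
  expect_identical(substr(fx_design$oligo, 1, 3), "NNK")

  plain <- design_library("KSPWFTTL", integer(0), "NNK")
  expect_identical(plain$template_string, "KSPWFTTL")
  expect_false(grepl("[^ACGT]", plain$oligo))

  expect_identical(design_library("SIINFEKL", c(2, 3), "NNK")$template_string,
                   "SXXNFEKL")
  expect_error(design_library("KSPWFTTL", c(0, 4)), "positions")
  expect_error(design_library("KSPWFTTL", 9), "positions")
})

test_that("the NNK codon table matches brute-force genetic-code enumeration", {
  tab <- codon_table("NNK")
  expect_equal(nrow(tab), 32)
  expect_setequal(unique(tab$aa[tab$aa != "*"]),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_identical(tab$codon[tab$aa == "*"], "TAG")

  # independent enumeration: all codons with third base in {G, T}
  gc <- Biostrings::GENETIC_CODE
  expected <- sort(names(gc)[substr(names(gc), 3, 3) %in% c("G", "T")])
  expect_identical(tab$codon, expected)
  expect_identical(tab$aa, unname(as.character(gc[expected])))

  expect_equal(nrow(codon_table("NNN")), 64)
  expect_error(codon_table("NNX"))
})

test_that("library diversity follows the counting identities", {
  d <- diversity(fx_design)
  expect_equal(d$nt_variants, 32^4)
  expect_equal(d$nt_variants, 1048576)
  expect_equal(d$stop_free_peptides, 160000)
  expect_equal(d$stop_containing_fraction, 1 - (31 / 32)^4)
  d0 <- diversity(design_library("KSPWFTTL", integer(0)))
  expect_equal(unlist(d0), c(nt_variants = 1, stop_free_peptides = 1,
                             stop_containing_fraction = 0))
})

test_that("read-pair merging finds the planted overlap", {
  withr::local_seed(21)
  amplicon <- mimoseq:::random_nt(1, 250)
  r1 <- substr(amplicon, 1, 150)
  r2 <- mimoseq:::revcomp(substr(amplicon, 101, 250))
  m <- merge_pairs(r1, r2, min_overlap = 10)
  expect_identical(m$status, "merged")
  expect_equal(m$overlap, 50)
  expect_identical(m$merged, amplicon)

  # a read merged with its own full reverse complement is itself
  r <- mimoseq:::random_nt(1, 80)
  self <- merge_pairs(r, mimoseq:::revcomp(r))
  expect_identical(self$merged, r)
  expect_equal(self$overlap, 80)

  # 40% mismatches in the best candidate overlap: rejected
  r1c <- paste0(strrep("A", 30), "TTTTTTTTTT")
  r2c_fwd <- paste0("TTTTTTCCCC", strrep("G", 30))  # 4 of 10 disagree
  m2 <- merge_pairs(r1c, mimoseq:::revcomp(r2c_fwd),
                    min_overlap = 10, max_mismatch_frac = 0.25)
  expect_identical(m2$status, "no_overlap")

  # disagreements resolve to the higher-quality base, ties to read 1
  x <- "AAAAACAAAA"
  y <- "AAAAAGAAAA"  # one mid-overlap disagreement
  m3 <- merge_pairs(x, mimoseq:::revcomp(y), q1 = strrep("I", 10),
                    q2 = strrep("#", 10), min_overlap = 10)
  expect_identical(m3$merged, x)
  m4 <- merge_pairs(x, mimoseq:::revcomp(y), q1 = strrep("#", 10),
                    q2 = strrep("I", 10), min_overlap = 10)
  expect_identical(m4$merged, y)
  m5 <- merge_pairs(x, mimoseq:::revcomp(y), min_overlap = 10)
  expect_identical(m5$merged, x)
})

test_that("region extraction enforces anchors and length", {
  withr::local_seed(3)
  flank5 <- mimoseq:::random_nt(1, 15)
  flank3 <- mimoseq:::random_nt(1, 15)
  insert <- mimoseq:::random_nt(1, 24)
  read <- paste0(flank5, insert, flank3)
  r <- extract_region(read, flank5, flank3, max_mm = 1, expected_length = 24)
  expect_identical(r$insert, insert)

  short <- paste0(flank5, substr(insert, 1, 23), flank3)
  expect_identical(extract_region(short, flank5, flank3, max_mm = 1,
                                  expected_length = 24)$status, "length")

  mut5 <- flank5
  substr(mut5, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                substr(mut5, 3, 3))[1]
  expect_identical(extract_region(paste0(mut5, insert, flank3), flank5,
                                  flank3, max_mm = 1,
                                  expected_length = 24)$insert, insert)

  expect_identical(extract_region(insert, flank5, flank3, max_mm = 1)$status,
                   "no_anchor")
})

test_that("translate-filter accepts designed mimotopes and rejects violations", {
  # the published mimotope VSPWFNTL differs from template only at X positions
  nt <- reverse_translate("VSPWFNTL")
  tf <- translate_filter(nt, fx_design)
  expect_identical(tf$status, "ok")
  expect_identical(tf$peptide, "VSPWFNTL")

  with_stop <- paste0("TAG", substr(nt, 4, 24))  # TAG at diversified pos 1
  expect_identical(translate_filter(with_stop, fx_design)$status, "stop")

  mismatch <- reverse_translate("KAPWFTTL")  # position 2 != S
  expect_identical(translate_filter(mismatch, fx_design)$status,
                   "template_mismatch")
})

test_that("peptide tallies count exactly and absorb lone near-neighbours on request", {
  t1 <- tally_peptides(c("A", "A", "B"))
  expect_identical(t1$peptide, c("A", "B"))
  expect_identical(t1$count, c(2L, 1L))
  expect_equal(nrow(tally_peptides(character(0))), 0)

  reads <- c(rep("VSPWFNTL", 100), "VSPWFNTI")
  t2 <- tally_peptides(reads, absorb_singletons = TRUE)
  expect_identical(t2$peptide, "VSPWFNTL")
  expect_equal(t2$count, 101L)
  t3 <- tally_peptides(reads, absorb_singletons = FALSE)
  expect_equal(nrow(t3), 2)
})

test_that("preference matrices are read-count-weighted and column-normalised", {
  tab <- mimoseq:::peptide_counts(c("VSPWFNTL", "KSPWFTTL"), c(3L, 1L))
  pm <- preference_matrix(tab, fx_design)
  expect_equal(pm[1, "V"], 0.75)
  expect_equal(pm[1, "K"], 0.25)
  expect_equal(unname(rowSums(pm)), rep(1, 8), tolerance = 1e-12)
  # fixed positions are one-hot at the template residue
  expect_equal(pm[2, "S"], 1)
  expect_equal(pm[5, "F"], 1)

  one <- preference_matrix(mimoseq:::peptide_counts("KSPWFTTL", 7L), fx_design)
  expect_true(all(one[cbind(1:8, strsplit("KSPWFTTL", "")[[1]])] == 1))
  expect_error(preference_matrix(mimoseq:::peptide_counts(character(0),
                                                          integer(0)),
                                 fx_design), "empty")
})

test_that("pooled preference matrices aggregate counts over rounds", {
  t0 <- mimoseq:::peptide_counts("VSPWFNTL", 1L, 0)
  t1 <- mimoseq:::peptide_counts(c("VSPWFNTL", "KSPWFTTL"), c(2L, 1L), 1)
  pm <- pooled_preference_matrix(list(t0, t1), fx_design)
  expect_equal(pm[1, "V"], 0.75)
  expect_equal(pm[1, "K"], 0.25)
  expect_equal(unname(rowSums(pm)), rep(1, 8))
})

test_that("enrichment trajectories follow the pseudocount arithmetic", {
  t0 <- mimoseq:::peptide_counts(c("A", "B"), c(10L, 10L), 0)
  t1 <- mimoseq:::peptide_counts(c("A", "B"), c(30L, 10L), 1)
  tr <- enrichment_trajectory(list(t0, t1), pseudocount = 0)
  a <- tr[tr$peptide == "A", ]
  expect_equal(a$fold_1, 0.75 / 0.5)
  expect_equal(a$cumulative_fold, 1.5)

  # a peptide absent in round 0 keeps a finite fold with pseudocount 1
  t0b <- mimoseq:::peptide_counts("A", 20L, 0)
  t1b <- mimoseq:::peptide_counts(c("A", "B"), c(10L, 10L), 1)
  trb <- enrichment_trajectory(list(t0b, t1b), pseudocount = 1)
  expect_true(is.finite(trb$cumulative_fold[trb$peptide == "B"]))
  expect_gt(trb$cumulative_fold[trb$peptide == "B"], 1)

  expect_error(enrichment_trajectory(list(t0)), "2 selection rounds")
})

test_that("candidate ranking is deterministic and rescaling-invariant", {
  t0 <- mimoseq:::peptide_counts(c("A", "B", "C"), c(10L, 10L, 20L), 0)
  t1 <- mimoseq:::peptide_counts(c("A", "B", "C"), c(30L, 30L, 20L), 1)
  rk <- rank_mimotopes(enrichment_trajectory(list(t0, t1), pseudocount = 0))
  # A and B tie on fold and final frequency: lexicographic order
  expect_identical(rk$peptide, c("A", "B", "C"))

  # uniform depth rescaling leaves the ranking unchanged
  t0s <- mimoseq:::peptide_counts(c("A", "B", "C"), c(100L, 100L, 200L), 0)
  t1s <- mimoseq:::peptide_counts(c("A", "B", "C"), c(300L, 300L, 200L), 1)
  rks <- rank_mimotopes(enrichment_trajectory(list(t0s, t1s), pseudocount = 0))
  expect_identical(rks$peptide, rk$peptide)

  single <- rank_mimotopes(enrichment_trajectory(
    list(mimoseq:::peptide_counts("A", 5L, 0),
         mimoseq:::peptide_counts("A", 9L, 1)), pseudocount = 0))
  expect_identical(single$peptide, "A")
  expect_equal(single$rank, 1L)
})

test_that("count tables round-trip through CSV", {
  tabs <- list(mimoseq:::peptide_counts(c("AA", "AB"), c(5L, 2L), 0, "tcr1"),
               mimoseq:::peptide_counts("AA", 9L, 1, "tcr1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peptide_counts(tabs, path)
  back <- read_peptide_counts(path, tcr_label = "tcr1")
  expect_equal(length(back), 2)
  expect_identical(back[[1]]$peptide, tabs[[1]]$peptide)
  expect_identical(back[[2]]$count, tabs[[2]]$count)
  expect_equal(attr(back[[2]], "round_index"), 1L)
})
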