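make_read <- function(g, p, c_, r, insert = "ACGT") {
  paste0(fx_tiny_scheme$fields$group[[g]], fx_tiny_scheme$fields$plate[[p]],
         fx_tiny_scheme$fields$column[[c_]], fx_tiny_scheme$fields$row[[r]],
         insert)
}

test_that("demultiplexing follows the unique-best rule", {
  exact <- make_read("g1", "p1", "c3", "rA")
  dm <- demultiplex(exact, fx_tiny_scheme)
  a <- dm$assignments
  expect_true(a$assigned)
  expect_identical(a$well_id, "g1|p1|rA|c3")
  expect_identical(a$insert, "ACGT")

  # one mismatch in one field is tolerated at max_mismatch = 1
  one_mm <- exact
  substr(one_mm, 1, 1) <- "T"
  expect_true(demultiplex(one_mm, fx_tiny_scheme)$assignments$assigned)

  # row "ACGTAA" is at distance 1 from both rA ("ACGTAC") and rB ("ACGTCA"):
  # equidistant best matches leave the read unassigned
  tie <- make_read("g1", "p1", "c3", "rA")
  substr(tie, 19, 24) <- "ACGTAA"
  at <- demultiplex(tie, fx_tiny_scheme)$assignments
  expect_false(at$assigned)
  expect_identical(at$reason, "ambiguous")

  # distance beyond tolerance in one field
  far <- make_read("g1", "p1", "c3", "rA")
  substr(far, 1, 6) <- "AATTAA"
  af <- demultiplex(far, fx_tiny_scheme)$assignments
  expect_false(af$assigned)
  expect_identical(af$reason, "no_match")

  # malformed short read
  short <- demultiplex("ACGT", fx_tiny_scheme)$assignments
  expect_false(short$assigned)
  expect_identical(short$reason, "too_short")
})

test_that("demultiplexing partitions the input reads", {
  reads <- c(make_read("g1", "p1", "c1", "rA"),
             make_read("g2", "p2", "c2", "rB"),
             "ACGT", make_read("g1", "p2", "c3", "rB"))
  a <- demultiplex(reads, fx_tiny_scheme)$assignments
  expect_equal(nrow(a), length(reads))
  expect_equal(sum(a$assigned) + sum(!a$assigned), length(reads))
  # every assigned read belongs to exactly one well
  expect_true(all(!is.na(a$well_id[a$assigned])))
})

test_that("chain segregation requires a clear constant-region match", {
  cc <- fx_ref[fx_ref$kind == "C", ]
  crefs <- setNames(cc$nt, ifelse(cc$locus == "TRA", "TRAC", "TRBC"))
  read_a <- paste0(mimoseq:::random_nt(1, 60), crefs[["TRAC"]])
  expect_identical(assign_chain(read_a, crefs), "alpha")
  read_b <- paste0(mimoseq:::random_nt(1, 60), crefs[["TRBC"]])
  expect_identical(assign_chain(read_b, crefs), "beta")
  expect_identical(assign_chain(strrep("AC", 40), crefs), "unknown")
})

test_that("read collapse matches the worked absorption examples", {
  base <- strrep("ACGT", 10)
  variant <- function(s, i, b) { substr(s, i, i) <- b; s }
  reads <- c(rep(base, 100), variant(base, 1, "T"), variant(base, 5, "G"),
             variant(base, 9, "C"))
  out <- collapse_reads(reads, ratio_threshold = 10, max_mm = 1)
  expect_equal(nrow(out), 1)
  expect_identical(out$consensus, base)
  expect_equal(out$support, 103)

  # a 50/50 split is below any sensible ratio threshold: both retained
  out2 <- collapse_reads(c(rep("AAAA", 50), rep("AAAT", 50)),
                         ratio_threshold = 10, max_mm = 1)
  expect_equal(out2$support, c(50, 50))

  # identity
  out3 <- collapse_reads("ACGT")
  expect_identical(out3, data.frame(consensus = "ACGT", support = 1L))

  expect_equal(nrow(collapse_reads(character(0))), 0)
})

test_that("read collapse agrees with the brute-force absorption rule", {
  withr::local_seed(42)
  for (trial in 1:300) {
    n_unique <- sample(1:6, 1)
    seqs <- unique(replicate(n_unique, paste(
      sample(c("A", "C"), 5, replace = TRUE), collapse = "")))
    counts <- sample(1:120, length(seqs), replace = TRUE)
    reads <- rep(seqs, counts)
    ratio <- sample(c(2, 5, 10), 1)
    mm <- sample(0:2, 1)
    expect_identical(collapse_reads(reads, ratio, mm),
                     brute_collapse(reads, ratio, mm),
                     info = sprintf("trial %d ratio %g mm %d", trial, ratio, mm))
  }
})

test_that("V/J annotation recovers planted segments and breaks ties lexicographically", {
  amp <- build_chain_amplicon("CAAKDYSNNRLTL", "TRAV10", "TRAJ7", fx_ref)
  ann <- annotate_vj(amp, fx_ref, "alpha")
  expect_identical(ann$v_call, "TRAV10")
  expect_identical(ann$j_call, "TRAJ7")
  expect_gt(ann$v_score, 20)

  # two V references with identical sequence (hence identical score):
  # the lexicographically first name is reported
  ref2 <- fx_ref
  dup <- ref2[ref2$name == "TRAV10", ]
  dup$name <- "TRAV09Z"
  ref2 <- structure(rbind(ref2, dup),
                    class = c("germline_reference", "data.frame"))
  ann2 <- annotate_vj(amp, ref2, "alpha")
  expect_identical(ann2$v_call, "TRAV09Z")

  # an unrelated random sequence is unannotatable
  expect_error(annotate_vj(strrep("ACGGT", 30), fx_ref, "alpha"),
               class = "mimoseq_unannotatable")
})

test_that("CDR3 extraction reproduces the published junctions", {
  amp_a <- build_chain_amplicon("CAAKDYSNNRLTL", "TRAV7-2", "TRAJ7", fx_ref)
  ann_a <- annotate_vj(amp_a, fx_ref, "alpha")
  expect_identical(ann_a$cdr3_aa, "CAAKDYSNNRLTL")
  expect_true(ann_a$productive)
  expect_identical(translate_nt(ann_a$cdr3_nt), "CAAKDYSNNRLTL")

  amp_b <- build_chain_amplicon("CASSPPGDTQYF", "TRBV3", "TRBJ2-5", fx_ref)
  ann_b <- annotate_vj(amp_b, fx_ref, "beta")
  expect_identical(ann_b$cdr3_aa, "CASSPPGDTQYF")

  # doubled-anchor junctions must not be truncated
  amp_ff <- build_chain_amplicon("CASSPPGGSEVFF", "TRBV5", "TRBJ1-1", fx_ref)
  expect_identical(annotate_vj(amp_ff, fx_ref, "beta")$cdr3_aa,
                   "CASSPPGGSEVFF")

  # an in-junction stop codon clears the productive flag
  v <- germline_segment(fx_ref, "TRAV10")
  j <- germline_segment(fx_ref, "TRAJ7")
  stop_amp <- paste0(substr(v$nt, 1, v$conserved_cys_offset + 2), "TAA",
                     substr(j$nt, j$j_anchor_offset, nchar(j$nt)),
                     fx_ref$nt[fx_ref$kind == "C" & fx_ref$locus == "TRA"])
  ann_s <- annotate_vj(stop_amp, fx_ref, "alpha")
  expect_false(ann_s$productive)
  expect_match(ann_s$cdr3_aa, "\\*")
})

test_that("well pairing applies the dominance rule", {
  cons <- function(...) {
    x <- list(...)
    data.frame(consensus = vapply(x, `[[`, "", 1),
               support = as.integer(vapply(x, `[[`, "", 2)))
  }
  one_a <- cons(c("AAAA", 5)); one_b <- cons(c("CCCC", 7))
  expect_identical(pair_well(one_a, one_b)$status, "paired")
  expect_identical(pair_well(one_a, NULL)$status, "alpha_only")
  expect_identical(pair_well(NULL, one_b)$status, "beta_only")
  expect_identical(pair_well(NULL, NULL)$status, "empty")

  two_a <- cons(c("AAAA", 90), c("AAAT", 5))
  pw <- pair_well(two_a, one_b, dominance_threshold = 10)
  expect_identical(pw$status, "paired")
  expect_identical(pw$alpha$consensus, "AAAA")

  split_a <- cons(c("AAAA", 50), c("TTTT", 50))
  expect_identical(pair_well(split_a, one_b, dominance_threshold = 10)$status,
                   "multiplet")
})

test_that("clonotype calling groups the published table into 14 lineages", {
  cells <- expand_clones_to_cells(fx_clones)
  cl <- call_clonotypes(cells)
  expect_equal(nrow(cl), 14)
  expect_equal(sum(cl$size), sum(fx_clones$clone_size))
  expect_equal(cl$size[1], 26)
  expect_identical(cl$cdr3_alpha_aa[1], "CAAKDYSNNRLTL")
  expect_identical(cl$cdr3_beta_aa[1], "CASSPPGDTQYF")
  expect_equal(cl$size, sort(fx_clones$clone_size, decreasing = TRUE))

  # order invariance
  perm <- cells[sample(nrow(cells)), ]
  expect_equal(as.data.frame(call_clonotypes(perm)),
               as.data.frame(cl))

  # same CDR3s but different V-beta are distinct lineages
  two <- cells[c(1, 1), ]
  two$well_id <- c("w1", "w2")
  two$beta_v[2] <- "TRBV99"
  expect_equal(nrow(call_clonotypes(two)), 2)

  # nucleotide-level grouping splits convergent rearrangements
  conv <- cells[c(1, 1), ]
  conv$well_id <- c("w1", "w2")
  conv$alpha_cdr3_nt[2] <- sub("AAG", "AAA", conv$alpha_cdr3_nt[2])
  expect_equal(nrow(call_clonotypes(conv, level = "aa")), 1)
  expect_equal(nrow(call_clonotypes(conv, level = "nt")), 2)
})

test_that("contaminant flagging is exact-match only", {
  cl <- call_clonotypes(expand_clones_to_cells(fx_clones))
  flags <- flag_contaminants(cl, blacklist_nt = cl$cdr3_alpha_nt[2])
  expect_true(flags[2])
  # the shared CDR3-alpha means other clones carry the same rearrangement
  expect_identical(flags, cl$cdr3_alpha_nt %in% cl$cdr3_alpha_nt[2])

  near <- sub("^TGC", "TGT", cl$cdr3_alpha_nt[1])
  expect_false(any(flag_contaminants(cl[1, ], blacklist_nt = near)))
  expect_false(any(flag_contaminants(cl, character(0), character(0))))
})

test_that("clonality summaries are normalised", {
  cl <- data.frame(size = c(4, 3, 2, 1))
  s <- clonality(cl, k = 3)
  expect_equal(s$total_cells, 10)
  expect_equal(sum(s$fractions$fraction), 1)
  expect_equal(s$top_k_cumulative, 0.9)
  expect_equal(clonality(data.frame(size = c(5, 3, 2)), k = 3)$top_k_cumulative, 1)
  expect_error(clonality(data.frame(size = numeric(0))), "no clonotypes")
})
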