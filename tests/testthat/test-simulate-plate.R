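test_that("zero-noise plates emit exact planted amplicons at the right depth", {
  clones <- fx_clones[fx_clones$clone_size >= 22, ]  # two clones
  clones$clone_size <- 1L
  truth <- plate_truth(fx_ref, fx_scheme, clones = clones,
                       error_rate = 0, depth = 10, seed = 3)
  plate <- simulate_tcr_plate(truth)
  expect_equal(nrow(plate$reads), 2 * 2 * 10)
  m <- merge_pairs(plate$reads$r1, plate$reads$r2)
  expect_true(all(m$status == "merged"))
  w <- truth$wells
  expected <- character(nrow(plate$reads))
  for (i in seq_len(nrow(plate$reads))) {
    wi <- plate$reads$.well[i]
    chain_nt <- if (plate$reads$.chain[i] == "alpha") w$alpha_nt[wi]
                else w$beta_nt[wi]
    expected[i] <- paste0(
      mimoseq:::well_prefix(fx_scheme, w[wi, c("group", "plate", "column", "row")]),
      chain_nt)
  }
  expect_identical(m$merged, expected)
})

test_that("plate simulation is byte-identical for a fixed seed", {
  truth <- plate_truth(fx_ref, fx_scheme, n_wells = 8, error_rate = 0.02,
                       depth = 5, seed = 11)
  a <- simulate_tcr_plate(truth)
  b <- simulate_tcr_plate(truth)
  expect_identical(a$reads, b$reads)
  truth2 <- plate_truth(fx_ref, fx_scheme, n_wells = 8, error_rate = 0.02,
                        depth = 5, seed = 12)
  expect_false(identical(simulate_tcr_plate(truth2)$reads, a$reads))
})

test_that("barcode collisions are a configuration error", {
  expect_error(
    barcode_scheme(group = c(g1 = "AAAAAA", g2 = "AAAAAT"),
                   plate = c(p1 = "GGGGGG"),
                   column = c(c1 = "ACACAC"), row = c(rA = "ACGTAC")),
    "collision")
})

test_that("demultiplex + chain segregation recover planted assignments at 1% error", {
  clones <- fx_clones[1:3, ]
  truth <- plate_truth(fx_ref, fx_scheme, clones = clones,
                       error_rate = 0.01, depth = 20, seed = 9)
  plate <- simulate_tcr_plate(truth)
  m <- merge_pairs(plate$reads$r1, plate$reads$r2, plate$reads$q1, plate$reads$q2)
  dm <- demultiplex(m$merged, fx_scheme)
  a <- dm$assignments
  w <- truth$wells
  planted_well <- paste(w$group, w$plate, w$row, w$column,
                        sep = "|")[plate$reads$.well]
  chain <- rep(NA_character_, nrow(a))
  chain[a$assigned] <- assign_chain(a$insert[a$assigned], fx_ref)
  correct <- a$assigned & a$well_id == planted_well &
    chain == plate$reads$.chain
  expect_gte(mean(correct, na.rm = FALSE), 0.99)
  # chain labels alone are near-perfect among assigned reads
  expect_gte(mean(chain[a$assigned] == plate$reads$.chain[a$assigned]), 0.995)
})

test_that("optional indel noise changes read lengths but the pipeline absorbs it", {
  truth <- plate_truth(fx_ref, fx_scheme, clones = fx_clones[1:2, ],
                       error_rate = 0, indel_rate = 0.002, depth = 30,
                       seed = 6)
  plate <- simulate_tcr_plate(truth)
  m <- merge_pairs(plate$reads$r1, plate$reads$r2)
  lens <- nchar(m$merged[m$status == "merged"])
  expect_gt(length(unique(lens)), 1)  # indels shift amplicon lengths
  res <- process_plate_reads(m$merged[m$status == "merged"], fx_scheme, fx_ref)
  expect_gte(score_plate_recovery(truth, res$cells), 0.95)
})

test_that("FASTQ round trip preserves reads and qualities", {
  truth <- plate_truth(fx_ref, fx_scheme, n_wells = 4, error_rate = 0,
                       depth = 3, seed = 2)
  plate <- simulate_tcr_plate(truth)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_plate_fastq(plate, r1, r2)
  back <- read_fastq(r1)
  expect_identical(back$seq, plate$reads$r1)
  expect_identical(back$qual, plate$reads$q1)
  expect_identical(read_fastq(r2)$seq, plate$reads$r2)
})
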