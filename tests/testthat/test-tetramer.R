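test_that("fraction frequencies normalise per fraction", {
  tab <- clonotype_count_table(c(A = 2L, B = 2L), c(A = 1L, B = 1L))
  f <- fraction_frequencies(tab)
  expect_equal(f$freq_pos[f$clonotype_id == "A"], 0.5)
  expect_equal(f$freq_neg[f$clonotype_id == "A"], 0.5)
  expect_equal(sum(f$freq_pos), 1)
  expect_equal(sum(f$freq_neg), 1)
  expect_error(fraction_frequencies(clonotype_count_table(c(A = 1L), c(A = 0L))),
               "fractions")
})

test_that("the enrichment filter applies the worked threshold arithmetic", {
  # n_pos = 5/100 vs n_neg = 0/100 with pseudocount 1: fold 5.05 -> pass
  tab <- clonotype_count_table(c(hit = 5L, rest = 95L),
                               c(hit = 0L, rest = 100L))
  hits <- select_enriched(tab, min_cells = 3, min_fold = 5, pseudocount = 1)
  expect_true("hit" %in% hits$clonotype_id)
  expect_equal(hits$fold[hits$clonotype_id == "hit"],
               0.05 / (1 / 101), tolerance = 1e-12)

  # two positive cells fail the size rule regardless of fold
  tab2 <- clonotype_count_table(c(hit = 2L, rest = 98L),
                                c(hit = 0L, rest = 100L))
  expect_false("hit" %in% select_enriched(tab2)$clonotype_id)

  # 10/100 vs 3/100 without pseudocount: fold 3.33 -> fail
  tab3 <- clonotype_count_table(c(hit = 10L, rest = 90L),
                                c(hit = 3L, rest = 97L))
  expect_false("hit" %in%
                 select_enriched(tab3, pseudocount = 0)$clonotype_id)
})

test_that("the enrichment filter matches brute force and is threshold-monotone", {
  withr::local_seed(7)
  for (trial in 1:200) {
    n <- sample(1:50, 1)
    ids <- sprintf("c%02d", seq_len(n))
    tab <- clonotype_count_table(
      setNames(stats::rpois(n, 3), ids),
      setNames(stats::rpois(n, 3), ids))
    if (tab$N_pos == 0 || tab$N_neg == 0) next
    mc <- sample(1:5, 1); mf <- stats::runif(1, 1, 10)
    pc <- sample(c(0, 1), 1)
    got <- sort(select_enriched(tab, mc, mf, pc)$clonotype_id)
    expect_identical(got, brute_enriched_ids(tab, mc, mf, pc))
    # monotonicity: raising either threshold never adds lineages
    expect_lte(nrow(select_enriched(tab, mc + 1, mf, pc)), length(got))
    expect_lte(nrow(select_enriched(tab, mc, mf * 2, pc)), length(got))
  }
})

test_that("simulated tetramer fractions conserve totals and respect limits", {
  freqs <- setNames(rep(0.1, 10), letters[1:10])
  tab <- simulate_tetramer_fractions(freqs, specific = c("a", "b"),
                                     capture_p = 1, leak_p = 0,
                                     n_pos = 500, n_neg = 500, seed = 4)
  expect_equal(tab$N_pos, 500)
  expect_equal(tab$N_neg, 500)
  pos_ids <- tab$rows$clonotype_id[tab$rows$n_pos > 0]
  expect_true(all(pos_ids %in% c("a", "b")))
  expect_error(simulate_tetramer_fractions(numeric(0), "a"), "empty")

  # frequencies recovered within multinomial noise of the planted weights
  tab2 <- simulate_tetramer_fractions(freqs, specific = c("a", "b"),
                                      capture_p = 0.9, leak_p = 0.01,
                                      n_pos = 4000, n_neg = 4000, seed = 5)
  f <- fraction_frequencies(tab2)
  w_pos <- freqs * ifelse(names(freqs) %in% c("a", "b"), 0.9, 0.01)
  w_pos <- w_pos / sum(w_pos)
  sds <- sqrt(w_pos * (1 - w_pos) / 4000)
  expect_true(all(abs(f$freq_pos[match(names(freqs), f$clonotype_id)] - w_pos)
                  < 5 * sds + 1e-9))
})

test_that("planted expanded specific lineages pass the downstream filter", {
  # 5 expanded specific clonotypes at 2% each, 45 bystanders sharing the rest
  freqs <- c(setNames(rep(0.02, 5), paste0("spec", 1:5)),
             setNames(rep(0.9 / 45, 45), paste0("bys", 1:45)))
  pass <- logical(100)
  spec_called <- 0; spec_total <- 0
  for (s in 1:100) {
    tab <- simulate_tetramer_fractions(freqs, paste0("spec", 1:5),
                                       capture_p = 0.9, leak_p = 0.01,
                                       n_pos = 2000, n_neg = 2000, seed = s)
    hits <- select_enriched(tab, min_cells = 3, min_fold = 5, pseudocount = 1)
    planted3 <- tab$rows$clonotype_id[
      tab$rows$n_pos >= 3 & grepl("^spec", tab$rows$clonotype_id)]
    pass[s] <- all(planted3 %in% hits$clonotype_id)
    spec_total <- spec_total + length(planted3)
    spec_called <- spec_called + sum(planted3 %in% hits$clonotype_id)
  }
  expect_gte(mean(pass), 0.95)
  expect_gte(spec_called / spec_total, 0.95)
})

test_that("motif share fractions are exact", {
  enr <- data.frame(clonotype_id = letters[1:8],
                    j_alpha = c(rep("TRAJ7", 3), rep("TRAJ21", 5)))
  ms <- motif_share(enr, function(d) d$j_alpha == "TRAJ7")
  expect_equal(ms$fraction, 0.375)
  expect_equal(motif_share(enr, rep(TRUE, 8))$fraction, 1)
  expect_error(motif_share(enr[0, ], function(d) TRUE), "no enriched")
})

test_that("count tables survive a CSV round trip", {
  tab <- clonotype_count_table(c(A = 5L, B = 1L), c(A = 0L, B = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(back$rows, tab$rows)
  expect_equal(c(back$N_pos, back$N_neg), c(tab$N_pos, tab$N_neg))
})
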