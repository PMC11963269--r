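test_that("flank extraction does exact coordinate bookkeeping", {
  g <- with_seed_test(41, c(chr1 = random_dna(200000)))
  hit <- data.frame(genome_id = "chr1", start = 50000L, end = 50476L)
  fl <- extract_flanks(g, hit, window = 10000)
  expect_identical(nchar(fl$seq), 20477L)
  expect_false(fl$left_truncated || fl$right_truncated)
  ## round trip window -> genome is the identity
  expect_identical(substr(fl$seq, fl$rt_start, fl$rt_end),
                   substr(g[[1]], hit$start, hit$end))
  expect_identical(fl$rt_start + fl$offset, hit$start)

  hit2 <- data.frame(genome_id = "chr1", start = 2000L, end = 2476L)
  fl2 <- extract_flanks(g, hit2, window = 10000)
  expect_true(fl2$left_truncated)
  expect_identical(fl2$rt_start, 2000L)  # only 1,999 bp of left flank
})

test_that("identical LTR pairs are found exactly; diverged pairs are not", {
  ltr <- with_seed_test(42, random_dna(600))
  mid <- with_seed_test(43, random_dna(3000))
  left <- with_seed_test(44, random_dna(2000))
  right <- with_seed_test(45, random_dna(2000))
  win <- paste0(left, ltr, mid, ltr, right)
  rt_s <- 2000 + 600 + 1000
  pair <- find_ltr_pair(win, rt_s, rt_s + 476)
  expect_identical(pair$ltr5, c(2001L, 2600L))
  expect_identical(pair$ltr3, c(2001L + 600L + 3000L, 2600L + 600L + 3000L))
  expect_identical(pair$length, 600L)

  ## diverged copy: substitutions every ~80 bp keep every exact run < 100
  ltr2 <- ltr
  for (p in seq(60, 600, by = 80)) {
    old <- substr(ltr2, p, p)
    substr(ltr2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  win2 <- paste0(left, ltr, mid, ltr2, right)
  ## verify the construction: longest common run is indeed < 100
  runs <- prareminer:::.maximal_exact_repeats(win2, 1, rt_s - 1,
                                              rt_s + 477, nchar(win2))
  expect_lt(max(runs$len), 100)
  expect_null(find_ltr_pair(win2, rt_s, rt_s + 476, min_ltr = 100))

  ## windows with no repeat at all
  expect_null(find_ltr_pair(with_seed_test(46, random_dna(5000)),
                            2000, 2476))
  expect_error(find_ltr_pair(win, rt_s, rt_s + 476, min_ltr = 500,
                             max_ltr = 100), "min_ltr")
})

test_that("insertion-repeat checks accept only identical flanks", {
  g <- c(chr = paste0("ACGTA", strrep("G", 100), "ACGTA",
                      strrep("C", 20)))
  expect_identical(check_insertion_repeat(g, c(6, 105), 5)$tsd, "ACGTA")
  g2 <- c(chr = paste0("ACGTA", strrep("G", 100), "ACGTT",
                       strrep("C", 20)))
  res <- check_insertion_repeat(g2, c(6, 105), 5)
  expect_null(res$tsd)
  expect_false(res$edge)
  edge <- check_insertion_repeat(g, c(1, 105), 5)
  expect_null(edge$tsd)
  expect_true(edge$edge)
})

test_that("elements are rebuilt exactly and decoys rejected with reasons", {
  scn <- get_small_scenario()
  q <- get_queries()
  hits <- find_rt_hits(scn$genomes, q, min_score = 150)
  cand <- assign_lineage(hits, get_panel())
  retand <- cand[cand$lineage == "Retand", ]
  built <- build_elements(scn$genomes, retand)

  truth_el <- scn$truth[scn$truth$feature == "element", ]
  eligible <- truth_el[truth_el$is_prare_eligible, ]
  expect_identical(nrow(built$elements), nrow(eligible))
  expect_identical(
    paste(built$elements$genome_id, built$elements$start,
          built$elements$end),
    paste(eligible$genome_id, eligible$start, eligible$end))
  ## every invariant holds literally on the sequences
  for (i in seq_len(nrow(built$elements))) {
    e <- built$elements[i, ]
    g <- scn$genomes[[e$genome_id]]
    expect_identical(substr(g, e$ltr5_start, e$ltr5_end),
                     substr(g, e$ltr3_start, e$ltr3_end))
    expect_identical(substr(g, e$start - 5, e$start - 1),
                     substr(g, e$end + 1, e$end + 5))
    expect_true(e$rt_start >= e$internal_start &&
                  e$rt_end <= e$internal_end)
  }
  ## diverged and truncated plantings fail element reconstruction
  expect_true(all(built$rejected$reason %in%
                    c("no-ltr-pair", "no-tsd", "edge")))
  expect_identical(nrow(built$rejected),
                   sum(truth_el$type %in% c("diverged", "truncated")))

  ## output is independent of hit order
  built2 <- build_elements(scn$genomes,
                           retand[rev(seq_len(nrow(retand))), ])
  expect_identical(built$elements, built2$elements)
})

test_that("reverse-strand elements carry the same oriented LTR sequence
           as their forward twins", {
  q <- get_queries()
  spec <- element_spec(ltr_length = 400, internal_length = 9000,
                       rt_protein = q[[1]])
  cas <- build_cassette(spec, rng_seed = 8, profiles = get_profiles())
  g0 <- with_seed_test(48, c(chr1 = random_dna(60000)))
  pf <- plant_element(g0, cas, position = 12000, strand = "+", id = "f")
  pr <- plant_element(pf$genome, cas, position = 45000, strand = "-",
                      id = "r")
  hits <- find_rt_hits(pr$genome, q, min_score = 150)
  built <- build_elements(pr$genome, hits)
  expect_identical(nrow(built$elements), 2L)
  expect_identical(built$elements$ltr_seq[1], built$elements$ltr_seq[2])
  expect_identical(sort(built$elements$strand), c("+", "-"))
})
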