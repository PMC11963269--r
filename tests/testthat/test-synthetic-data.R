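test_that("planting an element does exact length and TSD bookkeeping", {
  q <- get_queries()
  spec <- element_spec(ltr_length = 600, internal_length = 10000,
                       tsd_length = 5, rt_protein = q[[1]])
  g <- with_seed_test(1, c(chrA = random_dna(10000)))
  pl <- plant_element(g, spec, position = 4000, rng_seed = 9)
  expect_identical(nchar(pl$genome[[1]]), 10000L + 2L * 600L + 10000L + 5L)

  t <- pl$truth
  el <- t[t$feature == "element", ]
  l5 <- t[t$feature == "ltr5", ]
  l3 <- t[t$feature == "ltr3", ]
  ## the 5 bases immediately 5' of the 5'LTR equal those 3' of the 3'LTR
  expect_identical(substr(pl$genome[[1]], el$start - 5, el$start - 1),
                   substr(pl$genome[[1]], el$end + 1, el$end + 5))
  ## identical LTR copies by construction
  expect_identical(substr(pl$genome[[1]], l5$start, l5$end),
                   substr(pl$genome[[1]], l3$start, l3$end))
  ## spans nested inside the element span
  inner <- t[!t$feature %in% c("element", "tsd_left", "tsd_right"), ]
  expect_true(all(inner$start >= el$start & inner$end <= el$end))
})

test_that("planted coding features translate cleanly and match the truth", {
  se <- get_single_element()
  g <- se$genome[[1]]
  t <- se$truth
  q <- get_queries()
  rt <- t[t$feature == "domain" & t$name == "RT", ]
  expect_identical(
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(g, rt$start, rt$end)))),
    unname(q[[2]]))
  for (i in which(t$feature == "orf")) {
    dna <- substr(g, t$start[i], t$end[i])
    if (t$strand[i] == "-") dna <- revcomp(dna)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
  ## tandem arrays are exact and maximal (guard bases on both sides)
  for (i in which(t$feature == "tandem_array")) {
    p <- t$period[i]; s <- t$start[i]; e <- t$end[i]
    body <- substr(g, s, e)
    unit <- substr(body, 1, p)
    expect_identical(body, strrep(unit, t$copies[i]))
    expect_false(substr(g, s - 1, s - 1) == substr(g, s - 1 + p, s - 1 + p))
    expect_false(substr(g, e + 1, e + 1) == substr(g, e + 1 - p, e + 1 - p))
  }
})

test_that("ltr_divergence and decoy constructions behave as specified", {
  q <- get_queries()
  spec <- element_spec(ltr_length = 400, internal_length = 9000,
                       rt_protein = q[[1]], ltr_divergence = 6)
  cas <- build_cassette(spec, rng_seed = 2, profiles = get_profiles())
  l5 <- substr(cas$seq, 1, 400)
  l3 <- substr(cas$seq, 9401, 9800)
  subs <- sum(strsplit(l5, "")[[1]] != strsplit(l3, "")[[1]])
  expect_true(subs >= 6 && subs <= 12)  # up to 6 per copy, may overlap
  expect_identical(nchar(l5), nchar(l3))

  base <- build_cassette(element_spec(ltr_length = 400,
                                      internal_length = 9000,
                                      rt_protein = q[[1]]),
                         rng_seed = 2, profiles = get_profiles())
  solo <- prareminer:::solo_cassette(base)
  expect_identical(nchar(solo$seq), 400L)
  trunc <- prareminer:::truncate_cassette(base)
  expect_identical(nchar(trunc$seq), 9000L + 400L)
  expect_false("ltr5" %in% trunc$features$feature)
})

test_that("scenarios are deterministic, truth-complete and feasible-checked", {
  cfg <- small_config()
  scn1 <- get_small_scenario()
  scn2 <- generate_scenario(cfg, rng_seed = 11, profiles = get_profiles(),
                            panel = get_panel())
  expect_identical(scn1$genomes, scn2$genomes)
  expect_identical(scn1$truth, scn2$truth)

  el <- scn1$truth[scn1$truth$feature == "element", ]
  expect_identical(sum(el$is_prare_eligible), 6L)
  expect_identical(sum(el$type == "intact"), 6L)
  expect_false(any(el$is_prare_eligible[el$type != "intact"]))
  solo <- scn1$truth[scn1$truth$feature == "solo_ltr", ]
  expect_identical(nrow(solo), 1L)
  expect_false(any(solo$is_prare_eligible))

  ## byte-identical FASTA on rerun
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(scn1, d1)
  write_scenario(scn2, d2)
  expect_identical(readLines(file.path(d1, "genomes.fasta")),
                   readLines(file.path(d2, "genomes.fasta")))

  expect_error(
    generate_scenario(scenario_config(genome_length = 100000,
                                      n_intact = 12),
                      rng_seed = 1, profiles = get_profiles(),
                      panel = get_panel()),
    "infeasible")
})

test_that("infeasible feature packing and bad positions are rejected", {
  q <- get_queries()
  expect_error(build_cassette(
    element_spec(ltr_length = 300, internal_length = 2000,
                 rt_protein = q[[1]]),
    rng_seed = 1, profiles = get_profiles()), "too small")
  spec <- element_spec(rt_protein = q[[1]])
  g <- with_seed_test(2, c(chrA = random_dna(1000)))
  expect_error(plant_element(g, spec, position = 5000), "out of range")
})

test_that("reverse-strand planting mirrors the forward construction", {
  q <- get_queries()
  spec <- element_spec(ltr_length = 350, internal_length = 8800,
                       rt_protein = q[[3]])
  cas <- build_cassette(spec, rng_seed = 13, profiles = get_profiles())
  g <- with_seed_test(14, c(chr1 = random_dna(25000)))
  fwd <- plant_element(g, cas, position = 10000, strand = "+", id = "f")
  rev <- plant_element(g, cas, position = 10000, strand = "-", id = "r")
  ef <- fwd$truth[fwd$truth$feature == "element", ]
  er <- rev$truth[rev$truth$feature == "element", ]
  sf <- substr(fwd$genome[[1]], ef$start, ef$end)
  sr <- substr(rev$genome[[1]], er$start, er$end)
  ## identical element content up to the two site-dependent guard bases
  a <- strsplit(sf, "")[[1]]
  b <- strsplit(revcomp(sr), "")[[1]]
  expect_lte(sum(a != b), 2L)
  ## feature strands flip, spans mirror
  rt_f <- fwd$truth[fwd$truth$name == "RT", ]
  rt_r <- rev$truth[rev$truth$name == "RT", ]
  expect_identical(rt_f$strand, "+")
  expect_identical(rt_r$strand, "-")
  expect_identical(rt_f$start - ef$start, er$end - rt_r$end)
})
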