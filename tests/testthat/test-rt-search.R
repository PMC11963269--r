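test_that("six-frame translation follows the standard code and symmetry", {
  fr <- six_frame_translate("ATGGCA")
  fwd0 <- fr[fr$strand == "+" & fr$frame == 0, ]
  expect_identical(fwd0$protein, "MA")
  expect_identical(six_frame_translate("TAA")$protein[1], "*")
  expect_error(six_frame_translate(""), "empty")
  ## N-containing codons give X
  expect_identical(six_frame_translate("ATGNNN")$protein[1], "MX")

  cds <- with_seed_test(3, encode_protein(random_protein(40)))
  f1 <- six_frame_translate(cds)
  f2 <- six_frame_translate(revcomp(cds))
  expect_identical(f1$protein[f1$strand == "+" & f1$frame == 0],
                   f2$protein[f2$strand == "-" & f2$frame == 0])
})

test_that("planted RT domains are recovered with exact coordinates", {
  se <- get_single_element()
  q <- get_queries()
  hits <- find_rt_hits(se$genome, q, min_score = 150)
  rt <- se$truth[se$truth$name == "RT", ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, rt$start)
  expect_identical(hits$end, rt$end)
  expect_identical(hits$query_id, "Gret1")
  expect_identical(hits$end - hits$start + 1L, 3L * hits$length_aa)
  expect_false(grepl("[*]", hits$protein))

  ## strand symmetry: reverse-complementing the genome mirrors the hit
  n <- nchar(se$genome[[1]])
  rcg <- stats::setNames(revcomp(se$genome[[1]]), "chr1")
  h2 <- find_rt_hits(rcg, q, min_score = 150)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$start, n - hits$end + 1L)
  expect_identical(h2$end, n - hits$start + 1L)
  expect_identical(h2$strand, "-")
  expect_identical(h2$score, hits$score)
})

test_that("random background yields no hits at the default threshold", {
  g <- with_seed_test(17, c(chrR = random_dna(100000)))
  hits <- find_rt_hits(g, get_queries(), min_score = 150)
  expect_identical(nrow(hits), 0L)
})

test_that("RT regions with an internal stop codon are rejected", {
  se <- get_single_element()
  rt <- se$truth[se$truth$name == "RT", ]
  g <- se$genome[[1]]
  ## overwrite an in-frame codon in the middle of the RT domain with TAA
  mid <- rt$start + 3 * 70
  broken <- g
  substr(broken, mid, mid + 2) <- "TAA"
  hits <- find_rt_hits(stats::setNames(broken, "chr1"), get_queries(),
                       min_score = 150)
  expect_identical(nrow(hits), 0L)
})

test_that("scaffold-named sequences can be excluded from the search", {
  se <- get_single_element()
  g <- c(se$genome, stats::setNames(se$genome[[1]], "scaffold_1"))
  all_hits <- find_rt_hits(g, get_queries(), min_score = 150)
  expect_identical(sort(unique(all_hits$genome_id)),
                   c("chr1", "scaffold_1"))
  chr_hits <- find_rt_hits(g, get_queries(), min_score = 150,
                           seqname_pattern = "^chr")
  expect_identical(unique(chr_hits$genome_id), "chr1")
})

test_that("score calibration is deterministic and monotone in background", {
  q <- get_queries()[1]
  s1 <- calibrate_min_score(q, background_length = 1e6, target_rate = 0,
                            rng_seed = 4)
  s2 <- calibrate_min_score(q, background_length = 1e6, target_rate = 0,
                            rng_seed = 4)
  expect_identical(s1, s2)
  s_big <- calibrate_min_score(q, background_length = 2e6, target_rate = 0,
                               rng_seed = 4)
  expect_gte(s_big, s1)
  ## null scores sit far below both the default threshold and planted scores
  expect_lt(s1, 150)
  expect_error(calibrate_min_score(q, 1e6, target_rate = -1), "target_rate")
})

test_that("the seeded search agrees with an unseeded full-DP scan", {
  ## windowed/seeded search vs exhaustive per-frame local alignment
  q <- get_queries()[c(1, 3)]
  mat <- {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    get("BLOSUM62", envir = environment())
  }
  for (case in 1:10) {
    g <- with_seed_test(100 + case, {
      bg <- random_dna(3000)
      if (case %% 2 == 0) {
        ## plant a mutated copy of a query (borderline homology)
        prot <- mutate_fraction(q[[1]], 0.10, protect = 3)
        ins <- encode_protein(prot, add_start = FALSE, add_stop = FALSE)
        paste0(substr(bg, 1, 1500), ins, substr(bg, 1501, 3000))
      } else bg
    })
    hits <- find_rt_hits(c(chr = g), q, min_score = 150)
    frames <- six_frame_translate(g)
    best <- 0
    for (fi in seq_len(nrow(frames))) {
      for (qq in q) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(qq),
          Biostrings::AAString(frames$protein[fi]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 11, gapExtension = 1)
        best <- max(best, Biostrings::score(aln))
      }
    }
    if (nrow(hits)) {
      expect_identical(max(hits$score), best)
    } else {
      ## either nothing scores >= 150 anywhere, or the best full-DP match
      ## fails the completeness filter; both mean "no complete RT domain"
      expect_true(best < 150 || case %% 2 == 0)
    }
  }
})

test_that("the local-alignment engine matches a plain-R DP oracle", {
  mat <- {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    get("BLOSUM62", envir = environment())
  }
  for (case in 1:20) {
    qp <- with_seed_test(200 + case, random_protein(25))
    sp <- with_seed_test(300 + case, {
      s <- random_protein(70)
      if (case %% 2 == 0) {
        at <- sample(40, 1)
        paste0(substr(s, 1, at - 1), mutate_fraction(qp, 0.1),
               substr(s, at + 25, 70))
      } else s
    })
    o <- oracle_sw(qp, sp, mat)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(qp), Biostrings::AAString(sp), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    expect_equal(max(0, Biostrings::score(aln)), o$score)
    if (o$score > 0) {
      expect_identical(Biostrings::end(Biostrings::subject(aln)), o$end_j)
    }
  }
})
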