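test_that("consensus and conservation follow the documented column rules", {
  aln <- c(a = "MKVAW", b = "MKVAW", c = "MKVAW")
  expect_identical(consensus_sequence(aln), "MKVAW")
  ## 6 x A vs 4 x V -> A; 5/5 tie -> residue earlier in the fixed order
  col_aln <- c(rep("A", 6), rep("V", 4))
  expect_identical(consensus_sequence(stats::setNames(col_aln,
                                                      paste0("s", 1:10))),
                   "A")
  tie <- c(rep("V", 5), rep("A", 5))
  expect_identical(consensus_sequence(stats::setNames(tie,
                                                      paste0("s", 1:10))),
                   "A")
  ## columns with >= 50% gaps are dropped from the consensus
  gappy <- c(a = "M-K", b = "M-K", c = "MAK", d = "M-K")
  expect_identical(consensus_sequence(gappy), "MK")
  expect_error(consensus_sequence(character(0)), "empty")

  prof <- conservation_profile(c(a = "MKV", b = "MKV", c = "MKV"))
  expect_true(all(prof$bins$max_freq == 1))
  expect_true(all(prof$bins$bin == ">45%"))
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-12))

  ## a 40% column falls in the >35% bin; bins follow the max residue
  mixed <- c(s1 = "G", s2 = "G", s3 = "G", s4 = "G", s5 = "A",
             s6 = "C", s7 = "D", s8 = "E", s9 = "F", s10 = "H")
  p2 <- conservation_profile(mixed)
  expect_identical(p2$bins$residue, "G")
  expect_equal(p2$bins$max_freq, 0.4)
  expect_identical(p2$bins$bin, ">35%")
})

test_that("conservation frequencies ignore sequence order", {
  aln <- with_seed_test(81, stats::setNames(
    vapply(1:6, function(i) random_protein(30), character(1)),
    paste0("s", 1:6)))
  p1 <- conservation_profile(aln)
  p2 <- conservation_profile(aln[c(4, 2, 6, 1, 5, 3)])
  expect_identical(p1$freq, p2$freq)
  expect_identical(p1$bins, p2$bins)
})

test_that("cluster summaries use exact min/max and half-up rounded means", {
  one <- data.frame(ltr_bp = 500, internal_bp = 9000, pol3ltr_bp = 4000)
  s1 <- summarize_clusters(one)
  expect_identical(unname(s1$ltr), c(500, 500, 500))
  two <- data.frame(ltr_bp = c(500, 501), internal_bp = c(9000, 9001),
                    pol3ltr_bp = c(4000, 4001))
  s2 <- summarize_clusters(two)
  expect_identical(unname(s2$ltr), c(500, 501, 501))  # 500.5 rounds up
  def <- data.frame(ltr_bp = 1:3, internal_bp = 1:3, pol3ltr_bp = 1:3,
                    gag = c("NO", "YES", "NO"), ap = c("YES", "YES", "NO"),
                    rh = "YES", int = "YES", tandem_arrays = c(0, 2, 1))
  s3 <- summarize_clusters(def)
  expect_identical(s3$n_defective, 2L)
  expect_identical(as.integer(s3$defective[["GAG"]]), 1L)
  expect_identical(as.integer(s3$defective[["GAG+AP"]]), 1L)
  expect_identical(s3$total_tandem_arrays, 3)
})

test_that("the packaged cluster reference table loads with 63 rows", {
  tab <- retand_cluster_table()
  expect_identical(nrow(tab), 63L)
  expect_true(all(c("cluster", "copy_number", "ltr_bp", "internal_bp",
                    "pol3ltr_bp", "gag", "ap", "rh", "int", "trp28",
                    "tandem_arrays") %in% names(tab)))
  expect_true(all(tab$ltr_bp > 0 & tab$internal_bp > 0 &
                    tab$pol3ltr_bp > 0))
})

test_that("pipeline reports round-trip through GFF3 and rerun
           byte-identically", {
  run <- get_small_run()
  scn <- get_small_scenario()
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  write_run(run, scn$genomes, d1)
  write_run(run, scn$genomes, d2)
  for (f in c("elements.tsv", "cluster_summary.tsv", "annotations.tsv",
              "rt_hits.tsv", "elements.gff3", "annotations.gff3",
              "cluster_tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  ## GFF3 round trip recovers the written element coordinates exactly
  gr <- rtracklayer::import(file.path(d1, "elements.gff3"))
  el <- gr[gr$type == "element"]
  expect_identical(sort(BiocGenerics::start(el)), sort(run$prare$start))
  expect_identical(sort(BiocGenerics::end(el)), sort(run$prare$end))
  ann <- rtracklayer::import(file.path(d1, "annotations.gff3"))
  ann_tsv <- utils::read.delim(file.path(d1, "annotations.tsv"))
  expect_identical(length(ann), nrow(ann_tsv))
  expect_identical(sort(BiocGenerics::start(ann)), sort(ann_tsv$start))
})

test_that("the cluster consensus tree covers clusters and references", {
  run <- get_small_run()
  expect_false(is.null(run$tree))
  tips <- run$tree$tree$tip.label
  expect_true(all(paste0("Retand|", names(get_queries())) %in% tips))
  expect_true(any(grepl("^C0", tips)))
  expect_true(all(run$tree$supports >= 0 & run$tree$supports <= 25))
})

test_that("an empty genome set produces an empty report with a warning", {
  expect_warning(run0 <- run_pipeline(character(0), panel = get_panel(),
                                      profiles = get_profiles()),
                 "empty")
  expect_identical(nrow(run0$hits), 0L)
  expect_identical(nrow(run0$prare), 0L)
  expect_null(run0$summary)
})

test_that("scenario configs round-trip through the key-value file format", {
  cfg <- scenario_config(n_genomes = 2, genome_length = 123456,
                         n_intact = 7, seqname_prefix = "chr")
  p <- tempfile()
  write_scenario_config(cfg, p)
  back <- read_scenario_config(p)
  expect_identical(unclass(back), unclass(cfg))
  expect_error(read_scenario_config(
    textConnection("this is not = a = config")), "malformed")
})
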