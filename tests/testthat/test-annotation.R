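test_that("ORF finding matches a brute-force six-frame oracle", {
  for (case in 1:50) {
    seq <- with_seed_test(1000 + case, {
      bg <- random_dna(600)
      if (case %% 2 == 0) {
        orf <- encode_protein(random_protein(sample(40:90, 1)))
        at <- sample(250, 1)
        ## in-frame stop right before the ORF keeps it maximal
        paste0(substr(bg, 1, at), "TAA", orf,
               substr(bg, at + 1, 600))
      } else bg
    })
    got <- find_orfs(seq, min_len = 90)
    want <- oracle_orfs(seq, min_len = 90)
    expect_identical(got[, c("start", "end", "strand", "length")], want)
  }
})

test_that("planted ORFs and domains are recovered with exact spans", {
  se <- get_single_element()
  el <- se$row
  a <- annotate_element(se$genome, el, get_profiles())
  t <- se$truth
  shift <- el$start - 1
  ## every planted ORF appears with its exact local span and orientation
  for (i in which(t$feature == "orf")) {
    loc_s <- t$start[i] - shift
    loc_e <- t$end[i] - shift
    j <- which(a$orfs$start == loc_s & a$orfs$end == loc_e)
    expect_length(j, 1)
    expect_identical(a$orfs$orientation[j],
                     ifelse(t$strand[i] == "+", "sense", "antisense"))
  }
  ## planted domains are hit in the right ORFs
  doms <- unlist(lapply(a$orfs$domains, function(d) d$name))
  for (nm in c("GAG", "AP", "RT", "RH", "INT", "TRP28")) {
    expect_true(nm %in% doms)
  }
  expect_identical(a$autonomy$class, "complete")
  expect_identical(a$gag_pol_layout, "two-ORF")
  ## planted tandem arrays with exact spans
  planted <- t[t$feature == "tandem_array", ]
  for (i in seq_len(nrow(planted))) {
    j <- which(a$tandem_arrays$start == planted$start[i] - shift &
                 a$tandem_arrays$end == planted$end[i] - shift)
    expect_length(j, 1)
    expect_identical(a$tandem_arrays$period[j], planted$period[i])
    expect_identical(a$tandem_arrays$copies[j], planted$copies[i])
  }
  ## POL-3'LTR region: from the pol ORF stop to the 3'LTR start
  pol_orf <- t[t$feature == "orf" & t$name == "pol", ]
  ltr3 <- t[t$feature == "ltr3", ]
  expect_identical(a$pol_3ltr$length,
                   as.integer(ltr3$start - pol_orf$end - 1))
})

test_that("annotation is orientation-symmetric under reverse-complement", {
  se <- get_single_element()
  g <- se$genome[[1]]
  n <- nchar(g)
  el <- se$row
  rc <- stats::setNames(revcomp(g), "chr1")
  el_rc <- el
  el_rc$start <- n - se$row$end + 1L
  el_rc$end <- n - se$row$start + 1L
  el_rc$strand <- "-"
  a_fwd <- annotate_element(se$genome, el, get_profiles())
  a_rc <- annotate_element(rc, el_rc, get_profiles())
  ## local sense coordinates must be identical in both presentations
  expect_identical(a_fwd$orfs[, c("start", "end", "orientation")],
                   a_rc$orfs[, c("start", "end", "orientation")])
  expect_identical(a_fwd$tandem_arrays$start, a_rc$tandem_arrays$start)
  expect_identical(a_fwd$pol_3ltr, a_rc$pol_3ltr)
})

test_that("short ORFs are kept only when they carry a TRP28 domain", {
  profiles <- get_profiles()
  trp <- profiles$TRP28$consensus
  with_trp <- with_seed_test(61, {
    naa <- 164  # 498-bp ORF, under the 600-bp default
    p <- random_protein(naa)
    paste0(substr(p, 1, 50), trp, substr(p, 51 + nchar(trp), naa))
  })
  without <- with_seed_test(62, random_protein(164))
  mk <- function(prot) {
    with_seed_test(63, paste0(random_dna(100), "TAA", encode_protein(prot),
                              random_dna(100)))
  }
  o1 <- find_orfs(mk(with_trp), min_len = 600, profiles = profiles)
  expect_identical(nrow(o1), 1L)
  expect_true(o1$short)
  expect_identical(o1$length, 3L * 166L)
  o0 <- find_orfs(mk(without), min_len = 600, profiles = profiles)
  expect_identical(nrow(o0), 0L)
  ## no ATG on either strand -> no ORFs at all
  expect_identical(nrow(find_orfs(strrep("C", 300), min_len = 30)), 0L)
})

test_that("domain scanning maximizes at the consensus and stays silent on
           shuffled proteins", {
  profiles <- get_profiles()
  p <- profiles$TRP28
  ## consensus embedded verbatim scores the profile maximum at its offset
  host <- with_seed_test(64, random_protein(200))
  prot <- paste0(substr(host, 1, 70), p$consensus,
                 substr(host, 71 + p$width, 200))
  hits <- scan_domains(prot, profiles["TRP28"])
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 71L)
  expect_equal(hits$score, p$width * log2(0.7 * 20))
  ## two non-overlapping planted copies give two hits
  prot2 <- paste0(p$consensus, strrep("G", 30), p$consensus)
  hits2 <- scan_domains(prot2, profiles["TRP28"])
  expect_identical(nrow(hits2), 2L)
  expect_identical(hits2$start, c(1L, 31L + p$width))
  ## shuffled gag-pol-scale protein: nothing at calibrated thresholds
  shuffled <- with_seed_test(65, paste(
    sample(strsplit(paste0(prot, prot2), "")[[1]]), collapse = ""))
  expect_identical(nrow(scan_domains(shuffled, profiles)), 0L)
  ## profile wider than the protein: no hit, no error
  expect_identical(nrow(scan_domains("MKV", profiles["TRP28"])), 0L)
})

test_that("tandem-array detection matches the exhaustive oracle", {
  for (case in 1:50) {
    seq <- with_seed_test(2000 + case, {
      bg <- random_dna(300)
      if (case %% 2 == 0) {
        p <- sample(2:20, 1)
        unit <- random_dna(p)
        copies <- sample(3:8, 1)
        at <- sample(150, 1)
        paste0(substr(bg, 1, at), strrep(unit, copies),
               substr(bg, at + 1, 300))
      } else bg
    })
    got <- find_tandem_arrays(seq, min_copies = 3, max_period = 20,
                              min_span = 24)
    want <- oracle_tandems(seq, min_copies = 3, max_period = 20,
                           min_span = 24)
    expect_identical(got[, c("start", "end", "period", "copies")], want,
                     info = paste("case", case))
    expect_true(all(got$mean_identity == 1))
  }
})

test_that("homopolymers report once with the smallest period", {
  seq <- with_seed_test(71, paste0(random_dna(50), "G", strrep("A", 30),
                                   "C", random_dna(50)))
  got <- find_tandem_arrays(seq, min_span = 24)
  expect_identical(nrow(got), 1L)
  expect_identical(got$period, 1L)
  expect_identical(got$copies, 30L)
  expect_identical(got$unit, "A")
  expect_error(find_tandem_arrays("ACGT", min_period = 10, max_period = 5),
               "min_period")
})

test_that("POL-3'LTR delimitation handles layouts and edge cases", {
  mk_orfs <- function(ends, orient, doms) {
    data.frame(start = ends - 99, end = ends, orientation = orient,
               domains = I(lapply(doms, function(d)
                 data.frame(name = d, start = 1, end = 2, score = 1))))
  }
  ## two-ORF layout: measured from the pol ORF, not the gag ORF
  orfs <- mk_orfs(c(1000, 5000), c("sense", "sense"),
                  list("GAG", c("RT", "RH", "INT")))
  expect_identical(delimit_pol_3ltr(orfs, ltr3_start = 9001)$length, 4000L)
  ## pol ORF abutting the 3'LTR
  orfs2 <- mk_orfs(9000, "sense", list("RT"))
  expect_identical(delimit_pol_3ltr(orfs2, ltr3_start = 9001)$length, 0L)
  ## no pol domain -> undefined
  expect_null(delimit_pol_3ltr(mk_orfs(1000, "sense", list("GAG")), 9001))
})

test_that("autonomy classification lists exactly the missing domains", {
  mk <- function(doms) {
    data.frame(start = 1, end = 2, orientation = "sense",
               domains = I(list(data.frame(name = doms, start = 1,
                                           end = 2, score = 1))))
  }
  expect_identical(classify_autonomy(mk(c("GAG", "AP", "RT", "RH",
                                          "INT")))$class, "complete")
  d1 <- classify_autonomy(mk(c("AP", "RT", "RH", "INT")))
  expect_identical(d1$class, "defective")
  expect_identical(d1$missing, "GAG")
  d2 <- classify_autonomy(mk(c("RT", "RH", "INT")))
  expect_identical(sort(d2$missing), c("AP", "GAG"))
})
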