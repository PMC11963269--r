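## Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

get_panel <- function() memo("panel", synthetic_rt_panel())
get_queries <- function() memo("queries", rt_queries(get_panel()))
get_profiles <- function() memo("profiles", retand_domain_profiles())

## compact scenario shared by element-builder / clustering / pipeline tests
small_config <- function() {
  scenario_config(n_genomes = 1, genome_length = 340000,
                  n_families = 2, n_intact = 6, n_diverged = 2,
                  n_solo = 1, n_truncated = 1, n_nonretand = 1,
                  min_separation = 25000)
}

get_small_scenario <- function() {
  memo("small_scenario",
       generate_scenario(small_config(), rng_seed = 11,
                         profiles = get_profiles(), panel = get_panel()))
}

get_small_run <- function() {
  memo("small_run", {
    scn <- get_small_scenario()
    run_pipeline(scn$genomes, panel = get_panel(),
                 profiles = get_profiles(), min_copies_tree = 2,
                 tree_replicates = 25, rng_seed = 5)
  })
}

## one intact cassette + planted genome reused by annotation tests
get_single_element <- function() {
  memo("single_element", {
    q <- get_queries()
    spec <- element_spec(
      ltr_length = 500, internal_length = 9800, rt_protein = q[[2]],
      gag_pol_layout = "two-ORF",
      antisense_orf_lengths = c(1200, 900), antisense_trp28 = c(TRUE, FALSE),
      tandem_arrays = list(
        list(unit_length = 24, copy_count = 6, position = "pol-adjacent"),
        list(unit_length = 60, copy_count = 4, position = "ltr3-adjacent")))
    cas <- build_cassette(spec, rng_seed = 21, profiles = get_profiles())
    g <- with_seed_test(31, c(chr1 = random_dna(40000)))
    pl <- plant_element(g, cas, position = 15000, id = "el1")
    el <- pl$truth[pl$truth$feature == "element", ]
    list(spec = spec, cassette = cas, genome = pl$genome, truth = pl$truth,
         row = data.frame(genome_id = "chr1", start = el$start, end = el$end,
                          ltr_size = 500, strand = "+", element_id = "el1",
                          stringsAsFactors = FALSE))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
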