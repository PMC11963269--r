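## Whole-scenario simulation: several element families planted as identical
## copies (recently active families are near-identical in real genomes),
## plus decoys, across one or more chromosome-named genome sequences.

#' Scenario configuration
#'
#' Counts and sizes for [generate_scenario()]. Defaults describe a compact
#' test scenario; the published element-size ranges (LTR 315-1,194 bp,
#' internal 7,380-12,869 bp) bound the per-family size draws.
#'
#' @param n_genomes Number of genome sequences.
#' @param genome_length Length of each background sequence in bp.
#' @param gc Background GC content.
#' @param n_families Number of element families (each family has its own
#'   LTR, internal layout and RT query).
#' @param n_intact Total intact (PRARE-eligible) insertions, distributed
#'   round-robin over families.
#' @param n_diverged Diverged-LTR decoy insertions.
#' @param n_solo Solo-LTR decoy insertions.
#' @param n_truncated 5'-truncated decoy insertions.
#' @param n_nonretand Non-Retand RT decoy insertions (naked coding regions
#'   from outgroup panel lineages).
#' @param tsd_length TSD length for intact/diverged/solo plantings.
#' @param ltr_range,internal_range Per-family size draw ranges in bp.
#' @param min_separation Minimum bp between consecutive insertion points
#'   (keeps each element's 10-kb flank windows free of its neighbours).
#' @param margin Minimum bp between an insertion point and a sequence end.
#' @param seqname_prefix Sequence-name prefix (`"chr"` marks
#'   chromosome-level sequences for the scaffold filter).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_genomes = 1, genome_length = 600000, gc = 0.5,
                            n_families = 3, n_intact = 12, n_diverged = 3,
                            n_solo = 2, n_truncated = 2, n_nonretand = 2,
                            tsd_length = 5,
                            ltr_range = c(315, 1194),
                            internal_range = c(7380, 12869),
                            min_separation = 25000, margin = 2000,
                            seqname_prefix = "chr") {
  cfg <- list(n_genomes = as.integer(n_genomes),
              genome_length = as.integer(genome_length), gc = gc,
              n_families = as.integer(n_families),
              n_intact = as.integer(n_intact),
              n_diverged = as.integer(n_diverged),
              n_solo = as.integer(n_solo),
              n_truncated = as.integer(n_truncated),
              n_nonretand = as.integer(n_nonretand),
              tsd_length = as.integer(tsd_length),
              ltr_range = as.integer(ltr_range),
              internal_range = as.integer(internal_range),
              min_separation = as.integer(min_separation),
              margin = as.integer(margin),
              seqname_prefix = seqname_prefix)
  stopifnot(cfg$n_genomes >= 1, cfg$genome_length >= 1, cfg$n_families >= 1)
  structure(cfg, class = "scenario_config")
}

#' Read / write a scenario configuration as a key-value text file
#'
#' Plain `key = value` lines (TOML-like); vectors are comma-separated.
#' @param path File path.
#' @return `read_scenario_config()` returns a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    val <- strsplit(p[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(val))
    args[[p[1]]] <- if (!anyNA(num)) num else val
  }
  do.call(scenario_config, args)
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste(k, "=", paste(config[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## exact DNA length of the gag-pol coding block (insulators + ORFs), which
## is deterministic given layout, domain widths and linker length
.coding_block_length <- function(layout, missing, rt_len, linker, profiles) {
  doms <- setdiff(CORE_DOMAINS, missing)
  width <- function(nm) if (nm == "RT") rt_len else nchar(profiles[[nm]]$consensus)
  piece <- function(names) {
    naa <- sum(vapply(names, width, numeric(1))) + linker * (length(names) + 1)
    9L + 3L * naa   # TAA insulator + ATG + codons + stop
  }
  if (layout == "one-ORF" || "GAG" %in% missing) {
    piece(doms)
  } else {
    piece("GAG") + 12L + piece(setdiff(doms, "GAG"))
  }
}

#' Generate a synthetic scenario with ground truth
#'
#' Builds `n_families` element cassettes, plants intact copies and decoys
#' at well-separated positions on random background sequences, and returns
#' the genomes together with one truth row per planted feature. Intact
#' plantings are flagged `is_prare_eligible = TRUE`; all decoys `FALSE`.
#' Output is deterministic in `(config, rng_seed)`.
#'
#' @param config A [scenario_config()].
#' @param rng_seed Integer seed.
#' @param profiles Domain profiles used for planted coding features.
#' @param panel Model RT panel; Retand entries become the family RT
#'   domains, other lineages supply non-Retand RT decoys.
#' @return A list of class `prare_scenario`: `genomes` (named character
#'   vector), `truth` (data.frame), `config`, `families` (list of specs).
#' @export
generate_scenario <- function(config = scenario_config(), rng_seed = 1,
                              profiles = retand_domain_profiles(),
                              panel = synthetic_rt_panel()) {
  with_seed(rng_seed, {
    queries <- rt_queries(panel)
    lin <- sub("\\|.*$", "", names(panel))
    outgroup <- as.character(panel[!lin %in% c("Retand", "Caulimoviridae")])

    ## ---- family specs and cassettes -------------------------------------
    ## The 5' leader absorbs the slack between the drawn internal size and
    ## the coding block, so POL-3'LTR sizes stay inside the published
    ## 2,933-6,566 bp range (and hence inside the 10-kb flank windows).
    fam_specs <- vector("list", config$n_families)
    fam_cassettes <- vector("list", config$n_families)
    for (f in seq_len(config$n_families)) {
      arrays <- list()
      n_arr <- sample(0:2, 1)
      if (n_arr >= 1) {
        arrays <- lapply(seq_len(n_arr), function(i) {
          list(unit_length = sample(8:100, 1),
               copy_count = sample(3:10, 1),
               position = sample(c("pol-adjacent", "ltr3-adjacent"), 1))
        })
      }
      layout <- sample(c("one-ORF", "two-ORF"), 1)
      missing <- if (f == 3) "GAG" else character(0)
      rt <- queries[[(f - 1) %% length(queries) + 1]]
      aorf_lens <- if (f %% 2 == 1) 1200L else c(1200L, 900L)
      internal <- sample(config$internal_range[1]:config$internal_range[2], 1)
      linker <- 15L
      coding <- .coding_block_length(layout, missing, nchar(rt), linker,
                                     profiles)
      pol3_fixed <- sum(vapply(arrays, function(a)
        SPACER + a$unit_length * a$copy_count, numeric(1))) +
        sum(SPACER + aorf_lens + 3L) + SPACER
      pol3_min <- max(3000L, pol3_fixed + 60L)
      pol3 <- sample(pol3_min:6500L, 1)
      utr5 <- internal - coding - pol3
      if (utr5 < 300L) {
        utr5 <- 300L
        pol3 <- internal - coding - utr5
      }
      stopifnot(pol3 >= pol3_fixed)
      fam_specs[[f]] <- element_spec(
        ltr_length = sample(config$ltr_range[1]:config$ltr_range[2], 1),
        internal_length = internal,
        tsd_length = config$tsd_length,
        rt_protein = rt,
        gag_pol_layout = layout,
        antisense_orf_lengths = aorf_lens,
        antisense_trp28 = c(TRUE, FALSE),
        tandem_arrays = arrays,
        missing_domains = missing,
        utr5_length = utr5,
        linker_aa = linker
      )
      fam_cassettes[[f]] <- .build_cassette_impl(fam_specs[[f]], profiles)
    }

    ## ---- planting plan ---------------------------------------------------
    plan <- list()
    addp <- function(type, fam, cassette, tsd) {
      plan[[length(plan) + 1]] <<- list(type = type, fam = fam,
                                        cassette = cassette, tsd = tsd)
    }
    for (i in seq_len(config$n_intact)) {
      f <- (i - 1) %% config$n_families + 1
      addp("intact", f, fam_cassettes[[f]], config$tsd_length)
    }
    for (i in seq_len(config$n_diverged)) {
      f <- (i - 1) %% config$n_families + 1
      cas <- fam_cassettes[[f]]
      n_subs <- max(8L, ceiling(cas$spec$ltr_length / 40))
      addp("diverged", f,
           diverge_cassette(cas, n_subs, rng_seed = sample.int(1e6, 1)),
           config$tsd_length)
    }
    for (i in seq_len(config$n_solo)) {
      f <- (i - 1) %% config$n_families + 1
      addp("solo", f, solo_cassette(fam_cassettes[[f]]), config$tsd_length)
    }
    for (i in seq_len(config$n_truncated)) {
      f <- (i - 1) %% config$n_families + 1
      addp("truncated", f, truncate_cassette(fam_cassettes[[f]]), 0L)
    }
    for (i in seq_len(config$n_nonretand)) {
      rt <- outgroup[[(i - 1) %% length(outgroup) + 1]]
      addp("nonretand_rt", NA_integer_,
           nonretand_cassette(rt, rng_seed = sample.int(1e6, 1)), 0L)
    }

    ## ---- place insertions ------------------------------------------------
    n_total <- length(plan)
    genome_of <- rep(seq_len(config$n_genomes), length.out = n_total)
    max_len <- max(vapply(plan, function(p) nchar(p$cassette$seq), integer(1)))
    ## insertion points live on the pre-insertion coordinate scale, where
    ## point spacing equals the final inter-element distance
    gap <- config$min_separation
    genomes <- character(config$n_genomes)
    names(genomes) <- paste0("g", seq_len(config$n_genomes), "_",
                             config$seqname_prefix, seq_len(config$n_genomes))
    truth <- list()
    el_i <- 0L
    for (gi in seq_len(config$n_genomes)) {
      idx <- which(genome_of == gi)
      k <- length(idx)
      usable <- config$genome_length - 2 * config$margin
      slot <- if (k > 0) usable / k else usable
      if (k > 0 && slot < gap) {
        stop("infeasible packing: ", k, " insertions of up to ", max_len,
             " bp with separation ", config$min_separation,
             " do not fit in ", config$genome_length, " bp")
      }
      g <- stats::setNames(random_dna(config$genome_length, config$gc),
                           names(genomes)[gi])
      pts <- if (k > 0) {
        config$margin + round((seq_len(k) - 1) * slot +
                                stats::runif(k, 0, slot - gap))
      } else integer(0)
      offset <- 0L
      for (j in seq_along(idx)) {
        p <- plan[[idx[j]]]
        el_i <- el_i + 1L
        res <- plant_element(
          g, p$cassette, position = pts[j] + offset,
          strand = sample(c("+", "-"), 1),
          id = sprintf("el%03d", el_i), type = p$type,
          family = if (is.na(p$fam)) NA_character_
                   else sprintf("fam%d", p$fam),
          tsd_length = p$tsd
        )
        g <- res$genome
        offset <- nchar(g) - config$genome_length
        truth[[el_i]] <- res$truth
      }
      genomes[gi] <- g
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(genomes = genomes, truth = truth, config = config,
                   families = fam_specs),
              class = "prare_scenario")
  })
}

#' @export
print.prare_scenario <- function(x, ...) {
  el <- x$truth[x$truth$feature == "element", ]
  solo <- x$truth[x$truth$feature == "solo_ltr", ]
  cat(sprintf("<prare_scenario: %d genome(s) of %s bp, %d plantings (%d eligible)>\n",
              length(x$genomes),
              format(nchar(x$genomes[[1]]), big.mark = ","),
              length(unique(x$truth$element_id)),
              sum(el$is_prare_eligible)))
  invisible(x)
}

#' Write a scenario to disk
#'
#' Emits genomes as FASTA, truth records as JSON-lines (one feature per
#' line) and GFF3, and the configuration as a key-value text file.
#'
#' @param scenario A `prare_scenario`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genomes.fasta"),
    truth_jsonl = file.path(dir, "truth.jsonl"),
    truth_gff3 = file.path(dir, "truth.gff3"),
    config = file.path(dir, "scenario_config.txt")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(scenario$genomes), paths["fasta"])
  writeLines(vapply(seq_len(nrow(scenario$truth)), function(i) {
    jsonlite::toJSON(as.list(scenario$truth[i, ]), auto_unbox = TRUE,
                     na = "null")
  }, character(1)), paths["truth_jsonl"])
  export_features_gff3(scenario$truth, paths["truth_gff3"],
                       source = "prareminer_truth")
  write_scenario_config(scenario$config, paths["config"])
  invisible(paths)
}
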