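## Synthetic genomes with planted Retand-like elements and decoys.
##
## The generator emulates the element architecture the pipeline is built to
## recover: an intact element is TSD + LTR + internal + LTR + TSD, where the
## internal region carries a gag-pol coding region (GAG, AP, RT, RH, INT
## domains; one or two ORFs), and a long POL-3'LTR region hosting antisense
## ORFs (usually with a TRP28 domain) and tandem-repeat arrays. Decoys are
## diverged-LTR elements, solo LTRs, 5'-truncated elements and non-Retand
## RT coding regions. Every planted feature is reported in a truth table
## with exact 1-based coordinates.

SPACER <- 15L      # bp between consecutive internal features
INSULATOR <- "TAA" # in-frame stop placed directly 5' of each planted ATG,
                   # so the planted ORF is the maximal ATG-to-stop ORF

#' Specification of a synthetic Retand-like element
#'
#' Sizes default to mid-range values of the published Retand spectrum
#' (LTRs 315-1,194 bp, internal regions 7,380-12,869 bp, 5-bp TSDs, RT
#' domains of 157-162 aa, antisense ORFs in the POL-3'LTR region, tandem
#' arrays of period 8-100 with at least three copies).
#'
#' @param ltr_length LTR length in bp.
#' @param internal_length Internal-region length in bp (must fit all
#'   requested features).
#' @param tsd_length Target-site-duplication length in bp (default 5).
#' @param rt_protein Amino-acid sequence of the RT domain to embed
#'   (157-162 aa; default: the first packaged Retand query).
#' @param gag_pol_layout `"one-ORF"` (single gag-pol ORF) or `"two-ORF"`
#'   (separate gag and pol ORFs).
#' @param antisense_orf_lengths Integer vector of antisense-ORF lengths in
#'   bp (ATG through stop codon; multiples of 3).
#' @param antisense_trp28 Logical vector (recycled): which antisense ORFs
#'   carry the TRP28 domain consensus.
#' @param tandem_arrays List of arrays, each `list(unit_length, copy_count,
#'   position)` with `unit_length` in `[8, 100]` bp, `copy_count >= 3` and
#'   `position` `"pol-adjacent"` or `"ltr3-adjacent"`.
#' @param ltr_divergence Number of substitutions applied independently to
#'   each LTR copy (0 = identical LTRs).
#' @param missing_domains Subset of `c("GAG", "AP", "RH", "INT")` to omit
#'   from the coding region (defective elements).
#' @param utr5_length bp between the 5'LTR and the gag-pol ORF.
#' @param linker_aa Residues of random linker between coding domains.
#' @return An object of class `element_spec`.
#' @export
element_spec <- function(ltr_length = 600,
                         internal_length = 10000,
                         tsd_length = 5,
                         rt_protein = rt_queries()[[1]],
                         gag_pol_layout = c("one-ORF", "two-ORF"),
                         antisense_orf_lengths = 1200,
                         antisense_trp28 = TRUE,
                         tandem_arrays = list(),
                         ltr_divergence = 0,
                         missing_domains = character(0),
                         utr5_length = 400,
                         linker_aa = 15) {
  gag_pol_layout <- match.arg(gag_pol_layout)
  stopifnot(
    ltr_length >= 1, internal_length >= 1, tsd_length >= 0,
    ltr_divergence >= 0,
    all(antisense_orf_lengths >= 0),
    all(antisense_orf_lengths %% 3 == 0),
    all(missing_domains %in% c("GAG", "AP", "RH", "INT"))
  )
  for (ta in tandem_arrays) {
    stopifnot(ta$unit_length >= 8, ta$unit_length <= 100, ta$copy_count >= 3,
              ta$position %in% c("pol-adjacent", "ltr3-adjacent"))
  }
  nrt <- nchar(rt_protein)
  if (nrt < 157 || nrt > 162) {
    stop("rt_protein must be 157-162 aa, got ", nrt)
  }
  structure(list(
    ltr_length = as.integer(ltr_length),
    internal_length = as.integer(internal_length),
    tsd_length = as.integer(tsd_length),
    rt_protein = rt_protein,
    gag_pol_layout = gag_pol_layout,
    antisense_orf_lengths = as.integer(antisense_orf_lengths),
    antisense_trp28 = rep_len(antisense_trp28,
                              length(antisense_orf_lengths)),
    tandem_arrays = tandem_arrays,
    ltr_divergence = as.integer(ltr_divergence),
    missing_domains = missing_domains,
    utr5_length = as.integer(utr5_length),
    linker_aa = as.integer(linker_aa)
  ), class = "element_spec")
}

## Build one coding ORF (TAA insulator + ATG + domains/linkers + stop).
## Returns the DNA piece plus domain coordinates relative to the piece.
.make_coding_orf <- function(domain_peptides, linker_aa) {
  prot <- character(0)
  aa_spans <- list()
  pos <- 0L
  for (nm in names(domain_peptides)) {
    link <- random_protein(linker_aa)
    prot <- c(prot, link)
    pos <- pos + linker_aa
    pep <- domain_peptides[[nm]]
    prot <- c(prot, pep)
    aa_spans[[nm]] <- c(pos + 1L, pos + nchar(pep))
    pos <- pos + nchar(pep)
  }
  prot <- c(prot, random_protein(linker_aa))
  protein <- paste(prot, collapse = "")
  orf <- encode_protein(protein)                  # ATG ... stop
  piece <- paste0(INSULATOR, orf)
  ## residue i of `protein` occupies ORF bases 3i+1 .. 3i+3 (after the
  ## ATG); the insulator shifts everything by 3 within the piece, so a
  ## residue span [s, e] sits at piece bases [3s+4, 3e+6]
  dom <- lapply(aa_spans, function(sp) c(3L * sp[1] + 4L, 3L * sp[2] + 6L))
  list(piece = piece, orf_rel = c(4L, nchar(piece)), protein = protein,
       domains = dom)
}

## A primitive (aperiodic) random repeat unit of the requested period.
.random_unit <- function(p) {
  repeat {
    u <- random_dna(p)
    divs <- which(p %% seq_len(p - 1) == 0)
    periodic <- any(vapply(divs, function(d) {
      u == strrep(substr(u, 1, d), p / d)
    }, logical(1)))
    if (!periodic) return(u)
  }
}

#' Build a synthetic element cassette
#'
#' Constructs the full element sequence (5'LTR + internal + 3'LTR) for an
#' [element_spec()], together with a feature table in cassette-relative
#' 1-based coordinates. Coding features are built codon-wise (ATG, sense
#' codons, stop) behind an in-frame stop insulator so each planted ORF is
#' the maximal ATG-to-stop ORF in its frame; tandem arrays get guard bases
#' so their maximal extent equals the planted span.
#'
#' @param spec An [element_spec()].
#' @param rng_seed Integer seed; the cassette is deterministic in
#'   `(spec, rng_seed)`.
#' @param profiles Domain-profile set providing the planted consensus
#'   peptides (default [retand_domain_profiles()]).
#' @return A list of class `element_cassette` with `seq` (character),
#'   `features` (data.frame) and `spec`.
#' @export
build_cassette <- function(spec, rng_seed = 1,
                           profiles = retand_domain_profiles()) {
  with_seed(rng_seed, .build_cassette_impl(spec, profiles))
}

.build_cassette_impl <- function(spec, profiles) {
  L <- spec$ltr_length
  ltr <- random_dna(L)

  dom_order <- setdiff(CORE_DOMAINS, spec$missing_domains)
  peptides <- lapply(dom_order, function(nm) {
    if (nm == "RT") spec$rt_protein else profiles[[nm]]$consensus
  })
  names(peptides) <- dom_order

  ## --- assemble the internal region as an ordered list of pieces ---------
  pieces <- list()   # each: list(seq=, kind=, name=, meta=list())
  add <- function(seq, kind = "spacer", name = "", meta = list()) {
    pieces[[length(pieces) + 1]] <<- list(seq = seq, kind = kind,
                                          name = name, meta = meta)
  }
  add(random_dna(spec$utr5_length), "utr5")

  if (spec$gag_pol_layout == "one-ORF" || "GAG" %in% spec$missing_domains) {
    o <- .make_coding_orf(peptides, spec$linker_aa)
    add(o$piece, "orf", "gagpol", list(orf_rel = o$orf_rel,
                                       domains = o$domains,
                                       protein = o$protein))
  } else {
    gag <- .make_coding_orf(peptides["GAG"], spec$linker_aa)
    add(gag$piece, "orf", "gag", list(orf_rel = gag$orf_rel,
                                      domains = gag$domains,
                                      protein = gag$protein))
    add(random_dna(12))
    pol <- .make_coding_orf(peptides[setdiff(dom_order, "GAG")],
                            spec$linker_aa)
    add(pol$piece, "orf", "pol", list(orf_rel = pol$orf_rel,
                                      domains = pol$domains,
                                      protein = pol$protein))
  }

  tag <- function(pos) vapply(spec$tandem_arrays,
                              function(ta) ta$position == pos, logical(1))
  n_arr <- 0L
  for (ta in spec$tandem_arrays[tag("pol-adjacent")]) {
    n_arr <- n_arr + 1L
    add(random_dna(SPACER))
    unit <- .random_unit(ta$unit_length)
    add(strrep(unit, ta$copy_count), "tandem_array",
        paste0("array", n_arr),
        list(period = ta$unit_length, copies = ta$copy_count, unit = unit))
  }

  i_anti <- 0L
  for (len in spec$antisense_orf_lengths) {
    i_anti <- i_anti + 1L
    naa <- len %/% 3L - 2L   # residues after the initiator M, before stop
    trp <- spec$antisense_trp28[i_anti]
    trp_pep <- profiles[["TRP28"]]$consensus
    if (trp && naa < nchar(trp_pep)) {
      stop("antisense ORF ", len, " bp too short for the TRP28 consensus")
    }
    prot <- random_protein(naa)
    trp_span <- NULL
    if (trp) {
      w <- nchar(trp_pep)
      at <- sample.int(naa - w + 1L, 1)
      prot <- paste0(substr(prot, 1, at - 1), trp_pep,
                     substr(prot, at + w, naa))
      trp_span <- c(at + 1L, at + w)  # residue coords incl. initiator M
    }
    orf <- encode_protein(prot)
    add(random_dna(SPACER))
    add(paste0(revcomp(orf), revcomp(INSULATOR)), "antisense_orf",
        paste0("aorf", i_anti),
        list(orf_len = len, trp_span = trp_span, protein = prot))
  }

  add("", "filler")
  for (ta in spec$tandem_arrays[tag("ltr3-adjacent")]) {
    n_arr <- n_arr + 1L
    add(random_dna(SPACER))
    unit <- .random_unit(ta$unit_length)
    add(strrep(unit, ta$copy_count), "tandem_array",
        paste0("array", n_arr),
        list(period = ta$unit_length, copies = ta$copy_count, unit = unit))
  }
  add(random_dna(SPACER))

  fixed <- sum(vapply(pieces, function(p) nchar(p$seq), integer(1)))
  filler_len <- spec$internal_length - fixed
  if (filler_len < 0) {
    stop("internal_length (", spec$internal_length,
         ") too small for the requested features (need ", fixed, " bp)")
  }
  for (i in seq_along(pieces)) {
    if (pieces[[i]]$kind == "filler") pieces[[i]]$seq <- random_dna(filler_len)
  }

  ## --- lay out coordinates ------------------------------------------------
  internal <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")
  feat <- list()
  off <- L  # internal starts at cassette position L + 1
  frow <- function(feature, name, start, end, strand = "+",
                   orientation = NA_character_, period = NA_integer_,
                   copies = NA_integer_, protein = NA_character_) {
    start <- as.integer(start); end <- as.integer(end)
    data.frame(feature = feature, name = name, start = start, end = end,
               strand = strand, orientation = orientation,
               period = as.integer(period), copies = as.integer(copies),
               protein = protein, stringsAsFactors = FALSE)
  }
  for (p in pieces) {
    s <- off + 1L
    e <- off + nchar(p$seq)
    if (p$kind == "orf") {
      orf_s <- s + p$meta$orf_rel[1] - 1L
      orf_e <- s + p$meta$orf_rel[2] - 1L
      feat[[length(feat) + 1]] <- frow("orf", p$name, orf_s, orf_e, "+",
                                       "sense", protein = p$meta$protein)
      for (dn in names(p$meta$domains)) {
        d <- p$meta$domains[[dn]]
        feat[[length(feat) + 1]] <-
          frow("domain", dn, s + d[1] - 1L, s + d[2] - 1L, "+", "sense")
      }
    } else if (p$kind == "antisense_orf") {
      ## the ORF occupies the piece minus the 3-bp insulator at its plus end
      feat[[length(feat) + 1]] <- frow("orf", p$name, s, e - 3L, "-",
                                       "antisense", protein = p$meta$protein)
      if (!is.null(p$meta$trp_span)) {
        ## residue r of the minus-strand ORF maps to plus coords counted
        ## from the ORF's plus-strand end
        orf_e_plus <- e - 3L
        r <- p$meta$trp_span
        feat[[length(feat) + 1]] <-
          frow("domain", "TRP28", orf_e_plus - 3L * r[2] + 1L,
               orf_e_plus - 3L * (r[1] - 1L), "-", "antisense")
      }
    } else if (p$kind == "tandem_array") {
      feat[[length(feat) + 1]] <- frow("tandem_array", p$name, s, e, "+",
                                       NA_character_, p$meta$period,
                                       p$meta$copies)
    }
    off <- e
  }
  stopifnot(off == L + spec$internal_length)

  ## guard bases: a tandem array must not extend past its planted span
  ichars <- strsplit(internal, "")[[1]]
  for (f in feat) {
    if (f$feature != "tandem_array") next
    s <- f$start - L; e <- f$end - L; p <- f$period
    if (s - 1 >= 1 && ichars[s - 1] == ichars[s - 1 + p]) {
      ichars[s - 1] <- sample(setdiff(DNA_BASES, ichars[s - 1 + p]), 1)
    }
    if (e + 1 <= length(ichars) && ichars[e + 1] == ichars[e + 1 - p]) {
      ichars[e + 1] <- sample(setdiff(DNA_BASES, ichars[e + 1 - p]), 1)
    }
  }
  internal <- paste(ichars, collapse = "")

  ltr5 <- ltr
  ltr3 <- ltr
  if (spec$ltr_divergence > 0) {
    ltr5 <- mutate_string(ltr5, spec$ltr_divergence)
    ltr3 <- mutate_string(ltr3, spec$ltr_divergence)
  }

  features <- do.call(rbind, c(
    list(frow("ltr5", "ltr5", 1L, L),
         frow("internal", "internal", L + 1L, L + spec$internal_length),
         frow("ltr3", "ltr3", L + spec$internal_length + 1L,
              2L * L + spec$internal_length)),
    feat
  ))
  structure(list(seq = paste0(ltr5, internal, ltr3), features = features,
                 spec = spec),
            class = "element_cassette")
}

#' @export
print.element_cassette <- function(x, ...) {
  cat(sprintf("<element_cassette: %d bp, %d features>\n",
              nchar(x$seq), nrow(x$features)))
  invisible(x)
}

## Derived cassettes for decoys ---------------------------------------------

## Re-mutate both LTR copies of an existing cassette (diverged-LTR decoy).
diverge_cassette <- function(cassette, n_subs, rng_seed = 1) {
  with_seed(rng_seed, {
    f <- cassette$features
    L <- f$end[f$feature == "ltr5"]
    I <- f$end[f$feature == "internal"] - L
    s <- cassette$seq
    ltr5 <- mutate_string(substr(s, 1, L), n_subs)
    ltr3 <- mutate_string(substr(s, L + I + 1, 2 * L + I), n_subs)
    cassette$seq <- paste0(ltr5, substr(s, L + 1, L + I), ltr3)
    cassette$spec$ltr_divergence <- as.integer(n_subs)
    cassette
  })
}

## 5'-truncated cassette: internal region + 3'LTR only (no 5'LTR, no TSD).
truncate_cassette <- function(cassette) {
  f <- cassette$features
  L <- f$end[f$feature == "ltr5"]
  keep <- f$feature != "ltr5"
  f <- f[keep, , drop = FALSE]
  f$start <- f$start - L
  f$end <- f$end - L
  cassette$seq <- substr(cassette$seq, L + 1, nchar(cassette$seq))
  cassette$features <- f
  cassette
}

## Naked non-Retand RT coding region (outgroup decoy, no LTRs).
nonretand_cassette <- function(rt_protein, rng_seed = 1, linker_aa = 15) {
  with_seed(rng_seed, {
    o <- .make_coding_orf(list(RT = rt_protein), linker_aa)
    features <- data.frame(
      feature = c("orf", "domain"),
      name = c("decoy_orf", "RT"),
      start = c(o$orf_rel[1], o$domains$RT[1]),
      end = c(o$orf_rel[2], o$domains$RT[2]),
      strand = "+", orientation = "sense",
      period = NA_integer_, copies = NA_integer_,
      protein = c(o$protein, NA_character_),
      stringsAsFactors = FALSE
    )
    structure(list(seq = o$piece, features = features, spec = NULL),
              class = "element_cassette")
  })
}

## Solo LTR cassette built from a family cassette's LTR.
solo_cassette <- function(cassette) {
  f <- cassette$features
  L <- f$end[f$feature == "ltr5"]
  structure(list(
    seq = substr(cassette$seq, 1, L),
    features = data.frame(feature = "solo_ltr", name = "solo_ltr",
                          start = 1L, end = L, strand = "+",
                          orientation = NA_character_,
                          period = NA_integer_, copies = NA_integer_,
                          protein = NA_character_, stringsAsFactors = FALSE),
    spec = NULL
  ), class = "element_cassette")
}

## Reverse-complement a cassette, remapping its feature table.
revcomp_cassette <- function(cassette) {
  n <- nchar(cassette$seq)
  f <- cassette$features
  new_start <- n - f$end + 1L
  new_end <- n - f$start + 1L
  f$start <- new_start
  f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  swap <- c(ltr5 = "ltr3", ltr3 = "ltr5")
  hit <- f$feature %in% names(swap)
  f$feature[hit] <- swap[f$feature[hit]]
  f$name[f$name %in% names(swap)] <- swap[f$name[f$name %in% names(swap)]]
  cassette$seq <- revcomp(cassette$seq)
  cassette$features <- f[order(f$start, f$end), , drop = FALSE]
  cassette
}

#' Plant an element into a genome
#'
#' Inserts an element cassette after `position`, duplicating the
#' `tsd_length` bases at the insertion point as the target-site
#' duplication, and returns the updated genome with a truth table of all
#' planted features in genome coordinates. Two spacer bases of the
#' cassette may be adjusted to the insertion site so that the maximal
#' exact LTR repeat equals the planted LTR pair exactly.
#'
#' @param genome A single named sequence: a length-1 named character
#'   vector or [Biostrings::DNAStringSet].
#' @param spec An [element_spec()], or an `element_cassette` from
#'   [build_cassette()] (for planting identical family copies).
#' @param position Insertion point: the element is inserted after this
#'   base (0 <= position <= genome length - tsd_length).
#' @param rng_seed Seed used when `spec` needs to be built into a cassette.
#' @param strand Strand of the element's gag-pol reading direction.
#' @param id Element identifier used in the truth table.
#' @param type Truth-record type tag.
#' @param eligible Is the planting PRARE-eligible (identical LTRs, no
#'   planted size aberration)?
#' @param family Family tag recorded in the truth table.
#' @param tsd_length Override of the target-site-duplication length; by
#'   default taken from the cassette's spec (0 when the cassette has none,
#'   e.g. truncated or naked-ORF decoys).
#' @return A list with `genome` (named character vector) and `truth`
#'   (data.frame, one row per planted feature).
#' @export
plant_element <- function(genome, spec, position, rng_seed = 1,
                          strand = "+", id = "el1", type = "intact",
                          eligible = NA, family = NA_character_,
                          tsd_length = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), length(genome) == 1, !is.null(names(genome)))
  gname <- names(genome)
  g <- unname(genome)
  n <- nchar(g)
  cassette <- if (inherits(spec, "element_cassette")) spec
              else build_cassette(spec, rng_seed)
  tsd_len <- if (!is.null(tsd_length)) as.integer(tsd_length)
             else if (!is.null(cassette$spec)) cassette$spec$tsd_length
             else 0L
  if (position < 0 || position + tsd_len > n) {
    stop("position out of range: ", position)
  }
  if (strand == "-") cassette <- revcomp_cassette(cassette)
  cs <- cassette$seq
  clen <- nchar(cs)
  tsd <- if (tsd_len > 0) substr(g, position + 1, position + tsd_len) else ""

  ## guard bases: keep the maximal exact LTR repeat equal to the LTR pair
  f <- cassette$features
  if (all(c("ltr5", "ltr3") %in% f$feature)) {
    L1 <- range(f$start[f$feature %in% c("ltr5", "ltr3")])
    ints <- f[f$feature == "internal", ]
    left_nb <- if (position + tsd_len >= 1)
      substr(g, position + tsd_len, position + tsd_len) else ""
    right_nb <- if (position + 1 <= n) substr(g, position + 1, position + 1)
                else ""
    if (nzchar(left_nb) && substr(cs, ints$end, ints$end) == left_nb) {
      alt <- setdiff(DNA_BASES, left_nb)[1]
      substr(cs, ints$end, ints$end) <- alt
    }
    if (nzchar(right_nb) && substr(cs, ints$start, ints$start) == right_nb) {
      alt <- setdiff(DNA_BASES, right_nb)[1]
      substr(cs, ints$start, ints$start) <- alt
    }
  }

  out <- paste0(substr(g, 1, position + tsd_len), cs,
                substr(g, position + 1, n))
  el_start <- position + tsd_len + 1L
  shift <- el_start - 1L

  truth <- cassette$features
  truth$start <- as.integer(truth$start + shift)
  truth$end <- as.integer(truth$end + shift)
  base <- data.frame(feature = "element", name = id,
                     start = el_start, end = el_start + clen - 1L,
                     strand = strand, orientation = NA_character_,
                     period = NA_integer_, copies = NA_integer_,
                     protein = NA_character_, stringsAsFactors = FALSE)
  if (tsd_len > 0) {
    base <- rbind(base,
      data.frame(feature = c("tsd_left", "tsd_right"),
                 name = c("tsd_left", "tsd_right"),
                 start = c(position + 1L, el_start + clen),
                 end = c(position + tsd_len, el_start + clen + tsd_len - 1L),
                 strand = "+", orientation = NA_character_,
                 period = NA_integer_, copies = NA_integer_,
                 protein = NA_character_, stringsAsFactors = FALSE))
  }
  truth <- rbind(base, truth)
  truth$start <- as.integer(truth$start)
  truth$end <- as.integer(truth$end)
  truth$genome_id <- gname
  truth$element_id <- id
  truth$type <- type
  truth$family <- family
  truth$tsd <- tsd
  truth$is_prare_eligible <-
    if (is.na(eligible)) type == "intact" else eligible
  rownames(truth) <- NULL

  list(genome = stats::setNames(out, gname), truth = truth)
}
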