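## Structural annotation of reconstructed elements: ORFs relative to the
## gag-pol reading direction, domain hits, the POL-3'LTR region, tandem
## arrays and autonomy classification. All per-element work happens in
## element-local coordinates oriented so that the RT strand reads forward;
## orientation labels (sense/antisense) are relative to that direction.

#' Find open reading frames in all six frames
#'
#' ORFs are ATG-initiated and maximal: within each frame, the ORF runs
#' from the first ATG after the previous stop codon through the next stop
#' codon (the stop is included in the span and the length). ORFs shorter
#' than `min_len` are kept only when their protein carries a TRP28 domain
#' hit, and are then flagged `short`.
#'
#' @param seq Element sequence (character).
#' @param min_len Minimum ORF length in bp (default 600).
#' @param profiles Domain profiles; when present and containing `TRP28`,
#'   short ORFs with a TRP28 hit are rescued.
#' @return A data.frame: `start`, `end` (1-based, forward strand of
#'   `seq`), `strand`, `length`, `protein` (without the stop), `short`.
#' @export
find_orfs <- function(seq, min_len = 600, profiles = NULL) {
  n <- nchar(seq)
  frames <- six_frame_translate(seq)
  trp <- if (!is.null(profiles) && "TRP28" %in% names(profiles))
    profiles[["TRP28"]] else NULL
  min_rescue_aa <- if (is.null(trp)) Inf else trp$width
  rows <- list()
  for (fi in seq_len(nrow(frames))) {
    aa <- strsplit(frames$protein[fi], "")[[1]]
    if (!length(aa)) next
    stops <- which(aa == "*")
    seg_start <- 1L
    for (st in stops) {
      if (st > seg_start) {
        ms <- which(aa[seg_start:(st - 1)] == "M")
        if (length(ms)) {
          a <- seg_start + ms[1] - 1L
          len_bp <- 3L * (st - a + 1L)
          keep <- len_bp >= min_len
          short <- FALSE
          prot <- paste(aa[a:(st - 1)], collapse = "")
          if (!keep && (st - a) >= min_rescue_aa) {
            sc <- profile_window_scores(prot, trp)
            if (length(sc) && max(sc) >= trp$threshold) {
              keep <- TRUE
              short <- TRUE
            }
          }
          if (keep) {
            d <- frame_to_dna(a, st, frames$strand[fi], frames$frame[fi], n)
            rows[[length(rows) + 1]] <- data.frame(
              start = d[1], end = d[2], strand = frames$strand[fi],
              length = len_bp, protein = prot, short = short,
              stringsAsFactors = FALSE)
          }
        }
      }
      seg_start <- st + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      protein = character(0), short = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein with domain profiles
#'
#' Reports the best-scoring ungapped placements of each profile with
#' score at or above the profile threshold; multiple non-overlapping hits
#' of the same profile are allowed (greedy, best first). A profile wider
#' than the protein yields no hit.
#'
#' @param protein Amino-acid string.
#' @param profiles Named list of `domain_profile` objects.
#' @return A data.frame: `name`, `start`, `end` (1-based residue
#'   coordinates), `score`.
#' @export
scan_domains <- function(protein, profiles) {
  rows <- list()
  for (p in profiles) {
    sc <- profile_window_scores(protein, p)
    if (!length(sc)) next
    cand <- which(sc >= p$threshold)
    if (!length(cand)) next
    cand <- cand[order(-sc[cand], cand)]
    taken <- logical(nchar(protein))
    for (at in cand) {
      span <- at:(at + p$width - 1)
      if (any(taken[span])) next
      taken[span] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        name = p$name, start = at, end = at + p$width - 1L,
        score = sc[at], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect tandem-repeat arrays
#'
#' For each period, positions where the sequence equals itself shifted by
#' the period are collected; maximal runs give candidate arrays of exact
#' adjacent copies, which are then extended copy-wise while additional
#' units match the running consensus at `min_identity` or better.
#' Candidate arrays must have at least `min_copies` full copies.
#' Overlapping candidates are resolved best-first by `copies x period`,
#' ties to the smaller period, then the leftmost start.
#'
#' @param seq Character sequence.
#' @param min_copies Minimum full copies (default 3).
#' @param min_period,max_period Period range in bp (published unit sizes
#'   span 8-100 bp; period 1 homopolymers are reported once, as period 1).
#' @param min_identity Copy-to-consensus identity for extension.
#' @param min_span Minimum array footprint `period x copies` in bp; plays
#'   the role of the replaced tool's alignment-score threshold and keeps
#'   chance micro-runs (e.g. 3-bp homopolymers) out of the report.
#' @return A data.frame: `start`, `end`, `period`, `copies`, `unit`
#'   (consensus unit), `mean_identity`.
#' @export
find_tandem_arrays <- function(seq, min_copies = 3, min_period = 1,
                               max_period = 100, min_identity = 0.8,
                               min_span = 24) {
  if (min_period > max_period) stop("min_period > max_period")
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  cand <- list()
  for (p in min_period:max_period) {
    if (L < p * min_copies) break
    eq <- x[seq_len(L - p)] == x[(p + 1):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ## a run of m shift-matches spans m + p bases = floor((m+p)/p) copies
    good <- which(r$values & r$lengths >= p * (min_copies - 1L))
    for (k in good) {
      copies <- (r$lengths[k] + p) %/% p
      ref <- .refine_array(x, starts[k], p, copies, min_identity)
      if (ref$copies * ref$period < min_span) next
      ## a periodic consensus unit means this is a sub-harmonic of a
      ## shorter true period; the primitive-period candidate covers it
      if (!.is_primitive(ref$unit)) next
      cand[[length(cand) + 1]] <- ref
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = integer(0),
                      unit = character(0), mean_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- unique(cand)
  cand <- cand[order(-(cand$copies * cand$period), cand$period, cand$start),
               , drop = FALSE]
  sel <- logical(nrow(cand))
  occupied <- logical(L)
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(occupied[span])) {
      sel[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.is_primitive <- function(unit) {
  p <- nchar(unit)
  if (p == 1) return(TRUE)
  for (d in which(p %% seq_len(p - 1) == 0)) {
    if (unit == strrep(substr(unit, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

## consensus-guided copy-wise extension of an exact seed run
.refine_array <- function(x, start, p, copies, min_identity) {
  L <- length(x)
  unit_at <- function(s) x[s:(s + p - 1)]
  consensus <- function(s, k) {
    m <- matrix(x[s:(s + k * p - 1)], nrow = p)
    ## fast path: unanimous rows (exact arrays) need no voting
    first <- m[, 1]
    unan <- rowSums(m == first) == k
    if (all(unan)) return(first)
    cons <- first
    for (r in which(!unan)) {
      tb <- table(m[r, ])
      cons[r] <- names(tb)[which.max(tb)]
    }
    cons
  }
  s <- as.integer(start); k <- as.integer(copies)
  cons <- consensus(s, k)
  repeat {  # extend right
    ns <- s + k * p
    if (ns + p - 1 > L) break
    if (mean(unit_at(ns) == cons) >= min_identity) {
      k <- k + 1L
      cons <- consensus(s, k)
    } else break
  }
  repeat {  # extend left
    ns <- s - p
    if (ns < 1) break
    if (mean(unit_at(ns) == cons) >= min_identity) {
      s <- as.integer(ns); k <- k + 1L
      cons <- consensus(s, k)
    } else break
  }
  ident <- mean(vapply(seq_len(k), function(i) {
    mean(unit_at(s + (i - 1) * p) == cons)
  }, numeric(1)))
  data.frame(start = s, end = as.integer(s + k * p - 1L),
             period = as.integer(p), copies = k,
             unit = paste(cons, collapse = ""), mean_identity = ident,
             stringsAsFactors = FALSE)
}

#' Delimit the POL-3'LTR region
#'
#' The span from just after the stop codon of the 3'-most sense ORF
#' carrying a pol domain (RT, RH or INT) to just before the 3'LTR, in
#' element-local sense coordinates.
#'
#' @param orfs Annotated ORF table (with `domains` list-column).
#' @param ltr3_start Local start of the 3'LTR.
#' @return `NULL` when no sense ORF has a pol domain, else a list with
#'   `start`, `end`, `length` (`length` 0 when the pol ORF abuts the LTR).
#' @export
delimit_pol_3ltr <- function(orfs, ltr3_start) {
  pol <- vapply(seq_len(nrow(orfs)), function(i) {
    orfs$orientation[i] == "sense" &&
      any(orfs$domains[[i]]$name %in% c("RT", "RH", "INT"))
  }, logical(1))
  if (!any(pol)) return(NULL)
  pol_end <- max(orfs$end[pol])
  list(start = as.integer(pol_end + 1), end = as.integer(ltr3_start - 1),
       length = as.integer(ltr3_start - pol_end - 1))
}

#' Classify element autonomy from domain presence
#'
#' @param orfs Annotated ORF table (with `domains` list-column).
#' @return A list: `class` (`"complete"` or `"defective"`) and `missing`
#'   (character vector of absent core domains among GAG, AP, RT, RH, INT).
#' @export
classify_autonomy <- function(orfs) {
  sense <- orfs[orfs$orientation == "sense", , drop = FALSE]
  present <- unique(unlist(lapply(sense$domains, function(d) d$name)))
  missing <- setdiff(CORE_DOMAINS, present)
  if (!length(missing)) list(class = "complete", missing = character(0))
  else list(class = "defective", missing = missing)
}

#' Annotate a reconstructed element
#'
#' Extracts the element sequence, orients it so the RT strand reads
#' forward, finds ORFs (labeling orientation relative to the gag-pol
#' direction), scans ORF proteins with the domain profiles, delimits the
#' POL-3'LTR region, detects tandem arrays in the internal region, and
#' classifies autonomy.
#'
#' @param genomes Named character vector of genome sequences.
#' @param element One row of a [build_elements()] element table.
#' @param profiles Domain profiles ([retand_domain_profiles()]).
#' @param min_orf Minimum ORF length in bp.
#' @param max_period Maximum tandem period to search.
#' @return A list of class `annotated_element`: `element_id`, `strand`,
#'   `length`, `ltr_local` (LTR length), `orfs` (with `orientation` and a
#'   `domains` list-column), `gag_pol_layout`, `pol_3ltr`,
#'   `tandem_arrays`, `autonomy`. All coordinates are element-local in
#'   the sense orientation; see [local_to_genome()].
#' @export
annotate_element <- function(genomes, element, profiles, min_orf = 600,
                             max_period = 100) {
  seqel <- substr(genomes[[element$genome_id]], element$start, element$end)
  if (element$strand == "-") seqel <- revcomp(seqel)
  len <- nchar(seqel)
  L <- element$ltr_size
  orfs <- find_orfs(seqel, min_len = min_orf, profiles = profiles)
  orfs$orientation <- ifelse(orfs$strand == "+", "sense", "antisense")
  orfs$domains <- lapply(orfs$protein, scan_domains, profiles = profiles)
  pol3 <- delimit_pol_3ltr(orfs, ltr3_start = len - L + 1L)
  internal <- substr(seqel, L + 1, len - L)
  ta <- find_tandem_arrays(internal, max_period = max_period)
  if (nrow(ta)) {
    ta$start <- ta$start + L
    ta$end <- ta$end + L
  }
  sense_coding <- which(orfs$orientation == "sense" &
                          vapply(orfs$domains, nrow, integer(1)) > 0)
  layout <- if (length(sense_coding) >= 2) "two-ORF" else "one-ORF"
  structure(list(
    element_id = element$element_id,
    genome_id = element$genome_id,
    strand = element$strand,
    length = len,
    ltr_size = L,
    orfs = orfs,
    gag_pol_layout = layout,
    pol_3ltr = pol3,
    tandem_arrays = ta,
    autonomy = classify_autonomy(orfs)
  ), class = "annotated_element")
}

#' @export
print.annotated_element <- function(x, ...) {
  cat(sprintf(
    "<annotated_element %s: %d bp, %d ORFs (%d antisense), %s, %d arrays>\n",
    x$element_id, x$length, nrow(x$orfs),
    sum(x$orfs$orientation == "antisense"), x$autonomy$class,
    nrow(x$tandem_arrays)))
  invisible(x)
}

#' Annotate all elements of a table
#' @param genomes Named character vector of genome sequences.
#' @param elements Element table from [build_elements()].
#' @inheritParams annotate_element
#' @return A named list of [annotate_element()] results keyed by element id.
#' @export
annotate_elements <- function(genomes, elements, profiles, min_orf = 600,
                              max_period = 100) {
  out <- lapply(seq_len(nrow(elements)), function(i) {
    annotate_element(genomes, elements[i, ], profiles, min_orf, max_period)
  })
  stats::setNames(out, elements$element_id)
}

#' Convert element-local sense coordinates to genome coordinates
#'
#' @param local Integer `c(start, end)` in element-local sense
#'   orientation.
#' @param element One element-table row (uses `start`, `end`, `strand`).
#' @return Integer `c(start, end)` on the genome's forward strand.
#' @export
local_to_genome <- function(local, element) {
  if (element$strand == "+") {
    c(element$start + local[1] - 1L, element$start + local[2] - 1L)
  } else {
    c(element$end - local[2] + 1L, element$end - local[1] + 1L)
  }
}
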