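## Element reconstruction around Retand RT hits.
##
## For each hit the 10-kb up/downstream window is searched for a maximal
## exact repeat pair (one copy upstream of the RT domain, one downstream):
## the "identical LTRs" criterion operationalized as exact string equality,
## implemented as a k-mer-anchored diagonal match (anchor k = 21, runs of
## consecutive anchors on one diagonal are maximal exact matches). The
## element is retained only if the 5-bp sequences flanking the implied
## element boundaries are identical (the target-site duplication).

#' Extract the windows flanking an RT hit
#'
#' @param genome Named character vector (the hit's genome must be present)
#'   or a single named sequence.
#' @param hit One row of a [find_rt_hits()] table.
#' @param window Flank size in bp on each side (default 10,000).
#' @return A list: `seq` (window sequence), `offset` (genome coordinate of
#'   window position 1 minus 1, so genome = window + offset), `rt_start`,
#'   `rt_end` (window coordinates of the hit), `left_truncated`,
#'   `right_truncated`.
#' @export
extract_flanks <- function(genome, hit, window = 10000) {
  g <- if (length(genome) > 1 || !is.null(hit$genome_id))
    genome[[hit$genome_id]] else genome[[1]]
  n <- nchar(g)
  stopifnot(hit$start >= 1, hit$end <= n)
  w1 <- max(1L, hit$start - window)
  w2 <- min(n, hit$end + window)
  list(seq = substr(g, w1, w2),
       offset = as.integer(w1 - 1),
       rt_start = as.integer(hit$start - w1 + 1),
       rt_end = as.integer(hit$end - w1 + 1),
       left_truncated = (hit$start - window) < 1,
       right_truncated = (hit$end + window) > n)
}

## All maximal exact repeats (same orientation) between two substrings of
## `seq` given by 1-based [a1,a2] (upstream) and [b1,b2] (downstream).
## Returns a data.frame of pairs in `seq` coordinates.
.maximal_exact_repeats <- function(seq, a1, a2, b1, b2, k = 21) {
  if (a2 - a1 + 1 < k || b2 - b1 + 1 < k) {
    return(data.frame(s1 = integer(0), e1 = integer(0),
                      s2 = integer(0), e2 = integer(0), len = integer(0)))
  }
  up <- substr(seq, a1, a2)
  down <- substr(seq, b1, b2)
  nu <- nchar(up); nd <- nchar(down)
  ku <- substring(up, 1:(nu - k + 1), k:nu)
  kd <- substring(down, 1:(nd - k + 1), k:nd)
  pos_by_kmer <- split(seq_along(ku), ku)
  hits_j <- which(kd %in% names(pos_by_kmer))
  if (!length(hits_j)) {
    return(data.frame(s1 = integer(0), e1 = integer(0),
                      s2 = integer(0), e2 = integer(0), len = integer(0)))
  }
  pairs_i <- pos_by_kmer[kd[hits_j]]
  reps <- lengths(pairs_i)
  i <- unlist(pairs_i, use.names = FALSE)
  j <- rep(hits_j, reps)
  diag <- j - i
  out <- list()
  for (d in unique(diag)) {
    ii <- sort(i[diag == d])
    runs <- split(ii, cumsum(c(1L, diff(ii) != 1L)))
    for (r in runs) {
      s1 <- r[1]; len <- r[length(r)] - r[1] + k
      out[[length(out) + 1]] <- data.frame(
        s1 = as.integer(a1 + s1 - 1), e1 = as.integer(a1 + s1 + len - 2),
        s2 = as.integer(b1 + s1 + d - 1),
        e2 = as.integer(b1 + s1 + d + len - 2),
        len = as.integer(len))
    }
  }
  do.call(rbind, out)
}

#' Find the identical LTR pair around an RT domain
#'
#' Searches a flank window for maximal exact same-orientation repeats with
#' one copy entirely upstream and one entirely downstream of the RT span,
#' length within `[min_ltr, max_ltr]`. Among valid pairs the longest wins;
#' ties resolve to the outermost placement (widest implied element), then
#' leftmost.
#'
#' @param window A window list from [extract_flanks()], or a plain
#'   character sequence.
#' @param rt_start,rt_end RT span in window coordinates (taken from
#'   `window` when it is an [extract_flanks()] result).
#' @param min_ltr,max_ltr Accepted LTR length range in bp. The defaults
#'   (100 and 3,000) bracket the published 315-1,194 bp range with
#'   generous margins.
#' @param k Anchor k-mer size.
#' @return `NULL` if no pair qualifies, else a list with `ltr5`, `ltr3`
#'   (integer `c(start, end)` in window coordinates) and `length`.
#' @export
find_ltr_pair <- function(window, rt_start = NULL, rt_end = NULL,
                          min_ltr = 100, max_ltr = 3000, k = 21) {
  if (min_ltr > max_ltr) stop("min_ltr > max_ltr")
  if (is.list(window)) {
    rt_start <- window$rt_start
    rt_end <- window$rt_end
    seq <- window$seq
  } else seq <- window
  stopifnot(rt_start >= 1, rt_end <= nchar(seq))
  reps <- .maximal_exact_repeats(seq, 1L, rt_start - 1L,
                                 rt_end + 1L, nchar(seq), k = k)
  reps <- reps[reps$len >= min_ltr & reps$len <= max_ltr &
                 reps$e1 < rt_start & reps$s2 > rt_end, , drop = FALSE]
  if (!nrow(reps)) return(NULL)
  reps <- reps[order(-reps$len, -(reps$e2 - reps$s1), reps$s1), , drop = FALSE]
  best <- reps[1, ]
  list(ltr5 = c(best$s1, best$e1), ltr3 = c(best$s2, best$e2),
       length = best$len)
}

#' Check the identical insertion repeat (TSD) at an element boundary
#'
#' @param genome Single sequence (character) or named vector with one entry.
#' @param element_span Integer `c(start, end)` of the element (5'LTR start
#'   to 3'LTR end) in genome coordinates.
#' @param tsd_len TSD length (default 5).
#' @return A list: `tsd` (the duplicated sequence, or `NULL` if the flanks
#'   differ) and `edge` (`TRUE` when the span is too close to a sequence
#'   end to test).
#' @export
check_insertion_repeat <- function(genome, element_span, tsd_len = 5) {
  g <- genome[[1]]
  n <- nchar(g)
  s <- element_span[1]; e <- element_span[2]
  if (s - tsd_len < 1 || e + tsd_len > n) {
    return(list(tsd = NULL, edge = TRUE))
  }
  left <- substr(g, s - tsd_len, s - 1)
  right <- substr(g, e + 1, e + tsd_len)
  if (left == right) list(tsd = left, edge = FALSE)
  else list(tsd = NULL, edge = FALSE)
}

#' Reconstruct elements around RT hits
#'
#' Applies [extract_flanks()], [find_ltr_pair()] and
#' [check_insertion_repeat()] to every hit; hits failing a criterion are
#' reported in a rejection table with a reason code (`no-ltr-pair`,
#' `no-tsd`, `edge`).
#'
#' @param genomes Named character vector or [Biostrings::DNAStringSet].
#' @param hits Hit table from [find_rt_hits()] (typically already filtered
#'   to the Retand lineage).
#' @param window Flank window in bp.
#' @param min_ltr,max_ltr LTR length range.
#' @param tsd_len TSD length.
#' @return A list with `elements` (data.frame, one row per accepted
#'   element, genome coordinates: element/LTR/internal spans, TSD, strand,
#'   RT span, LTR sequence) and `rejected` (data.frame of hit spans with
#'   reason codes). Elements are sorted by genome and start, independent
#'   of hit order.
#' @export
build_elements <- function(genomes, hits, window = 10000,
                           min_ltr = 100, max_ltr = 3000, tsd_len = 5) {
  if (methods::is(genomes, "DNAStringSet")) {
    genomes <- stats::setNames(as.character(genomes), names(genomes))
  }
  els <- list()
  rej <- list()
  if (nrow(hits)) hits <- hits[order(hits$genome_id, hits$start), , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    fl <- extract_flanks(genomes, hit, window)
    pair <- find_ltr_pair(fl, min_ltr = min_ltr, max_ltr = max_ltr)
    if (is.null(pair)) {
      rej[[length(rej) + 1]] <- cbind(hit, reason = "no-ltr-pair")
      next
    }
    span <- c(pair$ltr5[1], pair$ltr3[2]) + fl$offset
    tsd <- check_insertion_repeat(genomes[[hit$genome_id]], span, tsd_len)
    if (is.null(tsd$tsd)) {
      rej[[length(rej) + 1]] <-
        cbind(hit, reason = if (tsd$edge) "edge" else "no-tsd")
      next
    }
    ltr5 <- pair$ltr5 + fl$offset
    ltr3 <- pair$ltr3 + fl$offset
    els[[length(els) + 1]] <- data.frame(
      genome_id = hit$genome_id,
      start = span[1], end = span[2],
      ltr5_start = ltr5[1], ltr5_end = ltr5[2],
      ltr3_start = ltr3[1], ltr3_end = ltr3[2],
      internal_start = ltr5[2] + 1L, internal_end = ltr3[1] - 1L,
      ltr_size = pair$length,
      internal_size = ltr3[1] - ltr5[2] - 1L,
      tsd = tsd$tsd, strand = hit$strand,
      rt_start = hit$start, rt_end = hit$end,
      rt_query = hit$query_id,
      rt_protein = hit$protein,
      ## LTR sequence read in the element's sense orientation, so copies
      ## of one family cluster together regardless of insertion strand
      ltr_seq = if (hit$strand == "-")
        revcomp(substr(genomes[[hit$genome_id]], ltr3[1], ltr3[2]))
      else substr(genomes[[hit$genome_id]], ltr5[1], ltr5[2]),
      stringsAsFactors = FALSE)
  }
  elements <- if (length(els)) do.call(rbind, els) else
    data.frame(genome_id = character(0), start = integer(0),
               end = integer(0), ltr5_start = integer(0),
               ltr5_end = integer(0), ltr3_start = integer(0),
               ltr3_end = integer(0), internal_start = integer(0),
               internal_end = integer(0), ltr_size = integer(0),
               internal_size = integer(0), tsd = character(0),
               strand = character(0), rt_start = integer(0),
               rt_end = integer(0), rt_query = character(0),
               rt_protein = character(0),
               ltr_seq = character(0), stringsAsFactors = FALSE)
  if (nrow(elements)) {
    elements <- elements[order(elements$genome_id, elements$start), ,
                         drop = FALSE]
    elements$element_id <- sprintf("LTR%03d", seq_len(nrow(elements)))
    rownames(elements) <- NULL
  } else elements$element_id <- character(0)
  rejected <- if (length(rej)) do.call(rbind, rej) else
    cbind(.empty_hits(), data.frame(reason = character(0)))
  rownames(rejected) <- NULL
  list(elements = elements, rejected = rejected)
}
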