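## Cluster consensus sequences, conservation profiles and summary tables.

#' Majority-rule consensus of aligned sequences
#'
#' Per-column majority residue with gaps excluded from the vote; columns
#' with a gap fraction of 0.5 or more are dropped. Ties go to the residue
#' earlier in the fixed ordering ACDEFGHIKLMNPQRSTVWY.
#'
#' @param alignment Aligned sequences ([Biostrings::AAStringSet] or named
#'   character vector of equal lengths).
#' @return The consensus as a character string.
#' @export
consensus_sequence <- function(alignment) {
  if (methods::is(alignment, "AAStringSet")) {
    alignment <- as.character(alignment)
  }
  if (!length(alignment)) stop("empty alignment")
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  cons <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapf <- mean(col == "-")
    if (gapf >= 0.5) next
    col <- col[col != "-"]
    tb <- table(factor(col, levels = AA_ORDER))
    cons <- c(cons, names(tb)[which.max(tb)])  # which.max: first = earlier residue
  }
  paste(cons, collapse = "")
}

#' Per-column conservation profile
#'
#' Exact residue frequencies per alignment column (fractions of non-gap
#' residues, summing to 1), the gap fraction, and a conservation bin from
#' the maximum residue frequency using the thresholds >45%, >35%, >25%.
#'
#' @param alignment Aligned sequences (at least 2).
#' @return A list: `freq` (20 x L matrix), `gap_fraction` (length-L
#'   vector), `bins` (data.frame with `column`, `residue`, `max_freq`,
#'   `bin`).
#' @export
conservation_profile <- function(alignment) {
  if (methods::is(alignment, "AAStringSet")) {
    alignment <- as.character(alignment)
  }
  stopifnot(length(alignment) >= 2)
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  L <- ncol(m)
  freq <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ORDER, NULL))
  gapf <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    gapf[j] <- mean(col == "-")
    col <- col[col != "-"]
    if (length(col)) {
      freq[, j] <- as.numeric(table(factor(col, levels = AA_ORDER))) /
        length(col)
    }
  }
  mx <- apply(freq, 2, max)
  res <- AA_ORDER[apply(freq, 2, which.max)]
  bin <- ifelse(mx > 0.45, ">45%",
                ifelse(mx > 0.35, ">35%",
                       ifelse(mx > 0.25, ">25%", "below")))
  list(freq = freq, gap_fraction = gapf,
       bins = data.frame(column = seq_len(L), residue = res, max_freq = mx,
                         bin = bin, stringsAsFactors = FALSE))
}

#' Packaged reference table of published Retand cluster characteristics
#'
#' A transcription of the structural characteristics of 63 published
#' Retand PRARE cluster consensus elements (per-cluster average LTR,
#' internal-region and POL-3'LTR sizes in bp, domain presence flags,
#' auxiliary domains and tandem-array counts), used as a fixed input for
#' summary-statistic checks.
#'
#' @return A data.frame with one row per cluster.
#' @export
retand_cluster_table <- function() {
  utils::read.delim(system.file("extdata", "retand_cluster_table.tsv",
                                package = "prareminer"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Summary statistics over a cluster table
#'
#' Computes min / max / mean (mean rounded half-up to integer bp) for the
#' LTR, internal-region and POL-3'LTR sizes, counts defective clusters by
#' missing-domain pattern, and totals the tandem arrays. Min/max are
#' exact integer arithmetic on the input.
#'
#' @param clusters A cluster table with columns `ltr_bp`, `internal_bp`,
#'   `pol3ltr_bp` and optionally `gag`, `ap`, `rh`, `int` (YES/NO),
#'   `trp28`, `tandem_arrays` (as in [retand_cluster_table()]).
#' @return A list: `n_clusters`, `ltr`, `internal`, `pol3ltr` (each
#'   `c(min, max, mean)`), `defective` (named integer vector of clusters
#'   per missing-domain pattern), `n_defective`, `total_tandem_arrays`.
#' @export
summarize_clusters <- function(clusters) {
  stopifnot(nrow(clusters) >= 1)
  stat <- function(x) c(min = min(x), max = max(x),
                        mean = round_half_up(mean(x)))
  out <- list(n_clusters = nrow(clusters),
              ltr = stat(clusters$ltr_bp),
              internal = stat(clusters$internal_bp),
              pol3ltr = stat(clusters$pol3ltr_bp))
  dom_cols <- intersect(c("gag", "ap", "rh", "int"), names(clusters))
  if (length(dom_cols)) {
    miss <- apply(clusters[dom_cols], 1, function(row) {
      paste(toupper(dom_cols[row == "NO"]), collapse = "+")
    })
    def <- miss[nzchar(miss)]
    out$defective <- if (length(def)) sort(table(def), decreasing = TRUE)
                     else table(character(0))
    out$n_defective <- length(def)
  }
  if ("tandem_arrays" %in% names(clusters)) {
    out$total_tandem_arrays <- sum(clusters$tandem_arrays)
  }
  out
}

## Build Table-1-style per-cluster rows from pipeline results.
.cluster_summary_rows <- function(prare, annotations, representatives) {
  rows <- list()
  for (cl in names(representatives)) {
    members <- prare[prare$cluster_id == cl & prare$is_prare, , drop = FALSE]
    rep_id <- representatives[[cl]]
    a <- annotations[[rep_id]]
    doms_sense <- unique(unlist(lapply(
      a$orfs$domains[a$orfs$orientation == "sense"], function(d) d$name)))
    doms_anti <- unique(unlist(lapply(
      a$orfs$domains[a$orfs$orientation == "antisense"], function(d) d$name)))
    trp_rows <- which(vapply(seq_len(nrow(a$orfs)), function(i)
      "TRP28" %in% a$orfs$domains[[i]]$name, logical(1)))
    trp28 <- length(trp_rows) > 0
    trp28_short <- trp28 && all(a$orfs$short[trp_rows])
    aux <- setdiff(c(doms_sense, doms_anti), CORE_DOMAINS)
    aux <- setdiff(aux, "TRP28")
    pol3 <- annotations[members$element_id]
    pol3_sizes <- vapply(pol3, function(x)
      if (is.null(x$pol_3ltr)) NA_real_ else as.numeric(x$pol_3ltr$length),
      numeric(1))
    rows[[cl]] <- data.frame(
      cluster = cl,
      representative = rep_id,
      copy_number = nrow(members),
      ltr_bp = round_half_up(mean(members$ltr_size)),
      internal_bp = round_half_up(mean(members$internal_size)),
      pol3ltr_bp = round_half_up(mean(pol3_sizes, na.rm = TRUE)),
      gag = if ("GAG" %in% doms_sense) "YES" else "NO",
      ap = if ("AP" %in% doms_sense) "YES" else "NO",
      rh = if ("RH" %in% doms_sense) "YES" else "NO",
      int = if ("INT" %in% doms_sense) "YES" else "NO",
      trp28 = if (trp28) "YES" else "NO",
      trp28_short_orf = trp28_short,
      other_domains = if (length(aux)) paste(sort(aux), collapse = ",")
                      else ".",
      tandem_arrays = nrow(a$tandem_arrays),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
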