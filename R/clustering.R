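## Greedy LTR clustering and the 2% size-deviation filter that defines
## PRAREs.

#' Greedy incremental clustering of LTR sequences
#'
#' Sequences are sorted by length (descending, ties lexicographic by id)
#' and processed in order: each sequence joins the first existing cluster
#' whose representative (founder) it matches at `identity >= cutoff`,
#' otherwise it founds a new cluster. Identity is matches divided by the
#' total column count of a global BLOSUM-free nucleotide alignment (match
#' +1 / mismatch -1, gap open 5, extend 2) - an exact global-alignment
#' identity rather than a k-mer estimate.
#'
#' @param ltr_sequences Named character vector (names are element ids).
#' @param identity_cutoff Identity threshold in (0, 1] (default 0.90).
#' @return A data.frame with `element_id`, `cluster_id`,
#'   `representative_id`, `identity` (to the representative).
#' @export
cluster_ltrs <- function(ltr_sequences, identity_cutoff = 0.90) {
  stopifnot(length(ltr_sequences) > 0)
  if (identity_cutoff <= 0 || identity_cutoff > 1) {
    stop("identity cutoff outside (0, 1]")
  }
  ids <- names(ltr_sequences)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ord <- order(-nchar(ltr_sequences), ids)
  reps <- character(0)       # representative ids in founding order
  assign_cluster <- character(length(ltr_sequences))
  names(assign_cluster) <- ids
  ident <- stats::setNames(numeric(length(ltr_sequences)), ids)
  for (i in ord) {
    id <- ids[i]
    s <- ltr_sequences[[i]]
    placed <- FALSE
    for (r in reps) {
      pid <- .global_identity(ltr_sequences[[r]], s)
      if (pid >= identity_cutoff) {
        assign_cluster[id] <- r
        ident[id] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign_cluster[id] <- id
      ident[id] <- 1
    }
  }
  cluster_id <- stats::setNames(sprintf("C%03d", seq_along(reps)), reps)
  data.frame(element_id = ids,
             cluster_id = unname(cluster_id[assign_cluster[ids]]),
             representative_id = unname(assign_cluster[ids]),
             identity = unname(ident[ids]),
             stringsAsFactors = FALSE)
}

## global DNA alignment identity: matches / alignment columns
.global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  alen <- nchar(as.character(Biostrings::pattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' Consensus sizes of a cluster
#'
#' The consensus size is the member median; even member counts take the
#' lower middle value, so the consensus is always an observed size.
#'
#' @param members Element table rows (needs `ltr_size`, `internal_size`).
#' @return A list with `consensus_ltr_size` and `consensus_internal_size`.
#' @export
consensus_sizes <- function(members) {
  stopifnot(nrow(members) >= 1)
  list(consensus_ltr_size = median_lower(members$ltr_size),
       consensus_internal_size = median_lower(members$internal_size))
}

#' Apply the 2% size-deviation PRARE filter
#'
#' An element is retained iff both its LTR size and its internal size are
#' within `tolerance` (relative deviation) of the cluster consensus sizes;
#' an element whose LTR *or* internal size deviates more is excluded.
#'
#' @param clusters Cluster assignment from [cluster_ltrs()].
#' @param elements Element table from [build_elements()].
#' @param tolerance Relative size deviation (default 0.02).
#' @return The element table with columns `cluster_id`, `ltr_dev`,
#'   `internal_dev`, `is_prare` appended.
#' @export
prare_filter <- function(clusters, elements, tolerance = 0.02) {
  stopifnot(nrow(elements) == nrow(clusters))
  out <- merge(elements, clusters[, c("element_id", "cluster_id")],
               by = "element_id", sort = FALSE)
  out$ltr_dev <- NA_real_
  out$internal_dev <- NA_real_
  for (cl in unique(out$cluster_id)) {
    idx <- which(out$cluster_id == cl)
    cs <- consensus_sizes(out[idx, ])
    if (cs$consensus_ltr_size == 0 || cs$consensus_internal_size == 0) {
      stop("consensus size 0 in cluster ", cl)
    }
    out$ltr_dev[idx] <- abs(out$ltr_size[idx] - cs$consensus_ltr_size) /
      cs$consensus_ltr_size
    out$internal_dev[idx] <-
      abs(out$internal_size[idx] - cs$consensus_internal_size) /
      cs$consensus_internal_size
  }
  out$is_prare <- out$ltr_dev <= tolerance & out$internal_dev <= tolerance
  out <- out[order(out$genome_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick a cluster's representative element
#'
#' Each member is summarized as a structure vector (sense/antisense ORF
#' counts, the set of domains present, tandem-array count); the
#' representative is a member matching the modal vector, ties broken by
#' smallest total size deviation then lexicographic element id.
#'
#' @param members Filtered element rows of one cluster (with `ltr_dev`,
#'   `internal_dev`).
#' @param annotations Named list of per-element annotations
#'   ([annotate_element()] results) covering the members.
#' @return The representative element id.
#' @export
pick_representative <- function(members, annotations) {
  stopifnot(nrow(members) >= 1)
  vecs <- vapply(members$element_id, function(id) {
    a <- annotations[[id]]
    orfs <- a$orfs
    doms <- sort(unique(unlist(lapply(orfs$domains, function(d) d$name))))
    paste(sum(orfs$orientation == "sense"),
          sum(orfs$orientation == "antisense"),
          paste(doms, collapse = ","),
          nrow(a$tandem_arrays), sep = "|")
  }, character(1))
  tab <- table(vecs)
  modal <- names(tab)[tab == max(tab)]
  modal <- sort(modal)[1]
  cand <- members[vecs == modal, , drop = FALSE]
  dev <- cand$ltr_dev + cand$internal_dev
  cand$element_id[order(dev, cand$element_id)][1]
}
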