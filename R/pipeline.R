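## End-to-end orchestration: RT search -> lineage assignment -> element
## reconstruction -> clustering + PRARE filter -> annotation -> reports.

#' Run the full PRARE discovery pipeline
#'
#' @param genomes Named character vector, [Biostrings::DNAStringSet], or a
#'   path to a FASTA file.
#' @param panel Model RT panel (`lineage|name` protein set); its Retand
#'   entries are the search queries.
#' @param profiles Domain profiles for annotation.
#' @param min_score RT-search score threshold (see [calibrate_min_score()]).
#' @param min_len,max_len Complete-RT-domain length window in aa.
#' @param window Flank window around RT hits in bp.
#' @param min_ltr,max_ltr Accepted LTR length range in bp.
#' @param tsd_len TSD length tested at element boundaries.
#' @param identity_cutoff LTR clustering identity cutoff.
#' @param tolerance PRARE size-deviation tolerance.
#' @param min_orf Minimum ORF length in bp.
#' @param seqname_pattern Optional regexp restricting the search to
#'   matching sequence names (e.g. `"chr"` to skip scaffolds).
#' @param min_copies_tree Minimum PRARE copies for a cluster to enter the
#'   consensus RT tree (the published rule is 10).
#' @param tree_replicates Bootstrap replicates for the cluster tree.
#' @param rng_seed Seed for the bootstrap stage.
#' @param output_dir If non-NULL, reports are written here (GFF3, FASTA,
#'   TSV, BED, Newick and a JSON run log).
#' @return A list of class `prare_run` with `hits`, `candidates` (hits +
#'   lineage), `elements`, `rejected`, `prare` (element table with cluster
#'   ids, deviations and the `is_prare` flag), `annotations`,
#'   `representatives`, `cluster_table`, `summary`, `tree` (or NULL),
#'   `params`.
#' @export
run_pipeline <- function(genomes,
                         panel = synthetic_rt_panel(),
                         profiles = retand_domain_profiles(),
                         min_score = 150, min_len = 157, max_len = 162,
                         window = 10000, min_ltr = 100, max_ltr = 3000,
                         tsd_len = 5, identity_cutoff = 0.90,
                         tolerance = 0.02, min_orf = 600,
                         seqname_pattern = NULL,
                         min_copies_tree = 10, tree_replicates = 1000,
                         rng_seed = 1, output_dir = NULL) {
  if (is.character(genomes) && length(genomes) == 1 && file.exists(genomes)) {
    genomes <- read_genomes(genomes)
  }
  if (methods::is(genomes, "DNAStringSet")) {
    genomes <- stats::setNames(as.character(genomes), names(genomes))
  }
  params <- list(min_score = min_score, min_len = min_len,
                 max_len = max_len, window = window, min_ltr = min_ltr,
                 max_ltr = max_ltr, tsd_len = tsd_len,
                 identity_cutoff = identity_cutoff, tolerance = tolerance,
                 min_orf = min_orf, seqname_pattern = seqname_pattern,
                 min_copies_tree = min_copies_tree,
                 tree_replicates = tree_replicates, rng_seed = rng_seed)

  empty <- length(genomes) == 0
  if (empty) warning("empty genome set: producing an empty report")
  queries <- rt_queries(panel)

  hits <- if (empty) .empty_hits() else
    find_rt_hits(genomes, queries, min_score = min_score,
                 min_len = min_len, max_len = max_len,
                 seqname_pattern = seqname_pattern)
  candidates <- assign_lineage(hits, panel)
  retand_hits <- if (nrow(candidates))
    candidates[candidates$lineage == "Retand", , drop = FALSE]
  else candidates

  built <- build_elements(genomes, retand_hits, window = window,
                          min_ltr = min_ltr, max_ltr = max_ltr,
                          tsd_len = tsd_len)
  elements <- built$elements

  if (nrow(elements)) {
    clusters <- cluster_ltrs(
      stats::setNames(elements$ltr_seq, elements$element_id),
      identity_cutoff = identity_cutoff)
    prare <- prare_filter(clusters, elements, tolerance = tolerance)
  } else {
    clusters <- data.frame(element_id = character(0),
                           cluster_id = character(0),
                           representative_id = character(0),
                           identity = numeric(0))
    prare <- cbind(elements,
                   data.frame(cluster_id = character(0),
                              ltr_dev = numeric(0),
                              internal_dev = numeric(0),
                              is_prare = logical(0)))
  }

  retained <- prare[prare$is_prare, , drop = FALSE]
  annotations <- if (nrow(retained))
    annotate_elements(genomes, retained, profiles, min_orf = min_orf)
  else list()

  representatives <- list()
  for (cl in unique(retained$cluster_id)) {
    members <- retained[retained$cluster_id == cl, , drop = FALSE]
    representatives[[cl]] <- pick_representative(members, annotations)
  }

  cluster_table <- if (length(representatives))
    .cluster_summary_rows(prare, annotations, representatives)
  else NULL
  summary <- if (!is.null(cluster_table)) summarize_clusters(cluster_table)
             else NULL

  ## consensus RT tree over well-populated clusters plus the Retand refs
  tree <- NULL
  if (!is.null(cluster_table)) {
    big <- cluster_table$cluster[cluster_table$copy_number >= min_copies_tree]
    if (length(big) + length(queries) >= 3 && length(big) >= 1) {
      cons <- vapply(big, function(cl) {
        ids <- retained$element_id[retained$cluster_id == cl]
        prots <- stats::setNames(retained$rt_protein[match(ids, retained$element_id)], ids)
        if (length(prots) == 1) unname(prots)
        else consensus_sequence(align_panel(prots))
      }, character(1))
      taxa <- c(cons, stats::setNames(unname(queries),
                                      paste0("Retand|", names(queries))))
      aln <- align_panel(taxa)
      tree <- bootstrap_support(aln, replicates = tree_replicates,
                                rng_seed = rng_seed)
    }
  }

  run <- structure(list(hits = hits, candidates = candidates,
                        elements = elements, rejected = built$rejected,
                        clusters = clusters, prare = prare,
                        annotations = annotations,
                        representatives = representatives,
                        cluster_table = cluster_table, summary = summary,
                        tree = tree, params = params),
                   class = "prare_run")
  if (!is.null(output_dir)) write_run(run, genomes, output_dir)
  run
}

#' @export
print.prare_run <- function(x, ...) {
  cat(sprintf(
    "<prare_run: %d RT hits, %d Retand candidates, %d elements, %d PRAREs in %d clusters>\n",
    nrow(x$hits),
    sum(x$candidates$lineage == "Retand"),
    nrow(x$elements), sum(x$prare$is_prare),
    length(unique(x$prare$cluster_id[x$prare$is_prare]))))
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits elements and annotations as GFF3, element/LTR/representative
#' sequences as FASTA, hits as TSV + BED, cluster membership and cluster
#' summaries as TSV, the cluster consensus tree as Newick (bootstrap
#' supports as node labels), and a JSON run log with all parameters.
#'
#' @param run A `prare_run`.
#' @param genomes The genome set the run was computed on.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (methods::is(genomes, "DNAStringSet")) {
    genomes <- stats::setNames(as.character(genomes), names(genomes))
  }
  write_hits(run$hits, tsv = file.path(dir, "rt_hits.tsv"),
             bed = file.path(dir, "rt_hits.bed"))
  write_tsv(run$candidates, file.path(dir, "rt_candidates.tsv"))
  write_tsv(run$rejected, file.path(dir, "rejected_hits.tsv"))
  write_tsv(run$prare[, setdiff(names(run$prare),
                                c("ltr_seq", "rt_protein"))],
            file.path(dir, "elements.tsv"))

  ## element features as GFF3
  feats <- list()
  for (i in seq_len(nrow(run$prare))) {
    e <- run$prare[i, ]
    feats[[length(feats) + 1]] <- data.frame(
      genome_id = e$genome_id,
      feature = c("element", "ltr5", "ltr3", "tsd"),
      start = c(e$start, e$ltr5_start, e$ltr3_start, e$start - nchar(e$tsd)),
      end = c(e$end, e$ltr5_end, e$ltr3_end, e$start - 1L),
      strand = e$strand,
      element_id = e$element_id,
      cluster_id = e$cluster_id,
      is_prare_eligible = e$is_prare,
      stringsAsFactors = FALSE)
  }
  el_feat <- if (length(feats)) do.call(rbind, feats) else
    data.frame(genome_id = character(0), feature = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  export_features_gff3(el_feat, file.path(dir, "elements.gff3"))

  if (nrow(run$prare)) {
    el_seqs <- vapply(seq_len(nrow(run$prare)), function(i) {
      e <- run$prare[i, ]
      substr(genomes[[e$genome_id]], e$start, e$end)
    }, character(1))
    names(el_seqs) <- run$prare$element_id
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(el_seqs),
                                file.path(dir, "elements.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(
        stats::setNames(run$prare$ltr_seq, run$prare$element_id)),
      file.path(dir, "ltrs.fasta"))
  }

  ## annotations as GFF3 + per-element TSV
  ann <- list()
  for (id in names(run$annotations)) {
    a <- run$annotations[[id]]
    e <- run$prare[run$prare$element_id == id, ]
    if (nrow(a$orfs)) for (i in seq_len(nrow(a$orfs))) {
      sp <- local_to_genome(c(a$orfs$start[i], a$orfs$end[i]), e)
      gstrand <- if ((a$orfs$strand[i] == "+") == (e$strand == "+")) "+" else "-"
      ann[[length(ann) + 1]] <- data.frame(
        genome_id = e$genome_id, feature = "ORF", start = sp[1], end = sp[2],
        strand = gstrand, element_id = id,
        name = paste0("orf_", i),
        orientation = a$orfs$orientation[i],
        period = NA_integer_, copies = NA_integer_, stringsAsFactors = FALSE)
      d <- a$orfs$domains[[i]]
      if (nrow(d)) for (k in seq_len(nrow(d))) {
        ## residue -> local nt within the ORF, then to genome
        if (a$orfs$strand[i] == "+") {
          loc <- c(a$orfs$start[i] + 3 * (d$start[k] - 1),
                   a$orfs$start[i] + 3 * d$end[k] - 1)
        } else {
          loc <- c(a$orfs$end[i] - 3 * d$end[k] + 1,
                   a$orfs$end[i] - 3 * (d$start[k] - 1))
        }
        sp <- local_to_genome(loc, e)
        ann[[length(ann) + 1]] <- data.frame(
          genome_id = e$genome_id, feature = "domain", start = sp[1],
          end = sp[2], strand = gstrand, element_id = id, name = d$name[k],
          orientation = a$orfs$orientation[i],
          period = NA_integer_, copies = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(a$tandem_arrays)) for (i in seq_len(nrow(a$tandem_arrays))) {
      t <- a$tandem_arrays[i, ]
      sp <- local_to_genome(c(t$start, t$end), e)
      ann[[length(ann) + 1]] <- data.frame(
        genome_id = e$genome_id, feature = "tandem_repeat", start = sp[1],
        end = sp[2], strand = "+", element_id = id,
        name = paste0("array_", i), orientation = NA_character_,
        period = t$period, copies = t$copies, stringsAsFactors = FALSE)
    }
  }
  ann_df <- if (length(ann)) do.call(rbind, ann) else
    data.frame(genome_id = character(0), feature = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  export_features_gff3(ann_df, file.path(dir, "annotations.gff3"))
  write_tsv(ann_df, file.path(dir, "annotations.tsv"))

  if (!is.null(run$cluster_table)) {
    write_tsv(run$cluster_table, file.path(dir, "cluster_summary.tsv"))
    rep_ids <- unlist(run$representatives)
    rep_rows <- run$prare[match(rep_ids, run$prare$element_id), ]
    rep_seqs <- vapply(seq_len(nrow(rep_rows)), function(i) {
      e <- rep_rows[i, ]
      substr(genomes[[e$genome_id]], e$start, e$end)
    }, character(1))
    names(rep_seqs) <- paste0(names(run$representatives), "_", rep_ids)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rep_seqs),
                                file.path(dir, "representatives.fasta"))
  }
  if (!is.null(run$tree)) {
    tr <- run$tree$tree
    tr$node.label <- ifelse(is.na(tr$node.label), "", tr$node.label)
    ape::write.tree(tr, file.path(dir, "cluster_tree.nwk"))
  }
  log <- c(run$params, list(n_hits = nrow(run$hits),
                            n_elements = nrow(run$elements),
                            n_prare = sum(run$prare$is_prare)))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(dir, "run_log.json"))
  invisible(dir)
}
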