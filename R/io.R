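## File-format plumbing: FASTA via Biostrings, GFF3/BED via rtracklayer,
## TSV via write.table with fixed options so reruns are byte-identical.

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return A named character vector of sequences.
#' @export
read_genomes <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## Feature data.frame (genome_id/start/end/strand/feature/name/...) -> GFF3.
export_features_gff3 <- function(df, path, source = "prareminer") {
  if (!nrow(df)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- ifelse(is.na(df$strand) | !df$strand %in% c("+", "-"),
                   "*", df$strand)
  gr <- GenomicRanges::GRanges(df$genome_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = strand)
  meta <- data.frame(source = source, type = df$feature,
                     stringsAsFactors = FALSE)
  for (col in intersect(c("element_id", "name", "orientation", "period",
                          "copies", "type_tag", "family", "tsd",
                          "is_prare_eligible", "cluster_id", "reason"),
                        names(df))) {
    meta[[col]] <- df[[col]]
  }
  if (!is.null(df$type) && !"type_tag" %in% names(df)) {
    meta$type_tag <- df$type
  }
  S4Vectors::mcols(gr) <- meta
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## Deterministic TSV writer shared by all reports.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write RT hits as TSV and BED
#'
#' The TSV carries 1-based coordinates; the BED export converts to the
#' format's 0-based half-open convention.
#'
#' @param hits A hit table from [find_rt_hits()].
#' @param tsv,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_hits <- function(hits, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) write_tsv(hits, tsv)
  if (!is.null(bed)) {
    if (nrow(hits)) {
      gr <- GenomicRanges::GRanges(hits$genome_id,
                                   IRanges::IRanges(hits$start, hits$end),
                                   strand = hits$strand)
      S4Vectors::mcols(gr)$name <- paste0(hits$query_id, "_", hits$start)
      S4Vectors::mcols(gr)$score <- hits$score
      rtracklayer::export(gr, bed, format = "bed")
    } else {
      file.create(bed)
    }
  }
  invisible(c(tsv = tsv, bed = bed))
}
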