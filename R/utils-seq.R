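## Low-level sequence helpers shared by all modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Reverse lookup of the standard genetic code: amino acid -> codons.
codon_table_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' Draws an i.i.d. sequence over A/C/G/T, optionally biased to a target
#' GC content. Uses the current RNG stream.
#'
#' @param n Sequence length in bp.
#' @param gc Target GC content as a fraction (default 0.5, i.e. uniform).
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Random amino-acid sequence (uniform over the 20 residues)
#' @param n Protein length in residues.
#' @return A character string.
#' @export
random_protein <- function(n) {
  paste(sample(AA_ORDER, n, replace = TRUE), collapse = "")
}

## Apply k substitutions at distinct positions; each substitution changes
## the character to a different symbol from `alphabet`.
mutate_string <- function(x, k, alphabet = DNA_BASES) {
  chars <- strsplit(x, "")[[1]]
  if (k == 0) return(x)
  stopifnot(k <= length(chars))
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

## Substitute a fraction of positions (interior only when protect > 0, so
## that e.g. domain termini stay recognizable).
mutate_fraction <- function(x, rate, alphabet = AA_ORDER, protect = 0L) {
  n <- nchar(x)
  interior <- seq_len(n)
  if (protect > 0) interior <- interior[interior > protect & interior <= n - protect]
  k <- round(rate * length(interior))
  if (k == 0) return(x)
  chars <- strsplit(x, "")[[1]]
  pos <- sample(interior, k)
  for (p in pos) chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Reverse complement of a DNA string
#' @param x A character string over A/C/G/T/N.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Encode a protein as DNA, codon by codon
#'
#' Builds `ATG` + one sense codon per residue + a stop codon, choosing
#' synonymous codons with the current RNG stream. The first residue of
#' `protein` is encoded as written (it need not be M); the initiator ATG
#' is prepended separately, so the full open reading frame translates to
#' `M<protein>`.
#'
#' @param protein Amino-acid string without stop characters.
#' @param add_start,add_stop Include the initiator ATG / a stop codon.
#' @return A DNA character string of length `3 * (nchar(protein) + add_start + add_stop)`.
#' @export
encode_protein <- function(protein, add_start = TRUE, add_stop = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  stopifnot(!any(aa == "*"))
  tab <- codon_table_by_aa()
  codons <- vapply(aa, function(a) {
    cands <- tab[[a]]
    if (is.null(cands)) stop("cannot encode residue: ", a)
    cands[sample.int(length(cands), 1)]
  }, character(1))
  stops <- c("TAA", "TAG", "TGA")
  paste0(
    if (add_start) "ATG" else "",
    paste(codons, collapse = ""),
    if (add_stop) stops[sample.int(3, 1)] else ""
  )
}

#' Translate all six reading frames
#'
#' Translates a DNA sequence in frames 0/1/2 on the forward strand and
#' frames 0/1/2 on the reverse-complement, under the standard genetic
#' code. Codons containing N translate to `X`; stop codons to `*`.
#'
#' @param dna A character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @return A data.frame with columns `strand` (`+`/`-`), `frame` (0, 1, 2:
#'   offset from the 5' end of the translated strand) and `protein`.
#' @export
six_frame_translate <- function(dna) {
  if (is.character(dna)) dna <- Biostrings::DNAString(dna)
  n <- length(dna)
  if (n == 0) stop("empty sequence")
  rc <- Biostrings::reverseComplement(dna)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (off in 0:2) {
      len <- ((n - off) %/% 3) * 3
      prot <- if (len >= 3) {
        codons <- Biostrings::subseq(s, start = off + 1, width = len)
        ## the fuzzy-codon path is slow; only take it when needed.
        ## no.init.codon: never promote TTG/CTG at the window start to M
        if (grepl("[^ACGT]", as.character(codons))) {
          as.character(Biostrings::translate(codons, if.fuzzy.codon = "X",
                                             no.init.codon = TRUE))
        } else {
          as.character(Biostrings::translate(codons, no.init.codon = TRUE))
        }
      } else ""
      rows[[length(rows) + 1]] <-
        data.frame(strand = strand, frame = off, protein = prot,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Map an amino-acid interval [aa_start, aa_end] in a translated frame back
## to 1-based DNA coordinates on the forward strand of a sequence of length n.
frame_to_dna <- function(aa_start, aa_end, strand, frame, n) {
  d1 <- frame + 3 * (aa_start - 1) + 1
  d2 <- frame + 3 * aa_end
  as.integer(if (strand == "+") c(d1, d2) else c(n - d2 + 1, n - d1 + 1))
}

## Deterministic formatting helpers -----------------------------------------

## round half up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

## fixed lower-middle median: sorted[floor((n+1)/2)]
median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}
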