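## Model RT panel and protein-domain profiles.
##
## Real surveys query public RT sequences (Tat4-1, Gret1, Cinful-1,
## Grande1-4) and search Pfam/CDD profile databases. This package ships no
## third-party database content: the RT panel and the domain models are
## synthetic stand-ins generated deterministically, with the same shape as
## the real objects (a 62-sequence lineage-labeled protein panel; one
## position-specific scoring matrix per domain). Users can substitute real
## panels (protein FASTA with "lineage|name" headers) and their own score
## tables at every entry point.

PANEL_SEED <- 20240401L

GYPSY_LINEAGES <- c("Tekay", "Athila", "Ogre", "Tat", "CRM", "Reina",
                    "Galadriel", "Selgy")
RETAND_REF_NAMES <- c("Tat4-1", "Gret1", "Cinful-1", "Grande1-4")

#' Synthetic model RT panel
#'
#' Generates a deterministic 62-sequence reverse-transcriptase domain panel:
#' four Retand reference sequences (stand-ins for the characterized Tat4-1,
#' Gret1, Cinful-1 and Grande1-4 RT domains, 159-160 aa), seven members for
#' each of eight other Ty3/gypsy lineages, and two distant Caulimoviridae
#' outgroup sequences. Lineages are simulated by substituting interior
#' residues of a common ancestral domain (lineage founders at 35%
#' divergence, members at 8-10% from their founder, Caulimoviridae at 50%);
#' the five terminal residues on each side are kept invariant, emulating
#' conserved domain-boundary motifs.
#'
#' @return An [Biostrings::AAStringSet] with `lineage|name` headers.
#' @export
synthetic_rt_panel <- function() {
  with_seed(PANEL_SEED, {
    anc <- random_protein(159)
    seqs <- character(0)
    ## Retand references
    founder <- mutate_fraction(anc, 0.35, protect = 5)
    for (nm in RETAND_REF_NAMES) {
      s <- mutate_fraction(founder, 0.08, protect = 5)
      if (nm == "Grande1-4") {
        ## one-residue insertion: the stand-in mirrors the 160-aa query
        s <- paste0(substr(s, 1, 80), sample(AA_ORDER, 1), substr(s, 81, 159))
      }
      seqs[paste0("Retand|", nm)] <- s
    }
    for (lin in GYPSY_LINEAGES) {
      lf <- mutate_fraction(anc, 0.35, protect = 5)
      for (i in 1:7) {
        seqs[paste0(lin, "|", lin, "-", i)] <- mutate_fraction(lf, 0.10, protect = 5)
      }
    }
    for (i in 1:2) {
      seqs[paste0("Caulimoviridae|CaMV-like-", i)] <-
        mutate_fraction(anc, 0.50, protect = 5)
    }
    Biostrings::AAStringSet(seqs)
  })
}

#' Retand RT query sequences from a panel
#'
#' Extracts the Retand reference entries of a `lineage|name` panel as the
#' query set for [find_rt_hits()].
#'
#' @param panel An [Biostrings::AAStringSet] with `lineage|name` headers
#'   (default: [synthetic_rt_panel()]).
#' @return A named character vector of protein sequences (names without the
#'   lineage prefix).
#' @export
rt_queries <- function(panel = synthetic_rt_panel()) {
  lin <- sub("\\|.*$", "", names(panel))
  q <- as.character(panel[lin == "Retand"])
  names(q) <- sub("^Retand\\|", "", names(q))
  lens <- nchar(q)
  stopifnot(all(lens >= 150 & lens <= 170))
  q
}

## Domain profiles -----------------------------------------------------------

#' Build a position-specific scoring matrix from a consensus peptide
#'
#' Columns are log2-odds scores against a uniform residue background: the
#' consensus residue is modeled at probability `p_match`, all others share
#' the remainder. Unknown residues (X) score `unknown_score` at every
#' column.
#'
#' @param name Domain name.
#' @param consensus Consensus amino-acid string.
#' @param p_match Modeled match probability of the consensus residue.
#' @param threshold Score threshold for reporting a hit (see
#'   [calibrate_profile_threshold()]).
#' @param unknown_score Per-position score of an X residue.
#' @return An object of class `domain_profile`: a list with `name`, `width`,
#'   `mat` (21 x width score matrix, row 21 = unknown) and `threshold`.
#' @export
profile_from_consensus <- function(name, consensus, p_match = 0.7,
                                   threshold = 0, unknown_score = -2) {
  aa <- strsplit(consensus, "")[[1]]
  stopifnot(all(aa %in% AA_ORDER))
  w <- length(aa)
  bg <- 1 / 20
  mism <- (1 - p_match) / 19
  mat <- matrix(log2(mism / bg), nrow = 21, ncol = w,
                dimnames = list(c(AA_ORDER, "X"), NULL))
  mat[cbind(match(aa, AA_ORDER), seq_len(w))] <- log2(p_match / bg)
  mat["X", ] <- unknown_score
  structure(list(name = name, width = w, mat = mat, threshold = threshold,
                 consensus = consensus),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile %s: width %d aa, threshold %.1f>\n",
              x$name, x$width, x$threshold))
  invisible(x)
}

## All sliding-window scores of a profile along a protein.
profile_window_scores <- function(protein, profile) {
  idx <- match(strsplit(protein, "")[[1]], AA_ORDER)
  idx[is.na(idx)] <- 21L
  L <- length(idx)
  w <- profile$width
  if (L < w) return(numeric(0))
  n <- L - w + 1
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + profile$mat[cbind(idx[j:(j + n - 1)], j)]
  }
  scores
}

#' Calibrate a domain-profile score threshold on shuffled background
#'
#' Scores the profile along `n` random proteins (uniform residue
#' composition, length `protein_length`) and returns the smallest threshold
#' whose per-protein false-positive rate on that background is at most
#' `fpr`. With the defaults the returned value is the maximum observed
#' null window score plus one.
#'
#' @param profile A `domain_profile`.
#' @param n Number of background proteins.
#' @param protein_length Length of each background protein.
#' @param fpr Tolerated fraction of background proteins with a hit.
#' @param rng_seed Seed for background generation.
#' @return A numeric threshold.
#' @export
calibrate_profile_threshold <- function(profile, n = 500, protein_length = 500,
                                        fpr = 0, rng_seed = 1) {
  stopifnot(fpr >= 0, fpr < 1)
  maxima <- with_seed(rng_seed, {
    vapply(seq_len(n), function(i) {
      s <- profile_window_scores(random_protein(protein_length), profile)
      if (length(s)) max(s) else -Inf
    }, numeric(1))
  })
  if (fpr == 0) return(max(maxima) + 1)
  as.numeric(quantile(maxima, 1 - fpr, type = 1)) + 1e-9
}

POL_DOMAINS <- c("AP", "RT", "RH", "INT")
CORE_DOMAINS <- c("GAG", "AP", "RT", "RH", "INT")

#' Packaged domain-profile set
#'
#' Loads the packaged synthetic domain models (GAG, AP, RT, RH, INT, the
#' antisense TRP28 domain, and several auxiliary domains observed in
#' POL-3'LTR antisense ORFs) as `domain_profile` objects with
#' pre-calibrated thresholds. The consensus peptides and thresholds ship
#' as a plain-text table; see [profile_from_consensus()] to build profiles
#' from user-supplied consensus sequences and
#' [calibrate_profile_threshold()] to recalibrate.
#'
#' @param file Path to a consensus table (columns `name`, `threshold`,
#'   `consensus`); defaults to the packaged fixture.
#' @return A named list of `domain_profile` objects.
#' @export
retand_domain_profiles <- function(file = system.file("extdata",
                                                      "domain_consensus.tsv",
                                                      package = "prareminer")) {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  profs <- lapply(seq_len(nrow(tab)), function(i) {
    profile_from_consensus(tab$name[i], tab$consensus[i],
                           threshold = tab$threshold[i])
  })
  stats::setNames(profs, tab$name)
}
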