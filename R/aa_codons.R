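# Amino-acid and codon conventions shared across the package.

#' Fixed amino-acid column order
#'
#' Alphabetical one-letter order used everywhere substitutions are
#' enumerated or laid out (variant enumeration, heatmap columns).
#'
#' @return Character vector of the 20 standard amino acids.
#' @export
aa_order <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Codons per amino acid, ordered by approximate human usage (most used
# first). Only the ordering matters: it makes codon choices deterministic.
codon_preference <- function() {
  list(
    A = c("GCC", "GCT", "GCA", "GCG"),
    C = c("TGC", "TGT"),
    D = c("GAC", "GAT"),
    E = c("GAG", "GAA"),
    F = c("TTC", "TTT"),
    G = c("GGC", "GGA", "GGG", "GGT"),
    H = c("CAC", "CAT"),
    I = c("ATC", "ATT", "ATA"),
    K = c("AAG", "AAA"),
    L = c("CTG", "CTC", "TTG", "CTT", "TTA", "CTA"),
    M = c("ATG"),
    N = c("AAC", "AAT"),
    P = c("CCC", "CCT", "CCA", "CCG"),
    Q = c("CAG", "CAA"),
    R = c("AGA", "AGG", "CGG", "CGC", "CGA", "CGT"),
    S = c("AGC", "TCC", "TCT", "AGT", "TCA", "TCG"),
    T = c("ACC", "ACA", "ACT", "ACG"),
    V = c("GTG", "GTC", "GTT", "GTA"),
    W = c("TGG"),
    Y = c("TAC", "TAT")
  )
}

# Most-used codon per amino acid (deterministic back-translation).
preferred_codon <- function(aa) {
  pref <- codon_preference()
  bad <- !aa %in% names(pref)
  if (any(bad)) {
    stop("no codon for non-standard amino acid(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  vapply(pref[aa], `[[`, character(1), 1L)
}

# First synonymous codon differing from `current` for amino acid `aa`.
alternative_codon <- function(aa, current) {
  choices <- codon_preference()[[aa]]
  alt <- setdiff(choices, current)
  if (length(alt) == 0L) {
    stop("amino acid ", aa, " has a single codon; no synonymous alternative")
  }
  alt[[1L]]
}

# Split a coding DNA string into its codons.
split_codons <- function(dna) {
  n <- nchar(dna)
  stopifnot(n %% 3L == 0L)
  substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Translate a coding DNA string using the standard genetic code.
translate_dna <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[split_codons(toupper(dna))]
  if (anyNA(aa)) stop("sequence contains non-ACGT codons")
  paste(aa, collapse = "")
}

# Codon -> amino acid lookup for vectors of codons; unknown codons give NA.
codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}
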