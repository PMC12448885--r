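# Library design: the mutagenized domain, overlapping amplicon fragments,
# and the marked-WT / stop-control spike-in constructs.

# Synthetic stand-in for the tandem BRCT region of human BRCA1 (residues
# 1646-1859 of NP_009225, 214 aa). The true sequence is not bundled; this
# fixed surrogate has the documented wild-type identities at the residues
# the screen literature names explicitly (S1655, F1668, R1699, D1739,
# V1741, P1749) and arbitrary composition elsewhere. All positional
# machinery (numbering, fragmentation, spike-ins) is independent of the
# actual letters.
BRCT_SYNTHETIC_AA <- paste0(
  "AIHTMSVGHSDLNDDWTTTVLKFAGTWTWQIMTPPNQVRGKCGKWQPGHATNARMFVLSTYCRLFWSSVASVEK",
  "WYPCFSHMFHFTLREKGMADRVGNKQSTYPYQGKNSTTIRCFQIFHCYGIMGQPANSGNAAWLDPSPSDKPVCR",
  "ARVRHMFMFYWPNATQFDMHNWPFWTRDMSMIRCPAGCNSDENMDEPRFQNKDKDKRFGMPITRGD"
)

#' Describe the mutagenized domain
#'
#' A `domain_spec` holds the wild-type amino-acid and coding DNA sequence
#' of the region covered by the site-saturation library, together with its
#' absolute (full-protein) residue coordinates. Residue numbering is
#' 1-based and inclusive; all positions elsewhere in the package are in
#' this absolute numbering.
#'
#' @param wt_aa_seq Wild-type amino-acid sequence (one-letter, length L).
#' @param wt_dna_seq Optional coding DNA (length 3L). When omitted it is
#'   back-translated with the most-used human codon per residue.
#' @param start_pos Absolute residue number of the first position
#'   (default 1646, the first residue of the BRCA1 BRCT region).
#' @param protein_label Free-text protein name.
#' @return A `domain_spec` list with fields `protein_label`, `start_pos`,
#'   `end_pos`, `length`, `wt_aa`, `wt_dna`.
#' @export
domain_spec <- function(wt_aa_seq, wt_dna_seq = NULL, start_pos = 1646L,
                        protein_label = "BRCA1-BRCT") {
  wt_aa_seq <- toupper(wt_aa_seq)
  aa <- strsplit(wt_aa_seq, "")[[1]]
  bad <- which(!aa %in% aa_order())
  if (length(bad) > 0L) {
    stop("non-standard residue(s) in wt_aa_seq at position(s): ",
         paste(bad + start_pos - 1L, collapse = ", "),
         " (", paste(unique(aa[bad]), collapse = ", "), ")")
  }
  L <- length(aa)
  if (is.null(wt_dna_seq)) {
    wt_dna_seq <- paste(preferred_codon(aa), collapse = "")
  }
  wt_dna_seq <- toupper(wt_dna_seq)
  if (nchar(wt_dna_seq) != 3L * L) {
    stop("wt_dna_seq must have length 3 * length(wt_aa_seq)")
  }
  if (translate_dna(wt_dna_seq) != wt_aa_seq) {
    stop("wt_dna_seq does not translate to wt_aa_seq")
  }
  structure(
    list(
      protein_label = protein_label,
      start_pos = as.integer(start_pos),
      end_pos = as.integer(start_pos) + L - 1L,
      length = L,
      wt_aa = wt_aa_seq,
      wt_dna = wt_dna_seq
    ),
    class = "domain_spec"
  )
}

#' @export
print.domain_spec <- function(x, ...) {
  cat("<domain_spec> ", x$protein_label, ": residues ", x$start_pos, "-",
      x$end_pos, " (L = ", x$length, ")\n", sep = "")
  invisible(x)
}

#' Default BRCT-like domain
#'
#' The default study domain: 214 residues numbered 1646-1859, matching the
#' coordinates of the tandem BRCT repeats of human BRCA1. The bundled
#' sequence is a synthetic surrogate (see source comments); real analyses
#' should pass the genuine sequence to [domain_spec()].
#'
#' @return A `domain_spec`.
#' @export
brct_domain <- function() {
  domain_spec(BRCT_SYNTHETIC_AA, start_pos = 1646L,
              protein_label = "BRCA1-BRCT (synthetic surrogate sequence)")
}

# wild-type amino acid at absolute position(s)
wt_aa_at <- function(domain, pos) {
  rel <- pos - domain$start_pos + 1L
  if (any(rel < 1L | rel > domain$length)) {
    stop("position(s) outside domain [", domain$start_pos, ", ",
         domain$end_pos, "]: ",
         paste(pos[rel < 1L | rel > domain$length], collapse = ", "))
  }
  substring(domain$wt_aa, rel, rel)
}

#' Enumerate the site-saturation library
#'
#' Every position of the domain mutated to the 19 alternative amino
#' acids, in deterministic position-major order with alphabetical
#' amino-acid order within a position. The default 214-residue domain
#' yields 19 x 214 = 4,066 unique missense variants.
#'
#' @param domain A [domain_spec()].
#' @return Tibble with columns `pos` (absolute residue number), `wt`,
#'   `alt`; one row per variant.
#' @export
enumerate_variants <- function(domain) {
  stopifnot(inherits(domain, "domain_spec"))
  aa <- strsplit(domain$wt_aa, "")[[1]]
  positions <- seq(domain$start_pos, domain$end_pos)
  alt <- unlist(lapply(aa, function(w) setdiff(aa_order(), w)))
  tibble(
    pos = rep(positions, each = 19L),
    wt = rep(aa, each = 19L),
    alt = alt
  )
}

# smallest fragment count that satisfies the amplicon length bound
min_fragments <- function(L, overlap, max_amplicon_nt) {
  for (f in seq_len(L)) {
    covered <- L + (f - 1L) * overlap
    if (3L * ceiling(covered / f) <= max_amplicon_nt) return(f)
  }
  NA_integer_
}

#' Partition the domain into overlapping amplicon fragments
#'
#' Sequencing read length caps the amplicon size, so long domains are read
#' in several overlapping fragments; the overlap residues are later used
#' to put the per-fragment score scales on a common footing. Fragment
#' windows are near-equal in size (any remainder goes to the earlier
#' fragments) and deterministic.
#'
#' @param domain A [domain_spec()].
#' @param n_fragments Number of fragments (default 3).
#' @param overlap Residues shared by adjacent fragments (default 4).
#' @param max_amplicon_nt Maximum coding nucleotides per amplicon
#'   (default 250, a single Illumina read).
#' @return Tibble with columns `fragment`, `first_pos`, `last_pos`
#'   (absolute, inclusive), `n_res`, `nt_len`.
#' @export
build_fragments <- function(domain, n_fragments = 3L, overlap = 4L,
                            max_amplicon_nt = 250L) {
  stopifnot(inherits(domain, "domain_spec"), n_fragments >= 1L, overlap >= 0L)
  L <- domain$length
  covered <- L + (n_fragments - 1L) * overlap
  widths <- rep(covered %/% n_fragments, n_fragments)
  rem <- covered %% n_fragments
  if (rem > 0L) widths[seq_len(rem)] <- widths[seq_len(rem)] + 1L
  if (n_fragments > 1L && any(widths <= overlap)) {
    stop("infeasible fragmentation: windows no longer than the overlap")
  }
  if (3L * max(widths) > max_amplicon_nt) {
    need <- min_fragments(L, overlap, max_amplicon_nt)
    stop("amplicon length ", 3L * max(widths), " nt exceeds ",
         max_amplicon_nt, " nt; at least ",
         if (is.na(need)) "no feasible number of" else need,
         " fragments required")
  }
  first_rel <- integer(n_fragments)
  first_rel[1L] <- 1L
  if (n_fragments > 1L) {
    for (i in 2L:n_fragments) {
      first_rel[i] <- first_rel[i - 1L] + widths[i - 1L] - overlap
    }
  }
  tibble(
    fragment = seq_len(n_fragments),
    first_pos = domain$start_pos + first_rel - 1L,
    last_pos = domain$start_pos + first_rel + widths - 2L,
    n_res = widths,
    nt_len = 3L * widths
  )
}

#' Design the synonymously marked wild-type spike-in
#'
#' A wild-type construct carrying a synonymous codon change every
#' `marker_spacing` residues. Because a fragment-local wild-type read can
#' come from a variant mutated in another fragment, only reads carrying
#' the full set of marker codons of their fragment are trusted as true
#' wild type; the marked-WT class is the scoring reference. Markers that
#' would land on a single-codon residue (Met/Trp) are shifted to the
#' nearest position with a synonymous alternative and flagged.
#'
#' @param domain A [domain_spec()].
#' @param marker_spacing Residues between markers (default 15).
#' @return List of class `marked_wt_spec` with elements `markers` (tibble:
#'   `pos_rel`, `pos_abs`, `wt_codon`, `marker_codon`, `shifted`) and
#'   `marked_dna`.
#' @export
build_marked_wt <- function(domain, marker_spacing = 15L) {
  stopifnot(inherits(domain, "domain_spec"), marker_spacing >= 1L)
  L <- domain$length
  aa <- strsplit(domain$wt_aa, "")[[1]]
  codons <- split_codons(domain$wt_dna)
  shiftable <- !aa %in% c("M", "W")
  target <- seq(marker_spacing, L, by = marker_spacing)
  placed <- integer(0)
  shifted <- logical(0)
  for (t in target) {
    if (shiftable[t] && !(t %in% placed)) {
      placed <- c(placed, t)
      shifted <- c(shifted, FALSE)
      next
    }
    # nearest shiftable, unused position
    cand <- order(abs(seq_len(L) - t))
    cand <- cand[shiftable[cand] & !(cand %in% placed)]
    if (length(cand) == 0L) stop("no shiftable position for marker near ", t)
    placed <- c(placed, cand[[1L]])
    shifted <- c(shifted, TRUE)
  }
  o <- order(placed)
  placed <- placed[o]
  shifted <- shifted[o]
  marker_codon <- vapply(placed, function(i) {
    alternative_codon(aa[i], codons[i])
  }, character(1))
  marked <- codons
  marked[placed] <- marker_codon
  res <- list(
    markers = tibble(
      pos_rel = placed,
      pos_abs = placed + domain$start_pos - 1L,
      wt_codon = codons[placed],
      marker_codon = marker_codon,
      shifted = shifted
    ),
    marked_dna = paste(marked, collapse = "")
  )
  stopifnot(translate_dna(res$marked_dna) == domain$wt_aa)
  class(res) <- "marked_wt_spec"
  res
}

# fixed anchor (primer) sequences flanking each fragment amplicon;
# distinct 20-mers, supporting designs of up to 6 fragments
anchor_table <- function(n_fragments) {
  fwd <- c("ACGGTCTAGCATCGTGAACC", "TGCACGATCCGTTAGGTCAA",
           "GATCCGAACTGGTTACGCAG", "CCTAGGTTCAGATCGCATCG",
           "GGATCACGTTGACCTAGCTA", "TTGACGCATGGACTACCGAT")
  rev <- c("CAGTTACGGATCCTAGCACA", "AGTCCATGCGATACCAGGTT",
           "TCAGGATACGCTAGTTCCGA", "GTTCGACCATAGGCTTACGA",
           "CATGGTACGATCGAACTGGA", "ACCTGATCGTTAGCAGGTCA")
  if (n_fragments > length(fwd)) {
    stop("anchor table supports at most ", length(fwd), " fragments")
  }
  tibble(
    fragment = seq_len(n_fragments),
    anchor_fwd = fwd[seq_len(n_fragments)],
    anchor_rev = rev[seq_len(n_fragments)]
  )
}

#' Assemble the full screen design
#'
#' Bundles the domain, its fragmentation, the marked-WT spike-in, the
#' stop-control spike-in, and per-fragment anchor (primer) sequences.
#' The stop control carries a TAA codon at the second residue of every
#' fragment window, so it is recognizable in every fragment's reads.
#'
#' @param domain A [domain_spec()] (default [brct_domain()]).
#' @param n_fragments,overlap,max_amplicon_nt See [build_fragments()].
#' @param marker_spacing See [build_marked_wt()].
#' @return List of class `screen_design` with elements `domain`,
#'   `fragments`, `marked_wt`, `anchors`, `stop_positions` (absolute),
#'   `stop_dna`.
#' @export
screen_design <- function(domain = brct_domain(), n_fragments = 3L,
                          overlap = 4L, max_amplicon_nt = 250L,
                          marker_spacing = 15L) {
  fragments <- build_fragments(domain, n_fragments, overlap, max_amplicon_nt)
  marked <- build_marked_wt(domain, marker_spacing)
  # every fragment must contain at least one marker
  for (i in seq_len(nrow(fragments))) {
    inside <- marked$markers$pos_abs >= fragments$first_pos[i] &
      marked$markers$pos_abs <= fragments$last_pos[i]
    if (!any(inside)) {
      stop("fragment ", i, " contains no marked-WT marker; decrease ",
           "marker_spacing or enlarge fragments")
    }
  }
  stop_rel <- pmin(fragments$first_pos - domain$start_pos + 2L, domain$length)
  codons <- split_codons(domain$wt_dna)
  codons[stop_rel] <- "TAA"
  design <- list(
    domain = domain,
    fragments = fragments,
    marked_wt = marked,
    anchors = anchor_table(n_fragments),
    stop_positions = stop_rel + domain$start_pos - 1L,
    stop_dna = paste(codons, collapse = "")
  )
  class(design) <- "screen_design"
  design
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  print(x$domain)
  cat("  fragments: ", nrow(x$fragments), " (",
      paste(sprintf("%d-%d", x$fragments$first_pos, x$fragments$last_pos),
            collapse = ", "), ")\n", sep = "")
  cat("  marked-WT markers: ", nrow(x$marked_wt$markers),
      "; stop-control codons at ",
      paste(x$stop_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# fragment membership of an absolute position: vector of fragment indices
fragments_of <- function(design, pos) {
  fr <- design$fragments
  lapply(pos, function(p) fr$fragment[p >= fr$first_pos & p <= fr$last_pos])
}

# coding DNA of construct `which` restricted to fragment `f` (no anchors)
fragment_coding <- function(design, f, which = c("wt", "marked", "stop")) {
  which <- match.arg(which)
  dna <- switch(which,
    wt = design$domain$wt_dna,
    marked = design$marked_wt$marked_dna,
    stop = design$stop_dna
  )
  fr <- design$fragments[design$fragments$fragment == f, ]
  rel1 <- fr$first_pos - design$domain$start_pos + 1L
  rel2 <- fr$last_pos - design$domain$start_pos + 1L
  substring(dna, 3L * (rel1 - 1L) + 1L, 3L * rel2)
}

# full reference amplicon (anchors + coding) for construct `which`
fragment_amplicon <- function(design, f, which = c("wt", "marked", "stop")) {
  an <- design$anchors[design$anchors$fragment == f, ]
  paste0(an$anchor_fwd, fragment_coding(design, f, which), an$anchor_rev)
}

# amplicon carrying one missense variant (preferred codon for alt)
variant_amplicon <- function(design, f, pos, alt) {
  coding <- fragment_coding(design, f, "wt")
  fr <- design$fragments[design$fragments$fragment == f, ]
  rel <- pos - fr$first_pos + 1L
  stopifnot(rel >= 1L, rel <= fr$n_res)
  substr(coding, 3L * (rel - 1L) + 1L, 3L * rel) <- preferred_codon(alt)
  an <- design$anchors[design$anchors$fragment == f, ]
  paste0(an$anchor_fwd, coding, an$anchor_rev)
}

#' Serialize a screen design
#'
#' Writes the design as a YAML config plus a companion FASTA holding the
#' wild-type, marked-WT, and stop-control coding sequences.
#'
#' @param design A [screen_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, dir) {
  stopifnot(inherits(design, "screen_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    protein_label = design$domain$protein_label,
    start_pos = design$domain$start_pos,
    end_pos = design$domain$end_pos,
    fragments = lapply(seq_len(nrow(design$fragments)), function(i) {
      as.list(design$fragments[i, c("fragment", "first_pos", "last_pos")])
    }),
    anchors = lapply(seq_len(nrow(design$anchors)), function(i) {
      as.list(design$anchors[i, ])
    }),
    markers = lapply(seq_len(nrow(design$marked_wt$markers)), function(i) {
      as.list(design$marked_wt$markers[i, ])
    }),
    stop_positions = design$stop_positions
  )
  yaml_path <- file.path(dir, "design.yaml")
  yaml::write_yaml(cfg, yaml_path)
  seqs <- Biostrings::DNAStringSet(c(
    wt = design$domain$wt_dna,
    marked_wt = design$marked_wt$marked_dna,
    stop_control = design$stop_dna
  ))
  fasta_path <- file.path(dir, "design.fasta")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(yaml_path, fasta_path))
}
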