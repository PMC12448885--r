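# Small designs built in code for fast tests.

# 40-residue two-fragment design derived from the default sequence
mini_design <- function(L = 40L, n_fragments = 2L, overlap = 3L,
                        marker_spacing = 8L, start_pos = 101L) {
  dom <- domain_spec(substr(satscreen:::BRCT_SYNTHETIC_AA, 1L, L),
                     start_pos = start_pos, protein_label = "mini")
  screen_design(dom, n_fragments = n_fragments, overlap = overlap,
                max_amplicon_nt = 3L * L + 30L,
                marker_spacing = marker_spacing)
}

# all-neutral, injection-free effect configuration
neutral_config <- function(baits = "A") {
  effect_config(baits = baits, critical_residues = integer(0),
                intermediate_residues = integer(0),
                b_neutral = c(1, 1), injections = NULL)
}

# hand-built counts for a single-fragment screen: one variant with given
# per-replicate (nonselective, selective) counts, a marked-WT reference,
# and one well-behaved filler variant
one_variant_counts <- function(non, sel, w = 100L, pos = 12L,
                               wt = "A", alt = "K") {
  reps <- seq_along(non)
  dplyr::bind_rows(lapply(reps, function(r) {
    tibble::tibble(
      bait = "A", replicate = r,
      condition = rep(c("nonselective", "selective"), each = 3L),
      fragment = 1L,
      class = rep(c("missense", "missense", "marked_wt"), 2L),
      pos = rep(c(pos, pos + 1L, NA), 2L),
      wt = rep(c(wt, wt, NA), 2L),
      alt = rep(c(alt, "R", NA), 2L),
      count = c(non[r], w, w, sel[r], w, w)
    )
  }))
}

# minimal score-table tibble accepted by the downstream analyses
fake_scores <- function(pos, alt, score, bait = "A", wt = "A",
                        status = "scored") {
  tibble::tibble(
    bait = bait, class = "missense", pos = pos, wt = wt, alt = alt,
    score = score, se = 0.1, status = status,
    n_rep = 3L, n_fragments = 1L, offset = 0
  )
}
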