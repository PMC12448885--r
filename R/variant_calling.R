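# Codon-level variant calling: amplicon reads -> per-variant counts,
# decoding the marked-WT / apparent-WT / stop-control scheme.

# hamming distance between equal-length strings x (vector) and ref (scalar)
hamming_to <- function(x, ref) {
  if (length(x) == 0L) return(integer(0))
  rc <- strsplit(ref, "")[[1]]
  m <- matrix(unlist(strsplit(x, ""), use.names = FALSE), nrow = length(rc))
  colSums(m != rc)
}

#' Read a FASTQ file
#'
#' @param file FASTQ path (optionally gzipped).
#' @return Tibble (`id`, `seq`, `mean_q`).
#' @export
read_fastq <- function(file) {
  fq <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(file),
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (length(fq) == 0L) {
    return(tibble(id = character(0), seq = character(0), mean_q = numeric(0)))
  }
  q <- methods::as(Biostrings::quality(fq), "IntegerList")
  tibble(
    id = names(fq),
    seq = as.character(fq),
    mean_q = vapply(q, mean, numeric(1))
  )
}

#' Classify amplicon reads at codon resolution
#'
#' Each read is assigned to a fragment by best anchor match, compared
#' codon-by-codon to the wild-type fragment reference (frame-anchored at
#' the amplicon start; no alignment, amplicons are fixed-length), and
#' classified:
#'
#' * `stop_control` — matches the stop-control construct;
#' * `apparent_wt` — no amino-acid change, no marker codons (an
#'   unresolvable mix of true WT and variants mutated in other fragments);
#' * `marked_wt` — no amino-acid change and *all* of the fragment's
#'   marker codons present (partial marker sets are discarded as
#'   ambiguous);
#' * `missense` — exactly one amino-acid change, no marker codons, and at
#'   most `max_err_nt` additional nucleotide mismatches, all silent;
#' * otherwise `discard` with a reason in `multi_aa_change`,
#'   `indel_or_length`, `low_quality`, `anchor_fail`, `ambiguous`.
#'
#' @param reads Tibble from [read_fastq()], or a character vector of
#'   sequences (then quality filtering is skipped).
#' @param design A [screen_design()].
#' @param max_err_nt Tolerated extra (silent) nucleotide mismatches
#'   (default 1).
#' @param anchor_mismatch Tolerated mismatches per anchor (default 0).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @return Tibble (`fragment`, `class`, `pos`, `wt`, `alt`, `reason`,
#'   `n_mismatched_codons`), one row per read, in input order.
#' @export
classify_reads <- function(reads, design, max_err_nt = 1L,
                           anchor_mismatch = 0L, min_mean_q = 20) {
  if (is.character(reads)) {
    reads <- tibble(id = as.character(seq_along(reads)), seq = reads,
                    mean_q = Inf)
  }
  n <- nrow(reads)
  res <- tibble(
    fragment = rep(NA_integer_, n), class = rep(NA_character_, n),
    pos = rep(NA_integer_, n), wt = rep(NA_character_, n),
    alt = rep(NA_character_, n), reason = rep(NA_character_, n),
    n_mismatched_codons = rep(NA_integer_, n)
  )
  if (n == 0L) return(res)
  seqs <- toupper(reads$seq)
  an <- design$anchors
  alen <- nchar(an$anchor_fwd[[1L]])
  rlen <- nchar(an$anchor_rev[[1L]])

  # fragment assignment by best forward-anchor match; the reverse anchor
  # is checked after the length gate (a truncated read should report
  # indel_or_length, not a shifted reverse anchor)
  long_enough <- nchar(seqs) >= alen + rlen + 3L
  mm <- matrix(Inf, nrow = n, ncol = nrow(an))
  for (f in seq_len(nrow(an))) {
    pre <- substr(seqs[long_enough], 1L, alen)
    mm[long_enough, f] <- hamming_to(pre, an$anchor_fwd[[f]])
  }
  best <- max.col(-mm, ties.method = "first")
  best_mm <- mm[cbind(seq_len(n), best)]
  anchor_ok <- is.finite(best_mm) & best_mm <= anchor_mismatch
  res$reason[!anchor_ok] <- "anchor_fail"
  res$class[!anchor_ok] <- "discard"
  res$fragment[anchor_ok] <- best[anchor_ok]

  code <- Biostrings::GENETIC_CODE
  for (f in unique(res$fragment[anchor_ok])) {
    sel <- which(anchor_ok & res$fragment == f)
    fr <- design$fragments[design$fragments$fragment == f, ]
    wt_cod <- split_codons(fragment_coding(design, f, "wt"))
    stop_cod <- split_codons(fragment_coding(design, f, "stop"))
    marked_cod <- split_codons(fragment_coding(design, f, "marked"))
    wt_aa <- code[wt_cod]
    ref_len <- alen + 3L * fr$n_res + rlen
    w <- fr$n_res

    len_ok <- nchar(seqs[sel]) == ref_len
    res$class[sel[!len_ok]] <- "discard"
    res$reason[sel[!len_ok]] <- "indel_or_length"
    sel <- sel[len_ok]
    if (length(sel) == 0L) next

    rev_mm <- hamming_to(substring(seqs[sel], ref_len - rlen + 1L),
                         an$anchor_rev[[f]])
    rev_ok <- rev_mm <= anchor_mismatch
    res$class[sel[!rev_ok]] <- "discard"
    res$reason[sel[!rev_ok]] <- "anchor_fail"
    sel <- sel[rev_ok]
    if (length(sel) == 0L) next

    q_ok <- reads$mean_q[sel] >= min_mean_q
    res$class[sel[!q_ok]] <- "discard"
    res$reason[sel[!q_ok]] <- "low_quality"
    sel <- sel[q_ok]
    if (length(sel) == 0L) next

    coding <- substr(seqs[sel], alen + 1L, alen + 3L * w)
    # reads x codons matrix
    cod <- matrix(NA_character_, nrow = length(sel), ncol = w)
    for (j in seq_len(w)) {
      cod[, j] <- substr(coding, 3L * (j - 1L) + 1L, 3L * j)
    }
    aa <- matrix(code[cod], nrow = length(sel))
    aa[is.na(aa)] <- "?"
    diff_wt <- sweep(cod, 2L, wt_cod, FUN = "!=")
    aa_diff <- sweep(aa, 2L, wt_aa, FUN = "!=")
    marker_idx <- which(marked_cod != wt_cod)
    # marker codon present: read codon equals the designed marker codon
    # (markers are synonymous, so these are never amino-acid changes)
    marker_match <- sweep(cod[, marker_idx, drop = FALSE], 2L,
                          marked_cod[marker_idx], FUN = "==")
    n_marker <- rowSums(marker_match)
    M <- length(marker_idx)
    n_aa <- rowSums(aa_diff)
    has_stop_aa <- rowSums(aa == "*") > 0L
    n_cod_mm <- rowSums(diff_wt)
    res$n_mismatched_codons[sel] <- as.integer(n_cod_mm)

    # nt mismatches inside silent (aa-preserving) changed codons that are
    # not designed marker codons
    silent_cod <- diff_wt & !aa_diff
    silent_cod[, marker_idx] <- silent_cod[, marker_idx, drop = FALSE] &
      !marker_match
    silent_nt <- rep(0L, length(sel))
    any_silent <- which(rowSums(silent_cod) > 0L)
    for (i in any_silent) {
      js <- which(silent_cod[i, ])
      silent_nt[i] <- sum(vapply(js, function(j) {
        sum(strsplit(cod[i, j], "")[[1]] != strsplit(wt_cod[j], "")[[1]])
      }, integer(1)))
    }

    # stop-control first: the designed stop codons must be present
    # exactly, the remainder may deviate from wild type by at most
    # max_err_nt nucleotides
    stop_idx <- which(stop_cod != wt_cod)
    stop_ok <- rowSums(sweep(cod[, stop_idx, drop = FALSE], 2L,
                             stop_cod[stop_idx], FUN = "!=")) == 0L
    other_mm <- rep(0L, length(sel))
    if (length(stop_idx) < w) {
      wt_rest <- paste(wt_cod[-stop_idx], collapse = "")
      rest <- apply(cod[, -stop_idx, drop = FALSE], 1L, paste,
                    collapse = "")
      other_mm <- hamming_to(rest, wt_rest)
    }
    is_stop <- stop_ok & other_mm <= max_err_nt
    res$class[sel[is_stop]] <- "stop_control"
    keep <- !is_stop

    cls <- rep("discard", length(sel))
    rsn <- rep("ambiguous", length(sel))
    p <- rep(NA_integer_, length(sel))
    wtc <- rep(NA_character_, length(sel))
    altc <- rep(NA_character_, length(sel))

    zero_aa <- n_aa == 0L & !has_stop_aa
    ok_silent <- silent_nt <= max_err_nt
    app <- zero_aa & n_marker == 0L & ok_silent
    mwt <- zero_aa & n_marker == M & M > 0L & ok_silent
    cls[app] <- "apparent_wt"
    cls[mwt] <- "marked_wt"
    rsn[app | mwt] <- NA_character_

    one_aa <- n_aa == 1L & !has_stop_aa & n_marker == 0L & ok_silent
    if (any(one_aa)) {
      ji <- apply(aa_diff[one_aa, , drop = FALSE], 1L, which)
      alt_aa_call <- aa[cbind(which(one_aa), ji)]
      std <- alt_aa_call %in% aa_order()
      hit <- which(one_aa)[std]
      p[hit] <- fr$first_pos + ji[std] - 1L
      wtc[hit] <- wt_aa[ji[std]]
      altc[hit] <- alt_aa_call[std]
      cls[hit] <- "missense"
      rsn[hit] <- NA_character_
    }
    multi <- n_aa >= 2L
    rsn[multi] <- "multi_aa_change"

    res$class[sel[keep]] <- cls[keep]
    res$reason[sel[keep]] <- rsn[keep]
    res$pos[sel[keep]] <- p[keep]
    res$wt[sel[keep]] <- wtc[keep]
    res$alt[sel[keep]] <- altc[keep]
  }
  res
}

#' Tabulate read calls into a count table
#'
#' Counts calls per variant key and observation class for one sample.
#' When a design is supplied, in-fragment library variants absent from
#' the call stream appear with count 0 (so downstream dropout logic sees
#' them). Discarded reads are tallied per reason in the `discards`
#' attribute; kept plus discarded always equals the number of input
#' calls.
#'
#' @param calls Output of [classify_reads()].
#' @param bait,replicate,condition Sample metadata recorded on each row.
#' @param design Optional [screen_design()] used to complete zero rows.
#' @return Count tibble in the schema of [simulate_counts()], with a
#'   `discards` attribute (tibble `reason`, `n`).
#' @export
tabulate_calls <- function(calls, bait, replicate, condition, design = NULL) {
  kept <- calls %>% filter(class != "discard")
  disc <- calls %>%
    filter(class == "discard") %>%
    group_by(reason) %>%
    summarise(n = n(), .groups = "drop")
  counts <- kept %>%
    group_by(fragment, class, pos, wt, alt) %>%
    summarise(count = n(), .groups = "drop")
  if (!is.null(design)) {
    frames <- unique(c(counts$fragment, design$fragments$fragment))
    full <- bind_rows(lapply(frames, function(f) {
      fr <- design$fragments[design$fragments$fragment == f, ]
      vars <- enumerate_variants(design$domain) %>%
        filter(pos >= fr$first_pos, pos <= fr$last_pos)
      bind_rows(
        tibble(fragment = f, class = "missense", pos = vars$pos,
               wt = vars$wt, alt = vars$alt),
        tibble(fragment = f,
               class = c("marked_wt", "apparent_wt", "stop_control"),
               pos = NA_integer_, wt = NA_character_, alt = NA_character_)
      )
    }))
    counts <- full %>%
      left_join(counts, by = c("fragment", "class", "pos", "wt", "alt")) %>%
      mutate(count = if_else(is.na(count), 0L, count))
  }
  out <- counts %>%
    mutate(bait = bait, replicate = replicate, condition = condition) %>%
    select(bait, replicate, condition, fragment, class, pos, wt, alt, count) %>%
    arrange(fragment, class, pos, alt)
  attr(out, "discards") <- disc
  stopifnot(sum(out$count) + sum(disc$n) == nrow(calls))
  out
}

#' Call variants from a set of FASTQ files
#'
#' Convenience wrapper: classifies and tabulates every file of a read
#' manifest (as produced by [emit_reads()], or hand-built with columns
#' `bait`, `replicate`, `condition`, `file`).
#'
#' @param manifest Tibble with columns `bait`, `replicate`, `condition`,
#'   `file`.
#' @param design A [screen_design()].
#' @param ... Passed to [classify_reads()].
#' @return Count tibble covering all samples, with a combined `discards`
#'   attribute (per sample).
#' @export
call_fastq <- function(manifest, design, ...) {
  stopifnot(all(c("bait", "replicate", "condition", "file") %in%
                  colnames(manifest)))
  pieces <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    calls <- classify_reads(read_fastq(m$file), design, ...)
    tab <- tabulate_calls(calls, m$bait, m$replicate, m$condition,
                          design = design)
    d <- attr(tab, "discards")
    if (nrow(d) > 0L) {
      d <- mutate(d, bait = m$bait, replicate = m$replicate,
                  condition = m$condition)
    }
    list(tab = tab, disc = d)
  })
  out <- bind_rows(lapply(pieces, `[[`, "tab")) %>%
    group_by(bait, replicate, condition, fragment, class, pos, wt, alt) %>%
    summarise(count = sum(count), .groups = "drop")
  attr(out, "discards") <- bind_rows(lapply(pieces, `[[`, "disc"))
  out
}
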