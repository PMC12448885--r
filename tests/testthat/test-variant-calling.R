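library(dplyr)

d <- mini_design()
amp_wt <- satscreen:::fragment_amplicon(d, 1L, "wt")
amp_marked <- satscreen:::fragment_amplicon(d, 1L, "marked")
amp_stop <- satscreen:::fragment_amplicon(d, 1L, "stop")

test_that("reference constructs classify to their classes", {
  calls <- classify_reads(c(amp_wt, amp_marked, amp_stop), d)
  expect_equal(calls$class, c("apparent_wt", "marked_wt", "stop_control"))
  expect_equal(calls$fragment, rep(1L, 3L))
})

test_that("a single non-synonymous codon change is called missense", {
  read <- satscreen:::variant_amplicon(d, 1L, 110L, "K")
  call <- classify_reads(read, d)
  expect_equal(call$class, "missense")
  expect_equal(call$pos, 110L)
  expect_equal(call$alt, "K")
  expect_equal(call$wt, satscreen:::wt_aa_at(d$domain, 110L))
  expect_equal(call$n_mismatched_codons, 1L)
})

test_that("two non-synonymous changes are discarded as multi_aa_change", {
  v1 <- satscreen:::variant_amplicon(d, 1L, 110L, "K")
  alen <- nchar(d$anchors$anchor_fwd[[1]])
  # overwrite a second codon (relative position 5) with a different residue
  codon_at <- function(s, rel) substr(s, alen + 3 * (rel - 1) + 1, alen + 3 * rel)
  v2 <- v1
  stopifnot(codon_at(v2, 5L) != "AAG")
  substr(v2, alen + 13L, alen + 15L) <- "AAG"
  call <- classify_reads(v2, d)
  expect_equal(call$class, "discard")
  expect_equal(call$reason, "multi_aa_change")
})

test_that("length changes, anchor failures and low quality are discarded", {
  short <- substr(amp_wt, 1L, nchar(amp_wt) - 3L)
  bad_anchor <- paste0(strrep("T", 20L), substr(amp_wt, 21L, nchar(amp_wt)))
  calls <- classify_reads(c(short, bad_anchor), d)
  expect_equal(calls$class, c("discard", "discard"))
  expect_equal(calls$reason, c("indel_or_length", "anchor_fail"))
  lowq <- tibble(id = "r1", seq = amp_wt, mean_q = 10)
  expect_equal(classify_reads(lowq, d)$reason, "low_quality")
})

test_that("partial marker sets are ambiguous, not marked_wt", {
  # revert the first marker codon of fragment 1 back to wild type
  mk <- d$marked_wt$markers
  fr <- d$fragments[1, ]
  m1 <- mk[mk$pos_abs >= fr$first_pos & mk$pos_abs <= fr$last_pos, ][1, ]
  alen <- nchar(d$anchors$anchor_fwd[[1]])
  rel <- m1$pos_abs - fr$first_pos + 1L
  partial <- amp_marked
  substr(partial, alen + 3L * (rel - 1L) + 1L, alen + 3L * rel) <- m1$wt_codon
  call <- classify_reads(partial, d)
  expect_equal(call$class, "discard")
  expect_equal(call$reason, "ambiguous")
})

test_that("classification is deterministic and order-independent", {
  reads <- c(amp_wt, satscreen:::variant_amplicon(d, 1L, 105L, "W"),
             amp_marked, amp_stop,
             satscreen:::variant_amplicon(d, 2L, 130L, "C"))
  fwd <- classify_reads(reads, d)
  rev_calls <- classify_reads(rev(reads), d)
  expect_equal(fwd, rev_calls[rev(seq_len(nrow(rev_calls))), ],
               ignore_attr = TRUE)
  expect_equal(fwd$fragment, c(1L, 1L, 1L, 1L, 2L))
})

test_that("tabulation conserves reads and counts identical calls", {
  reads <- c(rep(satscreen:::variant_amplicon(d, 1L, 110L, "K"), 4L),
             amp_marked, substr(amp_wt, 1L, 10L))
  calls <- classify_reads(reads, d)
  tab <- tabulate_calls(calls, bait = "A", replicate = 1L,
                        condition = "selective")
  expect_equal(tab$count[tab$class == "missense" & tab$pos == 110], 4L)
  disc <- attr(tab, "discards")
  expect_equal(sum(tab$count) + sum(disc$n), length(reads))
  empty <- tabulate_calls(classify_reads(character(0), d), "A", 1L,
                          "selective", design = d)
  expect_true(all(empty$count == 0L))
  expect_gt(nrow(empty), 0L)
})

test_that("simulate -> reads -> call round-trips count tables exactly", {
  eff <- draw_effects(d, effect_config(baits = "A", injections = NULL),
                      seed = 3L)
  for (plain_wt in c(FALSE, TRUE)) {
    cnt <- simulate_counts(
      d, eff, depth_config(n_per_sample = 1500L, n_replicates = 2L,
                           include_plain_wt = plain_wt), seed = 3L)
    dir <- withr::local_tempdir()
    man <- emit_reads(cnt, d, error_rate = 0, seed = 3L, dir = dir)
    called <- call_fastq(man, d)
    cmp <- full_join(
      cnt, called,
      by = c("bait", "replicate", "condition", "fragment", "class",
             "pos", "wt", "alt"),
      suffix = c("_sim", "_call")
    ) %>%
      mutate(count_call = coalesce(count_call, 0L),
             count_sim = coalesce(count_sim, 0L))
    expect_equal(cmp$count_call, cmp$count_sim)
    if (!plain_wt) {
      expect_true(all(called$count[called$class == "apparent_wt"] == 0L))
    }
    expect_equal(nrow(attr(called, "discards")), 0L)
  }
})

test_that("a silent sequencing error is tolerated, two are not", {
  read <- satscreen:::variant_amplicon(d, 1L, 110L, "K")
  alen <- nchar(d$anchors$anchor_fwd[[1]])
  # make a synonymous change at relative position 2 (third codon base)
  fr <- d$fragments[1, ]
  wt_cod <- satscreen:::split_codons(satscreen:::fragment_coding(d, 1L, "wt"))
  syn <- satscreen:::alternative_codon(
    satscreen:::codon_to_aa(wt_cod[2L]), wt_cod[2L])
  one_err <- read
  substr(one_err, alen + 4L, alen + 6L) <- syn
  call <- classify_reads(one_err, d)
  if (sum(strsplit(syn, "")[[1]] != strsplit(wt_cod[2L], "")[[1]]) == 1L) {
    expect_equal(call$class, "missense")
    expect_equal(call$pos, 110L)
  } else {
    expect_equal(call$class, "discard")
  }
})
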