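# Depletion scoring: per-replicate WT-referenced log-ratio scores,
# random-effects replicate combination, cross-fragment normalization via
# overlap residues, and the dropout floor.

#' Per-replicate depletion score
#'
#' Two-condition ratio score with pseudocounts, referenced to the
#' marked-WT class of the same sample so library-size normalization
#' cancels:
#' `s_r = ln((c_sel + p) / (w_sel + p)) - ln((c_non + p) / (w_non + p))`,
#' with standard error
#' `se_r = sqrt(1/(c_sel+p) + 1/(c_non+p) + 1/(w_sel+p) + 1/(w_non+p))`.
#' Negative scores mean depletion under selection, i.e. loss of binding.
#' All arguments are vectorized.
#'
#' @param c_sel,c_non Variant counts in the selective / non-selective
#'   sample.
#' @param w_sel,w_non Marked-WT counts in the same samples.
#' @param pseudocount Added to every count (default 0.5).
#' @return Tibble (`s_r`, `se_r`).
#' @export
replicate_score <- function(c_sel, c_non, w_sel, w_non, pseudocount = 0.5) {
  counts <- cbind(c_sel, c_non, w_sel, w_non)
  if (any(counts < 0)) stop("counts must be non-negative")
  p <- pseudocount
  s <- log((c_sel + p) / (w_sel + p)) - log((c_non + p) / (w_non + p))
  se <- sqrt(1 / (c_sel + p) + 1 / (c_non + p) +
               1 / (w_sel + p) + 1 / (w_non + p))
  tibble(s_r = s, se_r = se)
}

#' Combine replicate scores
#'
#' Random-effects meta-analytic combination: the between-replicate
#' variance is estimated by the method of moments (DerSimonian-Laird,
#' clamped at zero), replicate weights are `1 / (se_r^2 + sigma2_b)`, and
#' the combined score is the weighted mean. A single replicate passes
#' through unchanged. `method = "mean"` gives the unweighted arithmetic
#' mean (for ablation).
#'
#' @param s_r,se_r Per-replicate scores and standard errors.
#' @param method `"rem"` (default) or `"mean"`.
#' @return List with `s`, `se`, `sigma2_b`, `n_rep`.
#' @export
combine_replicates <- function(s_r, se_r, method = c("rem", "mean")) {
  method <- match.arg(method)
  keep <- !is.na(s_r)
  s_r <- s_r[keep]
  se_r <- se_r[keep]
  k <- length(s_r)
  if (k == 0L) stop("no replicates to combine")
  if (k == 1L) {
    return(list(s = s_r, se = se_r, sigma2_b = 0, n_rep = 1L))
  }
  if (method == "mean") {
    return(list(s = mean(s_r), se = sqrt(sum(se_r^2)) / k, sigma2_b = 0,
                n_rep = k))
  }
  w <- 1 / se_r^2
  s_fix <- sum(w * s_r) / sum(w)
  Q <- sum(w * (s_r - s_fix)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  sigma2_b <- max(0, (Q - (k - 1)) / cc)
  w2 <- 1 / (se_r^2 + sigma2_b)
  list(
    s = sum(w2 * s_r) / sum(w2),
    se = sqrt(1 / sum(w2)),
    sigma2_b = sigma2_b,
    n_rep = k
  )
}

# row-wise DerSimonian-Laird combination over replicate matrices
combine_rows <- function(s_mat, se_mat, method = "rem") {
  ok <- !is.na(s_mat)
  k <- rowSums(ok)
  if (any(k == 0L)) stop("variant with no replicate scores")
  if (method == "mean") {
    s <- rowMeans(s_mat, na.rm = TRUE)
    se <- sqrt(rowSums(se_mat^2, na.rm = TRUE)) / k
    return(tibble(score = s, se = se, n_rep = as.integer(k)))
  }
  w <- ifelse(ok, 1 / se_mat^2, 0)
  sw <- rowSums(w)
  s_fix <- rowSums(w * ifelse(ok, s_mat, 0)) / sw
  Q <- rowSums(w * (ifelse(ok, s_mat, 0) - s_fix)^2 * ok)
  cc <- sw - rowSums(w^2) / sw
  sigma2_b <- pmax(0, (Q - (k - 1)) / cc)
  sigma2_b[k == 1L] <- 0
  w2 <- ifelse(ok, 1 / (se_mat^2 + sigma2_b), 0)
  sw2 <- rowSums(w2)
  tibble(
    score = rowSums(w2 * ifelse(ok, s_mat, 0)) / sw2,
    se = sqrt(1 / sw2),
    n_rep = as.integer(k)
  )
}

# per-(bait, fragment) score tables: replicate scores combined across
# replicates; includes detection flags used later by the floor rule
score_fragments_one_bait <- function(counts, pseudocount = 0.5,
                                     method = "rem") {
  wt_ref <- counts %>%
    filter(class == "marked_wt") %>%
    select(replicate, fragment, condition, count) %>%
    pivot_wider(names_from = condition, values_from = count,
                names_prefix = "w_")
  if (nrow(wt_ref) == 0L || anyNA(wt_ref$w_selective) ||
      anyNA(wt_ref$w_nonselective)) {
    stop("marked_wt reference counts missing for some sample")
  }
  per_rep <- counts %>%
    filter(class %in% c("missense", "stop_control")) %>%
    pivot_wider(names_from = condition, values_from = count,
                values_fill = 0L) %>%
    left_join(wt_ref, by = c("replicate", "fragment"))
  sc <- replicate_score(per_rep$selective, per_rep$nonselective,
                        per_rep$w_selective, per_rep$w_nonselective,
                        pseudocount = pseudocount)
  per_rep$s_r <- sc$s_r
  per_rep$se_r <- sc$se_r
  reps <- sort(unique(per_rep$replicate))
  wide <- per_rep %>%
    select(fragment, class, pos, wt, alt, replicate, s_r, se_r,
           selective, nonselective) %>%
    pivot_wider(names_from = replicate,
                values_from = c(s_r, se_r, selective, nonselective))
  s_mat <- as.matrix(wide[paste0("s_r_", reps)])
  se_mat <- as.matrix(wide[paste0("se_r_", reps)])
  sel_mat <- as.matrix(wide[paste0("selective_", reps)])
  non_mat <- as.matrix(wide[paste0("nonselective_", reps)])
  cmb <- combine_rows(s_mat, se_mat, method = method)
  tibble(
    fragment = wide$fragment, class = wide$class, pos = wide$pos,
    wt = wide$wt, alt = wide$alt,
    score = cmb$score, se = cmb$se, n_rep = cmb$n_rep,
    sel_any = rowSums(sel_mat > 0L, na.rm = TRUE) > 0L,
    max_non = apply(non_mat, 1L, max, na.rm = TRUE)
  )
}

#' Normalize score scales across fragments
#'
#' Adjacent fragments share a few overlap residues whose variants are
#' scored in both; the per-junction offset is the median (or mean) of
#' their left-minus-right score differences over reliably scored overlap
#' variants. Fragment 1 anchors the scale; offsets accumulate
#' left-to-right and are added to downstream fragments. Overlap variants
#' end with the mean of their two aligned scores. Junctions with fewer
#' than `min_overlap_scored` usable variants fall back to offset 0 with a
#' warning.
#'
#' @param frag_scores Tibble with columns `fragment`, `class`, `pos`,
#'   `wt`, `alt`, `score`, `se` (plus optional `n_rep`, `sel_any`,
#'   `max_non` carried through).
#' @param estimator `"median"` (default) or `"mean"`.
#' @param min_overlap_scored Minimum usable overlap variants per junction
#'   (default 5).
#' @return Tibble of unified scores (one row per variant) with columns
#'   `class`, `pos`, `wt`, `alt`, `score`, `se`, `n_rep`, `n_fragments`,
#'   `offset`, plus an `offsets` attribute (tibble `fragment`, `offset`).
#' @export
normalize_fragments <- function(frag_scores,
                                estimator = c("median", "mean"),
                                min_overlap_scored = 5L) {
  estimator <- match.arg(estimator)
  est <- if (estimator == "median") median else mean
  frs <- sort(unique(frag_scores$fragment))
  if (!"sel_any" %in% colnames(frag_scores)) frag_scores$sel_any <- TRUE
  if (!"n_rep" %in% colnames(frag_scores)) frag_scores$n_rep <- NA_integer_
  if (!"max_non" %in% colnames(frag_scores)) frag_scores$max_non <- Inf
  offsets <- setNames(rep(0, length(frs)), frs)
  if (length(frs) > 1L) {
    for (i in seq_len(length(frs) - 1L)) {
      lf <- frag_scores %>%
        filter(fragment == frs[i], class == "missense", sel_any)
      rf <- frag_scores %>%
        filter(fragment == frs[i + 1L], class == "missense", sel_any)
      shared <- lf %>%
        dplyr::inner_join(rf, by = c("pos", "wt", "alt"),
                          suffix = c("_l", "_r"))
      if (nrow(shared) < min_overlap_scored) {
        warning("junction ", frs[i], "-", frs[i + 1L], ": only ",
                nrow(shared), " usable overlap variants; offset set to 0")
        delta <- 0
      } else {
        delta <- est(shared$score_l - shared$score_r)
      }
      offsets[i + 1L] <- offsets[i] + delta
    }
  }
  adj <- frag_scores %>%
    mutate(offset = unname(offsets[as.character(fragment)]),
           score = score + offset)
  out <- adj %>%
    group_by(class, pos, wt, alt) %>%
    summarise(
      se = sqrt(sum(se^2)) / n(),
      n_rep = max(n_rep),
      n_fragments = n(),
      offset = mean(offset),
      sel_any = any(sel_any),
      max_non = max(max_non),
      score = mean(score),
      .groups = "drop"
    )
  attr(out, "offsets") <- tibble(fragment = as.integer(names(offsets)),
                                 offset = unname(offsets))
  out
}

#' Apply the dropout floor
#'
#' A variant undetected in the selective pool of every replicate, yet
#' well represented in the input (non-selective count of at least
#' `min_input_count` in some replicate), is a complete non-binder beyond
#' the dynamic range of the log-ratio: its score is set to the floor
#' constant (default -5) with status `floored`. Variants absent from the
#' input pool as well get status `missing` (library dropout, no score).
#' Everything detected under selection stays `scored`.
#'
#' @param unified Output of [normalize_fragments()] (needs the `sel_any`
#'   and `max_non` detection columns).
#' @param min_input_count Minimum non-selective evidence (default 10).
#' @param floor Floor constant (default -5).
#' @return The table with final `score` and `status` columns.
#' @export
apply_floor <- function(unified, min_input_count = 10L, floor = -5) {
  unified %>%
    mutate(
      status = dplyr::case_when(
        sel_any ~ "scored",
        max_non >= min_input_count ~ "floored",
        TRUE ~ "missing"
      ),
      score = dplyr::case_when(
        status == "scored" ~ score,
        status == "floored" ~ floor,
        TRUE ~ NA_real_
      ),
      se = if_else(status == "scored", se, NA_real_)
    )
}

#' Score a screen from its count table
#'
#' Full scoring path for one or more baits: per-replicate WT-referenced
#' log-ratio scores, random-effects combination across replicates,
#' cross-fragment offset normalization, and the dropout floor. Every
#' library variant of the design appears exactly once per bait, with
#' status `scored`, `floored`, or `missing`; the marked-WT reference has
#' score exactly 0 and the stop control is retained as a `stop_control`
#' row.
#'
#' @param counts Count table in the [simulate_counts()] schema.
#' @param design Optional [screen_design()]; when supplied, library
#'   variants absent from `counts` are reported as `missing`.
#' @param pseudocount See [replicate_score()].
#' @param combine See [combine_replicates()].
#' @param estimator,min_overlap_scored See [normalize_fragments()].
#' @param min_input_count,floor See [apply_floor()].
#' @return Tibble (`bait`, `class`, `pos`, `wt`, `alt`, `score`, `se`,
#'   `status`, `n_rep`, `n_fragments`, `offset`) of class `score_table`,
#'   with per-bait fragment offsets in the `offsets` attribute.
#' @export
score_screen <- function(counts, design = NULL, pseudocount = 0.5,
                         combine = c("rem", "mean"),
                         estimator = c("median", "mean"),
                         min_overlap_scored = 5L,
                         min_input_count = 10L, floor = -5) {
  combine <- match.arg(combine)
  estimator <- match.arg(estimator)
  out <- list()
  offs <- list()
  for (bt in unique(counts$bait)) {
    cb <- counts %>% filter(bait == bt)
    frag <- score_fragments_one_bait(cb, pseudocount = pseudocount,
                                     method = combine)
    unified <- normalize_fragments(frag, estimator = estimator,
                                   min_overlap_scored = min_overlap_scored)
    final <- apply_floor(unified, min_input_count = min_input_count,
                         floor = floor) %>%
      select(class, pos, wt, alt, score, se, status, n_rep, n_fragments,
             offset)
    wt_row <- tibble(class = "marked_wt", pos = NA_integer_,
                     wt = NA_character_, alt = NA_character_,
                     score = 0, se = NA_real_, status = "scored",
                     n_rep = max(final$n_rep, na.rm = TRUE),
                     n_fragments = NA_integer_, offset = NA_real_)
    final <- bind_rows(final, wt_row)
    if (!is.null(design)) {
      universe <- enumerate_variants(design$domain)
      absent <- universe %>%
        anti_join(filter(final, class == "missense"),
                  by = c("pos", "wt", "alt"))
      if (nrow(absent) > 0L) {
        final <- bind_rows(final, tibble(
          class = "missense", pos = absent$pos, wt = absent$wt,
          alt = absent$alt, score = NA_real_, se = NA_real_,
          status = "missing", n_rep = 0L, n_fragments = 0L,
          offset = NA_real_
        ))
      }
    }
    final <- final %>%
      mutate(bait = bt) %>%
      select(bait, dplyr::everything()) %>%
      arrange(factor(class, levels = c("missense", "stop_control",
                                       "marked_wt", "apparent_wt")),
              pos, alt)
    out[[bt]] <- final
    offs[[bt]] <- mutate(attr(unified, "offsets"), bait = bt)
  }
  res <- bind_rows(out)
  attr(res, "offsets") <- bind_rows(offs)
  attr(res, "floor") <- floor
  class(res) <- c("score_table", class(res))
  res
}
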