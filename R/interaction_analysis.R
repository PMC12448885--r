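# Downstream analysis of score tables: heatmap matrices, per-residue
# aggregation, separation-of-function calls, concordance with external
# annotations, and per-residue attribute export for structure mapping.

# missense rows of a score table for one bait
missense_scores <- function(table, bait = NULL) {
  out <- dplyr::filter(table, class == "missense")
  if (!is.null(bait)) out <- out[out$bait == bait, ]
  if ("bait" %in% colnames(out) && length(unique(out$bait)) > 1L) {
    stop("score table contains several baits; pass `bait`")
  }
  out
}

#' Aggregate substitution scores per residue
#'
#' For structure mapping: each residue gets the sum of the scores of its
#' substitutions that negatively affected binding (score below `tau`);
#' residues where no substitution falls below `tau` get 0. Missing
#' variants are excluded. More negative aggregates mean more severe
#' disruption when the residue is mutated.
#'
#' @param table A [score_screen()] table (one bait, or pass `bait`).
#' @param tau Threshold below which a substitution counts (default 0).
#' @param bait Optional bait label to select.
#' @return Tibble (`pos`, `R_i`, `n_sub`): aggregate score and number of
#'   substitutions counted, one row per scored position.
#' @export
residue_aggregate <- function(table, tau = 0, bait = NULL) {
  ms <- missense_scores(table, bait) %>% filter(status != "missing")
  ms %>%
    group_by(pos) %>%
    summarise(
      R_i = sum(score[score < tau]),
      n_sub = sum(score < tau),
      .groups = "drop"
    ) %>%
    arrange(pos)
}

#' Classify separation-of-function variants
#'
#' Joint classification of each variant's scores against two baits:
#' binding to bait X is *lost* when `s_X <= tau_loss` and *retained* when
#' `s_X >= tau_ret`. Classes: `both_lost`, `A_specific_loss` (lost A,
#' retained B), `B_specific_loss`, `both_retained`, `indeterminate`
#' (between thresholds for at least one bait). Variants missing in either
#' table are skipped; their number is reported in the `n_skipped`
#' attribute.
#'
#' @param table_A,table_B [score_screen()] tables for the two baits (or
#'   one combined table plus `baits = c(A, B)` labels).
#' @param tau_loss Loss threshold (default -2).
#' @param tau_ret Retention threshold (default -1); must exceed
#'   `tau_loss`.
#' @param baits When `table_A` holds both baits, the two bait labels to
#'   split on (first = A, second = B).
#' @return Tibble (`pos`, `wt`, `alt`, `s_A`, `s_B`, `sof_class`).
#' @export
classify_sof <- function(table_A, table_B = NULL, tau_loss = -2,
                         tau_ret = -1, baits = NULL) {
  if (tau_loss >= tau_ret) stop("tau_loss must be below tau_ret")
  if (is.null(table_B)) {
    stopifnot(length(baits) == 2L)
    table_B <- table_A[table_A$bait == baits[[2L]], ]
    table_A <- table_A[table_A$bait == baits[[1L]], ]
  }
  a <- missense_scores(table_A) %>% select(pos, wt, alt, score, status)
  b <- missense_scores(table_B) %>% select(pos, wt, alt, score, status)
  joined <- dplyr::inner_join(a, b, by = c("pos", "wt", "alt"),
                              suffix = c("_A", "_B"))
  usable <- joined$status_A != "missing" & joined$status_B != "missing"
  n_skipped <- nrow(joined) - sum(usable)
  joined <- joined[usable, ]
  loss_A <- joined$score_A <= tau_loss
  loss_B <- joined$score_B <= tau_loss
  ret_A <- joined$score_A >= tau_ret
  ret_B <- joined$score_B >= tau_ret
  cls <- dplyr::case_when(
    loss_A & loss_B ~ "both_lost",
    loss_A & ret_B ~ "A_specific_loss",
    loss_B & ret_A ~ "B_specific_loss",
    ret_A & ret_B ~ "both_retained",
    TRUE ~ "indeterminate"
  )
  out <- tibble(
    pos = joined$pos, wt = joined$wt, alt = joined$alt,
    s_A = joined$score_A, s_B = joined$score_B, sof_class = cls
  )
  attr(out, "n_skipped") <- n_skipped
  attr(out, "thresholds") <- c(tau_loss = tau_loss, tau_ret = tau_ret)
  out
}

# rank-sum AUC: probability that a group_pos score is BELOW a group_neg
# score (binding-loss variants score lower), ties counted half
auc_rank <- function(x_pos, x_neg) {
  n1 <- length(x_pos)
  n2 <- length(x_neg)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(x_pos, x_neg))
  # W = rank-sum statistic of the positive group
  (n1 * n2 + n1 * (n1 + 1) / 2 - sum(r[seq_len(n1)])) / (n1 * n2)
}

#' Concordance with external variant annotations
#'
#' Joins per-variant annotations (clinical classes or numeric
#' functionality scores keyed by position and substitution) onto the
#' screen scores. The combined binding statistic per variant is
#' `min(s_A, s_B)` — loss of either interaction counts. For numeric
#' annotations the report carries Spearman rank correlations (per bait
#' and combined); for categorical annotations it carries the rank-sum
#' AUC separating `group_pos` labels (expected binding-loss-enriched,
#' e.g. pathogenic) from `group_neg` labels (e.g. benign) — the
#' probability that a `group_pos` variant scores below a `group_neg`
#' one — plus per-label score summaries and the list of `vus_label`
#' variants with combined score at or below `tau_loss`.
#'
#' @param table_A,table_B Score tables for the two baits.
#' @param annotations Tibble with columns `pos`, `alt`, and `annotation`
#'   (character labels or numeric values).
#' @param group_pos,group_neg Label sets for the AUC (categorical
#'   annotations only).
#' @param tau_loss Flagging threshold for VUS variants (default -2).
#' @param vus_label Label identifying variants of uncertain significance
#'   (default `"VUS"`).
#' @return List of class `concordance_report`: `n_joined`, `spearman`
#'   (named vector), `auc`, `label_summary`, `vus_flagged`, `data`.
#' @export
external_concordance <- function(table_A, table_B, annotations,
                                 group_pos = NULL, group_neg = NULL,
                                 tau_loss = -2, vus_label = "VUS") {
  stopifnot(all(c("pos", "alt", "annotation") %in% colnames(annotations)))
  a <- missense_scores(table_A) %>%
    filter(status != "missing") %>%
    select(pos, wt, alt, s_A = score)
  b <- missense_scores(table_B) %>%
    filter(status != "missing") %>%
    select(pos, alt, s_B = score)
  joined <- a %>%
    dplyr::inner_join(b, by = c("pos", "alt")) %>%
    dplyr::inner_join(annotations, by = c("pos", "alt")) %>%
    mutate(combined = pmin(s_A, s_B))
  if (nrow(joined) == 0L) stop("no variant overlaps the annotations")
  numeric_ann <- is.numeric(joined$annotation)
  spearman <- NULL
  auc <- NULL
  label_summary <- NULL
  vus_flagged <- NULL
  if (numeric_ann) {
    spearman <- c(
      A = cor(joined$s_A, joined$annotation, method = "spearman"),
      B = cor(joined$s_B, joined$annotation, method = "spearman"),
      combined = cor(joined$combined, joined$annotation,
                     method = "spearman")
    )
  } else {
    label_summary <- joined %>%
      group_by(label = annotation) %>%
      summarise(n = n(), median_combined = median(combined),
                mean_combined = mean(combined), .groups = "drop")
    if (!is.null(group_pos) && !is.null(group_neg)) {
      x_pos <- joined$combined[joined$annotation %in% group_pos]
      x_neg <- joined$combined[joined$annotation %in% group_neg]
      if (length(x_pos) == 0L || length(x_neg) == 0L) {
        message("empty annotation group after join; AUC not computed")
      } else {
        auc <- c(
          combined = auc_rank(x_pos, x_neg),
          A = auc_rank(joined$s_A[joined$annotation %in% group_pos],
                       joined$s_A[joined$annotation %in% group_neg]),
          B = auc_rank(joined$s_B[joined$annotation %in% group_pos],
                       joined$s_B[joined$annotation %in% group_neg])
        )
      }
    }
    vus_flagged <- joined %>%
      filter(annotation %in% vus_label, combined <= tau_loss) %>%
      select(pos, wt, alt, s_A, s_B, combined)
  }
  structure(
    list(n_joined = nrow(joined), spearman = spearman, auc = auc,
         label_summary = label_summary, vus_flagged = vus_flagged,
         data = joined),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_joined, " variants joined\n", sep = "")
  if (!is.null(x$spearman)) {
    cat("  Spearman (A, B, combined): ",
        paste(sprintf("%.3f", x$spearman), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$auc)) {
    cat("  AUC (combined, A, B): ",
        paste(sprintf("%.3f", x$auc), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$vus_flagged)) {
    cat("  VUS flagged at tau_loss: ", nrow(x$vus_flagged), "\n", sep = "")
  }
  invisible(x)
}

#' Substitution heatmap matrix
#'
#' Lays one bait's scores out as a positions x 20 amino-acid matrix in
#' the fixed alphabetical column order, with a status mask: `wt` cells
#' (the wild-type residue of each row), `floored` cells (carrying the
#' floor constant), `missing` cells (`NA` score), and `scored` cells.
#'
#' @param table A [score_screen()] table (one bait, or pass `bait`).
#' @param design A [screen_design()] giving the position range.
#' @param bait Optional bait label to select.
#' @return List of class `dms_matrix`: `score` (numeric matrix, rownames
#'   absolute positions), `status` (character matrix, same shape).
#' @export
heatmap_matrix <- function(table, design, bait = NULL) {
  ms <- missense_scores(table, bait)
  dom <- design$domain
  positions <- seq(dom$start_pos, dom$end_pos)
  aa <- aa_order()
  score <- matrix(NA_real_, nrow = length(positions), ncol = length(aa),
                  dimnames = list(positions, aa))
  status <- matrix("missing", nrow = length(positions), ncol = length(aa),
                   dimnames = list(positions, aa))
  wt_vec <- strsplit(dom$wt_aa, "")[[1]]
  status[cbind(seq_along(positions), match(wt_vec, aa))] <- "wt"
  ri <- match(ms$pos, positions)
  ci <- match(ms$alt, aa)
  keep <- !is.na(ri) & !is.na(ci)
  score[cbind(ri[keep], ci[keep])] <- ms$score[keep]
  status[cbind(ri[keep], ci[keep])] <- ms$status[keep]
  structure(list(score = score, status = status), class = "dms_matrix")
}

#' Write a substitution matrix as TSV
#'
#' @param m A [heatmap_matrix()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_heatmap_tsv <- function(m, path) {
  stopifnot(inherits(m, "dms_matrix"))
  df <- as.data.frame(m$score)
  df <- cbind(pos = rownames(m$score), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Export per-residue attributes for structure mapping
#'
#' Writes aggregate residue scores in the plain-text per-residue
#' attribute ("defattr") convention understood by molecular viewers: a
#' header naming the attribute, then one `TAB:posTABvalue` line per
#' residue.
#'
#' @param residues A [residue_aggregate()] table.
#' @param attr_name Attribute name (non-empty, no whitespace).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_residue_attributes <- function(residues, attr_name, path) {
  if (!is.character(attr_name) || length(attr_name) != 1L ||
      nchar(attr_name) == 0L || grepl("\\s", attr_name)) {
    stop("attr_name must be a non-empty string without whitespace")
  }
  if (nrow(residues) == 0L) stop("empty residue table")
  lines <- c(
    paste0("attribute: ", attr_name),
    "match mode: any",
    "recipient: residues",
    sprintf("\t:%d\t%s", residues$pos, as.character(residues$R_i))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a per-residue attribute file
#'
#' @param path File written by [write_residue_attributes()].
#' @return List with `attr_name` and `residues` (tibble `pos`, `R_i`).
#' @export
read_residue_attributes <- function(path) {
  lines <- readLines(path)
  attr_name <- sub("^attribute: ", "", lines[[1L]])
  body <- lines[grepl("^\t:", lines)]
  parts <- strsplit(sub("^\t:", "", body), "\t")
  list(
    attr_name = attr_name,
    residues = tibble(
      pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
      R_i = as.numeric(vapply(parts, `[[`, character(1), 2L))
    )
  )
}
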