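# Pipeline orchestration: configuration, count-table validation, and the
# end-to-end run (simulate -> call -> score -> analyze) with bit-stable
# TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' Every stage parameter with its default, plus the root seed from which
#' all per-stage random streams are derived.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @param baits Bait labels.
#' @param design A [screen_design()], or `NULL` for the default design.
#' @param counts_in Optional path to a counts TSV; when set, the
#'   simulate/call stages are skipped and these counts are scored.
#' @param via_reads Simulate FASTQ and call variants from reads instead
#'   of scoring simulated counts directly (slower; exercises the full
#'   path).
#' @param error_rate Read error rate when `via_reads` is used.
#' @param effect,depth [effect_config()] / [depth_config()] for
#'   simulation.
#' @param annotations Optional annotation tibble for the concordance
#'   report (see [external_concordance()]), plus `group_pos`/`group_neg`.
#' @param group_pos,group_neg Label groups for the AUC.
#' @param pseudocount,combine,estimator,min_overlap_scored,min_input_count,floor
#'   Scoring parameters, see [score_screen()].
#' @param tau,tau_loss,tau_ret Analysis thresholds, see
#'   [residue_aggregate()] and [classify_sof()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, baits = c("A", "B"),
                            design = NULL, counts_in = NULL,
                            via_reads = FALSE, error_rate = 0,
                            effect = effect_config(baits = baits),
                            depth = depth_config(),
                            annotations = NULL, group_pos = NULL,
                            group_neg = NULL,
                            pseudocount = 0.5, combine = "rem",
                            estimator = "median", min_overlap_scored = 5L,
                            min_input_count = 10L, floor = -5,
                            tau = 0, tau_loss = -2, tau_ret = -1) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), baits = baits,
         design = design, counts_in = counts_in, via_reads = via_reads,
         error_rate = error_rate, effect = effect, depth = depth,
         annotations = annotations, group_pos = group_pos,
         group_neg = group_neg, pseudocount = pseudocount,
         combine = combine, estimator = estimator,
         min_overlap_scored = min_overlap_scored,
         min_input_count = min_input_count, floor = floor, tau = tau,
         tau_loss = tau_loss, tau_ret = tau_ret),
    class = "pipeline_config"
  )
}

#' Validate a counts table
#'
#' Schema and integrity checks for user-supplied (or pipeline-produced)
#' counts: required columns, known condition and class labels,
#' non-negative integer counts, missense keys complete and inside the
#' design, and a marked-WT reference row present for every
#' (bait, replicate, condition, fragment) sample. Problems are
#' enumerated, never silently dropped.
#'
#' @param counts Count tibble or path to a counts TSV.
#' @param design Optional [screen_design()] for coordinate checks.
#' @return Tibble (`row`, `problem`) of issues — zero rows means pass —
#'   with attribute `pass`.
#' @export
validate_counts <- function(counts, design = NULL) {
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  issues <- list()
  note <- function(row, problem) {
    issues[[length(issues) + 1L]] <<- tibble(row = row, problem = problem)
  }
  required <- c("bait", "replicate", "condition", "fragment", "class",
                "pos", "wt", "alt", "count")
  missing_cols <- setdiff(required, colnames(counts))
  if (length(missing_cols) > 0L) {
    note(NA_integer_, paste("missing column(s):",
                            paste(missing_cols, collapse = ", ")))
    out <- bind_rows(issues)
    attr(out, "pass") <- FALSE
    return(out)
  }
  bad_cond <- which(!counts$condition %in% c("nonselective", "selective"))
  for (i in bad_cond) note(i, paste("unknown condition:", counts$condition[i]))
  known_class <- c("missense", "marked_wt", "apparent_wt", "stop_control")
  bad_class <- which(!counts$class %in% known_class)
  for (i in bad_class) note(i, paste("unknown class:", counts$class[i]))
  bad_count <- which(is.na(counts$count) | counts$count < 0 |
                       counts$count != floor(counts$count))
  for (i in bad_count) {
    note(i, paste("count not a non-negative integer:", counts$count[i]))
  }
  mis <- counts$class == "missense"
  bad_key <- which(mis & (is.na(counts$pos) | is.na(counts$alt) |
                            is.na(counts$wt)))
  for (i in bad_key) note(i, "missense row lacks pos/wt/alt")
  if (!is.null(design)) {
    dom <- design$domain
    out_range <- which(mis & !is.na(counts$pos) &
                         (counts$pos < dom$start_pos |
                            counts$pos > dom$end_pos))
    for (i in out_range) {
      note(i, paste("position outside design:", counts$pos[i]))
    }
  }
  samples <- distinct(counts, bait, replicate, condition, fragment)
  has_wt <- distinct(filter(counts, class == "marked_wt"),
                     bait, replicate, condition, fragment)
  no_wt <- anti_join(samples, has_wt,
                     by = c("bait", "replicate", "condition", "fragment"))
  if (nrow(no_wt) > 0L) {
    for (i in seq_len(nrow(no_wt))) {
      note(NA_integer_, sprintf(
        "no marked_wt row for sample bait=%s replicate=%s condition=%s fragment=%s",
        no_wt$bait[i], no_wt$replicate[i], no_wt$condition[i],
        no_wt$fragment[i]))
    }
  }
  out <- if (length(issues) > 0L) bind_rows(issues) else {
    tibble(row = integer(0), problem = character(0))
  }
  attr(out, "pass") <- nrow(out) == 0L
  out
}

#' Read / write count tables
#'
#' TSV interchange for count tables in the [simulate_counts()] schema.
#'
#' @param counts Count tibble.
#' @param path File path.
#' @return `read_counts_tsv`: the tibble; `write_counts_tsv`: the path,
#'   invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    bait = readr::col_character(), replicate = readr::col_integer(),
    condition = readr::col_character(), fragment = readr::col_integer(),
    class = readr::col_character(), pos = readr::col_integer(),
    wt = readr::col_character(), alt = readr::col_character(),
    count = readr::col_integer()
  ))
}

#' Run the full pipeline
#'
#' Executes simulate (or loads `counts_in`) -> (optionally) emit reads
#' and call variants -> score -> analyze, writing TSV artifacts, the
#' serialized configuration, and a JSON run manifest under
#' `config$out_dir`. Identical configuration and seed give byte-identical
#' TSV outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the scored tables and analysis objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  if (is.null(design)) design <- screen_design()
  stages <- character(0)

  if (!is.null(config$counts_in)) {
    if (!file.exists(config$counts_in)) {
      stop("counts file not found: ", config$counts_in)
    }
    counts <- read_counts_tsv(config$counts_in)
    chk <- validate_counts(counts, design)
    if (!attr(chk, "pass")) {
      stop("invalid counts table: ", paste(chk$problem, collapse = "; "))
    }
    effects <- NULL
    stages <- c(stages, "load_counts")
  } else {
    effects <- draw_effects(design, config$effect,
                            seed = derive_seed(config$seed, "effects"))
    counts <- simulate_counts(design, effects, config$depth,
                              seed = derive_seed(config$seed, "counts"))
    stages <- c(stages, "simulate")
    if (isTRUE(config$via_reads)) {
      read_dir <- file.path(config$out_dir, "reads")
      manifest <- emit_reads(counts, design,
                             error_rate = config$error_rate,
                             seed = derive_seed(config$seed, "reads"),
                             dir = read_dir)
      counts <- call_fastq(manifest, design)
      stages <- c(stages, "emit_reads", "call")
    }
    readr::write_tsv(effects, file.path(config$out_dir, "effects_truth.tsv"))
  }
  write_counts_tsv(counts, file.path(config$out_dir, "counts.tsv"))

  scores <- score_screen(
    counts, design, pseudocount = config$pseudocount,
    combine = config$combine, estimator = config$estimator,
    min_overlap_scored = config$min_overlap_scored,
    min_input_count = config$min_input_count, floor = config$floor
  )
  stages <- c(stages, "score")
  files <- character(0)
  for (bt in unique(scores$bait)) {
    f <- file.path(config$out_dir, sprintf("scores_%s.tsv", bt))
    readr::write_tsv(filter(scores, bait == bt), f)
    files <- c(files, f)
    m <- heatmap_matrix(scores, design, bait = bt)
    f <- file.path(config$out_dir, sprintf("heatmap_%s.tsv", bt))
    write_heatmap_tsv(m, f)
    files <- c(files, f)
    res <- residue_aggregate(scores, tau = config$tau, bait = bt)
    f <- file.path(config$out_dir, sprintf("residue_%s.tsv", bt))
    readr::write_tsv(res, f)
    files <- c(files, f)
    f <- file.path(config$out_dir, sprintf("residue_%s.defattr", bt))
    write_residue_attributes(res, paste0("bindingLoss_", bt), f)
    files <- c(files, f)
  }
  readr::write_tsv(attr(scores, "offsets"),
                   file.path(config$out_dir, "fragment_offsets.tsv"))

  sof <- NULL
  if (length(unique(scores$bait)) >= 2L) {
    bts <- unique(scores$bait)[1:2]
    sof <- classify_sof(scores, baits = bts, tau_loss = config$tau_loss,
                        tau_ret = config$tau_ret)
    f <- file.path(config$out_dir, "sof_calls.tsv")
    readr::write_tsv(sof, f)
    files <- c(files, f)
    stages <- c(stages, "sof")
  }
  conc <- NULL
  if (!is.null(config$annotations) && !is.null(sof)) {
    bts <- unique(scores$bait)[1:2]
    conc <- external_concordance(
      scores[scores$bait == bts[[1L]], ], scores[scores$bait == bts[[2L]], ],
      config$annotations, group_pos = config$group_pos,
      group_neg = config$group_neg, tau_loss = config$tau_loss
    )
    jsonlite::write_json(
      list(n_joined = conc$n_joined, spearman = as.list(conc$spearman),
           auc = as.list(conc$auc)),
      file.path(config$out_dir, "concordance.json"), auto_unbox = TRUE,
      digits = NA
    )
    stages <- c(stages, "concordance")
  }

  cfg_out <- config
  cfg_out$design <- NULL
  cfg_out$annotations <- NULL
  yaml::write_yaml(
    lapply(cfg_out[!vapply(cfg_out, is.function, logical(1))],
           function(x) if (is.data.frame(x)) as.list(x) else unclass(x)),
    file.path(config$out_dir, "config.yaml")
  )
  manifest <- list(
    package = "satscreen",
    version = as.character(packageVersion("satscreen")),
    seed = config$seed,
    stages = stages,
    files = basename(c(file.path(config$out_dir, "counts.tsv"), files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(design = design, effects = effects, counts = counts,
                 scores = scores, sof = sof, concordance = conc))
}
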