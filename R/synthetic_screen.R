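# Synthetic screens with known ground truth: latent per-variant binding
# effects, pool counts under non-selective and selective growth, and
# optional simulated reads.

#' Configure the ground-truth effect generator
#'
#' Residues are grouped into three classes with class-specific binding
#' fitness distributions: `critical` residues (defaults to the core
#' phospho-binding-pocket residues 1655, 1656, 1699, 1701, 1702, 1704,
#' 1775 and 1839) draw near-zero fitness; `intermediate` residues
#' (defaults to the immediate neighbours of the critical set) draw
#' partial-binding fitness; all other residues are `neutral`. Explicit
#' separation-of-function injections override the class draw for single
#' (bait, pos, alt) combinations; the defaults mirror the four
#' experimentally validated calls (R1699C losing bait A only; D1739F,
#' V1741K and P1749R losing bait B only).
#'
#' @param baits Character vector of bait labels (default
#'   `c("A", "B")`, standing for ABRAXAS1 and CtIP).
#' @param critical_residues,intermediate_residues Absolute residue
#'   numbers per class.
#' @param b_critical,b_intermediate,b_neutral Two-element `c(min, max)`
#'   uniform ranges for the binding fitness of each class.
#' @param injections Tibble with columns `bait`, `pos`, `alt`, `b`
#'   (fitness in `[0, 1]`), or `NULL` for none.
#' @return List of class `effect_config`.
#' @export
effect_config <- function(baits = c("A", "B"),
                          critical_residues = c(1655, 1656, 1699, 1701,
                                                1702, 1704, 1775, 1839),
                          intermediate_residues = NULL,
                          b_critical = c(0, 0.02),
                          b_intermediate = c(0.05, 0.6),
                          b_neutral = c(0.6, 1),
                          injections = default_sof_injections(baits)) {
  if (is.null(intermediate_residues)) {
    intermediate_residues <- setdiff(
      sort(unique(c(critical_residues - 1, critical_residues + 1))),
      critical_residues
    )
  }
  structure(
    list(
      baits = baits,
      critical_residues = critical_residues,
      intermediate_residues = intermediate_residues,
      b_critical = b_critical,
      b_intermediate = b_intermediate,
      b_neutral = b_neutral,
      injections = injections
    ),
    class = "effect_config"
  )
}

#' Default separation-of-function injections
#'
#' The four validated separation-of-function substitutions, as explicit
#' ground-truth overrides: one bait-A-specific loss (1699C) and three
#' bait-B-specific losses (1739F, 1741K, 1749R). Returns `NULL` when
#' fewer than two baits are simulated.
#'
#' @param baits Bait labels; the first is "A", the second "B".
#' @return Tibble (`bait`, `pos`, `alt`, `b`) or `NULL`.
#' @export
default_sof_injections <- function(baits = c("A", "B")) {
  if (length(baits) < 2L) return(NULL)
  a <- baits[[1L]]
  b <- baits[[2L]]
  tibble(
    bait = c(a, b, a, b, a, b, a, b),
    pos = c(1699, 1699, 1739, 1739, 1741, 1741, 1749, 1749),
    alt = c("C", "C", "F", "F", "K", "K", "R", "R"),
    b = c(0, 1, 1, 0, 1, 0, 1, 0)
  )
}

#' Draw ground-truth binding effects
#'
#' Assigns each library variant, per bait, a latent binding fitness
#' `b` in `[0, 1]` (1 = binds like wild type, 0 = no binding). The
#' marked-WT spike-in always has `b = 1` and the stop control `b = 0`.
#' Deterministic for a fixed seed.
#'
#' @param design A [screen_design()].
#' @param config An [effect_config()].
#' @param seed Integer seed.
#' @return Tibble (`bait`, `class`, `pos`, `wt`, `alt`, `b`); spike-in
#'   rows carry `NA` position columns.
#' @export
draw_effects <- function(design, config = effect_config(), seed = 1L) {
  stopifnot(inherits(design, "screen_design"), inherits(config, "effect_config"))
  dom <- design$domain
  variants <- enumerate_variants(dom)
  cls <- rep("neutral", nrow(variants))
  cls[variants$pos %in% config$intermediate_residues] <- "intermediate"
  cls[variants$pos %in% config$critical_residues] <- "critical"
  rng <- list(
    critical = config$b_critical,
    intermediate = config$b_intermediate,
    neutral = config$b_neutral
  )
  inj <- config$injections
  if (!is.null(inj)) {
    out_of_range <- inj$pos < dom$start_pos | inj$pos > dom$end_pos
    if (any(out_of_range)) {
      stop("injection position(s) outside domain: ",
           paste(unique(inj$pos[out_of_range]), collapse = ", "))
    }
    bad_alt <- inj$alt == wt_aa_at(dom, inj$pos)
    if (any(bad_alt)) {
      stop("injection alt equals wild-type residue at position(s): ",
           paste(inj$pos[bad_alt], collapse = ", "))
    }
  }
  per_bait <- lapply(config$baits, function(bt) {
    b <- withr::with_seed(derive_seed(seed, "effects", bt), {
      lo <- vapply(rng[cls], `[[`, numeric(1), 1L)
      hi <- vapply(rng[cls], `[[`, numeric(1), 2L)
      runif(nrow(variants), lo, hi)
    })
    out <- tibble(
      bait = bt, class = "missense",
      pos = variants$pos, wt = variants$wt, alt = variants$alt, b = b
    )
    if (!is.null(inj)) {
      ib <- inj[inj$bait == bt, ]
      if (nrow(ib) > 0L) {
        key <- paste(out$pos, out$alt)
        ikey <- paste(ib$pos, ib$alt)
        hit <- match(ikey, key)
        stopifnot(!anyNA(hit))
        out$b[hit] <- ib$b
      }
    }
    bind_rows(
      out,
      tibble(bait = bt, class = c("marked_wt", "stop_control"),
             pos = NA_integer_, wt = NA_character_, alt = NA_character_,
             b = c(1, 0))
    )
  })
  bind_rows(per_bait)
}

#' Configure simulated sequencing depth and pool composition
#'
#' @param n_per_sample Reads per (replicate, condition, fragment) sample.
#' @param sigma Log-normal dispersion of input library abundances.
#' @param n_replicates Number of selection replicates (default 3).
#' @param generations Selection rounds; survival is proportional to
#'   `b^generations` (default 1: plate selection as a single viability
#'   readout).
#' @param include_plain_wt Include an unmarked wild-type control in the
#'   pool (as in the screened library); its reads are fragment-local wild
#'   type and are tabulated as `apparent_wt`.
#' @return List of class `depth_config`.
#' @export
depth_config <- function(n_per_sample = 2e5, sigma = 0.3, n_replicates = 3L,
                         generations = 1, include_plain_wt = TRUE) {
  stopifnot(n_per_sample >= 1, sigma >= 0, n_replicates >= 1L,
            generations >= 1)
  structure(
    list(n_per_sample = n_per_sample, sigma = sigma,
         n_replicates = n_replicates, generations = generations,
         include_plain_wt = include_plain_wt),
    class = "depth_config"
  )
}

#' Simulate screen count tables
#'
#' Each replicate draws log-normal input abundances `a_v` (shared across
#' conditions and fragments within the replicate); the marked-WT,
#' stop-control and optional plain-WT spike-ins receive the median
#' library abundance. Each (condition, fragment) sample is a multinomial
#' draw of `n_per_sample` reads over the fragment's member variants plus
#' spike-ins, with selective-sample probabilities proportional to
#' `a_v * b_v^generations`. Variants fully unable to bind therefore drop
#' out of the selective pool.
#'
#' @param design A [screen_design()].
#' @param effects Output of [draw_effects()].
#' @param depth A [depth_config()].
#' @param seed Integer seed.
#' @return Tibble (`bait`, `replicate`, `condition`, `fragment`, `class`,
#'   `pos`, `wt`, `alt`, `count`) including zero-count rows, so dropout
#'   is explicit.
#' @export
simulate_counts <- function(design, effects, depth = depth_config(),
                            seed = 1L) {
  stopifnot(inherits(design, "screen_design"), inherits(depth, "depth_config"))
  fr <- design$fragments
  out <- list()
  for (bt in unique(effects$bait)) {
    eff <- effects[effects$bait == bt, ]
    mis <- eff[eff$class == "missense", ]
    if (all(eff$b == 0)) {
      stop("all binding effects are zero for bait ", bt,
           ": no selective pool to draw from")
    }
    spike_classes <- c("marked_wt", "stop_control",
                       if (depth$include_plain_wt) "apparent_wt")
    # spike-in fitness from the effect map (plain WT binds like WT)
    b_of <- function(cl) {
      hit <- eff$b[eff$class == cl]
      if (length(hit) == 1L) hit else 1
    }
    spike_b <- vapply(spike_classes, b_of, numeric(1))
    for (r in seq_len(depth$n_replicates)) {
      a_mis <- withr::with_seed(
        derive_seed(seed, "abundance", bt, r),
        rlnorm(nrow(mis), meanlog = 0, sdlog = depth$sigma)
      )
      a_spike <- rep(median(a_mis), length(spike_classes))
      for (cond in c("nonselective", "selective")) {
        for (f in fr$fragment) {
          inside <- mis$pos >= fr$first_pos[f] & mis$pos <= fr$last_pos[f]
          a <- c(a_mis[inside], a_spike)
          b <- c(mis$b[inside], spike_b)
          p <- a * if (cond == "selective") b^depth$generations else 1
          counts <- withr::with_seed(
            derive_seed(seed, "counts", bt, r, cond, f),
            as.vector(rmultinom(1L, size = depth$n_per_sample,
                                prob = p / sum(p)))
          )
          k <- sum(inside)
          out[[length(out) + 1L]] <- tibble(
            bait = bt, replicate = r, condition = cond, fragment = f,
            class = c(rep("missense", k), spike_classes),
            pos = c(mis$pos[inside], rep(NA_integer_, length(spike_classes))),
            wt = c(mis$wt[inside], rep(NA_character_, length(spike_classes))),
            alt = c(mis$alt[inside], rep(NA_character_, length(spike_classes))),
            count = counts
          )
        }
      }
    }
  }
  bind_rows(out)
}

# construct the read sequence for one counted class in one fragment
construct_amplicon <- function(design, f, class, pos, alt) {
  switch(class,
    missense = variant_amplicon(design, f, pos, alt),
    marked_wt = fragment_amplicon(design, f, "marked"),
    apparent_wt = fragment_amplicon(design, f, "wt"),
    stop_control = fragment_amplicon(design, f, "stop"),
    stop("cannot emit reads for class ", class)
  )
}

# apply iid per-base substitution errors to a character vector of reads
add_read_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[[1L]])
  n_err <- rbinom(length(reads), size = len, prob = error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(len, n_err[i])
    ch <- strsplit(reads[[i]], "")[[1]]
    for (j in at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Emit simulated FASTQ reads
#'
#' One read per counted molecule: the construct's full amplicon (anchors
#' included) with i.i.d. per-base substitution errors, a fixed Q40
#' quality string, written as one FASTQ file per (bait, replicate,
#' condition, fragment) sample.
#'
#' @param counts Output of [simulate_counts()].
#' @param design A [screen_design()].
#' @param error_rate Per-base substitution probability in `[0, 0.05]`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Tibble (`bait`, `replicate`, `condition`, `fragment`, `file`,
#'   `n_reads`) describing the files written.
#' @export
emit_reads <- function(counts, design, error_rate = 0, seed = 1L, dir) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- distinct(counts, bait, replicate, condition, fragment)
  manifest <- list()
  for (i in seq_len(nrow(samples))) {
    sm <- samples[i, ]
    rows <- counts %>%
      filter(bait == sm$bait, replicate == sm$replicate,
             condition == sm$condition, fragment == sm$fragment,
             count > 0L)
    reads <- character(0)
    if (nrow(rows) > 0L) {
      reads <- unlist(lapply(seq_len(nrow(rows)), function(j) {
        rep(construct_amplicon(design, rows$fragment[j], rows$class[j],
                               rows$pos[j], rows$alt[j]),
            rows$count[j])
      }))
    }
    reads <- withr::with_seed(
      derive_seed(seed, "reads", sm$bait, sm$replicate, sm$condition,
                  sm$fragment),
      add_read_errors(reads, error_rate)
    )
    file <- file.path(dir, sprintf("%s_rep%d_%s_frag%d.fastq", sm$bait,
                                   sm$replicate, sm$condition, sm$fragment))
    write_fastq(reads, file,
                id_prefix = sprintf("%s:%d:%s:%d", sm$bait, sm$replicate,
                                    sm$condition, sm$fragment))
    manifest[[i]] <- tibble(
      bait = sm$bait, replicate = sm$replicate, condition = sm$condition,
      fragment = sm$fragment, file = file, n_reads = length(reads)
    )
  }
  bind_rows(manifest)
}

# plain 4-line FASTQ writer with a fixed Q40 quality string
write_fastq <- function(reads, file, id_prefix = "read") {
  n <- length(reads)
  if (n == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  qual <- vapply(nchar(reads), function(k) strrep("I", k), character(1))
  rec <- as.vector(rbind(
    paste0("@", id_prefix, ":", seq_len(n)),
    reads,
    rep("+", n),
    qual
  ))
  writeLines(rec, file)
  invisible(file)
}
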