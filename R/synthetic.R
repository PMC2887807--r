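# Self-contained synthetic phosphoproteome fixtures: sequences, PSSM files
# and positive-site tables with controlled class signal and imbalance.

# average amino-acid frequencies in well-curated protein databases
AA_FREQ <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
             E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
             M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
             Y = 2.92, V = 6.87) / 100

#' Configuration for the synthetic phosphoproteome generator
#'
#' The generator emulates the statistical structure the classifier relies
#' on: per-protein L x 20 integer profiles whose rows are i.i.d. background
#' noise except inside windows around planted phosphosites, where a mean
#' shift of `effect_size` is added — evolutionary conservation rendered as
#' an additive log-odds signal.  Sequence geometry is arranged so that,
#' after the distance-based exclusion rule, the expected number of
#' negatives per positive matches `imbalance`.
#'
#' @param n_proteins number of proteins to simulate.
#' @param len_min,len_max admissible protein lengths; a protein whose
#'   geometry cannot fit within `len_max` is an error.
#' @param positives_per_protein integer vector from which the per-protein
#'   positive count is sampled uniformly (default `1:2`).
#' @param composition named amino-acid frequency vector (defaults to
#'   database-average frequencies).
#' @param positive_residue_weights sampling weights over S/T/Y for the
#'   residue type of each planted site.  Default proportional to the
#'   composition, which makes the realized per-residue imbalance match
#'   `imbalance` for every residue type.
#' @param effect_size mean log-odds shift added at signal positions of
#'   positive windows (delta >= 0; 0 gives a null dataset).
#' @param signal_width number of consecutive profile rows centered on the
#'   site that carry the shift (odd, default 7 — no wider than the
#'   smallest supported window).
#' @param background integer score range `c(min, max)` for the i.i.d.
#'   background (default `c(-5, 5)`, mean 0).
#' @param imbalance expected negatives per positive after labeling
#'   (default 5.6, the serine-like regime; threonine/tyrosine corpora run
#'   closer to 25).
#' @param distance exclusion radius used when sizing the geometry
#'   (default 50).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L, len_min = 60L, len_max = 5000L,
                       positives_per_protein = 1:2,
                       composition = AA_FREQ,
                       positive_residue_weights = NULL,
                       effect_size = 3, signal_width = 7L,
                       background = c(-5L, 5L), imbalance = 5.6,
                       distance = 50L, seed = 1L) {
  if (effect_size < 0) stop_config("effect_size must be >= 0")
  signal_width <- as.integer(signal_width)
  if (signal_width < 1L || signal_width %% 2L == 0L) {
    stop_config("signal_width must be a positive odd integer")
  }
  if (signal_width > 7L) {
    warning("signal_width wider than the smallest supported window (7)")
  }
  if (length(background) != 2L || background[1L] > background[2L]) {
    stop_config("background must be c(min, max) with min <= max")
  }
  if (imbalance <= 0) stop_config("imbalance must be positive")
  composition <- composition / sum(composition)
  if (!all(PHOSPHO_RESIDUES %in% names(composition))) {
    stop_config("composition must include S, T and Y")
  }
  if (is.null(positive_residue_weights)) {
    positive_residue_weights <- composition[PHOSPHO_RESIDUES]
  }
  w <- positive_residue_weights[PHOSPHO_RESIDUES]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop_config("positive residue weights must not all be 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 len_min = as.integer(len_min),
                 len_max = as.integer(len_max),
                 positives_per_protein = as.integer(positives_per_protein),
                 composition = composition,
                 positive_residue_weights = w / sum(w),
                 effect_size = effect_size, signal_width = signal_width,
                 background = as.integer(background),
                 imbalance = imbalance, distance = as.integer(distance),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @noRd
sample_aa <- function(n, composition, exclude_sty = FALSE) {
  if (n <= 0L) return(character(0))
  freq <- composition
  if (exclude_sty) freq[PHOSPHO_RESIDUES] <- 0
  sample(names(freq), n, replace = TRUE, prob = freq)
}

# integer-valued additive shift with mean delta
#' @noRd
integer_shift <- function(n, delta) {
  base <- floor(delta)
  frac <- delta - base
  base + stats::rbinom(n, 1L, frac)
}

#' Simulate a synthetic phosphoproteome
#'
#' Generates protein sequences, PSSM profiles and a positive-site table
#' whose statistical structure is controlled by a [sim_config()].  Each
#' protein is laid out as: a short phosphosite block per planted positive
#' (an exclusion zone of `2 * distance + 1` residues with the site at its
#' center, drawn from the full composition), followed by a negative region
#' sized so that its expected S/T/Y count delivers the configured
#' imbalance, with S/T/Y-free padding in between.  Profile rows are i.i.d.
#' integers from the background range; rows within `signal_width` of a
#' planted site are shifted by `effect_size` across all 20 columns.
#'
#' A gold table records the true label (positive / negative / excluded) of
#' every S/T/Y site, computed by brute force from the planted positions,
#' for oracle comparison against the pipeline's own labeling.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `proteins.fasta`, one `<id>.pssm` per protein, `annotations.tsv` and
#'   `gold.tsv`.
#' @return (Invisibly when `dir` is given.)  List with `profiles` (named
#'   list of [pssm_profile()]), `annotations`, `gold` data.frames and the
#'   `config`.
#' @export
simulate_phosphoproteome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_local_seed(config$seed, {
    profiles <- list()
    ann <- list()
    gold <- list()
    zone <- 2L * config$distance + 1L
    q_pos <- sum(config$composition[PHOSPHO_RESIDUES][
      config$positive_residue_weights > 0])
    for (i in seq_len(config$n_proteins)) {
      id <- sprintf("SYN%04d", i)
      m <- if (length(config$positives_per_protein) == 1L) {
        config$positives_per_protein
      } else {
        sample(config$positives_per_protein, 1L)
      }
      len_neg <- as.integer(round(config$imbalance * m / q_pos))
      needed <- m * zone + len_neg
      if (needed > config$len_max) {
        stop_config("protein ", id, " needs ", needed,
                    " residues for ", m, " positives at imbalance ",
                    config$imbalance, " but len_max is ", config$len_max)
      }
      res_types <- sample(PHOSPHO_RESIDUES, m, replace = TRUE,
                          prob = config$positive_residue_weights)
      chars <- character(0)
      positions <- integer(m)
      for (j in seq_len(m)) {
        gap <- sample(0:10, 1L)
        chars <- c(chars, sample_aa(gap, config$composition,
                                    exclude_sty = TRUE))
        block <- sample_aa(zone, config$composition)
        block[config$distance + 1L] <- res_types[j]
        positions[j] <- length(chars) + config$distance + 1L
        chars <- c(chars, block)
      }
      chars <- c(chars, sample_aa(len_neg, config$composition))
      if (length(chars) < config$len_min) {
        chars <- c(chars, sample_aa(config$len_min - length(chars),
                                    config$composition,
                                    exclude_sty = TRUE))
      }
      if (length(chars) > config$len_max) {
        stop_config("protein ", id, " exceeds len_max after padding")
      }
      L <- length(chars)
      scores <- matrix(
        sample(config$background[1L]:config$background[2L], L * 20L,
               replace = TRUE),
        nrow = L, ncol = 20L)
      if (config$effect_size > 0) {
        h <- (config$signal_width - 1L) %/% 2L
        for (p in positions) {
          rows <- max(1L, p - h):min(L, p + h)
          scores[rows, ] <- scores[rows, ] +
            matrix(integer_shift(length(rows) * 20L, config$effect_size),
                   nrow = length(rows))
        }
      }
      prof <- pssm_profile(id, paste(chars, collapse = ""), scores)
      profiles[[id]] <- prof
      ann[[id]] <- data.frame(protein_id = id, position = positions,
                              residue = res_types,
                              stringsAsFactors = FALSE)
      # gold labels by brute force over (site, annotation) pairs
      sty <- which(chars %in% PHOSPHO_RESIDUES)
      glab <- vapply(sty, function(p) {
        if (p %in% positions) return("positive")
        if (any(abs(p - positions) <= config$distance)) return("excluded")
        "negative"
      }, character(1))
      gold[[id]] <- data.frame(protein_id = id, position = sty,
                               residue = chars[sty], label = glab,
                               stringsAsFactors = FALSE)
    }
    list(profiles = profiles,
         annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))),
         gold = do.call(rbind, c(gold, list(make.row.names = FALSE))),
         config = config)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    seqs <- vapply(out$profiles, `[[`, character(1), "sequence")
    write_fasta(seqs, file.path(dir, "proteins.fasta"))
    for (prof in out$profiles) {
      write_pssm(prof, file.path(dir, paste0(prof$protein_id, ".pssm")))
    }
    write_annotations(out$annotations, file.path(dir, "annotations.tsv"))
    utils::write.table(out$gold, file.path(dir, "gold.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Check pipeline labeling against the generator's gold labels
#'
#' Re-reads a simulated fixture directory with the package's own readers,
#' runs the labeling rule on every protein and compares site-by-site with
#' `gold.tsv`.  A healthy pipeline agrees on 100% of sites.
#'
#' @param dir directory written by [simulate_phosphoproteome()].
#' @param distance exclusion radius (default 50; must match the one used
#'   at simulation time).
#' @return List with `agreement` (fraction between 0 and 1), `n_sites`, and
#'   `disagreements` (data.frame of mismatching sites with both labels).
#' @export
gold_check <- function(dir, distance = 50L) {
  gold_path <- file.path(dir, "gold.tsv")
  if (!file.exists(gold_path)) stop_data("gold.tsv not found in ", dir)
  gold <- utils::read.delim(gold_path, colClasses = c(
    protein_id = "character", position = "integer", residue = "character",
    label = "character"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  pssm_files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  labs <- do.call(rbind, lapply(pssm_files, function(f) {
    prof <- parse_pssm(f)
    label_sites(prof, ann$position[ann$protein_id == prof$protein_id],
                distance = distance)
  }))
  key <- function(d) paste(d$protein_id, d$position)
  merged <- merge(gold, labs, by = c("protein_id", "position"),
                  suffixes = c("_gold", "_pipeline"), all = TRUE)
  mismatch <- is.na(merged$label_gold) | is.na(merged$label_pipeline) |
    merged$label_gold != merged$label_pipeline
  list(agreement = 1 - sum(mismatch) / nrow(merged),
       n_sites = nrow(merged),
       disagreements = merged[mismatch, , drop = FALSE])
}
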