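# Turning profiles + positive annotations into labeled, windowed,
# ratio-balanced instance sets per residue type.

#' Label every S/T/Y site of a protein
#'
#' Applies the negative-site rule: a non-annotated S/T/Y residue is labeled
#' `negative` only if it lies more than `distance` residues (default 50)
#' from every annotated phosphosite of the protein, regardless of that
#' site's residue type.  Non-annotated sites within the exclusion zone are
#' labeled `excluded` and contribute to neither class; annotated positions
#' are `positive`.  Non-S/T/Y positions are never labeled.
#'
#' @param profile a [pssm_profile()].
#' @param positives integer vector of 1-based annotated positions.  Every
#'   one must fall on an S, T or Y of the sequence.
#' @param distance exclusion radius in residues (default 50).
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `label` (one row per S/T/Y position, ascending).
#' @export
label_sites <- function(profile, positives, distance = 50L) {
  stopifnot(inherits(profile, "pssm_profile"))
  positives <- as.integer(positives)
  seq_chars <- strsplit(profile$sequence, "")[[1]]
  L <- length(seq_chars)
  if (length(positives)) {
    if (any(positives < 1L | positives > L)) {
      stop_data(profile$protein_id, ": annotated position outside [1, ", L,
                "]")
    }
    bad <- positives[!seq_chars[positives] %in% PHOSPHO_RESIDUES]
    if (length(bad)) {
      stop_data(profile$protein_id, ": annotated position(s) ",
                paste(bad, collapse = ", "), " not on an S/T/Y residue")
    }
  }
  sty <- which(seq_chars %in% PHOSPHO_RESIDUES)
  if (!length(sty)) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  label <- rep("negative", length(sty))
  if (length(positives)) {
    # min distance from each site to any annotated position
    dmin <- vapply(sty, function(p) min(abs(p - positives)), numeric(1))
    label[dmin <= distance] <- "excluded"
    label[sty %in% positives] <- "positive"
  }
  data.frame(protein_id = profile$protein_id, position = sty,
             residue = seq_chars[sty], label = label,
             stringsAsFactors = FALSE)
}

#' Extract a flattened PSSM window around a position
#'
#' Concatenates the `W` score rows centered on `position` (ascending
#' position order) into one numeric vector of length `20 * W`.  Window rows
#' falling outside the sequence contribute 20 zeros each — zero is neutral
#' in log-odds space.
#'
#' @param profile a [pssm_profile()].
#' @param position 1-based center position.
#' @param W odd window size (the classical choices are 7, 9, 11, 13, 15).
#' @return Numeric vector of length `20 * W`.
#' @export
extract_window <- function(profile, position, W) {
  stopifnot(inherits(profile, "pssm_profile"))
  W <- as.integer(W)
  if (length(W) != 1L || is.na(W) || W < 1L || W %% 2L == 0L) {
    stop_config("window size W must be a positive odd integer, got ", W)
  }
  L <- nrow(profile$scores)
  position <- as.integer(position)
  if (position < 1L || position > L) {
    stop_data("position ", position, " outside profile of length ", L)
  }
  half <- (W - 1L) %/% 2L
  out <- matrix(0, nrow = W, ncol = 20L)
  rows <- (position - half):(position + half)
  inside <- rows >= 1L & rows <= L
  out[inside, ] <- profile$scores[rows[inside], , drop = FALSE]
  as.numeric(t(out))
}

#' Construct an instance set
#'
#' Instances are the unit of SVM training: a feature matrix (one row per
#' site, `20 * W` columns), a target vector in {+1, -1} and a provenance
#' table locating each row in its protein.
#'
#' @param features numeric matrix, n x (20 * W).
#' @param target integer/numeric vector in {+1, -1}.
#' @param provenance data.frame with `protein_id`, `position`, `residue`.
#' @param residue which residue type the set belongs to (`S`, `T` or `Y`).
#' @param W window size used for the features.
#' @return An object of class `instance_set`.
#' @export
instance_set <- function(features, target, provenance, residue, W) {
  features <- as.matrix(features)
  if (nrow(features) != length(target) ||
      nrow(features) != nrow(provenance)) {
    stop_data("features, target and provenance sizes disagree")
  }
  if (length(target) && !all(target %in% c(-1, 1))) {
    stop_data("targets must be +1 or -1")
  }
  if (ncol(features) != 20L * W && nrow(features) > 0L) {
    stop_data("feature dimension ", ncol(features),
              " does not match 20*W = ", 20L * W)
  }
  structure(list(features = features, target = as.numeric(target),
                 provenance = provenance, residue = residue,
                 W = as.integer(W)),
            class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf(
    "<instance_set> residue %s, W=%d: %d instances (%d +, %d -)\n",
    x$residue, x$W, nrow(x$features), sum(x$target > 0),
    sum(x$target < 0)))
  invisible(x)
}

#' Number of instances in a set
#' @param set an [instance_set()].
#' @return Integer count.
#' @export
n_instances <- function(set) nrow(set$features)

#' @noRd
subset_instances <- function(set, idx) {
  instance_set(set$features[idx, , drop = FALSE], set$target[idx],
               set$provenance[idx, , drop = FALSE], set$residue, set$W)
}

#' Merge instance sets (same residue and window size)
#' @param ... [instance_set()] objects.
#' @return A single [instance_set()].
#' @export
merge_instances <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "instance_set")) {
    sets <- sets[[1]]
  }
  residues <- unique(vapply(sets, `[[`, character(1), "residue"))
  Ws <- unique(vapply(sets, `[[`, integer(1), "W"))
  if (length(residues) != 1L || length(Ws) != 1L) {
    stop_data("cannot merge instance sets with differing residue or W")
  }
  instance_set(do.call(rbind, lapply(sets, `[[`, "features")),
               unlist(lapply(sets, `[[`, "target")),
               do.call(rbind, lapply(sets, `[[`, "provenance")),
               residues, Ws)
}

#' Build positive and negative instance sets for one residue type
#'
#' Runs [label_sites()] on every annotated protein, keeps the sites of the
#' requested residue type, and encodes each with [extract_window()].
#' Excluded sites produce nothing.  Order is deterministic: proteins in the
#' order of `profiles`, positions ascending within each protein.
#'
#' By default only proteins carrying at least one positive annotation
#' (phosphoproteins) contribute instances; set
#' `phosphoproteins_only = FALSE` to draw negatives from unannotated
#' proteins too.
#'
#' @param profiles named list of [pssm_profile()] objects.
#' @param annotations data.frame of positive annotations (`protein_id`,
#'   `position`, `residue`), e.g. from [read_annotations()].
#' @param residue one of `"S"`, `"T"`, `"Y"`.
#' @param W odd window size.
#' @param distance exclusion radius for the negative rule (default 50).
#' @param phosphoproteins_only drop proteins without positives (default
#'   `TRUE`).
#' @return List with elements `positives` and `negatives`, both
#'   [instance_set()] objects.
#' @export
build_instances <- function(profiles, annotations, residue, W,
                            distance = 50L, phosphoproteins_only = TRUE) {
  residue <- match.arg(residue, PHOSPHO_RESIDUES)
  missing_ids <- setdiff(unique(annotations$protein_id), names(profiles))
  if (length(missing_ids)) {
    stop_data("annotations reference proteins without profiles: ",
              paste(missing_ids, collapse = ", "))
  }
  ids <- names(profiles)
  if (phosphoproteins_only) {
    ids <- ids[ids %in% unique(annotations$protein_id)]
  }
  pos_feat <- list(); pos_prov <- list()
  neg_feat <- list(); neg_prov <- list()
  for (id in ids) {
    prof <- profiles[[id]]
    ann <- annotations$position[annotations$protein_id == id]
    lab <- label_sites(prof, ann, distance = distance)
    lab <- lab[lab$residue == residue & lab$label != "excluded", ,
               drop = FALSE]
    if (!nrow(lab)) next
    feats <- t(vapply(lab$position,
                      function(p) extract_window(prof, p, W),
                      numeric(20L * W)))
    is_pos <- lab$label == "positive"
    if (any(is_pos)) {
      pos_feat[[id]] <- feats[is_pos, , drop = FALSE]
      pos_prov[[id]] <- lab[is_pos, c("protein_id", "position", "residue")]
    }
    if (any(!is_pos)) {
      neg_feat[[id]] <- feats[!is_pos, , drop = FALSE]
      neg_prov[[id]] <- lab[!is_pos, c("protein_id", "position", "residue")]
    }
  }
  bind_side <- function(feat, prov, tgt) {
    if (length(feat)) {
      f <- do.call(rbind, feat)
      p <- do.call(rbind, prov)
      rownames(p) <- NULL
    } else {
      f <- matrix(numeric(0), 0L, 20L * W)
      p <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), stringsAsFactors = FALSE)
    }
    instance_set(f, rep(tgt, nrow(f)), p, residue, W)
  }
  list(positives = bind_side(pos_feat, pos_prov, +1),
       negatives = bind_side(neg_feat, neg_prov, -1))
}

#' Plan the negative-class reduction
#'
#' To keep roughly `factor` negatives per positive, negatives are thinned
#' by keeping every r-th instance with `r = max(1, floor(n / (factor *
#' p)))`.  The positive set is never touched.
#'
#' @param p number of positive instances.
#' @param n number of negative instances before reduction.
#' @param factor target negatives-per-positive; the classical grid is
#'   2, 1.5, 1, 0.5.
#' @return Object of class `balance_plan` with fields `p`, `n`, `factor`,
#'   `r`.
#' @export
balance_plan <- function(p, n, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop_config("balance factor must be a positive number")
  }
  if (p < 1L) stop_data("need at least one positive instance")
  r <- max(1L, as.integer(floor(n / (factor * p))))
  structure(list(p = as.integer(p), n = as.integer(n), factor = factor,
                 r = r),
            class = "balance_plan")
}

#' @export
print.balance_plan <- function(x, ...) {
  cat(sprintf("<balance_plan> p=%d n=%d factor=%g -> keep every %d-th (%d kept)\n",
              x$p, x$n, x$factor, x$r, ceiling(x$n / x$r)))
  invisible(x)
}

#' Reduce a negative instance set by stride selection
#'
#' Keeps the negatives at 0-based indices `0, r, 2r, ...` (i.e. the 1st,
#' (r+1)-th, ... in input order), yielding `ceiling(n / r)` instances.
#' Order and provenance are preserved.
#'
#' @param negatives an [instance_set()] of negatives in deterministic
#'   order.
#' @param plan a [balance_plan()].
#' @return The thinned [instance_set()].
#' @export
balance <- function(negatives, plan) {
  stopifnot(inherits(negatives, "instance_set"),
            inherits(plan, "balance_plan"))
  n <- n_instances(negatives)
  if (n != plan$n) {
    stop_data("plan was made for n=", plan$n, " negatives, got ", n)
  }
  if (n == 0L) return(negatives)
  keep <- seq(1L, n, by = plan$r)
  subset_instances(negatives, keep)
}

#' Stratified k-fold split
#'
#' Partitions an instance set into `folds` class-stratified folds whose
#' per-class sizes differ by at most one.  Reproducible for a fixed seed.
#'
#' @param instances an [instance_set()] containing both classes.
#' @param folds number of folds (default 3).
#' @param seed integer RNG seed.
#' @return List of length `folds`; each element has integer index vectors
#'   `train` and `test` into `instances`.
#' @export
split_folds <- function(instances, folds = 3L, seed = 1L) {
  stopifnot(inherits(instances, "instance_set"))
  folds <- as.integer(folds)
  if (folds < 2L) stop_config("need at least 2 folds")
  idx_pos <- which(instances$target > 0)
  idx_neg <- which(instances$target < 0)
  if (length(idx_pos) < folds || length(idx_neg) < folds) {
    stop_data("fewer instances than folds in at least one class (",
              length(idx_pos), " positive, ", length(idx_neg),
              " negative, ", folds, " folds)")
  }
  assign_class <- function(idx) {
    shuffled <- with_local_seed(seed, sample(idx))
    split(shuffled, rep_len(seq_len(folds), length(shuffled)))
  }
  # seed offset for the negative class so the two shuffles are independent
  pos_folds <- assign_class(idx_pos)
  neg_folds <- with_local_seed(seed + 1L, {
    shuffled <- sample(idx_neg)
    split(shuffled, rep_len(seq_len(folds), length(shuffled)))
  })
  lapply(seq_len(folds), function(f) {
    test <- sort(c(pos_folds[[f]], neg_folds[[f]]))
    list(train = setdiff(seq_len(n_instances(instances)), test),
         test = test)
  })
}

#' Write an instance set in the sparse libsvm interchange format
#'
#' One line per instance: `label index:value ...` with 1-based feature
#' indices and zero-valued features omitted.  A provenance sidecar TSV
#' (`<path>.prov.tsv`) records protein, position, residue, residue type
#' and window size per line.
#'
#' @param set an [instance_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(set, path) {
  stopifnot(inherits(set, "instance_set"))
  lines <- vapply(seq_len(n_instances(set)), function(i) {
    x <- set$features[i, ]
    nz <- which(x != 0)
    paste(c(sprintf("%+d", as.integer(set$target[i])),
            sprintf("%d:%s", nz, format(x[nz], trim = TRUE,
                                        scientific = FALSE))),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  prov <- set$provenance
  prov$residue_type <- rep(set$residue, nrow(prov))
  prov$W <- rep(set$W, nrow(prov))
  utils::write.table(prov, paste0(path, ".prov.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an instance set written by [write_libsvm()]
#'
#' @param path libsvm-format file (its `.prov.tsv` sidecar must sit next
#'   to it).
#' @param k feature dimension; inferred from the sidecar's `W` column when
#'   omitted.
#' @return An [instance_set()].
#' @export
read_libsvm <- function(path, k = NULL) {
  if (!file.exists(path)) stop_data("instance file not found: ", path)
  prov_path <- paste0(path, ".prov.tsv")
  if (!file.exists(prov_path)) {
    stop_data("provenance sidecar not found: ", prov_path)
  }
  prov <- utils::read.delim(prov_path, colClasses = c(
    protein_id = "character", position = "integer", residue = "character",
    residue_type = "character", W = "integer"))
  W <- if (nrow(prov)) prov$W[1L] else NA_integer_
  residue <- if (nrow(prov)) prov$residue_type[1L] else "S"
  if (is.null(k)) {
    if (is.na(W)) stop_config("cannot infer dimension from empty sidecar; supply k")
    k <- 20L * W
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  target <- numeric(length(lines))
  feats <- matrix(0, nrow = length(lines), ncol = k)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    target[i] <- as.numeric(toks[1L])
    if (length(toks) > 1L) {
      kv <- strsplit(toks[-1L], ":", fixed = TRUE)
      idx <- vapply(kv, function(z) as.integer(z[1L]), integer(1))
      val <- vapply(kv, function(z) as.numeric(z[2L]), numeric(1))
      if (any(idx < 1L | idx > k)) {
        stop_data("feature index out of range on line ", i)
      }
      feats[i, idx] <- val
    }
  }
  if (is.na(W)) W <- k %/% 20L
  instance_set(feats, target, prov[, c("protein_id", "position", "residue")],
               residue, W)
}

#' Per-residue site count summary
#'
#' Counts positive/negative/excluded S, T and Y sites across a set of
#' labeled proteins — the bookkeeping view used to judge class imbalance
#' before balancing.
#'
#' @param profiles named list of [pssm_profile()] objects.
#' @param annotations positive annotation data.frame.
#' @param distance exclusion radius (default 50).
#' @param phosphoproteins_only restrict to annotated proteins (default
#'   `TRUE`).
#' @return data.frame with one row per residue and columns `residue`,
#'   `positive`, `negative`, `excluded`.
#' @export
site_count_summary <- function(profiles, annotations, distance = 50L,
                               phosphoproteins_only = TRUE) {
  ids <- names(profiles)
  if (phosphoproteins_only) {
    ids <- ids[ids %in% unique(annotations$protein_id)]
  }
  labs <- do.call(rbind, lapply(ids, function(id) {
    label_sites(profiles[[id]],
                annotations$position[annotations$protein_id == id],
                distance = distance)
  }))
  out <- data.frame(residue = PHOSPHO_RESIDUES, positive = 0L,
                    negative = 0L, excluded = 0L)
  if (!is.null(labs) && nrow(labs)) {
    for (i in seq_len(3L)) {
      sub <- labs[labs$residue == PHOSPHO_RESIDUES[i], ]
      out$positive[i] <- sum(sub$label == "positive")
      out$negative[i] <- sum(sub$label == "negative")
      out$excluded[i] <- sum(sub$label == "excluded")
    }
  }
  out
}

#' Dataset lineage bookkeeping
#'
#' Reproduces the standard curation chain for a phosphosite corpus: from
#' the full annotation table (dataset A), drop the protein(s) carrying
#' non-S/T/Y annotations (A'), then drop proteins shared with an
#' independent benchmark (A'').  Returns entry and per-residue annotation
#' counts at each stage.
#'
#' @param annotations_raw data.frame with `protein_id`, `position`,
#'   `residue` — may include non-S/T/Y rows.
#' @param benchmark_proteins character vector of protein ids in the
#'   benchmark set.
#' @return List with `A`, `A_prime`, `A_double_prime`; each holds
#'   `proteins` (entry count), `annotations` (row count) and `by_residue`
#'   (named count vector over S/T/Y, plus `other` for A).
#' @export
dataset_lineage <- function(annotations_raw, benchmark_proteins = character()) {
  res <- toupper(annotations_raw$residue)
  count_stage <- function(tab) {
    r <- toupper(tab$residue)
    list(proteins = length(unique(tab$protein_id)),
         annotations = nrow(tab),
         by_residue = c(S = sum(r == "S"), T = sum(r == "T"),
                        Y = sum(r == "Y"),
                        other = sum(!r %in% PHOSPHO_RESIDUES)))
  }
  A <- count_stage(annotations_raw)
  off_proteins <- unique(annotations_raw$protein_id[!res %in% PHOSPHO_RESIDUES])
  a_prime <- annotations_raw[!annotations_raw$protein_id %in% off_proteins, ,
                             drop = FALSE]
  A_prime <- count_stage(a_prime)
  a_dp <- a_prime[!a_prime$protein_id %in% benchmark_proteins, , drop = FALSE]
  A_double_prime <- count_stage(a_dp)
  list(A = A, A_prime = A_prime, A_double_prime = A_double_prime)
}
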