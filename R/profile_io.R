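# Readers and writers for protein sequences, PSI-BLAST ASCII PSSM profiles
# and phosphosite annotation tables.

#' Construct a PSSM profile object
#'
#' A `pssm_profile` holds the per-protein evolutionary profile used as the
#' sole feature source for phosphosite classification: an L x 20 integer
#' matrix of position-specific log-odds scores (one row per sequence
#' position, columns in a fixed amino-acid order) together with the protein
#' sequence itself.
#'
#' @param protein_id character scalar identifier.
#' @param sequence amino-acid string of length L (uppercase one-letter
#'   codes; `X` allowed for unknown residues).
#' @param scores L x 20 numeric matrix of log-odds scores; column names, if
#'   present, must be the 20 amino-acid letters.
#' @param aa_order character vector of 20 amino-acid letters giving the
#'   column order of `scores`.  Defaults to the canonical blastpgp order
#'   `A R N D C Q E G H I L K M F P S T W Y V`.
#' @return An object of class `pssm_profile` with fields `protein_id`,
#'   `sequence` and `scores` (columns reordered to canonical order).
#' @examples
#' p <- pssm_profile("toy", "MKS", matrix(0L, 3, 20))
#' p$sequence
#' @export
pssm_profile <- function(protein_id, sequence, scores,
                         aa_order = AA_ORDER) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (!is.matrix(scores) || ncol(scores) != 20L) {
    stop_data("'scores' must be a matrix with 20 columns")
  }
  if (nrow(scores) != L) {
    stop_data("profile '", protein_id, "': ", nrow(scores),
              " score rows for a sequence of length ", L)
  }
  if (!all(strsplit(sequence, "")[[1]] %in% c(LETTERS))) {
    stop_data("profile '", protein_id,
              "': sequence must be uppercase one-letter codes")
  }
  if (length(aa_order) != 20L || anyDuplicated(aa_order)) {
    stop_config("'aa_order' must name 20 distinct amino acids")
  }
  # store in canonical column order so downstream features are comparable
  # across input dialects
  if (!identical(aa_order, AA_ORDER)) {
    scores <- scores[, match(AA_ORDER, aa_order), drop = FALSE]
  }
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(list(protein_id = protein_id, sequence = sequence,
                 scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d residues x 20 scores\n",
              x$protein_id, nchar(x$sequence)))
  invisible(x)
}

#' Parse a blastpgp ASCII PSSM file
#'
#' Reads the text matrix written by PSI-BLAST's `blastpgp -Q` option.  Only
#' the first block of 20 integer columns (the position-specific log-odds
#' scores) is used; the weighted-percentage block and the trailing
#' per-position statistics are ignored.  The protein sequence is
#' reconstructed from the residue-letter column.  The amino-acid column
#' order is taken from the file's own header line when present, falling
#' back to the canonical order otherwise.
#'
#' @param path path to the PSSM file, or `NULL` when `text` is given.
#' @param text optional character vector of lines (alternative to `path`).
#' @param protein_id identifier for the returned profile; defaults to the
#'   file name without its extension.
#' @return A [pssm_profile()].
#' @export
parse_pssm <- function(path = NULL, text = NULL, protein_id = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop_config("one of 'path' or 'text' is required")
    if (!file.exists(path)) stop_data("PSSM file not found: ", path)
    text <- readLines(path, warn = FALSE)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  protein_id <- protein_id %||% "profile"
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    stop_data("empty PSSM file")
  }

  # header: a line of single amino-acid letters (20 for one block, 40 for
  # the log-odds + percentage layout)
  aa_order <- AA_ORDER
  data_start <- 1L
  for (ln in seq_along(text)) {
    toks <- strsplit(trimws(text[ln]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(nchar(toks) == 1L) &&
        all(toks %in% LETTERS)) {
      aa_order <- toks[seq_len(20L)]
      data_start <- ln + 1L
      break
    }
  }

  row_re <- "^\\s*([0-9]+)\\s+([A-Za-z])\\s+(-?[0-9].*)$"
  rows <- list()
  letters_seq <- character()
  for (ln in seq(data_start, length(text))) {
    line <- text[ln]
    if (!grepl(row_re, line)) next
    pos <- as.integer(sub(row_re, "\\1", line))
    res <- toupper(sub(row_re, "\\2", line))
    rest <- sub(row_re, "\\3", line)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rest), "\\s+")[[1]]))
    # first 20 fields must be parseable integers (the log-odds block)
    if (length(vals) < 20L || anyNA(vals[1:20]) ||
        any(vals[1:20] != round(vals[1:20]))) {
      stop_data("malformed PSSM row at line ", ln,
                ": expected 20 integer log-odds columns")
    }
    rows[[length(rows) + 1L]] <- vals[1:20]
    letters_seq <- c(letters_seq, res)
    if (pos != length(rows)) {
      stop_data("malformed PSSM row at line ", ln,
                ": position index ", pos, " out of order")
    }
  }
  if (length(rows) == 0L) stop_data("no PSSM data rows found")
  scores <- do.call(rbind, rows)
  pssm_profile(protein_id, paste(letters_seq, collapse = ""), scores,
               aa_order = aa_order)
}

#' Write a PSSM profile in the blastpgp ASCII dialect
#'
#' Emits a file that [parse_pssm()] (and other tools expecting blastpgp
#' `-Q` output) can read back.  The weighted-percentage block is written as
#' zeros and the per-position statistics as `0.00`, since only the log-odds
#' block carries information in this package.
#'
#' @param profile a [pssm_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- nchar(profile$sequence)
  if (L == 0L) stop_data("refusing to write an empty profile")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_data("cannot open '", path,
                                                "' for writing"))
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts")
  ), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", AA_ORDER), collapse = ""), " ",
                    paste(sprintf("%3s", AA_ORDER), collapse = "")), con)
  res <- strsplit(profile$sequence, "")[[1]]
  for (i in seq_len(L)) {
    writeLines(sprintf("%5d %s %s  %s  0.00 0.00", i, res[i],
                       paste(sprintf("%3d", as.integer(profile$scores[i, ])),
                             collapse = ""),
                       paste(sprintf("%3d", rep(0L, 20L)), collapse = "")),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176"), con)
  invisible(path)
}

#' Read protein sequences from FASTA or raw single-sequence text
#'
#' FASTA files (possibly multi-record) are read with Biostrings; a file
#' with no `>` header is treated as one raw sequence (whitespace stripped),
#' named after the file.
#'
#' @param path input file.
#' @return Named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop_data("sequence file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    set <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    raw <- paste(readLines(path, warn = FALSE), collapse = "")
    seqs <- toupper(gsub("\\s", "", raw))
    names(seqs) <- sub("\\.[^.]*$", "", basename(path))
  }
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a phosphosite annotation table
#'
#' Reads a TSV with columns `protein_id`, `position`, `residue` (1-based
#' positions, Phospho.ELM convention).  Each row becomes one positive site
#' annotation.  Rows whose residue is not S, T or Y — e.g. the occasional
#' histidine phosphosite — are dropped, with the count reported via
#' [message()] and recorded in the `dropped` attribute.
#'
#' @param path TSV file path.
#' @param profiles optional named list of [pssm_profile()] objects; when
#'   given, each annotation is validated against the protein sequence
#'   (position within range and residue letter matching).
#' @return A data.frame with columns `protein_id`, `position`, `residue`,
#'   `label` (all `"positive"`), plus attribute `dropped` (number of
#'   non-S/T/Y rows removed).
#' @export
read_annotations <- function(path, profiles = NULL) {
  if (!file.exists(path)) stop_data("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  required <- c("protein_id", "position", "residue")
  if (!all(required %in% names(tab))) {
    stop_data("annotation table must have columns: ",
              paste(required, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    out <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), label = character(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1L]
    stop_data("annotation row ", bad,
              ": position must be a positive 1-based integer")
  }
  res <- toupper(tab$residue)
  keep <- res %in% PHOSPHO_RESIDUES
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " annotation(s) on non-S/T/Y residues dropped")
  }
  out <- data.frame(protein_id = tab$protein_id[keep],
                    position = pos[keep], residue = res[keep],
                    label = "positive", stringsAsFactors = FALSE)
  if (!is.null(profiles)) {
    for (i in seq_len(nrow(out))) {
      pr <- profiles[[out$protein_id[i]]]
      if (is.null(pr)) next
      L <- nchar(pr$sequence)
      if (out$position[i] > L) {
        stop_data("annotation row ", i, " (", out$protein_id[i], "): ",
                  "position ", out$position[i],
                  " outside protein of length ", L)
      }
      actual <- substr(pr$sequence, out$position[i], out$position[i])
      if (actual != out$residue[i]) {
        stop_data("annotation row ", i, " (", out$protein_id[i], "): ",
                  "residue ", out$residue[i], " does not match sequence (",
                  actual, ") at position ", out$position[i])
      }
    }
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write a phosphosite annotation table
#' @param annotations data.frame with `protein_id`, `position`, `residue`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("protein_id", "position", "residue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Print the external PSI-BLAST command used to build a real profile
#'
#' Profiles for real proteins come from PSI-BLAST against NCBI nr, an
#' external step this package documents but does not run.  This helper
#' renders the exact command; it never executes anything unless
#' `execute = TRUE` is set explicitly (and `blastpgp` is on the PATH).
#'
#' @param seq_file protein sequence file (raw or FASTA).
#' @param out_file path for the ASCII PSSM (`-Q` output).
#' @param db target database (default `"nr"`).
#' @param iterations PSI-BLAST iterations (`-j`, default 3).
#' @param evalue inclusion E-value cutoff (`-h`, default 0.001).
#' @param execute run the command via [system()] (default `FALSE`).
#' @return The command string, invisibly when printed.
#' @export
blastpgp_command <- function(seq_file, out_file, db = "nr",
                             iterations = 3, evalue = 0.001,
                             execute = FALSE) {
  cmd <- sprintf('blastpgp -d %s -i "%s" -j %d -h %s -Q "%s"',
                 db, seq_file, as.integer(iterations),
                 format(evalue, scientific = FALSE), out_file)
  if (isTRUE(execute)) {
    status <- system(cmd)
    if (status != 0L) stop_data("blastpgp exited with status ", status)
  }
  cmd
}
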