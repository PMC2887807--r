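# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# random profile with integer scores in the blastpgp-typical range
rand_profile <- function(L, id = "P1", seed = NULL) {
  gen <- function() {
    seqs <- sample(names(pssmphos:::AA_FREQ), L, replace = TRUE,
                   prob = pssmphos:::AA_FREQ)
    pssm_profile(id, paste(seqs, collapse = ""),
                 matrix(sample(-9:9, L * 20, replace = TRUE), L, 20))
  }
  if (is.null(seed)) gen() else pssmphos:::with_local_seed(seed, gen())
}

# profile whose score rows are distinct, predictable integers: row i is
# (i-1)*20 + 1:20 — handy for window-flattening oracles
counting_profile <- function(L, id = "P1", sequence = NULL) {
  if (is.null(sequence)) sequence <- paste(rep("S", L), collapse = "")
  pssm_profile(id, sequence,
               matrix(seq_len(L * 20), nrow = L, ncol = 20, byrow = TRUE))
}

# brute-force labeling oracle: independent double loop over (site,
# annotation) pairs
oracle_labels <- function(sequence, positives, distance = 50) {
  chars <- strsplit(sequence, "")[[1]]
  sty <- which(chars %in% c("S", "T", "Y"))
  vapply(sty, function(p) {
    if (p %in% positives) return("positive")
    for (a in positives) {
      if (abs(p - a) <= distance) return("excluded")
    }
    "negative"
  }, character(1))
}

# feature-space generator: background integer noise, with the first
# `signal_cols` columns of positives shifted by delta (bypasses sequence
# geometry for classifier-only tests)
make_feature_instances <- function(n_pos, n_neg, W = 9L, delta = 0,
                                   signal_rows = 7L, seed = 1L,
                                   residue = "S") {
  k <- 20L * W
  pssmphos:::with_local_seed(seed, {
    X <- matrix(sample(-5:5, (n_pos + n_neg) * k, replace = TRUE),
                n_pos + n_neg, k)
    if (delta > 0 && n_pos > 0) {
      half <- (W - 1L) %/% 2L
      rows <- (half + 1L - (signal_rows - 1L) %/% 2L):
              (half + 1L + (signal_rows - 1L) %/% 2L)
      cols <- as.vector(outer(1:20, (rows - 1L) * 20L, `+`))
      X[seq_len(n_pos), cols] <- X[seq_len(n_pos), cols] + delta
    }
    y <- c(rep(1, n_pos), rep(-1, n_neg))
    prov <- data.frame(protein_id = sprintf("P%05d", seq_along(y)),
                       position = seq_along(y),
                       residue = residue, stringsAsFactors = FALSE)
    instance_set(X, y, prov, residue, W)
  })
}

# minimal blastpgp-style PSSM text written by hand (log-odds block only
# plus a fake percentage block), for parser tests independent of
# write_pssm()
hand_pssm_lines <- function(scores, residues) {
  stopifnot(nrow(scores) == length(residues))
  header <- paste0("           ",
                   paste(sprintf("%3s", pssmphos:::AA_ORDER), collapse = ""),
                   " ",
                   paste(sprintf("%3s", pssmphos:::AA_ORDER), collapse = ""))
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    sprintf("%5d %s %s  %s  0.31 0.09", i, residues[i],
            paste(sprintf("%3d", scores[i, ]), collapse = ""),
            paste(sprintf("%3d", sample(0:40, 20, replace = TRUE)),
                  collapse = ""))
  }, character(1))
  c("", "Last position-specific scoring matrix computed", header, rows,
    "", "                      K         Lambda")
}

run_phos_cli <- function(...) {
  phos_cli(c(...), exit = FALSE)
}
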