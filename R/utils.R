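# Internal helpers shared across modules.

# canonical blastpgp column order
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

PHOSPHO_RESIDUES <- c("S", "T", "Y")

#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All seeded operations in the package funnel through here so
# that determinism contracts hold regardless of surrounding code.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# classed conditions so the CLI can map error families to exit codes
#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pssmphos_config_error",
                                             "pssmphos_error")))
}

#' @noRd
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pssmphos_data_error",
                                             "pssmphos_error")))
}

#' @noRd
stop_model <- function(...) {
  stop(errorCondition(paste0(...), class = c("pssmphos_model_error",
                                             "pssmphos_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
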