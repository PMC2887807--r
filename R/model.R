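# Per-residue, per-window RBF support vector classifiers.

#' Model configuration
#'
#' The classifier configuration used throughout: an RBF-kernel C-SVC with
#' `C = 1` and `gamma = 1/k`, where `k = 20 * W` is the number of features
#' per instance.  One model is trained per (residue, window size) pair.
#'
#' @param residue `"S"`, `"T"` or `"Y"`.
#' @param W odd window size.
#' @param C box constraint (default 1).
#' @param gamma RBF width; defaults to `1 / (20 * W)`.
#' @param scale min-max scale features to `[-1, 1]` per feature before
#'   training (default `TRUE`, the standard libsvm preprocessing).  With
#'   raw integer log-odds scores and `gamma = 1/k`, squared distances
#'   between window vectors are of order `2 * Var * k`, the kernel
#'   saturates at `exp(-20)` or below and the classifier degenerates to a
#'   majority vote; scaling restores a well-conditioned kernel.  Set
#'   `scale = FALSE` to feed raw scores.
#' @return Object of class `model_config`.
#' @export
model_config <- function(residue, W, C = 1, gamma = NULL, scale = TRUE) {
  residue <- match.arg(residue, PHOSPHO_RESIDUES)
  W <- as.integer(W)
  if (is.na(W) || W < 1L || W %% 2L == 0L) {
    stop_config("W must be a positive odd integer")
  }
  k <- 20L * W
  gamma <- gamma %||% (1 / k)
  if (C <= 0 || gamma <= 0) stop_config("C and gamma must be positive")
  structure(list(residue = residue, W = W, k = k, C = C, gamma = gamma,
                 kernel = "rbf", scale = isTRUE(scale)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> residue %s, W=%d (k=%d), RBF C=%g gamma=%g%s\n",
              x$residue, x$W, x$k, x$C, x$gamma,
              if (x$scale) ", scaled" else ""))
  invisible(x)
}

#' Train an RBF-SVM on an instance set
#'
#' Fits a binary C-SVC by sequential minimal optimization.  The resulting
#' model emits hard labels only (+1 phosphorylated, -1 not) — it is a
#' discrete classifier with no probability output.  Training is
#' deterministic for fixed inputs; `seed` is recorded in the bundle
#' metadata for provenance.
#'
#' @param instances an [instance_set()] containing both classes with
#'   feature dimension `20 * config$W`.
#' @param config a [model_config()].
#' @param seed integer, recorded in metadata.
#' @return Object of class `model_bundle`.
#' @export
train_model <- function(instances, config, seed = 1L) {
  stopifnot(inherits(instances, "instance_set"),
            inherits(config, "model_config"))
  X <- instances$features
  y <- instances$target
  if (ncol(X) != config$k) {
    stop_model("instance dimension ", ncol(X),
               " does not match config k = ", config$k)
  }
  if (length(unique(y)) < 2L) {
    stop_model("training data contains a single class")
  }
  scaling <- NULL
  if (config$scale) {
    lo <- apply(X, 2L, min)
    hi <- apply(X, 2L, max)
    rng <- pmax(hi - lo, .Machine$double.eps)
    scaling <- list(lo = lo, rng = rng)
    X <- sweep(sweep(X, 2L, lo), 2L, rng, "/") * 2 - 1
  }
  fit <- .smo_train(X, y, C = config$C, gamma = config$gamma)
  if (!isTRUE(fit$converged)) {
    warning("SMO reached its iteration cap before meeting the tolerance")
  }
  structure(list(
    config = config,
    fit = fit[c("sv", "coef", "rho")],
    scaling = scaling,
    meta = list(n_positive = sum(y > 0), n_negative = sum(y < 0),
                n_sv = nrow(fit$sv), iterations = fit$iterations,
                seed = as.integer(seed),
                trained_at = format(Sys.time(), tz = "UTC"),
                version = as.character(utils::packageVersion("pssmphos")))),
    class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> residue %s, W=%d: %d SVs from %d+/%d- instances\n",
    x$config$residue, x$config$W, x$meta$n_sv, x$meta$n_positive,
    x$meta$n_negative))
  invisible(x)
}

#' Predict hard labels for instances
#'
#' @param object a `model_bundle` from [train_model()] or [load_bundle()].
#' @param instances an [instance_set()] or bare numeric feature matrix of
#'   matching dimension.
#' @param decision_values also return the raw decision values as an
#'   attribute (default `FALSE`).
#' @param ... unused.
#' @return Numeric vector of labels in {+1, -1}, one per instance, in
#'   input order.
#' @export
predict.model_bundle <- function(object, instances,
                                 decision_values = FALSE, ...) {
  X <- if (inherits(instances, "instance_set")) instances$features
       else as.matrix(instances)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != object$config$k) {
    stop_model("instance dimension ", ncol(X),
               " does not match model k = ", object$config$k)
  }
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2L, object$scaling$lo), 2L,
               object$scaling$rng, "/") * 2 - 1
  }
  dv <- .svm_decision_values(object$fit$sv, object$fit$coef,
                             object$fit$rho, object$config$gamma, X)
  labels <- ifelse(dv > 0, 1, -1)
  if (decision_values) attr(labels, "decision_values") <- dv
  labels
}

#' Save a model bundle to disk
#'
#' Bundles are written as self-describing JSON: residue type, window size
#' and hyperparameters are embedded so that a mismatched bundle can be
#' refused at load time.
#'
#' @param bundle a `model_bundle`.
#' @param path output file (conventionally `<residue>_W<W>.svm.json`).
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  payload <- list(
    format = "pssmphos_svm_bundle",
    format_version = 1L,
    config = unclass(bundle$config),
    meta = bundle$meta,
    scaling = bundle$scaling,
    fit = list(sv = bundle$fit$sv, coef = bundle$fit$coef,
               rho = bundle$fit$rho))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model bundle, optionally enforcing residue/window identity
#'
#' @param path file written by [save_bundle()].
#' @param residue if given, refuse a bundle trained for another residue.
#' @param W if given, refuse a bundle trained with another window size.
#' @return A `model_bundle`.
#' @export
load_bundle <- function(path, residue = NULL, W = NULL) {
  if (!file.exists(path)) stop_model("model bundle not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "pssmphos_svm_bundle")) {
    stop_model("'", path, "' is not a model bundle")
  }
  if (!identical(as.integer(payload$format_version), 1L)) {
    stop_model("unsupported bundle format version: ",
               payload$format_version)
  }
  cfg <- payload$config
  if (!is.null(residue) && !identical(cfg$residue, residue)) {
    stop_model("bundle is for residue ", cfg$residue, ", requested ",
               residue)
  }
  if (!is.null(W) && !identical(as.integer(cfg$W), as.integer(W))) {
    stop_model("bundle is for W=", cfg$W, ", requested W=", W)
  }
  config <- model_config(cfg$residue, cfg$W, C = cfg$C, gamma = cfg$gamma,
                         scale = isTRUE(cfg$scale))
  sv <- payload$fit$sv
  if (is.null(dim(sv))) sv <- matrix(sv, nrow = 1L)
  if (ncol(sv) != config$k) {
    stop_model("bundle support vectors have dimension ", ncol(sv),
               ", expected ", config$k)
  }
  scaling <- payload$scaling
  if (!is.null(scaling) && length(scaling)) {
    scaling <- list(lo = as.numeric(scaling$lo),
                    rng = as.numeric(scaling$rng))
  } else {
    scaling <- NULL
  }
  structure(list(config = config,
                 fit = list(sv = sv, coef = as.numeric(payload$fit$coef),
                            rho = as.numeric(payload$fit$rho)),
                 scaling = scaling,
                 meta = payload$meta),
            class = "model_bundle")
}

#' Default bundle file name for a (residue, W) pair
#' @param residue `"S"`, `"T"` or `"Y"`.
#' @param W window size.
#' @return File name such as `"S_W11.svm.json"`.
#' @export
bundle_filename <- function(residue, W) {
  sprintf("%s_W%d.svm.json", residue, as.integer(W))
}
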