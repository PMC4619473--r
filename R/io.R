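#' Read a labeled feature table
#'
#' Reads a delimited text file with a header row, numeric feature columns
#' and an integer label column. Labels are remapped to contiguous
#' `0..M-1` (sorted by original value) and the map recorded; row order is
#' preserved. Missing or non-numeric cells and single-class tables are
#' rejected with messages naming the offending location.
#'
#' @param path File path (CSV by default).
#' @param label_column Name of the label column.
#' @param sep Field separator.
#' @return List with `X` (`n x D` matrix), `y` (0-based labels),
#'   `label_map` (named vector original -> 0-based), `M`, `feature_names`.
#' @export
read_labeled_table <- function(path, label_column = "label", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
  }
  feats <- setdiff(names(df), label_column)
  if (!length(feats)) stop("no feature columns", call. = FALSE)
  for (cn in names(df)) {
    bad <- which(is.na(df[[cn]]))
    if (length(bad)) {
      stop(sprintf("missing/non-numeric value at row %d, column '%s'", bad[1L], cn),
           call. = FALSE)
    }
    if (!is.numeric(df[[cn]])) {
      stop(sprintf("column '%s' is not numeric", cn), call. = FALSE)
    }
  }
  raw <- df[[label_column]]
  if (any(raw != floor(raw))) stop("labels must be integers", call. = FALSE)
  lev <- sort(unique(raw))
  if (length(lev) < 2L) stop("need at least two classes", call. = FALSE)
  y <- match(raw, lev) - 1L
  X <- as.matrix(df[feats])
  list(X = X, y = y, label_map = stats::setNames(seq_along(lev) - 1L, lev),
       M = length(lev), feature_names = feats)
}

#' Write a risk report (or any result list) as JSON
#'
#' Serializes with full numeric precision so that reports round-trip
#' losslessly; matrices become nested arrays.
#'
#' @param report A `"risk_report"` or plain list.
#' @param path Output path.
#' @return Invisible `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(prep_json(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

prep_json <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), prep_json))
  if (is.matrix(x)) return(apply(unclass(x), 1L, identity, simplify = FALSE))
  if (is.array(x)) return(as.numeric(x))
  x
}

#' Read a run configuration (YAML or JSON)
#'
#' Parses a model/estimation configuration and builds the corresponding
#' posterior objects. The schema has three blocks: `model` (either
#' `type: discrete` with `b`, `M`, `alpha`, or a Gaussian block with
#' `structure`, `coupling`, `D`, `M`, `nu`, `m`, and `kappa`/`S` or
#' `Sigma`; scalar `S`/`Sigma` entries mean `scalar * I_D`), `class_prob`
#' (`mode` plus `c` or `alpha`), and `loss` (nested list, optional; zero-one
#' by default). Propriety violations are reported with the offending
#' hyperparameter named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `prior` (posterior object), `class_prior`, `loss`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$model)) stop("config must have a `model` block", call. = FALSE)
  m <- cfg$model
  prior <- if (identical(m$type, "discrete")) {
    alpha <- m$alpha
    if (length(alpha) == 1L) alpha <- matrix(alpha, m$b, m$M)
    discrete_prior(as.matrix(alpha))
  } else {
    mloc <- m$m
    if (is.list(mloc)) mloc <- do.call(cbind, mloc)
    Sarg <- m$S
    if (is.list(Sarg) && !is.matrix(Sarg)) {
      Sarg <- lapply(Sarg, function(s) if (length(s) == 1L) diag(as.numeric(s), m$D) else as.matrix(s))
    }
    gaussian_prior(D = m$D, M = m$M, structure = m$structure %||% "arbitrary",
                   coupling = m$coupling %||% "independent",
                   nu = m$nu, m = mloc, kappa = m$kappa, S = Sarg,
                   Sigma = m$Sigma)
  }
  cp <- cfg$class_prob %||% list(mode = "known", c = rep(1 / prior$M, prior$M))
  class_prior_obj <- class_prior(cp$mode, c = cp$c,
                                 alpha = cp$alpha)
  loss <- if (is.null(cfg$loss)) zero_one_loss(prior$M) else {
    loss_matrix(do.call(rbind, lapply(cfg$loss, as.numeric)))
  }
  list(prior = prior, class_prior = class_prior_obj, loss = loss, raw = cfg)
}
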