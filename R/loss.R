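#' Loss matrices
#'
#' A loss matrix holds the penalty `lambda(i, y)` incurred when predicting
#' class `i` (row) while the truth is class `y` (column). `zero_one_loss(M)`
#' is the special case `lambda(i, y) = 1 - delta_ij`, under which expected
#' risk reduces to the probability of misclassification.
#'
#' @param lambda Numeric `M x M` matrix with finite nonnegative entries.
#' @return An object of class `"loss_matrix"` (a validated matrix).
#' @export
loss_matrix <- function(lambda) {
  lambda <- as.matrix(lambda)
  if (nrow(lambda) != ncol(lambda) || nrow(lambda) < 2L) {
    stop("loss matrix must be square with M >= 2", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("loss entries must be finite and >= 0", call. = FALSE)
  }
  storage.mode(lambda) <- "double"
  structure(lambda, class = c("loss_matrix", "matrix"))
}

#' @rdname loss_matrix
#' @param M Number of classes.
#' @export
zero_one_loss <- function(M) {
  loss_matrix(1 - diag(M))
}

as_loss <- function(loss, M) {
  if (inherits(loss, "loss_matrix")) {
    if (nrow(loss) != M) stop("loss matrix does not match M classes", call. = FALSE)
    return(loss)
  }
  if (is.null(loss)) return(zero_one_loss(M))
  lm <- loss_matrix(loss)
  if (nrow(lm) != M) stop("loss matrix does not match M classes", call. = FALSE)
  lm
}
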