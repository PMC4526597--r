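# Firth-penalized logistic regression (Jeffreys-prior bias reduction).
# Used for per-subject stay models, where perfect stay/switch patterns
# (separation) would send ordinary ML estimates to infinity; the penalty
# keeps the per-subject indices finite.

#' Firth-penalized logistic regression
#'
#' Newton-Raphson on the Firth-modified score
#' \eqn{U^*_j = \sum_i (y_i - p_i + h_i(1/2 - p_i)) x_{ij}}, where
#' \eqn{h_i} are the leverages of the working weighted design. Standard
#' errors come from the inverse Fisher information at the solution.
#'
#' @param x model matrix (n x p, including the intercept column).
#' @param y binary response (0/1).
#' @param max_iter,tol Newton iteration controls.
#' @return List with `coefficients`, `se`, `vcov`, `converged`, `iter`.
#' @export
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  p <- ncol(x)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(x %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    wt <- mu * (1 - mu)
    xw <- x * sqrt(wt)
    info <- crossprod(xw)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) stop("singular information matrix in Firth fit",
                                call. = FALSE)
    h <- rowSums((xw %*% info_inv) * xw)
    score <- drop(crossprod(x, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% score)
    # dampen oversized steps for stability near separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(x %*% beta), -30), 30)
  wt <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vcov <- solve(crossprod(x * sqrt(wt)))
  list(coefficients = stats::setNames(beta, colnames(x)),
       se = stats::setNames(sqrt(diag(vcov)), colnames(x)),
       vcov = vcov, converged = converged, iter = it)
}
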