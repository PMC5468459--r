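# The Jones-Taylor-Thornton (1992) empirical amino-acid substitution
# model.  The accepted-point-mutation exchangeability counts and the
# equilibrium frequencies below are the published JTT tables (the same
# values distributed with every phylogenetics tool, e.g. PAML's
# jones.dat); amino acids in the conventional
# A R N D C Q E G H I L K M F P S T W Y V order.

.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# lower triangle, column-major (col 1 = A vs R..V, col 2 = R vs N..V, ...)
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475,
  9, 11, 298,
  45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17,
  528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70, 16,
  10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31,
  9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62,
  323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20,
  119, 26, 12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45,
  23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11,
  229, 21, 479, 89, 10, 40, 245, 9, 32, 961,
  14, 388, 248, 102, 59, 25, 52, 24, 180,
  65, 4, 21, 47, 103, 10, 8, 14,
  43, 16, 29, 226, 24, 18, 323,
  17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23,
  477, 35, 63, 38,
  12, 21, 112,
  71, 25,
  16)

.JTT_FREQ <- c(0.076748, 0.051691, 0.042645, 0.051544, 0.019803,
               0.040752, 0.061830, 0.073152, 0.022944, 0.053761,
               0.091904, 0.058676, 0.023826, 0.040126, 0.050901,
               0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' The JTT amino-acid substitution model
#'
#' Builds the Jones-Taylor-Thornton (1992) empirical model as a
#' continuous-time reversible Markov generator.  The rate matrix
#' \eqn{Q} is assembled from the published exchangeabilities \eqn{s_{ij}}
#' and equilibrium frequencies \eqn{\pi_j} as
#' \eqn{Q_{ij} = s_{ij}\pi_j} (\eqn{i \neq j}), rows summing to zero,
#' and is normalized so that \eqn{-\sum_i \pi_i Q_{ii} = 1}: one unit of
#' evolutionary time equals one expected substitution per site, so ML
#' distances are in expected substitutions/site.  The spectral
#' decomposition of the symmetrized generator is cached so transition
#' matrices \eqn{P(t) = e^{Qt}} are cheap for many values of \eqn{t}.
#'
#' @return An object of class `substitution_model` with fields `name`,
#'   `frequencies` (named 20-vector summing to 1), `exchangeabilities`
#'   (symmetric 20x20), `rate_matrix` (normalized generator `Q`), and
#'   cached eigensystem components.
#' @examples
#' m <- jtt_model()
#' range(rowSums(m$rate_matrix))  # rows of Q sum to 0
#' @export
jtt_model <- function() {
  s <- matrix(0, 20, 20, dimnames = list(.AA_ORDER, .AA_ORDER))
  s[lower.tri(s)] <- .JTT_EXCH
  s <- s + t(s)
  pi <- .JTT_FREQ / sum(.JTT_FREQ)
  names(pi) <- .AA_ORDER
  Q <- s * rep(pi, each = 20)           # Q[i, j] = s[i, j] * pi[j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))         # 1 expected substitution / unit t
  # reversibility => D^{1/2} Q D^{-1/2} is symmetric; eigendecompose once
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2                   # clean numeric asymmetry
  e <- eigen(A, symmetric = TRUE)
  structure(list(
    name = "JTT",
    frequencies = pi,
    exchangeabilities = s,
    rate_matrix = Q,
    eigenvalues = e$values,
    right = e$vectors * rep(1 / sq, times = 1),  # D^{-1/2} U (row scale)
    left = t(e$vectors * sq)                     # U' D^{1/2}
  ), class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("<substitution_model %s> 20 states, generator normalized %s\n",
              x$name, "to 1 expected substitution/site/unit time"))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [jtt_model()] object.
#' @param t non-negative evolutionary time (expected substitutions/site).
#' @return 20x20 stochastic matrix, rows = ancestral state.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  P <- model$right %*% (exp(model$eigenvalues * t) * model$left)
  # clamp eigen-roundoff; rows renormalized to machine precision
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$rate_matrix)
  P
}

# internal: collapse two equal-length degapped residue vectors to a 20x20
# count matrix over the model's alphabet (other symbols dropped)
.pair_counts <- function(model, a, b) {
  states <- rownames(model$rate_matrix)
  ia <- match(a, states)
  ib <- match(b, states)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) return(NULL)
  n <- matrix(0, 20, 20)
  tab <- table(factor(ia[keep], levels = 1:20),
               factor(ib[keep], levels = 1:20))
  n[] <- tab
  n
}

# internal: log-likelihood of a pair-count matrix at time(s) t;
# vectorized over t via the cached spectral decomposition
.pair_loglik <- function(model, counts, t) {
  idx <- which(counts > 0, arr.ind = TRUE)
  n <- counts[idx]
  lpi <- log(model$frequencies[idx[, 1]])
  # C[k, m] = right[i_k, m] * left[m, j_k] so P_ij(t) = C %*% exp(lambda t)
  C <- model$right[idx[, 1], , drop = FALSE] *
    t(model$left[, idx[, 2], drop = FALSE])
  E <- exp(outer(model$eigenvalues, t))        # 20 x length(t)
  P <- C %*% E                                  # npairs x length(t)
  P[P < 1e-300] <- 1e-300
  colSums(n * (lpi + log(P)))
}
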