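# Maximum-likelihood pairwise distances under the JTT model, per-domain
# distance summaries, and the rank test used to compare domains.

#' Maximum-likelihood distance under an empirical substitution model
#'
#' Estimates the evolutionary time \eqn{t} (expected substitutions per
#' site, given the normalized generator) maximizing the pairwise
#' log-likelihood
#' \deqn{\ell(t) = \sum_{\mathrm{columns}} \log(\pi_x P_{xy}(t)),}
#' over the alignment columns with a model residue in both rows (gap and
#' ambiguous columns are excluded pairwise).  \eqn{t} is searched on
#' \eqn{[10^{-6}, 10]} by Brent's bracketed optimizer to absolute
#' tolerance \eqn{10^{-6}}.  Identical sequences give exactly 0; pairs
#' whose optimum is pinned at the upper bound are reported as 10 with a
#' `saturated` attribute.
#'
#' @param aln a protein `pairwise_alignment`.
#' @param model a [jtt_model()] (or compatible) object.
#' @return numeric distance with attribute `saturated` (logical).
#' @examples
#' m <- jtt_model()
#' a <- bio_seq("x", strrep("ARNDCQEGHILKMFPSTWYV", 5), "protein")
#' jtt_ml_distance(global_align(a, a), m)  # 0
#' @export
jtt_ml_distance <- function(aln, model = jtt_model()) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(model, "substitution_model"))
  cols <- .aln_columns(aln)
  counts <- .pair_counts(model, cols[1, ], cols[2, ])
  if (is.null(counts))
    .fail("alignment of '%s' and '%s' has no comparable columns",
          aln$id_a, aln$id_b)
  if (sum(counts) == sum(diag(counts)))
    return(structure(0, saturated = FALSE))
  opt <- stats::optimize(function(t) .pair_loglik(model, counts, t),
                         interval = c(1e-6, 10), maximum = TRUE,
                         tol = 1e-6)
  t_hat <- opt$maximum
  if (t_hat > 10 - 1e-4 &&
      .pair_loglik(model, counts, 10) >= opt$objective - 1e-9)
    return(structure(10, saturated = TRUE))
  structure(unname(t_hat), saturated = FALSE)
}

#' Pairwise ML distance summary for one domain
#'
#' Globally aligns every pair of domain sequences, computes the JTT ML
#' distance for each, and assembles a symmetric distance matrix together
#' with the mean of the \eqn{n(n-1)/2} off-diagonal values (the statistic
#' compared between hemocyanin domains D1/D2/D3).
#'
#' @param domain_seqs list of \eqn{\ge 2} protein [bio_seq] objects, all
#'   from one domain.
#' @param model a [jtt_model()] object.
#' @param scoring alignment scoring passed to [global_align()].
#' @param domain_name label stored on the summary.
#' @return An object of class `distance_summary`: `domain_name`, `taxa`,
#'   `matrix` (symmetric, zero diagonal), `pairs` (data.frame with one
#'   row per pair), and `mean`.
#' @export
domain_distance_summary <- function(domain_seqs, model = jtt_model(),
                                    scoring = NULL, domain_name = "") {
  stopifnot(length(domain_seqs) >= 2L)
  taxa <- vapply(domain_seqs, `[[`, "", "id")
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  pairs <- utils::combn(n, 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dist_ij <- tryCatch({
      aln <- global_align(domain_seqs[[i]], domain_seqs[[j]], scoring)
      jtt_ml_distance(aln, model)
    }, error = function(e)
      .fail("pair %s / %s: %s", taxa[i], taxa[j], conditionMessage(e)))
    d[i, j] <- d[j, i] <- as.numeric(dist_ij)
    rows[[k]] <- data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                            distance = as.numeric(dist_ij),
                            saturated = isTRUE(attr(dist_ij, "saturated")))
  }
  pairs_df <- do.call(rbind, rows)
  structure(list(domain_name = domain_name, taxa = taxa, matrix = d,
                 pairs = pairs_df, mean = mean(pairs_df$distance)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, digits = 6, ...) {
  cat(sprintf("<distance_summary%s> %d taxa, %d pairs, mean %s\n",
              if (nzchar(x$domain_name)) paste0(" ", x$domain_name) else "",
              length(x$taxa), nrow(x$pairs),
              format(x$mean, digits = digits)))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with midranks for ties.  The p-value is exact
#' (enumeration over labelings) for small tie-free samples and otherwise
#' uses the normal approximation with tie and continuity corrections, as
#' provided by [stats::wilcox.test()].  If every value in both samples is
#' identical the comparison is degenerate and `p = 1` is returned with a
#' flag.
#'
#' @param a,b non-empty numeric samples.
#' @param alternative currently `"two.sided"`.
#' @return list with `U`, `p.value`, `degenerate`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value  # exact 0.1
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  alternative <- match.arg(alternative, "two.sided")
  stopifnot(length(a) > 0L, length(b) > 0L,
            is.numeric(a), is.numeric(b))
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p.value = 1,
                degenerate = TRUE, method = "degenerate (all values equal)"))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       degenerate = FALSE, method = wt$method)
}

#' Pairwise domain-divergence comparisons
#'
#' Applies [mann_whitney_u()] to every pair of distance summaries,
#' treating each domain's \eqn{n(n-1)/2} pairwise distances as a sample
#' (the convention used when comparing hemocyanin domain divergences;
#' the pairwise values are not independent, so read the p-values as
#' descriptive).
#'
#' @param summaries named list of `distance_summary` objects.
#' @return data.frame with columns `domain_a`, `domain_b`, `mean_a`,
#'   `mean_b`, `U`, `p.value`, `p.printed`.
#' @export
domain_divergence_tests <- function(summaries) {
  stopifnot(length(summaries) >= 2L)
  nm <- vapply(summaries, `[[`, "", "domain_name")
  nm[!nzchar(nm)] <- names(summaries)[!nzchar(nm)]
  idx <- utils::combn(length(summaries), 2)
  out <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    u <- mann_whitney_u(summaries[[i]]$pairs$distance,
                        summaries[[j]]$pairs$distance)
    data.frame(domain_a = nm[i], domain_b = nm[j],
               mean_a = summaries[[i]]$mean, mean_b = summaries[[j]]$mean,
               U = u$U, p.value = u$p.value,
               p.printed = format_pvalue(u$p.value))
  })
  do.call(rbind, out)
}
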