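# Independent oracles used across the suite.  Each reimplements the
# checked quantity by brute force or from an independent decomposition,
# never by calling the code path under test.

# exhaustive best global-alignment score with affine gaps
# (gap of length L costs open + L * ext), via recursion over all
# monotone alignments of two short sequences
brute_align_score <- function(a, b, score_fun, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, acc, state) {
    # state: 0 = last column was match, 1 = gap in b (a consumed),
    # 2 = gap in a (b consumed)
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, acc + score_fun(ca[i], cb[j]), 0)
    if (i <= length(ca))
      rec(i + 1, j, acc - ext - if (state == 1) 0 else open, 1)
    if (j <= length(cb))
      rec(i, j + 1, acc - ext - if (state == 2) 0 else open, 2)
  }
  rec(1, 1, 0, -1)
  best
}

# grid-search ML distance oracle: independent eigendecomposition of the
# generator (plain eigen of Q, not the symmetrized form the package
# caches) and an explicit grid over t
grid_jtt_distance <- function(model, aln, step = 2e-4, tmax = 10) {
  cols <- rbind(strsplit(aln$gapped_a, "")[[1]],
                strsplit(aln$gapped_b, "")[[1]])
  states <- rownames(model$rate_matrix)
  ia <- match(cols[1, ], states); ib <- match(cols[2, ], states)
  keep <- !is.na(ia) & !is.na(ib)
  key <- paste(ia[keep], ib[keep])
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  n <- as.numeric(tab)
  e <- eigen(model$rate_matrix)        # non-symmetric decomposition
  V <- Re(e$vectors); lam <- Re(e$values); W <- solve(V)
  tg <- seq(1e-6, tmax, by = step)
  C <- V[i, , drop = FALSE] * t(W[, j, drop = FALSE])
  P <- C %*% exp(outer(lam, tg))
  P[P < 1e-300] <- 1e-300
  ll <- colSums(n * (log(model$frequencies[i]) + log(P)))
  tg[which.max(ll)]
}

# exhaustive unit matcher: maximum matched-unit count over all subsets
# and anchor placements under the spacer length budgets
brute_match_units <- function(query, pattern) {
  qchars <- strsplit(query$residues, "")[[1]]
  qlen <- length(qchars)
  units <- pattern$units
  m <- length(units)
  lens <- vapply(units, function(u) length(u$positions), 0L)
  ok_at <- function(i, p) {
    L <- lens[i]
    if (p < 1 || p + L - 1 > qlen) return(FALSE)
    for (k in seq_len(L))
      if (!qchars[p + k - 1] %in% units[[i]]$positions[[k]]) return(FALSE)
    TRUE
  }
  gap_ok <- function(j, pj, i, pi) {
    smin <- vapply(units, `[[`, 0, "spacer_min")
    smax <- vapply(units, function(u)
      if (is.infinite(u$spacer_max)) qlen else u$spacer_max, 0)
    ks <- j:(i - 1)
    skipped <- if (i - j > 1) (j + 1):(i - 1) else integer(0)
    g <- pi - (pj + lens[j])
    g >= sum(smin[ks]) + sum(lens[skipped]) &&
      g <= sum(smax[ks]) + sum(lens[skipped])
  }
  best <- 0L
  rec <- function(i, last_i, last_p, count) {
    best <<- max(best, count)
    if (i > m) return(invisible())
    rec(i + 1, last_i, last_p, count)              # skip unit i
    for (p in seq_len(max(0, qlen - lens[i] + 1))) {
      if (!ok_at(i, p)) next
      if (last_i > 0 && !gap_ok(last_i, last_p, i, p)) next
      rec(i + 1, i, p, count + 1L)
    }
  }
  rec(1L, 0L, 0L, 0L)
  best
}

# exact two-sided Mann-Whitney p by enumeration over all labelings,
# using the symmetry of U about mn/2 for tie-free data
enum_mwu_p <- function(a, b) {
  vals <- c(a, b)
  na <- length(a); mn <- na * length(b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u0 <- u_of(a, b)
  cs <- utils::combn(length(vals), na)
  us <- apply(cs, 2, function(ix) u_of(vals[ix], vals[-ix]))
  mean(abs(us - mn / 2) >= abs(u0 - mn / 2) - 1e-9)
}

# random unit-pattern instance for matcher fuzzing: loose spacers,
# query built independently of both matcher implementations
random_unit_instance <- function(n_units_max = 10, qlen_max = 30) {
  m <- sample(2:n_units_max, 1)
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lines <- vapply(seq_len(m), function(i) {
    L <- sample(1:2, 1)
    cons <- paste(sample(residues, L, replace = TRUE), collapse = "")
    smin <- sample(0:2, 1); smax <- smin + sample(0:2, 1)
    sprintf("%s[%d-%d]", cons, smin, smax)
  }, "")
  pattern <- parse_unit_pattern(text = lines, pattern_id = "fuzz")
  qlen <- sample(5:qlen_max, 1)
  query <- bio_seq("fuzz_query",
                   paste(sample(residues, qlen, replace = TRUE),
                         collapse = ""), "protein")
  list(pattern = pattern, query = query)
}

# direct (alignment-free) substitution counts of equal-length clones
# against a reference: the ground truth for recurrence-filter checks
direct_sub_counts <- function(clones, reference, offset = 0L) {
  refc <- strsplit(reference$residues, "")[[1]]
  keys <- character(0)
  for (cl in clones) {
    cc <- strsplit(cl$residues, "")[[1]]
    d <- which(cc != refc & cc %in% c("A", "C", "G", "T"))
    keys <- c(keys, paste(d + offset, cc[d], sep = ":"))
  }
  table(keys)
}

# minimal catalog builder for set-algebra tests
fake_catalog <- function(positions, alts = NULL, subunit = "S-HMC",
                         n_clones = 96) {
  if (is.null(alts)) alts <- rep("A", length(positions))
  structure(list(
    scope = list(subunit = subunit), n_clones = n_clones, n_rejected = 0L,
    sites = data.frame(position = positions, ref_base = "G",
                       alt_base = alts,
                       recurrence = rep(2L, length(positions)),
                       frequency_pct = rep(2.08, length(positions))),
    min_recurrence = 2L), class = "snp_catalog")
}

random_protein <- function(n, id = "p") {
  bio_seq(id, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                           replace = TRUE), collapse = ""), "protein")
}
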