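# Ka/Ks by Li's (1993) unweighted-pathway method.
#
# Codon positions are partitioned by degeneracy (nondegenerate, twofold,
# fourfold); transitional/transversional differences are counted per
# class, averaging equally over all stop-free minimal pathways when two
# codons differ at more than one position; Kimura-type corrections A_i,
# B_i per class then combine into Ka and Ks.

.GENETIC_CODE <- NULL

.genetic_code <- function() {
  # standard code from Biostrings, cached; names are DNA codons
  gc <- Biostrings::GENETIC_CODE
  as.list(gc)
}

.BASES <- c("A", "C", "G", "T")
.is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) |
    (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

# degeneracy class (0, 2, 4) of each position of a sense codon:
# number of synonymous alternatives among the 3 possible changes
# (0 -> nondegenerate, 3 -> fourfold, 1 or 2 -> twofold)
.codon_degeneracy <- function(codon, code = .genetic_code()) {
  aa <- code[[codon]]
  if (is.null(aa) || aa == "*") return(rep(NA_integer_, 3))
  ch <- strsplit(codon, "")[[1]]
  vapply(1:3, function(p) {
    alts <- setdiff(.BASES, ch[p])
    syn <- sum(vapply(alts, function(b) {
      ch2 <- ch; ch2[p] <- b
      code[[paste(ch2, collapse = "")]] == aa
    }, TRUE))
    if (syn == 0L) 0L else if (syn == 3L) 4L else 2L
  }, integer(1))
}

# all minimal pathways between two codons, each a list of steps
# (position, from_base, to_base, codon_before, codon_after); pathways
# passing through a stop codon are discarded
.codon_pathways <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  perms <- if (length(pos) == 1L) list(pos)
  else if (length(pos) == 2L) list(pos, rev(pos))
  else list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
            pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  paths <- list()
  for (ord in perms) {
    cur <- strsplit(ca, "")[[1]]
    tgt <- strsplit(cb, "")[[1]]
    steps <- vector("list", length(ord))
    ok <- TRUE
    for (s in seq_along(ord)) {
      p <- ord[s]
      before <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      after <- paste(cur, collapse = "")
      # cb itself was checked upstream, so only intermediates can be stops
      if (code[[after]] == "*" && s < length(ord)) { ok <- FALSE; break }
      steps[[s]] <- list(pos = p, from = substr(before, p, p),
                         to = tgt[p], before = before, after = after)
    }
    if (ok) paths[[length(paths) + 1L]] <- steps
  }
  paths
}

# split an aligned gap-free in-frame nucleotide string into codons
.codons_of <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Ka and Ks by Li's (1993) method
#'
#' Computes nonsynonymous (Ka) and synonymous (Ks) substitution rates
#' from an in-frame pairwise coding-sequence alignment.  Each codon
#' position is classified as nondegenerate (0-fold), twofold or fourfold
#' degenerate in each sequence; site counts \eqn{L_0, L_2, L_4} are the
#' means over the two sequences.  Transitional (\eqn{P_i}) and
#' transversional (\eqn{Q_i}) difference proportions per class are
#' obtained by averaging equally over all stop-free minimal pathways for
#' codons differing at more than one position, assigning each change half
#' to the site class in the codon before and half to the class in the
#' codon after the change.  With
#' \deqn{A_i = \tfrac12\ln\frac{1}{1-2P_i-Q_i} -
#'       \tfrac14\ln\frac{1}{1-2Q_i}, \qquad
#'       B_i = \tfrac12\ln\frac{1}{1-2Q_i},}
#' the rates are
#' \deqn{K_s = \frac{L_2 A_2 + L_4 A_4}{L_2 + L_4} + B_4, \qquad
#'       K_a = A_0 + \frac{L_0 B_0 + L_2 B_2}{L_0 + L_2}.}
#' A log argument \eqn{\le 0} (saturation) flags the affected estimate as
#' undefined (`NA`).
#'
#' @param x either a DNA `pairwise_alignment` (codon-aligned; codons
#'   containing a gap or ambiguity in either row are dropped) or a
#'   gap-free DNA [bio_seq]; in the latter case `y` must be a second
#'   [bio_seq] of the same length.
#' @param y optional second [bio_seq] when `x` is a [bio_seq].
#' @return An object of class `kaks_result` with fields `Ka`, `Ks`,
#'   `sites` (L0, L2, L4), `P`, `Q`, `A`, `B`, `n_codons`,
#'   `skipped_codons`, `saturated_Ka`, `saturated_Ks`.
#' @examples
#' a <- bio_seq("a", "AAATTTGGG", "dna")
#' b <- bio_seq("b", "AAGTTTGGG", "dna")   # one synonymous transition
#' ka_li93(a, b)
#' @export
ka_li93 <- function(x, y = NULL) {
  if (inherits(x, "pairwise_alignment")) {
    if (x$alphabet != "dna") .fail("ka_li93 needs a DNA alignment")
    cols <- .aln_columns(x)
    if (ncol(cols) %% 3L != 0L)
      .fail("alignment length %d is not a multiple of 3", ncol(cols))
    sa <- .codons_of(x$gapped_a)
    sb <- .codons_of(x$gapped_b)
    gap <- grepl("-", sa) | grepl("-", sb)
    sa <- sa[!gap]; sb <- sb[!gap]
    ids <- c(x$id_a, x$id_b)
  } else {
    stopifnot(inherits(x, "bio_seq"), inherits(y, "bio_seq"),
              x$alphabet == "dna", y$alphabet == "dna")
    if (nchar(x$residues) != nchar(y$residues))
      .fail("sequences '%s' and '%s' differ in length", x$id, y$id)
    if (nchar(x$residues) %% 3L != 0L)
      .fail("sequence length %d is not a multiple of 3", nchar(x$residues))
    sa <- .codons_of(x$residues)
    sb <- .codons_of(y$residues)
    ids <- c(x$id, y$id)
  }
  amb <- !grepl("^[ACGT]{3}$", sa) | !grepl("^[ACGT]{3}$", sb)
  sa <- sa[amb == FALSE]; sb <- sb[amb == FALSE]
  if (length(sa) == 0L) .fail("no comparable codons")
  code <- .genetic_code()
  if (any(vapply(sa, function(c) code[[c]] == "*", TRUE)) ||
      any(vapply(sb, function(c) code[[c]] == "*", TRUE)))
    .fail("internal stop codon in '%s'/'%s'", ids[1], ids[2])

  # site counts per sequence, averaged
  deg_a <- vapply(sa, .codon_degeneracy, integer(3), code = code)
  deg_b <- vapply(sb, .codon_degeneracy, integer(3), code = code)
  L <- (table(factor(deg_a, levels = c(0, 2, 4))) +
          table(factor(deg_b, levels = c(0, 2, 4)))) / 2
  L <- as.numeric(L); names(L) <- c("L0", "L2", "L4")

  # difference counts per class and type
  ts <- c(`0` = 0, `2` = 0, `4` = 0)
  tv <- c(`0` = 0, `2` = 0, `4` = 0)
  skipped <- 0L
  diff_idx <- which(sa != sb)
  for (k in diff_idx) {
    paths <- .codon_pathways(sa[k], sb[k], code)
    if (length(paths) == 0L) {
      warning(sprintf("codon %d (%s/%s): all pathways pass through a %s",
                      k, sa[k], sb[k], "stop codon; codon skipped"),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    w <- 1 / length(paths)
    for (path in paths) {
      for (st in path) {
        cls_before <- .codon_degeneracy(st$before, code)[st$pos]
        cls_after <- .codon_degeneracy(st$after, code)[st$pos]
        chem_ts <- .is_transition(st$from, st$to)
        syn <- code[[st$before]] == code[[st$after]]
        for (cls in c(cls_before, cls_after)) {
          # Li's interchange rule: at twofold sites a change counts as
          # "transitional" iff it is synonymous (covers the arginine
          # CGA/AGA first positions and the isoleucine ATA third
          # position, where the synonymous change is a transversion);
          # at 0- and 4-fold sites the chemical type is used
          as_ts <- if (cls == 2L) syn else chem_ts
          key <- as.character(cls)
          if (as_ts) ts[key] <- ts[key] + w / 2
          else tv[key] <- tv[key] + w / 2
        }
      }
    }
  }

  P <- ifelse(L > 0, ts / L, 0); names(P) <- c("P0", "P2", "P4")
  Q <- ifelse(L > 0, tv / L, 0); names(Q) <- c("Q0", "Q2", "Q4")
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  A <- ifelse(arg1 > 0 & arg2 > 0,
              0.5 * log(1 / arg1) - 0.25 * log(1 / arg2), NA_real_)
  B <- ifelse(arg2 > 0, 0.5 * log(1 / arg2), NA_real_)
  names(A) <- c("A0", "A2", "A4"); names(B) <- c("B0", "B2", "B4")

  Ks <- (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) + B[3]
  Ka <- A[1] + (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2])
  structure(list(
    ids = ids, Ka = unname(Ka), Ks = unname(Ks), sites = L, P = P, Q = Q,
    A = A, B = B, n_codons = length(sa), skipped_codons = skipped,
    saturated_Ka = is.na(Ka), saturated_Ks = is.na(Ks)
  ), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, digits = 5, ...) {
  cat(sprintf("<kaks_result> %s vs %s (%d codons)\n", x$ids[1], x$ids[2],
              x$n_codons))
  cat(sprintf("  Ka = %s%s   Ks = %s%s\n",
              format(x$Ka, digits = digits),
              if (x$saturated_Ka) " (saturated)" else "",
              format(x$Ks, digits = digits),
              if (x$saturated_Ks) " (saturated)" else ""))
  cat(sprintf("  sites L0/L2/L4 = %s\n",
              paste(format(x$sites, digits = digits), collapse = " / ")))
  invisible(x)
}

#' Mean Ka over all pairs of in-frame coding sequences
#'
#' Convenience wrapper mirroring [domain_distance_summary()] at the
#' nucleotide level: computes [ka_li93()] for every pair and returns the
#' per-pair table and mean Ka.
#'
#' @param cds list of \eqn{\ge 2} equal-length, gap-free, in-frame DNA
#'   [bio_seq] objects.
#' @param domain_name label for the result.
#' @return list with `domain_name`, `pairs` (data.frame `taxon_a`,
#'   `taxon_b`, `Ka`, `Ks`), `mean_Ka`, `mean_Ks` (NA pairs dropped from
#'   the means, counted in `n_saturated`).
#' @export
domain_ka_summary <- function(cds, domain_name = "") {
  stopifnot(length(cds) >= 2L)
  taxa <- vapply(cds, `[[`, "", "id")
  idx <- utils::combn(length(cds), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    r <- ka_li93(cds[[idx[1, k]]], cds[[idx[2, k]]])
    data.frame(taxon_a = taxa[idx[1, k]], taxon_b = taxa[idx[2, k]],
               Ka = r$Ka, Ks = r$Ks)
  })
  pairs <- do.call(rbind, rows)
  list(domain_name = domain_name, pairs = pairs,
       mean_Ka = mean(pairs$Ka, na.rm = TRUE),
       mean_Ks = mean(pairs$Ks, na.rm = TRUE),
       n_saturated = sum(is.na(pairs$Ka) | is.na(pairs$Ks)))
}
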