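# Conserved-domain "unit" patterns and the query-vs-units aligner.
#
# A unit is one row of a conserved-domain consensus: one or more
# conserved residue positions followed by a bracketed count or range of
# variable spacer residues before the next unit.  Matching maximizes the
# number of units placed in pattern order at increasing query positions
# under the spacer length budgets; a skipped unit forgives residue
# identity but still consumes its conserved length plus its spacer
# budget, so matched units stay positionally plausible in the consensus
# geometry.

#' Parse a unit-pattern file
#'
#' One unit per line: `<conserved>[m]` or `<conserved>[m-n]`, where
#' `<conserved>` is a string of residue letters in which a position may
#' also be a residue class in braces (e.g. `{FYW}` matches F, Y or W),
#' and the bracket gives the number (or range) of variable residues
#' before the next unit.  An unbounded spacer is written `[m-*]`.
#' Lines starting with `#` (and inline `#` comments) are ignored.
#'
#' @param path path to a pattern file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param pattern_id identifier stored on the pattern; defaults to the
#'   file base name.
#' @return An object of class `unit_pattern`: `pattern_id` and `units`,
#'   a list of `list(conserved, positions, spacer_min, spacer_max)` where
#'   `positions` is a list of allowed-residue vectors.  The last unit's
#'   spacer is parsed but never constrains a match.
#' @examples
#' p <- parse_unit_pattern(text = c("C[2-4]", "W[0]", "{FYW}Y[5]"))
#' length(p$units)
#' @export
parse_unit_pattern <- function(path = NULL, text = NULL, pattern_id = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      .fail("pattern file '%s' does not exist", path)
    text <- readLines(path, warn = FALSE)
    if (is.null(pattern_id))
      pattern_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(pattern_id)) pattern_id <- "pattern"
  units <- list()
  for (ln in seq_along(text)) {
    line <- sub("#.*$", "", text[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regmatches(line,
                    regexec("^([A-Za-z{}]+)\\[([0-9]+)(-([0-9]+|\\*))?\\]$",
                            line))[[1]]
    if (length(m) == 0L)
      .fail("line %d: cannot parse unit '%s'", ln, text[ln])
    conserved <- toupper(m[2])
    smin <- as.integer(m[3])
    smax <- if (!nzchar(m[4])) smin
    else if (m[5] == "*") Inf else as.integer(m[5])
    if (smax < smin)
      .fail("line %d: spacer range %d-%s is inverted", ln, smin, m[5])
    # split conserved string into positions; braces delimit classes
    toks <- regmatches(conserved,
                       gregexpr("\\{[A-Z]+\\}|[A-Z]", conserved))[[1]]
    if (paste(toks, collapse = "") != conserved)
      .fail("line %d: malformed conserved string '%s'", ln, m[2])
    if (length(toks) == 0L)
      .fail("line %d: empty conserved string", ln)
    positions <- lapply(toks, function(tk) {
      if (startsWith(tk, "{"))
        strsplit(gsub("[{}]", "", tk), "")[[1]]
      else tk
    })
    units[[length(units) + 1L]] <- list(
      conserved = conserved, positions = positions,
      spacer_min = smin, spacer_max = smax)
  }
  if (length(units) == 0L) .fail("pattern contains no units")
  structure(list(pattern_id = pattern_id, units = units),
            class = "unit_pattern")
}

#' @export
print.unit_pattern <- function(x, ...) {
  cat(sprintf("<unit_pattern %s> %d units\n", x$pattern_id,
              length(x$units)))
  invisible(x)
}

#' Write a unit pattern back to its text format
#'
#' @param pattern a `unit_pattern`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unit_pattern <- function(pattern, path) {
  lines <- vapply(pattern$units, function(u) {
    sp <- if (is.infinite(u$spacer_max))
      sprintf("[%d-*]", u$spacer_min)
    else if (u$spacer_min == u$spacer_max)
      sprintf("[%d]", u$spacer_min)
    else sprintf("[%d-%d]", u$spacer_min, u$spacer_max)
    paste0(u$conserved, sp)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# length of a unit's conserved region
.unit_len <- function(u) length(u$positions)

# logical: does the query match unit u starting at position p (1-based)?
.unit_ok_at <- function(qchars, u, p) {
  L <- .unit_len(u)
  if (p < 1L || p + L - 1L > length(qchars)) return(FALSE)
  for (k in seq_len(L))
    if (!qchars[p + k - 1L] %in% u$positions[[k]]) return(FALSE)
  TRUE
}

# gap budget between matched units j < i: bounds on the number of query
# residues between the end of unit j and the start of unit i
.gap_bounds <- function(units, j, i, qlen) {
  smin <- vapply(units, `[[`, 0, "spacer_min")
  smax <- vapply(units, function(u)
    if (is.infinite(u$spacer_max)) qlen else u$spacer_max, 0)
  lens <- vapply(units, .unit_len, 0L)
  ks <- j:(i - 1L)
  skipped <- if (i - j > 1L) (j + 1L):(i - 1L) else integer(0)
  c(lo = sum(smin[ks]) + sum(lens[skipped]),
    hi = sum(smax[ks]) + sum(lens[skipped]))
}

#' Match a query sequence against a unit pattern
#'
#' Places as many units as possible (a dynamic program over unit index
#' and query position) subject to: matched units appear in pattern order
#' at strictly increasing query positions, and the number of query
#' residues between two consecutively matched units lies within the sum
#' of the traversed spacer budgets, each skipped unit also consuming its
#' conserved length.  Ties between optimal placements are broken toward
#' the lexicographically smallest anchor-position vector.  With
#' `greedy = TRUE` a left-to-right first-fit scan is used instead (each
#' unit is matched at the earliest feasible position or skipped).
#'
#' @param query a protein [bio_seq].
#' @param pattern a [parse_unit_pattern()] result.
#' @param greedy logical; use the first-fit scan instead of the optimal
#'   dynamic program.
#' @return An object of class `unit_match_result`: `pattern_id`,
#'   `query_id`, `matched_flags`, `matched_count`, `matched_fraction`
#'   (percent, 1 decimal, half-up), `longest_run`,
#'   `longest_run_fraction`, `anchors` (1-based query positions, `NA`
#'   for unmatched units).
#' @examples
#' p <- parse_unit_pattern(text = c("A[1-2]", "C[1-2]", "D[0]"))
#' q <- bio_seq("q", "AXCXXD", "protein")
#' match_units(q, p)$matched_count   # 3
#' @export
match_units <- function(query, pattern, greedy = FALSE) {
  stopifnot(inherits(query, "bio_seq"), inherits(pattern, "unit_pattern"))
  if (query$alphabet != "protein")
    .fail("unit matching is defined for protein queries")
  qchars <- strsplit(query$residues, "")[[1]]
  qlen <- length(qchars)
  units <- pattern$units
  m <- length(units)
  lens <- vapply(units, .unit_len, 0L)

  # candidate anchor positions per unit
  ok <- lapply(seq_len(m), function(i) {
    ps <- seq_len(max(0L, qlen - lens[i] + 1L))
    ps[vapply(ps, function(p) .unit_ok_at(qchars, units[[i]], p), TRUE)]
  })

  anchors <- rep(NA_integer_, m)
  if (greedy) {
    last_i <- 0L; last_p <- 0L
    for (i in seq_len(m)) {
      cand <- ok[[i]]
      if (last_i > 0L) {
        gb <- .gap_bounds(units, last_i, i, qlen)
        lo <- last_p + lens[last_i] + gb["lo"]
        hi <- last_p + lens[last_i] + gb["hi"]
        cand <- cand[cand >= lo & cand <= hi]
      }
      if (length(cand)) {
        anchors[i] <- cand[1]
        last_i <- i; last_p <- cand[1]
      }
    }
  } else {
    # suffix DP: g[[i]][k] = max units matchable by a chain starting with
    # unit i anchored at ok[[i]][k]
    g <- lapply(seq_len(m), function(i) rep(1L, length(ok[[i]])))
    for (i in rev(seq_len(m))) {
      if (length(ok[[i]]) == 0L) next
      for (j in if (i < m) (i + 1L):m else integer(0)) {
        if (length(ok[[j]]) == 0L) next
        gb <- .gap_bounds(units, i, j, qlen)
        for (k in seq_along(ok[[i]])) {
          p <- ok[[i]][k]
          lo <- p + lens[i] + gb["lo"]
          hi <- p + lens[i] + gb["hi"]
          sel <- ok[[j]] >= lo & ok[[j]] <= hi
          if (any(sel))
            g[[i]][k] <- max(g[[i]][k], 1L + max(g[[j]][sel]))
        }
      }
    }
    best <- 0L
    for (i in seq_len(m)) if (length(g[[i]])) best <- max(best, max(g[[i]]))
    if (best > 0L) {
      # reconstruct, preferring the smallest anchor (then smallest unit
      # index) at every step => lexicographically smallest anchor vector
      target <- best; cur_i <- 0L; cur_p <- 0L
      repeat {
        cand <- NULL
        for (i in seq_len(m)) {
          if (cur_i > 0L && i <= cur_i) next
          if (length(ok[[i]]) == 0L) next
          sel <- g[[i]] == target
          if (cur_i > 0L) {
            gb <- .gap_bounds(units, cur_i, i, qlen)
            lo <- cur_p + lens[cur_i] + gb["lo"]
            hi <- cur_p + lens[cur_i] + gb["hi"]
            sel <- sel & ok[[i]] >= lo & ok[[i]] <= hi
          }
          if (any(sel)) {
            p <- min(ok[[i]][sel])
            if (is.null(cand) || p < cand$p) cand <- list(i = i, p = p)
          }
        }
        if (is.null(cand)) break
        anchors[cand$i] <- cand$p
        cur_i <- cand$i; cur_p <- cand$p
        target <- target - 1L
        if (target == 0L) break
      }
    }
  }

  flags <- !is.na(anchors)
  count <- sum(flags)
  run <- .longest_run(flags)
  structure(list(
    pattern_id = pattern$pattern_id, query_id = query$id,
    matched_flags = flags, matched_count = count,
    matched_fraction = round_half_up(100 * count / m, 1),
    longest_run = run,
    longest_run_fraction = round_half_up(100 * run / m, 1),
    anchors = anchors, n_units = m, greedy = greedy
  ), class = "unit_match_result")
}

#' @export
print.unit_match_result <- function(x, ...) {
  cat(sprintf("<unit_match_result> %s vs %s%s\n", x$query_id, x$pattern_id,
              if (x$greedy) " (greedy)" else ""))
  cat(sprintf("  matched %d/%d units (%.1f%%), longest run %d (%.1f%%)\n",
              x$matched_count, x$n_units, x$matched_fraction,
              x$longest_run, x$longest_run_fraction))
  invisible(x)
}
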