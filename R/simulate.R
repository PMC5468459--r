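# Seeded generators for every input the pipeline consumes: JTT-evolved
# protein families on a star tree, planted-SNP clone libraries,
# controlled codon alignments, and unit-pattern fixtures.
#
# Defaults mirror the study design the pipeline targets: six taxa, three
# hemocyanin domains (D1 129 aa, D2 258 aa, D3 245 aa) at the per-domain
# divergences reported for the subunit family, 96-clone libraries with
# planted substitution frequencies in the 0.17-20% range and a 0.1%
# per-base error rate.

#' Default per-domain divergence plan
#'
#' True pairwise divergence (expected substitutions/site) and length for
#' the three hemocyanin domains; D3, the Ig-like domain, is the fastest.
#'
#' @return data.frame with columns `domain`, `length`, `divergence`.
#' @export
hmc_domain_plan <- function() {
  data.frame(domain = c("D1", "D2", "D3"),
             length = c(129L, 258L, 245L),
             divergence = c(0.447528, 0.226219, 0.666782))
}

#' Simulate a protein family under JTT on a star tree
#'
#' The root sequence is drawn from the JTT equilibrium frequencies and
#' each taxon evolves independently along its star branch
#' (`divergence / 2` per branch, so the true pairwise distance between
#' any two taxa equals `divergence`), with per-site substitution by the
#' model's transition matrix.
#'
#' @param n_taxa number of taxa (default 6).
#' @param domains data.frame like [hmc_domain_plan()] (`domain`,
#'   `length`, `divergence`).
#' @param model a [jtt_model()] object.
#' @param seed optional integer seed (recorded in sequence descriptions).
#' @return list with `sequences` (named list, one list of [bio_seq] per
#'   domain) and `truth` (data.frame `domain`, `taxon_a`, `taxon_b`,
#'   `true_distance`).
#' @export
simulate_protein_family <- function(n_taxa = 6L,
                                    domains = hmc_domain_plan(),
                                    model = jtt_model(), seed = NULL) {
  stopifnot(n_taxa >= 2L, all(domains$divergence >= 0),
            all(domains$length > 0))
  if (!is.null(seed)) set.seed(seed)
  states <- names(model$frequencies)
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  seqs <- list(); truth <- list()
  for (d in seq_len(nrow(domains))) {
    L <- domains$length[d]
    t_branch <- domains$divergence[d] / 2
    root <- sample(states, L, replace = TRUE, prob = model$frequencies)
    P <- transition_probabilities(model, t_branch)
    dom_seqs <- lapply(taxa, function(tx) {
      idx <- match(root, states)
      evolved <- vapply(idx, function(i)
        sample(states, 1L, prob = P[i, ]), "")
      bio_seq(tx, paste(evolved, collapse = ""), "protein",
              desc = sprintf("domain=%s seed=%s", domains$domain[d],
                             if (is.null(seed)) "NA" else seed))
    })
    pairs <- utils::combn(n_taxa, 2)
    truth[[d]] <- data.frame(domain = domains$domain[d],
                             taxon_a = taxa[pairs[1, ]],
                             taxon_b = taxa[pairs[2, ]],
                             true_distance = domains$divergence[d])
    seqs[[domains$domain[d]]] <- dom_seqs
  }
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Simulate a clone library with planted substitutions
#'
#' Each of `n_clones` clones is the reference with (i) each planted
#' alternative base carried according to its frequency — independent
#' Bernoulli draws per clone by default, or exactly
#' `round(frequency * n_clones)` carriers with `carrier_mode = "exact"` —
#' and (ii) independent per-base errors at `error_rate`, uniform over the
#' three alternative bases.
#'
#' @param reference DNA [bio_seq] of the domain region.
#' @param planted data.frame with columns `position` (accession
#'   coordinates when `ann` is given, else 1-based in the reference),
#'   `alt`, `frequency` (in (0, 1]); positions must be distinct.
#' @param n_clones number of clones (default 96, one microtitre plate).
#' @param error_rate per-base error probability.
#' @param ann optional [domain_annotation] locating the reference region
#'   in accession coordinates.
#' @param carrier_mode `"bernoulli"` or `"exact"`.
#' @param seed optional integer seed.
#' @return list with `clones` (list of [bio_seq]) and `truth`
#'   (data.frame `position`, `ref`, `alt`, `frequency`, `carriers`).
#' @export
simulate_clone_library <- function(reference, planted = NULL,
                                   n_clones = 96L, error_rate = 0.001,
                                   ann = NULL,
                                   carrier_mode = c("bernoulli", "exact"),
                                   seed = NULL) {
  carrier_mode <- match.arg(carrier_mode)
  stopifnot(inherits(reference, "bio_seq"), reference$alphabet == "dna",
            n_clones >= 1L, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  offset <- if (is.null(ann)) 0L else ann$start - 1L
  ref_chars <- strsplit(reference$residues, "")[[1]]
  L <- length(ref_chars)
  if (is.null(planted))
    planted <- data.frame(position = integer(0), alt = character(0),
                          frequency = numeric(0))
  if (nrow(planted)) {
    local <- planted$position - offset
    if (any(local < 1L | local > L))
      .fail("planted position outside the reference region")
    if (anyDuplicated(planted$position))
      .fail("planted positions collide: %s",
            planted$position[duplicated(planted$position)][1])
    if (any(planted$alt == ref_chars[local]))
      .fail("planted alternative equals the reference base at position %d",
            planted$position[planted$alt == ref_chars[local]][1])
    stopifnot(all(planted$frequency > 0), all(planted$frequency <= 1))
  }
  clone_mat <- matrix(rep(ref_chars, n_clones), nrow = n_clones,
                      byrow = TRUE)
  carriers <- integer(nrow(planted))
  if (nrow(planted)) {
    local <- planted$position - offset
    for (s in seq_len(nrow(planted))) {
      who <- if (carrier_mode == "bernoulli")
        which(stats::runif(n_clones) < planted$frequency[s])
      else sample(n_clones, max(0L, round(planted$frequency[s] * n_clones)))
      carriers[s] <- length(who)
      clone_mat[who, local[s]] <- planted$alt[s]
    }
  }
  if (error_rate > 0) {
    err <- which(matrix(stats::runif(n_clones * L) < error_rate,
                        nrow = n_clones))
    for (e in err) {
      cur <- clone_mat[e]
      clone_mat[e] <- sample(setdiff(.BASES, cur), 1L)
    }
  }
  clones <- lapply(seq_len(n_clones), function(i)
    bio_seq(sprintf("clone%03d", i), paste(clone_mat[i, ], collapse = ""),
            "dna",
            desc = sprintf("seed=%s", if (is.null(seed)) "NA" else seed)))
  truth <- if (nrow(planted))
    data.frame(position = planted$position,
               ref = ref_chars[planted$position - offset],
               alt = planted$alt, frequency = planted$frequency,
               carriers = carriers)
  else data.frame(position = integer(0), ref = character(0),
                  alt = character(0), frequency = numeric(0),
                  carriers = integer(0))
  list(clones = clones, truth = truth)
}

#' Random reference region for clone-library simulations
#'
#' @param length region length in nucleotides (default 777, a typical
#'   D3 amplicon).
#' @param id sequence id.
#' @param seed optional integer seed.
#' @return DNA [bio_seq].
#' @export
simulate_reference <- function(length = 777L, id = "refD3", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bio_seq(id, paste(sample(.BASES, length, replace = TRUE), collapse = ""),
          "dna")
}

# feasible (codon, position, to-base) table for one change request
.codon_change_candidates <- function(class, type, synonymous = NA) {
  code <- .genetic_code()
  sense <- names(code)[unlist(code) != "*"]
  out <- list()
  for (cd in sense) {
    deg <- .codon_degeneracy(cd, code)
    ch <- strsplit(cd, "")[[1]]
    for (p in which(deg == class)) {
      for (b in setdiff(.BASES, ch[p])) {
        is_ts <- .is_transition(ch[p], b)
        if ((type == "transition") != is_ts) next
        ch2 <- ch; ch2[p] <- b
        cd2 <- paste(ch2, collapse = "")
        if (code[[cd2]] == "*") next
        syn <- code[[cd2]] == code[[cd]]
        if (!is.na(synonymous) && syn != synonymous) next
        out[[length(out) + 1L]] <- data.frame(
          codon = cd, pos = p, to = b, new_codon = cd2,
          class = class, type = type, synonymous = syn)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Simulate an in-frame codon pair with controlled changes
#'
#' Builds a pair of coding sequences where each requested change is
#' placed in its own codon at a site of the requested degeneracy class
#' and substitution type, so the Li-method class counts of the pair are
#' known exactly (one change per mutated codon, no stop codons).
#'
#' @param n_codons total codon count (filler codons are unchanged sense
#'   codons).
#' @param changes data.frame with columns `class` (0, 2 or 4), `type`
#'   (`"transition"` or `"transversion"`) and optionally `synonymous`
#'   (logical; `NA` = unconstrained).
#' @param seed optional integer seed.
#' @return list with `a`, `b` ([bio_seq] pair) and `truth` (data.frame
#'   `codon_index`, `position`, `class`, `type`, `from`, `to`,
#'   `synonymous`).
#' @export
simulate_codon_alignment <- function(n_codons = 100L, changes = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(changes))
    changes <- data.frame(class = integer(0), type = character(0))
  if (is.null(changes$synonymous))
    changes$synonymous <- rep(NA, nrow(changes))
  if (nrow(changes) > n_codons)
    .fail("more requested changes (%d) than codons (%d)", nrow(changes),
          n_codons)
  code <- .genetic_code()
  sense <- names(code)[unlist(code) != "*"]
  codons_a <- sample(sense, n_codons, replace = TRUE)
  codons_b <- codons_a
  truth <- list()
  for (r in seq_len(nrow(changes))) {
    cand <- .codon_change_candidates(changes$class[r], changes$type[r],
                                     changes$synonymous[r])
    if (is.null(cand))
      .fail("no codon admits a %s %s at a %d-fold site",
            if (isTRUE(changes$synonymous[r])) "synonymous"
            else if (isFALSE(changes$synonymous[r])) "nonsynonymous"
            else "", changes$type[r], changes$class[r])
    pick <- cand[sample(nrow(cand), 1L), ]
    codons_a[r] <- pick$codon
    codons_b[r] <- pick$new_codon
    truth[[r]] <- data.frame(codon_index = r, position = pick$pos,
                             class = pick$class, type = pick$type,
                             from = substr(pick$codon, pick$pos, pick$pos),
                             to = pick$to, synonymous = pick$synonymous)
  }
  list(a = bio_seq("cdsA", paste(codons_a, collapse = ""), "dna"),
       b = bio_seq("cdsB", paste(codons_b, collapse = ""), "dna"),
       truth = if (length(truth)) do.call(rbind, truth)
       else data.frame(codon_index = integer(0)))
}

#' Simulate a unit pattern and a query instantiating chosen units
#'
#' Builds a pattern of single-residue units with fixed (`rigid = TRUE`)
#' or ranged spacers and a query that instantiates exactly the units
#' flagged in `flags`: matched units contribute their conserved residue,
#' unmatched units and all spacers are filled with a residue excluded
#' from every conserved position, so a corrupted unit cannot match at its
#' planted location.  With rigid spacers the pattern geometry is fixed,
#' making the planned flags the unique optimal matching (up to the
#' vanishing chance of coincidental shifted matches).
#'
#' @param flags logical vector, one entry per unit; `TRUE` = instantiate.
#' @param spacer_max_range with `rigid = FALSE`, spacer maxima are drawn
#'   up to this many residues above the instantiated spacer.
#' @param rigid logical; `TRUE` gives every spacer an exact `[m]` budget.
#' @param filler residue used for spacers and corrupted units.
#' @param seed optional integer seed.
#' @return list with `pattern` ([parse_unit_pattern()]-compatible
#'   object), `query` ([bio_seq]), `expected_flags`, `expected_count`,
#'   `expected_longest_run`.
#' @export
simulate_unit_fixture <- function(flags, spacer_max_range = 2L,
                                  rigid = TRUE, filler = "A",
                                  seed = NULL) {
  stopifnot(is.logical(flags), length(flags) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  residues <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], filler)
  m <- length(flags)
  conserved <- sample(residues, m, replace = TRUE)
  spacer_inst <- sample(0:3, m, replace = TRUE)
  smin <- spacer_inst
  smax <- if (rigid) spacer_inst
  else spacer_inst + sample(0:spacer_max_range, m, replace = TRUE)
  lines <- sprintf("%s[%d%s]", conserved, smin,
                   ifelse(smax > smin, paste0("-", smax), ""))
  pattern <- parse_unit_pattern(text = lines, pattern_id = "synthetic")
  query <- character(0)
  for (i in seq_len(m)) {
    query <- c(query, if (flags[i]) conserved[i] else filler)
    if (i < m) query <- c(query, rep(filler, spacer_inst[i]))
  }
  list(pattern = pattern,
       query = bio_seq("synthetic_query", paste(query, collapse = ""),
                       "protein"),
       expected_flags = flags, expected_count = sum(flags),
       expected_longest_run = .longest_run(flags))
}

#' Unit flag layout mirroring a 34-unit consensus benchmark
#'
#' 26 of 34 units matched with a longest consecutive run of 15.
#'
#' @return logical vector of length 34.
#' @export
unit_benchmark_flags <- function() {
  rep(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      times = c(15L, 1L, 5L, 2L, 3L, 1L, 2L, 2L, 1L, 2L))
}
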