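# Pairwise global alignment and alignment-level statistics.
#
# Alignment itself is delegated to Biostrings::pairwiseAlignment
# (Needleman-Wunsch with affine gaps: a gap of length L costs
# gap_open + L * gap_extend).  Defaults follow common practice for the
# two alphabets: BLOSUM62/10/1 for proteins, +2/-3/5/2 for DNA.

.default_scoring <- function(alphabet) {
  if (alphabet == "protein")
    list(matrix_name = "BLOSUM62", gap_open = 10, gap_extend = 1)
  else
    list(matrix_name = "DNA+2/-3", match = 2, mismatch = -3,
         gap_open = 5, gap_extend = 2)
}

# fetch a named protein scoring matrix shipped with Biostrings
.scoring_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    .fail("unknown substitution matrix '%s'", name)
  get(name, envir = e)
}

# DNA scoring matrix over the IUPAC alphabet: match/mismatch on ACGT,
# anything involving an ambiguity code scores 0 (treated as uninformative)
.dna_matrix <- function(match, mismatch) {
  letters <- .DNA_LETTERS
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  acgt <- c("A", "C", "G", "T")
  m[acgt, acgt] <- mismatch
  m[cbind(acgt, acgt)] <- match
  m
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap costs
#' (a gap of length \eqn{L} costs `gap_open + L * gap_extend`).
#'
#' @param a,b [bio_seq] objects on the same alphabet.
#' @param scoring optional list; for proteins `matrix_name` (a Biostrings
#'   matrix name, default `"BLOSUM62"`), `gap_open`, `gap_extend`; for DNA
#'   `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return An object of class `pairwise_alignment` with fields `id_a`,
#'   `id_b`, `gapped_a`, `gapped_b` (equal-length, gap = `"-"`), `score`,
#'   `scoring_name`, `alphabet`.
#' @examples
#' a <- bio_seq("x", "HEAGAWGHEE", "protein")
#' global_align(a, a)$score
#' @export
global_align <- function(a, b, scoring = NULL) {
  stopifnot(inherits(a, "bio_seq"), inherits(b, "bio_seq"))
  if (!identical(a$alphabet, b$alphabet))
    .fail("cannot align '%s' (%s) with '%s' (%s): different alphabets",
          a$id, a$alphabet, b$id, b$alphabet)
  sc <- utils::modifyList(.default_scoring(a$alphabet),
                          if (is.null(scoring)) list() else scoring)
  if (a$alphabet == "protein") {
    mat <- .scoring_matrix(sc$matrix_name)
  } else {
    mat <- .dna_matrix(sc$match, sc$mismatch)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = a$residues, subject = b$residues, type = "global",
    substitutionMatrix = mat,
    gapOpening = sc$gap_open, gapExtension = sc$gap_extend)
  structure(list(
    id_a = a$id, id_b = b$id,
    gapped_a = as.character(Biostrings::alignedPattern(pa)),
    gapped_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    scoring_name = sc$matrix_name,
    alphabet = a$alphabet
  ), class = "pairwise_alignment")
}

#' Build a pairwise alignment object from pre-aligned strings
#'
#' For alignments produced elsewhere (e.g. projected from a multiple
#' alignment).  Columns gapped in both rows are dropped.
#'
#' @param id_a,id_b sequence identifiers.
#' @param gapped_a,gapped_b equal-length aligned strings, gap = `"-"`.
#' @param alphabet `"protein"` or `"dna"`.
#' @param scoring_name label recorded on the object.
#' @return A `pairwise_alignment`.
#' @export
pairwise_alignment <- function(id_a, gapped_a, id_b, gapped_b,
                               alphabet = c("protein", "dna"),
                               scoring_name = "precomputed") {
  alphabet <- match.arg(alphabet)
  gapped_a <- toupper(gapped_a); gapped_b <- toupper(gapped_b)
  if (nchar(gapped_a) != nchar(gapped_b))
    .fail("aligned strings differ in length (%d vs %d)",
          nchar(gapped_a), nchar(gapped_b))
  ca <- strsplit(gapped_a, "")[[1]]; cb <- strsplit(gapped_b, "")[[1]]
  both <- ca == "-" & cb == "-"
  if (any(both)) {
    ca <- ca[!both]; cb <- cb[!both]
    gapped_a <- paste(ca, collapse = ""); gapped_b <- paste(cb, collapse = "")
  }
  structure(list(id_a = id_a, id_b = id_b, gapped_a = gapped_a,
                 gapped_b = gapped_b, score = NA_real_,
                 scoring_name = scoring_name, alphabet = alphabet),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s (%s), %d columns, score %s\n",
              x$id_a, x$id_b, x$alphabet, nchar(x$gapped_a),
              format(x$score)))
  invisible(x)
}

# internal: aligned columns as a 2 x n character matrix
.aln_columns <- function(aln) {
  rbind(strsplit(aln$gapped_a, "")[[1]], strsplit(aln$gapped_b, "")[[1]])
}

#' Percent identity and similarity of a protein alignment
#'
#' Both percentages use the same denominator: columns with a residue in
#' both rows (gap columns excluded, so a self-alignment is always 100%).
#' Identity counts identical columns; similarity ("homology" in the
#' BioEdit/BLAST sense) counts columns whose substitution score is
#' positive, identities included.
#'
#' @param aln a protein `pairwise_alignment`.
#' @param matrix_name substitution matrix used for the similarity rule;
#'   defaults to the matrix the alignment was built with.
#' @return named numeric vector `c(identity_pct, similarity_pct)`,
#'   unrounded (round at reporting time).
#' @export
identity_similarity <- function(aln, matrix_name = NULL) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$alphabet != "protein")
    .fail("identity_similarity is defined for protein alignments")
  if (is.null(matrix_name)) {
    matrix_name <- if (aln$scoring_name %in% c("precomputed")) "BLOSUM62"
    else aln$scoring_name
  }
  mat <- .scoring_matrix(matrix_name)
  cols <- .aln_columns(aln)
  ok <- cols[1, ] != "-" & cols[2, ] != "-"
  if (!any(ok)) .fail("alignment of '%s' and '%s' has no residue-residue %s",
                      aln$id_a, aln$id_b, "columns")
  a <- cols[1, ok]; b <- cols[2, ok]
  known <- a %in% rownames(mat) & b %in% colnames(mat)
  scores <- rep(NA_real_, sum(ok))
  scores[known] <- mat[cbind(a[known], b[known])]
  c(identity_pct = 100 * mean(a == b),
    similarity_pct = 100 * mean(scores > 0, na.rm = TRUE))
}
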