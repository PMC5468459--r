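# Sequence, annotation and manifest input/output.
#
# Coordinates are 1-based inclusive throughout the user-facing interface,
# matching the accession-style intervals used for the hemocyanin domains
# (e.g. a nucleotide domain "1741-2528"); conversion to 0-based offsets
# happens only inside array arithmetic.

.PROTEIN_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      "B", "X", "Z")          # IUPAC ambiguity allowed
.DNA_LETTERS <- c("A", "C", "G", "T",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Construct a biological sequence
#'
#' A minimal container for a single gap-free upper-case sequence with a
#' declared alphabet.  All pipeline functions consume and return these.
#'
#' @param id character scalar, sequence identifier (first token of a
#'   FASTA header).
#' @param residues character scalar, the sequence; coerced to upper case.
#' @param alphabet `"protein"` or `"dna"`.
#' @param desc optional free-text description (rest of a FASTA header);
#'   carried as metadata, ignored by every algorithm.
#' @return An object of class `bio_seq` with fields `id`, `alphabet`,
#'   `residues`, `desc`.
#' @examples
#' bio_seq("a", "acgt", "dna")
#' @export
bio_seq <- function(id, residues, alphabet = c("protein", "dna"), desc = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) .fail("sequence '%s' is empty", id)
  allowed <- if (alphabet == "protein") .PROTEIN_LETTERS else .DNA_LETTERS
  ch <- strsplit(residues, "")[[1]]
  bad <- which(!ch %in% allowed)
  if (length(bad)) {
    if (ch[bad[1]] == "-")
      .fail("sequence '%s' contains a gap character at position %d; %s",
            id, bad[1], "gapped input is not accepted")
    .fail("sequence '%s' has illegal %s character '%s' at position %d",
          id, alphabet, ch[bad[1]], bad[1])
  }
  structure(list(id = id, alphabet = alphabet, residues = residues,
                 desc = desc),
            class = "bio_seq")
}

#' @export
print.bio_seq <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<bio_seq %s> %s, %d %s\n  %s\n", x$id, x$alphabet, n,
              if (x$alphabet == "dna") "nt" else "aa", head))
  invisible(x)
}

#' @export
length.bio_seq <- function(x) nchar(x$residues)

#' Read a FASTA file
#'
#' Records keep their file order; the id is the first whitespace-delimited
#' token of the header and the remainder is retained as `desc`.  Sequences
#' are upper-cased and validated against the declared alphabet; gaps are
#' rejected.
#'
#' @param path path to a FASTA file (wrapped or single-line).
#' @param alphabet `"protein"` or `"dna"`.
#' @return list of [bio_seq] objects.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .fail("FASTA file '%s' does not exist", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .fail("FASTA file '%s' contains no records", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  mapply(function(id, s, d) bio_seq(id, s, alphabet, desc = d),
         ids, as.character(set), descs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [bio_seq] objects.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    if (nzchar(s$desc)) paste(s$id, s$desc) else s$id, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Annotate a named interval on a reference sequence
#'
#' @param name domain name, e.g. `"D1"`, `"D2"`, `"D3"`.
#' @param start,end 1-based inclusive bounds.
#' @param coordinate_unit `"residue"` (protein) or `"nucleotide"`.
#' @param reference_id id of the sequence the interval refers to.
#' @return An object of class `domain_annotation`.
#' @examples
#' domain_annotation("D3", 413, 657, "residue", "S-HMC")
#' @export
domain_annotation <- function(name, start, end,
                              coordinate_unit = c("residue", "nucleotide"),
                              reference_id) {
  coordinate_unit <- match.arg(coordinate_unit)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    .fail("invalid interval [%s, %s] for domain '%s'", start, end, name)
  structure(list(name = name, start = start, end = end,
                 coordinate_unit = coordinate_unit,
                 reference_id = reference_id),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("<domain %s> %s:%d-%d (%s, length %d)\n", x$name,
              x$reference_id, x$start, x$end, x$coordinate_unit,
              x$end - x$start + 1L))
  invisible(x)
}

#' Extract an annotated region from a sequence
#'
#' @param seq a [bio_seq].
#' @param ann a [domain_annotation] whose `reference_id` matches `seq$id`.
#' @return A [bio_seq] of length `end - start + 1`, with id
#'   `"<seq id>:<domain name>"`.
#' @export
extract_region <- function(seq, ann) {
  stopifnot(inherits(seq, "bio_seq"), inherits(ann, "domain_annotation"))
  if (!identical(ann$reference_id, seq$id))
    .fail("annotation '%s' refers to '%s', not to sequence '%s'",
          ann$name, ann$reference_id, seq$id)
  if (ann$end > nchar(seq$residues))
    .fail("interval %d-%d of domain '%s' exceeds length %d of '%s'",
          ann$start, ann$end, ann$name, nchar(seq$residues), seq$id)
  bio_seq(paste0(seq$id, ":", ann$name),
          substr(seq$residues, ann$start, ann$end),
          seq$alphabet, desc = seq$desc)
}

#' Read a clone-library manifest
#'
#' The manifest is a tab-separated table with a header naming the columns
#' `library_id subunit level tissue individual stage fasta_path` (an
#' optional logical `control` column flags negative-control libraries,
#' e.g. beta-actin clones).  Paths are resolved relative to the manifest
#' file and checked for existence.
#'
#' @param path path to the TSV manifest.
#' @param check_fasta logical, verify the referenced FASTA files exist.
#' @return A `data.frame` of class `library_manifest`.
#' @export
read_manifest <- function(path, check_fasta = TRUE) {
  if (!file.exists(path)) .fail("manifest '%s' does not exist", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("library_id", "subunit", "level", "tissue", "individual",
                "stage", "fasta_path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    .fail("manifest '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(m) == 0L) .fail("manifest '%s' has no library rows", path)
  dup <- m$library_id[duplicated(m$library_id)]
  if (length(dup))
    .fail("duplicate library_id '%s' in manifest", dup[1])
  bad_level <- which(!m$level %in% c("genomic", "cDNA"))
  if (length(bad_level))
    .fail("row %d ('%s'): unknown level '%s' (expected genomic or cDNA)",
          bad_level[1], m$library_id[bad_level[1]], m$level[bad_level[1]])
  bad_sub <- which(!m$subunit %in% c("S-HMC", "L-HMC"))
  if (length(bad_sub))
    .fail("row %d ('%s'): unknown subunit '%s' (expected S-HMC or L-HMC)",
          bad_sub[1], m$library_id[bad_sub[1]], m$subunit[bad_sub[1]])
  if (is.null(m$control)) m$control <- FALSE
  m$control <- as.logical(m$control)
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$fasta_path), m$fasta_path,
                file.path(base, m$fasta_path))
  if (check_fasta) {
    gone <- which(!file.exists(abs))
    if (length(gone))
      .fail("row %d ('%s'): FASTA file '%s' does not exist",
            gone[1], m$library_id[gone[1]], m$fasta_path[gone[1]])
  }
  m$fasta_path <- abs
  class(m) <- c("library_manifest", "data.frame")
  m
}

#' Read a domain annotation table
#'
#' Tab-separated with header
#' `name reference_id start end coordinate_unit`.
#'
#' @param path path to the TSV file.
#' @return list of [domain_annotation] objects.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "reference_id", "start", "end", "coordinate_unit")
  missing <- setdiff(required, names(d))
  if (length(missing))
    .fail("domain table '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    domain_annotation(d$name[i], d$start[i], d$end[i],
                      d$coordinate_unit[i], d$reference_id[i]))
}
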