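# Clone-library SNP calling against a reference D3 domain, per-site
# frequencies, and cross-library set algebra.
#
# A SNP is a (position, alternative base) substitution observed at least
# `min_recurrence` times (default 2) among the accepted clones of the
# pooling scope, positions expressed in reference-accession coordinates
# via the domain annotation offset.  Indel columns and non-ACGT clone
# bases are never counted.

#' Map a clone onto its reference and list substitutions
#'
#' Globally aligns the clone to the reference domain sequence (DNA
#' scoring: match +2, mismatch -3, gap open 5, gap extend 2 by default)
#' and returns the substitution columns only; indel columns are excluded
#' and a non-ACGT base in either row is treated as missing data.  A clone
#' aligning over less than `min_coverage` of the reference is rejected.
#'
#' @param clone,reference DNA [bio_seq] objects; `reference` is the
#'   domain-region sequence whose first base is `ann$start` in accession
#'   coordinates.
#' @param ann optional [domain_annotation]; when supplied, reported
#'   positions are `local position + ann$start - 1`.
#' @param scoring optional DNA scoring list (see [global_align()]).
#' @param min_coverage minimum fraction of reference positions aligned to
#'   a clone base.
#' @return list with `accepted` (logical), `coverage`, and
#'   `substitutions`, a data.frame `position`, `ref_base`, `clone_base`.
#' @export
map_clone_to_reference <- function(clone, reference, ann = NULL,
                                   scoring = NULL, min_coverage = 0.8) {
  stopifnot(inherits(clone, "bio_seq"), inherits(reference, "bio_seq"),
            clone$alphabet == "dna", reference$alphabet == "dna")
  res <- .map_clones(list(clone), reference, ann, scoring, min_coverage)
  res[[1]]
}

# batched clone-vs-reference mapping: one vectorized alignment call
.map_clones <- function(clones, reference, ann = NULL, scoring = NULL,
                        min_coverage = 0.8) {
  offset <- if (is.null(ann)) 0L else ann$start - 1L
  sc <- utils::modifyList(.default_scoring("dna"),
                          if (is.null(scoring)) list() else scoring)
  mat <- .dna_matrix(sc$match, sc$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    pattern = vapply(clones, `[[`, "", "residues"),
    subject = reference$residues, type = "global",
    substitutionMatrix = mat,
    gapOpening = sc$gap_open, gapExtension = sc$gap_extend)
  ref_len <- nchar(reference$residues)
  # reference positions aligned to a clone base: the aligned-region
  # width (nchar excludes terminal gaps) minus internal gaps on both
  # sides of the alignment
  nid <- Biostrings::nindel(pa)
  ins_w <- Biostrings::insertion(nid)[, "WidthSum"]
  del_w <- Biostrings::deletion(nid)[, "WidthSum"]
  coverage <- unname(Biostrings::nchar(pa) - ins_w - del_w) / ref_len
  mt <- Biostrings::mismatchTable(pa)
  mt <- mt[mt$PatternSubstring %in% .BASES &
             mt$SubjectSubstring %in% .BASES, , drop = FALSE]
  lapply(seq_along(clones), function(i) {
    rows <- mt[mt$PatternId == i, , drop = FALSE]
    subs <- data.frame(position = rows$SubjectStart + offset,
                       ref_base = as.character(rows$SubjectSubstring),
                       clone_base = as.character(rows$PatternSubstring),
                       stringsAsFactors = FALSE)
    subs <- subs[order(subs$position), , drop = FALSE]
    rownames(subs) <- NULL
    list(accepted = coverage[i] >= min_coverage, coverage = coverage[i],
         substitutions = subs)
  })
}

#' Call SNPs from a set of clones with a recurrence filter
#'
#' Pools the substitutions of all accepted clones and promotes every
#' (position, alternative base) pair observed at least `min_recurrence`
#' times to a SNP site.
#'
#' @param clones list of DNA [bio_seq] clones.
#' @param reference domain-region reference [bio_seq].
#' @param ann optional [domain_annotation] giving accession coordinates.
#' @param min_recurrence minimum substitution count (default 2, i.e. a
#'   singleton is never a SNP).
#' @param min_coverage clone acceptance threshold, see
#'   [map_clone_to_reference()].
#' @param scoring optional DNA scoring list.
#' @param scope optional named list (e.g. `subunit`, `level`, `group`)
#'   recorded on the catalog.
#' @param control logical; a negative-control library (e.g. beta-actin
#'   clones) that yields any SNP raises a warning.
#' @return An object of class `snp_catalog`: `scope`, `n_clones`
#'   (accepted), `n_rejected`, `sites` (data.frame `position`,
#'   `ref_base`, `alt_base`, `recurrence`, `frequency_pct` relative to
#'   the accepted clone count, 2 decimals half-up).
#' @export
call_snps <- function(clones, reference, ann = NULL, min_recurrence = 2L,
                      min_coverage = 0.8, scoring = NULL, scope = list(),
                      control = FALSE) {
  stopifnot(length(clones) >= 1L, min_recurrence >= 1L)
  maps <- .map_clones(clones, reference, ann, scoring, min_coverage)
  accepted <- vapply(maps, `[[`, TRUE, "accepted")
  if (!any(accepted))
    .fail("no clone reached %.0f%% coverage of the reference (%d rejected)",
          100 * min_coverage, sum(!accepted))
  subs <- do.call(rbind, lapply(maps[accepted], `[[`, "substitutions"))
  n_acc <- sum(accepted)
  if (is.null(subs) || nrow(subs) == 0L) {
    sites <- data.frame(position = integer(0), ref_base = character(0),
                        alt_base = character(0), recurrence = integer(0),
                        frequency_pct = numeric(0))
  } else {
    key <- paste(subs$position, subs$clone_base, sep = ":")
    counts <- table(key)
    keep <- names(counts)[counts >= min_recurrence]
    if (length(keep)) {
      first <- subs[match(keep, key), ]
      sites <- data.frame(position = first$position,
                          ref_base = first$ref_base,
                          alt_base = first$clone_base,
                          recurrence = as.integer(counts[keep]),
                          stringsAsFactors = FALSE)
      sites <- sites[order(sites$position, sites$alt_base), ]
      rownames(sites) <- NULL
      sites$frequency_pct <- round_half_up(100 * sites$recurrence / n_acc, 2)
    } else {
      sites <- data.frame(position = integer(0), ref_base = character(0),
                          alt_base = character(0), recurrence = integer(0),
                          frequency_pct = numeric(0))
    }
  }
  if (control && nrow(sites) > 0L)
    warning(sprintf("negative-control library yielded %d SNP site(s); %s",
                    nrow(sites), "possible PCR/sequencing artefact"),
            call. = FALSE)
  structure(list(scope = scope, n_clones = n_acc,
                 n_rejected = sum(!accepted), sites = sites,
                 min_recurrence = as.integer(min_recurrence)),
            class = "snp_catalog")
}

#' @export
print.snp_catalog <- function(x, ...) {
  lbl <- paste(unlist(x$scope), collapse = "/")
  cat(sprintf("<snp_catalog%s> %d sites from %d clones (%d rejected)\n",
              if (nzchar(lbl)) paste0(" ", lbl) else "",
              nrow(x$sites), x$n_clones, x$n_rejected))
  invisible(x)
}

#' Call SNPs for every library of a manifest, pooled by group
#'
#' Reads each library's clone FASTA, maps clones to the subunit's
#' reference domain and pools substitution counts over the chosen
#' grouping (the default, `c("subunit", "level")`, reproduces the
#' genomic-vs-cDNA per-subunit catalogs; use
#' `c("subunit", "level", "library_id")` for per-library calling).
#'
#' @param manifest a [read_manifest()] result.
#' @param references named list of DNA [bio_seq] reference regions, one
#'   per subunit present in the manifest.
#' @param annotations named list of [domain_annotation] objects per
#'   subunit (optional).
#' @param group_by character vector of manifest columns to pool over.
#' @param ... passed to [call_snps()].
#' @return named list of `snp_catalog` objects, one per group.
#' @export
call_snps_by_group <- function(manifest, references, annotations = NULL,
                               group_by = c("subunit", "level"), ...) {
  stopifnot(inherits(manifest, "library_manifest"))
  keys <- do.call(paste, c(manifest[group_by], sep = "|"))
  out <- list()
  for (key in unique(keys)) {
    rows <- manifest[keys == key, , drop = FALSE]
    subunit <- rows$subunit[1]
    ref <- references[[subunit]]
    if (is.null(ref)) .fail("no reference supplied for subunit '%s'", subunit)
    clones <- do.call(c, lapply(rows$fasta_path, read_fasta,
                                alphabet = "dna"))
    scope <- as.list(rows[1, group_by, drop = FALSE])
    out[[key]] <- call_snps(clones, ref,
                            ann = annotations[[subunit]],
                            scope = scope,
                            control = all(rows$control), ...)
  }
  out
}

#' Per-site SNP frequencies under a chosen denominator
#'
#' The default denominator pools every clone sequenced for the subunit
#' across the supplied catalogs (so a site seen twice among 1,157 clones
#' reports 0.17%); `per_library` uses each catalog's own accepted clone
#' count.
#'
#' @param catalogs list of `snp_catalog` objects sharing a subunit.
#' @param denominator `"pooled_subunit_total"` or `"per_library"`.
#' @param total optional explicit denominator overriding the pooled
#'   count.
#' @return data.frame `catalog`, `position`, `ref_base`, `alt_base`,
#'   `recurrence`, `frequency_pct` (2 decimals, half-up).
#' @export
snp_frequencies <- function(catalogs,
                            denominator = c("pooled_subunit_total",
                                            "per_library"),
                            total = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(length(catalogs) >= 1L)
  if (is.null(names(catalogs)))
    names(catalogs) <- paste0("catalog", seq_along(catalogs))
  pooled <- if (is.null(total))
    sum(vapply(catalogs, function(x) as.numeric(x[["n_clones"]]), 0))
  else total
  if (pooled <= 0) .fail("zero clone denominator")
  rows <- lapply(names(catalogs), function(nm) {
    cat_ <- catalogs[[nm]]
    if (nrow(cat_$sites) == 0L) return(NULL)
    denom <- if (denominator == "pooled_subunit_total") pooled
    else cat_$n_clones
    data.frame(catalog = nm, cat_$sites[c("position", "ref_base",
                                          "alt_base", "recurrence")],
               frequency_pct = round_half_up(
                 100 * cat_$sites$recurrence / denom, 2))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(catalog = character(0), position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      recurrence = integer(0), frequency_pct = numeric(0))
  rownames(out) <- NULL
  out
}

# site keys of a catalog under the chosen identity rule
.site_keys <- function(catalog, by) {
  if (nrow(catalog$sites) == 0L) return(character(0))
  if (by == "position") unique(as.character(catalog$sites$position))
  else unique(paste(catalog$sites$position, catalog$sites$alt_base,
                    sep = ":"))
}

#' Compare SNP catalogs: sizes, intersections, union
#'
#' Site identity is keyed by (position, alternative base) by default, or
#' by bare position (`by = "position"`) for accession-style position
#' lists.
#'
#' @param catalogs list of \eqn{\ge 2} `snp_catalog` objects.
#' @param by `"position_alt"` or `"position"`.
#' @param allow_mixed logical; permit catalogs whose scopes name
#'   different subunits.
#' @return An object of class `overlap_summary`: `labels`, `sizes`,
#'   `pairwise` (intersection-size matrix), `k_intersection`, `union`,
#'   `shared_positions` (sorted positions common to all catalogs), and
#'   `keys` (per-catalog site keys).
#' @export
compare_catalogs <- function(catalogs, by = c("position_alt", "position"),
                             allow_mixed = FALSE) {
  by <- match.arg(by)
  stopifnot(length(catalogs) >= 2L)
  if (is.null(names(catalogs)))
    names(catalogs) <- paste0("catalog", seq_along(catalogs))
  subunits <- unique(unlist(lapply(catalogs, function(x) x$scope$subunit)))
  if (length(subunits) > 1L && !allow_mixed)
    .fail("catalogs mix subunits (%s); set allow_mixed = TRUE to compare",
          paste(subunits, collapse = ", "))
  keys <- lapply(catalogs, .site_keys, by = by)
  n <- length(keys)
  sizes <- vapply(keys, length, 0L)
  pw <- matrix(0L, n, n, dimnames = list(names(catalogs), names(catalogs)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  k_int <- Reduce(intersect, keys)
  uni <- Reduce(union, keys)
  pos_of <- function(k) sort(unique(as.integer(sub(":.*$", "", k))))
  structure(list(labels = names(catalogs), by = by, sizes = sizes,
                 pairwise = pw, k_intersection = length(k_int),
                 union = length(uni), shared_positions = pos_of(k_int),
                 keys = keys),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d catalogs (by %s)\n", length(x$labels),
              x$by))
  cat("  sizes:", paste(sprintf("%s=%d", x$labels, x$sizes),
                        collapse = ", "), "\n")
  cat(sprintf("  union %d, common to all %d\n", x$union, x$k_intersection))
  invisible(x)
}

#' Serialize an overlap summary to JSON
#'
#' @param x an `overlap_summary`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
overlap_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "overlap_summary"))
  obj <- list(labels = x$labels, by = x$by,
              sizes = as.list(stats::setNames(as.integer(x$sizes),
                                              x$labels)),
              pairwise_intersections = x$pairwise,
              k_way_intersection = x$k_intersection, union = x$union,
              shared_positions = x$shared_positions)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export a SNP catalog as VCF 4.2
#'
#' Writes one record per site with the recurrence and frequency in the
#' INFO field (`RC`, `FP`); CHROM is the reference accession id and POS
#' the accession coordinate.
#'
#' @param catalog a `snp_catalog`.
#' @param path output path (plain-text `.vcf`).
#' @param reference_id CHROM value; defaults to the scope's subunit.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(catalog, path, reference_id = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  if (is.null(reference_id))
    reference_id <- if (!is.null(catalog$scope$subunit))
      catalog$scope$subunit else "ref"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=hmcdiv %s", as.character(utils::packageVersion("hmcdiv"))),
    sprintf("##contig=<ID=%s>", reference_id),
    paste0("##INFO=<ID=RC,Number=1,Type=Integer,",
           "Description=\"Recurrence: clones carrying the substitution\">"),
    paste0("##INFO=<ID=FP,Number=1,Type=Float,",
           "Description=\"Frequency percent among accepted clones\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  s <- catalog$sites
  body <- if (nrow(s) == 0L) character(0) else
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tRC=%d;FP=%.2f",
            reference_id, s$position, s$ref_base, s$alt_base,
            s$recurrence, s$frequency_pct)
  writeLines(c(header, body), path)
  invisible(path)
}
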