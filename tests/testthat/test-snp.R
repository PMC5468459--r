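ref200 <- simulate_reference(200, id = "refD3", seed = 61)
ann200 <- domain_annotation("D3", 101, 300, "nucleotide", "X")

test_that("clone coordinates are reported in accession space", {
  r <- bio_seq("r", "ACGTACGT", "dna")
  cl <- bio_seq("c", "ACGAACGT", "dna")
  m <- map_clone_to_reference(cl, r,
                              domain_annotation("D", 101, 108,
                                                "nucleotide", "r"))
  expect_true(m$accepted)
  expect_equal(m$substitutions$position, 104L)
  expect_equal(m$substitutions$ref_base, "T")
  expect_equal(m$substitutions$clone_base, "A")
})

test_that("identical clones yield no substitutions and full coverage", {
  m <- map_clone_to_reference(ref200, ref200, ann200)
  expect_equal(nrow(m$substitutions), 0L)
  expect_equal(m$coverage, 1)
})

test_that("indel columns never appear as substitutions", {
  del <- bio_seq("d", paste0(substr(ref200$residues, 1, 50),
                             substr(ref200$residues, 54, 200)), "dna")
  m <- map_clone_to_reference(del, ref200, ann200)
  expect_equal(nrow(m$substitutions), 0L)
  expect_lt(m$coverage, 1)
})

test_that("low-coverage clones are rejected and all-rejected errors", {
  frag <- bio_seq("f", substr(ref200$residues, 1, 80), "dna")
  m <- map_clone_to_reference(frag, ref200, ann200)
  expect_false(m$accepted)
  expect_error(call_snps(list(frag), ref200, ann200), "coverage")
})

test_that("ambiguous clone bases are ignored at the substitution step", {
  s <- ref200$residues
  substr(s, 20, 20) <- "N"
  m <- map_clone_to_reference(bio_seq("n", s, "dna"), ref200, ann200)
  expect_equal(nrow(m$substitutions), 0L)
})

test_that("the recurrence filter keeps recurrent sites and drops singletons", {
  mutate_at <- function(pos, base) {
    s <- ref200$residues
    substr(s, pos, pos) <- base
    s
  }
  refc <- strsplit(ref200$residues, "")[[1]]
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), refc[p])[1]
  clones <- c(
    lapply(1:5, function(i)
      bio_seq(paste0("carrier", i), mutate_at(50, alt_of(50)), "dna")),
    list(bio_seq("err1", mutate_at(10, alt_of(10)), "dna"),
         bio_seq("err2", mutate_at(110, alt_of(110)), "dna"),
         bio_seq("err3", mutate_at(170, alt_of(170)), "dna")),
    lapply(1:88, function(i) bio_seq(paste0("wt", i), ref200$residues,
                                     "dna")))
  cat_ <- call_snps(clones, ref200, ann200)
  expect_equal(nrow(cat_$sites), 1L)
  expect_equal(cat_$sites$position, 150L)     # 50 + offset 100
  expect_equal(cat_$sites$recurrence, 5L)
  expect_equal(cat_$n_clones, 96L)

  # all-identical library: empty catalog
  wt <- call_snps(lapply(1:10, function(i)
    bio_seq(paste0("w", i), ref200$residues, "dna")), ref200, ann200)
  expect_equal(nrow(wt$sites), 0L)
})

test_that("catalogs equal direct-diff counts filtered at the threshold", {
  for (seed in 1:20) {
    lib <- simulate_clone_library(ref200, NULL, n_clones = 96,
                                  error_rate = 0.001, ann = ann200,
                                  seed = seed)
    cat_ <- call_snps(lib$clones, ref200, ann200)
    truth <- direct_sub_counts(lib$clones, ref200, offset = 100L)
    expected <- sort(names(truth)[truth >= 2])
    got <- sort(paste(cat_$sites$position, cat_$sites$alt_base, sep = ":"))
    expect_equal(got, expected)
    expect_true(all(cat_$sites$recurrence >= 2))
  }
})

test_that("frequencies follow the pooled-denominator convention", {
  cat_a <- fake_catalog(c(10, 20), alts = c("A", "C"))
  cat_a$sites$recurrence <- c(2L, 39L)
  f <- snp_frequencies(list(cat_a), total = 1157)
  expect_equal(f$frequency_pct, c(0.17, 3.37))
  f67 <- snp_frequencies(list(fake_catalog(1)), total = 1157)
  expect_equal(f67$frequency_pct, 0.17)
  # per-library denominator uses the catalog's own clone count
  fl <- snp_frequencies(list(cat_a), denominator = "per_library")
  expect_equal(fl$frequency_pct,
               round_half_up(100 * c(2, 39) / 96, 2))
  expect_error(snp_frequencies(list(cat_a), total = 0), "zero")
})

test_that("frequencies are invariant to clone input order", {
  lib <- simulate_clone_library(ref200,
                                data.frame(position = 150, alt = "A",
                                           frequency = 0.1),
                                n_clones = 48, error_rate = 0.002,
                                ann = ann200, seed = 62)
  fwd <- call_snps(lib$clones, ref200, ann200)
  rev <- call_snps(base::rev(lib$clones), ref200, ann200)
  expect_equal(fwd$sites, rev$sites)
})

test_that("overlap summaries satisfy inclusion-exclusion", {
  set.seed(63)
  for (r in 1:20) {
    sets <- lapply(1:3, function(i)
      fake_catalog(sample(1000, sample(5:40, 1))))
    ov <- compare_catalogs(sets, by = "position")
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      ij_union <- length(union(sets[[i]]$sites$position,
                               sets[[j]]$sites$position))
      expect_equal(ij_union,
                   ov$sizes[i] + ov$sizes[j] - ov$pairwise[i, j],
                   ignore_attr = TRUE)
    }
    # triple inclusion-exclusion
    u3 <- length(Reduce(union, lapply(sets, function(s) s$sites$position)))
    i12 <- ov$pairwise[1, 2]; i13 <- ov$pairwise[1, 3]
    i23 <- ov$pairwise[2, 3]
    expect_equal(u3, sum(ov$sizes) - i12 - i13 - i23 + ov$k_intersection,
                 ignore_attr = TRUE)
  }
})

test_that("disjoint catalogs union additively", {
  ov <- compare_catalogs(list(a = fake_catalog(1:3),
                              b = fake_catalog(11:14)), by = "position")
  expect_equal(ov$union, 7L)
  expect_equal(ov$k_intersection, 0L)
})

test_that("mixed subunits require an explicit override", {
  a <- fake_catalog(1:3, subunit = "S-HMC")
  b <- fake_catalog(2:4, subunit = "L-HMC")
  expect_error(compare_catalogs(list(a, b)), "mix subunits")
  ov <- compare_catalogs(list(a, b), allow_mixed = TRUE, by = "position")
  expect_equal(ov$union, 4L)
})

test_that("site identity distinguishes alleles unless keyed by position", {
  a <- fake_catalog(c(5, 6), alts = c("A", "A"))
  b <- fake_catalog(c(5, 6), alts = c("C", "A"))
  by_allele <- compare_catalogs(list(a, b))
  expect_equal(by_allele$k_intersection, 1L)
  by_pos <- compare_catalogs(list(a, b), by = "position")
  expect_equal(by_pos$k_intersection, 2L)
})

test_that("a control library with SNPs warns", {
  clones <- lapply(1:5, function(i) {
    s <- ref200$residues
    substr(s, 30, 30) <- "A"
    bio_seq(paste0("ctl", i), s, "dna")
  })
  expect_warning(call_snps(clones, ref200, ann200, control = TRUE),
                 "negative-control")
})

test_that("manifest-driven calling pools by subunit and level", {
  dir <- withr::local_tempdir()
  refc <- strsplit(ref200$residues, "")[[1]]
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), refc[p - 100])[1]
  planted <- data.frame(position = c(150, 220),
                        alt = c(alt_of(150), alt_of(220)),
                        frequency = 0.2)
  rows <- list()
  for (i in 1:2) for (lev in c("genomic", "cDNA")) {
    lib <- simulate_clone_library(ref200, planted, n_clones = 24,
                                  error_rate = 0, ann = ann200,
                                  carrier_mode = "exact",
                                  seed = 64 + i * 10 +
                                    (lev == "cDNA"))
    fa <- file.path(dir, sprintf("lib_%s_%d.fasta", lev, i))
    write_fasta(lib$clones, fa)
    rows[[length(rows) + 1L]] <- data.frame(
      library_id = sprintf("lib_%s_%d", lev, i), subunit = "S-HMC",
      level = lev, tissue = "gill", individual = as.character(i),
      stage = "adult", fasta_path = basename(fa))
  }
  mpath <- file.path(dir, "libs.tsv")
  utils::write.table(do.call(rbind, rows), mpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- read_manifest(mpath)
  cats <- call_snps_by_group(manifest, references = list(`S-HMC` = ref200),
                             annotations = list(`S-HMC` = ann200))
  expect_length(cats, 2L)
  expect_equal(unname(vapply(cats, `[[`, 0L, "n_clones")), c(48L, 48L))
  for (cat_ in cats)
    expect_setequal(cat_$sites$position, c(150L, 220L))
})

test_that("VCF export is valid VCF 4.2", {
  skip_if_not_installed("VariantAnnotation")
  lib <- simulate_clone_library(ref200,
                                data.frame(position = 150, alt = "A",
                                           frequency = 0.2),
                                n_clones = 48, error_rate = 0,
                                ann = ann200, carrier_mode = "exact",
                                seed = 65)
  cat_ <- call_snps(lib$clones, ref200, ann200,
                    scope = list(subunit = "S-HMC"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(cat_, f, reference_id = "X82502.1")
  vcf <- VariantAnnotation::readVcf(f)
  expect_equal(length(vcf), nrow(cat_$sites))
  expect_equal(unname(BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))),
               cat_$sites$position)
  expect_equal(VariantAnnotation::info(vcf)$RC, cat_$sites$recurrence)
})

test_that("overlap summaries serialize to JSON", {
  ov <- compare_catalogs(list(g = fake_catalog(1:5), c = fake_catalog(3:9)),
                         by = "position")
  js <- jsonlite::fromJSON(overlap_to_json(ov))
  expect_equal(js$union, 9L)
  expect_equal(js$sizes$g, 5L)
  expect_equal(js$shared_positions, 3:5)
})
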