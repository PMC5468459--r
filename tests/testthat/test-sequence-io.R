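test_that("FASTA reading normalizes case, keeps order and splits headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first record", "acgt", ">b", "GGCC"), f)
  seqs <- read_fasta(f, "dna")
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]]$id, "a")
  expect_equal(seqs[[1]]$residues, "ACGT")
  expect_equal(seqs[[1]]$desc, "first record")
  expect_equal(seqs[[2]]$id, "b")
})

test_that("FASTA round-trip is the identity on (id, residues)", {
  set.seed(101)
  seqs <- lapply(seq_len(50), function(i)
    bio_seq(sprintf("s%02d", i),
            paste(sample(c("A", "C", "G", "T"), sample(5:120, 1),
                         replace = TRUE), collapse = ""), "dna"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f, "dna")
  expect_equal(lapply(back, `[[`, "id"), lapply(seqs, `[[`, "id"))
  expect_equal(lapply(back, `[[`, "residues"),
               lapply(seqs, `[[`, "residues"))
})

test_that("invalid FASTA input is rejected with a located message", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f, "dna"), "no records")
  writeLines(c(">x", "ACJT"), f)
  expect_error(read_fasta(f, "dna"), "'x'.*'J'.*position 3")
  writeLines(c(">y", "AC-T"), f)
  expect_error(read_fasta(f, "dna"), "gap")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa"), "dna"),
               "does not exist")
})

test_that("extract_region returns the 1-based inclusive interval", {
  set.seed(7)
  long <- bio_seq("X82502.1",
                  paste(sample(c("A", "C", "G", "T"), 2600, replace = TRUE),
                        collapse = ""), "dna")
  d3 <- extract_region(long, domain_annotation("D3", 1752, 2528,
                                               "nucleotide", "X82502.1"))
  expect_equal(nchar(d3$residues), 777L)
  expect_equal(d3$id, "X82502.1:D3")
  expect_equal(d3$residues, substr(long$residues, 1752, 2528))

  one <- extract_region(long, domain_annotation("pt", 10, 10,
                                                "nucleotide", "X82502.1"))
  expect_equal(nchar(one$residues), 1L)

  prot <- random_protein(700, "gi854403")
  d3p <- extract_region(prot, domain_annotation("D3", 413, 657, "residue",
                                                "gi854403"))
  expect_equal(nchar(d3p$residues), 245L)  # 657 - 413 + 1

  expect_error(extract_region(prot,
                              domain_annotation("D", 600, 900, "residue",
                                                "gi854403")),
               "exceeds length")
  expect_error(extract_region(prot,
                              domain_annotation("D", 1, 5, "residue",
                                                "other")),
               "refers to")
})

test_that("extract_region length always equals end - start + 1", {
  set.seed(11)
  s <- bio_seq("r", paste(sample(c("A", "C", "G", "T"), 500,
                                 replace = TRUE), collapse = ""), "dna")
  for (k in 1:25) {
    st <- sample(500, 1)
    en <- sample(st:500, 1)
    ann <- domain_annotation("d", st, en, "nucleotide", "r")
    expect_equal(nchar(extract_region(s, ann)$residues), en - st + 1L)
  }
})

write_demo_manifest <- function(dir, rows) {
  fa <- file.path(dir, "clones.fasta")
  write_fasta(list(bio_seq("c1", "ACGT", "dna")), fa)
  rows$fasta_path <- rep("clones.fasta", nrow(rows))
  path <- file.path(dir, "libs.tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("a 28-library manifest matching the study design loads", {
  dir <- withr::local_tempdir()
  # shrimp A: 4 tissues x 2 subunits x 2 levels; shrimps B/C and the
  # nauplius larva: hepatopancreas only => 16 + 8 + 4 = 28 libraries
  gridA <- expand.grid(tissue = c("heart", "stomach", "gill",
                                  "hepatopancreas"),
                       subunit = c("S-HMC", "L-HMC"),
                       level = c("genomic", "cDNA"),
                       stringsAsFactors = FALSE)
  gridA$individual <- "A"
  gridBC <- expand.grid(tissue = "hepatopancreas",
                        subunit = c("S-HMC", "L-HMC"),
                        level = c("genomic", "cDNA"),
                        individual = c("B", "C"),
                        stringsAsFactors = FALSE)
  gridN <- expand.grid(tissue = "whole", subunit = c("S-HMC", "L-HMC"),
                       level = c("genomic", "cDNA"), individual = "N",
                       stringsAsFactors = FALSE)
  rows <- rbind(gridA, gridBC, gridN)
  rows$stage <- ifelse(rows$individual == "N", "nauplius", "adult")
  rows$library_id <- sprintf("lib%02d", seq_len(nrow(rows)))
  m <- read_manifest(write_demo_manifest(dir, rows))
  expect_equal(nrow(m), 28L)
  expect_true(all(!m$control))
})

test_that("manifest validation names the offending row", {
  dir <- withr::local_tempdir()
  base <- data.frame(library_id = c("l1", "l2"),
                     subunit = "S-HMC", level = "genomic",
                     tissue = "gill", individual = "A", stage = "adult",
                     stringsAsFactors = FALSE)
  dup <- base; dup$library_id <- c("l1", "l1")
  expect_error(read_manifest(write_demo_manifest(dir, dup)),
               "duplicate library_id 'l1'")
  bad <- base; bad$level <- c("genomic", "rna")
  expect_error(read_manifest(write_demo_manifest(dir, bad)),
               "row 2.*'l2'.*unknown level 'rna'")
  empty <- base[0, ]
  expect_error(read_manifest(write_demo_manifest(dir, empty)),
               "no library rows")
  gone <- base
  path <- write_demo_manifest(dir, gone)
  file.remove(file.path(dir, "clones.fasta"))
  expect_error(read_manifest(path), "does not exist")
})

test_that("domain tables round through read_domains", {
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(name = c("D1", "D3"), reference_id = "X82502.1",
               start = c(20L, 1752L), end = c(148L, 2528L),
               coordinate_unit = c("residue", "nucleotide")),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  anns <- read_domains(f)
  expect_length(anns, 2L)
  expect_equal(anns[[2]]$end - anns[[2]]$start + 1L, 777L)
})
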