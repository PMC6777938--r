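test_that("read_fasta parses records, normalizes case, extracts species", {
  f <- write_temp_fasta(c(">x", "PVDLS"))
  p <- read_fasta(f)
  expect_equal(nrow(p), 1L)
  expect_equal(nchar(p$sequence), 5L)

  f <- write_temp_fasta(c(">x species=Strigamia_maritima extra", "pvdls"))
  p <- read_fasta(f)
  expect_equal(p$sequence, "PVDLS")
  expect_equal(p$species, "Strigamia_maritima")

  # wrapped lines + CRLF
  f <- write_temp_fasta(c(">y\r", "PVD\r", "LS\r"))
  expect_equal(read_fasta(f)$sequence, "PVDLS")

  ctx <- read_fasta(ext_fixture("survey_ctbp_contexts.fasta"))
  expect_equal(nrow(ctx), 35L)
  expect_true(all(nchar(ctx$sequence) == 15L))
})

test_that("read_fasta rejects empty files and non-residue characters", {
  f <- tempfile(); file.create(f)
  expect_error(read_fasta(f), "empty")
  f <- write_temp_fasta(c(">x", "PVXZLS"))
  expect_error(read_fasta(f), "position 3")
})

test_that("fasta write/read round-trips sequences and metadata", {
  set.seed(11)
  p <- protein_set(id = sprintf("p%02d", 1:20),
                   sequence = vapply(1:20, function(i)
                     random_peptide(sample(5:80, 1L)), ""),
                   species = sprintf("sp%d", 1:20),
                   region_boundary = c(rep(NA, 10), rep(3L, 10)))
  f <- tempfile(fileext = ".fasta")
  write_fasta(p, f, width = 17L)  # force wrapping
  expect_equal(read_fasta(f), p)
})

test_that("protein_set validates invariants", {
  expect_error(protein_set("x", ""), "empty")
  expect_error(protein_set("x", "PVDLS", region_boundary = 6L), "region_boundary")
  expect_silent(protein_set("x", "PVDLS", region_boundary = 5L))
})

test_that("read_gff_genes groups CDS in transcription order with family labels", {
  gff <- c("##gff-version 3",
           "s1\t.\tgene\t1\t21\t.\t+\t.\tID=gp;family=MTA",
           "s1\t.\tmRNA\t1\t21\t.\t+\t.\tID=gp.t1;Parent=gp",
           "s1\t.\tCDS\t1\t9\t.\t+\t0\tID=c1;Parent=gp.t1",
           "s1\t.\tCDS\t13\t21\t.\t+\t0\tID=c2;Parent=gp.t1",
           "s1\t.\tgene\t101\t121\t.\t-\t.\tID=gm;family=S-CAP",
           "s1\t.\tmRNA\t101\t121\t.\t-\t.\tID=gm.t1;Parent=gm",
           "s1\t.\tCDS\t101\t109\t.\t-\t0\tID=c3;Parent=gm.t1",
           "s1\t.\tCDS\t113\t121\t.\t-\t0\tID=c4;Parent=gm.t1")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  g <- read_gff_genes(f)
  expect_equal(g$gp$exons[, "start"], c(1L, 13L))      # plus: ascending
  expect_equal(cds_length(g$gp), 18L)
  expect_equal(g$gm$exons[, "start"], c(113L, 101L))   # minus: descending
  expect_equal(vapply(g, `[[`, "", "family"),
               c(gp = "MTA", gm = "S-CAP"))
  # missing scaffold in genome FASTA
  fa <- tempfile(fileext = ".fa")
  write_dna_fasta(c(other = "ACGT"), fa)
  expect_error(read_gff_genes(f, fa), "missing scaffold")
})

test_that("read_gff_genes warns on inconsistent phase and non-triplet CDS", {
  gff <- c("##gff-version 3",
           "s1\t.\tgene\t1\t21\t.\t+\t.\tID=g1",
           "s1\t.\tmRNA\t1\t21\t.\t+\t.\tID=g1.t1;Parent=g1",
           "s1\t.\tCDS\t1\t10\t.\t+\t0\tID=c1;Parent=g1.t1",
           "s1\t.\tCDS\t14\t21\t.\t+\t0\tID=c2;Parent=g1.t1")  # true phase 2
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  expect_warning(read_gff_genes(f), "phase")

  gff2 <- c("##gff-version 3",
            "s1\t.\tgene\t1\t10\t.\t+\t.\tID=g2",
            "s1\t.\tmRNA\t1\t10\t.\t+\t.\tID=g2.t1;Parent=g2",
            "s1\t.\tCDS\t1\t10\t.\t+\t0\tID=c1;Parent=g2.t1")
  f2 <- tempfile(fileext = ".gff3")
  writeLines(gff2, f2)
  expect_warning(read_gff_genes(f2), "not divisible by 3")
})

test_that("synthetic two-family annotation round-trips through GFF3", {
  gg <- gen_genes(
    c(scap = "MDSLKFFLGGRLVLKLNAQW", mta = "MELMSANTERW"),
    data.frame(gene_id = c("scap", "mta"), scaffold = "scaf1",
               strand = "+", family = c("S-CAP", "MTA")),
    introns = list(scap = data.frame(codon_index = 5L, phase = 2L)),
    seed = 0L)
  gff <- tempfile(fileext = ".gff3"); write_gff3(gg$genes, gff)
  fa <- tempfile(fileext = ".fa"); write_dna_fasta(gg$genome, fa)
  back <- read_gff_genes(gff, fa)
  expect_length(back, 2L)
  expect_equal(vapply(back, `[[`, "", "family"),
               c(scap = "S-CAP", mta = "MTA"))
  expect_equal(back$scap$exons, gg$genes$scap$exons)
  expect_equal(translate_cds(back$scap, gg$genome), "MDSLKFFLGGRLVLKLNAQW")
})

test_that("translate_cds honors strand and rejects internal stops", {
  genome <- c(s1 = "ATGGGTTAA")
  gm <- gene_model("g", "s1", "+", rbind(c(1, 9)))
  expect_equal(translate_cds(gm, genome), "MG")
  # same gene on the minus strand of the reverse-complemented scaffold
  genome_rc <- c(s1 = revcomp(genome[["s1"]]))
  gm_rc <- gene_model("g", "s1", "-", rbind(c(1, 9)))
  expect_equal(translate_cds(gm_rc, genome_rc), "MG")

  genome2 <- c(s1 = "ATGTAAGGTTAA")
  gm2 <- gene_model("g2", "s1", "+", rbind(c(1, 12)))
  expect_error(translate_cds(gm2, genome2), "codon index 2")
  expect_error(translate_cds(gene_model("g3", "s1", "+", rbind(c(1, 4))),
                             c(s1 = "ATGTT")), "divisible by 3")
})

test_that("translation is invariant to scaffold reverse-complementation", {
  for (seed in 1:25) {
    rg <- random_gene(seed)
    L <- nchar(rg$genome[[1]])
    flipped_genome <- setNames(revcomp(rg$genome[[1]]), names(rg$genome))
    flipped <- flip_gene(rg$model, L)
    expect_equal(translate_cds(flipped, flipped_genome),
                 translate_cds(rg$model, rg$genome))
    expect_equal(translate_cds(rg$model, rg$genome), rg$peptide)
  }
})

test_that("find_single_orf matches the spec examples", {
  expect_equal(find_single_orf("ATGTAA"), list(frame = 0L, peptide = "M"))
  expect_error(find_single_orf("ATGTAAATGTAA"), "no reading frame")
  smar <- load_constructs(ext_fixture("constructs.fasta"))[["SmarSuHex2-3_WT"]]
  orf <- find_single_orf(smar$insert_dna)
  expect_match(orf$peptide, "FADNHPVDLSNSHRG", fixed = TRUE)
})

test_that("find_single_orf agrees with a brute-force 3-frame scan", {
  set.seed(42)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  for (i in 1:1000) {
    insert <- paste0(
      paste(sample(c("A", "C", "G", "T"), sample(0:2, 1L), TRUE), collapse = ""),
      paste(sample(sense, sample(2:20, 1L), TRUE), collapse = ""),
      sample(stops, 1L),
      paste(sample(c("A", "C", "G", "T"), sample(0:8, 1L), TRUE), collapse = ""))
    expected <- orf_brute(insert)
    if (length(expected) == 1L) {
      expect_identical(find_single_orf(insert), expected[[1L]])
    } else {
      expect_error(find_single_orf(insert))
    }
  }
})
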