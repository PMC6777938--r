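# fixture paths and independent oracles shared across test files

ext_fixture <- function(f) {
  p <- system.file("extdata", f, package = "corecruit")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}

survey <- motif_survey(ext_fixture("motif_survey.tsv"))
models <- survey_motif_models(survey)

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# naive all-windows oracle for strict pattern scanning
naive_scan <- function(pattern, seq) {
  w <- length(pattern$columns)
  n <- nchar(seq)
  if (n < w) return(integer())
  Filter(function(st) {
    all(vapply(seq_len(w), function(j)
      substr(seq, st + j - 1L, st + j - 1L) %in% pattern$columns[[j]], NA))
  }, seq_len(n - w + 1L))
}

# brute-force minimum changes over all internal labelings (complete data)
fitch_brute <- function(tree, states) {
  nnode <- tree$Nnode
  leaf <- states[tree$tip.label]
  best <- Inf
  for (code in 0:(2^nnode - 1L)) {
    lab <- c(leaf, as.integer(intToBits(code))[seq_len(nnode)])
    best <- min(best, sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]]))
  }
  best
}

# brute-force frame analysis for find_single_orf
orf_brute <- function(insert) {
  insert <- toupper(insert)
  res <- list()
  for (f in 0:2) {
    n_cod <- (nchar(insert) - f) %/% 3L
    if (n_cod < 1L) next
    starts <- f + seq(1L, by = 3L, length.out = n_cod)
    aa <- unname(Biostrings::GENETIC_CODE[substring(insert, starts, starts + 2L)])
    if (sum(aa == "*") == 1L)
      res[[length(res) + 1L]] <- list(
        frame = f, peptide = paste(aa[seq_len(which(aa == "*") - 1L)],
                                   collapse = ""))
  }
  res
}

# brute-force coordinate walk: genomic positions of every CDS nucleotide
cds_walk <- function(model) {
  pos <- integer()
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1L]; e <- model$exons[i, 2L]
    pos <- c(pos, if (model$strand == "+") s:e else e:s)
  }
  pos
}

# mirror a gene model onto the reverse-complemented scaffold
flip_gene <- function(model, scaffold_len) {
  gene_model(model$gene_id, model$scaffold,
             if (model$strand == "+") "-" else "+",
             cbind(scaffold_len - model$exons[, 2L] + 1L,
                   scaffold_len - model$exons[, 1L] + 1L),
             protein_id = model$protein_id, family = model$family)
}

random_peptide <- function(n) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], character()),
               n, replace = TRUE), collapse = "")
}

# random multi-exon gene via the generator, with its ground-truth marks
random_gene <- function(seed, strand = sample(c("+", "-"), 1L)) {
  set.seed(seed)
  len <- sample(20:60, 1L)
  pep <- random_peptide(len)
  n_introns <- sample(0:3, 1L)
  marks <- if (n_introns > 0L) {
    ci <- sort(sample(2:(len - 1L), n_introns))
    data.frame(codon_index = ci, phase = sample(0:2, n_introns, replace = TRUE))
  } else data.frame(codon_index = integer(), phase = integer())
  gg <- gen_genes(setNames(pep, "g"),
                  data.frame(gene_id = "g", scaffold = "sc", strand = strand,
                             family = "fam"),
                  introns = list(g = marks), seed = seed)
  list(model = gg$genes$g, genome = gg$genome, peptide = pep, marks = marks)
}
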