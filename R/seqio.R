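AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a set of protein records
#'
#' A `protein_set` is the package's container for protein sequences: a
#' data frame with one row per protein and columns `id`, `species`,
#' `sequence` (uppercase, 20-letter amino-acid alphabet) and
#' `region_boundary`. The boundary, when set, is the 1-based index of the
#' last residue of the non-conserved N-terminal region that is scanned
#' for co-repressor recruitment motifs; hits beyond it are still reported
#' but flagged.
#'
#' @param id character vector of identifiers.
#' @param sequence character vector of residue strings (case-insensitive).
#' @param species character vector of species tags (recycled; default "").
#' @param region_boundary integer vector (recycled; `NA` = no boundary).
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id, sequence, species = "", region_boundary = NA_integer_) {
  x <- data.frame(id = unname(as.character(id)),
                  species = unname(as.character(species)),
                  sequence = unname(toupper(sequence)),
                  region_boundary = unname(as.integer(region_boundary)),
                  stringsAsFactors = FALSE)
  validate_protein_set(x)
}

#' @rdname protein_set
#' @export
protein_record <- function(id, sequence, species = "", region_boundary = NA_integer_) {
  protein_set(id, sequence, species, region_boundary)
}

validate_protein_set <- function(x) {
  if (any(!nzchar(x$sequence)))
    stop("protein_set: empty sequence for id '",
         x$id[!nzchar(x$sequence)][1L], "'")
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x$sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("protein_set: invalid residue '",
         substr(x$sequence[i], bad[i], bad[i]), "' at position ", bad[i],
         " in '", x$id[i], "'")
  }
  rb <- x$region_boundary
  n <- nchar(x$sequence)
  if (any(!is.na(rb) & (rb < 1L | rb > n)))
    stop("protein_set: region_boundary out of [1, length]")
  class(x) <- c("protein_set", "data.frame")
  x
}

parse_fasta_description <- function(desc) {
  toks <- strsplit(trimws(desc), "[ \t]+")[[1L]]
  id <- toks[1L]
  kv <- toks[-1L][grepl("=", toks[-1L], fixed = TRUE)]
  get <- function(key) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
  }
  species <- get("species")
  rb <- suppressWarnings(as.integer(get("region_boundary")))
  list(id = id,
       species = if (is.na(species)) "" else species,
       region_boundary = rb)
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each description line is the
#' record id; `species=` and `region_boundary=` key=value tokens are
#' recognized. Sequences are uppercased and validated against the
#' 20-letter amino-acid alphabet. Wrapped lines and CRLF endings are
#' tolerated.
#'
#' @param path FASTA file of protein sequences.
#' @return A [protein_set].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  meta <- lapply(names(x), parse_fasta_description)
  protein_set(id = vapply(meta, `[[`, "", "id"),
              sequence = as.character(x),
              species = vapply(meta, `[[`, "", "species"),
              region_boundary = vapply(meta, `[[`, NA_integer_, "region_boundary"))
}

#' Write a protein_set to FASTA
#'
#' Inverse of [read_fasta()]: species and region boundary are emitted as
#' key=value tokens on the description line so a round trip preserves
#' them.
#'
#' @param proteins a [protein_set].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(proteins)), function(i) {
    hdr <- paste0(">", proteins$id[i])
    if (nzchar(proteins$species[i]))
      hdr <- paste0(hdr, " species=", proteins$species[i])
    if (!is.na(proteins$region_boundary[i]))
      hdr <- paste0(hdr, " region_boundary=", proteins$region_boundary[i])
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read scaffold (nucleotide) sequences from FASTA
#'
#' @param path FASTA file.
#' @param preserve_case keep the case of the input (used for printed
#'   primer/insert fixtures where case encodes annotation); default
#'   uppercases.
#' @return Named character vector of sequences; names are the first
#'   description token.
#' @export
read_dna_fasta <- function(path, preserve_case = FALSE) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  out <- as.character(x)
  if (!preserve_case) out <- toupper(out)
  names(out) <- vapply(strsplit(names(x), "[ \t]+"),
                       `[[`, "", 1L)
  out
}

#' Write nucleotide sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_dna_fasta <- function(seqs, path, width = 60L) {
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", nm),
      substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' Case-preserving (lowercase annotation in printed primers survives).
#'
#' @param x character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Translate a DNA string with the standard genetic code
#'
#' Length must be a multiple of 3; ambiguity codes are rejected. Stops
#' are returned as `*` (callers decide how to treat them).
#'
#' @param dna a single DNA string (case-insensitive).
#' @return Character vector of single-letter residues, one per codon.
#' @keywords internal
translate_codons <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  if (grepl("[^ACGT]", dna)) stop("non-ACGT character in coding sequence")
  starts <- seq(1L, n, by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(dna, starts, starts + 2L)])
  aa
}

#' Construct a gene model
#'
#' A `gene_model` holds the ordered CDS exon intervals of one
#' protein-coding gene: genomic 1-based inclusive coordinates (GFF3
#' convention) in *transcription* order, so on the minus strand exon
#' starts decrease. Exons must not overlap.
#'
#' @param gene_id text id.
#' @param scaffold scaffold/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of CDS intervals in
#'   transcription order, or a data frame with `start`/`end`.
#' @param protein_id id of the encoded protein (optional).
#' @param family gene-family label such as `"MTA"`, `"Hairless"`,
#'   `"S-CAP"` (optional).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, strand, exons,
                       protein_id = NA_character_, family = NA_character_) {
  if (is.data.frame(exons)) exons <- cbind(exons$start, exons$end)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons[, 1L] > exons[, 2L])) stop("exon start > end")
  o <- order(exons[, 1L])
  starts <- exons[o, 1L]; ends <- exons[o, 2L]
  if (nrow(exons) > 1L && any(starts[-1L] <= ends[-nrow(exons)]))
    stop("overlapping exons in gene '", gene_id, "'")
  # enforce transcription order
  expected <- if (strand == "+") order(exons[, 1L]) else order(-exons[, 1L])
  if (!identical(expected, seq_len(nrow(exons)))) exons <- exons[expected, , drop = FALSE]
  x <- list(gene_id = as.character(gene_id), scaffold = as.character(scaffold),
            strand = strand, exons = exons,
            protein_id = as.character(protein_id), family = as.character(family))
  class(x) <- "gene_model"
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$gene_id, " [", x$scaffold, x$strand, "] ",
      nrow(x$exons), " CDS exon(s), CDS length ", cds_length(x),
      if (!is.na(x$family)) paste0(", family ", x$family), "\n", sep = "")
  invisible(x)
}

#' Total CDS length of a gene model (nt)
#' @param model a [gene_model].
#' @return Integer number of coding nucleotides.
#' @export
cds_length <- function(model) {
  sum(model$exons[, 2L] - model$exons[, 1L] + 1L)
}

#' Read protein-coding gene models from GFF3
#'
#' CDS features are grouped per gene (via their mRNA parent where
#' present) and ordered in transcription order. A gene-family label is
#' read from a configurable attribute key, and the stated GFF3 phase
#' column is checked against the phase implied by cumulative CDS length
#' (mismatches trigger a warning; the recomputed phase wins). A total CDS
#' length not divisible by 3 is flagged with a warning.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @param fasta optional scaffold FASTA; when given, every CDS scaffold
#'   must be present in it.
#' @param family_key attribute key carrying the family label.
#' @return Named list of [gene_model] objects.
#' @export
read_gff_genes <- function(path, fasta = NULL, family_key = "family") {
  g <- as.data.frame(rtracklayer::readGFF(path))
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, "")
  g$parent1 <- if ("Parent" %in% names(g)) first_parent(g$Parent) else NA_character_
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in ", path)
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  gene <- g[g$type == "gene", , drop = FALSE]
  # resolve each CDS to a gene id: CDS -> mRNA -> gene, else direct parent
  mrna_gene <- stats::setNames(mrna$parent1, mrna$ID)
  gid <- ifelse(cds$parent1 %in% names(mrna_gene),
                unname(mrna_gene[cds$parent1]), cds$parent1)
  gid[is.na(gid)] <- cds$ID[is.na(gid)]
  scaffolds <- NULL
  if (!is.null(fasta)) scaffolds <- read_dna_fasta(fasta)

  attr_of <- function(df, ids, key) {
    if (!key %in% names(df)) return(rep(NA_character_, length(ids)))
    v <- df[[key]]
    if (is.list(v)) v <- first_parent(v)
    stats::setNames(as.character(v), df$ID)[ids]
  }
  out <- list()
  for (id in unique(gid)) {
    rows <- cds[gid == id, , drop = FALSE]
    scaf <- as.character(rows$seqid[1L])
    strand <- as.character(rows$strand[1L])
    if (!is.null(scaffolds) && !scaf %in% names(scaffolds))
      stop("CDS of gene '", id, "' references missing scaffold '", scaf, "'")
    gm <- gene_model(id, scaf, strand,
                     cbind(rows$start, rows$end),
                     protein_id = {
                       pid <- unname(attr_of(rows, rows$ID[1L], "protein_id"))
                       if (is.na(pid))
                         pid <- unname(attr_of(mrna, rows$parent1[1L],
                                               "protein_id"))
                       if (is.na(pid)) rows$parent1[1L] else pid
                     },
                     family = {
                       fam <- unname(attr_of(gene, id, family_key))
                       if (is.na(fam)) fam <- unname(attr_of(mrna, rows$parent1[1L], family_key))
                       if (is.na(fam) && family_key %in% names(rows))
                         fam <- as.character(rows[[family_key]][1L])
                       fam
                     })
    # phase check against cumulative CDS length (GFF3 frame-restoration phase)
    if ("phase" %in% names(rows) && !all(is.na(rows$phase))) {
      ord <- if (strand == "+") order(rows$start) else order(-rows$start)
      stated <- suppressWarnings(as.integer(rows$phase[ord]))
      lens <- rows$end[ord] - rows$start[ord] + 1L
      expected <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
      expected <- (3L - expected) %% 3L  # GFF3: bases to remove to reach a codon start
      expected[1L] <- 0L
      if (any(!is.na(stated) & stated != expected))
        warning("gene '", id, "': GFF3 phase column inconsistent with ",
                "cumulative CDS length; recomputed phases used")
    }
    if (cds_length(gm) %% 3L != 0L)
      warning("gene '", id, "': CDS length ", cds_length(gm),
              " not divisible by 3")
    out[[id]] <- gm
  }
  out
}

#' Spliced CDS sequence of a gene model
#'
#' Exon sequences are extracted in transcription order;
#' minus-strand exons are reverse-complemented.
#'
#' @param model a [gene_model].
#' @param genome named character vector of scaffold sequences.
#' @return A single DNA string (the mRNA coding sequence).
#' @export
spliced_cds <- function(model, genome) {
  genome <- as_genome(genome)
  if (!model$scaffold %in% names(genome))
    stop("scaffold '", model$scaffold, "' not found in genome")
  scaf <- genome[[model$scaffold]]
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- substr(scaf, model$exons[i, 1L], model$exons[i, 2L])
    if (model$strand == "-") revcomp(s) else s
  }, "")
  paste(pieces, collapse = "")
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    out <- as.character(genome)
    names(out) <- vapply(strsplit(names(genome), "[ \t]+"), `[[`, "", 1L)
    return(out)
  }
  genome
}

#' Translate the CDS of a gene model
#'
#' Standard genetic code; minus-strand exons are reverse-complemented
#' before translation; the trailing stop codon is stripped. An internal
#' stop codon is an error naming the codon index.
#'
#' @param model a [gene_model].
#' @param genome named character vector (or `DNAStringSet`) of scaffolds.
#' @return The translated protein as a single residue string.
#' @export
translate_cds <- function(model, genome) {
  cds <- spliced_cds(model, genome)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  aa <- translate_codons(cds)
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  stop_at <- which(aa == "*")
  if (length(stop_at))
    stop("internal stop codon at codon index ", stop_at[1L],
         " in gene '", model$gene_id, "'")
  paste(aa, collapse = "")
}

#' Find the unique single-stop reading frame of an insert
#'
#' Expression-construct inserts printed with their cloning-site tails
#' carry the biological peptide followed by one stop codon and then a
#' few vector codons. The qualifying frame is the one whose
#' complete-codon translation contains exactly one stop codon; the
#' peptide is everything upstream of that stop. Zero qualifying frames,
#' or more than one, is an error (the ambiguous case reports all
#' qualifying frames).
#'
#' @param insert forward-strand nucleotide string.
#' @return A list with `frame` (0, 1 or 2) and `peptide`.
#' @export
find_single_orf <- function(insert) {
  insert <- toupper(insert)
  if (grepl("[^ACGT]", insert)) stop("non-ACGT character in insert")
  cands <- list()
  for (f in 0:2) {
    n_cod <- (nchar(insert) - f) %/% 3L
    if (n_cod < 1L) next
    aa <- translate_codons(substr(insert, f + 1L, f + 3L * n_cod))
    if (sum(aa == "*") == 1L) {
      stop_at <- which(aa == "*")
      cands[[length(cands) + 1L]] <-
        list(frame = f,
             peptide = paste(aa[seq_len(stop_at - 1L)], collapse = ""))
    }
  }
  if (length(cands) == 0L)
    stop("no reading frame with exactly one stop codon")
  if (length(cands) > 1L)
    stop("ambiguous insert: frames ",
         paste(vapply(cands, `[[`, 0L, "frame"), collapse = ", "),
         " each contain exactly one stop codon")
  cands[[1L]]
}
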