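#' Construct an expression-construct record
#'
#' Holds one printed expression-construct insert: the forward-strand
#' nucleotide sequence as printed (case preserved; lowercase marks
#' engineered positions in some fixtures), the stated residue range of
#' the encoded fragment in full-protein coordinates when the source
#' states one (e.g. amino acids 192-389), and the wild-type/mutant role.
#'
#' @param name construct name.
#' @param insert_dna nucleotide string as printed.
#' @param stated_range optional length-2 integer vector
#'   `(first_residue, last_residue)`.
#' @param role `"wild_type"` or `"mutant"`.
#' @param pair grouping key linking a WT/mutant pair.
#' @return An object of class `construct_record`.
#' @export
construct_record <- function(name, insert_dna, stated_range = NULL,
                             role = c("wild_type", "mutant"), pair = name) {
  role <- match.arg(role)
  if (!is.null(stated_range)) {
    stated_range <- as.integer(stated_range)
    if (length(stated_range) != 2L || stated_range[2L] < stated_range[1L])
      stop("stated_range must be (first, last) with last >= first")
  }
  structure(list(name = name, insert_dna = insert_dna,
                 stated_range = stated_range, role = role, pair = pair),
            class = "construct_record")
}

#' Load the packaged expression-construct inserts
#'
#' Six His-tag fusion inserts as printed (three wild-type/mutant pairs:
#' a centipede Su(H) exon 2-3 fragment, a fly Hairless 192-389 fragment,
#' and a spider S-CAP 233-432 fragment), with stated residue ranges and
#' roles parsed from the FASTA description key=value tokens.
#'
#' @param path FASTA of inserts; defaults to the packaged fixture.
#' @return Named list of [construct_record]s.
#' @export
load_constructs <- function(path = system.file("extdata", "constructs.fasta",
                                               package = "corecruit")) {
  x <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(x), function(i) {
    toks <- strsplit(names(x)[i], "[ \t]+")[[1L]]
    kv <- toks[-1L]
    get <- function(key) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
    }
    rng <- get("range")
    construct_record(
      name = toks[1L], insert_dna = as.character(x[[i]]),
      stated_range = if (!is.na(rng)) as.integer(strsplit(rng, "-")[[1L]]),
      role = if (identical(get("role"), "mutant")) "mutant" else "wild_type",
      pair = if (is.na(get("pair"))) toks[1L] else get("pair"))
  })
  setNames(out, vapply(out, `[[`, "", "name"))
}

#' Load the packaged primer sequences
#'
#' The printed amplification primers, case preserved as printed
#' (case distinguishes adapter/mutagenic from template-matching
#' segments in the source).
#'
#' @param path FASTA of primers; defaults to the packaged fixture.
#' @return Named character vector.
#' @export
load_primers <- function(path = system.file("extdata", "primers.fasta",
                                            package = "corecruit")) {
  read_dna_fasta(path, preserve_case = TRUE)
}

#' Translate a construct insert
#'
#' The peptide upstream of the unique terminal stop codon, including any
#' vector-linker residues at the N terminus (the linker is not stripped;
#' downstream operations anchor coordinates on the stop).
#'
#' @param construct a [construct_record].
#' @return The peptide as a residue string.
#' @export
construct_peptide <- function(construct) {
  find_single_orf(construct$insert_dna)$peptide
}

#' Count designed substitutions between a WT/mutant construct pair
#'
#' Protein-level Hamming distance between the two translated peptides
#' (silent codon differences are invisible by construction). Unequal
#' peptide lengths signal a frame or transcription error and are an
#' error.
#'
#' @param wt,mut [construct_record]s (or already-translated peptides).
#' @return A list with `n` and `substitutions` (data frame `position`,
#'   `wt`, `mut`, sorted by position; positions are peptide 1-based).
#' @export
substitution_count <- function(wt, mut) {
  pw <- if (inherits(wt, "construct_record")) construct_peptide(wt) else wt
  pm <- if (inherits(mut, "construct_record")) construct_peptide(mut) else mut
  if (nchar(pw) != nchar(pm))
    stop("peptides have unequal lengths (", nchar(pw), " vs ", nchar(pm),
         "): frame or transcription error")
  a <- strsplit(pw, "", fixed = TRUE)[[1L]]
  b <- strsplit(pm, "", fixed = TRUE)[[1L]]
  d <- which(a != b)
  list(n = length(d),
       substitutions = data.frame(position = d, wt = a[d], mut = b[d],
                                  stringsAsFactors = FALSE))
}

#' Map construct peptide positions to full-protein coordinates
#'
#' The printed inserts carry an unprinted vector linker at the N
#' terminus, so coordinates are anchored at the C terminus: the last
#' residue before the stop is assigned the `last_residue` of the stated
#' range and coordinates decrease toward the N terminus. Linker residues
#' receive coordinates below `first_residue` and are flagged.
#'
#' @param construct a [construct_record] with `stated_range` set.
#' @param peptide its peptide (computed if omitted).
#' @return Data frame `peptide_index`, `coordinate`, `linker`.
#' @export
anchor_coordinates <- function(construct, peptide = NULL) {
  if (is.null(construct$stated_range))
    stop("construct '", construct$name, "' has no stated residue range")
  if (is.null(peptide)) peptide <- construct_peptide(construct)
  first <- construct$stated_range[1L]; last <- construct$stated_range[2L]
  n <- nchar(peptide)
  if (n < last - first + 1L)
    stop("peptide (", n, " aa) shorter than stated range span (",
         last - first + 1L, " aa)")
  coord <- last - (n - seq_len(n))
  data.frame(peptide_index = seq_len(n), coordinate = coord,
             linker = coord < first)
}

#' Replacement peptide encoded by a mutagenic reverse primer
#'
#' Reverse-complements the primer, translates the unique reading frame
#' containing a single stop codon, and returns the residues between the
#' end of the template-derived block and the stop -- the sequence the
#' primer splices onto the template's C terminus. The template block is
#' located by its trailing residues (`template_tail`), the last
#' template-encoded amino acids shared by all primers of a mutagenesis
#' series; the default `"GPM"` is the C terminus of the truncated
#' helix-loop-helix template used in the packaged fixtures.
#'
#' @param reverse_primer primer nucleotide string (case ignored).
#' @param template_tail residue string ending the template-derived
#'   block.
#' @return The replacement residue string (may be empty for a pure
#'   truncation primer).
#' @export
primer_replacement_peptide <- function(reverse_primer, template_tail = "GPM") {
  sense <- toupper(revcomp(reverse_primer))
  orf <- tryCatch(find_single_orf(sense), error = function(e)
    stop("no unambiguous in-frame stop codon on the primer's reverse ",
         "complement: ", conditionMessage(e)))
  pep <- orf$peptide
  at <- max(gregexpr(template_tail, pep, fixed = TRUE)[[1L]])
  if (at < 0L)
    stop("template tail '", template_tail, "' not found in primer translation '",
         pep, "'")
  substring(pep, at + nchar(template_tail), nchar(pep))
}

#' Verify a set of printed construct pairs
#'
#' For every WT/mutant pair: translates both inserts, checks equal
#' peptide length, counts substitutions, reports whether all
#' substitutions are to alanine, and (when a stated range is present)
#' the anchored full-protein coordinates of the substituted positions.
#'
#' @param constructs named list of [construct_record]s
#'   (default: the packaged fixtures).
#' @return A list, one element per pair, JSON-serializable.
#' @export
verify_constructs <- function(constructs = load_constructs()) {
  pairs <- split(constructs, vapply(constructs, `[[`, "", "pair"))
  lapply(pairs, function(p) {
    roles <- vapply(p, `[[`, "", "role")
    wt <- p[[which(roles == "wild_type")[1L]]]
    mut <- p[[which(roles == "mutant")[1L]]]
    pep <- construct_peptide(wt)
    sub <- substitution_count(wt, mut)
    out <- list(pair = wt$pair, peptide_length = nchar(pep),
                n_substitutions = sub$n,
                all_to_alanine = all(sub$substitutions$mut == "A"),
                substitutions = sub$substitutions)
    if (!is.null(wt$stated_range)) {
      map <- anchor_coordinates(wt, pep)
      out$substitution_coordinates <-
        map$coordinate[match(sub$substitutions$position, map$peptide_index)]
      out$stated_range <- wt$stated_range
      out$linker_length <- sum(map$linker)
    }
    out
  })
}
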