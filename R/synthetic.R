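#' Consensus sequence of a PSSM
#'
#' @param pssm a [build_pssm()] result.
#' @return Residue string of per-column score maxima.
#' @export
pssm_consensus <- function(pssm) {
  paste(rownames(pssm$scores)[apply(pssm$scores, 2L, which.max)],
        collapse = "")
}

random_residues <- function(n, background = NULL) {
  p <- if (is.null(background)) rep(1 / 20, 20L) else background[AA_ALPHABET]
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic proteome with planted motif instances
#'
#' Background residues are drawn i.i.d. from the stated composition;
#' one motif instance is planted per flagged species at a controlled
#' similarity to the consensus: `"consensus"` (per-column maximum),
#' `"training"` (a training instance drawn at random), or `"decoy"`
#' (a random window rejection-sampled to score at least `decoy_margin`
#' bits below the threshold, so it must not be recovered at the default
#' cutoff). A ground-truth table records what was planted where, with
#' its PSSM score computed at generation time.
#'
#' @param pssm motif model used for planting and truth scores.
#' @param n number of proteins.
#' @param length protein length.
#' @param plant `"consensus"`, `"training"` or `"decoy"`.
#' @param present logical vector (recycled): plant in this protein?
#' @param background named residue frequency vector (default uniform).
#' @param decoy_margin bits below threshold required of a decoy.
#' @param seed mandatory RNG seed (no implicit randomness).
#' @return List with `proteins` (a [protein_set]) and `truth` (data
#'   frame `id`, `start`, `end`, `instance`, `score`, `planted`).
#' @export
gen_proteome <- function(pssm, n = 10L, length = 150L,
                         plant = c("consensus", "training", "decoy"),
                         present = TRUE, background = NULL,
                         decoy_margin = 2, seed = 0L) {
  plant <- match.arg(plant)
  set.seed(seed)
  w <- pssm$width
  if (w > length) stop("planted motif longer than sequence")
  present <- rep_len(present, n)
  score_one <- function(inst) pssm_window_scores(pssm, inst)[1L]
  draw_instance <- function() {
    switch(plant,
      consensus = pssm_consensus(pssm),
      training = sample(pssm$training, 1L),
      decoy = {
        repeat {
          cand <- random_residues(w, background)
          if (score_one(cand) <= pssm$threshold - decoy_margin) break
        }
        cand
      })
  }
  ids <- sprintf("synthsp%02d", seq_len(n))
  seqs <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    s <- random_residues(length, background)
    if (present[i]) {
      inst <- draw_instance()
      at <- sample.int(length - w + 1L, 1L)
      s <- paste0(substr(s, 1L, at - 1L), inst,
                  substr(s, at + w, length))
      truth[[length(truth) + 1L]] <- data.frame(
        id = ids[i], start = at, end = at + w - 1L, instance = inst,
        score = score_one(inst), planted = plant, stringsAsFactors = FALSE)
    }
    seqs[i] <- s
  }
  truth <- if (length(truth))
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else data.frame(id = character(), start = integer(), end = integer(),
                  instance = character(), score = numeric(),
                  planted = character(), stringsAsFactors = FALSE)
  list(proteins = protein_set(id = ids, sequence = seqs, species = ids),
       truth = truth)
}

#' Reverse-translate a peptide with random synonymous codons
#'
#' @param peptide residue string.
#' @param stop_codon appended stop (default `"TAA"`; `NULL` for none).
#' @return A DNA string encoding the peptide.
#' @export
reverse_translate <- function(peptide, stop_codon = "TAA") {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(by_aa))
  if (length(bad)) stop("cannot encode residue '", bad[1L], "'")
  codons <- vapply(res, function(a) {
    cs <- by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), stop_codon %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate gene models (scaffolds + GFF3-style annotation) from peptides
#'
#' Each peptide is reverse-translated (random synonymous codons, TAA
#' stop appended) and split into exons at the requested junction marks,
#' given as (codon_index, phase) pairs in protein coordinates with the
#' motif-interruption phase convention of [junctions_in_window()].
#' Genes are laid out on scaffolds per `layout` (order, strand, family),
#' separated by random intergenic spacers. By construction the CDSs
#' translate back to the input peptides exactly and the junction and
#' adjacency ground truth is known.
#'
#' @param peptides named character vector of protein sequences.
#' @param layout data frame `gene_id`, `scaffold`, `strand`, `family`
#'   (one row per peptide, in the order genes appear on each scaffold);
#'   `gene_id` must match `names(peptides)`.
#' @param introns named list (by gene_id) of data frames
#'   `codon_index`, `phase`; missing/empty entries give single-exon
#'   genes.
#' @param intron_len,intergenic_len base lengths of the random intron
#'   and spacer sequences.
#' @param seed mandatory RNG seed.
#' @return List with `genome` (named character), `genes` (named list of
#'   [gene_model]), `truth` (the junction marks and layout as given).
#' @export
gen_genes <- function(peptides, layout, introns = list(),
                      intron_len = 60L, intergenic_len = 200L, seed = 0L) {
  set.seed(seed)
  stopifnot(all(layout$gene_id %in% names(peptides)))
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  genome <- character()
  genes <- list()
  for (scaf in unique(layout$scaffold)) {
    rows <- layout[layout$scaffold == scaf, , drop = FALSE]
    seq_parts <- character()
    cursor <- 0L
    for (r in seq_len(nrow(rows))) {
      gid <- rows$gene_id[r]
      cds <- reverse_translate(peptides[[gid]])
      marks <- introns[[gid]]
      cuts <- integer()
      if (!is.null(marks) && nrow(marks) > 0L) {
        cuts <- sort(3L * (marks$codon_index - 1L) + marks$phase)
        if (any(cuts <= 0L | cuts >= nchar(cds)))
          stop("junction outside CDS for gene '", gid, "'")
      }
      bounds <- c(0L, cuts, nchar(cds))
      pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
      block <- pieces[1L]
      local_exons <- matrix(c(1L, nchar(pieces[1L])), ncol = 2L)
      for (p in seq_along(pieces)[-1L]) {
        intr <- paste0("GT", rand_dna(intron_len - 4L), "AG")
        st <- nchar(block) + nchar(intr) + 1L
        block <- paste0(block, intr, pieces[p])
        local_exons <- rbind(local_exons, c(st, st + nchar(pieces[p]) - 1L))
      }
      strand <- rows$strand[r]
      if (strand == "-") {
        block <- revcomp(block)
        bl <- nchar(block)
        local_exons <- cbind(bl - local_exons[, 2L] + 1L,
                             bl - local_exons[, 1L] + 1L)
      }
      spacer <- rand_dna(intergenic_len + sample.int(50L, 1L))
      seq_parts <- c(seq_parts, spacer, block)
      offset <- cursor + nchar(spacer)
      cursor <- offset + nchar(block)
      genes[[gid]] <- gene_model(gid, scaf, strand, local_exons + offset,
                                 protein_id = gid, family = rows$family[r])
    }
    seq_parts <- c(seq_parts, rand_dna(intergenic_len))
    genome[[scaf]] <- paste(seq_parts, collapse = "")
  }
  list(genome = genome, genes = genes,
       truth = list(junctions = introns, layout = layout))
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS rows with `ID`/`Parent` links, the family label
#' under the given attribute key, and the GFF3 frame-restoration phase
#' recomputed from cumulative CDS length.
#'
#' @param genes list of [gene_model]s.
#' @param path output file.
#' @param family_key attribute key for the family label.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, family_key = "family") {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- gene_span(g)
    fam <- if (!is.na(g$family)) paste0(";", family_key, "=", g$family) else ""
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      paste(g$scaffold, "corecruit", "gene", span["start"], span["end"], ".",
            g$strand, ".", paste0("ID=", g$gene_id, fam), sep = "\t"),
      paste(g$scaffold, "corecruit", "mRNA", span["start"], span["end"], ".",
            g$strand, ".",
            paste0("ID=", mid, ";Parent=", g$gene_id,
                   ";protein_id=", g$protein_id), sep = "\t"))
    lens <- g$exons[, 2L] - g$exons[, 1L] + 1L
    upstream <- c(0L, cumsum(lens)[-length(lens)])
    phase <- (3L - upstream %% 3L) %% 3L
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines,
        paste(g$scaffold, "corecruit", "CDS", g$exons[i, 1L], g$exons[i, 2L],
              ".", g$strand, phase[i],
              paste0("ID=", mid, ".cds;Parent=", mid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Evolve a binary character on a tree from stated events
#'
#' Starts in state 0 at the root and propagates root-to-tips, toggling
#' at the stated gain/loss branches (a branch is named by its child
#' node: a tip label, an internal node label, or an ape node number). A
#' gain on an already-1 background or a loss on 0 is inconsistent and
#' rejected.
#'
#' @param tree `ape::phylo`.
#' @param events data frame `node`, `type` (`"gain"`/`"loss"`); zero
#'   rows give all-0 leaves.
#' @return List with `states` (named leaf vector) and `node_states`.
#' @export
gen_characters <- function(tree, events = data.frame(node = character(),
                                                     type = character())) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && length(tree$node.label) == nnode)
                tree$node.label else paste0("node", seq_len(nnode) + ntip))
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, labels)
    if (is.na(i)) stop("unknown node '", x, "'")
    i
  }
  ev <- setNames(rep(NA_character_, ntip + nnode), NULL)
  if (nrow(events))
    ev[vapply(events$node, resolve, 0L)] <- as.character(events$type)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  state <- integer(ntip + nnode)
  root <- ntip + 1L
  if (!is.na(ev[root])) {  # event on the root stem applies to the whole tree
    if (ev[root] == "loss") stop("loss before gain on the path to the root")
    state[root] <- 1L
  }
  for (k in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    s <- state[p]
    if (!is.na(ev[ch])) {
      if (ev[ch] == "gain") {
        if (s == 1L) stop("gain on a branch already in state 1 (node ",
                          labels[ch], ")")
        s <- 1L
      } else {
        if (s == 0L) stop("loss before gain on the path to node ",
                          labels[ch])
        s <- 0L
      }
    }
    state[ch] <- s
  }
  list(states = setNames(state[seq_len(ntip)], tree$tip.label),
       node_states = setNames(state, labels))
}
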