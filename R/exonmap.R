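#' @noRd
#' Per-exon CDS coordinate bookkeeping: for each exon in transcription
#' order, the CDS positions it covers and its genomic anchor.
cds_segments <- function(model) {
  lens <- model$exons[, 2L] - model$exons[, 1L] + 1L
  cum <- cumsum(lens)
  data.frame(gstart = model$exons[, 1L], gend = model$exons[, 2L],
             len = lens,
             cds_from = c(1L, cum[-length(cum)] + 1L),
             cds_to = cum)
}

#' Map CDS nucleotide positions to genomic coordinates
#'
#' @param model a [gene_model].
#' @param cds_pos integer vector of 1-based positions in the spliced CDS.
#' @return Integer vector of genomic coordinates (same length).
#' @export
cds_to_genomic <- function(model, cds_pos) {
  seg <- cds_segments(model)
  total <- seg$cds_to[nrow(seg)]
  if (any(cds_pos < 1L | cds_pos > total)) stop("CDS position out of range")
  idx <- findInterval(cds_pos, seg$cds_from)
  off <- cds_pos - seg$cds_from[idx]
  if (model$strand == "+") seg$gstart[idx] + off else seg$gend[idx] - off
}

#' Map a genomic coordinate back to a protein residue
#'
#' @param model a [gene_model].
#' @param gpos genomic coordinate (must fall in a CDS exon).
#' @return A list with `residue` (1-based index) and `codon_offset`
#'   (1, 2 or 3: position within the codon).
#' @export
genomic_to_protein <- function(model, gpos) {
  seg <- cds_segments(model)
  hit <- which(gpos >= seg$gstart & gpos <= seg$gend)
  if (length(hit) != 1L) stop("genomic position ", gpos, " not in any CDS exon")
  cds <- if (model$strand == "+") seg$cds_from[hit] + (gpos - seg$gstart[hit])
         else seg$cds_from[hit] + (seg$gend[hit] - gpos)
  list(residue = (cds - 1L) %/% 3L + 1L, codon_offset = (cds - 1L) %% 3L + 1L)
}

#' Genomic interval(s) of one codon
#'
#' Returns the 1 or 2 genomic intervals (totalling 3 bases) occupied by
#' the codon of a protein residue; two intervals when the codon
#' straddles a splice junction. Intervals are reported with
#' `start <= end` regardless of strand, in transcription order.
#'
#' @param model a [gene_model].
#' @param residue_index 1-based residue position in the translated CDS.
#' @return Data frame with columns `start`, `end`.
#' @export
protein_to_genomic <- function(model, residue_index) {
  n_res <- cds_length(model) %/% 3L
  if (residue_index < 1L || residue_index > n_res)
    stop("residue index ", residue_index, " out of range [1, ", n_res, "]")
  g <- cds_to_genomic(model, (3L * residue_index - 2L):(3L * residue_index))
  step <- if (model$strand == "+") 1L else -1L
  breaks <- which(diff(g) != step)
  runs <- cbind(c(1L, breaks + 1L), c(breaks, 3L))
  data.frame(start = pmin(g[runs[, 1L]], g[runs[, 2L]]),
             end = pmax(g[runs[, 1L]], g[runs[, 2L]]))
}

#' Splice junctions inside a protein window
#'
#' For every intron of the gene model whose junction falls inside the
#' window's codon span, reports the junction in motif-relative codon
#' coordinates. The phase is the number of nucleotides of the
#' interrupted codon lying on the *upstream* exon: phase 0 means the
#' junction falls exactly between codons and is assigned to the
#' following codon index, so `motif_codon_index` can reach window width
#' + 1 (a junction immediately after the window's last codon). Note this
#' motif-interruption phase is not the GFF3 CDS phase column (which
#' counts bases to the next codon start); the two are related by
#' `gff3_phase = (3 - phase) %% 3`.
#'
#' @param model a [gene_model].
#' @param start_residue,end_residue 1-based window bounds in protein
#'   coordinates.
#' @return Data frame with columns `motif_codon_index`, `phase`
#'   (zero rows for a single-exon gene or a junction-free window).
#' @export
junctions_in_window <- function(model, start_residue, end_residue) {
  n_res <- cds_length(model) %/% 3L
  if (start_residue < 1L || end_residue > n_res || start_residue > end_residue)
    stop("window out of protein range")
  out <- data.frame(motif_codon_index = integer(), phase = integer())
  if (nrow(model$exons) < 2L) return(out)
  lens <- model$exons[, 2L] - model$exons[, 1L] + 1L
  upstream <- cumsum(lens)[-nrow(model$exons)]  # CDS nt before each intron
  phase <- as.integer(upstream %% 3L)
  codon <- as.integer(upstream %/% 3L + 1L)     # interrupted or following codon
  keep <- (phase > 0L & codon >= start_residue & codon <= end_residue) |
          (phase == 0L & codon >= start_residue & codon <= end_residue + 1L)
  data.frame(motif_codon_index = codon[keep] - start_residue + 1L,
             phase = phase[keep])
}

#' Compare splice-junction placements of two homologous motifs
#'
#' Two junction lists are "same" iff, after shifting list `a` by the
#' alignment offset, they are identical in (index, phase);
#' "incomparable" iff either list is empty (e.g. a single-exon
#' encoding). The comparison assumes a gap-free motif alignment
#' (offset 0 when the motifs were aligned without gaps).
#'
#' @param a,b data frames from [junctions_in_window()].
#' @param alignment_offset integer added to `a`'s codon indices to map
#'   them onto `b`'s coordinates.
#' @return `"same"`, `"different"`, or `"incomparable"`.
#' @export
compare_junctions <- function(a, b, alignment_offset = 0L) {
  if (nrow(a) == 0L || nrow(b) == 0L) return("incomparable")
  key <- function(d, off = 0L)
    paste(d$motif_codon_index + off, d$phase, sep = ":")
  ka <- sort(key(a, alignment_offset))
  kb <- sort(key(b))
  if (length(ka) == length(kb) && all(ka == kb)) "same" else "different"
}

#' Junction report for a set of motif hits
#'
#' Convenience wrapper producing the per-gene junction table used by the
#' pipeline reports: one row per (gene, hit, junction).
#'
#' @param models named list of [gene_model]s keyed by `protein_id`.
#' @param hits a hit data frame ([scan_strict()]/[scan_pssm()]).
#' @return Data frame `gene_id`, `pattern`, `start`, `end`,
#'   `motif_codon_index`, `phase`.
#' @export
junction_report <- function(models, hits) {
  by_protein <- setNames(models, vapply(models, `[[`, "", "protein_id"))
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    m <- by_protein[[hits$protein_id[i]]]
    if (is.null(m)) return(NULL)
    j <- junctions_in_window(m, hits$start[i], hits$end[i])
    if (nrow(j) == 0L)
      return(data.frame(gene_id = m$gene_id, pattern = hits$pattern[i],
                        start = hits$start[i], end = hits$end[i],
                        motif_codon_index = NA_integer_, phase = NA_integer_))
    cbind(data.frame(gene_id = m$gene_id, pattern = hits$pattern[i],
                     start = hits$start[i], end = hits$end[i]), j)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(gene_id = character(), pattern = character(),
                      start = integer(), end = integer(),
                      motif_codon_index = integer(), phase = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
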