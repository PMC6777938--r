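#' @noRd
gene_span <- function(model) {
  c(start = min(model$exons[, 1L]), end = max(model$exons[, 2L]))
}

#' Classify the relative orientation of two neighbouring genes
#'
#' Deterministic class from the genomic order (by leftmost coordinate)
#' and the strand pair: `tandem_ab` (A then B, same strand), `tandem_ba`
#' (B then A, same strand), `divergent` (head-to-head: the left gene on
#' `-`, the right on `+`), `convergent` (tail-to-tail: left `+`, right
#' `-`). Overlapping gene spans are rejected as ambiguous.
#'
#' @param a,b [gene_model]s on the same scaffold.
#' @return One of `"tandem_ab"`, `"tandem_ba"`, `"divergent"`,
#'   `"convergent"`.
#' @export
classify_orientation <- function(a, b) {
  if (a$scaffold != b$scaffold) stop("genes on different scaffolds")
  sa <- gene_span(a); sb <- gene_span(b)
  if (sa["start"] <= sb["end"] && sb["start"] <= sa["end"])
    stop("overlapping gene spans: order is ambiguous ('",
         a$gene_id, "' vs '", b$gene_id, "')")
  a_left <- sa["start"] < sb["start"]
  left_strand <- if (a_left) a$strand else b$strand
  if (a$strand == b$strand) {
    if (a_left) "tandem_ab" else "tandem_ba"
  } else if (left_strand == "+") "convergent" else "divergent"
}

#' Find microsynteny pairs between two gene families
#'
#' Every (A, B) gene pair sharing a scaffold with at most
#' `max_intervening` annotated genes strictly between them is reported,
#' with the intervening count, the distance between facing gene
#' boundaries, and the orientation class. "Immediately adjacent" in the
#' biological sense is `intervening == 0`. All qualifying pairs are
#' reported (paralogous copies give multiple rows; no one-to-one
#' matching is imposed).
#'
#' @param genes list of [gene_model]s (family labels set).
#' @param family_a,family_b family labels.
#' @param max_intervening maximum number of genes allowed between a pair
#'   (default 2, capturing near-proximate linkage; use `Inf` for all
#'   same-scaffold pairs).
#' @return Data frame `gene_a`, `gene_b`, `scaffold`, `intervening`,
#'   `separation_bp`, `orientation`, sorted by intervening then
#'   separation.
#' @export
neighbor_pairs <- function(genes, family_a, family_b, max_intervening = 2L) {
  if (max_intervening < 0) stop("max_intervening must be >= 0")
  fams <- vapply(genes, `[[`, "", "family")
  scafs <- vapply(genes, `[[`, "", "scaffold")
  spans <- t(vapply(genes, gene_span, c(start = 0L, end = 0L)))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      scaffold = character(), intervening = integer(),
                      separation_bp = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  ia <- which(fams == family_a); ib <- which(fams == family_b)
  if (!length(ia) || !length(ib)) return(empty)
  rows <- list()
  for (i in ia) for (j in ib) {
    if (i == j || scafs[i] != scafs[j]) next
    left <- if (spans[i, "start"] < spans[j, "start"]) i else j
    right <- if (left == i) j else i
    gap_lo <- spans[left, "end"]; gap_hi <- spans[right, "start"]
    between <- sum(vapply(seq_along(genes), function(k)
      k != i && k != j && scafs[k] == scafs[i] &&
        spans[k, "start"] > gap_lo && spans[k, "end"] < gap_hi,
      NA))
    if (between > max_intervening) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = genes[[i]]$gene_id, gene_b = genes[[j]]$gene_id,
      scaffold = scafs[i], intervening = between,
      separation_bp = max(0L, gap_hi - gap_lo - 1L),
      orientation = classify_orientation(genes[[i]], genes[[j]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$intervening, out$separation_bp), , drop = FALSE]
}

#' Per-species best-linkage summary
#'
#' One row per species: the pair with the smallest intervening count
#' (ties broken by separation), for figure-style linkage reports.
#'
#' @param pairs output of [neighbor_pairs()].
#' @param species named character vector mapping gene ids to species, or
#'   a single species label.
#' @return Data frame with one best pair per species.
#' @export
best_pair_per_species <- function(pairs, species) {
  if (nrow(pairs) == 0L) return(cbind(pairs, species = character()))
  sp <- if (length(species) == 1L && is.null(names(species)))
    rep(species, nrow(pairs)) else unname(species[pairs$gene_a])
  pairs$species <- sp
  pairs <- pairs[order(pairs$intervening, pairs$separation_bp), , drop = FALSE]
  pairs[!duplicated(pairs$species), , drop = FALSE]
}
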