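#' Compile a degenerate residue-class pattern
#'
#' Patterns are written with single residue letters and bracketed residue
#' classes, e.g. `"P[ILMV]D[ILMV]S"` for the canonical CtBP recruitment
#' motif PhiDPhiS (Phi = I, L, M or V). Each position becomes a set of
#' allowed residues; literal letters become singleton sets.
#'
#' @param spec pattern string.
#' @param name optional motif name (defaults to the spec string).
#' @return An object of class `motif_pattern` with a `columns` list.
#' @export
compile_pattern <- function(spec, name = spec) {
  chars <- strsplit(spec, "", fixed = TRUE)[[1L]]
  columns <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated bracket in pattern '", spec, "'")
      if (j == i + 1L) stop("empty residue class in pattern '", spec, "'")
      cls <- chars[seq(i + 1L, j - 1L)]
      columns[[length(columns) + 1L]] <- cls
      i <- j + 1L
    } else {
      columns[[length(columns) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  if (length(columns) == 0L) stop("empty pattern")
  for (col in columns)
    if (any(!col %in% AA_ALPHABET))
      stop("non-residue letter '", col[!col %in% AA_ALPHABET][1L],
           "' in pattern '", spec, "'")
  structure(list(name = name, columns = columns), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$name, "width", length(x$columns), "\n")
  invisible(x)
}

motif_width <- function(x) {
  if (inherits(x, "motif_pattern")) length(x$columns)
  else if (inherits(x, "pssm")) ncol(x$scores)
  else stop("not a motif object")
}

empty_hits <- function() {
  data.frame(protein_id = character(), pattern = character(),
             start = integer(), end = integer(), matched = character(),
             score = numeric(), in_region = logical(),
             stringsAsFactors = FALSE)
}

in_region_flag <- function(end, boundary) {
  if (is.na(boundary)) rep(NA, length(end)) else end <= boundary
}

#' Scan proteins for strict matches of a degenerate pattern
#'
#' Reports every window whose residues all fall in the pattern's
#' per-position classes. Overlapping hits are all reported; hits are
#' sorted by start. Strict hits carry `score = Inf` (they are exact by
#' definition). Hits lying entirely within a protein's
#' `region_boundary` window are flagged `in_region = TRUE`; hits beyond
#' it are reported with `in_region = FALSE` rather than suppressed.
#'
#' @param pattern a [compile_pattern()] result.
#' @param proteins a [protein_set] (or one row of one).
#' @return A hit data frame: `protein_id`, `pattern`, `start`, `end`,
#'   `matched`, `score`, `in_region`.
#' @export
scan_strict <- function(pattern, proteins) {
  w <- motif_width(pattern)
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    n <- nchar(s)
    if (n < w) return(empty_hits())
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    ok <- rep(TRUE, n - w + 1L)
    for (j in seq_len(w))
      ok <- ok & chars[seq(j, n - w + j)] %in% pattern$columns[[j]]
    starts <- which(ok)
    if (!length(starts)) return(empty_hits())
    data.frame(protein_id = proteins$id[i], pattern = pattern$name,
               start = starts, end = starts + w - 1L,
               matched = substring(s, starts, starts + w - 1L),
               score = Inf,
               in_region = in_region_flag(starts + w - 1L,
                                          proteins$region_boundary[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build a position-specific scoring matrix from aligned instances
#'
#' Scores are log-odds in bits:
#' `score(col, a) = log2((count(col, a) + pseudocount * bg[a]) / (N + pseudocount)) - log2(bg[a])`.
#' The default threshold is the minimum score attained by any training
#' instance under the finished matrix, so every training instance is
#' recovered by construction. With `leave_one_out = TRUE` the threshold
#' is instead the minimum score of each instance under the matrix built
#' from the remaining instances, an honest (lower) cutoff that does not
#' score instances against themselves.
#'
#' @param instances character vector of aligned, equal-length, gap-free
#'   residue strings (at least 2).
#' @param background named per-residue frequency vector (default uniform
#'   1/20).
#' @param pseudocount nonnegative smoothing mass (default 0.5).
#' @param name motif name.
#' @param leave_one_out use leave-one-out threshold calibration.
#' @return An object of class `pssm` with `scores` (20 x width matrix in
#'   bits), `background`, `pseudocount`, `threshold`, `training`.
#' @export
build_pssm <- function(instances, background = NULL, pseudocount = 0.5,
                       name = "pssm", leave_one_out = FALSE) {
  if (length(instances) < 2L) stop("need at least 2 training instances")
  w <- nchar(instances[1L])
  if (any(nchar(instances) != w)) stop("training instances have unequal lengths")
  if (any(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                toupper(instances))))
    stop("training instances contain non-residue (or gap) characters")
  instances <- toupper(instances)
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
  background <- background[AA_ALPHABET]
  if (any(is.na(background) | background <= 0)) {
    obs <- unique(strsplit(paste(instances, collapse = ""), "")[[1L]])
    bad <- obs[is.na(background[obs]) | background[obs] <= 0]
    if (length(bad))
      stop("zero background frequency for observed residue '", bad[1L], "'")
    background[is.na(background) | background <= 0] <- .Machine$double.xmin
  }
  score_matrix <- function(insts) {
    N <- length(insts)
    counts <- vapply(seq_len(w), function(j) {
      col <- substring(insts, j, j)
      tab <- table(factor(col, levels = AA_ALPHABET))
      as.numeric(tab)
    }, numeric(20L))
    rownames(counts) <- AA_ALPHABET
    log2((counts + pseudocount * background) / (N + pseudocount)) -
      log2(background)
  }
  scores <- score_matrix(instances)
  score_one <- function(S, inst) {
    idx <- match(strsplit(inst, "", fixed = TRUE)[[1L]], AA_ALPHABET)
    sum(S[cbind(idx, seq_len(w))])
  }
  threshold <-
    if (leave_one_out && length(instances) > 2L) {
      min(vapply(seq_along(instances), function(i)
        score_one(score_matrix(instances[-i]), instances[i]), 0))
    } else {
      min(vapply(instances, function(inst) score_one(scores, inst), 0))
    }
  structure(list(name = name, width = w, scores = scores,
                 background = background, pseudocount = pseudocount,
                 threshold = threshold, training = instances,
                 leave_one_out = leave_one_out),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm", x$name, "width", x$width, "trained on", length(x$training),
      "instances, threshold", round(x$threshold, 3), "bits\n")
  invisible(x)
}

#' Score every window of a residue string under a PSSM
#'
#' @param pssm a [build_pssm()] result.
#' @param sequence a single residue string.
#' @return Numeric vector of window scores (bits), one per start position.
#' @export
pssm_window_scores <- function(pssm, sequence) {
  w <- pssm$width
  n <- nchar(sequence)
  if (n < w) return(numeric(0))
  idx <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], AA_ALPHABET)
  if (anyNA(idx)) stop("non-residue character in sequence")
  sc <- numeric(n - w + 1L)
  for (j in seq_len(w))
    sc <- sc + pssm$scores[cbind(idx[seq(j, n - w + j)], j)]
  sc
}

#' Scan proteins with a PSSM
#'
#' All windows scoring at or above the threshold are reported, sorted by
#' start then descending score. Region flagging as in [scan_strict()].
#'
#' @param pssm a [build_pssm()] result.
#' @param proteins a [protein_set].
#' @param threshold_override optional score cutoff replacing the
#'   calibrated threshold.
#' @return A hit data frame (see [scan_strict()]).
#' @export
scan_pssm <- function(pssm, proteins, threshold_override = NULL) {
  thr <- if (is.null(threshold_override)) pssm$threshold else threshold_override
  w <- pssm$width
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    sc <- pssm_window_scores(pssm, s)
    starts <- which(sc >= thr)
    if (!length(starts)) return(empty_hits())
    h <- data.frame(protein_id = proteins$id[i], pattern = pssm$name,
                    start = starts, end = starts + w - 1L,
                    matched = substring(s, starts, starts + w - 1L),
                    score = sc[starts],
                    in_region = in_region_flag(starts + w - 1L,
                                               proteins$region_boundary[i]),
                    stringsAsFactors = FALSE)
    h[order(h$start, -h$score), , drop = FALSE]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Specify Su(H)-contact requirements for an SBD-like motif hit
#'
#' The main-body contacts are (motif-relative offset, residue class)
#' pairs; the distinguished downstream rule looks for a tryptophan
#' within `w_max_dist` residues after the hit that is followed by a
#' hydrophobic residue (typically V or I).
#'
#' @param offsets integer vector of 1-based motif-relative offsets.
#' @param classes list (or character vector) of allowed residues per
#'   offset; a single string like `"ILMV"` is split into residues.
#' @param w_max_dist search window after the motif for the downstream W
#'   (default 20).
#' @param hydrophobic residue class used for the residue following the W.
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(offsets = integer(), classes = list(),
                         w_max_dist = 20L, hydrophobic = HYDROPHOBIC) {
  if (length(offsets) != length(classes))
    stop("offsets and classes must have equal length")
  classes <- lapply(classes, function(cl)
    if (length(cl) == 1L && nchar(cl) > 1L) strsplit(cl, "")[[1L]] else cl)
  if (w_max_dist < 0L) stop("w_max_dist must be >= 0")
  structure(list(offsets = as.integer(offsets), classes = classes,
                 w_max_dist = as.integer(w_max_dist),
                 hydrophobic = hydrophobic),
            class = "contact_spec")
}

#' Check Su(H)-contact residues of a motif hit
#'
#' For each contact offset, reports the observed residue and whether it
#' belongs to the required class; then searches the window after the hit
#' for a tryptophan followed by a hydrophobic residue and reports its
#' absolute position (or `NA`).
#'
#' @param hit one row of a hit data frame.
#' @param protein the matching [protein_set] row.
#' @param spec a [contact_spec()].
#' @return A list with `contacts` (data frame offset/position/residue/
#'   required/satisfied), `n_violations`, `w_position`, and
#'   `w_followed_hydrophobic`.
#' @export
check_contacts <- function(hit, protein, spec) {
  if (hit$protein_id != protein$id)
    stop("hit does not refer to the supplied protein")
  s <- protein$sequence
  w <- hit$end - hit$start + 1L
  if (length(spec$offsets) && any(spec$offsets < 1L | spec$offsets > w))
    stop("contact offset beyond motif width")
  pos <- hit$start + spec$offsets - 1L
  if (any(pos > nchar(s))) stop("contact offset beyond protein end")
  if (length(pos)) {
    contacts <- data.frame(
      offset = spec$offsets, position = pos,
      residue = substring(s, pos, pos),
      required = vapply(spec$classes, paste, "", collapse = ""),
      stringsAsFactors = FALSE)
    contacts$satisfied <- mapply(function(r, cl) r %in% cl,
                                 contacts$residue, spec$classes,
                                 USE.NAMES = FALSE)
  } else {
    contacts <- data.frame(offset = integer(), position = integer(),
                           residue = character(), required = character(),
                           satisfied = logical(), stringsAsFactors = FALSE)
  }
  # downstream tryptophan followed by a hydrophobic residue
  lo <- hit$end + 1L
  hi <- min(nchar(s) - 1L, hit$end + spec$w_max_dist)
  w_pos <- NA_integer_
  w_hyd <- NA
  if (lo <= hi) {
    for (p in lo:hi) {
      if (substring(s, p, p) == "W" &&
          substring(s, p + 1L, p + 1L) %in% spec$hydrophobic) {
        w_pos <- p
        w_hyd <- TRUE
        break
      }
    }
  }
  list(contacts = contacts,
       n_violations = sum(!contacts$satisfied),
       w_position = w_pos,
       w_followed_hydrophobic = w_hyd)
}

#' Write motif hits to TSV
#'
#' @param hits a hit data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
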