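test_that("compile_pattern handles classes, literals and errors", {
  p <- compile_pattern("P[ILMV]D[ILMV]S")
  expect_length(p$columns, 5L)
  expect_setequal(p$columns[[2L]], c("I", "L", "M", "V"))
  expect_equal(p$columns[[1L]], "P")

  wrpw <- compile_pattern("WRPW")
  expect_length(wrpw$columns, 4L)
  expect_true(all(lengths(wrpw$columns) == 1L))

  wild <- compile_pattern("[ACDEFGHIKLMNPQRSTVWY]")
  expect_length(wild$columns, 1L)
  expect_length(wild$columns[[1L]], 20L)

  expect_error(compile_pattern("P[]S"), "empty residue class")
  expect_error(compile_pattern("PXB"), "non-residue")
  expect_error(compile_pattern("P[IL"), "unterminated")
})

test_that("scan_strict finds canonical CtBP motifs but not near-matches", {
  pat <- models$ctbp_strict
  h <- scan_strict(pat, protein_set("smar", "FADNHPVDLSNSHRG"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$matched, "PVDLS")
  expect_equal(h$start, 6L)
  # a functional near-match (terminal T) is invisible to the strict pattern
  expect_equal(nrow(scan_strict(pat, protein_set("mgro", "LHYDNPLDLTNRLDE"))), 0L)
  # sequence shorter than the pattern
  expect_equal(nrow(scan_strict(pat, protein_set("tiny", "PVD"))), 0L)
  # overlapping hits are all reported, sorted by start
  h2 <- scan_strict(compile_pattern("[AC][AC]"), protein_set("x", "ACAG"))
  expect_equal(h2$start, c(1L, 2L))
})

test_that("scan_strict agrees with the naive all-windows oracle", {
  set.seed(7)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:1000) {
    # small alphabet so matches actually occur
    seq <- paste(sample(alphabet[1:4], sample(10:40, 1L), TRUE), collapse = "")
    cols <- lapply(seq_len(sample(2:5, 1L)), function(j)
      sample(alphabet[1:4], sample(1:3, 1L)))
    pat <- structure(list(name = "rnd", columns = cols),
                     class = "motif_pattern")
    got <- scan_strict(pat, protein_set("p", seq))
    expect_equal(got$start, naive_scan(pat, seq))
  }
})

test_that("build_pssm scores follow the log-odds formula and calibrate on training", {
  # degenerate training set: consensus attains the per-column maximum sum
  pd <- build_pssm(c("PVDLS", "PVDLS", "PVDLS"))
  expect_equal(pssm_window_scores(pd, "PVDLS")[1L],
               sum(apply(pd$scores, 2L, max)))
  # symmetry between the two observed residues
  ps <- build_pssm(c("AA", "CC"))
  expect_equal(unname(ps$scores["A", 1L]), unname(ps$scores["C", 1L]))
  expect_equal(unname(ps$scores["A", 2L]), unname(ps$scores["C", 2L]))

  # independent recomputation of one score from raw counts
  insts <- survey$ctbp_motif
  pc <- 0.5; bg <- 1 / 20; N <- length(insts)
  n_L2 <- sum(substr(insts, 2L, 2L) == "L")
  manual <- log((n_L2 + pc * bg) / (N + pc) / bg) / log(2)
  expect_equal(unname(models$ctbp$scores["L", 2L]), manual)

  expect_error(build_pssm(c("AA", "CCC")), "unequal")
  expect_error(build_pssm("AA"), "at least 2")
  bg0 <- setNames(rep(0.05, 20L), rownames(models$ctbp$scores))
  bg0["C"] <- 0
  expect_error(build_pssm(c("CA", "CC"), background = bg0), "zero background")
})

test_that("survey-calibrated CtBP PSSM recovers all printed instances", {
  thr <- models$ctbp$threshold
  scores <- vapply(survey$ctbp_motif, function(m)
    pssm_window_scores(models$ctbp, m)[1L], 0)
  expect_true(all(scores >= thr))
  expect_gte(pssm_window_scores(models$ctbp, "PLDLT")[1L], thr)
})

test_that("scan_pssm finds the Gro motif core in survey contexts", {
  h <- scan_pssm(models$gro, protein_set("smar", "SHMIAGSLTPPDKVNGEHGHQL"))
  expect_true("GSLTPPDKV" %in% h$matched)
  expect_equal(h$start[h$matched == "GSLTPPDKV"], 6L)
  h2 <- scan_pssm(models$gro, protein_set("cscu", "MQLISGSMTSHDKVNGDQHSLG"))
  expect_true("GSMTSHDKV" %in% h2$matched)
})

test_that("every PSSM training instance is recovered in isolation", {
  for (m in list(models$ctbp, models$gro)) {
    hits <- scan_pssm(m, protein_set(paste0("t", seq_along(m$training)),
                                     m$training))
    expect_equal(nrow(hits), length(m$training))
    expect_true(all(hits$start == 1L))
  }
})

test_that("leave-one-out threshold is not above the resubstitution threshold", {
  loo <- build_pssm(survey$ctbp_motif, leave_one_out = TRUE)
  expect_lte(loo$threshold, models$ctbp$threshold)
})

test_that("raising the threshold never increases the hit count", {
  prot <- protein_set("p", paste(survey$gro_context, collapse = ""))
  thrs <- seq(models$gro$threshold - 10, models$gro$threshold + 20, by = 2)
  counts <- vapply(thrs, function(t)
    nrow(scan_pssm(models$gro, prot, threshold_override = t)), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("hit spans are invariant to flanking sequence up to the shift", {
  prot <- protein_set("p", "SHMIAGSLTPPDKVNGEHGHQL")
  base <- scan_pssm(models$gro, prot)
  flank <- "MNQRSTED"
  shifted <- scan_pssm(models$gro, protein_set(
    "p", paste0(flank, prot$sequence, "EDKWYH")))
  expect_equal(shifted$start, base$start + nchar(flank))
  expect_equal(shifted$matched, base$matched)
  expect_equal(shifted$score, base$score)
})

test_that("shuffled sequences yield hits at the empirical false-positive rate", {
  set.seed(13)
  s <- "SHMIAGSLTPPDKVNGEHGHQL"
  chars <- strsplit(s, "")[[1L]]
  n_hits <- 0L
  n_windows <- 0L
  for (i in 1:1000) {
    shuf <- paste(sample(chars), collapse = "")
    sc <- pssm_window_scores(models$gro, shuf)
    n_hits <- n_hits + sum(sc >= models$gro$threshold)
    n_windows <- n_windows + length(sc)
  }
  # per-window tail probability under the uniform background, by
  # convolving the per-column score distributions (independent oracle);
  # scores are binned to 0.01 bit, with the comparison slackened by the
  # worst-case accumulated rounding so the expectation is an upper bound
  probs <- 1
  vals <- 0
  for (j in seq_len(models$gro$width)) {
    v <- round(as.vector(outer(vals, models$gro$scores[, j], `+`)), 2)
    p <- as.vector(outer(probs, rep(1 / 20, 20L)))
    agg <- rowsum(p, group = v)
    vals <- as.numeric(rownames(agg))
    probs <- agg[, 1L]
  }
  p_fp <- sum(probs[vals >= models$gro$threshold - 0.1])
  expected <- n_windows * p_fp
  # composition-shuffling is not exactly the uniform background; allow a
  # generous Poisson-style band around the analytic expectation
  expect_lte(n_hits, stats::qpois(0.9999, lambda = max(expected, 0.01)) + 1)
})

test_that("in_region flags hits relative to the scan window boundary", {
  seq <- paste0("AAAAA", "PVDLS", "GGGGG", "PVDLS")
  h <- scan_strict(models$ctbp_strict,
                   protein_set("p", seq, region_boundary = 10L))
  expect_equal(h$in_region, c(TRUE, FALSE))  # reported, not suppressed
})

test_that("check_contacts validates SBD contact residues and downstream W", {
  cs <- load_constructs(ext_fixture("constructs.fasta"))
  wt <- construct_peptide(cs[["DmelHairless192-389_WT"]])
  prot <- protein_set("dmel", wt)
  st <- as.integer(regexpr("GRLQFFKDGKFILEL", wt, fixed = TRUE))
  hit <- data.frame(protein_id = "dmel", pattern = "SBD", start = st,
                    end = st + 14L, matched = "GRLQFFKDGKFILEL",
                    score = Inf, in_region = NA)
  spec <- contact_spec(offsets = c(3L, 5L, 13L, 15L),
                       classes = list("ILMVF", "ILMVF", "ILMVF", "ILMVF"))
  rep <- check_contacts(hit, prot, spec)
  expect_equal(rep$n_violations, 0L)
  expect_false(is.na(rep$w_position))
  expect_true(rep$w_followed_hydrophobic)
  expect_equal(substr(wt, rep$w_position, rep$w_position), "W")

  mut <- construct_peptide(cs[["DmelHairless192-389_5Amut"]])
  prot_m <- protein_set("dmel", mut)
  hit_m <- hit
  hit_m$matched <- substr(mut, st, st + 14L)
  rep_m <- check_contacts(hit_m, prot_m, spec)
  expect_equal(rep_m$n_violations, 4L)
  expect_true(is.na(rep_m$w_position))

  # empty contact list is vacuously satisfied
  rep_0 <- check_contacts(hit, prot, contact_spec())
  expect_equal(rep_0$n_violations, 0L)
  expect_error(check_contacts(hit, prot, contact_spec(99L, list("L"))),
               "offset beyond motif width")
})
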