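#' Load the packaged co-repressor motif survey table
#'
#' The packaged survey of Su(H) N-terminal co-repressor recruitment
#' motifs across 35 protostome (plus outgroup) species: a 15-mer context
#' around each CtBP-class motif (residues 6-10) and, where present, a
#' 22-mer context around the Gro-class motif (the annotated span is
#' residues 6-17; the named 9-mer core is residues 6-14).
#'
#' @param path TSV fixture; defaults to the packaged copy.
#' @return Data frame `species`, `ctbp_context`, `gro_context`, plus
#'   derived columns `ctbp_motif` (5-mer), `gro_span` (12-mer or `NA`)
#'   and `gro_core` (9-mer or `NA`).
#' @export
motif_survey <- function(path = system.file("extdata", "motif_survey.tsv",
                                            package = "corecruit")) {
  d <- read.delim(path, colClasses = "character")
  d$gro_context[is.na(d$gro_context)] <- ""
  d$ctbp_motif <- substr(d$ctbp_context, 6L, 10L)
  d$gro_span <- ifelse(nzchar(d$gro_context),
                       substr(d$gro_context, 6L, 17L), NA)
  d$gro_core <- ifelse(nzchar(d$gro_context),
                       substr(d$gro_context, 6L, 14L), NA)
  d
}

#' Survey-calibrated CtBP and Gro motif models
#'
#' Builds the two PSSMs the package ships calibrated on the packaged
#' survey: the CtBP model on the 35 aligned 5-mers (so known functional
#' but non-canonical instances such as PLDLT score above threshold),
#' and the Gro model on the 9-mer cores of the 27 annotated Gro spans.
#'
#' @param survey output of [motif_survey()].
#' @param pseudocount,leave_one_out passed to [build_pssm()].
#' @return List with elements `ctbp` and `gro` ([build_pssm()] objects)
#'   and `ctbp_strict` (the canonical P\[ILMV\]D\[ILMV\]S pattern).
#' @export
survey_motif_models <- function(survey = motif_survey(), pseudocount = 0.5,
                                leave_one_out = FALSE) {
  list(ctbp = build_pssm(survey$ctbp_motif, pseudocount = pseudocount,
                         name = "CtBP", leave_one_out = leave_one_out),
       gro = build_pssm(survey$gro_core[!is.na(survey$gro_core)],
                        pseudocount = pseudocount, name = "Gro",
                        leave_one_out = leave_one_out),
       ctbp_strict = compile_pattern("P[ILMV]D[ILMV]S", name = "CtBP_strict"))
}

round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Protein length summary with clade grouping and size extremes
#'
#' Per-group minimum/median/maximum lengths plus the global extreme pair
#' and their fold ratio (max/min), rounded half-up to one decimal --
#' adaptor proteins of this family vary enormously in size between
#' orders while staying fairly stable within one.
#'
#' @param proteins a [protein_set], or a (possibly named) numeric vector
#'   of lengths.
#' @param groups optional named vector mapping protein id (or species)
#'   to a clade label.
#' @return List with `per_group` (data frame `group`, `n`, `min`,
#'   `median`, `max`), `min_id`, `max_id`, `min`, `max`, `fold_ratio`.
#' @export
length_summary <- function(proteins, groups = NULL) {
  if (inherits(proteins, "protein_set") || is.data.frame(proteins)) {
    len <- setNames(nchar(proteins$sequence), proteins$id)
  } else {
    len <- proteins
  }
  if (!length(len)) stop("no proteins supplied")
  if (is.null(names(len))) names(len) <- paste0("p", seq_along(len))
  grp <- if (is.null(groups)) rep("all", length(len))
         else unname(groups[names(len)])
  grp[is.na(grp)] <- "ungrouped"
  per_group <- do.call(rbind, lapply(split(len, grp), function(v)
    data.frame(n = length(v), min = min(v), median = median(v), max = max(v))))
  per_group <- cbind(group = rownames(per_group), per_group)
  rownames(per_group) <- NULL
  i_min <- which.min(len); i_max <- which.max(len)
  list(per_group = per_group,
       min_id = names(len)[i_min], max_id = names(len)[i_max],
       min = unname(len[i_min]), max = unname(len[i_max]),
       fold_ratio = round_half_up(len[[i_max]] / len[[i_min]], 1L))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full comparative pipeline from one config
#'
#' The config (JSON file or equivalent list) names the inputs; each
#' present section triggers the matching stage and report. Sections:
#' \describe{
#'   \item{proteins}{protein FASTA; enables motif scanning and the
#'     length summary.}
#'   \item{motifs}{`strict` = named pattern strings; `pssm` = list of
#'     `{name, instances, pseudocount}` blocks (instances inline or via
#'     `instances_file`, one per line).}
#'   \item{genes}{`gff` + `genome` FASTA; enables the junction report
#'     for motif hits and translation checks.}
#'   \item{synteny}{`family_a`, `family_b`, `max_intervening`.}
#'   \item{phylo}{`tree` (newick) + `characters` (TSV); Fitch and Dollo
#'     reconstructions per character and the hybrid-species list.}
#'   \item{groups}{named id-to-clade map for the length summary.}
#' }
#' Outputs are deterministic for fixed inputs; the run log records the
#' package version, config hash and per-stage counts. An empty input
#' set produces empty reports, a warning, and success.
#'
#' @param config path to a JSON config, or a list.
#' @param out output directory (created).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- c(paste("corecruit", as.character(utils::packageVersion("corecruit"))),
           paste("config_md5", cfg_hash))
  res <- list()

  proteins <- NULL
  if (!is.null(config$proteins)) {
    proteins <- stage("read_proteins", read_fasta(config$proteins))
    log <- c(log, paste("proteins", nrow(proteins)))
  }
  if (is.null(proteins) && is.null(config$phylo)) {
    warning("empty input set: writing empty reports")
    writeLines(c(log, "empty_input TRUE"), file.path(out, "log.txt"))
    write_hits_tsv(empty_hits(), file.path(out, "motif_hits.tsv"))
    return(invisible(res))
  }

  hits <- empty_hits()
  if (!is.null(config$motifs) && !is.null(proteins)) {
    hits <- stage("motif_scan", {
      h <- list()
      for (nm in names(config$motifs$strict))
        h[[length(h) + 1L]] <-
          scan_strict(compile_pattern(config$motifs$strict[[nm]], name = nm),
                      proteins)
      pssms <- config$motifs$pssm
      if (!is.null(pssms) && !is.null(pssms$name)) pssms <- list(pssms)
      for (p in pssms) {
        inst <- p$instances %||% readLines(p$instances_file)
        h[[length(h) + 1L]] <-
          scan_pssm(build_pssm(inst, pseudocount = p$pseudocount %||% 0.5,
                               name = p$name),
                    proteins, threshold_override = p$threshold)
      }
      do.call(rbind, c(h, list(make.row.names = FALSE)))
    })
    write_hits_tsv(hits, file.path(out, "motif_hits.tsv"))
    # survey-style table: species x motif, best-scoring hit
    tab <- stage("motif_table", {
      if (nrow(hits)) {
        sp <- setNames(proteins$species, proteins$id)
        hits$species <- unname(sp[hits$protein_id])
        ord <- hits[order(hits$pattern, hits$species, -hits$score), ]
        ord[!duplicated(ord[, c("pattern", "species")]),
            c("species", "pattern", "matched", "start", "end", "score",
              "in_region")]
      } else hits
    })
    write.table(tab, file.path(out, "motif_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- c(log, paste("motif_hits", nrow(hits)))
    res$hits <- hits
  }

  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- stage("read_genes",
                   read_gff_genes(config$genes$gff, config$genes$genome,
                                  family_key = config$genes$family_key %||% "family"))
    log <- c(log, paste("genes", length(genes)))
    if (nrow(hits)) {
      jr <- stage("junctions", junction_report(genes, hits))
      write.table(jr, file.path(out, "junctions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$junctions <- jr
      log <- c(log, paste("junction_rows", nrow(jr)))
    }
    if (!is.null(config$synteny)) {
      sy <- stage("synteny", neighbor_pairs(
        genes, config$synteny$family_a, config$synteny$family_b,
        max_intervening = config$synteny$max_intervening %||% 2L))
      write.table(sy, file.path(out, "synteny.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$synteny <- sy
      log <- c(log, paste("synteny_pairs", nrow(sy)))
    }
  }

  if (!is.null(config$phylo)) {
    ph <- stage("parsimony", {
      tree <- ape::read.tree(config$phylo$tree)
      m <- read_character_matrix(config$phylo$characters)
      recs <- lapply(colnames(m), function(ch) {
        st <- setNames(m[, ch], rownames(m))
        f <- fitch_parsimony(tree, st)
        d <- tryCatch(dollo_parsimony(tree, st), error = function(e) NULL)
        list(character = ch,
             fitch = list(min_changes = f$min_changes, events = f$events,
                          non_unique = f$non_unique,
                          tree = annotate_tree(tree, f)),
             dollo = if (!is.null(d))
               list(changes = d$min_changes, events = d$events))
      })
      names(recs) <- colnames(m)
      hyb <- tryCatch(hybrid_species(m), error = function(e) character())
      list(reconstructions = recs, hybrid_species = hyb)
    })
    jsonlite::write_json(ph, file.path(out, "parsimony.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$phylo <- ph
    log <- c(log, paste("characters", length(ph$reconstructions)))
  }

  if (!is.null(proteins)) {
    groups <- if (!is.null(config$groups)) unlist(config$groups)
    ls <- stage("length_summary", length_summary(proteins, groups))
    write.table(ls$per_group, file.path(out, "lengths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ls[c("min_id", "max_id", "min", "max", "fold_ratio")],
                         file.path(out, "lengths.json"), auto_unbox = TRUE,
                         digits = NA)
    res$lengths <- ls
    log <- c(log, paste("length_fold_ratio", ls$fold_ratio))
  }

  writeLines(log, file.path(out, "log.txt"))
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `scan` (motif scan of a FASTA against a motif config),
#' `synteny`, `parsimony`, `constructs-verify`, `simulate` (synthetic
#' end-to-end dataset), `report` (full pipeline). Global flags:
#' `--config`, `--out`, `--seed`. Designed for
#' `Rscript -e 'corecruit::corecruit_cli()' <subcommand> ...`.
#'
#' @param args character vector (defaults to the process arguments).
#' @return Invisibly, the subcommand result.
#' @export
corecruit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: corecruit <scan|synteny|parsimony|",
                          "constructs-verify|simulate|report> [--flags]")
  cmd <- args[1L]
  flag <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i)) args[i[1L] + 1L] else default
  }
  out <- flag("out", "corecruit_out")
  seed <- as.integer(flag("seed", "0"))
  switch(cmd,
    report = run_pipeline(flag("config"), out),
    scan = {
      cfg <- jsonlite::read_json(flag("config"), simplifyVector = TRUE)
      run_pipeline(list(proteins = cfg$proteins, motifs = cfg$motifs), out)
    },
    synteny = {
      genes <- read_gff_genes(flag("gff"), flag("genome"))
      sy <- neighbor_pairs(genes, flag("family-a"), flag("family-b"),
                           as.integer(flag("max-intervening", "2")))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write.table(sy, file.path(out, "synteny.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      invisible(sy)
    },
    parsimony = run_pipeline(list(
      proteins = flag("proteins"),
      phylo = list(tree = flag("tree"), characters = flag("characters"))),
      out),
    `constructs-verify` = {
      v <- verify_constructs()
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(v, file.path(out, "constructs.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      invisible(v)
    },
    simulate = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      models <- survey_motif_models()
      sim <- gen_proteome(models$gro, seed = seed)
      write_fasta(sim$proteins, file.path(out, "proteins.fasta"))
      jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(sim)
    },
    stop("unknown subcommand '", cmd, "'"))
}
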