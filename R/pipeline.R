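#' Run configuration for the full characterization pipeline
#'
#' @param fasta path to unaligned FASTA of candidate sequences.
#' @param alignment path to the corresponding aligned FASTA.
#' @param pdb optional path to a complex in PDB format; \code{NULL}
#'   disables the interface stage only.
#' @param chain_a,chain_b enzyme / inhibitor chain ids (used when
#'   \code{pdb} is given).
#' @param out_dir output directory (created if missing).
#' @param thresholds consensus thresholds (percent).
#' @param min_cys curation minimum cysteine count.
#' @param anchor_threshold motif-derivation anchor threshold (percent).
#' @param n_reps,seed,correction phylogeny bootstrap settings.
#' @param scheme,constants,geometry analysis parameter objects.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(fasta, alignment, pdb = NULL, chain_a = "A",
                       chain_b = "I", out_dir = "results",
                       thresholds = c(100, 90, 80, 70), min_cys = 5L,
                       anchor_threshold = 90, n_reps = 1000L, seed = 17L,
                       correction = "kimura",
                       scheme = residue_class_scheme(),
                       constants = physchem_constants(),
                       geometry = geometry_params()) {
  structure(list(fasta = fasta, alignment = alignment, pdb = pdb,
                 chain_a = chain_a, chain_b = chain_b, out_dir = out_dir,
                 thresholds = thresholds, min_cys = min_cys,
                 anchor_threshold = anchor_threshold, n_reps = n_reps,
                 seed = seed, correction = correction, scheme = scheme,
                 constants = constants, geometry = geometry),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Scalar/vector fields of [run_config()] may be given in a single JSON
#' config file; unspecified fields keep their defaults. Relative input
#' paths are resolved against the config file's directory.
#'
#' @param path JSON config path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("fasta", "alignment", "pdb", "chain_a", "chain_b",
               "out_dir", "thresholds", "min_cys", "anchor_threshold",
               "n_reps", "seed", "correction")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ","))
  base <- dirname(normalizePath(path))
  for (f in intersect(c("fasta", "alignment", "pdb"), names(raw))) {
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(run_config, raw)
}

stage <- function(log_con, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  writeLines(sprintf("stage %-14s %.2fs", name,
                     proc.time()[["elapsed"]] - t0), log_con)
  res
}

#' Run the full characterization pipeline
#'
#' curate -> trim -> consensus/motif -> physicochemical panel -> phylogeny
#' (-> interface interactions when a PDB is configured). Writes, under
#' \code{cfg$out_dir}: \code{kept.fasta}, \code{rejected.tsv},
#' \code{consensus.tsv}, \code{freqs.tsv}, \code{motif.txt},
#' \code{match_rate.txt}, \code{panel.tsv}, \code{tree.nwk},
#' \code{supports.tsv}, optionally \code{interactions.tsv}, and
#' \code{run.log} with versions, seed and per-stage timings. Deterministic:
#' the same config, inputs and seed give byte-identical outputs.
#'
#' @param cfg a [run_config()] (or path to a JSON config file).
#' @return named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_con <- file(out("run.log"), "w")
  on.exit(close(log_con))
  writeLines(c(sprintf("cpikit %s | R %s.%s",
                       as.character(utils::packageVersion("cpikit")),
                       R.version$major, R.version$minor),
               sprintf("seed %d | n_reps %d | correction %s",
                       cfg$seed, cfg$n_reps, cfg$correction),
               sprintf("thresholds %s | min_cys %d | anchor_threshold %s",
                       paste(cfg$thresholds, collapse = ","), cfg$min_cys,
                       cfg$anchor_threshold)), log_con)

  report <- stage(log_con, "curate", {
    curate(read_fasta(cfg$fasta), min_cys = cfg$min_cys)
  })
  write_fasta(report$kept, out("kept.fasta"))
  write_rejection_report(report, out("rejected.tsv"))

  aln <- stage(log_con, "alignment", {
    a <- read_alignment(cfg$alignment)
    keep <- a$ids %in% report$kept$id
    peptide_alignment(a$ids[keep], a$seqs[keep])
  })

  motif <- stage(log_con, "motif", {
    derive_spacing_motif(aln, cfg$anchor_threshold)
  })
  writeLines(c(format(motif), format(motif, style = "prosite")),
             out("motif.txt"))

  profile <- stage(log_con, "consensus", {
    consensus_profile(aln, cfg$thresholds, cfg$scheme)
  })
  write_consensus_tsv(profile, out("consensus.tsv"), out("freqs.tsv"))

  trimmed <- stage(log_con, "trim", {
    trim_to_mature(report$kept, motif)
  })
  rate <- stage(log_con, "match_rate", motif_match_rate(trimmed, motif))
  writeLines(sprintf("%.1f", rate), out("match_rate.txt"))

  panel <- stage(log_con, "physchem", physchem_table(trimmed, cfg$constants))
  utils::write.table(panel, out("panel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tree <- stage(log_con, "phylogeny", {
    bootstrap_supports(aln, n_reps = cfg$n_reps, seed = cfg$seed,
                       correction = cfg$correction)
  })
  write_newick(tree, out("tree.nwk"))
  write_supports_tsv(tree, out("supports.tsv"))

  paths <- c(kept = out("kept.fasta"), rejected = out("rejected.tsv"),
             motif = out("motif.txt"), consensus = out("consensus.tsv"),
             freqs = out("freqs.tsv"), match_rate = out("match_rate.txt"),
             panel = out("panel.tsv"), tree = out("tree.nwk"),
             supports = out("supports.tsv"), log = out("run.log"))

  if (!is.null(cfg$pdb)) {
    interactions <- stage(log_con, "interactions", {
      detect_interactions(parse_structure(cfg$pdb), cfg$chain_a,
                          cfg$chain_b, cfg$geometry)
    })
    interaction_table(interactions, out("interactions.tsv"))
    paths <- c(paths, interactions = out("interactions.tsv"))
  }
  invisible(paths)
}
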