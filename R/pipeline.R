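# Pipeline orchestration: fixed stage order, one config, deterministic
# outputs, and a machine-readable run manifest.

DEFAULT_CONFIG <- list(
  stages = c("preprocess", "annotate", "novel", "de", "target",
             "degradome", "enrich"),
  # cleaning
  min_len = 18L, max_len = 30L, adapter_5p = "", adapter_3p = "",
  # known-miRNA identification
  species = "hvu", min_overlap = 16L, overlap_mismatches = 0L,
  cross_species_mismatches = 2L,
  # novel-miRNA calling
  flank = 250L, min_mfei = 0.9, min_novel_count = 5L,
  # six-rule target prediction
  max_mismatch = 4, max_5p_mismatch = 2.5, min_energy_ratio = 0.75,
  gu_is_mismatch = FALSE,
  # differential expression
  fc_threshold = 1, alpha = 1e-5, de_method = "audic_claverie",
  # degradome validation
  degradome_window = 1L, degradome_min_reads = 2L,
  # enrichment
  enrich_alpha = 0.05,
  seed = 1L)

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (thresholds of the published
#' protocol: 18-30 nt length window, 16-nt overlap, at most 2
#' cross-species mismatches, MFEI >= 0.9, the six-rule parameters with a
#' 0.75 energy ratio, |log2FC| >= 1 with p < 1e-5, enrichment p < 0.05,
#' +-1 nt degradome window with >= 2 reads) and overrides them from a
#' YAML file and/or a named list. Referenced input files must exist.
#'
#' @param path optional YAML config file.
#' @param overrides named list of overrides (applied after the file).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- DEFAULT_CONFIG
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$min_len > 0L, cfg$min_len <= cfg$max_len,
            cfg$min_overlap >= 1L, cfg$min_mfei >= 0,
            cfg$min_energy_ratio >= 0, cfg$min_energy_ratio <= 1,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$enrich_alpha > 0, cfg$enrich_alpha <= 1,
            cfg$degradome_window >= 0L)
  for (key in c("reads", "genome", "transcripts", "degradome", "mature",
                "hairpin", "term_table", "count_table")) {
    for (ref in grep(paste0("^", key), names(cfg), value = TRUE)) {
      p <- cfg[[ref]]
      if (is.character(p) && nzchar(p) && !file.exists(p)) {
        stop("configured input does not exist: ", ref, " = ", p)
      }
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

read_reads_any <- function(path, library_id) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) {
    read_fastq(path)
  } else if (grepl("_x[0-9]+$", sub("\\s.*$", "", first))) {
    read_collapsed_fasta(path, library_id)
  } else {
    unname(read_fasta(path))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in fixed order (preprocess, annotate,
#' novel, de, target, degradome, enrich), writing one TSV per stage into
#' `out_dir` plus `manifest.json` recording the package version, a config
#' hash, the seed and per-stage row counts. Outputs are byte-reproducible
#' for identical (inputs, config, seed). A stage failure retains earlier
#' outputs and is recorded in the manifest.
#'
#' @param config a [pipeline_config()]; inputs used per stage:
#'   `reads` (preprocess), `rRNA`/`tRNA`/`snRNA`/`snoRNA`/`repeat_fa`/
#'   `exon`/`intron` reference FASTAs and `mature`/`hairpin` miRBase-style
#'   FASTAs (annotate), `genome` (novel), `count_table` + `de_pair` (de),
#'   `transcripts` (target), `degradome` (degradome), `term_table`
#'   (enrich).
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "mirseed",
    version = as.character(utils::packageVersion("mirseed")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list(), failed_stage = NULL)
  tags <- NULL; ann <- NULL; novel_tab <- NULL; sites <- NULL
  mirnas <- character(0)

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    counts <- tryCatch(fun(), error = function(e) e)
    if (inherits(counts, "error")) {
      manifest$failed_stage <<- list(stage = name,
                                     message = conditionMessage(counts))
      manifest$stages[[name]] <<- list(status = "error")
      stop("stage '", name, "' failed: ", conditionMessage(counts),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), counts)
  }
  on.exit(jsonlite::write_json(manifest,
                               file.path(out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA,
                               null = "null"))

  run_stage("preprocess", function() {
    raw <- read_reads_any(config$reads, "lib1")
    cc <- cleaning_config(config$min_len, config$max_len,
                          config$adapter_5p, config$adapter_3p)
    res <- clean_reads(raw, cc)
    tags <<- res$tags
    write_collapsed_fasta(res$tags, file.path(out_dir, "clean.fa"))
    ld <- length_distribution(res$tags)
    utils::write.table(ld, file.path(out_dir, "length_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    as.list(res$stats)
  })

  run_stage("annotate", function() {
    if (is.null(tags)) tags <<- read_collapsed_fasta(config$reads, "lib1")
    ref_keys <- c(rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA",
                  snoRNA = "snoRNA", "repeat" = "repeat_fa",
                  exon = "exon", intron = "intron")
    refsets <- list()
    for (cls in names(ref_keys)) {
      p <- config[[ref_keys[[cls]]]]
      if (!is.null(p) && nzchar(p)) {
        refsets[[length(refsets) + 1L]] <- reference_set(cls, read_fasta(p))
      }
    }
    seqs <- vapply(tags, function(t) t$sequence, character(1L))
    cls <- classify_tags(seqs, refsets)
    known <- rep(NA_character_, length(tags))
    if (!is.null(config$mature) && nzchar(config$mature)) {
      db <- mirna_db(read_fasta(config$mature),
                     if (!is.null(config$hairpin) && nzchar(config$hairpin))
                       read_fasta(config$hairpin) else character(0))
      pc <- if (!is.null(config$genome) && nzchar(config$genome))
        make_precursor_check(read_fasta(config$genome), config$flank,
                             config$min_mfei) else NULL
      for (i in which(cls == "unassigned")) {
        call <- call_known_mirna(seqs[i], db, species = config$species,
                                 min_overlap = config$min_overlap,
                                 overlap_mismatches =
                                   config$overlap_mismatches,
                                 max_cross_mm =
                                   config$cross_species_mismatches,
                                 precursor_check = pc)
        if (!is.null(call)) {
          cls[i] <- "known_miRNA"
          known[i] <- call$mirna_id
        }
      }
    }
    ann <<- data.frame(sequence = seqs, annotation = cls,
                       mirna_id = known, stringsAsFactors = FALSE)
    utils::write.table(ann[order(ann$sequence), ],
                       file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_tags = length(seqs),
         n_known = sum(cls == "known_miRNA"))
  })

  run_stage("novel", function() {
    if (is.null(tags)) tags <<- read_collapsed_fasta(config$reads, "lib1")
    genome <- read_fasta(config$genome)
    idx <- if (!is.null(ann))
      which(ann$annotation %in% c("unassigned", "exon", "intron")) else
        seq_along(tags)
    rows <- list()
    for (i in idx) {
      cands <- excise_candidates(tags[[i]]$sequence, genome, config$flank)
      hp <- call_novel(tags[[i]], cands, min_mfei = config$min_mfei,
                       min_count = config$min_novel_count)
      if (!is.null(hp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = tags[[i]]$sequence, chrom = hp$chrom,
          win_start = hp$win_start, win_end = hp$win_end,
          strand = hp$strand, arm = hp$arm, mfe = hp$precursor_mfe,
          mfei = hp$mfei, stringsAsFactors = FALSE)
      }
    }
    novel_tab <<- if (length(rows)) do.call(rbind, rows) else NULL
    out <- if (is.null(novel_tab))
      data.frame(sequence = character(0), chrom = character(0),
                 win_start = integer(0), win_end = integer(0),
                 strand = character(0), arm = character(0),
                 mfe = numeric(0), mfei = numeric(0)) else
      novel_tab[order(novel_tab$sequence), ]
    utils::write.table(out, file.path(out_dir, "novel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_candidates = length(idx), n_novel = nrow(out))
  })

  run_stage("de", function() {
    mat <- read_count_table(config$count_table)
    de <- call_de(mat, config$de_pair, fc_threshold = config$fc_threshold,
                  alpha = config$alpha, method = config$de_method)
    utils::write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_features = nrow(de), n_significant = sum(de$significant))
  })

  run_stage("target", function() {
    txs <- read_fasta(config$transcripts)
    mir_seqs <- c()
    if (!is.null(config$mirnas) && nzchar(config$mirnas)) {
      mir_seqs <- read_fasta(config$mirnas)
    } else {
      if (!is.null(ann)) {
        k <- ann$sequence[ann$annotation == "known_miRNA"]
        mir_seqs <- c(mir_seqs, stats::setNames(k, ann$mirna_id[
          ann$annotation == "known_miRNA"]))
      }
      if (!is.null(novel_tab)) {
        nv <- novel_tab$sequence
        mir_seqs <- c(mir_seqs,
                      stats::setNames(nv, sprintf("novel-%03d",
                                                  seq_along(nv))))
      }
    }
    rows <- list()
    for (i in seq_along(mir_seqs)) {
      for (tx in names(txs)) {
        s <- scan_transcript(mir_seqs[[i]], txs[[tx]], transcript_id = tx,
                             mirna_id = names(mir_seqs)[i],
                             max_mismatch = config$max_mismatch,
                             max_5p_mismatch = config$max_5p_mismatch,
                             min_energy_ratio = config$min_energy_ratio,
                             gu_is_mismatch = config$gu_is_mismatch)
        if (nrow(s)) rows[[length(rows) + 1L]] <- s
      }
    }
    sites <<- if (length(rows)) do.call(rbind, rows) else
      data.frame(mirna_id = character(0), transcript_id = character(0),
                 start = integer(0), end = integer(0),
                 expected_cut = integer(0), mismatch_total = numeric(0),
                 mismatch_5p_1_12 = numeric(0), energy = numeric(0),
                 energy_ratio = numeric(0), stringsAsFactors = FALSE)
    write_site_report(sites, file.path(out_dir, "sites.tsv"))
    list(n_mirnas = length(mir_seqs), n_sites = nrow(sites))
  })

  run_stage("degradome", function() {
    txs <- read_fasta(config$transcripts)
    deg <- read_degradome_tags(config$degradome)
    profiles <- map_tags(deg, txs)
    if (is.null(sites)) {
      sites <<- utils::read.delim(file.path(out_dir, "sites.tsv"),
                                  stringsAsFactors = FALSE)
    }
    validated <- report_validated_pairs(sites, profiles,
                                        window = config$degradome_window,
                                        min_reads =
                                          config$degradome_min_reads)
    write_site_report(validated, file.path(out_dir, "validated_sites.tsv"))
    sites <<- validated
    list(n_profiles = length(profiles), n_validated = nrow(validated))
  })

  run_stage("enrich", function() {
    term_table <- read_term_table(config$term_table)
    background <- names(read_fasta(config$transcripts))
    study <- unique(sites$transcript_id)
    enr <- hypergeom_enrich(study, background, term_table)
    enr$significant <- enr$p_value < config$enrich_alpha
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_terms = nrow(enr), n_significant = sum(enr$significant))
  })

  invisible(manifest)
}

config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  # serialisation-free stable hash of the flattened key=value text
  txt <- paste(names(x), vapply(x, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1L)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) *
                        (seq_along(utf8ToInt(txt)) %% 997L + 1L)) %%
            .Machine$integer.max)
}
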