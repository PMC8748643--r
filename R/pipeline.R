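# Orchestration: validated run configuration, staged analysis bundle and
# the command-line entry point.

.config_keys <- c("reference_order", "queries", "variant_fasta",
                  "variant_annotation", "orf_genes", "window", "step",
                  "genetic_code", "out", "seed")

#' Validate a run configuration
#'
#' A configuration is a JSON file (or an equivalent list) with keys:
#' `queries` (list of genome inputs, each `{fasta, table}` or
#' `{genbank}`), optional `reference_order` (`"ancestral"` or a
#' gene-order text file; default ancestral), optional `variant_fasta` +
#' `variant_annotation` (conspecific variant set), `orf_genes`,
#' parameter overrides `window`, `step`, `genetic_code`, and `out`,
#' `seed`. Unknown keys are rejected; every referenced path must exist.
#'
#' @param config list or path to a JSON config file.
#' @return the validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$queries) || !length(config$queries)) {
    stop("config must list at least one query genome")
  }
  config$reference_order <- config$reference_order %||% "ancestral"
  config$window <- as.integer(config$window %||% 500L)
  config$step <- as.integer(config$step %||% 100L)
  config$genetic_code <- as.integer(config$genetic_code %||% 5L)
  config$seed <- as.integer(config$seed %||% 1L)
  config$out <- config$out %||% "mitocomp_out"
  paths <- c(
    if (!identical(config$reference_order, "ancestral"))
      config$reference_order,
    unlist(lapply(config$queries, function(q)
      unlist(q[intersect(names(q), c("fasta", "table", "genbank"))]))),
    config$variant_fasta, config$variant_annotation)
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    stop("config references missing path(s): ",
         paste(missing, collapse = ", "))
  }
  config
}

load_query <- function(q) {
  if (!is.null(q$genbank)) {
    read_genbank(q$genbank)
  } else if (!is.null(q$fasta) && !is.null(q$table)) {
    read_fasta_with_table(q$fasta, q$table,
                          topology = q$topology %||% "circular")
  } else {
    stop("query must provide either {genbank} or {fasta, table}")
  }
}

#' Run the full comparative analysis bundle
#'
#' Executes the analysis stages against a validated configuration and
#' writes a deterministic report bundle into `config$out`: composition
#' and window-profile TSVs, terminal-codon and RSCU TSVs, rearrangement
#' JSON + event-matrix TSV, ORF-integrity JSON and — when a variant set
#' is configured — SNP and diversity TSVs, plus a run log recording
#' package version, parameters and seed (timestamps are confined to the
#' log). A stage failure aborts with a stage-named message and removes
#' the partial outputs of this run.
#'
#' @param config list or JSON path, see [validate_config()].
#' @param stages subset of
#'   `c("compose", "codon", "orf", "order-diff", "snp")` to run.
#' @return (invisibly) named list of written files.
#' @export
run_compare <- function(config,
                        stages = c("compose", "codon", "orf",
                                   "order-diff", "snp")) {
  config <- tryCatch(validate_config(config),
                     error = function(e) stop("stage [config]: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  fail <- function(stage, e) {
    unlink(written)
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) fail(stage, e))
  }
  log_lines <- c(
    sprintf("mitocomp %s", as.character(utils::packageVersion("mitocomp"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("window: %d  step: %d  genetic_code: %d",
            config$window, config$step, config$genetic_code),
    sprintf("reference_order: %s", config$reference_order),
    sprintf("stages: %s", paste(stages, collapse = ", ")))

  genomes <- run_stage("io", lapply(config$queries, load_query))
  reference <- run_stage("io", {
    if (identical(config$reference_order, "ancestral")) {
      ancestral_insect_order()
    } else read_gene_order(config$reference_order)
  })

  if ("compose" %in% stages) run_stage("compose", {
    tab <- composition_table(genomes)
    utils::write.table(tab, emit(file.path(out_dir, "composition.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in genomes) {
      prof <- window_profile(g, window = config$window, step = config$step)
      utils::write.table(
        data.frame(position = prof$positions,
                   at_deviation = prof$at_deviation,
                   gc_deviation = prof$gc_deviation),
        emit(file.path(out_dir, paste0("profile_", g$id, ".tsv"))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  if ("codon" %in% stages) run_stage("codon", {
    terms <- do.call(rbind, lapply(genomes, function(g) {
      cbind(genome = g$id,
            classify_terminals(g, genetic_code = config$genetic_code))
    }))
    utils::write.table(terms, emit(file.path(out_dir, "terminals.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rscu_cols <- lapply(genomes, function(g)
      suppressWarnings(rscu(g, genetic_code = config$genetic_code)))
    mat <- rscu_cols[[1]][, c("codon", "amino_acid")]
    for (i in seq_along(genomes)) mat[[genomes[[i]]$id]] <- rscu_cols[[i]]$rscu
    utils::write.table(mat, emit(file.path(out_dir, "rscu.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if ("order-diff" %in% stages) run_stage("order-diff", {
    orders <- lapply(genomes, extract_gene_order)
    mtx <- shared_event_matrix(reference, orders)
    reports <- lapply(mtx$reports, function(r) {
      list(reference = r$reference, query = r$query,
           moved_genes = r$moved_genes, events = as.list(r$events),
           n_transpositions = r$n_transpositions,
           n_inversions = r$n_inversions,
           n_inverse_transpositions = r$n_inverse_transpositions,
           excluded_genes = r$excluded_genes)
    })
    jsonlite::write_json(reports,
                         emit(file.path(out_dir, "rearrangements.json")),
                         auto_unbox = TRUE, pretty = TRUE)
    utils::write.table(
      data.frame(taxon = rownames(mtx$events), mtx$events,
                 check.names = FALSE),
      emit(file.path(out_dir, "event_matrix.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if ("orf" %in% stages) run_stage("orf", {
    orf_reports <- list()
    for (g in genomes) {
      pcgs <- config$orf_genes %||%
        g$annotations$symbol[g$annotations$class == "PCG"]
      for (sym in intersect(unlist(pcgs), g$annotations$symbol)) {
        cds <- extract_gene_sequence(g, sym)
        rep_i <- frameshift_hypotheses(cds,
                                       genetic_code = config$genetic_code,
                                       gene = sym)
        if (nrow(rep_i$internal_stops) == 0L) next
        orf_reports[[paste(g$id, sym, sep = ":")]] <- list(
          genome = g$id, gene = sym,
          internal_stops = rep_i$internal_stops,
          truncated_product_length = rep_i$truncated_product_length,
          hypotheses = lapply(rep_i$hypotheses, function(h) {
            list(type = h$type,
                 candidate_interval = h$candidate_interval,
                 n_candidates = length(h$candidate_positions),
                 candidate_positions = h$candidate_positions,
                 downstream_open = h$downstream_open)
          }))
      }
    }
    jsonlite::write_json(orf_reports,
                         emit(file.path(out_dir, "orf_integrity.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  if ("snp" %in% stages && !is.null(config$variant_fasta)) {
    run_stage("snp", {
      dss <- Biostrings::readDNAStringSet(config$variant_fasta)
      aln <- align_variants(dss)
      ann <- if (!is.null(config$variant_annotation)) {
        utils::read.delim(config$variant_annotation, sep = "\t",
                          stringsAsFactors = FALSE)
      } else NULL
      snps <- call_snps(aln, annotation = ann)
      utils::write.table(as.data.frame(snps),
                         emit(file.path(out_dir, "snps.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_snp_matrix(snps, emit(file.path(out_dir, "snp_matrix.tsv")))
      if (!is.null(ann)) {
        div <- diversity_report(snps, ann, aln)
        utils::write.table(div$per_gene,
                           emit(file.path(out_dir, "diversity.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(total_length = div$total_length,
                     total_snps = div$total_snps,
                     snp_density = div$snp_density, pi = div$pi),
          emit(file.path(out_dir, "diversity_total.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(stats::setNames(written, basename(written)))
}

#' Generate the bundled synthetic scenario
#'
#' Writes a complete seeded test scenario emulating the study system: an
#' ancestral-order AT-rich template; a derived genome with 6 planted
#' single-gene transpositions (trnA, trnS1, trnF, trnS2, trnL1, rrnS —
#' the genes moved in the most rearranged strepsipteran mitogenome) and
#' a -1 frameshift deletion at nad5 CDS position 291; 6 conspecific
#' variants with 10 SNPs planted in PCGs and one half-masked variant.
#' Emits FASTA + feature TSVs, a variants FASTA, `manifest.json` and a
#' ready-to-run `config.json`.
#'
#' @param out_dir output directory.
#' @param seed integer seed (drives every random choice).
#' @param length,at_fraction template parameters.
#' @return (invisibly) list with the in-memory `genome`, `variants` and
#'   combined `manifest`.
#' @export
simulate_scenario <- function(out_dir, seed = 1L, length = 16255L,
                              at_fraction = 0.84) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- generate_template(length = length, at_fraction = at_fraction,
                           seed = seed, id = "synth_ref")
  events <- data.frame(
    gene = c("trnA", "trnS1", "trnF", "trnS2", "trnL1", "rrnS"),
    type = "transposition", stringsAsFactors = FALSE)
  rea <- apply_rearrangements(tpl$genome, events, seed = seed + 1L)
  fs <- plant_frameshift(rea$genome, gene = "nad5", position = 291L,
                         seed = seed + 2L)
  genome <- fs$genome
  genome$id <- "synth_query"; genome$taxon <- "synthetic query"
  vars <- make_variants(genome, n_variants = 6L, n_snps = 10L,
                        within_classes = "PCG",
                        missing_pattern = list(variant = 6L,
                                               fraction = 0.5),
                        seed = seed + 3L)
  write_fasta_with_table(tpl$genome,
                         file.path(out_dir, "template.fasta"),
                         file.path(out_dir, "template.tsv"))
  write_fasta_with_table(genome,
                         file.path(out_dir, "query.fasta"),
                         file.path(out_dir, "query.tsv"))
  dss <- Biostrings::DNAStringSet(vars$variants)
  Biostrings::writeXStringSet(dss, file.path(out_dir, "variants.fasta"),
                              width = 70L)
  manifest <- list(seed = seed, template = tpl$manifest$template,
                   rearrangements = rea$manifest,
                   frameshift = fs$manifest[c("gene", "position",
                                              "major_position",
                                              "deleted_base")],
                   variants = vars$manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  config <- list(
    reference_order = "ancestral",
    queries = list(list(fasta = file.path(out_dir, "query.fasta"),
                        table = file.path(out_dir, "query.tsv"))),
    variant_fasta = file.path(out_dir, "variants.fasta"),
    variant_annotation = file.path(out_dir, "query.tsv"),
    out = file.path(out_dir, "results"),
    seed = seed)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, template = tpl$genome,
                 variants = vars$variants, manifest = manifest,
                 config = file.path(out_dir, "config.json")))
}

# stage name -> CLI exit code
.stage_codes <- c(config = 2L, io = 3L, compose = 4L, codon = 5L,
                  orf = 6L, `order-diff` = 7L, snp = 8L, simulate = 9L)

#' Command-line entry point
#'
#' Subcommands: `simulate`, `compose`, `codon`, `orf`, `order-diff`,
#' `snp`, `report`, `all` (`report` and `all` run every stage). Flags:
#' `--config FILE`, `--seed N`, `--out DIR`, `--window N`, `--step N`,
#' `--genetic-code N`. Exit code 0 on success and a distinct nonzero
#' code per failing stage.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return (invisibly) the exit code; when `args` came from the command
#'   line the function quits R with that status.
#' @export
mito_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  interactive_call <- !identical(args, commandArgs(trailingOnly = TRUE))
  finish <- function(code) {
    if (interactive_call) return(invisible(code))
    quit(save = "no", status = code)
  }
  usage <- paste(
    "usage: mitocomp <simulate|compose|codon|orf|order-diff|snp|report|all>",
    "[--config FILE] [--seed N] [--out DIR] [--window N] [--step N]",
    "[--genetic-code N]")
  if (!length(args)) { message(usage); return(finish(2L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed flag: ", rest[i]); return(finish(2L))
    }
    opt[[gsub("-", "_", key)]] <- rest[i + 1L]
    i <- i + 2L
  }
  result <- tryCatch({
    if (cmd == "simulate") {
      simulate_scenario(out_dir = opt$out %||% "mitocomp_scenario",
                        seed = as.integer(opt$seed %||% "1"))
      0L
    } else if (cmd %in% c("compose", "codon", "orf", "order-diff", "snp",
                          "report", "all")) {
      if (is.null(opt$config)) stop("stage [config]: --config is required")
      config <- tryCatch(validate_config(opt$config),
                         error = function(e) {
                           stop("stage [config]: ", conditionMessage(e),
                                call. = FALSE)
                         })
      if (!is.null(opt$out)) config$out <- opt$out
      if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
      if (!is.null(opt$window)) config$window <- as.integer(opt$window)
      if (!is.null(opt$step)) config$step <- as.integer(opt$step)
      if (!is.null(opt$genetic_code)) {
        config$genetic_code <- as.integer(opt$genetic_code)
      }
      stages <- if (cmd %in% c("report", "all")) {
        c("compose", "codon", "orf", "order-diff", "snp")
      } else cmd
      run_compare(config, stages = stages)
      0L
    } else {
      message("unknown subcommand: ", cmd); message(usage)
      2L
    }
  }, error = function(e) {
    msg <- conditionMessage(e)
    message(msg)
    stage <- sub("^stage \\[([^]]+)\\].*$", "\\1", msg)
    unname(.stage_codes[stage] %||% 1L)
  })
  if (is.na(result)) result <- 1L
  finish(as.integer(result))
}
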