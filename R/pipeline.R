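# One-command pipeline: (simulate or load) -> QC -> translated search ->
# quantification -> per-pathway statistics -> co-occurrence network, with
# a config document and a run manifest for provenance.

#' Pipeline configuration
#'
#' All thresholds of the analysis are named, defaulted fields; the
#' defaults are the screening settings the estimator is designed around
#' (mean Q of at least 20,
#' length of at least 70, alignment of 20 aa or more at 70% or higher
#' similarity, all-genes presence rule with four of nine bai genes,
#' network support rho > 0.35 with p and q < 0.05 in 3 or more datasets).
#'
#' @param seed Master seed for every stochastic stage.
#' @param simulate `NULL`, or a list of [community_spec()] arguments plus
#'   `n_samples` (samples to simulate; each gets seed `seed + i`).
#' @param fastq Named character vector of FASTQ paths (alternative to
#'   `simulate`).
#' @param refdb_dir Directory from [write_refdb()]; `NULL` uses the
#'   built-in synthetic template database.
#' @param sample_sheet Optional data.frame (sample_id, dataset, disease,
#'   arm, level, subject, timepoint).
#' @param qc,search,quantify,network Stage parameter lists (partial
#'   override of the defaults).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = NULL, fastq = NULL,
                            refdb_dir = NULL, sample_sheet = NULL,
                            qc = list(), search = list(), quantify = list(),
                            network = list()) {
  merge_defaults <- function(user, def) {
    for (k in names(user)) def[[k]] <- user[[k]]
    def
  }
  structure(list(
    seed = as.integer(seed),
    simulate = simulate, fastq = fastq, refdb_dir = refdb_dir,
    sample_sheet = sample_sheet,
    qc = merge_defaults(qc, list(min_mean_q = 20, min_len = 70)),
    search = merge_defaults(search, list(min_aln = 20, min_ident = 70,
                                         metric = "identity",
                                         gap_open = 11, gap_ext = 1,
                                         prefilter = TRUE, seed_k = 6L)),
    quantify = merge_defaults(quantify, list(median_over = "detected")),
    network = merge_defaults(network, list(rho_threshold = 0.35,
                                           p_threshold = 0.05,
                                           q_threshold = 0.05,
                                           min_datasets = 3L))
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON, or YAML if available)
#'
#' @param config A [pipeline_config()].
#' @param path File path; `.yaml`/`.yml` uses the yaml package.
#' @return `write_config`: path invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("yaml package not available; use a .json path")
    writeLines(yaml::as.yaml(unclass(config)), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[intersect(names(raw),
                                                names(formals(pipeline_config)))])
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Chains simulate/load -> QC -> translated search -> quantification ->
#' group statistics -> network, writing every table and a run manifest
#' to `out_dir`.  Deterministic: the same config and seed yield
#' byte-identical tables.
#'
#' @param config A [pipeline_config()] or a path readable by
#'   [read_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `abundance`, `genus_abundance`,
#'   `detection`, `hits`, `qc`, `stats`, `network` (NULL when not
#'   applicable) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is_string(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  manifest <- list(package_version = as.character(utils::packageVersion("pathofun")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   stages = list())

  refdb <- stage("refdb", {
    if (!is.null(config$refdb_dir)) read_refdb(config$refdb_dir)
    else template_refdb()
  })
  manifest$stages$refdb <- list(n_references = nrow(refdb$meta),
                                n_decoys = sum(refdb$meta$decoy))

  reads <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      n_samples <- sim$n_samples %||% 1L
      sim$n_samples <- NULL
      out <- list()
      for (i in seq_len(n_samples)) {
        sim$seed <- config$seed + i
        spec <- do.call(community_spec, sim)
        genomes <- make_genomes(spec, refdb)
        sid <- sprintf("sim%02d", i)
        out[[sid]] <- sample_reads(genomes, "MTG")
        attr(out[[sid]], "truth") <- truth_table(genomes)
      }
      out
    } else if (!is.null(config$fastq)) {
      missing <- config$fastq[!file.exists(config$fastq)]
      if (length(missing)) stopf("FASTQ not found: %s",
                                 paste(missing, collapse = ", "))
      setNames(lapply(config$fastq, read_fastq),
               names(config$fastq) %||% basename(config$fastq))
    } else stopf("config must provide either 'simulate' or 'fastq'")
  })
  manifest$stages$input <- list(n_samples = length(reads),
                                n_reads = vapply(reads, length, integer(1)))

  clean <- stage("qc", lapply(reads, function(r)
    filter_reads(r, config$qc$min_mean_q, config$qc$min_len)))
  qc_tab <- data.frame(sample_id = names(clean),
                       n_in = vapply(clean, function(x) qc_report(x)$n_in,
                                     integer(1)),
                       n_out = vapply(clean, function(x) qc_report(x)$n_out,
                                      integer(1)),
                       stringsAsFactors = FALSE)
  write_tsv(qc_tab, file.path(out_dir, "qc_report.tsv"))
  manifest$stages$qc <- list(reads_in = sum(qc_tab$n_in),
                             reads_out = sum(qc_tab$n_out))

  hits <- stage("search", {
    hs <- lapply(names(clean), function(sid) {
      h <- assign_top_hits(clean[[sid]], refdb,
                           min_aln = config$search$min_aln,
                           min_ident = config$search$min_ident,
                           metric = config$search$metric,
                           gap_open = config$search$gap_open,
                           gap_ext = config$search$gap_ext,
                           prefilter = config$search$prefilter,
                           seed_k = config$search$seed_k)
      if (nrow(h)) h$sample_id <- sid
      h
    })
    do.call(rbind, hs[vapply(hs, nrow, integer(1)) > 0])
  })
  if (is.null(hits)) hits <- cbind(empty_hits(),
                                   data.frame(sample_id = character()))
  write_hits(hits, file.path(out_dir, "hits.tsv"))
  manifest$stages$search <- list(n_hits = nrow(hits),
                                 n_decoy_hits = sum(hits$decoy))

  quant <- stage("quantify", {
    counts <- count_genes(hits, refdb)
    ab <- pathway_abundance(counts, refdb,
                            median_over = config$quantify$median_over,
                            samples = names(clean))
    ga <- genus_abundance(counts, refdb, samples = names(clean))
    list(counts = counts, abundance = ab, genus = ga,
         detection = detection_fraction(ab))
  })
  write_tsv(quant$abundance, file.path(out_dir, "abundance.tsv"))
  write_tsv(quant$genus, file.path(out_dir, "genus_abundance.tsv"))
  write_tsv(data.frame(pathway = names(quant$detection),
                       detection_pct = unname(quant$detection),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "detection.tsv"))
  manifest$stages$quantify <- list(n_samples = nrow(quant$abundance))

  sheet <- config$sample_sheet
  stats_tab <- NULL
  if (!is.null(sheet) && "arm" %in% names(sheet) &&
      length(unique(sheet$arm)) == 2L) {
    stats_tab <- stage("stats", {
      arm <- setNames(sheet$arm, sheet$sample_id)[quant$abundance$sample_id]
      pws <- setdiff(names(quant$abundance), "sample_id")
      rows <- lapply(pws, function(pw) {
        v <- quant$abundance[[pw]]
        ok <- !is.na(v) & !is.na(arm)
        res <- tryCatch(welch_t_test(log_transform(v[ok]), arm[ok]),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        cbind(data.frame(pathway = pw, stringsAsFactors = FALSE), res)
      })
      do.call(rbind, rows)
    })
    if (!is.null(stats_tab))
      write_tsv(stats_tab, file.path(out_dir, "group_tests.tsv"))
  }

  net <- NULL
  if (!is.null(sheet) && "dataset" %in% names(sheet) &&
      length(unique(sheet$dataset)) >= config$network$min_datasets) {
    net <- stage("network", {
      ds <- setNames(sheet$dataset, sheet$sample_id)
      tabs <- split(quant$abundance, ds[quant$abundance$sample_id])
      build_network(tabs, network_config(
        rho_threshold = config$network$rho_threshold,
        p_threshold = config$network$p_threshold,
        q_threshold = config$network$q_threshold,
        min_datasets = config$network$min_datasets))
    })
    write_network(net, file.path(out_dir, "network_edges.tsv"),
                  file.path(out_dir, "network.graphml"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(abundance = quant$abundance, genus_abundance = quant$genus,
                 detection = quant$detection, hits = hits, qc = qc_tab,
                 stats = stats_tab, network = net, manifest = manifest,
                 reads = reads))
}
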