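#' Write a complete synthetic dataset to disk
#'
#' Generates a toy genome, non-overlapping genes, two-condition ChIP read
#' sets (IP + matched uniform input per condition), a spike-in-bearing
#' counts table, a target gene list, two polysome traces, a category map,
#' and a ground-truth JSON sidecar, all under `out_dir`.
#'
#' The `demo` scale is the package's reference simulation: one 5-Mb
#' chromosome, 200 genes, 8-fold gene-body enrichment in condition 1
#' reduced by 40% in condition 2, 5e5 IP reads plus matched input per
#' condition, a 50-gene target set with 4-fold expression induction, and a
#' 2-fold library-scale distortion on condition 2. The `tiny` scale keeps
#' the same structure at roughly a tenth of the size for fast tests.
#'
#' @param out_dir Output directory (created if needed).
#' @param scale `"tiny"` or `"demo"`.
#' @param seed RNG seed driving every stochastic component.
#' @param loss `"global"`: condition 2 reduces body enrichment at every
#'   gene; `"up_only"`: only the expression-induced target genes lose body
#'   enrichment (for stratified-loss analyses).
#' @param promoter_gain Promoter enrichment factor applied to target genes
#'   in condition 2 (default 1 = none).
#' @return Invisibly, a list with the file `paths` and the ground `truth`.
#' @export
make_fixture <- function(out_dir, scale = c("tiny", "demo"), seed = 1,
                         loss = c("global", "up_only"),
                         promoter_gain = 1) {
  scale <- match.arg(scale)
  loss <- match.arg(loss)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (scale == "demo") {
    list(chrom_len = 5e6, n_genes = 200L, min_len = 1000, max_len = 10000,
         n_reads = 5e5, n_target = 50L, n_down = 30L, n_spike = 10L)
  } else {
    list(chrom_len = 4e5, n_genes = 40L, min_len = 1000, max_len = 4000,
         n_reads = 2.5e4, n_target = 10L, n_down = 8L, n_spike = 8L)
  }
  genome <- genome_spec(c(chr1 = cfg$chrom_len))
  genes <- make_genes(genome, cfg$n_genes, cfg$min_len, cfg$max_len,
                      seed = .sub_seed(seed, 10L))
  picks <- .with_seed(.sub_seed(seed, 11L),
                      sample(genes$gene_id, cfg$n_target + cfg$n_down))
  target <- picks[seq_len(cfg$n_target)]
  down <- picks[cfg$n_target + seq_len(cfg$n_down)]
  fc <- ifelse(genes$gene_id %in% target, 4,
               ifelse(genes$gene_id %in% down, 0.25, 1))
  body1 <- rep(8, cfg$n_genes)
  body2 <- if (loss == "global") body1 * 0.6 else
    ifelse(genes$gene_id %in% target, body1 * 0.6, body1)
  prom2 <- ifelse(genes$gene_id %in% target, promoter_gain, 1)
  sim <- function(body, prom, s, id) simulate_chip(
    genome, genes,
    chip_sim_params(body_enrichment = body, promoter_enrichment = prom,
                    n_reads = cfg$n_reads, seed = .sub_seed(seed, s)),
    sample_id = id)
  reads <- list(
    ip_cond1 = sim(body1, 1, 21L, "ip_cond1"),
    input_cond1 = sim(1, 1, 22L, "input_cond1"),
    ip_cond2 = sim(body2, prom2, 23L, "ip_cond2"),
    input_cond2 = sim(1, 1, 24L, "input_cond2"))
  counts <- simulate_expression(expr_sim_params(
    n_genes = cfg$n_genes, n_spikeins = cfg$n_spike, base_mean = 200,
    fold_changes = fc, library_scale = c(1, 2),
    exon_length = genes$end - genes$start, seed = .sub_seed(seed, 30L)))
  stopifnot(identical(counts$id[counts$type == "gene"], genes$gene_id))
  trace1 <- simulate_polysome_trace(1, 2.5, seed = .sub_seed(seed, 41L))
  trace2 <- simulate_polysome_trace(2, 1, seed = .sub_seed(seed, 42L))
  others <- setdiff(genes$gene_id, c(target, down))
  categories <- rbind(
    data.frame(category_id = "translation_like", gene_id = target),
    data.frame(category_id = "repressed_like", gene_id = down),
    data.frame(category_id = "bystander",
               gene_id = head(others, max(10L, length(others) %/% 3))))
  p <- function(f) file.path(out_dir, f)
  paths <- list(genome = p("genome.tsv"), genes = p("genes.bed12"),
                counts = p("counts.tsv"), targets = p("target_genes.txt"),
                categories = p("categories.tsv"),
                polysome_cond1 = p("polysome_cond1.tsv"),
                polysome_cond2 = p("polysome_cond2.tsv"),
                truth = p("truth.json"))
  for (nm in names(reads)) {
    paths[[nm]] <- p(paste0(nm, ".bed"))
    write_reads(reads[[nm]], paths[[nm]])
  }
  data.table::fwrite(data.table::data.table(chrom = names(genome),
                                            length = as.numeric(genome)),
                     paths$genome, sep = "\t")
  write_genes(genes, paths$genes)
  data.table::fwrite(counts, paths$counts, sep = "\t")
  writeLines(target, paths$targets)
  data.table::fwrite(categories, paths$categories, sep = "\t")
  # polysome region attributes travel in the truth sidecar
  data.table::fwrite(trace1, paths$polysome_cond1, sep = "\t")
  data.table::fwrite(trace2, paths$polysome_cond2, sep = "\t")
  truth <- list(
    scale = scale, seed = seed, loss = loss,
    chrom_len = cfg$chrom_len, n_genes = cfg$n_genes,
    n_reads = cfg$n_reads,
    body_enrichment = list(cond1 = body1, cond2 = body2),
    promoter_enrichment = list(cond1 = rep(1, cfg$n_genes), cond2 = prom2),
    fold_changes = fc, library_scale = c(1, 2),
    target_genes = target, down_genes = down,
    polysome = list(cond1 = list(mono = 1, poly = 2.5),
                    cond2 = list(mono = 2, poly = 1)),
    polysome_regions = list(mono = attr(trace1, "mono_region"),
                            poly = attr(trace1, "poly_region")))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, genes = genes,
                 genome = genome))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.default_params <- function() {
  list(window_size = 50, alpha = 1e-3, neighbor_rule = "both",
       tss_upstream = 1000, tss_downstream = 5000,
       body_scaled_length = 3000, flank = 1000, bin = 50,
       n_trials = 100, tss_halfwidth = 1000,
       fold_cutoff = 2, min_expr = 1, min_genes = 10,
       alpha_corrected = 0.01)
}

#' Run the end-to-end two-condition analysis
#'
#' Stages, in order: read inputs; per condition deduplicate, equalize
#' depth, tile into windows, and call peaks; associate genes with
#' condition-1 peaks within the -1/+5 kb TSS window (condition 1 defines
#' the reference gene universe); build the condition2 - condition1
#' difference track; summarize per-gene body signal and the fraction of
#' associated genes losing signal in condition 2; normalize expression on
#' spike-ins and classify fold changes; profile the difference track by
#' expression stratum; run the target-set resampling null; test category
#' enrichment of the up and down sets; quantify polysome traces. Every
#' stage's outputs are written under `out_dir` and listed in a manifest
#' JSON together with parameters, seed, package version, and input
#' checksums.
#'
#' @param config A named list, or a path to a YAML/JSON file containing
#'   one, with elements `genome` (2-column TSV chrom/length), `genes`
#'   (BED12), `reads` (nested list: `cond1`/`cond2`, each with `ip` and
#'   `input` BED6 paths), `counts` (TSV as written by [make_fixture()]),
#'   `targets` (one gene id per line), `categories` (2-column TSV),
#'   optional `polysome` (named list of trace TSVs + `mono_region`,
#'   `poly_region`), `params` (overrides of the defaults), `seed`, and
#'   `out_dir`.
#' @return Invisibly, the result bundle: peaks per condition, associated
#'   gene ids, `global_loss`, DE table, stratified difference profiles,
#'   `resampling` result, enrichment tables, polysome ratios, and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML/JSON path")
  for (f in c("genome", "genes", "reads", "counts", "targets",
              "categories", "out_dir"))
    .assert(!is.null(config[[f]]), "config is missing '", f, "'")
  prm <- utils::modifyList(.default_params(), config$params %||% list())
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inp <- .stage("load_inputs", {
    gtab <- data.table::fread(config$genome, sep = "\t")
    genome <- genome_spec(setNames(as.numeric(gtab[[2]]),
                                   as.character(gtab[[1]])))
    genes <- read_genes(config$genes, format = "bed12")
    rd <- lapply(c(cond1 = "cond1", cond2 = "cond2"), function(cd)
      list(ip = read_reads(config$reads[[cd]]$ip, genome = genome),
           input = read_reads(config$reads[[cd]]$input, genome = genome)))
    counts <- as.data.frame(data.table::fread(config$counts, sep = "\t"))
    targets <- readLines(config$targets)
    categories <- as.data.frame(data.table::fread(config$categories,
                                                  sep = "\t"))
    list(genome = genome, genes = genes, reads = rd, counts = counts,
         targets = targets, categories = categories)
  })
  pparams <- peak_call_params(prm$window_size, prm$alpha,
                              prm$neighbor_rule, seed = seed)
  calls <- .stage("peak_calling", lapply(inp$reads, function(r)
    call_peaks(r$ip, r$input, inp$genome, pparams)))
  prof_par <- profile_params(prm$tss_upstream, prm$tss_downstream,
                             prm$body_scaled_length, prm$flank, prm$bin)
  assoc <- .stage("associate_genes",
                  associate_genes(calls$cond1$peaks, inp$genes, prof_par))
  diff <- .stage("difference_track",
                 differential_track(calls$cond2$ip_track,
                                    calls$cond1$ip_track))
  loss <- .stage("global_loss", {
    ag <- inp$genes[inp$genes$gene_id %in% assoc, , drop = FALSE]
    r1 <- rpm_track(calls$cond1$ip_track)
    r2 <- rpm_track(calls$cond2$ip_track)
    body <- function(tr) vapply(seq_len(nrow(ag)), function(i)
      interval_means(tr, ag$chrom[i], ag$start[i], ag$end[i]), numeric(1))
    s1 <- body(r1); s2 <- body(r2)
    tab <- data.frame(gene_id = ag$gene_id, body_rpm_1 = s1,
                      body_rpm_2 = s2)
    list(table = tab, n_genes = nrow(tab),
         fraction_lower = mean(s2 < s1),
         percent_lower = 100 * mean(s2 < s1))
  })
  expr <- .stage("expression", {
    et <- spikein_normalize(expression_table(inp$counts))
    list(table = et, de = classify_de(et, prm$fold_cutoff, prm$min_expr))
  })
  strata <- .stage("stratified_profiles", {
    labs <- c("up", "down", "unchanged")
    lst <- lapply(labs, function(lb) {
      ids <- intersect(expr$de$id[expr$de$label == lb], inp$genes$gene_id)
      if (length(ids) == 0) return(NULL)
      g <- inp$genes[inp$genes$gene_id %in% ids, , drop = FALSE]
      pr <- tss_profile(diff, g, prof_par)
      list(label = lb, n = nrow(g), profile = pr,
           mean_diff = mean(pr$signal))
    })
    lst[!vapply(lst, is.null, logical(1))]
  })
  meta <- .stage("metagene", {
    ag <- inp$genes[inp$genes$gene_id %in% assoc, , drop = FALSE]
    if (nrow(ag) == 0) NULL else
      suppressWarnings(metagene(rpm_track(calls$cond1$ip_track), ag,
                                prof_par))
  })
  resamp <- .stage("resampling", {
    tset <- intersect(inp$targets, inp$genes$gene_id)
    resample_null(diff, inp$genes, tset,
                  params = resampling_params(prm$n_trials,
                                             prm$tss_halfwidth, prm$bin,
                                             seed = .sub_seed(seed, 50L)))
  })
  enrich <- .stage("category_enrichment", {
    uni <- expr$de$id
    lapply(c(up = "up", down = "down"), function(lb)
      category_enrichment(expr$de$id[expr$de$label == lb],
                          inp$categories, uni, prm$min_genes,
                          prm$alpha_corrected))
  })
  poly <- .stage("polysome", {
    pcfg <- config$polysome
    if (is.null(pcfg)) NULL else {
      traces <- setdiff(names(pcfg), c("mono_region", "poly_region"))
      vapply(traces, function(nm) {
        tr <- as.data.frame(data.table::fread(pcfg[[nm]], sep = "\t"))
        polysome_ratio(tr, unlist(pcfg$mono_region),
                       unlist(pcfg$poly_region))
      }, numeric(1))
    }
  })
  outputs <- .stage("write_outputs", {
    o <- function(f) file.path(out_dir, f)
    files <- c(peaks_cond1 = o("peaks_cond1.tsv"),
               peaks_cond2 = o("peaks_cond2.tsv"),
               diff_track = o("difference.bedgraph"),
               associated = o("associated_genes.txt"),
               body_signal = o("body_signal.tsv"),
               de = o("de_labels.tsv"),
               resampling = o("resampling.json"))
    data.table::fwrite(calls$cond1$peaks, files["peaks_cond1"], sep = "\t")
    data.table::fwrite(calls$cond2$peaks, files["peaks_cond2"], sep = "\t")
    write_track(diff, files["diff_track"])
    writeLines(assoc, files["associated"])
    data.table::fwrite(loss$table, files["body_signal"], sep = "\t")
    data.table::fwrite(expr$de, files["de"], sep = "\t")
    jsonlite::write_json(
      list(observed_summary = resamp$observed_summary,
           null_summaries = resamp$null_summaries,
           empirical_p = resamp$empirical_p, n_trials = resamp$n_trials),
      files["resampling"], auto_unbox = TRUE, digits = NA)
    for (lb in names(enrich)) {
      f <- o(paste0("enrichment_", lb, ".tsv"))
      data.table::fwrite(enrich[[lb]], f, sep = "\t")
      files[paste0("enrichment_", lb)] <- f
    }
    if (!is.null(meta)) {
      files["metagene"] <- o("metagene_cond1.tsv")
      data.table::fwrite(meta, files["metagene"], sep = "\t")
    }
    files
  })
  manifest <- .stage("manifest", {
    input_files <- c(config$genome, config$genes, config$counts,
                     config$targets, config$categories,
                     unlist(config$reads))
    mf <- list(package_version = as.character(packageVersion("chromadapt")),
               seed = seed, params = prm,
               inputs = as.list(tools::md5sum(input_files)),
               outputs = as.list(outputs),
               depth = lapply(calls, `[[`, "depth"),
               n_peaks = lapply(calls, function(x) nrow(x$peaks)),
               n_associated = length(assoc),
               global_loss_percent = loss$percent_lower,
               resampling_p = resamp$empirical_p,
               polysome_ratios = as.list(poly))
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    mf
  })
  invisible(list(peaks = lapply(calls, `[[`, "peaks"),
                 tracks = list(ip_cond1 = calls$cond1$ip_track,
                               ip_cond2 = calls$cond2$ip_track,
                               difference = diff),
                 associated_genes = assoc, global_loss = loss,
                 expression = expr, strata = strata, metagene = meta,
                 resampling = resamp, enrichment = enrich,
                 polysome_ratios = poly, manifest = manifest))
}

#' Config skeleton for [run_pipeline()] from a fixture directory
#'
#' Builds the config list wiring a [make_fixture()] output directory into
#' the pipeline, so `run_pipeline(fixture_config(dir))` runs end to end.
#'
#' @param fixture_dir Directory previously populated by [make_fixture()].
#' @param out_dir Where pipeline outputs go (default: `<fixture_dir>/out`).
#' @param seed RNG seed.
#' @param params Optional parameter overrides (see [run_pipeline()]).
#' @return A config list.
#' @export
fixture_config <- function(fixture_dir, out_dir = file.path(fixture_dir,
                                                            "out"),
                           seed = 1, params = list()) {
  p <- function(f) file.path(fixture_dir, f)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(genome = p("genome.tsv"), genes = p("genes.bed12"),
       reads = list(cond1 = list(ip = p("ip_cond1.bed"),
                                 input = p("input_cond1.bed")),
                    cond2 = list(ip = p("ip_cond2.bed"),
                                 input = p("input_cond2.bed"))),
       counts = p("counts.tsv"), targets = p("target_genes.txt"),
       categories = p("categories.tsv"),
       polysome = list(cond1 = p("polysome_cond1.tsv"),
                       cond2 = p("polysome_cond2.tsv"),
                       mono_region = truth$polysome_regions$mono,
                       poly_region = truth$polysome_regions$poly),
       params = params, seed = seed, out_dir = out_dir)
}
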