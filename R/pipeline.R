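# End-to-end orchestration: structure pipeline (scan -> rank -> thread ->
# interface -> report) and rescue pipeline (broods -> line summaries ->
# fractions -> classifications -> compensation -> bootstrap CIs), with a
# validated config, stage logs and machine-readable outputs.

PIPELINE_KEYS <- c(
  "query_fasta", "query_offset", "templates", "spacing", "cutoff",
  "weighting", "reference_genotype", "thresholds", "compensation",
  "broods_csv", "seed", "out_dir", "bootstrap_B", "exclude_genotypes")

#' Read and validate a pipeline configuration
#'
#' YAML or JSON (chosen by extension).  Unknown top-level keys are rejected
#' so typos fail before any stage runs.
#'
#' @param path Config file, or a named list already in memory.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  defaults <- list(query_offset = 1L, cutoff = 5.0, weighting = "unweighted",
                   seed = 1L, bootstrap_B = 1000L,
                   thresholds = c(null_like = 0.10, full = 0.80),
                   exclude_genotypes = character())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  th <- unlist(cfg$thresholds)
  cfg$thresholds <- c(null_like = as.numeric(th[["null_like"]]),
                      full = as.numeric(th[["full"]]))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(log, stage, ...) {
  entry <- list(stage = stage, ...)
  c(log, list(entry))
}

abort_stage <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

#' Run the structure analysis pipeline
#'
#' Scan the query for its zinc-ligand assignment, rank the annotated
#' templates, thread the query onto the best template's backbone, call the
#' interface residues against the template's partner chain, and write scan
#' JSON, ranking TSV, threaded-model PDB, interface TSV/JSON and a combined
#' JSON report stamped with the config hash.  Deterministic: rerunning on the
#' same inputs reproduces the same files.
#'
#' @param config A `pipeline_config` (or path, passed to
#'   [read_pipeline_config()]).  Uses keys `query_fasta`, `query_offset`,
#'   `templates` (list of `id`, `pdb`, `sequence` or `fasta`,
#'   `ligand_positions`, optional `partner_chain`), `spacing`, `cutoff`,
#'   `out_dir`.
#' @return Invisible list with the stage results and output paths.
#' @export
run_structure_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  out_dir <- cfg$out_dir %||% stop("out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  if (is.null(cfg$query_fasta)) abort_stage("scan", "query_fasta missing")
  query <- read_fasta(cfg$query_fasta, offset = cfg$query_offset)[[1L]]
  model <- if (is.null(cfg$spacing)) spacing_model()
           else do.call(spacing_model, cfg$spacing)
  assignments <- scan_ring_ligands(query, model)
  assignment <- tryCatch(assign_unique(assignments),
                         error = function(e) abort_stage("scan",
                                                         conditionMessage(e)))
  scan_path <- file.path(out_dir, "scan.json")
  scan_to_json(assignments, scan_path)
  log <- stage_log(log, "scan", n_assignments = length(assignments),
                   positions = assignment$positions)

  if (is.null(cfg$templates) || length(cfg$templates) == 0L)
    abort_stage("rank", "no templates configured")
  templates <- lapply(cfg$templates, function(t) {
    if (is.null(t$ligand_positions))
      abort_stage("rank", sprintf("template %s lacks ligand annotation",
                                  t$id %||% "<unnamed>"))
    if (is.null(t$sequence) && !is.null(t$fasta))
      t$sequence <- read_fasta(t$fasta)[[1L]]$residues
    t$structure <- read_structure(t$pdb)
    t
  })
  ranking <- rank_templates(list(sequence = query, assignment = assignment),
                            templates)
  rank_path <- file.path(out_dir, "template_ranking.tsv")
  utils::write.table(as.data.frame(ranking), rank_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "rank", best = ranking$template_id[1L])

  best <- templates[[which(vapply(templates, `[[`, "", "id") ==
                             ranking$template_id[1L])[1L]]]
  aln <- pairwise_global_align(query, protein_sequence(best$id, best$sequence))
  threaded <- thread_model(query, best$structure, aln,
                           template_chain = best$template_chain %||% NULL)
  model_path <- file.path(out_dir, "model.pdb")
  write_structure(threaded, model_path)
  log <- stage_log(log, "thread", template = best$id,
                   n_unmodeled = length(attr(threaded, "unmodeled")))

  partner_chain <- best$partner_chain
  if (is.null(partner_chain)) abort_stage("interface",
                                          "best template has no partner_chain")
  partner_atoms <- best$structure$atoms[
    best$structure$atoms$chain == partner_chain, , drop = FALSE]
  if (nrow(partner_atoms) == 0L)
    abort_stage("interface", sprintf("chain %s absent from template %s",
                                     partner_chain, best$id))
  partner <- structure_model(partner_atoms)
  iface <- interface_residues(threaded, partner, cutoff = cfg$cutoff)
  write_interface_report(iface, file.path(out_dir, "interface.tsv"))
  write_interface_report(iface, file.path(out_dir, "interface.json"))
  log <- stage_log(log, "interface", cutoff = cfg$cutoff,
                   n_residues = nrow(iface))

  combined <- list(
    config_hash = config_hash(cfg),
    scan = list(n_assignments = length(assignments),
                positions = assignment$positions,
                excluded_candidates = assignment$excluded_candidates),
    ranking = as.data.frame(ranking),
    interface = as.data.frame(iface),
    unmodeled = attr(threaded, "unmodeled"),
    stages = log)
  jsonlite::write_json(combined, file.path(out_dir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assignment = assignment, ranking = ranking,
                 threaded = threaded, interface = iface, log = log,
                 out_dir = out_dir))
}

#' Run the rescue quantification pipeline
#'
#' Reads a brood CSV (long or summary format), applies the recombinant
#' filter where control broods are present, summarises each genotype against
#' the reference, classifies rescue strength, runs the configured
#' compensation triples, attaches bootstrap intervals, and writes JSON and
#' TSV reports stamped with the config hash.
#'
#' @param config A `pipeline_config` (or path).  Uses keys `broods_csv`,
#'   `reference_genotype`, `weighting`, `thresholds`, `compensation` (list of
#'   `list(single_a =, single_b =, double =)` genotype triples),
#'   `bootstrap_B`, `seed`, `out_dir`, `exclude_genotypes`.
#' @return Invisible list with genotype summaries, compensation results and
#'   output paths.
#' @export
run_rescue_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  out_dir <- cfg$out_dir %||% stop("out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$broods_csv)) abort_stage("read", "broods_csv missing")
  lines <- read_brood_csv(cfg$broods_csv)
  log <- list()
  log <- stage_log(log, "read", n_lines = length(lines))

  has_controls <- any(vapply(lines, function(l) !is.null(l$control_counts),
                             TRUE))
  if (has_controls) {
    filt <- suppressWarnings(recombinant_filter(lines))
    lines <- filt$retained
    log <- stage_log(log, "recombinant_filter",
                     n_excluded = length(filt$excluded))
  }

  by_geno <- split_by_genotype(lines)
  by_geno <- by_geno[setdiff(names(by_geno), cfg$exclude_genotypes)]
  ref_label <- cfg$reference_genotype %||% "wild type"
  if (!ref_label %in% names(by_geno))
    abort_stage("rescue", sprintf("reference genotype '%s' absent", ref_label))
  reference <- by_geno[[ref_label]]
  summaries <- lapply(by_geno, function(g)
    genotype_rescue(g, reference, weighting = cfg$weighting,
                    thresholds = cfg$thresholds))
  cis <- lapply(names(by_geno), function(g)
    suppressWarnings(bootstrap_ci(by_geno[[g]], reference,
                                  B = cfg$bootstrap_B, seed = cfg$seed,
                                  weighting = cfg$weighting)))
  names(cis) <- names(by_geno)
  log <- stage_log(log, "rescue", n_genotypes = length(summaries),
                   reference = ref_label)

  comp <- lapply(cfg$compensation, function(tr) {
    for (k in c("single_a", "single_b", "double"))
      if (is.null(summaries[[tr[[k]]]]))
        abort_stage("compensation", sprintf("genotype '%s' absent", tr[[k]]))
    compensation_test(summaries[[tr$single_a]], summaries[[tr$single_b]],
                      summaries[[tr$double]], thresholds = cfg$thresholds)
  })
  if (length(comp)) log <- stage_log(log, "compensation", n = length(comp))

  tab <- do.call(rbind, lapply(names(summaries), function(g) {
    s <- summaries[[g]]
    data.frame(genotype = g, n_lines = length(s$line_means),
               grand_mean = s$grand_mean,
               rescue_fraction = s$rescue_fraction,
               rescue_percent = 100 * s$rescue_fraction,
               classification = s$classification,
               ci_lower = cis[[g]][1L], ci_upper = cis[[g]][2L])
  }))
  utils::write.table(tab, file.path(out_dir, "rescue.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  payload <- list(
    config_hash = config_hash(cfg),
    reference = ref_label,
    genotypes = tab,
    compensation = lapply(comp, unclass),
    stages = log)
  jsonlite::write_json(payload, file.path(out_dir, "rescue.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summaries = summaries, compensation = comp, ci = cis,
                 table = tab, log = log, out_dir = out_dir))
}
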