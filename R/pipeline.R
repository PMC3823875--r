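#' Configuration for an end-to-end run
#'
#' @param input_dir Directory of input files (as written by
#'   [write_benchmark()]); `NULL` (default) simulates a benchmark instead.
#' @param sim_params [benchmark_params()] used when simulating.
#' @param sources Drug-kernel variants to evaluate: any of `"chem"`,
#'   `"inter"` (target), `"side-effect"`, `"comb"` (fusion of all three).
#' @param aggregator Target-set / disease-set aggregator, `"max"` or `"mean"`.
#' @param alignment [alignment_params()] for target similarity.
#' @param d Rarity-weight smoothing parameter for binary profiles.
#' @param folds Outer CV folds.
#' @param grid,inner_folds Penalty grid and inner folds for [select_C()].
#' @param C Fixed penalty; `NULL` selects per fold.
#' @param lodo Also run leave-one-drug-out CV per source.
#' @param seed Master integer seed; all sampling seeds derive from it.
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, sim_params = benchmark_params(),
                       sources = c("chem", "inter", "side-effect", "comb"),
                       aggregator = "max", alignment = alignment_params(),
                       d = 10, folds = 10, grid = default_C_grid(),
                       inner_folds = 3, C = NULL, lodo = FALSE,
                       seed = 1, out_dir = NULL) {
  sources <- match.arg(sources, c("chem", "inter", "side-effect", "comb"),
                       several.ok = TRUE)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_fmt("input directory '%s' does not exist", input_dir)
  }
  structure(as.list(environment()), class = "run_config")
}

config_echo <- function(config) {
  flat <- c(
    input_dir = config$input_dir %||% "(simulated)",
    sources = paste(config$sources, collapse = ","),
    aggregator = config$aggregator,
    substitution_matrix = config$alignment$substitution_matrix_name,
    gap_open = config$alignment$gap_open,
    gap_extend = config$alignment$gap_extend,
    d = config$d, folds = config$folds,
    grid = paste(format(config$grid), collapse = ","),
    inner_folds = config$inner_folds,
    C = if (is.null(config$C)) "(inner CV)" else format(config$C),
    lodo = config$lodo, seed = config$seed
  )
  if (is.null(config$input_dir)) {
    sp <- config$sim_params
    flat <- c(flat, unlist(lapply(sp[setdiff(names(sp), "targets_per_drug")], format)),
              targets_per_drug = paste(sp$targets_per_drug, collapse = "-"))
  }
  paste0("config.", names(flat), "=", unname(flat))
}

load_inputs <- function(config) {
  if (is.null(config$input_dir)) {
    b <- generate_benchmark(config$sim_params)
    return(list(chem = b$chem, se = b$se, targets = b$targets,
                sequences = b$sequences, pheno = b$pheno,
                associations = b$associations))
  }
  dir <- config$input_dir
  td <- read_target_data(file.path(dir, "drug_targets.tsv"),
                         file.path(dir, "target_sequences.fasta"))
  pheno <- read_similarity_matrix(file.path(dir, "phenotype_similarity.tsv"))
  chem <- read_fingerprints(file.path(dir, "chem_fingerprints.tsv"))
  list(chem = chem,
       se = read_fingerprints(file.path(dir, "side_effects.tsv")),
       targets = td$targets, sequences = td$sequences, pheno = pheno,
       associations = read_associations(
         file.path(dir, "associations.tsv"),
         drugs = rownames(chem), diseases = rownames(pheno)))
}

#' Build the per-source drug kernels
#'
#' Computes the chemical, target and side-effect drug similarity matrices and
#' their unweighted-mean fusion ("comb") over a common drug universe.
#'
#' @param inputs List with `chem`, `se`, `targets`, `sequences` (as produced
#'   by [generate_benchmark()] or the readers).
#' @param drugs Drug universe (row order of the output matrices).
#' @param aggregator,alignment,d See [run_config()].
#' @return Named list of similarity matrices: `chem`, `inter`, `side-effect`,
#'   `comb`.
#' @export
build_drug_kernels <- function(inputs, drugs, aggregator = "max",
                               alignment = alignment_params(), d = 10) {
  chem <- weighted_cosine_matrix(inputs$chem[drugs, , drop = FALSE], d = d)
  se <- weighted_cosine_matrix(inputs$se[drugs, , drop = FALSE], d = d)
  inter <- target_set_similarity_matrix(inputs$targets, inputs$sequences,
                                        params = alignment,
                                        aggregator = aggregator,
                                        drugs = drugs)
  list("chem" = chem, "inter" = inter, "side-effect" = se,
       "comb" = combine_drug_kernels(list(chem, inter, se)))
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[predr] stage %s ...", name))
  out <- tryCatch(expr, error = function(e) {
    stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
  })
  message(sprintf("[predr] stage %s done (%.1fs)", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full pipeline
#'
#' Executes the three phases end to end — collect (simulate or read inputs),
#' build similarities, then kernel + SVM + cross-validated evaluation per
#' requested source — and, when `out_dir` is set, writes a report bundle:
#' per-source per-fold TSVs, a JSON metrics report, and a provenance file
#' echoing the configuration with its MD5 hash and seed (two runs with equal
#' hashes and seeds produce identical reports). Progress is logged to standard
#' error; results never are.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cv` (per-source [kfold_cv()] objects),
#'   `lodo` (if requested), `kernels`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  inputs <- run_stage("collect", load_inputs(config))
  a <- inputs$associations
  kernels <- run_stage("similarities", build_drug_kernels(
    inputs, a$drugs, aggregator = config$aggregator,
    alignment = config$alignment, d = config$d))
  cv <- list(); lodo <- list()
  for (src in config$sources) {
    cv[[src]] <- run_stage(paste0("cv/", src), kfold_cv(
      a, kernels[[src]], inputs$pheno, k = config$folds, seed = config$seed,
      C = config$C, grid = config$grid, inner_folds = config$inner_folds))
    if (isTRUE(config$lodo)) {
      lodo[[src]] <- run_stage(paste0("lodo/", src), leave_one_drug_out(
        a, kernels[[src]], inputs$pheno, seed = config$seed,
        C = config$C, grid = config$grid, inner_folds = config$inner_folds))
    }
  }
  hash <- NA_character_
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(config$out_dir, "config.txt")
    writeLines(config_echo(config), cfg_path)
    hash <- unname(tools::md5sum(cfg_path))
    report <- list(config_hash = hash, seed = config$seed)
    for (src in names(cv)) {
      per_fold <- cv[[src]]$per_fold
      per_fold$config_hash <- hash
      utils::write.table(per_fold,
                         file.path(config$out_dir, paste0("cv_", gsub("-", "_", src), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report[[src]] <- list(cv_mean = as.list(cv[[src]]$mean),
                            cv_pooled = as.list(cv[[src]]$pooled))
      if (isTRUE(config$lodo)) {
        report[[src]]$lodo <- list(mean_auc = lodo[[src]]$mean_auc,
                                   micro_auc = lodo[[src]]$micro_auc)
      }
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cv = cv, lodo = lodo, kernels = kernels,
                 pheno = inputs$pheno, associations = a, config_hash = hash))
}
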