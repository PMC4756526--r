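#' Write a patient-allocation table
#'
#' One CSV row per patient, sorted by patient index, with the header
#' `patient_id,main_pool,control_pool`. Pool numbering is global: main pools
#' `1..p_m`, control pools continuing `p_m+1..p_m+p_c`, so e.g. the first
#' control pool of a 5-main-pool design is `P6`. NoReplica leaves
#' `control_pool` empty; for the interleaved OptReplica design the two
#' columns hold each patient's two pools in ascending id order. Output is
#' deterministic and locale-independent (byte-identical across runs).
#'
#' @param design A [pooling design][allocate].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_allocation_table <- function(design, path) {
  stopifnot(inherits(design, "pooling_design"))
  sp <- signature_pairs(design)
  df <- data.frame(patient_id = seq_len(design$n_patients),
                   main_pool = sp[, 1], control_pool = sp[, 2])
  lines <- c("patient_id,main_pool,control_pool",
             sprintf("%d,%d,%s", df$patient_id, df$main_pool,
                     ifelse(is.na(df$control_pool), "",
                            as.character(df$control_pool))))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a patient-allocation table
#'
#' Inverse of [write_allocation_table()]: reconstructs the pooling design
#' from the CSV (pool members come back in ascending patient order).
#'
#' @param path CSV file written by [write_allocation_table()].
#' @param algorithm The algorithm the table was produced by (the CSV itself
#'   is layout-only).
#' @param pool_size Pool size of the design; inferred from the largest pool
#'   when `NULL`.
#' @return A `pooling_design`.
#' @export
read_allocation_table <- function(path, algorithm, pool_size = NULL) {
  algorithm <- match.arg(algorithm, planner_algorithms())
  df <- read.csv(path, colClasses = c("integer", "integer", "integer"))
  n <- nrow(df)
  stopifnot(identical(df$patient_id, seq_len(n)))
  interleaved <- algorithm == "optreplica"
  ids <- sort(unique(c(df$main_pool, df$control_pool[!is.na(df$control_pool)])))
  pools <- lapply(ids, function(i)
    df$patient_id[!is.na(df$main_pool) & df$main_pool == i |
                    (!is.na(df$control_pool) & df$control_pool == i)])
  names(pools) <- NULL
  if (interleaved) {
    main <- pools
    ctrl <- list()
  } else {
    p_m <- max(df$main_pool)
    main <- pools[ids <= p_m]
    ctrl <- pools[ids > p_m]
  }
  m <- pool_size %||% max(lengths(pools))
  new_pooling_design(algorithm, m, n, main, ctrl, interleaved = interleaved)
}

#' Serialize planner results
#'
#' Writes a machine-readable JSON rendering and, for tabular objects, a CSV
#' rendering. Sweeps use the columns
#' `pool_size,num_pools,sanger_tests,waiting,total_cost,optimal`;
#' comparisons write the metric-by-algorithm summary. Money is rendered as
#' plain integers (all costs are whole euros), never scientific notation.
#'
#' @param x A `configuration_sweep`, `algorithm_comparison` or
#'   `design_verification` object.
#' @param json_path Path of the JSON file (`NULL` to skip).
#' @param csv_path Path of the CSV file (`NULL` to skip; ignored for
#'   verification reports).
#' @return Invisibly, the list representation that was serialized.
#' @export
write_summary <- function(x, json_path = NULL, csv_path = NULL) {
  rep <- summary_payload(x)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csv_path)) {
    tab <- summary_table(x)
    if (!is.null(tab)) write.csv(tab, csv_path, row.names = FALSE,
                                 quote = FALSE)
  }
  invisible(rep)
}

summary_payload <- function(x) {
  if (inherits(x, "configuration_sweep")) {
    list(kind = "configuration_sweep",
         algorithm = attr(x, "algorithm"),
         configurations = lapply(seq_len(nrow(x)), function(i) {
           r <- as.list(x[i, , drop = FALSE])
           if (!r$applicable) {
             r <- r[c("pool_size", "applicable")]
             r$reason <- "fewer main pools than the pool size"
           }
           r
         }))
  } else if (inherits(x, "algorithm_comparison")) {
    list(kind = "algorithm_comparison",
         params = x$params[c("n_patients", "m_max", "n_mutations",
                             "ngs_cost", "sanger_cost")],
         metadata = x$params$metadata,
         algorithms = lapply(x$algorithms, function(e) {
           if (!e$applicable) return(list(applicable = FALSE,
                                          reason = e$reason))
           b <- e$breakdown
           list(applicable = TRUE,
                optimal = as.list(e$optimal),
                breakdown = b[c("algorithm", "pool_size", "num_pools",
                                "ngs_cost", "sanger_tests", "sanger_cost",
                                "total", "waiting")])
         }))
  } else if (inherits(x, "design_verification")) {
    c(list(kind = "design_verification"),
      x[c("algorithm", "pool_size", "n_patients", "trials", "seed",
          "carrier_fraction", "ok", "budget", "worst_sanger",
          "worst_seed")],
      list(violations = x$violations))
  } else stop("no summary serialization for class ",
              paste(class(x), collapse = "/"), call. = FALSE)
}

summary_table <- function(x) {
  if (inherits(x, "configuration_sweep")) {
    data.frame(pool_size = x$pool_size,
               num_pools = x$num_pools,
               sanger_tests = x$sanger_tests,
               waiting = x$waiting,
               total_cost = format(x$total_cost, scientific = FALSE,
                                   trim = TRUE),
               optimal = tolower(x$optimal))
  } else if (inherits(x, "algorithm_comparison")) {
    tab <- x$summary
    for (alg in planner_algorithms())
      tab[[alg]] <- format(tab[[alg]], scientific = FALSE, trim = TRUE)
    tab
  } else NULL
}

cli_log <- function(quiet, ...) {
  if (!quiet) message("[poolplan] ", sprintf(...))
}

cli_params_options <- function() {
  list(
    optparse::make_option("--patients", type = "integer",
                          help = "number of patients in the cohort"),
    optparse::make_option("--max-pool-size", type = "integer",
                          dest = "max_pool_size",
                          help = "maximum patients per pool"),
    optparse::make_option("--mutations", type = "integer", default = 0L,
                          help = "expected mutations per patient [%default]"),
    optparse::make_option("--ngs-cost", type = "double", default = 0,
                          dest = "ngs_cost",
                          help = "euros per sequenced pool [%default]"),
    optparse::make_option("--sanger-cost", type = "double", default = 0,
                          dest = "sanger_cost",
                          help = "euros per Sanger test [%default]"),
    optparse::make_option("--config", type = "character",
                          help = "YAML or JSON file with any of these flags"),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir", help = "output directory [%default]"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE,
                          help = "suppress progress messages"),
    optparse::make_option("--mapping-quality", type = "character",
                          dest = "mapping_quality",
                          help = "pass-through metadata (unused)"),
    optparse::make_option("--min-reads", type = "character",
                          dest = "min_reads",
                          help = "pass-through metadata (unused)"),
    optparse::make_option("--coverage", type = "character",
                          help = "pass-through metadata (unused)"),
    optparse::make_option("--dna-range", type = "character",
                          dest = "dna_range",
                          help = "pass-through metadata (unused)"))
}

cli_read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

cli_build_params <- function(opt) {
  if (!is.null(opt$config)) {
    cfg <- cli_read_config(opt$config)
    for (nm in names(cfg)) {
      key <- gsub("-", "_", nm)
      if (is.null(opt[[key]]) ||
          key %in% c("mutations", "ngs_cost", "sanger_cost") &&
          identical(opt[[key]], formals_default(key)))
        opt[[key]] <- cfg[[nm]]
    }
  }
  if (is.null(opt$patients) || is.null(opt$max_pool_size))
    stop("--patients and --max-pool-size are required", call. = FALSE)
  meta <- opt[c("mapping_quality", "min_reads", "coverage", "dna_range")]
  meta <- meta[!vapply(meta, is.null, logical(1))]
  params <- suppressWarnings(
    design_parameters(opt$patients, opt$max_pool_size, opt$mutations,
                      opt$ngs_cost, opt$sanger_cost, metadata = meta))
  if (length(meta))
    cli_log(isTRUE(opt$quiet),
            "pass-through metadata accepted unvalidated: %s",
            paste(names(meta), collapse = ", "))
  params
}

formals_default <- function(key) {
  switch(key, mutations = 0L, ngs_cost = 0, sanger_cost = 0, NULL)
}

#' Command-line interface of the planner
#'
#' Subcommands:
#' \describe{
#'   \item{`plan`}{one algorithm (`--algorithm`, optional fixed
#'     `--pool-size`); writes `allocation.csv`, `sweep.csv`, `sweep.json`
#'     and `summary.json` to `--out-dir` and prints the chosen
#'     configuration.}
#'   \item{`compare`}{all four algorithms; prints the side-by-side table and
#'     writes `comparison.csv` / `comparison.json`.}
#'   \item{`verify`}{Monte-Carlo decodability check (`--trials`, `--seed`,
#'     optional `--carrier-fraction`); writes `verification.json`.}
#' }
#' Shared flags: `--patients`, `--max-pool-size`, `--mutations`,
#' `--ngs-cost`, `--sanger-cost`, `--config` (YAML/JSON file of the same
#' keys), `--out-dir`, `--quiet`, and the pass-through metadata flags
#' `--mapping-quality`, `--min-reads`, `--coverage`, `--dna-range` (recorded
#' in the JSON summary, never used in any computation).
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit code, invisibly: 0 on success, 2 on usage or
#'   validation errors.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: poolplan <plan|compare|verify> [options]; see --help"
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1]
  if (!cmd %in% c("plan", "compare", "verify")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(invisible(2L))
  }
  rest <- args[-1]
  res <- tryCatch(
    switch(cmd,
           plan = cli_plan(rest),
           compare = cli_compare(rest),
           verify = cli_verify(rest)),
    error = function(e) {
      message("error: ", conditionMessage(e))
      2L
    })
  invisible(res)
}

cli_plan <- function(args) {
  opts <- c(cli_params_options(), list(
    optparse::make_option("--algorithm", type = "character",
                          default = "diagwalks",
                          help = "allocation algorithm [%default]"),
    optparse::make_option("--pool-size", type = "integer",
                          dest = "pool_size",
                          help = "fix the pool size instead of optimizing")))
  opt <- optparse::parse_args(
    optparse::OptionParser(option_list = opts, prog = "poolplan plan"),
    args = args)
  params <- cli_build_params(opt)
  alg <- match.arg(opt$algorithm, planner_algorithms())
  quiet <- isTRUE(opt$quiet)
  sw <- sweep_configurations(params, alg)
  m <- if (!is.null(opt$pool_size)) {
    if (!opt$pool_size %in% sw$pool_size[sw$applicable])
      stop("pool size ", opt$pool_size, " is not applicable for ", alg)
    opt$pool_size
  } else sw$pool_size[sw$optimal]
  cli_log(quiet, "planning %s for %d patients, pool size %d%s",
          alg, params$n_patients, m,
          if (is.null(opt$pool_size)) " (cost-optimal)" else " (fixed)")
  design <- suppressWarnings(allocate(alg, params$n_patients, m))
  cb <- cost_breakdown(design, params)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_allocation_table(design, file.path(opt$out_dir, "allocation.csv"))
  write_summary(sw, file.path(opt$out_dir, "sweep.json"),
                file.path(opt$out_dir, "sweep.csv"))
  jsonlite::write_json(
    c(list(kind = "plan", algorithm = alg, pool_size = m),
      cb[c("num_pools", "ngs_cost", "sanger_tests", "sanger_cost",
           "total", "waiting")],
      list(metadata = params$metadata)),
    file.path(opt$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  print(cb)
  cli_log(quiet, "wrote allocation.csv, sweep.csv, sweep.json, summary.json to %s",
          opt$out_dir)
  0L
}

cli_compare <- function(args) {
  opt <- optparse::parse_args(
    optparse::OptionParser(option_list = cli_params_options(),
                           prog = "poolplan compare"),
    args = args)
  params <- cli_build_params(opt)
  cmp <- compare_algorithms(params)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summary(cmp, file.path(opt$out_dir, "comparison.json"),
                file.path(opt$out_dir, "comparison.csv"))
  print(cmp)
  cli_log(isTRUE(opt$quiet), "wrote comparison.csv, comparison.json to %s",
          opt$out_dir)
  0L
}

cli_verify <- function(args) {
  opts <- c(cli_params_options(), list(
    optparse::make_option("--algorithm", type = "character",
                          default = "diagwalks",
                          help = "allocation algorithm [%default]"),
    optparse::make_option("--pool-size", type = "integer",
                          dest = "pool_size",
                          help = "pool size (default: cost-optimal)"),
    optparse::make_option("--trials", type = "integer", default = 100L,
                          help = "number of random scenarios [%default]"),
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "random seed [%default]"),
    optparse::make_option("--carrier-fraction", type = "double",
                          default = 0.05, dest = "carrier_fraction",
                          help = "per-patient carrier probability [%default]")))
  opt <- optparse::parse_args(
    optparse::OptionParser(option_list = opts, prog = "poolplan verify"),
    args = args)
  params <- cli_build_params(opt)
  alg <- match.arg(opt$algorithm, planner_algorithms())
  m <- opt$pool_size %||%
    {
      sw <- sweep_configurations(params, alg)
      sw$pool_size[sw$optimal]
    }
  design <- suppressWarnings(allocate(alg, params$n_patients, m))
  ver <- verify_design(design, params, trials = opt$trials,
                       seed = opt$seed,
                       carrier_fraction = opt$carrier_fraction)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summary(ver, file.path(opt$out_dir, "verification.json"))
  print(ver)
  if (ver$ok) 0L else 1L
}
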