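#' Ambiguity groups of a pooling design
#'
#' Patients sharing an identical pool-membership signature cannot be told
#' apart from pool-level sequencing results alone: a mutation carried by one
#' of them lights up exactly the same set of pools whichever of them carries
#' it. Each such maximal set is an ambiguity group. For replica designs a
#' group of size `o >= 2` exists precisely where a main pool and a control
#' pool share `o` patients; for the NoReplica design every main pool is one
#' group, since a pool is each member's entire signature.
#'
#' @param design A [pooling design][allocate].
#' @return A data frame with one row per group: `group_id`, `main_pool`,
#'   `control_pool` (`NA` when the signature has a single pool), `size`, and
#'   a list column `members` of patient indices. Rows are ordered by the
#'   smallest member index.
#' @examples
#' ambiguity_groups(allocate("diagwalks", 15, 3))
#' @export
ambiguity_groups <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  sp <- signature_pairs(design)
  key <- signature_keys(sp, length(all_pools(design)))
  grp <- unname(split(seq_len(design$n_patients), key))
  grp <- grp[order(vapply(grp, `[`, 0L, 1L))]
  first <- vapply(grp, `[`, 0L, 1L)
  data.frame(
    group_id = seq_along(grp),
    main_pool = sp[first, 1],
    control_pool = sp[first, 2],
    size = lengths(grp),
    members = I(grp),
    row.names = NULL)
}

#' Sanger test budget of a design
#'
#' Number of confirmatory Sanger tests the design requires in the planning
#' (worst-case) model, in which every patient carries `n_mutations`
#' mutations. Each ambiguity group of size `o` costs `o^2` tests per
#' mutation (each of the `o` indistinguishable mutations is confirmed
#' against each of the `o` candidate patients). Replica designs pay only for
#' groups of size two or more; NoReplica pays for every pool member
#' (`sum(m_i^2)` over pool sizes), the literal worst case of assigning every
#' pooled mutation.
#'
#' @param design A [pooling design][allocate].
#' @param n_mutations Expected mutations per patient (non-negative integer).
#' @return Integer count of Sanger tests (cost is applied separately).
#' @examples
#' sanger_test_count(allocate("noreplica", 2000, 3), 20)  # 119960
#' @export
sanger_test_count <- function(design, n_mutations) {
  stopifnot(inherits(design, "pooling_design"),
            length(n_mutations) == 1, n_mutations >= 0)
  key <- signature_keys(signature_pairs(design),
                        length(all_pools(design)))
  k <- sort.int(key, method = "radix")
  sizes <- diff(c(which(!duplicated(k)), length(k) + 1L))
  if (design$algorithm != "noreplica") sizes <- sizes[sizes > 1]
  tests <- as.numeric(n_mutations) * sum(as.numeric(sizes)^2)
  if (tests > .Machine$integer.max)
    stop("Sanger test count exceeds integer range", call. = FALSE)
  as.integer(tests)
}

#' Waiting time of a design
#'
#' Number of patient samples that must have arrived (patient index doubling
#' as arrival order) before the first complete main + control unit can go on
#' the sequencer. For Transposition and DiagWalks this is the largest
#' patient index in the first control pool — the pool containing patient 1;
#' the designs without a separable control partition (NoReplica,
#' OptReplica) must wait for the whole cohort, by convention `n`.
#'
#' @param design A [pooling design][allocate].
#' @return Integer number of patients.
#' @examples
#' waiting_time(allocate("transposition", 64, 6))  # 56
#' @export
waiting_time <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  if (length(design$control_pools) == 0 || design$interleaved)
    return(design$n_patients)
  has1 <- vapply(design$control_pools, function(p) 1L %in% p, logical(1))
  first <- design$control_pools[[which(has1)[1]]]
  as.integer(max(first))
}

#' Cost breakdown of a pooling design
#'
#' Total cost of the experiment: every pool (main and control alike) is one
#' NGS sequencing run at `ngs_cost`, and each ambiguity group of size `o`
#' adds `n_mutations * o^2` Sanger tests at `sanger_cost` (see
#' [sanger_test_count()]).
#'
#' @param design A [pooling design][allocate].
#' @param params A [design_parameters()] object.
#' @return An object of class `cost_breakdown`: list with `algorithm`,
#'   `pool_size`, `num_pools`, `ngs_cost`, `sanger_tests`, `sanger_cost`,
#'   `total` (euros) and `waiting` (patients).
#' @examples
#' p <- design_parameters(2000, 20, 20, 1000, 8)
#' cost_breakdown(allocate("diagwalks", 2000, 20), p)
#' @export
cost_breakdown <- function(design, params) {
  stopifnot(inherits(design, "pooling_design"))
  params <- validate_parameters(params)
  np <- n_pools(design)[["total"]]
  tests <- sanger_test_count(design, params$n_mutations)
  ngs <- np * params$ngs_cost
  sang <- tests * params$sanger_cost
  structure(
    list(algorithm = design$algorithm,
         pool_size = design$pool_size,
         num_pools = np,
         ngs_cost = ngs,
         sanger_tests = tests,
         sanger_cost = sang,
         total = ngs + sang,
         waiting = waiting_time(design)),
    class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Cost breakdown (%s, pool size %d)\n", x$algorithm,
              x$pool_size))
  cat(sprintf("  pools:        %d (NGS %s)\n", x$num_pools,
              format_euro(x$ngs_cost)))
  cat(sprintf("  Sanger tests: %d (%s)\n", x$sanger_tests,
              format_euro(x$sanger_cost)))
  cat(sprintf("  total:        %s\n", format_euro(x$total)))
  cat(sprintf("  waiting:      %d patients\n", x$waiting))
  invisible(x)
}

#' Sweep candidate pool sizes for one algorithm
#'
#' Evaluates every pool size `m` in `1..min(m_max, n)`, marking sizes where
#' the algorithm is inapplicable (Transposition with fewer main pools than
#' the pool size) rather than dropping them, and flags the applicable row
#' with the minimum total cost as optimal. Cost ties are broken in favour of
#' the larger pool size (fewer NGS batches).
#'
#' @param params A [design_parameters()] object (or raw list; see
#'   [validate_parameters()]).
#' @param algorithm One of the four algorithm names.
#' @return A data frame of class `configuration_sweep` with columns
#'   `pool_size`, `applicable`, `num_main`, `num_control`, `num_pools`,
#'   `sanger_tests`, `waiting`, `total_cost`, `optimal`.
#' @examples
#' sweep_configurations(design_parameters(128, 8, 7, 1000, 10), "noreplica")
#' @export
sweep_configurations <- function(params,
                                 algorithm = c("noreplica", "optreplica",
                                               "transposition",
                                               "diagwalks")) {
  params <- validate_parameters(params)
  algorithm <- match.arg(algorithm)
  sizes <- seq_len(params$m_eff)
  rows <- lapply(sizes, function(m) {
    if (!algorithm_applicable(algorithm, params$n_patients, m))
      return(data.frame(pool_size = m, applicable = FALSE,
                        num_main = NA_integer_, num_control = NA_integer_,
                        num_pools = NA_integer_, sanger_tests = NA_integer_,
                        waiting = NA_integer_, total_cost = NA_real_,
                        optimal = FALSE))
    d <- suppressWarnings(allocate(algorithm, params$n_patients, m))
    cb <- cost_breakdown(d, params)
    np <- n_pools(d)
    data.frame(pool_size = m, applicable = TRUE,
               num_main = np[["main"]], num_control = np[["control"]],
               num_pools = np[["total"]], sanger_tests = cb$sanger_tests,
               waiting = cb$waiting, total_cost = cb$total, optimal = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$applicable))
    stop("no applicable pool size for algorithm '", algorithm, "'",
         call. = FALSE)
  ok <- which(out$applicable)
  best <- ok[out$total_cost[ok] == min(out$total_cost[ok])]
  out$optimal[max(best)] <- TRUE   # tie -> larger pool size
  class(out) <- c("configuration_sweep", "data.frame")
  attr(out, "algorithm") <- algorithm
  out
}

#' Compare the four allocation algorithms
#'
#' Runs [sweep_configurations()] for each algorithm, extracts each one's
#' cost-optimal configuration, and lays the results out side by side (pool
#' size, pools, Sanger tests, waiting time, total cost). Inapplicability is
#' reported in-column, not raised.
#'
#' @param params A [design_parameters()] object (or raw list).
#' @return An object of class `algorithm_comparison`: list with `params`,
#'   `summary` (metric x algorithm data frame), and per-algorithm entries
#'   holding the sweep, the optimal row, the design and its
#'   [cost_breakdown()].
#' @examples
#' compare_algorithms(design_parameters(64, 6, 5, 1000, 8))
#' @export
compare_algorithms <- function(params) {
  params <- validate_parameters(params)
  per <- lapply(setNames(nm = planner_algorithms()), function(alg) {
    sw <- tryCatch(sweep_configurations(params, alg), error = function(e) e)
    if (inherits(sw, "error"))
      return(list(applicable = FALSE, reason = conditionMessage(sw)))
    row <- sw[sw$optimal, ]
    d <- suppressWarnings(allocate(alg, params$n_patients, row$pool_size))
    list(applicable = TRUE, sweep = sw, optimal = row,
         design = d, breakdown = cost_breakdown(d, params))
  })
  metric <- c("pool_size", "num_pools", "sanger_tests", "waiting",
              "total_cost")
  summary <- data.frame(metric = metric)
  for (alg in planner_algorithms()) {
    e <- per[[alg]]
    summary[[alg]] <- if (!e$applicable) rep(NA_real_, length(metric))
      else unlist(e$optimal[metric], use.names = FALSE)
  }
  structure(list(params = params, summary = summary, algorithms = per),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  cat(sprintf("Algorithm comparison (n = %d, max pool size = %d, N_m = %d)\n",
              x$params$n_patients, x$params$m_max, x$params$n_mutations))
  tab <- x$summary
  rownames(tab) <- c("Pool size", "Num pools", "Num Sanger tests",
                     "Expected patient (waiting)", "Total cost (EUR)")
  tab$metric <- NULL
  print(format(tab, big.mark = ",", scientific = FALSE))
  best <- names(tab)[which.min(as.numeric(tab["Total cost (EUR)", ]))]
  cat(sprintf("Cheapest design: %s\n", best))
  invisible(x)
}
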