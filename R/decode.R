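#' Simulate mutation carriers on a cohort
#'
#' Builds a reproducible carrier scenario: each patient independently is a
#' carrier with probability `carrier_fraction`, and each carrier receives
#' between 1 and `n_mutations` private rare mutations (uniformly). Rare
#' variants in distinct patients are modelled as distinct alleles, so every
#' simulated mutation has exactly one true owner.
#'
#' @param n Cohort size.
#' @param n_mutations Maximum mutations a carrier may bring (>= 1 for any
#'   carrier to exist).
#' @param carrier_fraction Probability that a patient is a carrier, in
#'   `[0, 1]`.
#' @param seed Integer seed; identical inputs give identical scenarios.
#' @param carriers Optional named integer vector (names = patient indices,
#'   values = mutation counts) to build a fixed scenario directly, bypassing
#'   sampling.
#' @return An object of class `carrier_scenario`: list with `n`, `carriers`
#'   (named integer vector) and `seed`.
#' @examples
#' simulate_carriers(15, 2, 0.2, seed = 1)
#' simulate_carriers(15, 1, carriers = c("7" = 1))  # forced scenario
#' @export
simulate_carriers <- function(n, n_mutations, carrier_fraction = 0.05,
                              seed = 1L, carriers = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1, n_mutations >= 0)
  if (is.null(carriers)) {
    if (carrier_fraction < 0 || carrier_fraction > 1)
      stop("'carrier_fraction' must be in [0, 1]", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    who <- which(runif(n) < carrier_fraction)
    cnt <- if (n_mutations == 0) integer(0) else
      sample.int(n_mutations, length(who), replace = TRUE)
    if (n_mutations == 0) who <- integer(0)
    carriers <- setNames(as.integer(cnt), who)
  } else {
    idx <- as.integer(names(carriers))
    if (anyNA(idx) || any(idx < 1 | idx > n) || anyDuplicated(idx))
      stop("'carriers' names must be unique patient indices in 1..n",
           call. = FALSE)
    if (any(carriers < 0) || (length(carriers) &&
                              max(carriers) > max(1, n_mutations)))
      stop("carrier mutation counts must be in 0..n_mutations",
           call. = FALSE)
    carriers <- setNames(as.integer(carriers), idx)
    carriers <- carriers[carriers > 0]
  }
  structure(list(n = n, carriers = carriers, seed = as.integer(seed)),
            class = "carrier_scenario")
}

# mutation events of a scenario: one row per (mutation, owner)
mutation_events <- function(scenario) {
  owners <- rep(as.integer(names(scenario$carriers)), scenario$carriers)
  data.frame(mutation = if (length(owners))
    paste0("M", seq_along(owners)) else character(0),
    owner = owners)
}

#' Idealized pool-level readout
#'
#' Sequencing each pool is modelled as perfect: a pool is positive for a
#' mutation exactly when it contains that mutation's carrier. No
#' false-positive or false-negative model is applied — the cost model this
#' simulator validates presumes perfect pool-level detection.
#'
#' @param design A [pooling design][allocate].
#' @param scenario A [simulate_carriers()] scenario over the same cohort.
#' @return A logical matrix (pools x mutations, class `pool_readout`) with
#'   rownames `P1..` and one column per simulated mutation; the attribute
#'   `pool_positive` gives the per-pool any-mutation summary.
#' @export
pool_readout <- function(design, scenario) {
  stopifnot(inherits(design, "pooling_design"),
            inherits(scenario, "carrier_scenario"),
            design$n_patients == scenario$n)
  pools <- all_pools(design)
  ev <- mutation_events(scenario)
  sig <- pool_signatures(design)
  out <- matrix(FALSE, nrow = length(pools), ncol = nrow(ev),
                dimnames = list(paste0("P", seq_along(pools)), ev$mutation))
  for (j in seq_len(nrow(ev))) out[sig[[ev$owner[j]]], j] <- TRUE
  attr(out, "pool_positive") <- apply(out, 1, any)
  attr(out, "owner") <- ev$owner
  class(out) <- c("pool_readout", class(out))
  out
}

#' Decode pool-level positives back to patients
#'
#' For each mutation, the candidate set is every patient whose complete
#' pool-membership signature equals the set of pools positive for that
#' mutation. A singleton candidate set resolves the mutation; larger sets
#' are ambiguous and must be settled by Sanger tests — one test per
#' (mutation, candidate) pair, plus one per resolved mutation under the
#' NoReplica design, whose budget formula charges every pool member.
#'
#' @param design A [pooling design][allocate].
#' @param readout A [pool_readout()] matrix over the design's pools.
#' @return An object of class `decode_result`: list with `table` (one row
#'   per mutation: `mutation`, `n_candidates`, `resolved`, `consistent`,
#'   list column `candidates`), `sanger_needed` (budget convention),
#'   `sanger_strict` (tests for ambiguous mutations only) and
#'   `inconsistent` (count of readouts matching no patient signature).
#' @export
decode_mutations <- function(design, readout) {
  stopifnot(inherits(design, "pooling_design"), is.matrix(readout))
  if (nrow(readout) != length(all_pools(design)))
    stop("readout rows must match the design's pools", call. = FALSE)
  n_pool <- length(all_pools(design))
  key <- signature_keys(signature_pairs(design), n_pool)
  nm <- ncol(readout)
  cand <- vector("list", nm)
  for (j in seq_len(nm)) {
    pos <- unname(which(readout[, j]))
    cand[[j]] <- if (length(pos) %in% 1:2)
      which(key == pos[1] + (n_pool + 1) *
              (if (length(pos) == 2) pos[2] else 0L))
    else integer(0)
  }
  nc <- lengths(cand)
  tab <- data.frame(
    mutation = colnames(readout) %||% sprintf("M%d", seq_len(nm)),
    n_candidates = nc,
    resolved = nc == 1L,
    consistent = nc >= 1L,
    candidates = I(cand))
  strict <- sum(nc[nc >= 2L])
  needed <- if (design$algorithm == "noreplica") sum(nc) else strict
  structure(list(table = tab,
                 sanger_needed = as.integer(needed),
                 sanger_strict = as.integer(strict),
                 inconsistent = sum(nc == 0L)),
            class = "decode_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Decode result: %d mutation(s), %d resolved, %d ambiguous",
              nrow(x$table), sum(x$table$resolved),
              sum(x$table$n_candidates >= 2)))
  if (x$inconsistent) cat(sprintf(", %d inconsistent", x$inconsistent))
  cat(sprintf("\n  Sanger tests needed: %d (budget convention), %d (strict)\n",
              x$sanger_needed, x$sanger_strict))
  invisible(x)
}

#' Exhaustive single-carrier decode partition
#'
#' Runs the full readout-and-decode pipeline for each of the `n`
#' single-carrier scenarios and returns the candidate set observed for each
#' patient. Since a design's pool signatures are fixed, these candidate sets
#' partition the cohort; the partition must coincide with the design's
#' [ambiguity_groups()].
#'
#' @param design A [pooling design][allocate].
#' @return List of integer vectors, indexed by carrier patient: the decoded
#'   candidate set when that patient is the sole carrier of one mutation.
#' @export
single_carrier_partition <- function(design) {
  lapply(seq_len(design$n_patients), function(k) {
    sc <- simulate_carriers(design$n_patients, 1,
                            carriers = setNames(1L, k))
    dec <- decode_mutations(design, pool_readout(design, sc))
    dec$table$candidates[[1]]
  })
}

#' Verify a design's decodability against its Sanger budget
#'
#' Monte-Carlo harness: over `trials` random carrier scenarios it checks
#' that (i) every ambiguous candidate set is contained in one ambiguity
#' group computed analytically by [ambiguity_groups()], (ii) no readout is
#' inconsistent, and (iii) the realized Sanger demand never exceeds the
#' worst-case budget [sanger_test_count()]. Any violation is reported with
#' the offending scenario's seed.
#'
#' @param design A [pooling design][allocate].
#' @param params A [design_parameters()] object (supplies `n_mutations`).
#' @param trials Number of random scenarios (>= 1).
#' @param seed Integer seed for the harness; scenario `i` uses `seed + i`.
#' @param carrier_fraction Carrier probability per patient (default 0.05,
#'   a rare-variant regime).
#' @return An object of class `design_verification`: list with `ok`,
#'   `trials`, `seed`, `budget`, `worst_sanger` (largest realized demand),
#'   `worst_seed`, and `violations` (data frame, empty when `ok`).
#' @examples
#' p <- design_parameters(15, 3, 1, 1000, 8)
#' verify_design(allocate("transposition", 15, 3), p, trials = 20, seed = 1)
#' @export
verify_design <- function(design, params, trials = 100, seed = 1L,
                          carrier_fraction = 0.05) {
  stopifnot(inherits(design, "pooling_design"), trials >= 1)
  params <- validate_parameters(params)
  budget <- sanger_test_count(design, params$n_mutations)
  groups <- ambiguity_groups(design)$members
  gid <- integer(design$n_patients)
  for (i in seq_along(groups)) gid[groups[[i]]] <- i
  worst <- 0L
  worst_seed <- NA_integer_
  viol <- list()
  for (i in seq_len(trials)) {
    s <- as.integer(seed) + i
    sc <- simulate_carriers(design$n_patients, params$n_mutations,
                            carrier_fraction, seed = s)
    dec <- decode_mutations(design, pool_readout(design, sc))
    if (dec$sanger_needed > worst) {
      worst <- dec$sanger_needed
      worst_seed <- s
    }
    bad_group <- vapply(dec$table$candidates, function(cs)
      length(cs) >= 2 && length(unique(gid[cs])) != 1, logical(1))
    if (any(bad_group))
      viol[[length(viol) + 1]] <- data.frame(
        seed = s, kind = "candidates_span_groups")
    if (dec$inconsistent > 0)
      viol[[length(viol) + 1]] <- data.frame(
        seed = s, kind = "inconsistent_readout")
    if (dec$sanger_needed > budget)
      viol[[length(viol) + 1]] <- data.frame(
        seed = s, kind = "budget_exceeded")
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(seed = integer(0), kind = character(0))
  structure(list(ok = nrow(violations) == 0,
                 trials = as.integer(trials), seed = as.integer(seed),
                 carrier_fraction = carrier_fraction,
                 budget = budget, worst_sanger = worst,
                 worst_seed = worst_seed, violations = violations,
                 algorithm = design$algorithm,
                 pool_size = design$pool_size,
                 n_patients = design$n_patients),
            class = "design_verification")
}

#' @export
print.design_verification <- function(x, ...) {
  cat(sprintf("Design verification: %s (pool size %d, %d patients)\n",
              x$algorithm, x$pool_size, x$n_patients))
  cat(sprintf("  %d trials (seed %d): %s\n", x$trials, x$seed,
              if (x$ok) "all checks passed" else
                sprintf("%d violation(s)", nrow(x$violations))))
  cat(sprintf("  worst realized Sanger demand %d of budget %d\n",
              x$worst_sanger, x$budget))
  invisible(x)
}
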