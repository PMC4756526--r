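#' Design parameters for a pooled sequencing experiment
#'
#' Bundles and validates the five scalar inputs of the planner: cohort size,
#' maximum pool size, expected number of rare mutations per patient, and the
#' two unit costs. The effective maximum pool size is clamped to the cohort
#' size, so `m_max > n_patients` describes the meaningful degenerate design
#' of a single pool holding the whole cohort.
#'
#' @param n_patients Number of patients in the cohort (positive integer).
#' @param m_max Maximum number of patients allowed in a single pool
#'   (positive integer).
#' @param n_mutations Expected number of rare mutations carried per patient
#'   (non-negative integer); multiplies the Sanger test budget.
#' @param ngs_cost Cost of sequencing one pool on the NGS platform, in
#'   euros (non-negative).
#' @param sanger_cost Cost of one confirmatory Sanger test, in euros
#'   (non-negative).
#' @param metadata Optional named list of pass-through experiment metadata
#'   (e.g. mapping quality, minimum reads per patient, coverage, DNA
#'   quantity range). Recorded verbatim; never influences any computation.
#'
#' @return An object of class `design_parameters`: a list with the validated
#'   fields plus `m_eff`, the effective maximum pool size
#'   `min(m_max, n_patients)`.
#' @examples
#' design_parameters(2000, 20, 20, 1000, 8)
#' @export
design_parameters <- function(n_patients, m_max, n_mutations = 0,
                              ngs_cost = 0, sanger_cost = 0,
                              metadata = list()) {
  check_count <- function(x, name, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x))
      stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    if (x != trunc(x))
      stop(sprintf("'%s' must be an integer", name), call. = FALSE)
    if (x < min)
      stop(sprintf("'%s' must be >= %d", name, min), call. = FALSE)
    as.integer(x)
  }
  check_money <- function(x, name) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0)
      stop(sprintf("'%s' must be a single non-negative number", name),
           call. = FALSE)
    as.numeric(x)
  }
  n_patients <- check_count(n_patients, "n_patients", min = 1)
  m_max <- check_count(m_max, "m_max", min = 1)
  n_mutations <- check_count(n_mutations, "n_mutations", min = 0)
  if (!is.list(metadata))
    stop("'metadata' must be a list", call. = FALSE)
  if (length(metadata) > 0) {
    if (is.null(names(metadata)) || any(names(metadata) == ""))
      stop("'metadata' entries must be named", call. = FALSE)
    warning("pass-through metadata recorded but not validated; ",
            "it has no effect on any computed quantity", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients,
         m_max = m_max,
         m_eff = min(m_max, n_patients),
         n_mutations = n_mutations,
         ngs_cost = check_money(ngs_cost, "ngs_cost"),
         sanger_cost = check_money(sanger_cost, "sanger_cost"),
         metadata = metadata),
    class = "design_parameters")
}

#' Validate (or coerce) design parameters
#'
#' Accepts either a ready [design_parameters()] object (returned unchanged)
#' or the raw scalars, which are validated and normalized.
#'
#' @param params A `design_parameters` object or a named list of the raw
#'   fields.
#' @return A validated `design_parameters` object.
#' @export
validate_parameters <- function(params) {
  if (inherits(params, "design_parameters")) return(params)
  if (!is.list(params)) stop("'params' must be a list", call. = FALSE)
  do.call(design_parameters, params)
}

#' @export
print.design_parameters <- function(x, ...) {
  cat("Pooled-experiment design parameters\n")
  cat(sprintf("  patients:            %d\n", x$n_patients))
  cat(sprintf("  max pool size:       %d (effective %d)\n", x$m_max, x$m_eff))
  cat(sprintf("  mutations/patient:   %d\n", x$n_mutations))
  cat(sprintf("  NGS cost per pool:   %s\n", format_euro(x$ngs_cost)))
  cat(sprintf("  Sanger cost per test:%s\n", format_euro(x$sanger_cost)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Main-pool matrix of a cohort
#'
#' Lays the cohort out column-major in an `m` x `ceiling(n/m)` matrix whose
#' columns are the main pools: patient `(c-1)*m + r` sits in cell `(r, c)`;
#' cells past patient `n` are `NA`. This layout is the coordinate system of
#' the diagonal-walk allocator.
#'
#' @param n Cohort size (positive integer).
#' @param m Pool size, `1 <= m <= n`.
#' @return An integer matrix of class `main_pool_matrix` with `m` rows and
#'   `ceiling(n/m)` columns.
#' @examples
#' build_main_matrix(15, 3)[1, 2]  # patient 4
#' @export
build_main_matrix <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || n < 1 || m < 1 || m > n)
    stop("require 1 <= m <= n", call. = FALSE)
  p_m <- ceiling(n / m)
  v <- rep(NA_integer_, m * p_m)
  v[seq_len(n)] <- seq_len(n)
  structure(matrix(v, nrow = m, ncol = p_m),
            class = c("main_pool_matrix", "matrix", "array"))
}

# constructor shared by all allocators; pools are integer vectors of
# 1-based patient indices, control pools numbered after main pools
new_pooling_design <- function(algorithm, pool_size, n_patients,
                               main_pools, control_pools = list(),
                               interleaved = FALSE) {
  structure(
    list(algorithm = algorithm,
         pool_size = as.integer(pool_size),
         n_patients = as.integer(n_patients),
         main_pools = main_pools,
         control_pools = control_pools,
         interleaved = interleaved),
    class = "pooling_design")
}

#' Number of pools of a design
#'
#' @param design A [pooling design][allocate].
#' @return Named integer vector with elements `main`, `control`, `total`.
#'   For the interleaved OptReplica design all pools are reported as `main`.
#' @export
n_pools <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  pm <- length(design$main_pools)
  pc <- length(design$control_pools)
  c(main = pm, control = pc, total = pm + pc)
}

# list of all pools in global id order (main 1..p_m, control p_m+1..)
all_pools <- function(design) {
  c(design$main_pools, design$control_pools)
}

# per-patient pool-membership signature: list of sorted global pool ids
pool_signatures <- function(design) {
  pools <- all_pools(design)
  pid <- rep.int(seq_along(pools), lengths(pools))
  pat <- unlist(pools, use.names = FALSE)
  o <- order(pat, pid)
  unname(split(pid[o], factor(pat[o], levels = seq_len(design$n_patients))))
}

# signatures as an n x 2 matrix (first/second pool id, NA when single);
# valid for all four algorithms, whose designs give each patient at most
# two pool memberships
signature_pairs <- function(design) {
  pools <- all_pools(design)
  pid <- rep.int(seq_along(pools), lengths(pools))
  pat <- unlist(pools, use.names = FALSE)
  o <- order(pat, pid)
  pat <- pat[o]
  pid <- pid[o]
  n <- design$n_patients
  s1 <- rep(NA_integer_, n)
  s2 <- rep(NA_integer_, n)
  f <- !duplicated(pat)
  s1[pat[f]] <- pid[f]
  s2[pat[!f]] <- pid[!f]
  cbind(s1, s2)
}

# collision-free scalar key for a (pool, pool-or-NA) signature; double
# arithmetic so large pool counts cannot overflow
signature_keys <- function(sp, n_pool) {
  unname(as.numeric(sp[, 1]) +
           (n_pool + 1) * ifelse(is.na(sp[, 2]), 0, as.numeric(sp[, 2])))
}

#' @export
print.pooling_design <- function(x, ...) {
  np <- n_pools(x)
  cat(sprintf("Pooling design: %s (pool size %d, %d patients)\n",
              x$algorithm, x$pool_size, x$n_patients))
  if (x$interleaved) {
    cat(sprintf("  %d interleaved pools (each patient in two)\n",
                np[["total"]]))
  } else {
    cat(sprintf("  %d main pool(s), %d control pool(s)\n",
                np[["main"]], np[["control"]]))
  }
  show <- utils::head(all_pools(x), 6)
  for (i in seq_along(show))
    cat(sprintf("  P%d: %s\n", i, paste(show[[i]], collapse = ", ")))
  if (np[["total"]] > 6) cat(sprintf("  ... (%d more)\n", np[["total"]] - 6))
  invisible(x)
}

# internal: shared argument checking for the allocators
check_nm <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 1) stop("'n' must be a positive integer", call. = FALSE)
  if (is.na(m) || m < 1 || m > n)
    stop("pool size 'm' must satisfy 1 <= m <= n", call. = FALSE)
  list(n = n, m = m)
}

format_euro <- function(x) {
  paste0(formatC(x, format = "f", digits = if (all(x == trunc(x))) 0 else 2,
                 big.mark = ",", mode = "double"), " €")
}
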