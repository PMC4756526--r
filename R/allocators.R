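#' Allocate patients into pools
#'
#' Dispatches to one of the four deterministic allocation algorithms.
#' Patient indices are 1-based and double as arrival order: patient `k` is
#' the k-th sample to arrive, which is what gives the waiting-time metric
#' its meaning.
#'
#' \describe{
#'   \item{`noreplica`}{Sequential block fill: pool `i` holds patients
#'     `(i-1)m+1 .. min(im, n)`. No replication; every mutation found in a
#'     pool must be assigned to a patient by Sanger testing.}
#'   \item{`optreplica`}{Every patient enters two distinct pools of one
#'     interleaved pool list, pre-sized to `2*ceiling(n/m)` pools: the first
#'     pool that is not yet completely filled, and the first pool with the
#'     smallest number of allocated patients that shares no patient with the
#'     former (keeping any two pools' overlap at most one, so pool-level
#'     results decode uniquely). A further pool is appended only when that
#'     choice is impossible (always for `m = 1`, a degenerate design that
#'     doubles the pool count and triggers a warning).}
#'   \item{`transposition`}{Main pool of patient `k` is `ceiling(k/m)`;
#'     its replica (control) pool is `((k-1) mod p_m) + 1` with
#'     `p_m = ceiling(n/m)` — the transposed-matrix pattern. Applicable only
#'     when `p_m >= m`, which guarantees that a main and a control pool
#'     share at most one patient.}
#'   \item{`diagwalks`}{Main pools as in `noreplica`; control pools built by
#'     a diagonal walk over the main-pool matrix (see
#'     [build_main_matrix()]), designed so that the first control pools
#'     complete early and sequencing can start long before the whole cohort
#'     has arrived, at the price of a few ambiguity groups that must be
#'     resolved by Sanger tests.}
#' }
#'
#' @param algorithm One of `"noreplica"`, `"optreplica"`, `"transposition"`,
#'   `"diagwalks"`.
#' @param n Cohort size.
#' @param m Pool size to use, `1 <= m <= n`.
#' @return An object of class `pooling_design`.
#' @examples
#' allocate("diagwalks", 15, 3)
#' @export
allocate <- function(algorithm = c("noreplica", "optreplica",
                                   "transposition", "diagwalks"), n, m) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         noreplica = allocate_noreplica(n, m),
         optreplica = allocate_optreplica(n, m),
         transposition = allocate_transposition(n, m),
         diagwalks = allocate_diagwalks(n, m))
}

#' @rdname allocate
#' @export
allocate_noreplica <- function(n, m) {
  a <- check_nm(n, m)
  main <- unname(split(seq_len(a$n), ceiling(seq_len(a$n) / a$m)))
  new_pooling_design("noreplica", a$m, a$n, main)
}

#' @rdname allocate
#' @export
allocate_optreplica <- function(n, m) {
  a <- check_nm(n, m)
  if (a$m == 1 && a$n > 1)
    warning("optreplica with pool size 1 is degenerate: ",
            "two distinct singleton pools per patient", call. = FALSE)
  pools <- cpp_optreplica_pools(a$n, a$m)
  new_pooling_design("optreplica", a$m, a$n, pools, interleaved = TRUE)
}

#' @rdname allocate
#' @export
allocate_transposition <- function(n, m) {
  a <- check_nm(n, m)
  p_m <- ceiling(a$n / a$m)
  if (p_m < a$m)
    stop("transposition inapplicable: number of main pools (", p_m,
         ") is smaller than the pool size (", a$m, ")", call. = FALSE)
  k <- seq_len(a$n)
  main <- unname(split(k, ceiling(k / a$m)))
  control <- unname(split(k, ((k - 1L) %% p_m) + 1L))
  new_pooling_design("transposition", a$m, a$n, main, control)
}

#' @rdname allocate
#' @export
allocate_diagwalks <- function(n, m) {
  a <- check_nm(n, m)
  k <- seq_len(a$n)
  main <- unname(split(k, ceiling(k / a$m)))
  control <- cpp_diagwalks_controls(a$n, a$m)
  new_pooling_design("diagwalks", a$m, a$n, main, control)
}

#' Algorithms supported by the planner
#' @return Character vector of the four algorithm names.
#' @export
planner_algorithms <- function() {
  c("noreplica", "optreplica", "transposition", "diagwalks")
}

#' Is an algorithm applicable at a given pool size?
#'
#' Transposition requires at least as many main pools as the pool size
#' (`ceiling(n/m) >= m`); the other three algorithms are applicable for any
#' `1 <= m <= n`.
#'
#' @inheritParams allocate
#' @return `TRUE` or `FALSE`.
#' @export
algorithm_applicable <- function(algorithm, n, m) {
  algorithm <- match.arg(algorithm, planner_algorithms())
  if (m < 1 || m > n) return(FALSE)
  if (algorithm == "transposition") ceiling(n / m) >= m else TRUE
}
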