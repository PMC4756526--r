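# Shared fixtures and independent oracles for the test suite. The oracles
# consume only the public design structure (lists of patient-index vectors)
# so they stay independent of the package's internal signature machinery.

case_study_1 <- function() design_parameters(64, 6, 5, 1000, 8)
case_study_2 <- function() design_parameters(128, 8, 7, 1000, 10)
case_study_3 <- function() design_parameters(2000, 20, 20, 1000, 8)

pools_of <- function(design) c(design$main_pools, design$control_pools)

# brute-force maximum pairwise overlap between pools
oracle_max_overlap <- function(design) {
  pools <- pools_of(design)
  mo <- 0L
  for (i in seq_along(pools))
    for (j in seq_len(i - 1L))
      mo <- max(mo, length(intersect(pools[[i]], pools[[j]])))
  mo
}

# brute-force membership counts per patient
oracle_membership_counts <- function(design) {
  tab <- table(factor(unlist(pools_of(design)),
                      levels = seq_len(design$n_patients)))
  as.integer(tab)
}

# brute-force signature partition: group patients by their exact pool set
oracle_signature_partition <- function(design) {
  pools <- pools_of(design)
  sig <- lapply(seq_len(design$n_patients), function(k)
    which(vapply(pools, function(p) k %in% p, logical(1))))
  key <- vapply(sig, paste, character(1), collapse = "-")
  grp <- unname(split(seq_len(design$n_patients), key))
  grp[order(vapply(grp, min, 0L))]
}

# set-wise design equality (pool member order is not semantic)
expect_same_pools <- function(a, b) {
  norm <- function(pl) lapply(pl, sort)
  expect_equal(norm(a$main_pools), norm(b$main_pools))
  expect_equal(norm(a$control_pools), norm(b$control_pools))
}
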