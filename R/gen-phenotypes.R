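#' Generate per-animal phenotype values from group-level specifications
#'
#' Draws i.i.d. normal values within each trait x group cell, matching the
#' normality premise under which two-group trait comparisons are made.
#' With `sd = 0` every animal gets the group mean exactly.
#'
#' @param trait_specs tibble with columns `trait`, `group`, `mean`, `sd`.
#' @param n_per_group animals per group (the target design uses 10).
#' @param seed integer seed.
#' @return tibble with columns `trait`, `group`, `animal_id`, `value`.
#' @export
gen_phenotypes <- function(trait_specs, n_per_group = 10L, seed = 1L) {
  req <- c("trait", "group", "mean", "sd")
  if (!all(req %in% names(trait_specs)))
    stop("trait_specs must have columns: ", paste(req, collapse = ", "))
  if (any(trait_specs$sd < 0)) stop("sd must be >= 0")
  withr::local_seed(derive_seed(seed, "phenotypes"))
  out <- lapply(seq_len(nrow(trait_specs)), function(i) {
    s <- trait_specs[i, ]
    tibble::tibble(
      trait = s$trait, group = s$group,
      animal_id = sprintf("%s_%02d", s$group, seq_len(n_per_group)),
      value = rnorm(n_per_group, s$mean, s$sd))
  })
  dplyr::bind_rows(out)
}

#' Trait specifications matching the packaged growth/beef-quality summaries
#'
#' Converts the packaged trait-summary fixture (group means and standard
#' errors at n = 10) into per-group normal specifications with
#' `sd = se * sqrt(n)`, for use with [gen_phenotypes()].
#'
#' @param traits optional character vector restricting the traits returned.
#' @return tibble with columns `trait`, `group`, `mean`, `sd`.
#' @export
table1_trait_specs <- function(traits = NULL) {
  t1 <- load_fixture("table1")
  if (!is.null(traits)) t1 <- t1[t1$trait %in% traits, ]
  tibble::tibble(trait = t1$trait, group = t1$group, mean = t1$mean,
                 sd = t1$se * sqrt(t1$n))
}
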