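#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gated ensemble into its member table
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return One row per committee member: algorithm, repetition, held-out
#'   AUC and TSS, MSS threshold, inclusion flag, combination weight.
#' @export
tidy.ensemble_model <- function(x, ...) {
  tibble::tibble(
    algorithm = vapply(x$members, `[[`, character(1), "algorithm"),
    repetition = vapply(x$members, `[[`, integer(1), "repetition"),
    heldout_auc = vapply(x$members, `[[`, numeric(1), "heldout_auc"),
    heldout_tss = vapply(x$members, `[[`, numeric(1), "heldout_tss"),
    mss = vapply(x$members, `[[`, numeric(1), "mss"),
    converged = vapply(x$members, `[[`, logical(1), "converged"),
    included = vapply(x$members, `[[`, logical(1), "included"),
    weight = x$weights
  )
}

#' One-row summary of a gated ensemble
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return A one-row tibble: member counts and mean held-out scores of the
#'   included members.
#' @export
glance.ensemble_model <- function(x, ...) {
  td <- tidy(x)
  inc <- td[td$included, ]
  tibble::tibble(
    n_members = nrow(td), n_included = nrow(inc),
    mean_auc = mean(inc$heldout_auc), mean_tss = mean(inc$heldout_tss),
    tss_gate = x$tss_gate, auc_gate = x$auc_gate
  )
}
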