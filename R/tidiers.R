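# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-abundance fit
#'
#' @param x A `smdiv_diff` object.
#' @param ... Unused.
#' @return The per-OTU test tibble (`otu_id`, `factor`, `lrt`, `p_boot`,
#'   `p_adj`, `converged`).
#' @method tidy smdiv_diff
#' @export
tidy.smdiv_diff <- function(x, ...) x$per_otu

#' One-row-per-factor summary of a differential-abundance fit
#'
#' @param x A `smdiv_diff` object.
#' @param ... Unused.
#' @return Tibble with `factor`, `stat` (summed LRT), `p_boot`, `n_otu`,
#'   `n_otu_excluded`, `n_boot`.
#' @method glance smdiv_diff
#' @export
glance.smdiv_diff <- function(x, ...) {
  dplyr::mutate(x$multivariate, n_otu = x$n_otu,
                n_otu_excluded = x$n_otu_excluded, n_boot = x$n_boot)
}

#' Tidy an NMDS ordination
#'
#' @param x A `smdiv_nmds` object.
#' @param ... Unused.
#' @return The coordinates tibble (`sample`, `NMDS1`, ...).
#' @method tidy smdiv_nmds
#' @export
tidy.smdiv_nmds <- function(x, ...) x$coordinates

#' One-row summary of an NMDS ordination
#'
#' @param x A `smdiv_nmds` object.
#' @param ... Unused.
#' @return Tibble with `k`, `stress`, `shepard_r`, `converged`.
#' @method glance smdiv_nmds
#' @export
glance.smdiv_nmds <- function(x, ...) {
  tibble(k = x$k, stress = x$stress, shepard_r = x$shepard_r,
         converged = x$converged)
}
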